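#' Nitrogen-oxide pathway profile of a genome
#'
#' Maps a genome's called enzyme complement onto the five nitrogen-oxide
#' reduction steps (NO3->NO2, NO2->NH3, NO2->NO, NO->N2O, N2O->N2), tagging
#' every enzyme with its mode (respiratory or assimilatory), and collects
#' nitrate/nitrite transporters (NarK) separately.
#'
#' @param presence_row named copy-number vector over catalog entries.
#' @param catalog a `gutresp_catalog` whose entries carry `pathway_step`
#'   tags.
#' @param genome_id id stored in the profile.
#' @return object of class `gutresp_profile`: `genome_id`, `steps` (named
#'   list over the five steps, each a data.frame `enzyme`, `mode`),
#'   `transporters` (character).
#' @export
pathway_profile <- function(presence_row, catalog, genome_id = NA_character_) {
  present <- names(presence_row)[presence_row > 0]
  steps <- stats::setNames(vector("list", length(pathway_steps)),
                           pathway_steps)
  for (s in pathway_steps) {
    hit <- present[vapply(catalog[present], function(e)
      identical(e$pathway_step, s), NA)]
    steps[[s]] <- data.frame(
      enzyme = hit,
      mode = vapply(catalog[hit], function(e)
        if (identical(e$mode, "assimilatory")) "assimilatory" else
          "respiratory", ""),
      stringsAsFactors = FALSE)
  }
  transporters <- present[vapply(catalog[present], function(e)
    identical(e$pathway_step, "transporter"), NA)]
  structure(list(genome_id = genome_id, steps = steps,
                 transporters = transporters),
            class = "gutresp_profile")
}

#' @export
print.gutresp_profile <- function(x, ...) {
  cat("Nitrogen-oxide profile for", x$genome_id, "\n")
  for (s in names(x$steps)) {
    df <- x$steps[[s]]
    if (nrow(df)) {
      cat(sprintf("  %-10s %s\n", s,
                  paste0(df$enzyme, " (", df$mode, ")", collapse = ", ")))
    }
  }
  if (length(x$transporters)) {
    cat("  transporters:", paste(x$transporters, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Profiles for every genome of a presence matrix
#'
#' @param presence genome-by-reductase matrix.
#' @param catalog a `gutresp_catalog`.
#' @return named list of `gutresp_profile` objects.
#' @export
pathway_profiles <- function(presence, catalog) {
  gids <- rownames(presence)
  stats::setNames(lapply(gids, function(g)
    pathway_profile(presence[g, ], catalog, g)), gids)
}

step_present <- function(profile, step, modes = c("respiratory",
                                                  "assimilatory")) {
  df <- profile$steps[[step]]
  any(df$mode %in% modes)
}

#' Classify the completeness of a genome's nitrogen-oxide reduction routes
#'
#' Ammonification requires the NO3->NO2 and NO2->NH3 steps; denitrification
#' requires NO3->NO2, NO2->NO, NO->N2O and N2O->N2. A profile covering all
#' steps of a route is complete for it (denitrification is checked first,
#' being the longer route); one covering some but not all steps of either
#' route is partial; an empty profile is "none". Only respiratory enzymes
#' count toward route completion by default.
#'
#' @param profile a `gutresp_profile`.
#' @param modes enzyme modes that satisfy a step (default respiratory only).
#' @return list: `class` ("complete_ammonification",
#'   "complete_denitrification", "partial", "none") and `missing` (named
#'   list of missing steps per route, empty for complete routes).
#' @export
classify_pathway <- function(profile, modes = "respiratory") {
  amm <- c("NO3_to_NO2", "NO2_to_NH3")
  den <- c("NO3_to_NO2", "NO2_to_NO", "NO_to_N2O", "N2O_to_N2")
  have <- pathway_steps[vapply(pathway_steps, function(s)
    step_present(profile, s, modes), NA)]
  miss_amm <- setdiff(amm, have)
  miss_den <- setdiff(den, have)
  cls <- if (length(have) == 0L) {
    "none"
  } else if (length(miss_den) == 0L) {
    "complete_denitrification"
  } else if (length(miss_amm) == 0L) {
    "complete_ammonification"
  } else {
    "partial"
  }
  list(class = cls,
       missing = list(ammonification = miss_amm, denitrification = miss_den))
}

# metabolite -> producing / consuming steps
exchange_metabolites <- function(include_n2o = FALSE) {
  m <- list(
    nitrite = list(produced_by = "NO3_to_NO2",
                   consumed_by = c("NO2_to_NH3", "NO2_to_NO")),
    nitric_oxide = list(produced_by = "NO2_to_NO",
                        consumed_by = "NO_to_N2O")
  )
  if (include_n2o) {
    m$nitrous_oxide <- list(produced_by = "NO_to_N2O",
                            consumed_by = "N2O_to_N2")
  }
  m
}

#' Infer the inter-genome nitrogen-oxide exchange network
#'
#' Proposes a directed exchange edge (producer, metabolite, consumer) when
#' the producer respires the step generating the metabolite while lacking
#' any enzyme (respiratory or assimilatory) for the steps consuming it, the
#' consumer respires a consuming step while lacking any enzyme for the
#' producing step, and both genomes are co-habitation eligible: by default
#' both microaerobic-capable or both anaerobic-class, since exchange
#' requires sharing a zone of the oxygen gradient. Assimilatory enzymes
#' block self-sufficiency but never make a genome a producer.
#'
#' @param profiles named list of `gutresp_profile` objects.
#' @param classes data.frame from [classify_panel()] covering the same
#'   genomes (`genome_id`, `class`, `has_microaerobic`).
#' @param eligibility which co-habitation groupings admit edges: any subset
#'   of `c("microaerobic", "anaerobic")` (default both).
#' @param include_n2o also propose nitrous-oxide edges (default FALSE).
#' @return data.frame `producer`, `metabolite`, `consumer`.
#' @export
infer_exchange_network <- function(profiles, classes,
                                   eligibility = c("microaerobic",
                                                   "anaerobic"),
                                   include_n2o = FALSE) {
  gids <- names(profiles)
  if (!setequal(gids, classes$genome_id)) {
    stop("profiles and classes cover different genome sets", call. = FALSE)
  }
  eligibility <- match.arg(eligibility, several.ok = TRUE)
  cls <- classes[match(gids, classes$genome_id), , drop = FALSE]
  micro_ok <- cls$has_microaerobic |
    cls$class %in% c("microaerophilic", "at_least_microaerophilic")
  anaer_ok <- cls$class %in% c("anaerobic", "most_likely_anaerobic")
  names(micro_ok) <- names(anaer_ok) <- gids

  mets <- exchange_metabolites(include_n2o)
  edges <- list()
  for (m in names(mets)) {
    prod_step <- mets[[m]]$produced_by
    cons_steps <- mets[[m]]$consumed_by
    producers <- gids[vapply(gids, function(g) {
      p <- profiles[[g]]
      step_present(p, prod_step, "respiratory") &&
        !any(vapply(cons_steps, function(s) step_present(p, s), NA))
    }, NA)]
    consumers <- gids[vapply(gids, function(g) {
      p <- profiles[[g]]
      any(vapply(cons_steps, function(s)
        step_present(p, s, "respiratory"), NA)) &&
        !step_present(p, prod_step)
    }, NA)]
    for (P in producers) {
      for (C in consumers) {
        if (P == C) next
        cohab <- ("microaerobic" %in% eligibility &&
                    micro_ok[P] && micro_ok[C]) ||
          ("anaerobic" %in% eligibility && anaer_ok[P] && anaer_ok[C])
        if (cohab) {
          edges[[length(edges) + 1L]] <- data.frame(
            producer = P, metabolite = m, consumer = C,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(edges)) do.call(rbind, edges) else
    data.frame(producer = character(0), metabolite = character(0),
               consumer = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
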