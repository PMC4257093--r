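#' Specification for a synthetic genome panel
#'
#' Describes the study conditions a generated panel emulates. The defaults
#' reproduce the gut reference-panel marginals used throughout the package's
#' regression tests: 254 genomes (55 finished, 149 probably complete, 50
#' incomplete), oxygen classes 25/92/87 among complete and 4/19/27 among
#' incomplete genomes, 27 strong microaerobes, the nitrogen-oxide pathway
#' mix (28 complete ammonification, 1 complete denitrification, 44 partial),
#' the metadata availability groups 98/136/5/15 with 56 and 122 consistent
#' rows, and the candidate cascade counts 187/42/75/7/3. Counts, not
#' probabilities, are specified, so realized marginals match exactly.
#'
#' @param seed RNG seed; the whole panel is a deterministic function of the
#'   spec.
#' @param n_finished,n_probably_complete,n_incomplete genome status mix.
#' @param classes_complete,classes_incomplete named counts (aerophilic,
#'   microaerophilic, anaerobic) within each completeness stratum.
#' @param strong_microaerobes complete microaerophilic genomes with no
#'   anaerobic reductase.
#' @param aerophilic_without_micro complete aerophilic genomes lacking
#'   microaerobic reductases.
#' @param pathway_mix named counts of nitrogen-oxide patterns among complete
#'   genomes: `ammonification`, `denitrification`, `nitrate_only`
#'   (nitrate reductase + NarK), `nitrite_ammonia_only` (Nrf only),
#'   `nitrate_to_no` (Nar + NirK), `nitrate_and_no_to_n2o` (Nar + Nor),
#'   `no_to_n2o_only` (Nor only).
#' @param label_groups named counts of label availability (both,
#'   metadata_only, assertion_only, none).
#' @param both_consistent_metadata,metadata_only_consistent consistent
#'   metadata rows within the first two groups.
#' @param cascade named counts for the candidate screen
#'   (keyword_families, families_with_hits, candidates, localization_pass,
#'   context_pass).
#' @param n_strains strains of the cascade-host species used by the
#'   co-occurrence filter.
#' @param amplified named integer vector of per-entry extra copy numbers
#'   planted in one genome (default `c(Dms = 12)`).
#' @param n_16s_tier drafts whose related finished genomes are found by 16S
#'   identity rather than shared taxon labels.
#' @return list of class `gutresp_panel_spec`.
#' @export
panel_spec <- function(seed = 1,
                       n_finished = 55, n_probably_complete = 149,
                       n_incomplete = 50,
                       classes_complete = c(aerophilic = 25,
                                            microaerophilic = 92,
                                            anaerobic = 87),
                       classes_incomplete = c(aerophilic = 4,
                                              microaerophilic = 19,
                                              anaerobic = 27),
                       strong_microaerobes = 27,
                       aerophilic_without_micro = 1,
                       pathway_mix = c(ammonification = 28,
                                       denitrification = 1,
                                       nitrate_only = 8,
                                       nitrite_ammonia_only = 29,
                                       nitrate_to_no = 1,
                                       nitrate_and_no_to_n2o = 3,
                                       no_to_n2o_only = 3),
                       label_groups = c(both = 98, metadata_only = 136,
                                        assertion_only = 5, none = 15),
                       both_consistent_metadata = 56,
                       metadata_only_consistent = 122,
                       cascade = c(keyword_families = 187,
                                   families_with_hits = 42,
                                   candidates = 75,
                                   localization_pass = 7,
                                   context_pass = 3),
                       n_strains = 5,
                       amplified = c(Dms = 12),
                       n_16s_tier = 5) {
  spec <- list(seed = seed, n_finished = n_finished,
               n_probably_complete = n_probably_complete,
               n_incomplete = n_incomplete,
               classes_complete = classes_complete,
               classes_incomplete = classes_incomplete,
               strong_microaerobes = strong_microaerobes,
               aerophilic_without_micro = aerophilic_without_micro,
               pathway_mix = pathway_mix, label_groups = label_groups,
               both_consistent_metadata = both_consistent_metadata,
               metadata_only_consistent = metadata_only_consistent,
               cascade = cascade, n_strains = n_strains,
               amplified = amplified, n_16s_tier = n_16s_tier)
  validate_panel_spec(spec)
  structure(spec, class = "gutresp_panel_spec")
}

validate_panel_spec <- function(s) {
  n_complete <- s$n_finished + s$n_probably_complete
  n <- n_complete + s$n_incomplete
  fail <- function(...) stop("infeasible panel spec: ", ..., call. = FALSE)
  if (sum(s$classes_complete) != n_complete) {
    fail("complete-genome class counts sum to ", sum(s$classes_complete),
         ", expected ", n_complete)
  }
  if (sum(s$classes_incomplete) != s$n_incomplete) {
    fail("incomplete-genome class counts sum to ",
         sum(s$classes_incomplete), ", expected ", s$n_incomplete)
  }
  if (s$strong_microaerobes > s$classes_complete[["microaerophilic"]]) {
    fail("more strong microaerobes than complete microaerophilic genomes")
  }
  if (s$aerophilic_without_micro > s$classes_complete[["aerophilic"]]) {
    fail("aerophilic_without_micro exceeds aerophilic count")
  }
  partial <- sum(s$pathway_mix) - s$pathway_mix[["ammonification"]] -
    s$pathway_mix[["denitrification"]]
  nonstrong <- s$classes_complete[["microaerophilic"]] -
    s$strong_microaerobes
  if (partial > nonstrong) {
    fail("partial-pathway genomes (", partial,
         ") exceed non-strong complete microaerophiles (", nonstrong, ")")
  }
  if (s$pathway_mix[["ammonification"]] + s$pathway_mix[["denitrification"]] +
      2L > s$classes_complete[["anaerobic"]]) {
    fail("anaerobic complete stratum too small for pathway + audit hosts")
  }
  if (sum(s$label_groups) != n) {
    fail("label availability groups sum to ", sum(s$label_groups),
         ", expected ", n)
  }
  if (s$both_consistent_metadata > s$label_groups[["both"]] ||
      s$metadata_only_consistent > s$label_groups[["metadata_only"]]) {
    fail("consistent label counts exceed their groups")
  }
  if (s$n_strains > 0L) {
    cc <- s$cascade
    if (!(cc[["context_pass"]] <= cc[["localization_pass"]] &&
          cc[["localization_pass"]] <= cc[["candidates"]] &&
          cc[["families_with_hits"]] <= cc[["keyword_families"]])) {
      fail("cascade counts must be monotone along the cascade")
    }
    if (cc[["context_pass"]] != 3L) {
      fail("the planted cascade host encodes exactly 3 context operons")
    }
    if (s$n_strains < 2L) fail("co-occurrence panel needs >= 2 strains")
    if (s$n_strains > s$strong_microaerobes) {
      fail("strains must fit inside the strong-microaerobe stratum")
    }
  }
  n_incons_both <- s$label_groups[["both"]] - s$both_consistent_metadata
  n_micro <- s$classes_complete[["microaerophilic"]] +
    s$classes_incomplete[["microaerophilic"]]
  if (n_incons_both > n_micro) {
    fail("both-group inconsistencies exceed microaerophilic genomes")
  }
  n_incons_meta <- s$label_groups[["metadata_only"]] -
    s$metadata_only_consistent
  n_anaer <- s$classes_complete[["anaerobic"]] +
    s$classes_incomplete[["anaerobic"]]
  if (n_incons_meta > n_anaer) {
    fail("metadata-only inconsistencies exceed anaerobic genomes")
  }
  invisible(s)
}

# ---- low-level panel builder ------------------------------------------

new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$genes <- list(); b$proteins <- list(); b$domains <- list()
  b$sims <- list(); b$cursor <- list(); b$counter <- list()
  b
}

bld_gene <- function(b, genome, families, signal = FALSE, tm = 0L,
                     compartment = "cytoplasmic", contig = "c1",
                     new_block = FALSE, len = 900L) {
  key <- paste(genome, contig, sep = "\r")
  cur <- b$cursor[[key]] %||% 0L
  gap <- if (new_block || cur == 0L) 1000L else 50L
  start <- cur + gap + 1L
  end <- start + len - 1L
  b$cursor[[key]] <- end
  cnt <- (b$counter[[genome]] %||% 0L) + 1L
  b$counter[[genome]] <- cnt
  gid <- sprintf("%s_g%04d", genome, cnt)
  pid <- paste0(gid, "_p")
  b$genes[[length(b$genes) + 1L]] <- data.frame(
    id = gid, genome_id = genome, contig = contig, start = start, end = end,
    strand = "+", protein_id = pid, stringsAsFactors = FALSE)
  b$proteins[[length(b$proteins) + 1L]] <- data.frame(
    id = pid, gene_id = gid, signal_peptide = signal,
    tm_segments = as.integer(tm), compartment = compartment,
    stringsAsFactors = FALSE)
  for (f in families) {
    b$domains[[length(b$domains) + 1L]] <- data.frame(
      protein_id = pid, family = f, stringsAsFactors = FALSE)
  }
  pid
}

bld_sim <- function(b, a, z, bits) {
  ev <- 10^(-bits / 5)
  b$sims[[length(b$sims) + 1L]] <- data.frame(
    query = c(a, z), subject = c(z, a), bitscore = bits, evalue = ev,
    stringsAsFactors = FALSE)
}

# role-dependent default localization of a planted subunit
role_loc <- function(role) {
  switch(role,
         membrane_anchor = list(signal = FALSE, tm = 4L,
                                compartment = "membrane"),
         list(signal = FALSE, tm = 0L, compartment = "cytoplasmic"))
}

# molybdopterin-superfamily entries: catalytic subunits also carry PF00384
molybdo_entries <- c("Nar", "Nap", "Dms", "Tor", "Ttr", "Phs", "Ynf",
                     "Arr", "NasBA")

ref_pid <- function(ref_ids, entry, copy, family) {
  ref_ids[[paste(entry, copy, family, sep = "\r")]]
}

# plant the reference blocks: one operon per entry copy, marker + subunits
plant_reference <- function(b, catalog, copies_needed, ref_genome = "REF") {
  ref_ids <- list()
  for (entry in catalog) {
    nm <- entry$name
    for (cp in seq_len(copies_needed[[nm]] %||% 1L)) {
      mfam <- sprintf("FAM_MARK_%s_%d", nm, cp)
      mk <- bld_gene(b, ref_genome, mfam, new_block = TRUE)
      ref_ids[[paste(nm, cp, "marker", sep = "\r")]] <- mk
      subs <- entry$subunits
      for (k in seq_len(nrow(subs))) {
        fams <- subs$family[k]
        if (subs$role[k] == "catalytic" && nm %in% molybdo_entries) {
          fams <- c(fams, "PF00384")
        }
        loc <- role_loc(subs$role[k])
        pid <- bld_gene(b, ref_genome, fams, signal = loc$signal,
                        tm = loc$tm, compartment = loc$compartment)
        ref_ids[[paste(nm, cp, subs$family[k], sep = "\r")]] <- pid
      }
    }
  }
  ref_ids
}

# plant one reductase instance in a panel genome; returns planted protein ids
plant_instance <- function(b, genome, entry, copy, ref_ids,
                           roles = NULL, loc_override = list(),
                           with_marker = TRUE, bits = 500, decoy = TRUE) {
  nm <- entry$name
  subs <- entry$subunits
  if (!is.null(roles)) subs <- subs[subs$role %in% roles, , drop = FALSE]
  pids <- character(0)
  if (with_marker) {
    mk <- bld_gene(b, genome, character(0), compartment = "unknown",
                   new_block = TRUE)
    bld_sim(b, mk, ref_ids[[paste(nm, copy, "marker", sep = "\r")]], 450)
    pids <- c(pids, marker = mk)
  }
  first <- !with_marker
  for (k in seq_len(nrow(subs))) {
    loc <- loc_override[[subs$role[k]]] %||% role_loc(subs$role[k])
    fams <- subs$family[k]
    if (subs$role[k] == "catalytic" && nm %in% molybdo_entries) {
      fams <- c(fams, "PF00384")
    }
    pid <- bld_gene(b, genome, fams, signal = loc$signal, tm = loc$tm,
                    compartment = loc$compartment, new_block = first)
    first <- FALSE
    rp <- ref_pid(ref_ids, nm, copy, subs$family[k])
    bld_sim(b, pid, rp, bits)
    if (decoy && subs$role[k] == "catalytic") {
      # lower-scoring off-target hit; must never win best-hit
      bld_sim(b, pid, ref_ids[[paste(nm, copy, "marker", sep = "\r")]], 350)
    }
    pids <- c(pids, stats::setNames(pid, subs$role[k]))
  }
  pids
}

# ---- the generator ----------------------------------------------------

#' Generate a synthetic genome panel with planted ground truth
#'
#' Builds a complete registry a scientist could have loaded from disk:
#' genomes with statuses, taxon labels and lengths calibrated to the
#' completeness marginals; genes laid out in operons; planted reductase
#' complements realizing the oxygen-class and pathway marginals; a
#' reference genome carrying the catalog reference proteins; a similarity
#' table with planted best-bidirectional-hit structure (ortholog scores
#' strictly above off-target noise, e-values monotone in bitscore); the
#' candidate-cascade host and its strain panel; an orphan accessory operon;
#' paralog- and soluble-variant audit fixtures; a 16S relatedness table;
#' and external lifestyle labels at the requested agreement rates.
#' `ground_truth` records every planted fact, sufficient to score every
#' downstream stage.
#'
#' @param spec a [panel_spec()].
#' @param catalog a `gutresp_catalog` (default: shipped catalog).
#' @return list of class `gutresp_panel`: `registry`, `similarity`,
#'   `catalog`, `relatedness`, `labels`, `keyword_families`, `spec`,
#'   `ground_truth`.
#' @export
generate_panel <- function(spec = panel_spec(), catalog = read_catalog()) {
  validate_panel_spec(spec)
  with_seed(spec$seed, generate_panel_impl(spec, catalog))
}

generate_panel_impl <- function(spec, catalog) {
  n_complete <- spec$n_finished + spec$n_probably_complete
  n <- n_complete + spec$n_incomplete
  ids <- sprintf("G%03d", seq_len(n))

  # ---- per-genome planted pattern, in block order over strata ----
  cc <- spec$classes_complete; ci <- spec$classes_incomplete
  pm <- spec$pathway_mix
  n_strong <- spec$strong_microaerobes
  n_nonstrong <- cc[["microaerophilic"]] - n_strong
  n_partial <- sum(pm) - pm[["ammonification"]] - pm[["denitrification"]]
  bact <- pm[["nitrite_ammonia_only"]]
  bact_patterns <- if (bact >= 2L) {
    c("bact_split", "bact_extracell", rep("bact", bact - 2L))
  } else rep("bact", bact)
  n_anaer_rest <- cc[["anaerobic"]] - pm[["ammonification"]] -
    pm[["denitrification"]] - 2L
  pattern <- c(
    # complete aerophilic
    rep("aero_nomicro", spec$aerophilic_without_micro),
    rep("aero", cc[["aerophilic"]] - spec$aerophilic_without_micro),
    # complete microaerophilic: strong first (strains lead)
    rep("strain", spec$n_strains),
    rep("strong", n_strong - spec$n_strains),
    rep("lacto", pm[["nitrate_only"]]),
    bact_patterns,
    rep("odonto", pm[["nitrate_to_no"]]),
    rep("veill", pm[["nitrate_and_no_to_n2o"]]),
    rep("nor_only", pm[["no_to_n2o_only"]]),
    rep("cyd_frd", n_nonstrong - n_partial),
    # complete anaerobic
    rep("amm", pm[["ammonification"]]),
    rep("denit", pm[["denitrification"]]),
    "orphan_host", "amplified",
    rep("frd_only", ceiling(n_anaer_rest / 2)),
    rep("none", floor(n_anaer_rest / 2)),
    # incomplete strata
    rep("aero_inc", ci[["aerophilic"]]),
    rep("micro_inc", ci[["microaerophilic"]]),
    rep("anaer_inc", ci[["anaerobic"]])
  )
  stopifnot(length(pattern) == n)

  planted_class <- vapply(seq_len(n), function(i) {
    p <- pattern[i]
    if (i <= n_complete) {
      if (p %in% c("aero", "aero_nomicro")) "aerophilic"
      else if (p %in% c("strain", "strong", "lacto", "bact", "bact_split",
                        "bact_extracell", "odonto", "veill", "nor_only",
                        "cyd_frd")) "microaerophilic"
      else "anaerobic"
    } else {
      switch(p, aero_inc = "aerophilic",
             micro_inc = "at_least_microaerophilic",
             "most_likely_anaerobic")
    }
  }, "")
  planted_strong <- planted_class == "microaerophilic" &
    pattern %in% c("strain", "strong")

  # ---- taxonomy, statuses, lengths (completeness calibration) ----
  status <- c(rep("finished", spec$n_finished),
              rep("draft", n - spec$n_finished))
  completeness_expected <- c(rep("complete", spec$n_finished),
                             rep("probably_complete",
                                 spec$n_probably_complete),
                             rep("incomplete", spec$n_incomplete))
  n_genera <- min(40L, spec$n_finished)
  genus <- character(n); species <- character(n)
  genus[seq_len(spec$n_finished)] <-
    sprintf("g%02d", ((seq_len(spec$n_finished) - 1L) %% n_genera) + 1L)
  species[seq_len(spec$n_finished)] <-
    sprintf("sp_f%03d", seq_len(spec$n_finished))
  # strains share one species (the cascade-host species) and are finished
  strain_idx <- which(pattern == "strain")
  stopifnot(all(strain_idx <= spec$n_finished))
  if (length(strain_idx)) {
    species[strain_idx] <- "sp_strainhost"
    genus[strain_idx] <- "g_strain"
  }
  # drafts draw only genera that still have finished, non-strain members
  good_genera <- unique(genus[setdiff(seq_len(spec$n_finished), strain_idx)])
  draft_idx <- (spec$n_finished + 1L):n
  genus[draft_idx] <- good_genera[((seq_along(draft_idx) - 1L) %%
                                     length(good_genera)) + 1L]
  species[draft_idx] <- sprintf("sp_d%03d", seq_along(draft_idx))
  # a few drafts share a species with a finished genome (species tier)
  sp_donor <- setdiff(seq_len(spec$n_finished), strain_idx)
  n_sp_tier <- min(3L, length(draft_idx), length(sp_donor))
  species[draft_idx[seq_len(n_sp_tier)]] <- species[sp_donor[seq_len(n_sp_tier)]]
  # 16S-tier drafts: genus with no finished member, related via identities
  n16 <- spec$n_16s_tier
  probably_idx <- (spec$n_finished + 1L):n_complete
  incomplete_idx <- if (spec$n_incomplete > 0) (n_complete + 1L):n else
    integer(0)
  s16_prob <- utils::tail(probably_idx, ceiling(n16 / 2))
  s16_inc <- utils::tail(incomplete_idx, floor(n16 / 2))
  s16 <- c(s16_prob, s16_inc)
  genus[s16] <- "g_orphantax"
  species[s16] <- sprintf("sp_16s%02d", seq_along(s16))

  length_bp <- numeric(n)
  length_bp[seq_len(spec$n_finished)] <-
    round(stats::runif(spec$n_finished, 2.5e6, 4.5e6))
  rel_rows <- list()
  fin_ids <- ids[status == "finished"]
  for (i in setdiff(draft_idx, s16)) {
    same_sp <- which(status == "finished" & species == species[i])
    rel <- if (length(same_sp)) same_sp else
      which(status == "finished" & genus == genus[i])
    minlen <- min(length_bp[rel])
    length_bp[i] <- if (completeness_expected[i] == "probably_complete") {
      round(minlen + stats::runif(1, 1e4, 4e5))
    } else {
      round(minlen - stats::runif(1, 2e5, 8e5))
    }
  }
  for (i in s16) {
    target <- fin_ids[1L + (match(i, s16) - 1L) %% length(fin_ids)]
    other <- fin_ids[which(fin_ids != target)[1]]
    rel_rows[[length(rel_rows) + 1L]] <- data.frame(
      genome_a = ids[i], genome_b = c(target, other),
      identity = c(0.97, 0.90), stringsAsFactors = FALSE)
    minlen <- length_bp[match(target, ids)]
    length_bp[i] <- if (completeness_expected[i] == "probably_complete") {
      round(minlen + stats::runif(1, 1e4, 4e5))
    } else {
      round(minlen - stats::runif(1, 2e5, 8e5))
    }
  }
  relatedness <- if (length(rel_rows)) do.call(rbind, rel_rows) else
    data.frame(genome_a = character(0), genome_b = character(0),
               identity = numeric(0), stringsAsFactors = FALSE)

  genomes <- data.frame(
    id = c(ids, "REF"),
    taxon = c(paste(genus, species), "gref sp_ref"),
    species = c(species, "sp_ref"),
    genus = c(genus, "gref"),
    status = c(status, "finished"),
    length_bp = c(length_bp, 4e6),
    stringsAsFactors = FALSE)

  # ---- genes, domains, similarity ----
  b <- new_builder()
  copies_needed <- stats::setNames(rep(1L, length(catalog)), names(catalog))
  for (nm in names(spec$amplified)) {
    copies_needed[nm] <- max(copies_needed[nm], spec$amplified[[nm]])
  }
  copies_needed["Nrf"] <- max(copies_needed["Nrf"], 2L)
  ref_ids <- plant_reference(b, catalog, as.list(copies_needed))

  plant <- function(genome, entry_name, copy = 1L, ...) {
    plant_instance(b, genome, catalog[[entry_name]], copy, ref_ids, ...)
  }
  presence_truth <- matrix(0L, nrow = n, ncol = length(catalog),
                           dimnames = list(ids, names(catalog)))
  mark <- function(gid, entry, k = 1L) {
    presence_truth[gid, entry] <<- presence_truth[gid, entry] + as.integer(k)
  }

  audit_truth <- list()
  for (i in seq_len(n)) {
    gid <- ids[i]
    # two filler genes open every genome
    bld_gene(b, gid, character(0), compartment = "unknown", new_block = TRUE)
    bld_gene(b, gid, character(0), compartment = "unknown")
    p <- pattern[i]
    if (p %in% c("aero", "aero_inc")) {
      plant(gid, "Cta"); mark(gid, "Cta")
      plant(gid, "Cyd"); mark(gid, "Cyd")
    } else if (p == "aero_nomicro") {
      plant(gid, "Cta"); mark(gid, "Cta")
    } else if (p %in% c("strong", "micro_inc")) {
      plant(gid, "Cyd"); mark(gid, "Cyd")
    } else if (p == "cyd_frd") {
      plant(gid, "Cyd"); mark(gid, "Cyd")
      plant(gid, "Frd"); mark(gid, "Frd")
    } else if (p == "lacto") {
      plant(gid, "Cyd"); mark(gid, "Cyd")
      plant(gid, "Nar"); mark(gid, "Nar")
      plant(gid, "NarK"); mark(gid, "NarK")
    } else if (p == "bact") {
      plant(gid, "Cyd"); mark(gid, "Cyd")
      plant(gid, "Nrf", loc_override = list(
        catalytic = list(signal = TRUE, tm = 0L,
                         compartment = "periplasmic")))
      mark(gid, "Nrf")
    } else if (p == "bact_split") {
      plant(gid, "Cyd"); mark(gid, "Cyd")
      # copy 1: full membrane-bound complex; copy 2: bare cytoplasmic copy
      plant(gid, "Nrf", copy = 1L, loc_override = list(
        catalytic = list(signal = TRUE, tm = 0L,
                         compartment = "periplasmic")))
      plant(gid, "Nrf", copy = 2L, roles = "catalytic")
      mark(gid, "Nrf", 2L)
      audit_truth$nrf_split_genome <- gid
    } else if (p == "bact_extracell") {
      plant(gid, "Cyd"); mark(gid, "Cyd")
      # catalytic subunit alone, exported: extracellular soluble variant
      plant(gid, "Nrf", roles = "catalytic", loc_override = list(
        catalytic = list(signal = TRUE, tm = 0L,
                         compartment = "extracellular")))
      mark(gid, "Nrf")
      audit_truth$nrf_extracell_genome <- gid
    } else if (p == "odonto") {
      plant(gid, "Cyd"); mark(gid, "Cyd")
      plant(gid, "Nar"); mark(gid, "Nar")
      plant(gid, "NirK"); mark(gid, "NirK")
    } else if (p == "veill") {
      plant(gid, "Cyd"); mark(gid, "Cyd")
      plant(gid, "Nar"); mark(gid, "Nar")
      plant(gid, "Nor"); mark(gid, "Nor")
    } else if (p == "nor_only") {
      plant(gid, "Cyd"); mark(gid, "Cyd")
      plant(gid, "Nor"); mark(gid, "Nor")
    } else if (p == "amm") {
      plant(gid, "Nar"); mark(gid, "Nar")
      plant(gid, "Nrf", loc_override = list(
        catalytic = list(signal = TRUE, tm = 0L,
                         compartment = "periplasmic")))
      mark(gid, "Nrf")
    } else if (p == "denit") {
      plant(gid, "Nar"); mark(gid, "Nar")
      plant(gid, "NirK"); mark(gid, "NirK")
      plant(gid, "Nor"); mark(gid, "Nor")
      plant(gid, "Nos"); mark(gid, "Nos")
    } else if (p == "orphan_host") {
      # accessory homologs of the nitrous-oxide-reductase operon, no NosZ,
      # plus a c-552/4-like cytochrome: the novel-thiosulfate-reductase
      # footprint
      bld_gene(b, gid, "FAM_NOSD", new_block = TRUE)
      bld_gene(b, gid, "FAM_NOSL")
      bld_gene(b, gid, "FAM_NOSY", tm = 4L, compartment = "membrane")
      cytc <- bld_gene(b, gid, "FAM_CYTC552", signal = TRUE,
                       compartment = "extracellular")
      audit_truth$orphan_genome <- gid
      audit_truth$orphan_candidate <- cytc
    } else if (p == "amplified") {
      n_amp <- spec$amplified[["Dms"]] %||% 0L
      for (cp in seq_len(n_amp)) plant(gid, "Dms", copy = cp)
      if (n_amp > 0) mark(gid, "Dms", n_amp)
      # TMAO reductase without membrane components: cytoplasmic soluble pair
      plant(gid, "Tor", roles = c("catalytic", "electron_transfer"))
      mark(gid, "Tor")
      plant(gid, "Frd"); mark(gid, "Frd")
      audit_truth$tor_soluble_genome <- gid
      audit_truth$amplified_genome <- gid
    } else if (p == "frd_only") {
      plant(gid, "Frd"); mark(gid, "Frd")
    }
    # "none", "anaer_inc": no reductase genes
  }

  # ---- cascade host, strains, co-occurrence operons ----
  strains <- ids[strain_idx]
  if (length(strains)) {
    kw <- c("PF01077", "FAM_CYFF", "KW_f003",
            sprintf("KW_f%03d",
                    seq_len(spec$cascade[["families_with_hits"]]))[-(1:3)],
            sprintf("KW_a%03d",
                    seq_len(spec$cascade[["keyword_families"]] -
                              spec$cascade[["families_with_hits"]])))
    cascade_truth <- plant_cascade(b, spec, catalog, ref_ids, strains, kw)
    presence_truth[strains, "Cyf"] <- 1L
  } else {
    kw <- character(0)
    cascade_truth <- NULL
  }

  genes <- do.call(rbind, b$genes)
  proteins <- do.call(rbind, b$proteins)
  domains <- do.call(rbind, b$domains)
  similarity <- read_similarity(do.call(rbind, b$sims))
  registry <- new_registry(genomes, genes, proteins, domains,
                           reference_genome = "REF")

  # ---- external lifestyle labels ----
  lab <- plant_labels(spec, ids, planted_class)

  truth <- list(
    genomes = data.frame(genome_id = ids, pattern = pattern,
                         class = planted_class, strong = planted_strong,
                         completeness = completeness_expected,
                         label_group = lab$group,
                         stringsAsFactors = FALSE),
    presence = presence_truth,
    cascade = cascade_truth,
    strains = strains,
    audit = audit_truth,
    counts = list(
      finished = spec$n_finished,
      probably_complete = spec$n_probably_complete,
      incomplete = spec$n_incomplete,
      classes_complete = spec$classes_complete,
      classes_incomplete = spec$classes_incomplete,
      strong_microaerobes = spec$strong_microaerobes,
      pathway = c(complete_ammonification = unname(spec$pathway_mix[["ammonification"]]),
                  complete_denitrification = unname(spec$pathway_mix[["denitrification"]]),
                  partial = unname(n_partial))
    )
  )
  structure(list(registry = registry, similarity = similarity,
                 catalog = catalog, relatedness = relatedness,
                 labels = lab$labels, keyword_families = kw,
                 spec = spec, ground_truth = truth),
            class = "gutresp_panel")
}

# cascade host: planted candidate/localization/context counts; strains get
# the shared operons, one strain lacks the third
plant_cascade <- function(b, spec, catalog, ref_ids, strains, kw) {
  host <- strains[1]
  cc <- spec$cascade
  op_prots <- list()
  for (s in strains) {
    # operon 1: the oxygen/thiol system (membrane FeS + AhpC/TSA partner);
    # doubles as the Cyf instance (context via the two subunit pairs)
    cyfB <- bld_gene(b, s, "PF01077", tm = 2L, compartment = "membrane",
                     new_block = TRUE)
    cyfA <- bld_gene(b, s, "PF00578", signal = TRUE,
                     compartment = "extracellular")
    bld_sim(b, cyfA, ref_pid(ref_ids, "Cyf", 1L, "PF00578"), 500)
    bld_sim(b, cyfB, ref_pid(ref_ids, "Cyf", 1L, "PF01077"), 500)
    # operon 2: extracellular flavin-binding component + partner
    cyfF <- bld_gene(b, s, "FAM_CYFF", tm = 1L, compartment = "membrane",
                     new_block = TRUE)
    cyfE <- bld_gene(b, s, "PF00578", signal = TRUE,
                     compartment = "extracellular")
    op_prots[[s]] <- list(op1 = c(cyfB, cyfA), op2 = c(cyfF, cyfE))
    # operon 3: present in all strains but the last
    if (s != strains[length(strains)]) {
      c3 <- bld_gene(b, s, "KW_f003", signal = TRUE,
                     compartment = "extracellular", new_block = TRUE)
      p3 <- bld_gene(b, s, "PF00578", compartment = "cytoplasmic")
      op_prots[[s]]$op3 <- c(c3, p3)
    }
  }
  # host <-> strain orthology for the shared operons
  for (s in strains[-1]) {
    for (op in intersect(names(op_prots[[host]]), names(op_prots[[s]]))) {
      for (k in seq_along(op_prots[[host]][[op]])) {
        bld_sim(b, op_prots[[host]][[op]][k], op_prots[[s]][[op]][k], 480)
      }
    }
  }
  # remaining candidates on the host: localization-pass but isolated, then
  # plain keyword hits with neither signal nor TM
  n_loc_only <- cc[["localization_pass"]] - cc[["context_pass"]]
  n_plain <- cc[["candidates"]] - cc[["localization_pass"]]
  hit_fams <- kw[seq_len(cc[["families_with_hits"]])]
  loc_only <- character(n_loc_only)
  for (j in seq_len(n_loc_only)) {
    loc_only[j] <- bld_gene(b, host, hit_fams[3L + j], signal = TRUE,
                            compartment = "extracellular", new_block = TRUE)
  }
  plain <- character(n_plain)
  remaining <- hit_fams[-seq_len(3L + n_loc_only)]
  for (j in seq_len(n_plain)) {
    fam <- remaining[1L + (j - 1L) %% length(remaining)]
    plain[j] <- bld_gene(b, host, fam, compartment = "unknown",
                         new_block = TRUE)
  }
  list(host = host,
       candidates = sort(c(op_prots[[host]]$op1[1], op_prots[[host]]$op2[1],
                           op_prots[[host]]$op3[1], loc_only, plain)),
       localization_pass = sort(c(op_prots[[host]]$op1[1],
                                  op_prots[[host]]$op2[1],
                                  op_prots[[host]]$op3[1], loc_only)),
       context_pass = sort(c(op_prots[[host]]$op1[1], op_prots[[host]]$op2[1],
                             op_prots[[host]]$op3[1])),
       cooccur_keep = c("op1", "op2"),
       op_prots = op_prots)
}

# availability groups and label rows at the planted agreement rates
plant_labels <- function(spec, ids, planted_class) {
  n <- length(ids)
  lg <- spec$label_groups
  n_incons_both <- lg[["both"]] - spec$both_consistent_metadata
  n_incons_meta <- lg[["metadata_only"]] - spec$metadata_only_consistent
  micro_ids <- ids[planted_class %in% c("microaerophilic",
                                        "at_least_microaerophilic")]
  anaer_ids <- ids[planted_class %in% c("anaerobic", "most_likely_anaerobic")]
  both_incons <- micro_ids[seq_len(n_incons_both)]
  meta_incons <- setdiff(anaer_ids, both_incons)[seq_len(n_incons_meta)]
  rest <- setdiff(ids, c(both_incons, meta_incons))
  both_cons <- rest[seq_len(spec$both_consistent_metadata)]
  rest <- setdiff(rest, both_cons)
  meta_cons <- rest[seq_len(spec$metadata_only_consistent)]
  rest <- setdiff(rest, meta_cons)
  assr_only <- rest[seq_len(lg[["assertion_only"]])]
  none <- setdiff(rest, assr_only)
  stopifnot(length(none) == lg[["none"]])

  group <- stats::setNames(rep("none", n), ids)
  group[c(both_incons, both_cons)] <- "both"
  group[c(meta_incons, meta_cons)] <- "metadata_only"
  group[assr_only] <- "assertion_only"

  consistent_label <- function(cl) {
    switch(cl,
           aerophilic = "aerobe",
           microaerophilic = ,
           at_least_microaerophilic = "microaerophile",
           "anaerobe")
  }
  cls <- stats::setNames(planted_class, ids)
  rows <- list()
  add <- function(gid, source, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      genome_id = gid, source = source, label = label,
      stringsAsFactors = FALSE)
  }
  for (g in c(both_cons, both_incons)) {
    meta <- if (g %in% both_incons) "anaerobe" else consistent_label(cls[[g]])
    add(g, "metadata", meta)
    add(g, "assertion", consistent_label(cls[[g]]))
  }
  for (g in c(meta_cons, meta_incons)) {
    meta <- if (g %in% meta_incons) "aerobe" else consistent_label(cls[[g]])
    add(g, "metadata", meta)
  }
  for (g in assr_only) add(g, "assertion", consistent_label(cls[[g]]))
  list(labels = do.call(rbind, rows), group = unname(group[ids]))
}
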