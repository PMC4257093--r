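#' Classify a genome's relation to oxygen from its reductase complement
#'
#' Finished / probably complete genomes: any aerobic-category reductase
#' makes the genome aerophilic; otherwise any microaerobic reductase makes
#' it microaerophilic (a strong microaerobe when no anaerobic reductase is
#' present either); otherwise it is anaerobic. Incomplete genomes can only
#' be bounded: an aerobic reductase still proves aerophilic, a microaerobic
#' one proves "at least microaerophilic", and an empty complement yields
#' "most likely anaerobic", because absence of a gene in an incomplete
#' assembly is not evidence of absence from the organism.
#'
#' @param presence_row named integer/logical vector over catalog entries
#'   (copy numbers; multiple copies count once here).
#' @param completeness one of "complete", "probably_complete",
#'   "incomplete"; "unset" is refused.
#' @param catalog a `gutresp_catalog`.
#' @return list with `value` (the class) and `strong_microaerobe` (logical).
#' @export
classify_oxygen <- function(presence_row, completeness, catalog) {
  if (is.na(completeness) || completeness == "unset") {
    stop("cannot classify a genome with unset completeness", call. = FALSE)
  }
  has <- function(cc) length(present_of_category(presence_row, catalog, cc)) > 0
  aero <- has("aerobic"); micro <- has("microaerobic"); anaer <- has("anaerobic")
  if (completeness %in% c("complete", "probably_complete")) {
    if (aero) {
      value <- "aerophilic"; strong <- FALSE
    } else if (micro) {
      value <- "microaerophilic"; strong <- !anaer
    } else {
      value <- "anaerobic"; strong <- FALSE
    }
  } else if (completeness == "incomplete") {
    if (aero) {
      value <- "aerophilic"; strong <- FALSE
    } else if (micro) {
      value <- "at_least_microaerophilic"; strong <- !anaer
    } else {
      value <- "most_likely_anaerobic"; strong <- FALSE
    }
  } else {
    stop("unknown completeness value: ", completeness, call. = FALSE)
  }
  list(value = value, strong_microaerobe = strong)
}

#' Classify every genome of a panel
#'
#' @param registry a `gutresp_registry` with completeness assessed.
#' @param presence genome-by-reductase matrix from [call_reductases()].
#' @param catalog a `gutresp_catalog`.
#' @return data.frame `genome_id`, `completeness`, `class`,
#'   `strong_microaerobe`, plus `has_aerobic` / `has_microaerobic` /
#'   `has_anaerobic` convenience flags.
#' @export
classify_panel <- function(registry, presence, catalog) {
  gids <- rownames(presence)
  cpl <- registry$genomes$completeness[match(gids, registry$genomes$id)]
  rows <- lapply(seq_along(gids), function(i) {
    cl <- classify_oxygen(presence[i, ], cpl[i], catalog)
    data.frame(
      genome_id = gids[i], completeness = cpl[i], class = cl$value,
      strong_microaerobe = cl$strong_microaerobe,
      has_aerobic = length(present_of_category(presence[i, ], catalog,
                                               "aerobic")) > 0,
      has_microaerobic = length(present_of_category(presence[i, ], catalog,
                                                    "microaerobic")) > 0,
      has_anaerobic = length(present_of_category(presence[i, ], catalog,
                                                 "anaerobic")) > 0,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Default mapping from external lifestyle labels to oxygen classes
#'
#' The controlled vocabulary and its mapping to predicted classes, shipped
#' as a configuration object: each class name maps to the set of external
#' labels considered consistent with it. Labels present in
#' `extra_vocabulary` are accepted on input but consistent with nothing
#' (they reconcile as inconsistent, with a warning).
#'
#' @return list with `mapping` (named list class -> labels) and
#'   `extra_vocabulary`.
#' @export
default_label_mapping <- function() {
  list(
    mapping = list(
      aerophilic = c("aerobe", "facultative"),
      microaerophilic = c("microaerophile", "facultative", "nanaerobe"),
      at_least_microaerophilic = c("microaerophile", "facultative",
                                   "nanaerobe"),
      anaerobic = c("anaerobe", "obligate anaerobe"),
      most_likely_anaerobic = c("anaerobe", "obligate anaerobe")
    ),
    extra_vocabulary = "aerotolerant"
  )
}

#' Reconcile a predicted class with one external label
#'
#' @param pred predicted oxygen class.
#' @param label external lifestyle label.
#' @param mapping label mapping (see [default_label_mapping()]).
#' @return "consistent" or "inconsistent". A label inside the vocabulary but
#'   mapped to no class (e.g. "aerotolerant") is inconsistent with a
#'   warning.
#' @export
reconcile_label <- function(pred, label, mapping = default_label_mapping()) {
  ok_labels <- mapping$mapping[[pred]]
  if (is.null(ok_labels)) stop("unknown predicted class: ", pred,
                               call. = FALSE)
  if (label %in% ok_labels) return("consistent")
  if (!label %in% unlist(mapping$mapping)) {
    warning("label '", label, "' maps to no oxygen class; ",
            "treated as inconsistent", call. = FALSE)
  }
  "inconsistent"
}

#' Consistency of predictions against external label sets
#'
#' Splits the panel into availability groups -- genomes with both metadata
#' and pathway-assertion labels, metadata only, assertion only, neither --
#' and reports consistent/inconsistent counts and percentages (one decimal,
#' half-up) per group and source, plus the pooled metadata consistency over
#' all genomes possessing metadata. Rows whose label falls outside the
#' controlled vocabulary are rejected and logged in `$rejected`.
#'
#' @param predictions data.frame `genome_id`, `class`
#'   (from [classify_panel()]).
#' @param labels data.frame `genome_id`, `source` ("metadata" or
#'   "assertion"), `label`.
#' @param mapping label mapping (see [default_label_mapping()]).
#' @param digits decimals for percentages (default 1).
#' @return object of class `gutresp_consistency`: per-group tallies,
#'   `pooled_metadata`, `group_sizes`, `rejected`.
#' @export
consistency_report <- function(predictions, labels,
                               mapping = default_label_mapping(),
                               digits = 1) {
  stopifnot(all(c("genome_id", "source", "label") %in% names(labels)))
  bad_src <- !labels$source %in% c("metadata", "assertion")
  if (any(bad_src)) {
    stop_listing("label rows with unknown source",
                 paste0("row ", which(bad_src)))
  }
  vocab <- unique(c(unlist(mapping$mapping), mapping$extra_vocabulary))
  rejected <- labels[!labels$label %in% vocab, , drop = FALSE]
  labels <- labels[labels$label %in% vocab, , drop = FALSE]

  gids <- predictions$genome_id
  has_meta <- gids %in% labels$genome_id[labels$source == "metadata"]
  has_assr <- gids %in% labels$genome_id[labels$source == "assertion"]
  group <- ifelse(has_meta & has_assr, "both",
                  ifelse(has_meta, "metadata_only",
                         ifelse(has_assr, "assertion_only", "none")))

  tally <- function(idx, source) {
    sub <- labels[labels$source == source &
                    labels$genome_id %in% gids[idx], , drop = FALSE]
    pred <- predictions$class[match(sub$genome_id, predictions$genome_id)]
    status <- suppressWarnings(
      mapply(reconcile_label, pred, sub$label,
             MoreArgs = list(mapping = mapping)))
    n <- length(status)
    cons <- sum(status == "consistent")
    list(n = n, consistent = cons, inconsistent = n - cons,
         pct_consistent = if (n > 0) percentage(cons, n, digits) else NA_real_)
  }

  groups <- list(
    both_metadata = tally(group == "both", "metadata"),
    both_assertion = tally(group == "both", "assertion"),
    metadata_only = tally(group == "metadata_only", "metadata"),
    assertion_only = tally(group == "assertion_only", "assertion")
  )
  meta_n <- groups$both_metadata$n + groups$metadata_only$n
  meta_cons <- groups$both_metadata$consistent + groups$metadata_only$consistent
  pooled <- list(
    n = meta_n, consistent = meta_cons,
    pct_consistent = if (meta_n > 0) percentage(meta_cons, meta_n, digits)
    else NA_real_,
    pct_inconsistent = if (meta_n > 0)
      percentage(meta_n - meta_cons, meta_n, digits) else NA_real_
  )
  structure(list(
    groups = groups,
    pooled_metadata = pooled,
    group_sizes = c(both = sum(group == "both"),
                    metadata_only = sum(group == "metadata_only"),
                    assertion_only = sum(group == "assertion_only"),
                    none = sum(group == "none")),
    rejected = rejected
  ), class = "gutresp_consistency")
}

#' @export
print.gutresp_consistency <- function(x, ...) {
  cat("Consistency against external labels\n")
  gs <- x$group_sizes
  cat(sprintf("  availability: both=%d metadata_only=%d assertion_only=%d none=%d\n",
              gs[["both"]], gs[["metadata_only"]], gs[["assertion_only"]],
              gs[["none"]]))
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    if (g$n > 0) {
      cat(sprintf("  %-15s %3d labels, %5.1f%% consistent\n", nm, g$n,
                  g$pct_consistent))
    }
  }
  if (x$pooled_metadata$n > 0) {
    cat(sprintf("  pooled metadata: %.1f%% consistent / %.1f%% inconsistent (n=%d)\n",
                x$pooled_metadata$pct_consistent,
                x$pooled_metadata$pct_inconsistent, x$pooled_metadata$n))
  }
  if (nrow(x$rejected)) {
    cat("  rejected rows (label outside vocabulary):", nrow(x$rejected), "\n")
  }
  invisible(x)
}
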