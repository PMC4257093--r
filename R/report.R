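#' Panel summary report
#'
#' Aggregates the pipeline's results for a genome panel: per-reductase
#' genome counts and percentages (denominator: all genomes of the presence
#' matrix; multiple copies in one genome count as one presence, copy
#' numbers are reported separately), oxygen-class counts, per-genome
#' reductase totals, specificity-assignment counts and pathway-class
#' counts. All percentages are rounded half-up at `digits` decimals.
#'
#' @param presence genome-by-reductase copy matrix.
#' @param classes optional data.frame from [classify_panel()].
#' @param assignments optional data.frame from [assign_specificities()].
#' @param profiles optional list from [pathway_profiles()].
#' @param digits decimals for percentages (default 1).
#' @return object of class `gutresp_summary`.
#' @export
summarize_panel <- function(presence, classes = NULL, assignments = NULL,
                            profiles = NULL, digits = 1) {
  n <- nrow(presence)
  present <- presence > 0
  reductase_counts <- data.frame(
    reductase = colnames(presence),
    n_genomes = colSums(present),
    pct = percentage(colSums(present), n, digits),
    max_copies = apply(presence, 2, max),
    stringsAsFactors = FALSE, row.names = NULL)
  per_genome <- data.frame(
    genome_id = rownames(presence),
    n_reductases = rowSums(presence),
    n_types = rowSums(present),
    stringsAsFactors = FALSE, row.names = NULL)
  class_counts <- NULL
  if (!is.null(classes)) {
    tab <- table(classes$class)
    class_counts <- data.frame(
      class = names(tab), n = as.integer(tab),
      pct = percentage(as.integer(tab), nrow(classes), digits),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  assignment_counts <- if (!is.null(assignments))
    summarize_assignments(assignments)$counts else NULL
  pathway_counts <- NULL
  if (!is.null(profiles)) {
    pc <- vapply(profiles, function(p) classify_pathway(p)$class, "")
    tabp <- table(factor(pc, levels = c("complete_ammonification",
                                        "complete_denitrification",
                                        "partial", "none")))
    pathway_counts <- data.frame(class = names(tabp),
                                 n = as.integer(tabp),
                                 stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(
    n_genomes = n,
    reductase_counts = reductase_counts,
    per_genome = per_genome,
    class_counts = class_counts,
    assignment_counts = assignment_counts,
    pathway_counts = pathway_counts,
    digits = digits
  ), class = "gutresp_summary")
}

#' @export
print.gutresp_summary <- function(x, ...) {
  cat("Panel summary:", x$n_genomes, "genomes\n")
  rc <- x$reductase_counts
  rc <- rc[rc$n_genomes > 0, , drop = FALSE]
  rc <- rc[order(-rc$n_genomes), , drop = FALSE]
  top <- utils::head(rc, 8)
  cat("  most common reductases:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-6s %4d genomes (%.1f%%)\n", top$reductase[i],
                top$n_genomes[i], top$pct[i]))
  }
  if (!is.null(x$class_counts)) {
    cat("  oxygen classes:\n")
    for (i in seq_len(nrow(x$class_counts))) {
      cat(sprintf("    %-26s %4d (%.1f%%)\n", x$class_counts$class[i],
                  x$class_counts$n[i], x$class_counts$pct[i]))
    }
  }
  if (!is.null(x$pathway_counts)) {
    cat("  nitrogen-oxide pathway classes:",
        paste(x$pathway_counts$class, x$pathway_counts$n, sep = "=",
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Write a summary report as JSON
#'
#' @param summary a `gutresp_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  out <- list(
    n_genomes = summary$n_genomes,
    reductase_counts = summary$reductase_counts,
    class_counts = summary$class_counts,
    assignment_counts = as.list(summary$assignment_counts),
    pathway_counts = summary$pathway_counts
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
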