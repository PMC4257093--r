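#' Write a generated panel to a fixture directory
#'
#' Serializes a synthetic panel in the on-disk formats the loader reads:
#' per-genome GFF3 annotation under `gff/`, `genomes.tsv`, `domains.tsv`,
#' `localization.tsv`, `similarity.tsv`, `relatedness.tsv`, `labels.tsv`, a
#' copy of the catalog YAML, and `ground_truth.json`.
#'
#' @param panel a `gutresp_panel` from [generate_panel()].
#' @param dir output directory (created if missing).
#' @param catalog_path catalog YAML to copy alongside (default: shipped).
#' @return `dir`, invisibly.
#' @export
write_panel_fixture <- function(panel, dir,
                                catalog_path = system.file(
                                  "extdata", "catalog.yaml",
                                  package = "gutresp")) {
  dir.create(file.path(dir, "gff"), recursive = TRUE, showWarnings = FALSE)
  reg <- panel$registry
  g <- reg$genomes
  g$reference <- g$id == (reg$reference_genome %||% "")
  utils::write.table(g, file.path(dir, "genomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (gid in g$id) {
    gg <- reg$genes[reg$genes$genome_id == gid, , drop = FALSE]
    write_gene_gff3(gg, file.path(dir, "gff", paste0(gid, ".gff3")))
  }
  utils::write.table(reg$domains, file.path(dir, "domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  loc <- reg$proteins[, c("id", "signal_peptide", "tm_segments",
                          "compartment")]
  names(loc)[1] <- "protein_id"
  utils::write.table(loc, file.path(dir, "localization.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$similarity, file.path(dir, "similarity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$relatedness, file.path(dir, "relatedness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(panel$keyword_families, file.path(dir, "keyword_families.txt"))
  file.copy(catalog_path, file.path(dir, "catalog.yaml"), overwrite = TRUE)
  truth <- panel$ground_truth
  truth$presence <- data.frame(genome_id = rownames(truth$presence),
                               truth$presence, check.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a panel fixture directory back into a registry
#'
#' Counterpart of [write_panel_fixture()]; exercises the same readers a
#' user would call on real data.
#'
#' @param dir fixture directory.
#' @return list: `registry`, `catalog`, `similarity`, `relatedness`,
#'   `labels`, `keyword_families`.
#' @export
read_panel_fixture <- function(dir) {
  gtab <- file.path(dir, "genomes.tsv")
  ids <- utils::read.delim(gtab, stringsAsFactors = FALSE)$id
  ann <- stats::setNames(file.path(dir, "gff", paste0(ids, ".gff3")), ids)
  loaded <- load_registry(gtab, ann, file.path(dir, "domains.tsv"),
                          file.path(dir, "localization.tsv"),
                          file.path(dir, "catalog.yaml"))
  loaded$similarity <- read_similarity(file.path(dir, "similarity.tsv"))
  loaded$relatedness <- utils::read.delim(file.path(dir, "relatedness.tsv"),
                                          stringsAsFactors = FALSE)
  loaded$labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                                     stringsAsFactors = FALSE)
  loaded$keyword_families <- readLines(file.path(dir,
                                                 "keyword_families.txt"))
  loaded
}

#' Write a family fixture (newick, aligned FASTA, context and known tables)
#'
#' @param fixture a `gutresp_family_fixture`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_family_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(fixture$tree, file.path(dir, "family.nwk"))
  con <- file(file.path(dir, "alignment.fasta"), "w")
  on.exit(close(con))
  for (p in rownames(fixture$alignment)) {
    writeLines(c(paste0(">", p),
                 paste(fixture$alignment[p, ], collapse = "")), con)
  }
  utils::write.table(
    data.frame(protein_id = names(fixture$known),
               specificity = unname(fixture$known)),
    file.path(dir, "known.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  ctx <- data.frame(
    protein_id = names(fixture$context),
    context = vapply(fixture$context, paste, "", collapse = ";"))
  utils::write.table(ctx, file.path(dir, "context.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fixture$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a family fixture directory
#'
#' @param dir directory written by [write_family_fixture()].
#' @return list: `tree`, `alignment`, `known`, `context`.
#' @export
read_family_fixture <- function(dir) {
  tree <- ape::read.tree(file.path(dir, "family.nwk"))
  bin <- ape::read.FASTA(file.path(dir, "alignment.fasta"), type = "AA")
  aln <- toupper(do.call(rbind, as.character(bin)))
  rownames(aln) <- names(bin)
  known_df <- utils::read.delim(file.path(dir, "known.tsv"),
                                stringsAsFactors = FALSE)
  known <- stats::setNames(known_df$specificity, known_df$protein_id)
  ctx_df <- utils::read.delim(file.path(dir, "context.tsv"),
                              stringsAsFactors = FALSE)
  context <- stats::setNames(strsplit(ctx_df$context, ";", fixed = TRUE),
                             ctx_df$protein_id)
  list(tree = tree, alignment = aln, known = known, context = context)
}
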