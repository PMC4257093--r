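#' Build a genome panel registry
#'
#' The registry is the package's central container: a cross-linked set of
#' genomes, genes, proteins, and protein-to-domain-family assignments for a
#' panel of (finished and draft) microbial genomes. All downstream stages --
#' completeness assessment, orthology, the filter cascade, classification --
#' read from it.
#'
#' Coordinates are 1-based inclusive throughout (GFF convention); no other
#' coordinate system is used anywhere in the package.
#'
#' @param genomes data.frame with columns `id`, `taxon`, `species`, `genus`,
#'   `status` ("finished" or "draft"), `length_bp`; optional `completeness`
#'   ("complete", "probably_complete", "incomplete", "unset").
#' @param genes data.frame with columns `id`, `genome_id`, `contig`, `start`,
#'   `end`, `strand` ("+"/"-"), `protein_id`.
#' @param proteins data.frame with columns `id`, `gene_id`, `signal_peptide`
#'   (logical), `tm_segments` (integer >= 0), `compartment` ("cytoplasmic",
#'   "membrane", "extracellular", "periplasmic", "unknown").
#' @param domains data.frame with columns `protein_id`, `family`; a protein
#'   may carry several families.
#' @param reference_genome id of the genome holding the catalog reference
#'   proteins (used by [call_reductases()]), or NULL.
#' @return object of class `gutresp_registry`.
#' @export
new_registry <- function(genomes, genes, proteins, domains,
                         reference_genome = NULL) {
  genomes <- as.data.frame(genomes, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  if (!"completeness" %in% names(genomes)) genomes$completeness <- "unset"
  errs <- character(0)
  add <- function(cond, msg, items = NULL) {
    if (cond) {
      errs <<- c(errs, if (is.null(items)) msg else
        paste0(msg, ": ", paste(utils::head(items, 8), collapse = ", ")))
    }
  }
  add(anyDuplicated(genomes$id) > 0, "duplicated genome ids",
      genomes$id[duplicated(genomes$id)])
  add(any(genomes$length_bp <= 0), "non-positive genome length",
      genomes$id[genomes$length_bp <= 0])
  add(!all(genomes$status %in% c("finished", "draft")),
      "genome status outside {finished, draft}",
      unique(genomes$status[!genomes$status %in% c("finished", "draft")]))
  add(anyDuplicated(genes$id) > 0, "duplicated gene ids",
      genes$id[duplicated(genes$id)])
  add(!all(genes$genome_id %in% genomes$id),
      "genes referencing unknown genomes",
      unique(genes$genome_id[!genes$genome_id %in% genomes$id]))
  add(any(genes$start > genes$end), "genes with start > end",
      genes$id[genes$start > genes$end])
  add(!all(genes$strand %in% c("+", "-")), "gene strand outside {+,-}",
      genes$id[!genes$strand %in% c("+", "-")])
  add(anyDuplicated(proteins$id) > 0, "duplicated protein ids",
      proteins$id[duplicated(proteins$id)])
  add(!all(genes$protein_id %in% proteins$id),
      "unresolvable gene->protein links",
      genes$id[!genes$protein_id %in% proteins$id])
  add(!all(proteins$gene_id %in% genes$id),
      "proteins referencing unknown genes",
      proteins$id[!proteins$gene_id %in% genes$id])
  add(any(proteins$tm_segments < 0), "negative tm_segments",
      proteins$id[proteins$tm_segments < 0])
  memb <- proteins$compartment == "membrane" & proteins$tm_segments < 1
  add(any(memb), "membrane proteins with no transmembrane segment",
      proteins$id[memb])
  add(!all(domains$protein_id %in% proteins$id),
      "domain rows referencing missing proteins",
      paste0("row ", which(!domains$protein_id %in% proteins$id),
             " (", domains$protein_id[!domains$protein_id %in% proteins$id],
             ")"))
  if (!is.null(reference_genome)) {
    add(!reference_genome %in% genomes$id,
        "reference_genome not in panel", reference_genome)
  }
  if (length(errs)) {
    stop("registry validation failed:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(genomes = genomes, genes = genes, proteins = proteins,
                 domains = domains, reference_genome = reference_genome),
            class = "gutresp_registry")
}

#' @export
print.gutresp_registry <- function(x, ...) {
  fin <- sum(x$genomes$status == "finished")
  cat("Genome panel registry\n")
  cat(sprintf("  genomes : %d (%d finished, %d draft)\n",
              nrow(x$genomes), fin, nrow(x$genomes) - fin))
  cat(sprintf("  genes   : %d   proteins: %d   domain assignments: %d\n",
              nrow(x$genes), nrow(x$proteins), nrow(x$domains)))
  if (!is.null(x$reference_genome)) {
    cat("  reference genome:", x$reference_genome, "\n")
  }
  cpl <- table(x$genomes$completeness)
  cat("  completeness:", paste(names(cpl), cpl, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

# protein id -> genome id lookup
protein_genome_map <- function(registry) {
  stats::setNames(
    registry$genes$genome_id[match(registry$proteins$gene_id,
                                   registry$genes$id)],
    registry$proteins$id)
}

# domain families of one protein
protein_families <- function(registry, protein_id) {
  registry$domains$family[registry$domains$protein_id == protein_id]
}

#' Load a registry from fixture files
#'
#' Reads a panel from on-disk files: one GFF3 gene-annotation file per genome
#' (gene features with `ID` and `protein_id` attributes), a genome metadata
#' table, a protein-to-domain table and a localization table, plus the
#' reductase catalog. Validation problems are aggregated and reported
#' together.
#'
#' @param genome_table TSV with columns `id`, `taxon`, `species`, `genus`,
#'   `status`, `length_bp` and optional `reference` (logical marking the
#'   catalog reference genome).
#' @param annotation_files named character vector of GFF3 paths, names are
#'   genome ids.
#' @param domain_table TSV with columns `protein_id`, `family`.
#' @param localization_table TSV with columns `protein_id`, `signal_peptide`,
#'   `tm_segments`, `compartment`.
#' @param catalog_config path to the catalog YAML (default: shipped catalog).
#' @return list with elements `registry` and `catalog`.
#' @export
load_registry <- function(genome_table, annotation_files, domain_table,
                          localization_table,
                          catalog_config = system.file(
                            "extdata", "catalog.yaml", package = "gutresp")) {
  genomes <- utils::read.delim(genome_table, stringsAsFactors = FALSE)
  ref <- NULL
  if ("reference" %in% names(genomes)) {
    ref_ids <- genomes$id[as.logical(genomes$reference)]
    if (length(ref_ids) > 1) {
      stop_listing("more than one reference genome flagged", ref_ids)
    }
    if (length(ref_ids) == 1) ref <- ref_ids
    genomes$reference <- NULL
  }
  gene_tabs <- lapply(names(annotation_files), function(gid) {
    g <- read_gene_gff3(annotation_files[[gid]])
    g$genome_id <- gid
    g
  })
  genes <- do.call(rbind, gene_tabs)
  domains <- utils::read.delim(domain_table, stringsAsFactors = FALSE)
  loc <- utils::read.delim(localization_table, stringsAsFactors = FALSE)
  loc$signal_peptide <- as.logical(loc$signal_peptide)
  proteins <- data.frame(
    id = genes$protein_id,
    gene_id = genes$id,
    stringsAsFactors = FALSE
  )
  m <- match(proteins$id, loc$protein_id)
  if (anyNA(m)) {
    stop_listing("localization table missing proteins", proteins$id[is.na(m)])
  }
  proteins$signal_peptide <- loc$signal_peptide[m]
  proteins$tm_segments <- as.integer(loc$tm_segments[m])
  proteins$compartment <- loc$compartment[m]
  registry <- new_registry(genomes, genes, proteins, domains,
                           reference_genome = ref)
  list(registry = registry, catalog = read_catalog(catalog_config))
}
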