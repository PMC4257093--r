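#' Predict operons from gene coordinates
#'
#' Structural operon proxy: maximal runs of same-strand genes on one contig
#' whose intergenic gaps do not exceed `max_gap_bp`. Genes are ordered by
#' start coordinate within each contig.
#'
#' @param registry a `gutresp_registry`.
#' @param genome_id genome to segment.
#' @param max_gap_bp maximum intergenic distance within an operon (default
#'   300 bp).
#' @return data.frame with one row per gene: `operon_id`, `genome_id`,
#'   `contig`, `strand`, `gene_id`, `protein_id`, `idx` (position within the
#'   operon).
#' @export
predict_operons <- function(registry, genome_id, max_gap_bp = 300) {
  g <- registry$genes[registry$genes$genome_id == genome_id, , drop = FALSE]
  out <- list()
  n_op <- 0L
  for (ctg in sort(unique(g$contig))) {
    gc <- g[g$contig == ctg, , drop = FALSE]
    gc <- gc[order(gc$start), , drop = FALSE]
    nb <- nrow(gc)
    newblock <- c(TRUE, if (nb > 1)
      gc$strand[-1] != gc$strand[-nb] |
        (gc$start[-1] - gc$end[-nb] - 1L) > max_gap_bp)
    block <- cumsum(newblock)
    for (b in unique(block)) {
      n_op <- n_op + 1L
      rows <- gc[block == b, , drop = FALSE]
      out[[n_op]] <- data.frame(
        operon_id = sprintf("%s_op%03d", genome_id, n_op),
        genome_id = genome_id,
        contig = ctg,
        strand = rows$strand[1],
        gene_id = rows$id,
        protein_id = rows$protein_id,
        idx = seq_len(nrow(rows)),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(operon_id = character(0), genome_id = character(0),
               contig = character(0), strand = character(0),
               gene_id = character(0), protein_id = character(0),
               idx = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Candidate-reductase filter cascade
#'
#' The three-stage screen used to predict a novel flavin- and thiol-
#' dependent microaerobic reductase in a single genome: (1) proteins whose
#' domain families intersect a user-supplied keyword family set (families
#' capable of binding flavins or interacting with flavin-binding proteins),
#' (2) of those, proteins with a signal peptide and/or at least one
#' transmembrane segment (extracellular or membrane localization), (3) of
#' those, proteins whose predicted operon also contains a partner protein
#' satisfying `partner_predicate` (by default, membership in the AhpC/TSA
#' oxygen/thiol-binding family). The returned trace records every stage's
#' membership; each stage is a subset of the one before.
#'
#' @param registry a `gutresp_registry`.
#' @param genome_id the genome to screen.
#' @param keyword_families character vector of family accessions (stage 1).
#' @param partner_predicate either a character vector of family accessions
#'   (a partner is any operon member carrying one of them) or a function
#'   `(protein_id, registry) -> logical`. Default: the AhpC/TSA family
#'   accession "PF00578".
#' @param max_gap_bp operon gap rule passed to [predict_operons()].
#' @return object of class `gutresp_cascade`: list with the per-stage sets
#'   `families_keyword_matched`, `families_with_genome_hits`,
#'   `candidate_proteins`, `localization_passed`, `context_passed`, and
#'   `counts`.
#' @export
run_cascade <- function(registry, genome_id, keyword_families,
                        partner_predicate = "PF00578", max_gap_bp = 300) {
  keyword_families <- unique(keyword_families)
  prots <- registry$proteins
  pg <- protein_genome_map(registry)
  mine <- prots[prots$id %in% names(pg)[pg == genome_id], , drop = FALSE]
  dom <- registry$domains[registry$domains$protein_id %in% mine$id, ,
                          drop = FALSE]
  hit_dom <- dom[dom$family %in% keyword_families, , drop = FALSE]
  fam_hits <- sort(unique(hit_dom$family))
  candidates <- sort(unique(hit_dom$protein_id))

  li <- mine[match(candidates, mine$id), , drop = FALSE]
  loc_pass <- candidates[li$signal_peptide | li$tm_segments >= 1]

  ops <- predict_operons(registry, genome_id, max_gap_bp)
  is_partner <- if (is.function(partner_predicate)) {
    function(pid) partner_predicate(pid, registry)
  } else {
    partner_set <- partner_predicate
    function(pid) any(dom$family[dom$protein_id == pid] %in% partner_set)
  }
  ctx_pass <- loc_pass[vapply(loc_pass, function(pid) {
    op <- ops$operon_id[ops$protein_id == pid]
    if (!length(op)) return(FALSE)
    mates <- setdiff(ops$protein_id[ops$operon_id == op[1]], pid)
    any(vapply(mates, is_partner, NA))
  }, NA)]

  structure(list(
    genome_id = genome_id,
    families_keyword_matched = sort(keyword_families),
    families_with_genome_hits = fam_hits,
    candidate_proteins = candidates,
    localization_passed = sort(loc_pass),
    context_passed = sort(ctx_pass),
    counts = c(keyword_families = length(keyword_families),
               families_with_hits = length(fam_hits),
               candidates = length(candidates),
               localization = length(loc_pass),
               context = length(ctx_pass))
  ), class = "gutresp_cascade")
}

#' @export
print.gutresp_cascade <- function(x, ...) {
  cat("Candidate-reductase cascade for", x$genome_id, "\n")
  cat(sprintf("  keyword families: %d, with hits: %d\n",
              x$counts[["keyword_families"]],
              x$counts[["families_with_hits"]]))
  cat(sprintf("  candidates %d -> localization %d -> context %d\n",
              x$counts[["candidates"]], x$counts[["localization"]],
              x$counts[["context"]]))
  invisible(x)
}

#' Cross-strain co-occurrence filter for candidate operons
#'
#' Keeps a candidate operon only when every strain of the panel carries an
#' ortholog-complete counterpart: a single operon of the strain containing
#' best-bidirectional-hit orthologs of every gene of the candidate. An empty
#' panel keeps everything (the universal condition holds vacuously).
#'
#' @param registry a `gutresp_registry` containing the focal genome and the
#'   panel strains.
#' @param operons operon table of the focal genome ([predict_operons()]).
#' @param operon_ids operon ids to test (default: all in `operons`).
#' @param strain_panel character vector of strain genome ids.
#' @param similarity a `gutresp_similarity` covering focal-vs-strain pairs.
#' @param cutoff BBH e-value cutoff.
#' @param max_gap_bp operon gap rule for the strains.
#' @return character vector of surviving operon ids.
#' @export
cooccurrence_filter <- function(registry, operons, operon_ids = NULL,
                                strain_panel, similarity, cutoff = 1e-20,
                                max_gap_bp = 300) {
  if (is.null(operon_ids)) operon_ids <- unique(operons$operon_id)
  if (length(strain_panel) == 0L) return(operon_ids)
  focal <- unique(operons$genome_id)
  stopifnot(length(focal) == 1L)
  strain_ops <- lapply(stats::setNames(strain_panel, strain_panel),
                       function(s) predict_operons(registry, s, max_gap_bp))
  bbh <- lapply(stats::setNames(strain_panel, strain_panel), function(s) {
    best_bidirectional_hits(similarity, registry, focal, s, cutoff)
  })
  keep <- vapply(operon_ids, function(op) {
    genes <- operons$protein_id[operons$operon_id == op]
    all(vapply(strain_panel, function(s) {
      orth <- bbh[[s]]
      mates <- orth$protein_b[match(genes, orth$protein_a)]
      if (anyNA(mates)) return(FALSE)
      sop <- strain_ops[[s]]
      ids <- sop$operon_id[match(mates, sop$protein_id)]
      length(unique(ids)) == 1L && !anyNA(ids)
    }, NA))
  }, NA)
  operon_ids[keep]
}

#' Scan for orphan accessory operons (novel-reductase candidates)
#'
#' Searches every predicted operon of every genome for the footprint of a
#' novel reductase assembled from known accessory parts: at least
#' `min_accessory` distinct accessory-subunit families (membrane anchor,
#' electron transfer, maturation) of one catalog entry, no protein matching
#' that entry's catalytic subunit family, and at least one protein from a
#' plausible alternative catalytic family (by default c-type cytochrome
#' families). The alternative-family protein is reported as the candidate
#' catalytic subunit.
#'
#' @param registry a `gutresp_registry`.
#' @param catalog a `gutresp_catalog`.
#' @param alt_catalytic_families accessions accepted as candidate catalytic
#'   subunits (default: `"FAM_CYTC552"`, c-552/4-like cytochromes).
#' @param min_accessory minimum distinct accessory families matched
#'   (default 2; one homolog is too weak to imply a complex).
#' @param max_gap_bp operon gap rule.
#' @param genomes genomes to scan (default: all except the reference).
#' @return data.frame `genome_id`, `operon_id`, `operon_genes`
#'   (comma-separated), `catalog_entry`, `n_accessory`,
#'   `candidate_catalytic` (protein id).
#' @export
orphan_accessory_scan <- function(registry, catalog,
                                  alt_catalytic_families = "FAM_CYTC552",
                                  min_accessory = 2, max_gap_bp = 300,
                                  genomes = NULL) {
  if (is.null(genomes)) {
    genomes <- setdiff(registry$genomes$id, registry$reference_genome)
  }
  dom <- registry$domains
  hits <- list()
  for (gid in genomes) {
    ops <- predict_operons(registry, gid, max_gap_bp)
    for (op in unique(ops$operon_id)) {
      prots <- ops$protein_id[ops$operon_id == op]
      fams <- dom[dom$protein_id %in% prots, , drop = FALSE]
      alt <- unique(fams$protein_id[fams$family %in% alt_catalytic_families])
      if (!length(alt)) next
      for (entry in catalog) {
        acc_f <- catalog_families(entry, "accessory")
        cat_f <- catalog_families(entry, "catalytic")
        n_acc <- length(intersect(acc_f, fams$family))
        if (n_acc < min_accessory) next
        if (any(cat_f %in% fams$family)) next
        hits[[length(hits) + 1L]] <- data.frame(
          genome_id = gid, operon_id = op,
          operon_genes = paste(ops$gene_id[ops$operon_id == op],
                               collapse = ","),
          catalog_entry = entry$name, n_accessory = n_acc,
          candidate_catalytic = alt[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(genome_id = character(0), operon_id = character(0),
                      operon_genes = character(0),
                      catalog_entry = character(0), n_accessory = integer(0),
                      candidate_catalytic = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res
}
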