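#' Best bidirectional hits between two genomes
#'
#' Orthology proxy: a pair (a, b) is reported when b is a's best-scoring
#' subject among the proteins of `genome_b`, a is b's best among the
#' proteins of `genome_a`, and both directed e-values pass the cutoff.
#' Score ties are broken by higher bitscore, then lexicographically smallest
#' subject id, so the result is deterministic under any row order of the
#' similarity table.
#'
#' @param similarity a `gutresp_similarity` table (see [read_similarity()]).
#' @param registry a `gutresp_registry` (supplies protein-to-genome links).
#' @param genome_a,genome_b genome ids.
#' @param cutoff e-value cutoff applied in both directions (default 1e-20).
#' @return data.frame with columns `protein_a`, `protein_b` (unordered
#'   pairs, reported with the `genome_a` member first) and the two e-values.
#' @export
best_bidirectional_hits <- function(similarity, registry, genome_a, genome_b,
                                    cutoff = 1e-20) {
  pg <- protein_genome_map(registry)
  prots_a <- names(pg)[pg == genome_a]
  prots_b <- names(pg)[pg == genome_b]
  best_ab <- best_hits(similarity, prots_a, prots_b)
  best_ba <- best_hits(similarity, prots_b, prots_a)
  if (nrow(best_ab) == 0L || nrow(best_ba) == 0L) {
    return(empty_bbh())
  }
  # mutual: a's best is b and b's best is a
  back <- best_ba$subject[match(best_ab$subject, best_ba$query)]
  mutual <- !is.na(back) & back == best_ab$query
  ab <- best_ab[mutual, , drop = FALSE]
  ev_ba <- best_ba$evalue[match(ab$subject, best_ba$query)]
  pass <- ab$evalue <= cutoff & ev_ba <= cutoff
  out <- data.frame(protein_a = ab$query[pass],
                    protein_b = ab$subject[pass],
                    evalue_ab = ab$evalue[pass],
                    evalue_ba = ev_ba[pass],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_bbh <- function() {
  data.frame(protein_a = character(0), protein_b = character(0),
              evalue_ab = numeric(0), evalue_ba = numeric(0),
              stringsAsFactors = FALSE)
}

# best subject per query restricted to given query/subject universes;
# ties: higher bitscore first, then lexicographic subject id
best_hits <- function(similarity, queries, subjects) {
  s <- similarity[similarity$query %in% queries &
                    similarity$subject %in% subjects, , drop = FALSE]
  if (nrow(s) == 0L) return(s)
  o <- order(s$query, -s$bitscore, s$subject)
  s <- s[o, , drop = FALSE]
  s[!duplicated(s$query), , drop = FALSE]
}

# rank of each gene along its contig (by start coordinate)
gene_ranks <- function(registry) {
  g <- registry$genes
  key <- paste(g$genome_id, g$contig, sep = "\r")
  rank <- stats::ave(g$start, key, FUN = function(x) rank(x, ties.method = "first"))
  data.frame(gene_id = g$id, key = key, rank = rank,
             protein_id = g$protein_id, stringsAsFactors = FALSE)
}

#' Confirm BBH pairs by shared genomic context
#'
#' A pair is context-confirmed when at least one other BBH pair of the same
#' set links genes lying within `window_k` genes of each member on its
#' contig. Windows are truncated at contig edges; a gene alone on its contig
#' can never be confirmed.
#'
#' @param pairs data.frame from [best_bidirectional_hits()].
#' @param registry a `gutresp_registry`.
#' @param window_k neighborhood half-width in genes (default 5).
#' @return `pairs` with a logical `context_confirmed` column appended.
#' @export
confirm_context <- function(pairs, registry, window_k = 5) {
  if (nrow(pairs) == 0L) {
    pairs$context_confirmed <- logical(0)
    return(pairs)
  }
  rk <- gene_ranks(registry)
  ia <- match(pairs$protein_a, rk$protein_id)
  ib <- match(pairs$protein_b, rk$protein_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop("BBH proteins missing from registry genes", call. = FALSE)
  }
  near <- function(i, j) {
    rk$key[i] == rk$key[j] & abs(rk$rank[i] - rk$rank[j]) <= window_k & i != j
  }
  n <- nrow(pairs)
  conf <- logical(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    if (!length(others)) break
    hit <- near(ia[others], ia[i]) & near(ib[others], ib[i])
    conf[i] <- any(hit)
  }
  pairs$context_confirmed <- conf
  pairs
}

#' Collect context-confirmed orthologs of a whole panel to the reference
#'
#' Runs [best_bidirectional_hits()] and [confirm_context()] for every panel
#' genome against the registry's reference genome (the genome carrying the
#' catalog reference proteins).
#'
#' @param registry a `gutresp_registry` with `reference_genome` set.
#' @param similarity a `gutresp_similarity` table.
#' @param cutoff BBH e-value cutoff (default 1e-20).
#' @param window_k context window in genes (default 5).
#' @return data.frame of pairs: `genome_id`, `protein_a` (panel protein),
#'   `protein_b` (reference protein), `context_confirmed`.
#' @export
panel_orthologs <- function(registry, similarity, cutoff = 1e-20,
                            window_k = 5) {
  ref <- registry$reference_genome
  if (is.null(ref)) stop("registry has no reference genome", call. = FALSE)
  gids <- setdiff(registry$genomes$id, ref)
  out <- lapply(gids, function(gid) {
    p <- best_bidirectional_hits(similarity, registry, gid, ref, cutoff)
    p <- confirm_context(p, registry, window_k)
    if (nrow(p)) p$genome_id <- gid
    p
  })
  out <- out[vapply(out, nrow, 0L) > 0]
  if (!length(out)) {
    e <- empty_bbh()
    e$context_confirmed <- logical(0)
    e$genome_id <- character(0)
    return(e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call reductase presence and copy number per genome
#'
#' A reductase type is present in a genome when at least one catalytic
#' subunit of its catalog entry has a (by default context-confirmed)
#' ortholog in that genome; the copy number is the count of distinct
#' catalytic-subunit orthologs. Membrane, electron-transfer and maturation
#' subunits never decide presence; their orthologs are recorded for the
#' complex-composition audit ([audit_complex()]).
#'
#' @param registry a `gutresp_registry` with a reference genome.
#' @param orthologs pairs from [panel_orthologs()].
#' @param catalog a `gutresp_catalog`.
#' @param require_context if TRUE (default) only context-confirmed pairs
#'   count.
#' @return list with `presence` (integer genome-by-reductase copy matrix)
#'   and `calls` (data.frame `genome_id`, `reductase`, `role`, `family`,
#'   `protein_id`, `ref_protein`).
#' @export
call_reductases <- function(registry, orthologs, catalog,
                            require_context = TRUE) {
  ref <- registry$reference_genome
  gids <- setdiff(registry$genomes$id, ref)
  presence <- matrix(0L, nrow = length(gids), ncol = length(catalog),
                     dimnames = list(gids, names(catalog)))
  if (require_context && nrow(orthologs)) {
    orthologs <- orthologs[orthologs$context_confirmed, , drop = FALSE]
  }
  # reference protein -> (entry, role, family) via domain families
  dom <- registry$domains
  pg <- protein_genome_map(registry)
  ref_dom <- dom[dom$protein_id %in% names(pg)[pg == ref], , drop = FALSE]
  calls <- list()
  for (entry in catalog) {
    subs <- entry$subunits
    for (k in seq_len(nrow(subs))) {
      ref_prots <- ref_dom$protein_id[ref_dom$family == subs$family[k]]
      hit <- orthologs[orthologs$protein_b %in% ref_prots, , drop = FALSE]
      if (!nrow(hit)) next
      calls[[length(calls) + 1L]] <- data.frame(
        genome_id = hit$genome_id,
        reductase = entry$name,
        role = subs$role[k],
        family = subs$family[k],
        protein_id = hit$protein_a,
        ref_protein = hit$protein_b,
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(genome_id = character(0), reductase = character(0),
               role = character(0), family = character(0),
               protein_id = character(0), ref_protein = character(0),
               stringsAsFactors = FALSE)
  cat_calls <- calls[calls$role == "catalytic", , drop = FALSE]
  if (nrow(cat_calls)) {
    # distinct catalytic orthologs per (genome, reductase)
    cp <- unique(cat_calls[, c("genome_id", "reductase", "protein_id")])
    tab <- table(cp$genome_id, cp$reductase)
    presence[rownames(tab), colnames(tab)] <-
      presence[rownames(tab), colnames(tab)] + as.integer(tab)
  }
  list(presence = presence, calls = calls)
}
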