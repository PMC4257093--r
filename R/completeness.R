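#' Fraction of essential gene families found in a genome
#'
#' Diagnostic completeness estimate: the share of a user-supplied set of
#' essential domain families with at least one member protein in the genome.
#' Even finished genomes can score well below 1 (one finished genome in the
#' gut panel scored 0.849), so this fraction is reported as a diagnostic
#' only and never decides the completeness verdict; the length-based
#' assessment of [assess_completeness_by_length()] does.
#'
#' @param registry a `gutresp_registry`.
#' @param genome_id genome to score.
#' @param essential_families character vector of family accessions; must be
#'   non-empty.
#' @return numeric in `[0, 1]`.
#' @export
essential_gene_fraction <- function(registry, genome_id, essential_families) {
  if (length(essential_families) == 0L) {
    stop("essential family set is empty", call. = FALSE)
  }
  essential_families <- unique(essential_families)
  prots <- registry$proteins$id[
    protein_genome_map(registry) == genome_id]
  fams <- unique(registry$domains$family[
    registry$domains$protein_id %in% prots])
  sum(essential_families %in% fams) / length(essential_families)
}

#' Find the finished genomes most closely related to a draft
#'
#' Tiered relatedness lookup: finished genomes of the same species if any;
#' otherwise finished genomes of the same genus; otherwise the finished
#' genome(s) with maximal 16S identity (all ties included); an empty vector
#' if the panel holds no finished genomes or no tier applies.
#'
#' @param registry a `gutresp_registry`.
#' @param genome_id the draft genome.
#' @param relatedness optional data.frame `genome_a`, `genome_b`, `identity`
#'   (16S identity in `[0, 1]`; treated as symmetric).
#' @return character vector of finished genome ids (possibly empty).
#' @export
find_related_finished <- function(registry, genome_id, relatedness = NULL) {
  g <- registry$genomes
  me <- g[g$id == genome_id, ]
  if (nrow(me) != 1L) stop("unknown genome: ", genome_id, call. = FALSE)
  fin <- g[g$status == "finished" & g$id != genome_id, ]
  if (nrow(fin) == 0L) return(character(0))
  if (!is.na(me$species) && nzchar(me$species)) {
    hit <- fin$id[!is.na(fin$species) & fin$species == me$species]
    if (length(hit)) return(hit)
  }
  if (!is.na(me$genus) && nzchar(me$genus)) {
    hit <- fin$id[!is.na(fin$genus) & fin$genus == me$genus]
    if (length(hit)) return(hit)
  }
  if (!is.null(relatedness)) {
    rel <- relatedness
    if (any(rel$identity < 0 | rel$identity > 1)) {
      stop("16S identities must lie in [0, 1]", call. = FALSE)
    }
    both <- rbind(
      data.frame(a = rel$genome_a, b = rel$genome_b, id = rel$identity),
      data.frame(a = rel$genome_b, b = rel$genome_a, id = rel$identity)
    )
    mine <- both[both$a == genome_id & both$b %in% fin$id, ]
    if (nrow(mine)) {
      best <- max(mine$id)
      return(sort(unique(mine$b[mine$id == best])))
    }
  }
  character(0)
}

#' Completeness verdict for a draft genome by length comparison
#'
#' A draft genome is judged probably complete when its length is at least
#' the length of one of its closely related finished genomes (ties count as
#' complete: equality carries no evidence of truncation), incomplete when it
#' is shorter than all of them, and unassessable when no related finished
#' genome exists.
#'
#' @param length_bp draft genome length in bp.
#' @param related_lengths lengths of the related finished genomes (possibly
#'   empty).
#' @return one of "probably_complete", "incomplete", "unassessable".
#' @export
assess_completeness_by_length <- function(length_bp, related_lengths) {
  if (length(related_lengths) == 0L) return("unassessable")
  if (length_bp >= min(related_lengths)) "probably_complete" else "incomplete"
}

#' Assess completeness for every genome in a panel
#'
#' Finished genomes are complete by definition and bypass the length
#' comparison; draft genomes are assessed against their related finished
#' genomes ([find_related_finished()], [assess_completeness_by_length()]).
#'
#' @param registry a `gutresp_registry`.
#' @param relatedness optional 16S identity table (see
#'   [find_related_finished()]).
#' @return the registry with `genomes$completeness` filled in.
#' @export
assess_completeness <- function(registry, relatedness = NULL) {
  g <- registry$genomes
  for (i in seq_len(nrow(g))) {
    if (g$status[i] == "finished") {
      g$completeness[i] <- "complete"
    } else {
      rel <- find_related_finished(registry, g$id[i], relatedness)
      g$completeness[i] <- assess_completeness_by_length(
        g$length_bp[i], g$length_bp[match(rel, g$id)])
    }
  }
  registry$genomes <- g
  registry
}
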