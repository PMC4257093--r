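#' Propagate substrate specificities down monophyletic clades
#'
#' Within the phylogenetic tree of a catalytic-subunit family (for anaerobic
#' reductases, the molybdopterin oxidoreductase family PF00384), the
#' specificity of experimentally known members is extrapolated to every
#' member of a maximal clade when (1) all known tips of the clade agree on
#' one specificity and (2) the genomic-context signatures of all tips of
#' the clade pairwise share at least one neighbor family accession. Known
#' labels are never changed; clades mixing specificities propagate nothing.
#'
#' Unrooted trees are midpoint-rooted by default; pass `unrooted = "error"`
#' to reject them instead.
#'
#' @param tree an `ape::phylo`; tip labels are protein ids.
#' @param known named character vector of known specificities (names are tip
#'   labels; tips absent from it are unknown). Must be non-empty.
#' @param context named list of character vectors: per-tip sets of neighbor
#'   family accessions.
#' @param unrooted "midpoint" (default) or "error".
#' @return data.frame `protein_id`, `specificity` (NA when unassigned),
#'   `method` ("known", "phylogeny" or "unassigned").
#' @export
propagate_by_clade <- function(tree, known, context,
                               unrooted = c("midpoint", "error")) {
  unrooted <- match.arg(unrooted)
  if (length(known) == 0L) stop("no known tips", call. = FALSE)
  if (!ape::is.rooted(tree)) {
    if (unrooted == "error") {
      stop("tree is unrooted; midpoint-root it first ",
           "(e.g. phangorn::midpoint) or call with unrooted = 'midpoint'",
           call. = FALSE)
    }
    tree <- phangorn::midpoint(tree)
  }
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("duplicated tip labels", call. = FALSE)
  stopifnot(all(names(known) %in% tips))
  ntip <- length(tips)
  spec <- stats::setNames(rep(NA_character_, ntip), tips)
  spec[names(known)] <- unname(known)

  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  clade_tips <- phangorn::Descendants(tree, nodes, type = "tips")
  qualifies <- vapply(clade_tips, function(idx) {
    labs <- tips[idx]
    kn <- spec[labs]
    kn <- kn[!is.na(kn)]
    if (length(kn) == 0L || length(unique(kn)) != 1L) return(FALSE)
    context_conserved(context[labs])
  }, NA)

  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- nodes[!nodes %in% tree$edge[, 2]]
  maximal <- qualifies & vapply(nodes, function(nd) {
    nd %in% root || !qualifies[match(parent[nd], nodes)]
  }, NA)

  method <- stats::setNames(
    ifelse(tips %in% names(known), "known", "unassigned"), tips)
  for (j in which(maximal)) {
    labs <- tips[clade_tips[[j]]]
    kn <- spec[labs]
    value <- unique(kn[!is.na(kn)])
    unk <- labs[is.na(spec[labs])]
    spec[unk] <- value
    method[unk] <- "phylogeny"
  }
  data.frame(protein_id = tips, specificity = unname(spec),
             method = unname(method), stringsAsFactors = FALSE,
             row.names = NULL)
}

# every pair of tip context signatures shares >= 1 accession
context_conserved <- function(ctx) {
  if (any(vapply(ctx, is.null, NA))) return(FALSE)
  n <- length(ctx)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!any(ctx[[i]] %in% ctx[[j]])) return(FALSE)
    }
  }
  TRUE
}

#' Fit a specificity-determining-position (SDP) model
#'
#' Ranks alignment columns by how well their residues discriminate the known
#' specificity groups: mutual information between residue and group label,
#' computed over non-gap entries, compared with a label-permutation null;
#' columns with a null z-score above `z_threshold` are retained. Columns
#' where any group exceeds `max_gap_fraction` gaps are excluded outright,
#' whatever their signal.
#'
#' @param alignment character matrix (rows = proteins, named; cols =
#'   alignment positions; gaps as "-").
#' @param groups named character vector mapping protein id to specificity
#'   group; needs at least two groups with at least two sequences each.
#' @param max_gap_fraction maximum tolerated per-group gap share per column
#'   (default 0.5).
#' @param z_threshold permutation-null z-score cutoff for column selection
#'   (default 3).
#' @param n_perm label permutations for the null (default 200).
#' @param margin decision threshold for [classify_by_sdp()], stored with the
#'   model (default 2, natural-log odds).
#' @param pseudocount Laplace pseudocount for residue profiles.
#' @return object of class `gutresp_sdp`: selected `columns`, per-group
#'   log-frequency `profiles`, and the scores; `columns` may be empty, in
#'   which case the model is flagged `empty = TRUE`.
#' @export
fit_sdp <- function(alignment, groups, max_gap_fraction = 0.5,
                    z_threshold = 3, n_perm = 200, margin = 2,
                    pseudocount = 0.5) {
  stopifnot(is.matrix(alignment), !is.null(rownames(alignment)))
  groups <- groups[names(groups) %in% rownames(alignment)]
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("SDP fitting needs >= 2 groups with >= 2 sequences each",
         call. = FALSE)
  }
  aln <- alignment[names(groups), , drop = FALSE]
  lab <- as.character(groups)
  ncol_a <- ncol(aln)

  gap_ok <- vapply(seq_len(ncol_a), function(j) {
    frac <- tapply(aln[, j] == "-", lab, mean)
    all(frac <= max_gap_fraction)
  }, NA)

  mi_col <- function(col, lab) {
    keep <- col != "-"
    if (sum(keep) < 2L) return(0)
    column_mi(col[keep], lab[keep])
  }
  mi <- vapply(seq_len(ncol_a), function(j) mi_col(aln[, j], lab), 0)

  null_mi <- matrix(0, nrow = n_perm, ncol = ncol_a)
  for (b in seq_len(n_perm)) {
    plab <- sample(lab)
    null_mi[b, ] <- vapply(seq_len(ncol_a),
                           function(j) mi_col(aln[, j], plab), 0)
  }
  mu <- colMeans(null_mi)
  sdv <- apply(null_mi, 2, stats::sd)
  z <- ifelse(sdv > 0, (mi - mu) / sdv, 0)
  columns <- which(gap_ok & z >= z_threshold)

  gset <- sort(unique(lab))
  alphabet <- sort(unique(c(aln[aln != "-"], LETTERS[c(1, 3:9, 11:14, 16:20, 22:23, 25)])))
  profiles <- lapply(stats::setNames(gset, gset), function(g) {
    rows <- aln[lab == g, columns, drop = FALSE]
    sapply(seq_along(columns), function(k) {
      col <- rows[, k]
      col <- col[col != "-"]
      cnt <- table(factor(col, levels = alphabet)) + pseudocount
      log(as.numeric(cnt) / sum(cnt))
    })
  })
  structure(list(columns = columns, profiles = profiles,
                 alphabet = alphabet, groups = gset, mi = mi, z = z,
                 gap_ok = gap_ok, margin = margin,
                 empty = length(columns) == 0L),
            class = "gutresp_sdp")
}

# mutual information (nats) between residue and group over given entries
column_mi <- function(res, lab) {
  jt <- table(res, lab)
  p <- jt / sum(jt)
  pr <- rowSums(p)
  pl <- colSums(p)
  e <- outer(pr, pl)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' @export
print.gutresp_sdp <- function(x, ...) {
  cat("SDP model:", length(x$columns), "specificity-determining columns,",
      length(x$groups), "groups\n")
  if (x$empty) cat("  (empty model: no column passed selection)\n")
  invisible(x)
}

#' Classify one aligned protein by an SDP model
#'
#' Scores the protein's residues at the model's SDP columns against each
#' group's log-frequency profile and assigns the top-scoring group when its
#' margin over the runner-up is at least the model's decision threshold;
#' otherwise (including a protein gapped at every SDP column, or an empty
#' model) returns `NA`.
#'
#' @param model a `gutresp_sdp`.
#' @param row character vector: the protein's alignment row.
#' @param margin override the model's stored log-odds margin.
#' @return the assigned group name, or `NA_character_`.
#' @export
classify_by_sdp <- function(model, row, margin = model$margin) {
  if (model$empty) return(NA_character_)
  res <- row[model$columns]
  use <- res != "-"
  if (!any(use)) return(NA_character_)
  idx <- match(res[use], model$alphabet)
  scores <- vapply(model$groups, function(g) {
    prof <- model$profiles[[g]]
    sum(prof[cbind(idx, which(use))], na.rm = TRUE)
  }, 0)
  o <- order(scores, decreasing = TRUE)
  if (length(scores) > 1L && scores[o[1]] - scores[o[2]] < margin) {
    return(NA_character_)
  }
  model$groups[o[1]]
}

#' Assign specificities by clade propagation, then SDP
#'
#' The full two-stage assignment used for the molybdopterin oxidoreductase
#' family: clade propagation with conserved genomic context first
#' ([propagate_by_clade()]), then SDP classification
#' ([fit_sdp()], [classify_by_sdp()]) for tips the tree could not place.
#' Known labels are never overwritten.
#'
#' @param tree,known,context as in [propagate_by_clade()].
#' @param alignment character matrix over all tips (rows named by tip).
#' @param params optional list overriding SDP parameters
#'   (`max_gap_fraction`, `z_threshold`, `n_perm`, `margin`).
#' @return data.frame `protein_id`, `specificity`, `method` with method in
#'   known / phylogeny / sdp / unassigned.
#' @export
assign_specificities <- function(tree, alignment, known, context,
                                 params = list()) {
  asn <- propagate_by_clade(tree, known, context)
  rest <- asn$protein_id[asn$method == "unassigned"]
  if (length(rest)) {
    model <- fit_sdp(alignment, known,
                     max_gap_fraction = params$max_gap_fraction %||% 0.5,
                     z_threshold = params$z_threshold %||% 3,
                     n_perm = params$n_perm %||% 200,
                     margin = params$margin %||% 2)
    for (p in rest) {
      hit <- classify_by_sdp(model, alignment[p, ])
      if (!is.na(hit)) {
        i <- asn$protein_id == p
        asn$specificity[i] <- hit
        asn$method[i] <- "sdp"
      }
    }
  }
  asn
}

#' Count specificity assignments per method
#'
#' @param assignments data.frame from [assign_specificities()] or
#'   [propagate_by_clade()].
#' @return list with `counts` (named integer vector over known / phylogeny /
#'   sdp / unassigned) and `unassigned` (protein ids still without a
#'   specificity).
#' @export
summarize_assignments <- function(assignments) {
  methods <- c("known", "phylogeny", "sdp", "unassigned")
  counts <- vapply(methods, function(m) sum(assignments$method == m), 0L)
  list(counts = counts,
       unassigned = assignments$protein_id[assignments$method == "unassigned"])
}
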