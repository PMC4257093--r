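#' Generate a protein-family fixture with planted specificity structure
#'
#' Builds everything the specificity module consumes: a rooted tree with
#' planted monophyletic specificity clades, per-tip genomic-context
#' signatures conserved within clades, a subset of tips marked as
#' experimentally known, an alignment with planted specificity-determining
#' columns (one characteristic residue per group, flipped to a random
#' residue with probability `sdp_noise`), and a set of "detached" members
#' placed in a mixed clade so that only the SDP classifier -- never clade
#' propagation -- can recover them.
#'
#' @param seed RNG seed.
#' @param n_tips total family members (default 100).
#' @param n_clades planted specificity groups (default 8; minimum 2).
#' @param known_fraction fraction of clade tips with known specificity
#'   (default 0.25; at least two known tips per group are guaranteed).
#' @param sdp_noise per-site flip probability at SDP columns (default 0.05).
#' @param n_detached tips detached from their group's clade (default 12).
#' @param n_columns alignment length (default 60).
#' @param n_sdp planted specificity-determining columns (default 16).
#' @param gap_prob per-site gap probability at non-SDP columns.
#' @return list of class `gutresp_family_fixture`: `tree` (ape phylo),
#'   `alignment` (character matrix), `known` (named vector), `context`
#'   (named list), and `ground_truth` (`tip_groups`, `detached`,
#'   `sdp_columns`, `groups`).
#' @export
generate_family_fixture <- function(seed = 1, n_tips = 100, n_clades = 8,
                                    known_fraction = 0.25, sdp_noise = 0.05,
                                    n_detached = 12, n_columns = 60,
                                    n_sdp = 16, gap_prob = 0.03) {
  if (n_clades < 2L) {
    stop("family fixture needs >= 2 specificity groups (SDP requires them)",
         call. = FALSE)
  }
  stopifnot(n_sdp <= n_columns, n_detached >= 2L,
            n_tips - n_detached >= 4L * n_clades)
  with_seed(seed, {
    groups <- c("nitrate", "DMSO_TMAO", "TMAO", "thiosulfate",
                "tetrathionate", "arsenate", "fumarate",
                "selenate")[seq_len(min(n_clades, 8L))]
    if (n_clades > 8L) groups <- c(groups, sprintf("group%02d", 9:n_clades))

    n_clade_tips <- n_tips - n_detached
    sizes <- rep(n_clade_tips %/% n_clades, n_clades)
    sizes[seq_len(n_clade_tips %% n_clades)] <-
      sizes[seq_len(n_clade_tips %% n_clades)] + 1L

    tip_groups <- character(0)
    clade_newick <- character(n_clades)
    tip_i <- 0L
    for (g in seq_len(n_clades)) {
      labs <- sprintf("prot%03d", tip_i + seq_len(sizes[g]))
      tip_i <- tip_i + sizes[g]
      tip_groups[labs] <- groups[g]
      sub <- ape::rtree(sizes[g], tip.label = labs)
      clade_newick[g] <- sub("\\;$", "", ape::write.tree(sub))
    }
    det_labs <- sprintf("prot%03d", n_clade_tips + seq_len(n_detached))
    tip_groups[det_labs] <- groups[1L + (seq_len(n_detached) - 1L) %%
                                     n_clades]
    det_tree <- ape::rtree(n_detached, tip.label = det_labs)
    det_newick <- sub("\\;$", "", ape::write.tree(det_tree))
    # ladder of clades, mixed (detached) clade last
    nwk <- clade_newick[1]
    for (g in seq_len(n_clades)[-1]) {
      nwk <- sprintf("(%s:1,%s:1)", nwk, clade_newick[g])
    }
    nwk <- sprintf("(%s:1,%s:1);", nwk, det_newick)
    tree <- ape::read.tree(text = nwk)

    # known tips: clade members only, >= 2 per group
    known <- character(0)
    for (g in seq_len(n_clades)) {
      labs <- names(tip_groups)[tip_groups == groups[g] &
                                  !names(tip_groups) %in% det_labs]
      k <- max(2L, round(known_fraction * length(labs)))
      pick <- sort(sample(labs, min(k, length(labs))))
      known[pick] <- groups[g]
    }

    # context: clade members share their group accession; detached tips get
    # private signatures so no clade containing them is context-conserved
    context <- lapply(stats::setNames(names(tip_groups), names(tip_groups)),
                      function(p) {
      if (p %in% det_labs) {
        paste0("CTX_private_", p)
      } else {
        c(paste0("CTX_", tip_groups[[p]]),
          paste0("CTX_extra_", sample(5L, 1L)))
      }
    })

    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    sdp_columns <- sort(sample(n_columns, n_sdp))
    group_res <- matrix("", nrow = n_clades, ncol = n_sdp)
    for (j in seq_len(n_sdp)) {
      group_res[, j] <- sample(aa, n_clades)
    }
    consensus <- sample(aa, n_columns, replace = TRUE)
    aln <- matrix("", nrow = n_tips, ncol = n_columns,
                  dimnames = list(names(tip_groups), NULL))
    for (p in names(tip_groups)) {
      gi <- match(tip_groups[[p]], groups)
      row <- consensus
      mut <- stats::runif(n_columns) < 0.2
      row[mut] <- sample(aa, sum(mut), replace = TRUE)
      row[sdp_columns] <- group_res[gi, ]
      flip <- stats::runif(n_sdp) < sdp_noise
      if (any(flip)) {
        row[sdp_columns[flip]] <- sample(aa, sum(flip), replace = TRUE)
      }
      gaps <- stats::runif(n_columns) < gap_prob
      gaps[sdp_columns] <- FALSE
      row[gaps] <- "-"
      aln[p, ] <- row
    }

    structure(list(
      tree = tree, alignment = aln, known = known, context = context,
      ground_truth = list(tip_groups = tip_groups, detached = det_labs,
                          sdp_columns = sdp_columns, groups = groups)
    ), class = "gutresp_family_fixture")
  })
}

#' Score specificity recovery on a family fixture
#'
#' Runs the two-stage assignment ([assign_specificities()]) on a fixture
#' and returns the fraction of planted (non-known) labels recovered.
#'
#' @param fixture from [generate_family_fixture()].
#' @param params SDP parameter overrides passed through.
#' @return list: `recovery` (fraction correct among unknown tips),
#'   `assignments` (the full table).
#' @export
score_family_recovery <- function(fixture, params = list()) {
  asn <- assign_specificities(fixture$tree, fixture$alignment,
                              fixture$known, fixture$context, params)
  truth <- fixture$ground_truth$tip_groups
  unknown <- setdiff(names(truth), names(fixture$known))
  got <- asn$specificity[match(unknown, asn$protein_id)]
  list(recovery = mean(!is.na(got) & got == truth[unknown]),
       assignments = asn)
}
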