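simple_tree <- function(text = "((k1:1,u1:1):1,(k2:1,u2:1):1);") {
  ape::read.tree(text = text)
}

shared_ctx <- function(tips, acc = "CTX_nar") {
  stats::setNames(rep(list(acc), length(tips)), tips)
}

test_that("a context-conserved clade propagates its known specificity", {
  tr <- simple_tree()
  asn <- propagate_by_clade(tr, c(k1 = "nitrate", k2 = "nitrate"),
                            shared_ctx(tr$tip.label))
  expect_equal(asn$specificity[asn$protein_id %in% c("u1", "u2")],
               c("nitrate", "nitrate"))
  expect_equal(asn$method[asn$protein_id == "u1"], "phylogeny")
  expect_equal(asn$method[asn$protein_id == "k1"], "known")
})

test_that("clades mixing specificities propagate nothing", {
  # the unknown tip's only enclosing clades contain both a nitrate and a
  # DMSO/TMAO known member, so nothing reaches it
  tr <- simple_tree("((k1:1,k2:1):1,u1:1);")
  asn <- propagate_by_clade(tr, c(k1 = "nitrate", k2 = "DMSO_TMAO"),
                            shared_ctx(tr$tip.label))
  expect_true(is.na(asn$specificity[asn$protein_id == "u1"]))
  # pure sub-clades below a mixed ancestor still propagate
  tr2 <- simple_tree()
  asn2 <- propagate_by_clade(tr2, c(k1 = "nitrate", k2 = "DMSO_TMAO"),
                             shared_ctx(tr2$tip.label))
  expect_equal(asn2$specificity[asn2$protein_id == "u1"], "nitrate")
  expect_equal(asn2$specificity[asn2$protein_id == "u2"], "DMSO_TMAO")
})

test_that("broken context blocks propagation even in a pure clade", {
  tr <- simple_tree()
  ctx <- list(k1 = "CTX_a", u1 = "CTX_b", k2 = "CTX_a", u2 = "CTX_a")
  asn <- propagate_by_clade(tr, c(k1 = "nitrate", k2 = "nitrate"), ctx)
  expect_true(is.na(asn$specificity[asn$protein_id == "u1"]))
  expect_equal(asn$specificity[asn$protein_id == "u2"], "nitrate")
})

test_that("unrooted trees are midpoint-rooted, or rejected on request", {
  tr <- ape::unroot(ape::read.tree(
    text = "((k1:1,u1:1):1,(k2:1,u2:1):1,(k3:9,u3:1):1);"))
  expect_false(ape::is.rooted(tr))
  known <- c(k1 = "nitrate", k2 = "nitrate", k3 = "fumarate")
  expect_error(propagate_by_clade(tr, known, shared_ctx(tr$tip.label),
                                  unrooted = "error"), "midpoint")
  asn <- propagate_by_clade(tr, known, shared_ctx(tr$tip.label))
  expect_equal(asn$specificity[asn$protein_id == "u1"], "nitrate")
})

test_that("known labels are never overwritten or contradicted", {
  for (seed in 1:5) {
    fx <- generate_family_fixture(seed, n_tips = 60, n_clades = 4,
                                  n_detached = 6, sdp_noise = 0)
    asn <- assign_specificities(fx$tree, fx$alignment, fx$known, fx$context,
                                params = list(n_perm = 60))
    kn <- asn[asn$protein_id %in% names(fx$known), ]
    expect_equal(stats::setNames(kn$specificity, kn$protein_id)[names(fx$known)],
                 fx$known)
    expect_true(all(kn$method == "known"))
  }
})

test_that("clade propagation is idempotent", {
  fx <- generate_family_fixture(3, n_tips = 60, n_clades = 4, n_detached = 6)
  a1 <- propagate_by_clade(fx$tree, fx$known, fx$context)
  known2 <- stats::setNames(a1$specificity, a1$protein_id)
  known2 <- known2[!is.na(known2)]
  a2 <- propagate_by_clade(fx$tree, known2, fx$context)
  got2 <- stats::setNames(a2$specificity, a2$protein_id)
  got1 <- stats::setNames(a1$specificity, a1$protein_id)
  expect_identical(got2[names(got1)], got1)
})

test_that("propagation is invariant to child rotation", {
  fx <- generate_family_fixture(4, n_tips = 40, n_clades = 3, n_detached = 4)
  a1 <- propagate_by_clade(fx$tree, fx$known, fx$context)
  tr2 <- ape::read.tree(text = ape::write.tree(
    ape::ladderize(fx$tree, right = FALSE)))
  a2 <- propagate_by_clade(tr2, fx$known, fx$context)
  m1 <- stats::setNames(a1$specificity, a1$protein_id)
  m2 <- stats::setNames(a2$specificity, a2$protein_id)
  expect_identical(m2[names(m1)], m1)
})

sdp_toy <- function() {
  # two groups, one perfectly discriminating column (1), one uniform (2),
  # one informative but gap-heavy in group B (3)
  aln <- rbind(
    A1 = c("A", "L", "W"), A2 = c("A", "V", "W"),
    A3 = c("A", "L", "W"), A4 = c("A", "V", "W"),
    B1 = c("G", "L", "-"), B2 = c("G", "V", "-"),
    B3 = c("G", "L", "-"), B4 = c("G", "V", "Y")
  )
  groups <- stats::setNames(rep(c("grpA", "grpB"), each = 4), rownames(aln))
  list(aln = aln, groups = groups)
}

test_that("SDP selection keeps discriminating columns, drops gappy ones", {
  fx <- sdp_toy()
  set.seed(9)
  m <- fit_sdp(fx$aln, fx$groups, n_perm = 200)
  expect_true(1 %in% m$columns)
  expect_false(2 %in% m$columns)
  # column 3: 75% gaps in group B exceeds the 50% rule, despite its signal
  expect_false(3 %in% m$columns)
  expect_false(m$gap_ok[3])
})

test_that("an i.i.d. uniform column is almost never selected", {
  set.seed(77)
  aa <- c("A", "C", "D", "E", "F", "G")
  picked <- logical(200)
  for (i in 1:200) {
    aln <- cbind(
      matrix(rep(c("A", "G"), each = 6), ncol = 1),  # real signal column
      matrix(sample(aa, 12, replace = TRUE), ncol = 1)  # null column
    )
    rownames(aln) <- sprintf("s%02d", 1:12)
    groups <- stats::setNames(rep(c("g1", "g2"), each = 6), rownames(aln))
    m <- fit_sdp(aln, groups, n_perm = 60)
    picked[i] <- 2 %in% m$columns
  }
  expect_gte(mean(!picked), 0.95)
})

test_that("SDP classification follows consensus and respects the margin", {
  fx <- sdp_toy()
  set.seed(10)
  m <- fit_sdp(fx$aln, fx$groups, n_perm = 200)
  expect_equal(classify_by_sdp(m, c("A", "L", "W")), "grpA")
  expect_equal(classify_by_sdp(m, c("G", "L", "W")), "grpB")
  # gapped at every SDP column -> unknown
  row <- c("A", "L", "W"); row[m$columns] <- "-"
  expect_true(is.na(classify_by_sdp(m, row)))
  # equidistant between the groups -> below margin -> unknown
  m2 <- m; m2$profiles$grpA <- m$profiles$grpB
  expect_true(is.na(classify_by_sdp(m2, c("A", "L", "W"))))
})

test_that("SDP fitting demands two groups of two sequences", {
  fx <- sdp_toy()
  expect_error(fit_sdp(fx$aln, fx$groups[1:4], n_perm = 10), ">= 2 groups")
  expect_error(fit_sdp(fx$aln, fx$groups[c(1, 5:8)], n_perm = 10),
               ">= 2 groups")
})

test_that("noise-free fixtures are fully recovered by the two-stage path", {
  fx <- generate_family_fixture(21, n_tips = 60, n_clades = 4,
                                n_detached = 6, sdp_noise = 0)
  sc <- score_family_recovery(fx, params = list(n_perm = 60))
  expect_equal(sc$recovery, 1.0)
  # detached members are reachable only through the SDP route
  det <- sc$assignments[sc$assignments$protein_id %in%
                          fx$ground_truth$detached, ]
  expect_true(all(det$method == "sdp"))
})

test_that("assignment counts split by method as planted", {
  asn <- data.frame(
    protein_id = sprintf("p%03d", 1:348),
    specificity = "x",
    method = rep(c("known", "phylogeny", "sdp", "unassigned"),
                 c(40, 151, 48, 109)),
    stringsAsFactors = FALSE)
  asn$specificity[asn$method == "unassigned"] <- NA
  s <- summarize_assignments(asn)
  expect_equal(unname(s$counts),  c(40L, 151L, 48L, 109L))
  expect_length(s$unassigned, 109)
  # all-known and no-known degenerate cases
  all_known <- data.frame(protein_id = "p1", specificity = "x",
                          method = "known")
  expect_equal(unname(summarize_assignments(all_known)$counts),
               c(1L, 0L, 0L, 0L))
  none <- data.frame(protein_id = c("a", "b"), specificity = NA,
                     method = "unassigned")
  expect_equal(unname(summarize_assignments(none)$counts), c(0L, 0L, 0L, 2L))
})
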