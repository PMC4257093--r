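test_that("BBH matches a brute-force enumeration on random fixtures", {
  set.seed(101)
  for (rep in 1:20) {
    nA <- sample(3:8, 1); nB <- sample(3:8, 1)
    reg <- toy_registry(list(gA = sprintf("a%d", seq_len(nA)),
                             gB = sprintf("b%d", seq_len(nB))))
    pa <- sprintf("a%d_p", seq_len(nA)); pb <- sprintf("b%d_p", seq_len(nB))
    rows <- list()
    for (q in pa) for (s in pb) {
      if (runif(1) < 0.6) {
        bits <- sample(50:600, 1)
        rows[[length(rows) + 1L]] <- sim_row(q, s, bits)
        if (runif(1) < 0.8) {
          rows[[length(rows) + 1L]] <- sim_row(s, q, bits)
        }
      }
    }
    if (!length(rows)) next
    sim <- read_similarity(do.call(rbind, rows))
    got <- best_bidirectional_hits(sim, reg, "gA", "gB", cutoff = 1e-20)
    keys <- sort(apply(got[, c("protein_a", "protein_b")], 1, function(p)
      paste(sort(p), collapse = "|")))
    expect_equal(unname(keys), unname(oracle_bbh(sim, pa, pb)))
  }
})

test_that("planted orthologs with strictly lower noise recover exactly", {
  reg <- toy_registry(list(gA = c("a1", "a2", "a3"),
                           gB = c("b1", "b2", "b3")))
  rows <- list()
  for (i in 1:3) {
    rows[[length(rows) + 1L]] <- sim_row(sprintf("a%d_p", i),
                                         sprintf("b%d_p", i), 500)
    rows[[length(rows) + 1L]] <- sim_row(sprintf("b%d_p", i),
                                         sprintf("a%d_p", i), 500)
  }
  # noise 10 bits lower, crossed
  rows[[length(rows) + 1L]] <- sim_row("a1_p", "b2_p", 490)
  rows[[length(rows) + 1L]] <- sim_row("b2_p", "a1_p", 490)
  sim <- read_similarity(do.call(rbind, rows))
  got <- best_bidirectional_hits(sim, reg, "gA", "gB")
  expect_setequal(paste(got$protein_a, got$protein_b),
                  c("a1_p b1_p", "a2_p b2_p", "a3_p b3_p"))
})

test_that("a whose best is b, while b's best is c, forms no pair", {
  reg <- toy_registry(list(gA = c("a1", "c1"), gB = c("b1")))
  sim <- sim_tab(sim_row("a1_p", "b1_p", 500),
                 sim_row("b1_p", "c1_p", 600),
                 sim_row("b1_p", "a1_p", 500),
                 sim_row("c1_p", "b1_p", 600))
  got <- best_bidirectional_hits(sim, reg, "gA", "gB")
  expect_false("a1_p" %in% got$protein_a)
  expect_true(any(got$protein_a == "c1_p" & got$protein_b == "b1_p"))
})

test_that("score ties break to the lexicographically smallest subject", {
  reg <- toy_registry(list(gA = c("a1"), gB = c("b1", "b2")))
  sim <- sim_tab(sim_row("a1_p", "b1_p", 500), sim_row("a1_p", "b2_p", 500),
                 sim_row("b1_p", "a1_p", 500), sim_row("b2_p", "a1_p", 500))
  got <- best_bidirectional_hits(sim, reg, "gA", "gB")
  expect_equal(got$protein_b, "b1_p")
})

test_that("the e-value cutoff applies in both directions", {
  reg <- toy_registry(list(gA = "a1", gB = "b1"))
  sim <- sim_tab(sim_row("a1_p", "b1_p", 500),
                 sim_row("b1_p", "a1_p", 60, ev = 1e-12))
  got <- best_bidirectional_hits(sim, reg, "gA", "gB", cutoff = 1e-20)
  expect_equal(nrow(got), 0L)
})

test_that("BBH is symmetric under genome swap", {
  panel <- the_small_panel()
  reg <- panel$registry
  gids <- setdiff(reg$genomes$id, "REF")[1:4]
  for (g in gids) {
    ab <- best_bidirectional_hits(panel$similarity, reg, g, "REF")
    ba <- best_bidirectional_hits(panel$similarity, reg, "REF", g)
    k1 <- sort(apply(ab[, 1:2], 1, function(p) paste(sort(p), collapse = "|")))
    k2 <- sort(apply(ba[, 1:2], 1, function(p) paste(sort(p), collapse = "|")))
    expect_equal(unname(k1), unname(k2))
  }
})

context_fixture <- function() {
  reg <- toy_registry(list(gA = c("a1", "a2", "a3", "a9"),
                           gB = c("b1", "b2", "b3", "b9")))
  rows <- list()
  for (i in c(1:3)) {
    rows[[length(rows) + 1L]] <- sim_row(sprintf("a%d_p", i),
                                         sprintf("b%d_p", i), 500)
    rows[[length(rows) + 1L]] <- sim_row(sprintf("b%d_p", i),
                                         sprintf("a%d_p", i), 500)
  }
  list(reg = reg, rows = rows)
}

test_that("a syntenic block confirms all of its pairs", {
  fx <- context_fixture()
  sim <- read_similarity(do.call(rbind, fx$rows))
  pairs <- best_bidirectional_hits(sim, fx$reg, "gA", "gB")
  pairs <- confirm_context(pairs, fx$reg, window_k = 5)
  expect_true(all(pairs$context_confirmed))
})

test_that("an isolated BBH with shuffled neighborhood stays unconfirmed", {
  fx <- context_fixture()
  # a9/b9 pair far from any other pair on a separate contig
  fx$reg$genes$contig[fx$reg$genes$id %in% c("a9", "b9")] <- "c2"
  rows <- c(fx$rows, list(sim_row("a9_p", "b9_p", 500),
                          sim_row("b9_p", "a9_p", 500)))
  sim <- read_similarity(do.call(rbind, rows))
  pairs <- best_bidirectional_hits(sim, fx$reg, "gA", "gB")
  pairs <- confirm_context(pairs, fx$reg, window_k = 5)
  expect_false(pairs$context_confirmed[pairs$protein_a == "a9_p"])
  expect_true(all(pairs$context_confirmed[pairs$protein_a != "a9_p"]))
})

test_that("a gene alone on its contig can never be context-confirmed", {
  reg <- toy_registry(list(gA = "a1", gB = "b1"))
  sim <- sim_tab(sim_row("a1_p", "b1_p", 500), sim_row("b1_p", "a1_p", 500))
  pairs <- best_bidirectional_hits(sim, reg, "gA", "gB")
  pairs <- confirm_context(pairs, reg)
  expect_false(any(pairs$context_confirmed))
})

test_that("presence matrix is invariant to similarity row order", {
  panel <- the_small_panel()
  reg <- panel$registry
  orth1 <- panel_orthologs(reg, panel$similarity)
  set.seed(3)
  shuffled <- panel$similarity[sample(nrow(panel$similarity)), ]
  orth2 <- panel_orthologs(reg, read_similarity(shuffled))
  p1 <- call_reductases(reg, orth1, panel$catalog)$presence
  p2 <- call_reductases(reg, orth2, panel$catalog)$presence
  expect_identical(p1, p2)
})

test_that("presence requires catalytic subunits and counts distinct copies", {
  panel <- the_small_panel()
  reg <- panel$registry
  orth <- panel_orthologs(reg, panel$similarity)
  res <- call_reductases(reg, orth, panel$catalog)
  gt <- panel$ground_truth
  expect_identical(res$presence[rownames(gt$presence), colnames(gt$presence)],
                   gt$presence)
  amp <- gt$audit$amplified_genome
  expect_equal(res$presence[amp, "Dms"], 3L)  # planted copy number
  # a genome with zero catalog orthologs has an empty row
  none_row <- gt$genomes$genome_id[gt$genomes$pattern == "anaer_inc"][1]
  expect_equal(sum(res$presence[none_row, ]), 0L)
})
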