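operon_registry <- function(starts, ends, strands) {
  n <- length(starts)
  genomes <- data.frame(id = "gA", taxon = "t", species = "s", genus = "g",
                        status = "finished", length_bp = 1e6)
  genes <- data.frame(id = sprintf("a%d", seq_len(n)), genome_id = "gA",
                      contig = "c1", start = starts, end = ends,
                      strand = strands,
                      protein_id = sprintf("a%d_p", seq_len(n)))
  proteins <- data.frame(id = genes$protein_id, gene_id = genes$id,
                         signal_peptide = FALSE, tm_segments = 0L,
                         compartment = "unknown")
  domains <- data.frame(protein_id = character(0), family = character(0))
  new_registry(genomes, genes, proteins, domains)
}

test_that("operon prediction follows the strand and gap rules", {
  # gap 120 <= 300: one operon
  reg <- operon_registry(c(1000, 2021), c(1900, 2900), c("+", "+"))
  expect_length(unique(predict_operons(reg, "gA")$operon_id), 1L)
  # strand flip splits
  reg <- operon_registry(c(1000, 2021), c(1900, 2900), c("+", "-"))
  expect_length(unique(predict_operons(reg, "gA")$operon_id), 2L)
  # gap 500 > 300 splits
  reg <- operon_registry(c(1000, 2401), c(1900, 3300), c("+", "+"))
  expect_length(unique(predict_operons(reg, "gA")$operon_id), 2L)
  # and survives with a larger threshold
  expect_length(unique(predict_operons(reg, "gA",
                                       max_gap_bp = 600)$operon_id), 1L)
})

test_that("the cascade reproduces its planted stage sets", {
  panel <- the_small_panel()
  gt <- panel$ground_truth$cascade
  tr <- run_cascade(panel$registry, gt$host, panel$keyword_families)
  expect_identical(tr$candidate_proteins, gt$candidates)
  expect_identical(tr$localization_passed, gt$localization_pass)
  expect_identical(tr$context_passed, gt$context_pass)
  expect_equal(unname(tr$counts[c("candidates", "localization", "context")]),
               unname(panel$spec$cascade[c("candidates", "localization_pass",
                                           "context_pass")]))
})

test_that("each cascade stage is a subset of the one before", {
  panel <- the_small_panel()
  gt <- panel$ground_truth$cascade
  tr <- run_cascade(panel$registry, gt$host, panel$keyword_families)
  expect_true(all(tr$localization_passed %in% tr$candidate_proteins))
  expect_true(all(tr$context_passed %in% tr$localization_passed))
  expect_true(tr$counts[["context"]] <= tr$counts[["localization"]])
  expect_true(tr$counts[["localization"]] <= tr$counts[["candidates"]])
})

test_that("stage 2 removes candidates without signal or TM, stage 3 those
           without an operon partner", {
  panel <- the_small_panel()
  reg <- panel$registry
  gt <- panel$ground_truth$cascade
  tr <- run_cascade(reg, gt$host, panel$keyword_families)
  dropped2 <- setdiff(tr$candidate_proteins, tr$localization_passed)
  p <- reg$proteins[match(dropped2, reg$proteins$id), ]
  expect_true(all(!p$signal_peptide & p$tm_segments == 0))
  dropped3 <- setdiff(tr$localization_passed, tr$context_passed)
  ops <- predict_operons(reg, gt$host)
  for (pid in dropped3) {
    op <- ops$operon_id[ops$protein_id == pid]
    mates <- setdiff(ops$protein_id[ops$operon_id %in% op], pid)
    fams <- reg$domains$family[reg$domains$protein_id %in% mates]
    expect_false("PF00578" %in% fams)
  }
})

test_that("an empty keyword set yields an empty, non-erroring trace", {
  panel <- the_small_panel()
  tr <- run_cascade(panel$registry, panel$ground_truth$cascade$host,
                    character(0))
  expect_length(tr$candidate_proteins, 0)
  expect_length(tr$context_passed, 0)
})

test_that("the cascade is invariant to gene input order", {
  panel <- the_small_panel()
  reg <- panel$registry
  gt <- panel$ground_truth$cascade
  set.seed(8)
  reg2 <- reg
  reg2$genes <- reg$genes[sample(nrow(reg$genes)), ]
  reg2$proteins <- reg$proteins[sample(nrow(reg$proteins)), ]
  reg2$domains <- reg$domains[sample(nrow(reg$domains)), ]
  t1 <- run_cascade(reg, gt$host, panel$keyword_families)
  t2 <- run_cascade(reg2, gt$host, panel$keyword_families)
  expect_identical(t1$candidate_proteins, t2$candidate_proteins)
  expect_identical(t1$localization_passed, t2$localization_passed)
  expect_identical(t1$context_passed, t2$context_passed)
})

test_that("co-occurrence keeps 5/5-strain operons and drops 4/5", {
  panel <- the_small_panel()
  reg <- panel$registry
  gt <- panel$ground_truth
  host <- gt$cascade$host
  ops <- predict_operons(reg, host)
  tr <- run_cascade(reg, host, panel$keyword_families)
  ctx_ops <- unique(ops$operon_id[ops$protein_id %in% tr$context_passed])
  surv <- cooccurrence_filter(reg, ops, ctx_ops,
                              setdiff(gt$strains, host), panel$similarity)
  expect_length(surv, 2L)
  # the dropped operon is the one holding the strain-absent candidate
  dropped <- setdiff(ctx_ops, surv)
  expect_equal(ops$protein_id[ops$operon_id == dropped][1],
               gt$cascade$op_prots[[host]]$op3[1])
})

test_that("an empty strain panel keeps every operon (vacuous universal)", {
  panel <- the_small_panel()
  ops <- predict_operons(panel$registry, panel$ground_truth$cascade$host)
  all_ops <- unique(ops$operon_id)
  expect_identical(
    cooccurrence_filter(panel$registry, ops, all_ops, character(0),
                        panel$similarity),
    all_ops)
})

test_that("growing the strain panel only shrinks the surviving set", {
  panel <- the_small_panel()
  reg <- panel$registry
  gt <- panel$ground_truth
  host <- gt$cascade$host
  ops <- predict_operons(reg, host)
  others <- setdiff(gt$strains, host)
  kept_prev <- NULL
  for (k in seq_along(others)) {
    kept <- cooccurrence_filter(reg, ops, unique(ops$operon_id),
                                others[seq_len(k)], panel$similarity)
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("orphan accessory operons are flagged by the planted footprint", {
  panel <- the_small_panel()
  gt <- panel$ground_truth
  orp <- orphan_accessory_scan(panel$registry, panel$catalog)
  expect_equal(nrow(orp), 1L)
  expect_equal(orp$genome_id, gt$audit$orphan_genome)
  expect_equal(orp$catalog_entry, "Nos")
  expect_equal(orp$candidate_catalytic, gt$audit$orphan_candidate)
  expect_gte(orp$n_accessory, 2)
})

test_that("full complements and single accessories never flag", {
  # an operon with the complete entry, catalytic subunit included
  genomes <- data.frame(id = "gA", taxon = "t", species = "s", genus = "g",
                        status = "finished", length_bp = 1e6)
  mk <- function(i, fam) {
    list(gene = data.frame(id = sprintf("a%d", i), genome_id = "gA",
                           contig = "c1", start = i * 1000L,
                           end = i * 1000L + 800L, strand = "+",
                           protein_id = sprintf("a%d_p", i)),
         dom = if (is.na(fam)) NULL else
           data.frame(protein_id = sprintf("a%d_p", i), family = fam))
  }
  full <- lapply(seq_along(c("FAM_NOSZ", "FAM_NOSD", "FAM_NOSL",
                             "FAM_CYTC552")), function(i)
    mk(i, c("FAM_NOSZ", "FAM_NOSD", "FAM_NOSL", "FAM_CYTC552")[i]))
  genes <- do.call(rbind, lapply(full, `[[`, "gene"))
  doms <- do.call(rbind, lapply(full, `[[`, "dom"))
  proteins <- data.frame(id = genes$protein_id, gene_id = genes$id,
                         signal_peptide = FALSE, tm_segments = 0L,
                         compartment = "unknown")
  reg <- new_registry(genomes, genes, proteins, doms)
  expect_equal(nrow(orphan_accessory_scan(reg, the_catalog(),
                                          genomes = "gA")), 0L)
  # one accessory homolog only: below the complex threshold
  one <- lapply(1:2, function(i) mk(i, c("FAM_NOSD", "FAM_CYTC552")[i]))
  genes1 <- do.call(rbind, lapply(one, `[[`, "gene"))
  doms1 <- do.call(rbind, lapply(one, `[[`, "dom"))
  proteins1 <- data.frame(id = genes1$protein_id, gene_id = genes1$id,
                          signal_peptide = FALSE, tm_segments = 0L,
                          compartment = "unknown")
  reg1 <- new_registry(genomes, genes1, proteins1, doms1)
  expect_equal(nrow(orphan_accessory_scan(reg1, the_catalog(),
                                          genomes = "gA")), 0L)
})
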