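test_that("profiles map enzymes onto steps with mode and transporter tags", {
  cat_ <- the_catalog()
  # nitrate reductase plus antiporter: one producing step, transporter noted
  p <- profile_of(cat_, "Nar", "NarK")
  expect_equal(p$steps$NO3_to_NO2$enzyme, "Nar")
  expect_equal(p$steps$NO3_to_NO2$mode, "respiratory")
  expect_equal(p$transporters, "NarK")
  expect_equal(nrow(p$steps$NO2_to_NH3), 0L)
  # periplasmic nitrite reductase only
  p2 <- profile_of(cat_, "Nrf")
  expect_equal(p2$steps$NO2_to_NH3$enzyme, "Nrf")
  expect_equal(nrow(p2$steps$NO3_to_NO2), 0L)
  # assimilatory enzymes carry the assimilatory tag
  p3 <- profile_of(cat_, "NirBD")
  expect_equal(p3$steps$NO2_to_NH3$mode, "assimilatory")
  # empty complement, empty profile
  p0 <- profile_of(cat_)
  expect_true(all(vapply(p0$steps, nrow, 0L) == 0L))
  expect_length(p0$transporters, 0)
})

test_that("route completeness classifies ammonification and denitrification", {
  cat_ <- the_catalog()
  expect_equal(classify_pathway(profile_of(cat_, "Nar", "Nrf"))$class,
               "complete_ammonification")
  expect_equal(classify_pathway(profile_of(cat_, "Nar", "NirK", "Nor",
                                           "Nos"))$class,
               "complete_denitrification")
  r <- classify_pathway(profile_of(cat_, "Nar", "Nor"))
  expect_equal(r$class, "partial")
  expect_true("NO2_to_NO" %in% r$missing$denitrification)
  expect_equal(classify_pathway(profile_of(cat_))$class, "none")
  # assimilatory enzymes do not complete a respiratory route by default
  expect_equal(classify_pathway(profile_of(cat_, "Nar", "NirBD"))$class,
               "partial")
})

micro_classes <- function(profiles) {
  data.frame(genome_id = names(profiles),
             class = "microaerophilic",
             has_microaerobic = TRUE,
             stringsAsFactors = FALSE)
}

test_that("complementary partial pathways exchange their intermediate", {
  cat_ <- the_catalog()
  profs <- list(
    lacto = profile_of(cat_, "Nar", "NarK", genome_id = "lacto"),
    bact = profile_of(cat_, "Nrf", genome_id = "bact"))
  e <- infer_exchange_network(profs, micro_classes(profs))
  expect_equal(nrow(e), 1L)
  expect_equal(e$producer, "lacto")
  expect_equal(e$metabolite, "nitrite")
  expect_equal(e$consumer, "bact")
  # nitrate -> nitric oxide producer feeding a NO -> N2O consumer
  profs2 <- list(
    odonto = profile_of(cat_, "Nar", "NirK", genome_id = "odonto"),
    veill = profile_of(cat_, "Nar", "Nor", genome_id = "veill"))
  e2 <- infer_exchange_network(profs2, micro_classes(profs2))
  expect_true(any(e2$producer == "odonto" & e2$metabolite == "nitric_oxide" &
                    e2$consumer == "veill"))
})

test_that("self-sufficient communities produce no edges", {
  cat_ <- the_catalog()
  profs <- list(a = profile_of(cat_, "Nar", "Nrf", genome_id = "a"),
                b = profile_of(cat_, "Nar", "NirK", "Nor", "Nos",
                               genome_id = "b"))
  e <- infer_exchange_network(profs, micro_classes(profs))
  expect_equal(nrow(e), 0L)
})

test_that("assimilatory enzymes block self-sufficiency but never produce", {
  cat_ <- the_catalog()
  # NirBD consumes nitrite assimilatorily: the genome is not a producer
  # candidate's valid partner, and NasBA alone never makes a producer
  profs <- list(
    nar_nirbd = profile_of(cat_, "Nar", "NirBD", genome_id = "nar_nirbd"),
    nasba = profile_of(cat_, "NasBA", genome_id = "nasba"),
    bact = profile_of(cat_, "Nrf", genome_id = "bact"))
  e <- infer_exchange_network(profs, micro_classes(profs))
  expect_false("nar_nirbd" %in% e$producer)  # it can consume its nitrite
  expect_false("nasba" %in% e$producer)      # assimilatory production
  expect_equal(nrow(e), 0L)
})

test_that("exchange requires shared oxygen habitat", {
  cat_ <- the_catalog()
  profs <- list(lacto = profile_of(cat_, "Nar", genome_id = "lacto"),
                bact = profile_of(cat_, "Nrf", genome_id = "bact"))
  cls <- data.frame(genome_id = c("lacto", "bact"),
                    class = c("microaerophilic", "anaerobic"),
                    has_microaerobic = c(TRUE, FALSE))
  expect_equal(nrow(infer_exchange_network(profs, cls)), 0L)
  cls2 <- transform(cls, class = "anaerobic", has_microaerobic = FALSE)
  expect_equal(nrow(infer_exchange_network(profs, cls2)), 1L)
  # and the eligibility set is honoured
  expect_equal(nrow(infer_exchange_network(profs, cls2,
                                           eligibility = "microaerobic")),
               0L)
})

test_that("mismatched genome sets are an error", {
  cat_ <- the_catalog()
  profs <- list(a = profile_of(cat_, "Nar", genome_id = "a"))
  cls <- data.frame(genome_id = c("a", "b"), class = "anaerobic",
                    has_microaerobic = FALSE)
  expect_error(infer_exchange_network(profs, cls), "different genome sets")
})

test_that("edges match the brute-force oracle over random communities", {
  cat_ <- the_catalog()
  pool <- c("Nar", "Nap", "Nrf", "NirK", "Nor", "Nos", "NirBD", "NasBA",
            "NarK", "Cyd", "Frd")
  set.seed(19)
  for (rep in 1:25) {
    k <- sample(3:8, 1)
    profs <- list()
    cls <- NULL
    for (i in seq_len(k)) {
      g <- sprintf("g%02d", i)
      on <- pool[runif(length(pool)) < 0.35]
      profs[[g]] <- profile_of(cat_, on, genome_id = g)
      cls <- rbind(cls, data.frame(
        genome_id = g,
        class = sample(c("microaerophilic", "anaerobic",
                         "at_least_microaerophilic",
                         "most_likely_anaerobic", "aerophilic"), 1),
        has_microaerobic = "Cyd" %in% on))
    }
    e <- infer_exchange_network(profs, cls)
    expect_identical(edge_keys(e), oracle_exchange(profs, cls))
  }
})

test_that("removing a genome never creates edges among the rest", {
  cat_ <- the_catalog()
  pool <- c("Nar", "Nrf", "NirK", "Nor", "NirBD", "Cyd")
  set.seed(23)
  for (rep in 1:10) {
    profs <- list(); cls <- NULL
    for (i in 1:6) {
      g <- sprintf("g%02d", i)
      on <- pool[runif(length(pool)) < 0.4]
      profs[[g]] <- profile_of(cat_, on, genome_id = g)
      cls <- rbind(cls, data.frame(genome_id = g, class = "microaerophilic",
                                   has_microaerobic = TRUE))
    }
    full <- edge_keys(infer_exchange_network(profs, cls))
    drop <- sample(names(profs), 1)
    sub <- edge_keys(infer_exchange_network(
      profs[setdiff(names(profs), drop)],
      cls[cls$genome_id != drop, ]))
    expect_true(all(sub %in% full))
  }
})

test_that("nitrous-oxide edges appear only behind the flag", {
  cat_ <- the_catalog()
  profs <- list(v = profile_of(cat_, "Nar", "NirK", "Nor", genome_id = "v"),
                r = profile_of(cat_, "Nos", genome_id = "r"))
  cls <- micro_classes(profs)
  e0 <- infer_exchange_network(profs, cls)
  expect_false("nitrous_oxide" %in% e0$metabolite)
  e1 <- infer_exchange_network(profs, cls, include_n2o = TRUE)
  expect_true(any(e1$metabolite == "nitrous_oxide" & e1$producer == "v" &
                    e1$consumer == "r"))
})

test_that("edge tables serialize to TSV and GraphML", {
  e <- data.frame(producer = "a", metabolite = "nitrite", consumer = "b")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_exchange_tsv(e, tsv)
  expect_equal(utils::read.delim(tsv)$producer, "a")
  write_exchange_graphml(e, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 1)
})
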