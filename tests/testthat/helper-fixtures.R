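# Shared fixtures and independent oracles for the test suite.

# A reduced panel spec with the same structure as the full study conditions
# but 20 genomes, so oracle-equivalence checks stay fast.
small_spec <- function(seed = 7) {
  panel_spec(
    seed = seed,
    n_finished = 10, n_probably_complete = 6, n_incomplete = 4,
    classes_complete = c(aerophilic = 2, microaerophilic = 10,
                         anaerobic = 4),
    classes_incomplete = c(aerophilic = 1, microaerophilic = 2,
                           anaerobic = 1),
    strong_microaerobes = 6,
    aerophilic_without_micro = 1,
    pathway_mix = c(ammonification = 1, denitrification = 1,
                    nitrate_only = 1, nitrite_ammonia_only = 2,
                    nitrate_to_no = 1, nitrate_and_no_to_n2o = 0,
                    no_to_n2o_only = 0),
    label_groups = c(both = 8, metadata_only = 8, assertion_only = 2,
                     none = 2),
    both_consistent_metadata = 6,
    metadata_only_consistent = 6,
    cascade = c(keyword_families = 20, families_with_hits = 10,
                candidates = 12, localization_pass = 5, context_pass = 3),
    n_strains = 5,
    amplified = c(Dms = 3),
    n_16s_tier = 2)
}

# generated once per test run and reused read-only
the_small_panel <- local({
  panel <- NULL
  function() {
    if (is.null(panel)) {
      panel <<- generate_panel(small_spec())
      panel$registry <<- assess_completeness(panel$registry,
                                             panel$relatedness)
    }
    panel
  }
})

# hand-built two-genome registry for orthology unit tests:
# each genome one contig, genes in the listed order, 100 bp apart
toy_registry <- function(genome_genes, statuses = NULL) {
  genomes <- data.frame(
    id = names(genome_genes),
    taxon = names(genome_genes), species = names(genome_genes),
    genus = names(genome_genes),
    status = statuses %||% rep("finished", length(genome_genes)),
    length_bp = 1e6, stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(names(genome_genes), function(g) {
    ids <- genome_genes[[g]]
    n <- length(ids)
    data.frame(id = ids, genome_id = g, contig = "c1",
               start = seq_len(n) * 1000L,
               end = seq_len(n) * 1000L + 800L,
               strand = "+", protein_id = paste0(ids, "_p"),
               stringsAsFactors = FALSE)
  }))
  proteins <- data.frame(id = genes$protein_id, gene_id = genes$id,
                         signal_peptide = FALSE, tm_segments = 0L,
                         compartment = "unknown", stringsAsFactors = FALSE)
  domains <- data.frame(protein_id = character(0), family = character(0),
                        stringsAsFactors = FALSE)
  new_registry(genomes, genes, proteins, domains)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sim_tab <- function(...) {
  read_similarity(do.call(rbind, list(...)))
}

sim_row <- function(q, s, bits, ev = 10^(-bits / 5)) {
  data.frame(query = q, subject = s, bitscore = bits, evalue = ev,
             stringsAsFactors = FALSE)
}

# ---- independent oracles ------------------------------------------------

# brute-force BBH: literal double loop over the definition
oracle_bbh <- function(similarity, prots_a, prots_b, cutoff = 1e-20) {
  best_of <- function(q, subjects) {
    s <- similarity[similarity$query == q &
                      similarity$subject %in% subjects, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    s <- s[order(-s$bitscore, s$subject), , drop = FALSE]
    s[1, ]
  }
  out <- list()
  for (a in prots_a) {
    ba <- best_of(a, prots_b)
    if (is.null(ba)) next
    bb <- best_of(ba$subject, prots_a)
    if (is.null(bb) || bb$subject != a) next
    if (ba$evalue <= cutoff && bb$evalue <= cutoff) {
      out[[length(out) + 1L]] <- c(a = a, b = ba$subject)
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, function(p) paste(sort(p), collapse = "|"), ""))
}

# brute-force exchange edges: literal restatement of the edge rule
oracle_exchange <- function(profiles, classes,
                            eligibility = c("microaerobic", "anaerobic")) {
  step_has <- function(p, s, resp_only = FALSE) {
    df <- p$steps[[s]]
    if (resp_only) any(df$mode == "respiratory") else nrow(df) > 0
  }
  mets <- list(nitrite = list(prod = "NO3_to_NO2",
                              cons = c("NO2_to_NH3", "NO2_to_NO")),
               nitric_oxide = list(prod = "NO2_to_NO", cons = "NO_to_N2O"))
  cls <- classes[match(names(profiles), classes$genome_id), ]
  micro <- cls$has_microaerobic |
    cls$class %in% c("microaerophilic", "at_least_microaerophilic")
  anaer <- cls$class %in% c("anaerobic", "most_likely_anaerobic")
  names(micro) <- names(anaer) <- names(profiles)
  edges <- character(0)
  for (m in names(mets)) {
    for (P in names(profiles)) {
      for (C in names(profiles)) {
        if (P == C) next
        pp <- profiles[[P]]; pc <- profiles[[C]]
        is_prod <- step_has(pp, mets[[m]]$prod, resp_only = TRUE) &&
          !any(vapply(mets[[m]]$cons, function(s) step_has(pp, s), NA))
        is_cons <- any(vapply(mets[[m]]$cons, function(s)
          step_has(pc, s, resp_only = TRUE), NA)) &&
          !step_has(pc, mets[[m]]$prod)
        cohab <- ("microaerobic" %in% eligibility && micro[P] && micro[C]) ||
          ("anaerobic" %in% eligibility && anaer[P] && anaer[C])
        if (is_prod && is_cons && cohab) {
          edges <- c(edges, paste(P, m, C, sep = "|"))
        }
      }
    }
  }
  sort(edges)
}

edge_keys <- function(edges) {
  sort(paste(edges$producer, edges$metabolite, edges$consumer, sep = "|"))
}

# presence row helper over the shipped catalog
presence_row <- function(catalog, ...) {
  on <- c(...)
  r <- stats::setNames(rep(0L, length(catalog)), names(catalog))
  r[on] <- 1L
  r
}

# profile straight from a list of present entries
profile_of <- function(catalog, ..., genome_id = "g") {
  pathway_profile(presence_row(catalog, ...), catalog, genome_id)
}

the_catalog <- local({
  cat_ <- NULL
  function() {
    if (is.null(cat_)) cat_ <<- read_catalog()
    cat_
  }
})
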