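#' Audit one called reductase instance for subunit-role completeness
#'
#' Respiratory reductases are combinatorial assemblies ("Lego" principle):
#' the same catalytic subunit appears with different partner sets in
#' different genomes. The audit reports which catalog roles are matched,
#' predicts the complex localization from the members' features (membrane
#' when any member has a transmembrane segment, extracellular when any has
#' a signal peptide but none a TM segment, cytoplasmic otherwise), and
#' flags soluble variants: a catalytic subunit present while every
#' membrane-anchor role of an entry that defines one is absent. When the
#' missing anchors do exist elsewhere in the genome (unlinked from this
#' instance), the flag is downgraded to "distally_encoded". The audit never
#' changes presence calls; it only annotates them.
#'
#' @param instance data.frame of this instance's matched subunits:
#'   `protein_id`, `role`.
#' @param catalog_entry one entry of a `gutresp_catalog`.
#' @param registry a `gutresp_registry` (localization features and the
#'   genome-wide anchor search).
#' @param genome_id genome of the instance (for the distal search); NA skips
#'   that search.
#' @return list: `roles_present`, `roles_absent`, `localization`,
#'   `soluble_variant`, `status` ("ok", "soluble_variant",
#'   "distally_encoded").
#' @export
audit_complex <- function(instance, catalog_entry, registry,
                          genome_id = NA_character_) {
  roles_defined <- unique(catalog_entry$subunits$role)
  roles_present <- unique(instance$role)
  roles_absent <- setdiff(roles_defined, roles_present)
  p <- registry$proteins[match(instance$protein_id, registry$proteins$id), ,
                         drop = FALSE]
  if (anyNA(p$id)) stop("instance protein missing from registry",
                        call. = FALSE)
  localization <- if (any(p$tm_segments >= 1)) {
    "membrane"
  } else if (any(p$signal_peptide)) {
    "extracellular"
  } else {
    "cytoplasmic"
  }
  anchors_defined <- "membrane_anchor" %in% roles_defined
  soluble <- anchors_defined &&
    "catalytic" %in% roles_present &&
    !"membrane_anchor" %in% roles_present
  status <- "ok"
  if (soluble) {
    status <- "soluble_variant"
    if (!is.na(genome_id)) {
      anchor_fams <- catalog_families(catalog_entry, "membrane_anchor")
      pg <- protein_genome_map(registry)
      gprots <- names(pg)[pg == genome_id]
      dom <- registry$domains
      distal <- dom$protein_id[dom$family %in% anchor_fams &
                                 dom$protein_id %in% gprots]
      distal <- setdiff(distal, instance$protein_id)
      if (length(distal)) status <- "distally_encoded"
    }
  }
  list(roles_present = sort(roles_present),
       roles_absent = sort(roles_absent),
       localization = localization,
       soluble_variant = soluble,
       status = status)
}

# subunits of one (genome, reductase) call grouped by operon of the
# catalytic copy: the catalytic protein plus co-operonic matched subunits
instance_subunits <- function(calls, registry, genome_id, reductase,
                              catalytic_protein, max_gap_bp = 300) {
  sub <- calls[calls$genome_id == genome_id &
                 calls$reductase == reductase, , drop = FALSE]
  ops <- predict_operons(registry, genome_id, max_gap_bp)
  my_op <- ops$operon_id[ops$protein_id == catalytic_protein]
  mates <- ops$protein_id[ops$operon_id %in% my_op]
  sub <- sub[sub$protein_id %in% mates, , drop = FALSE]
  unique(rbind(
    data.frame(protein_id = catalytic_protein, role = "catalytic",
               stringsAsFactors = FALSE),
    sub[, c("protein_id", "role")]))
}

#' Audit every called reductase instance of a panel
#'
#' One audit row per catalytic-subunit copy; subunits are grouped with the
#' catalytic copy by operon membership, so paralogous copies in one genome
#' are audited separately.
#'
#' @param registry a `gutresp_registry`.
#' @param calls `calls` data.frame from [call_reductases()].
#' @param catalog a `gutresp_catalog`.
#' @param max_gap_bp operon gap rule.
#' @return data.frame: `genome_id`, `reductase`, `catalytic_protein`,
#'   `roles_present`, `roles_absent` (comma-separated), `localization`,
#'   `soluble_variant`, `status`.
#' @export
audit_panel <- function(registry, calls, catalog, max_gap_bp = 300) {
  cat_calls <- unique(calls[calls$role == "catalytic",
                            c("genome_id", "reductase", "protein_id")])
  rows <- lapply(seq_len(nrow(cat_calls)), function(i) {
    gid <- cat_calls$genome_id[i]
    red <- cat_calls$reductase[i]
    inst <- instance_subunits(calls, registry, gid, red,
                              cat_calls$protein_id[i], max_gap_bp)
    a <- audit_complex(inst, catalog[[red]], registry, gid)
    data.frame(genome_id = gid, reductase = red,
               catalytic_protein = cat_calls$protein_id[i],
               roles_present = paste(a$roles_present, collapse = ","),
               roles_absent = paste(a$roles_absent, collapse = ","),
               localization = a$localization,
               soluble_variant = a$soluble_variant,
               status = a$status,
               stringsAsFactors = FALSE)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(0), reductase = character(0),
               catalytic_protein = character(0),
               roles_present = character(0), roles_absent = character(0),
               localization = character(0), soluble_variant = logical(0),
               status = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Detect duplicated catalytic subunits with divergent localization
#'
#' For a reductase with two or more catalytic-subunit copies in one genome,
#' reports every (membrane-associated copy, cytoplasmic copy) pair -- the
#' pattern left by duplication of a membrane-bound ancestor into a
#' cytoplasmic copy, a candidate assimilatory duplicate.
#'
#' @param registry a `gutresp_registry`.
#' @param calls `calls` data.frame from [call_reductases()].
#' @param catalog a `gutresp_catalog`.
#' @param genome_id genome to inspect.
#' @param reductase catalog entry name.
#' @param max_gap_bp operon gap rule.
#' @return data.frame `membrane_copy`, `cytoplasmic_copy` (protein ids),
#'   annotated `candidate = "assimilatory_duplicate"`; empty when fewer
#'   than two copies or no split.
#' @export
detect_paralog_localization_split <- function(registry, calls, catalog,
                                              genome_id, reductase,
                                              max_gap_bp = 300) {
  empty <- data.frame(membrane_copy = character(0),
                      cytoplasmic_copy = character(0),
                      candidate = character(0), stringsAsFactors = FALSE)
  copies <- unique(calls$protein_id[calls$genome_id == genome_id &
                                      calls$reductase == reductase &
                                      calls$role == "catalytic"])
  if (length(copies) < 2L) return(empty)
  loc <- vapply(copies, function(p) {
    inst <- instance_subunits(calls, registry, genome_id, reductase, p,
                              max_gap_bp)
    audit_complex(inst, catalog[[reductase]], registry, genome_id)$localization
  }, "")
  memb <- copies[loc %in% c("membrane", "extracellular")]
  cyto <- copies[loc == "cytoplasmic"]
  if (!length(memb) || !length(cyto)) return(empty)
  out <- expand.grid(membrane_copy = memb, cytoplasmic_copy = cyto,
                     stringsAsFactors = FALSE)
  out$candidate <- "assimilatory_duplicate"
  out
}
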