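#' Respiratory reductase catalog
#'
#' The catalog describes every reductase type the pipeline can call: its
#' oxygen category (aerobic, microaerobic, anaerobic, or `none` for
#' assimilatory enzymes, transporters and hydrogenases that must exist for
#' pathway profiling but never enter oxygen classification), its substrate,
#' the subunit composition with roles, and an optional nitrogen-oxide pathway
#' step tag. Subunits are matched to proteins through domain-family
#' accessions; each entry must declare at least one catalytic subunit.
#'
#' The default catalog shipped in `inst/extdata/catalog.yaml` seeds the
#' reductase types discussed for the human gut panel (Cyd, Cyf, Cyo, Qox,
#' Cta, Cco, Frd, Nar, Nap, Nrf, NirK, Nor, Nos, Dms, Tor, Ttr, Phs, Tsr,
#' Ynf, Asr, Apr, Hdr, Arr, plus assimilatory NirBD/NasBA and the NarK
#' transporter). Users extend it by editing the YAML.
#'
#' @param path path to a YAML catalog file; default ships with the package.
#' @return an object of class `gutresp_catalog`: a named list of entries,
#'   each a list with `name`, `category`, `substrate`, `mode`,
#'   `pathway_step` (or NULL) and a `subunits` data.frame with columns
#'   `role` and `family`.
#' @export
read_catalog <- function(path = system.file("extdata", "catalog.yaml",
                                            package = "gutresp")) {
  raw <- yaml::read_yaml(path)
  entries <- raw$reductases
  if (is.null(entries) || length(entries) == 0L) {
    stop("catalog has no 'reductases' entries", call. = FALSE)
  }
  out <- lapply(entries, validate_catalog_entry)
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out))) {
    stop_listing("duplicated catalog entry names",
                 names(out)[duplicated(names(out))])
  }
  structure(out, class = "gutresp_catalog")
}

catalog_categories <- c("aerobic", "microaerobic", "anaerobic", "none")
catalog_roles <- c("catalytic", "membrane_anchor", "electron_transfer",
                   "maturation")
pathway_steps <- c("NO3_to_NO2", "NO2_to_NH3", "NO2_to_NO", "NO_to_N2O",
                   "N2O_to_N2")

validate_catalog_entry <- function(e) {
  if (is.null(e$name) || !nzchar(e$name)) {
    stop("catalog entry without a name", call. = FALSE)
  }
  if (is.null(e$category) || !e$category %in% catalog_categories) {
    stop("catalog entry '", e$name, "': unknown category '",
         e$category %||% "<missing>", "' (allowed: ",
         paste(catalog_categories, collapse = ", "), ")", call. = FALSE)
  }
  subs <- e$subunits
  if (is.null(subs) || length(subs) == 0L) {
    stop("catalog entry '", e$name, "' has no subunits", call. = FALSE)
  }
  subs <- data.frame(
    role = vapply(subs, function(s) s$role %||% NA_character_, ""),
    family = vapply(subs, function(s) s$family %||% NA_character_, ""),
    stringsAsFactors = FALSE
  )
  if (anyNA(subs$role) || anyNA(subs$family)) {
    stop("catalog entry '", e$name, "': every subunit needs role and family",
         call. = FALSE)
  }
  bad <- setdiff(subs$role, catalog_roles)
  if (length(bad)) {
    stop("catalog entry '", e$name, "': unknown subunit role(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!any(subs$role == "catalytic")) {
    stop("catalog entry '", e$name, "' lacks a catalytic subunit",
         call. = FALSE)
  }
  step <- e$pathway_step
  if (!is.null(step) && !step %in% c(pathway_steps, "transporter")) {
    stop("catalog entry '", e$name, "': unknown pathway_step '", step, "'",
         call. = FALSE)
  }
  list(name = e$name,
       category = e$category,
       substrate = e$substrate %||% NA_character_,
       mode = e$mode %||% "respiratory",
       pathway_step = step,
       subunits = subs)
}

#' @export
print.gutresp_catalog <- function(x, ...) {
  cat("Reductase catalog:", length(x), "entries\n")
  cats <- vapply(x, `[[`, "", "category")
  for (cc in catalog_categories) {
    nm <- names(x)[cats == cc]
    if (length(nm)) cat(sprintf("  %-12s %s\n", cc, paste(nm, collapse = " ")))
  }
  invisible(x)
}

# families of a role (or all roles but catalytic when role = "accessory")
catalog_families <- function(entry, role = NULL) {
  subs <- entry$subunits
  if (is.null(role)) return(unique(subs$family))
  if (identical(role, "accessory")) {
    return(unique(subs$family[subs$role != "catalytic"]))
  }
  unique(subs$family[subs$role %in% role])
}

# entry names of a given oxygen category present in a presence row
present_of_category <- function(presence_row, catalog, category) {
  present <- names(presence_row)[presence_row > 0]
  present[vapply(catalog[present], function(e) e$category == category,
                 NA)]
}
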