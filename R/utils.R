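#' Round half away from zero
#'
#' Commercial ("round half up") rounding at a fixed number of decimals, used
#' for every percentage the package reports. Base R's `round()` rounds half to
#' even, which would print 11.45 as 11.4; reported percentages here always
#' carry the half up.
#'
#' @param x numeric vector.
#' @param digits integer, decimals to keep.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 11.45), 0:1 * 0 + 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with fixed rounding
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimals (default 1, the reporting convention).
#' @return numeric percentage rounded half-up.
#' @export
percentage <- function(num, den, digits = 1) {
  stopifnot(den > 0)
  round_half_up(100 * num / den, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a bullet list of offending items
stop_listing <- function(msg, items, n_show = 10L) {
  items <- as.character(items)
  shown <- utils::head(items, n_show)
  more <- length(items) - length(shown)
  stop(msg, ":\n  - ", paste(shown, collapse = "\n  - "),
       if (more > 0) paste0("\n  (and ", more, " more)"),
       call. = FALSE)
}

# deterministic RNG scope: run expr under a seed, restore global state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
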