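# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so simulation internals never disturb
#' the caller's RNG stream. All table generators draw through this, each with
#' a fixed offset from the master scenario seed, so tables can be regenerated
#' independently and reproducibly.
#'
#' @param seed integer seed (kept below 2^31 by callers).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a small fixed offset, staying
# inside the 32-bit signed integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}

#' Ten-year age band index from age in years
#'
#' Bands are `[0,10), [10,20), ..., [80,90), [90, Inf)`, indexed 0..9.
#' Ages are computed at an index day as `(day - birth_day) / 365.25`.
#'
#' @param age_years numeric vector of ages.
#' @return integer band index in 0..9.
#' @export
age_band <- function(age_years) {
  pmin(9L, pmax(0L, as.integer(floor(age_years / 10))))
}

#' @rdname age_band
#' @param band integer band index.
#' @return character label such as `"40-49"` or `"90+"`.
#' @export
age_band_label <- function(band) {
  ifelse(band >= 9L, "90+", paste0(band * 10L, "-", band * 10L + 9L))
}

# Length of the overlap of two half-open integer day intervals [a0, a1) and
# [b0, b1), in days.
overlap_days <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30L   # accrual months are 30-day blocks from surveillance start

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
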