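# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates, and restores the caller's RNG state so that
#' generators are pure functions of (spec, seed) without clobbering the
#' global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stream of child seeds from one parent seed
#'
#' Children stay below 2^31 so they remain valid R integers.
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

#' Canonical resting-state network symbols
#'
#' The 14 canonical resting-state networks used as channel labels throughout
#' the package, in alphabetical symbol order: auditory (AN), anterior
#' salience (aSN), basal ganglia (BGN), dorsal default mode (dDMN), high
#' visual (HVN), left executive control (LECN), language (LN), precuneus
#' (PCN), posterior salience (pSN), primary visual (PVN), right executive
#' control (RECN), sensorimotor (SMN), ventral default mode (vDMN), and
#' visuospatial (VSN).
#'
#' @return Character vector of length 14.
#' @export
#' @examples
#' rsn_symbols()
rsn_symbols <- function() {
  c("AN", "aSN", "BGN", "dDMN", "HVN", "LECN", "LN",
    "PCN", "pSN", "PVN", "RECN", "SMN", "vDMN", "VSN")
}
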