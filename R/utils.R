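#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages take an explicit seed; per-participant (or
#' per-replicate) streams are derived deterministically from one master seed
#' so that every draw in a pipeline run is attributable to it.
#'
#' @param master_seed Integer master seed.
#' @param index Positive integer stream index (participant, replicate, ...).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  # large prime stride keeps streams distinct; modulus keeps the result a
  # valid 32-bit integer
  as.integer((as.numeric(master_seed) + 104729 * as.numeric(index)) %% 2147483629)
}

# z-score with a hard error on degenerate columns (analysis path)
zscore <- function(x, name = "x") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero-variance column: ", name, call. = FALSE)
  (x - mean(x)) / s
}

# tolerant z-score used on the generative path, where a constant design
# variable simply contributes nothing
zscore_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop("non-finite ", what, call. = FALSE)
  invisible(x)
}
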