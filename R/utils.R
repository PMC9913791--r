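# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x, eps = 0) pmin(1 - eps, pmax(0 + eps, x))

#' Derive a per-stage random seed from the run seed
#'
#' All randomness in the package flows from a single integer seed; each
#' pipeline stage draws from its own named substream so that adding or
#' reordering stages does not perturb the others. The result always fits in
#' a 32-bit integer.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offsets <- c(
    annotation = 1L, beta = 2L, counts = 3L, compartments = 4L,
    survival = 5L, flow = 6L, gsea = 7L, de = 8L, pipeline = 9L,
    sets = 10L, logrank = 11L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((abs(as.numeric(seed)) + 104729 * offsets[[stage]]) %% 2147483587)
}

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
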