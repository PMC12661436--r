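#' @importFrom stats median sd rnorm runif rpois fft mvfft aov lm anova
#'   wilcox.test t.test binom.test chisq.test complete.cases plogis
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG seed
#'
#' All stochastic generators in this package route their randomness through
#' this helper so that every generator is a pure function of its parameters
#' and seed. The caller's RNG state is restored on exit.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Stages of the pipeline consume sub-seeds derived from the master seed by a
#' counter scheme, so that individual stages can be rerun independently with
#' identical randomness. Results stay below 2^31.
#'
#' @param seed Master integer seed.
#' @param counter Stage counter (1, 2, ...).
#' @return Integer sub-seed.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter))
  as.integer((as.double(seed) * 48271 + as.double(counter) * 1299709) %%
               2147483587)
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("optoentrain_domain_error",
                                             "error", "condition")))
}

stop_validation <- function(field, ...) {
  stop(errorCondition(sprintf("invalid field '%s': %s", field, paste0(...)),
                      class = c("optoentrain_validation_error",
                                "error", "condition")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("optoentrain_io_error",
                                             "error", "condition")))
}
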