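# Internal helpers shared across modules.

# Numerically stable inverse-logit.
expit <- function(x) stats::plogis(x)

# Reduce an hour-of-day value into [0, 24).
mod24 <- function(x) x %% 24

# Hours per radian for a 24-h period: 24 / (2*pi).
HOURS_PER_RADIAN <- 24 / (2 * pi)

#' Derive a stage-specific seed from a master seed
#'
#' A single pipeline seed fans out to per-stage seeds through a fixed affine
#' map so stages can be re-run in isolation with identical randomness.
#' Result always lies in [1, 2^31 - 2].
#'
#' @param seed master integer seed.
#' @param stage character stage name (must be one of the known stages) or an
#'   integer offset.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  stages <- c(
    simulate = 1L, params = 2L, nonwear = 3L, covariates = 4L, outcome = 5L,
    cluster = 6L, assoc = 7L, bootstrap = 8L, replicate = 9L
  )
  off <- if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    stages[[stage]]
  } else {
    as.integer(stage)
  }
  as.integer((as.double(seed) * 48271 + off * 1000003) %% 2147483629) + 1L
}

# Stop with a classed condition so tests can assert on error types.
stop_rar <- function(msg, class) {
  stop(structure(
    class = c(class, "rarfatigue_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
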