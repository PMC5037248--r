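# Internal helpers shared across the package.

# Round half away from zero ("half-up" on the magnitude), the convention used
# when rendering attributable fractions as one-decimal percentages.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic substream seeds: all randomness in a run flows from one user
# seed; independent consumers (latent exposures, outcomes, per-factor Monte
# Carlo runs) each take substream_seed(seed, counter) so results do not depend
# on the order in which analyses are executed. Kept below 2^31 - 1.
substream_seed <- function(seed, counter) {
  seed <- abs(as.double(seed)) %% 2147480000
  as.integer((seed + 1000003 * as.double(counter)) %% 2147483647)
}

stop_if_not_proportion <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("'%s' must be numeric with no missing values", name), call. = FALSE)
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!all(lo_ok & hi_ok)) {
    stop(sprintf("'%s' must be a proportion in %s0, 1%s", name,
                 if (allow_zero) "[" else "(", if (allow_one) "]" else ")"),
         call. = FALSE)
  }
  invisible(x)
}

#' Render a proportion-scale attributable fraction as a percentage
#'
#' Attributable fractions are computed and stored on the proportion scale
#' throughout the package; conversion to percent happens only at rendering.
#' Rounding is half away from zero, so `0.25105` prints as `25.1` and
#' `-0.02551` as `-2.6` at one decimal.
#'
#' @param par numeric vector of attributable fractions on the proportion scale.
#' @param digits decimal places of the rendered percentage (default 1).
#' @return numeric vector on the percent scale, rounded.
#' @examples
#' par_to_percent(0.251018)  # 25.1
#' par_to_percent(-0.026)    # -2.6
#' @export
par_to_percent <- function(par, digits = 1) {
  if (!is.numeric(par)) stop("'par' must be numeric", call. = FALSE)
  round_half_up(100 * par, digits)
}
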