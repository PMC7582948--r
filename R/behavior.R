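#' Poke rate in a half-open window
#'
#' Counts events in \code{[window_start, window_end)} and divides by the
#' window duration.
#'
#' @param pokes sorted numeric timestamps (seconds).
#' @param window_start,window_end window bounds, seconds;
#'   \code{window_end > window_start}.
#' @return rate in Hz.
#' @examples
#' pokeRate(c(1, 2, 3), 0, 20)   # 0.15 Hz
#' @export
pokeRate <- function(pokes, window_start, window_end) {
  if (window_end <= window_start) {
    stop("inverted window: window_end must exceed window_start", call. = FALSE)
  }
  sum(pokes >= window_start & pokes < window_end) / (window_end - window_start)
}

#' Conditioned suppression ratio
#'
#' \code{(baseline - cue) / (baseline + cue)}: 1 indicates complete
#' suppression of reward seeking (high fear), 0 none, negative values
#' elevated responding during the cue. When both rates are zero the ratio is
#' undefined; the default policy records \code{NA} (such trials drop out of
#' means and of the fear-output regressor), with \code{zero_policy = "zero"}
#' as the configurable alternative.
#'
#' @param baseline_rate,cue_rate non-negative rates, Hz.
#' @param zero_policy what to return when both rates are 0: \code{"na"}
#'   (default) or \code{"zero"}.
#' @return ratio in [-1, 1], or NA under the default zero policy.
#' @examples
#' suppressionRatio(2, 0)   # 1: full suppression
#' suppressionRatio(3, 1)   # 0.5
#' @export
suppressionRatio <- function(baseline_rate, cue_rate,
                             zero_policy = c("na", "zero")) {
  zero_policy <- match.arg(zero_policy)
  if (any(baseline_rate < 0) || any(cue_rate < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  denom <- baseline_rate + cue_rate
  out <- ifelse(denom > 0, (baseline_rate - cue_rate) / denom,
                if (zero_policy == "zero") 0 else NA_real_)
  out
}

#' Per-trial suppression for a session
#'
#' One record per trial; each trial's ratio uses exclusively its own 20 s
#' pre-onset baseline and the 10 s cue period (both half-open), per the
#' trial-wise definition of conditioned suppression.
#'
#' @param bundle a \code{\linkS4class{SessionBundle}}.
#' @param zero_policy passed to \code{\link{suppressionRatio}}.
#' @return data.frame with columns \code{trial_index}, \code{cue},
#'   \code{shock}, \code{baseline_rate_hz}, \code{cue_rate_hz}, \code{ratio}.
#' @export
sessionSuppression <- function(bundle, zero_policy = c("na", "zero")) {
  zero_policy <- match.arg(zero_policy)
  tr <- trials(bundle)
  cfg <- bundle@config
  pre <- if (!is.null(cfg$pre_window)) cfg$pre_window else 20
  dur <- if (!is.null(cfg$cue_duration)) cfg$cue_duration else 10
  pk <- pokes(bundle)
  bl <- vapply(tr$onset_s, function(on) pokeRate(pk, on - pre, on), 0)
  cr <- vapply(tr$onset_s, function(on) pokeRate(pk, on, on + dur), 0)
  data.frame(
    trial_index = tr$trial_index,
    cue = tr$cue,
    shock = tr$shock,
    baseline_rate_hz = bl,
    cue_rate_hz = cr,
    ratio = suppressionRatio(bl, cr, zero_policy)
  )
}
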