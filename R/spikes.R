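#' Bin one trial's spikes around cue onset
#'
#' Counts spikes in 250 ms half-open bins spanning -20 s to +30 s relative
#' to cue onset (20 s pre-cue, 10 s cue, 20 s post-offset; 200 bins) and
#' converts to Hz. Bin \code{i} covers \code{[-20 + (i-1)*0.25, -20 + i*0.25)}
#' seconds, so the cue occupies bins 81-120.
#'
#' @param spikes sorted spike timestamps, seconds.
#' @param onset cue onset, seconds.
#' @param window peri-onset window, seconds (default \code{c(-20, 30)}).
#' @param binWidth bin width, seconds (default 0.25).
#' @return numeric vector of per-bin rates (Hz).
#' @export
binTrial <- function(spikes, onset, window = c(-20, 30), binWidth = 0.25) {
  nb <- round(diff(window) / binWidth)
  rel <- spikes - onset
  rel <- rel[rel >= window[1] & rel < window[2]]
  idx <- floor((rel - window[1]) / binWidth) + 1L
  idx[idx > nb] <- nb  # guard against floating-point edge at window end
  tabulate(idx, nbins = nb) / binWidth
}

#' Spike rate in a named epoch of one trial
#'
#' Epochs (half-open, seconds from cue onset): \code{baseline10} [-10, 0),
#' \code{baseline2} [-2, 0), \code{first1} [0, 1), \code{first5} [0, 5),
#' \code{last5} [5, 10), \code{cue10} [0, 10), \code{baseline20} [-20, 0).
#'
#' @param spikes sorted spike timestamps, seconds.
#' @param onset cue onset, seconds.
#' @param epoch epoch name.
#' @return rate in Hz.
#' @export
epochRate <- function(spikes, onset, epoch) {
  w <- epochWindow(epoch) + onset
  sum(spikes >= w[1] & spikes < w[2]) / diff(epochWindow(epoch))
}

# Per-trial x per-epoch rate matrix for one unit.
epochRateTable <- function(spikes, trials,
                           epochs = c("baseline10", "first1", "first5", "last5")) {
  out <- sapply(epochs, function(e) {
    vapply(trials$onset_s, function(on) epochRate(spikes, on, e), 0)
  })
  out <- matrix(out, nrow = nrow(trials), dimnames = list(NULL, epochs))
  out
}

#' Mean peri-event traces per trial type
#'
#' Bins every trial and averages elementwise within trial type. With
#' \code{collapse = TRUE} (default) uncertainty-shock and
#' uncertainty-omission trials are pooled before averaging — during the cue
#' the animal cannot know the current uncertainty outcome.
#'
#' @param spikes sorted spike timestamps for one unit.
#' @param trials trial schedule data.frame.
#' @param collapse pool the uncertainty subtypes?
#' @param window,binWidth passed to \code{\link{binTrial}}.
#' @return matrix (trial types x bins) of mean rates, Hz.
#' @export
trialTypeMeanTraces <- function(spikes, trials, collapse = TRUE,
                                window = c(-20, 30), binWidth = 0.25) {
  if (nrow(trials) == 0) stop("no trials supplied", call. = FALSE)
  types <- trialTypeLabels(trials, collapse)
  lv <- if (collapse) CUE_LEVELS else
    c("danger", "uncertainty_shock", "uncertainty_omission", "safety")
  lv <- lv[lv %in% types]
  if (length(lv) == 0) stop("no trials of any requested type", call. = FALSE)
  binned <- t(vapply(trials$onset_s,
                     function(on) binTrial(spikes, on, window, binWidth),
                     numeric(round(diff(window) / binWidth))))
  out <- do.call(rbind, lapply(lv, function(ty) {
    colMeans(binned[types == ty, , drop = FALSE])
  }))
  rownames(out) <- lv
  out
}

#' Differential firing and unit-level Z-normalization
#'
#' For each trial type, subtracts that type's own 2 s pre-onset baseline
#' mean (bins covering [-2, 0) s) from every bin to give the differential
#' trace, then computes one (mu, sigma) over the concatenation of all trial
#' types' differential traces — each type contributing its bins once,
#' regardless of trial count — and Z-scores every bin with those constants.
#' Normalizing across the entire peri-event epoch rather than the baseline
#' alone keeps units with little baseline activity usable, at the cost that
#' normalized baseline activity need not be zero. A unit whose differential
#' traces have zero variance (sigma = 0) is flagged degenerate and excluded
#' from normalized analyses.
#'
#' @param meanTraces matrix from \code{\link{trialTypeMeanTraces}}.
#' @param unit unit id (metadata only).
#' @param window,binWidth bin geometry matching the traces.
#' @return a \code{\linkS4class{UnitTraces}}.
#' @export
znormUnit <- function(meanTraces, unit = "unit", window = c(-20, 30),
                      binWidth = 0.25) {
  blIdx <- baselineBinIdx(window, binWidth)
  diffs <- meanTraces - rowMeans(meanTraces[, blIdx, drop = FALSE])
  concat <- as.vector(t(diffs))
  mu <- mean(concat)
  sigma <- stats::sd(concat)
  degenerate <- !is.finite(sigma) || sigma <= 0
  z <- if (degenerate) diffs * NA_real_ else (diffs - mu) / sigma
  methods::new("UnitTraces",
    unit = unit, trialTypes = rownames(meanTraces),
    rate = meanTraces, diff = diffs, z = z,
    mu = mu, sigma = if (degenerate) 0 else sigma,
    degenerate = degenerate, binWidth = binWidth, window = window)
}

baselineBinIdx <- function(window = c(-20, 30), binWidth = 0.25,
                           baseline = c(-2, 0)) {
  starts <- window[1] + (seq_len(round(diff(window) / binWidth)) - 1) * binWidth
  which(starts >= baseline[1] - 1e-9 & starts < baseline[2] - 1e-9)
}

#' Per-trial normalized firing in an interval
#'
#' Builds the single-trial counterpart of the unit's normalized mean traces:
#' the trial's rate in the interval minus a 2 s pre-onset baseline, passed
#' through the unit-level (mu, sigma). With \code{baseline_mode = "trial"}
#' (default) the differencing baseline is the trial's own [-2, 0) s rate,
#' which keeps single-trial values consistent with the plotted mean z
#' traces; \code{"type"} uses the trial-type mean baseline instead (no
#' per-trial differencing).
#'
#' @param traces the unit's \code{\linkS4class{UnitTraces}}.
#' @param spikes the unit's spike timestamps.
#' @param trials trial schedule.
#' @param interval numeric length-2, seconds from cue onset, half-open.
#' @param baseline_mode \code{"trial"} or \code{"type"}.
#' @param collapse uncertainty pooling used when \code{baseline_mode="type"};
#'   must match how \code{traces} was built.
#' @return numeric vector, one normalized value per trial.
#' @export
znormTrialFiring <- function(traces, spikes, trials, interval,
                             baseline_mode = c("trial", "type"),
                             collapse = TRUE) {
  baseline_mode <- match.arg(baseline_mode)
  if (isDegenerate(traces)) {
    stop("unit '", traces@unit, "' is degenerate (sigma = 0); ",
         "no normalized firing defined", call. = FALSE)
  }
  stopifnot(length(interval) == 2, interval[2] > interval[1])
  rate <- vapply(trials$onset_s, function(on) {
    sum(spikes >= on + interval[1] & spikes < on + interval[2]) /
      diff(interval)
  }, 0)
  if (baseline_mode == "trial") {
    bl <- vapply(trials$onset_s, function(on) {
      sum(spikes >= on - 2 & spikes < on) / 2
    }, 0)
  } else {
    types <- trialTypeLabels(trials, collapse)
    blIdx <- baselineBinIdx(traces@window, traces@binWidth)
    typeBl <- rowMeans(traceRow(traces, "rate", NULL)[, blIdx, drop = FALSE])
    bl <- typeBl[types]
  }
  nc <- normConstants(traces)
  ((rate - bl) - nc[["mu"]]) / nc[["sigma"]]
}
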