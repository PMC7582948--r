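#' @import methods
NULL

CUE_LEVELS <- c("danger", "uncertainty", "safety")

#' SessionBundle: one recording session
#'
#' Container for a single fear-discrimination session: the trial schedule
#' (cue identity, shock flag, onset), nose-poke timestamps, per-unit spike
#' timestamps and session metadata. All event times are in seconds from
#' session start; trials are indexed from 0 in session order.
#'
#' @slot trials data.frame with columns \code{trial_index} (0-based integer),
#'   \code{cue} (one of \code{danger}, \code{uncertainty}, \code{safety}),
#'   \code{shock} (logical) and \code{onset_s} (numeric, seconds).
#' @slot pokes numeric vector of sorted nose-poke timestamps (seconds).
#' @slot spikes named list; one sorted numeric vector of spike timestamps
#'   per unit.
#' @slot meta list of session metadata (\code{rat}, \code{group},
#'   \code{session}, \code{seed}, ...).
#' @slot config list describing the task timing (cue duration, peri-event
#'   windows); see \code{\link{taskConfig}}.
#' @slot truth list of optional simulation ground truth (\code{units}
#'   data.frame of generating parameters, \code{s_true} per-trial suppression
#'   levels); empty for recorded data.
#'
#' @seealso \code{\link{simulateSession}}, \code{\link{readSession}},
#'   \code{\link{writeSession}}
#' @export
setClass("SessionBundle",
  representation(
    trials = "data.frame",
    pokes = "numeric",
    spikes = "list",
    meta = "list",
    config = "list",
    truth = "list"
  ),
  prototype(
    trials = data.frame(
      trial_index = integer(0), cue = character(0),
      shock = logical(0), onset_s = numeric(0)
    ),
    pokes = numeric(0), spikes = list(), meta = list(),
    config = list(), truth = list()
  )
)

setValidity("SessionBundle", function(object) {
  msgs <- character(0)
  tr <- object@trials
  need <- c("trial_index", "cue", "shock", "onset_s")
  if (!all(need %in% names(tr))) {
    return(paste("trials must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(tr) > 0) {
    if (!all(tr$cue %in% CUE_LEVELS)) {
      bad <- which(!(tr$cue %in% CUE_LEVELS))[1]
      msgs <- c(msgs, sprintf("unknown cue label '%s' at trial row %d",
                              tr$cue[bad], bad))
    }
    if (any(diff(tr$onset_s) <= 0)) {
      msgs <- c(msgs, "trial onsets must be strictly increasing")
    }
    cfg <- object@config
    if (length(cfg) > 0 && nrow(tr) > 1) {
      minGap <- cfg$pre_window + cfg$cue_duration + cfg$post_window
      if (any(diff(tr$onset_s) < minGap - 1e-9)) {
        msgs <- c(msgs, sprintf(
          "inter-onset gap below minimum legal spacing (%g s)", minGap))
      }
    }
    if (any(tr$shock & tr$cue == "safety")) {
      msgs <- c(msgs, "safety trials cannot carry a shock flag")
    }
  }
  checkTimes <- function(x, what) {
    if (length(x) == 0) return(character(0))
    out <- character(0)
    if (any(x < 0)) out <- c(out, paste(what, "timestamps must be non-negative"))
    if (is.unsorted(x)) out <- c(out, paste(what, "timestamps must be sorted"))
    out
  }
  msgs <- c(msgs, checkTimes(object@pokes, "poke"))
  for (u in names(object@spikes)) {
    msgs <- c(msgs, checkTimes(object@spikes[[u]], paste0("unit '", u, "' spike")))
  }
  if (length(object@spikes) > 0 && is.null(names(object@spikes))) {
    msgs <- c(msgs, "spikes list must be named by unit id")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' UnitTraces: peri-event normalized firing of one unit
#'
#' Per-trial-type mean firing traces of a single unit in 250 ms bins spanning
#' -20 s to +30 s around cue onset (200 bins), together with the differential
#' traces (each type's 2 s pre-onset baseline mean subtracted) and the
#' Z-normalized traces. The normalization constants (mu, sigma) are computed
#' over the concatenation of all trial types' differential traces, so phasic
#' excitation and inhibition both contribute; baseline z can therefore differ
#' from zero.
#'
#' @slot unit character unit id.
#' @slot trialTypes character vector of trial-type labels (row order of the
#'   trace matrices).
#' @slot rate matrix (types x 200) of mean firing rate, Hz.
#' @slot diff matrix of differential firing (Hz, baseline-subtracted).
#' @slot z matrix of Z-normalized differential firing.
#' @slot mu,sigma numeric normalization constants (Hz).
#' @slot degenerate logical; TRUE when sigma is zero (unit excluded from
#'   normalized analyses).
#' @slot binWidth numeric, bin width in seconds (0.25).
#' @slot window numeric length-2, peri-onset window in seconds (-20, 30).
#'
#' @seealso \code{\link{znormUnit}}, \code{\link{zTrace}}
#' @export
setClass("UnitTraces",
  representation(
    unit = "character",
    trialTypes = "character",
    rate = "matrix",
    diff = "matrix",
    z = "matrix",
    mu = "numeric",
    sigma = "numeric",
    degenerate = "logical",
    binWidth = "numeric",
    window = "numeric"
  )
)

setValidity("UnitTraces", function(object) {
  msgs <- character(0)
  nb <- round(diff(object@window) / object@binWidth)
  if (ncol(object@rate) != nb) {
    msgs <- c(msgs, sprintf("expected %d bins, found %d", nb, ncol(object@rate)))
  }
  if (!identical(dim(object@rate), dim(object@diff)) ||
      !identical(dim(object@rate), dim(object@z))) {
    msgs <- c(msgs, "rate, diff and z matrices must share dimensions")
  }
  if (nrow(object@rate) != length(object@trialTypes)) {
    msgs <- c(msgs, "one trace row per trial type required")
  }
  if (!object@degenerate) {
    if (object@sigma <= 0) msgs <- c(msgs, "sigma must be > 0 unless degenerate")
    zz <- as.vector(t(object@z))
    if (abs(mean(zz)) > 1e-9 || abs(stats::sd(zz) - 1) > 1e-9) {
      msgs <- c(msgs, "concatenated z traces must have mean 0 and SD 1")
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})
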