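#' Paired t test of epoch firing against baseline
#'
#' Two-tailed dependent-samples t test of per-trial raw firing rate (Hz) in a
#' cue epoch against the same trials' 10 s pre-cue baseline. Direction is the
#' sign of the mean paired difference. Zero-variance differences admit no t
#' statistic; such tests are flagged and reported non-significant (p = 1).
#'
#' @param baseline_rates,epoch_rates paired per-trial rates, Hz.
#' @return list with \code{t}, \code{df}, \code{p}, \code{direction}
#'   (-1, 0, 1) and \code{zero_variance} flag.
#' @export
epochTTest <- function(baseline_rates, epoch_rates) {
  stopifnot(length(baseline_rates) == length(epoch_rates))
  n <- length(epoch_rates)
  if (n < 2) stop("need >= 2 trials for a paired t test", call. = FALSE)
  d <- epoch_rates - baseline_rates
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = n - 1L, p = 1,
                direction = sign(mean(d)), zero_variance = TRUE))
  }
  tt <- stats::t.test(epoch_rates, baseline_rates, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, direction = sign(mean(d)), zero_variance = FALSE)
}

#' Classify a unit as cue-excited, cue-inhibited or outside criteria
#'
#' Screens raw firing rate (Hz) per cue (danger, uncertainty, safety;
#' uncertainty subtypes collapsed, 16 trials) against the 10 s pre-cue
#' baseline with paired t tests at the Bonferroni threshold 0.05/6. Under
#' the default \code{"classwise"} scheme the excitation screen uses the
#' first 1 s and last 5 s cue epochs and the inhibition screen the first
#' 5 s and last 5 s epochs; \code{"uniform"} uses first 1 s / last 5 s for
#' both directions. A unit is \emph{excited} if at least one screened epoch
#' shows a significant increase and none shows a significant decrease,
#' \emph{inhibited} for the converse, and \emph{osc} (outside selection
#' criteria) otherwise — including when both directions reach significance.
#'
#' @param spikes unit spike timestamps.
#' @param trials trial schedule.
#' @param scheme \code{"classwise"} (default) or \code{"uniform"} epoch
#'   assignment.
#' @param alpha corrected per-test threshold (default 0.05/6; six tests per
#'   direction screen).
#' @return list with \code{label} (\code{excited}/\code{inhibited}/\code{osc})
#'   and \code{tests}, a data.frame of all cue-by-epoch test results.
#' @export
classifyUnit <- function(spikes, trials, scheme = c("classwise", "uniform"),
                         alpha = 0.05 / 6) {
  scheme <- match.arg(scheme)
  excEpochs <- c("first1", "last5")
  inhEpochs <- if (scheme == "classwise") c("first5", "last5") else excEpochs
  epochs <- unique(c("baseline10", excEpochs, inhEpochs))
  tests <- do.call(rbind, lapply(CUE_LEVELS, function(cu) {
    sub <- trials[trials$cue == cu, , drop = FALSE]
    if (nrow(sub) < 2) {
      stop("need >= 2 trials of cue '", cu, "' to screen", call. = FALSE)
    }
    rates <- epochRateTable(spikes, sub, epochs)
    do.call(rbind, lapply(setdiff(epochs, "baseline10"), function(e) {
      r <- epochTTest(rates[, "baseline10"], rates[, e])
      data.frame(cue = cu, epoch = e, t = r$t, df = r$df, p = r$p,
                 direction = r$direction, zero_variance = r$zero_variance)
    }))
  }))
  sigUp <- with(tests, epoch %in% excEpochs & p < alpha & direction > 0)
  sigDown <- with(tests, epoch %in% inhEpochs & p < alpha & direction < 0)
  label <- if (any(sigUp) && !any(sigDown)) "excited"
           else if (any(sigDown) && !any(sigUp)) "inhibited"
           else "osc"
  list(label = label, tests = tests, alpha = alpha, scheme = scheme)
}

#' Responsive-proportion contingency table
#'
#' Builds the 2x2 table of responsive (excited + inhibited) vs
#' outside-selection-criteria unit counts per group, as handed to
#' \code{\link{chiSquare2x2}}.
#'
#' @param labels character vector of unit labels
#'   (\code{excited}/\code{inhibited}/\code{osc}).
#' @param groups parallel character vector of group memberships (exactly two
#'   distinct groups required).
#' @return 2x2 integer matrix, rows = groups, columns =
#'   \code{c("responsive", "osc")}.
#' @export
responsiveProportions <- function(labels, groups) {
  stopifnot(length(labels) == length(groups))
  gl <- unique(groups)
  if (length(gl) != 2) {
    stop("exactly two groups required, found ", length(gl), call. = FALSE)
  }
  resp <- labels %in% c("excited", "inhibited")
  out <- t(vapply(gl, function(g) {
    c(responsive = sum(resp & groups == g),
      osc = sum(!resp & groups == g))
  }, c(responsive = 0L, osc = 0L)))
  storage.mode(out) <- "integer"
  out
}
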