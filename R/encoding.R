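#' Build the trial-by-trial encoding design matrix
#'
#' Three columns: a constant, the fear-output regressor (each trial's
#' suppression ratio over the full 10 s cue) and the threat-probability
#' regressor (danger 1.00, safety 0.00, uncertainty — both subtypes — the
#' assignment \code{u}). Regressors are left on their raw scales. Trials
#' with a missing suppression ratio are dropped.
#'
#' @param trials trial schedule.
#' @param suppression per-trial table from \code{\link{sessionSuppression}}.
#' @param u probability assigned to the uncertainty cue, in [0, 1]
#'   (0.375 is the task's programmed value).
#' @param min_trials minimum usable trials; fewer raises an error so the
#'   unit-session is excluded and logged by the caller.
#' @return list with \code{X} (n x 3 matrix: \code{const}, \code{fear},
#'   \code{threat}), \code{trial_index} of retained trials, and
#'   \code{rank_deficient} flag (collinear columns, e.g. a constant fear
#'   column).
#' @export
buildDesign <- function(trials, suppression, u = 0.375, min_trials = 8) {
  if (u < 0 || u > 1) stop("u must lie in [0, 1]", call. = FALSE)
  m <- merge(trials[, c("trial_index", "cue")],
             suppression[, c("trial_index", "ratio")], by = "trial_index")
  m <- m[order(m$trial_index), ]
  keep <- !is.na(m$ratio)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < min_trials) {
    stop(sprintf("only %d usable trials (< %d); unit-session excluded",
                 nrow(m), min_trials), call. = FALSE)
  }
  threat <- c(danger = 1, uncertainty = u, safety = 0)[m$cue]
  X <- cbind(const = 1, fear = m$ratio, threat = unname(threat))
  rankDef <- qr(X)$rank < ncol(X)
  list(X = X, trial_index = m$trial_index, rank_deficient = rankDef)
}

#' Ordinary least-squares betas
#'
#' Least-squares solution for the three-column encoding design. For a
#' rank-deficient design the minimum-norm solution is returned (flagged);
#' callers may instead exclude such fits.
#'
#' @param y response vector (normalized per-trial firing).
#' @param design list from \code{\link{buildDesign}} or a bare matrix.
#' @return list with \code{beta} (named: \code{const}, \code{fear},
#'   \code{threat}) and \code{rank_deficient}.
#' @export
olsBetas <- function(y, design) {
  X <- if (is.list(design)) design$X else design
  stopifnot(length(y) == nrow(X))
  rankDef <- qr(X)$rank < ncol(X)
  beta <- if (rankDef) {
    as.vector(MASS::ginv(X) %*% y)
  } else {
    stats::lm.fit(X, y)$coefficients
  }
  names(beta) <- colnames(X)
  list(beta = beta, rank_deficient = rankDef)
}

#' Per-interval beta series for one unit
#'
#' Runs the encoding regression in each 1 s interval of the 10 s cue
#' (intervals \code{[k, k+1)} s from onset, k = 0..9): the response is the
#' unit's normalized per-trial firing in the interval
#' (\code{\link{znormTrialFiring}}), the design is
#' \code{\link{buildDesign}} at the given uncertainty assignment.
#'
#' @param traces the unit's \code{\linkS4class{UnitTraces}}.
#' @param spikes unit spike timestamps.
#' @param trials trial schedule.
#' @param suppression per-trial suppression table.
#' @param u uncertainty assignment (default 0.375, the programmed
#'   probability).
#' @param baseline_mode passed to \code{\link{znormTrialFiring}}.
#' @return data.frame with columns \code{interval} (0-based), \code{u},
#'   \code{beta_const}, \code{beta_fear}, \code{beta_threat},
#'   \code{rank_deficient}.
#' @export
unitBetaSeries <- function(traces, spikes, trials, suppression, u = 0.375,
                           baseline_mode = c("trial", "type")) {
  baseline_mode <- match.arg(baseline_mode)
  design <- buildDesign(trials, suppression, u)
  kept <- trials[trials$trial_index %in% design$trial_index, , drop = FALSE]
  do.call(rbind, lapply(0:9, function(k) {
    y <- znormTrialFiring(traces, spikes, kept, c(k, k + 1),
                          baseline_mode = baseline_mode)
    fit <- olsBetas(y, design)
    data.frame(interval = k, u = u,
               beta_const = fit$beta[["const"]],
               beta_fear = fit$beta[["fear"]],
               beta_threat = fit$beta[["threat"]],
               rank_deficient = fit$rank_deficient)
  }))
}

#' Threat-probability tuning curve for one unit
#'
#' Repeats the per-interval encoding regression nine times, sweeping the
#' value assigned to the uncertainty cue from 0 to 1 in 0.125 steps, and
#' averages the threat-probability beta over the 10 cue intervals at each
#' assignment. The resulting 9-point curve peaks where the assignment best
#' matches the probability the unit's firing actually assigns to
#' uncertainty.
#'
#' @inheritParams unitBetaSeries
#' @param u_grid the nine uncertainty assignments.
#' @return data.frame with columns \code{u} and \code{mean_beta_threat}
#'   (one row per assignment).
#' @export
tuningCurve <- function(traces, spikes, trials, suppression,
                        u_grid = seq(0, 1, by = 0.125),
                        baseline_mode = c("trial", "type")) {
  baseline_mode <- match.arg(baseline_mode)
  rows <- lapply(u_grid, function(u) {
    bs <- unitBetaSeries(traces, spikes, trials, suppression, u,
                         baseline_mode = baseline_mode)
    data.frame(u = u, mean_beta_threat = mean(bs$beta_threat),
               rank_deficient = any(bs$rank_deficient))
  })
  do.call(rbind, rows)
}
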