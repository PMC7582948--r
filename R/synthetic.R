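#' Generate a randomized trial schedule
#'
#' Draws a uniformly random permutation (under the seed carried by
#' \code{config}) of the session's trial multiset and lays trials out with
#' inter-onset gaps of \code{pre_window + cue_duration + post_window +
#' iti_margin} seconds, the minimum spacing under which peri-onset analysis
#' windows never overlap. Shock flags follow trial type: all danger trials
#' and the uncertainty-shock subset are shocked.
#'
#' @param config a \code{\link{taskConfig}}.
#' @param seed optional integer overriding \code{config$seed}.
#' @return data.frame with columns \code{trial_index} (0-based), \code{cue},
#'   \code{shock}, \code{onset_s}.
#' @examples
#' sched <- generateTrialSchedule(taskConfig(seed = 42))
#' table(sched$cue, sched$shock)
#' @export
generateTrialSchedule <- function(config = taskConfig(), seed = NULL) {
  stopifnot(inherits(config, "TaskConfig"))
  if (is.null(seed)) seed <- config$seed
  counts <- config$trial_counts
  typePool <- rep(names(counts), counts)
  withSeed(deriveSeed(seed, "schedule"), {
    order <- if (length(typePool) > 1) sample(typePool) else typePool
  })
  cue <- sub("_(shock|omission)$", "", order)
  shock <- order %in% c("danger", "uncertainty_shock")
  n <- length(order)
  gap <- config$pre_window + config$cue_duration + config$post_window +
    config$iti_margin
  onset0 <- config$pre_window + config$iti_margin
  data.frame(
    trial_index = seq_len(n) - 1L,
    cue = cue,
    shock = shock,
    onset_s = onset0 + (seq_len(n) - 1) * gap
  )
}

# Homogeneous Poisson event times on [a, b) at the given rate.
poissonSegment <- function(rate, a, b) {
  len <- b - a
  if (rate <= 0 || len <= 0) return(numeric(0))
  n <- stats::rpois(1L, rate * len)
  if (n == 0L) return(numeric(0))
  sort(stats::runif(n, a, b))
}

#' Simulate nose poking over a session
#'
#' Pokes are a piecewise-homogeneous Poisson process: the baseline rate
#' everywhere except cue periods, where the rate drops to
#' \code{baseline * (1 - s) / (1 + s)}. The per-trial true fear level
#' \code{s = clamp(target[cue] + N(0, trial_noise_sd), 0, 1)} lives on the
#' suppression-ratio scale: thinning by \code{(1 - s)/(1 + s)} inverts the
#' ratio formula, so the expected measured suppression ratio on a trial
#' equals \code{s} and targets are directly comparable to observed ratios.
#' The true \code{s} per trial is returned so measured ratios can be checked
#' against ground truth.
#'
#' @param schedule trial schedule from \code{\link{generateTrialSchedule}}.
#' @param params a \code{\link{behaviorParams}}.
#' @param config the \code{\link{taskConfig}} the schedule was built from.
#' @param seed optional integer overriding \code{params$seed}.
#' @return list with \code{pokes} (sorted timestamps) and \code{s_true}
#'   (per-trial suppression levels, schedule order).
#' @export
simulateBehavior <- function(schedule, params = behaviorParams(),
                             config = taskConfig(), seed = NULL) {
  stopifnot(inherits(params, "BehaviorParams"))
  if (is.null(seed)) seed <- params$seed
  base <- params$baseline_poke_rate
  dur <- config$cue_duration
  sessEnd <- sessionEnd(schedule, config)
  withSeed(deriveSeed(seed, "behavior"), {
    n <- nrow(schedule)
    sTrue <- numeric(n)
    pokes <- numeric(0)
    cursor <- 0
    for (i in seq_len(n)) {
      on <- schedule$onset_s[i]
      sTrue[i] <- clamp01(params$target_suppression[[schedule$cue[i]]] +
                            stats::rnorm(1L, 0, params$trial_noise_sd))
      pokes <- c(pokes,
                 poissonSegment(base, cursor, on),
                 poissonSegment(base * (1 - sTrue[i]) / (1 + sTrue[i]),
                                on, on + dur))
      cursor <- on + dur
    }
    pokes <- c(pokes, poissonSegment(base, cursor, sessEnd))
  })
  list(pokes = pokes, s_true = sTrue)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

sessionEnd <- function(schedule, config) {
  if (nrow(schedule) == 0) return(config$iti_margin)
  max(schedule$onset_s) + config$cue_duration + config$post_window +
    config$iti_margin
}

# Per-bin gain multipliers over the cue (250 ms grid).
cueProfile <- function(spec, config, binWidth = 0.25) {
  nb <- round(config$cue_duration / binWidth)
  if (!is.null(spec$temporal_profile)) {
    prof <- spec$temporal_profile
    if (length(prof) != nb) {
      stop(sprintf("temporal_profile needs %d values (one per %g s cue bin)",
                   nb, binWidth), call. = FALSE)
    }
    return(prof)
  }
  prof <- rep(1, nb)
  firstSec <- seq_len(min(nb, round(1 / binWidth)))
  prof[firstSec] <- 1 + spec$onset_phasic_fraction
  prof
}

#' Simulate one unit's spike train
#'
#' Inhomogeneous Poisson spikes. Outside cues the rate is the unit baseline.
#' Within a cue, each 250 ms bin fires at
#' \code{max(0, baseline + profile(bin) * (threat_gain * p + fear_gain * s + eps))}
#' where \code{p} is the internally assigned probability of the presented cue
#' (danger 1, safety 0, uncertainty = \code{internal_uncertainty_weight}),
#' \code{s} the trial's true fear level (suppression-ratio scale) and \code{eps ~ N(0,
#' trial_noise_sd)} drawn once per trial, matching the trial-by-trial
#' structure the encoding regression targets.
#'
#' @param schedule trial schedule.
#' @param spec a \code{\link{unitSpec}}.
#' @param s_true per-trial true fear levels (from
#'   \code{\link{simulateBehavior}}); zeros are used when absent.
#' @param config the \code{\link{taskConfig}}.
#' @param seed integer seed for this unit's stream.
#' @return sorted numeric vector of spike timestamps (seconds).
#' @export
simulateUnit <- function(schedule, spec = unitSpec(), s_true = NULL,
                         config = taskConfig(), seed = 1L) {
  stopifnot(inherits(spec, "UnitSpec"))
  n <- nrow(schedule)
  if (is.null(s_true)) s_true <- numeric(n)
  stopifnot(length(s_true) == n)
  binWidth <- 0.25
  prof <- cueProfile(spec, config, binWidth)
  pAssign <- c(danger = 1, safety = 0,
               uncertainty = spec$internal_uncertainty_weight)
  sessEnd <- sessionEnd(schedule, config)
  withSeed(deriveSeed(seed, "unit"), {
    spikes <- numeric(0)
    cursor <- 0
    for (i in seq_len(n)) {
      on <- schedule$onset_s[i]
      spikes <- c(spikes, poissonSegment(spec$baseline_rate, cursor, on))
      drive <- spec$threat_gain * pAssign[[schedule$cue[i]]] +
        spec$fear_gain * s_true[i] +
        stats::rnorm(1L, 0, spec$trial_noise_sd)
      for (b in seq_along(prof)) {
        a <- on + (b - 1) * binWidth
        rate <- max(0, spec$baseline_rate + prof[b] * drive)
        spikes <- c(spikes, poissonSegment(rate, a, a + binWidth))
      }
      cursor <- on + config$cue_duration
    }
    spikes <- c(spikes, poissonSegment(spec$baseline_rate, cursor, sessEnd))
  })
  spikes
}

#' Simulate one full session
#'
#' Draws a schedule, behavior and every unit's spike train from sub-streams
#' of one seed, and assembles a validated \code{\linkS4class{SessionBundle}}
#' with ground truth attached.
#'
#' @param config a \code{\link{taskConfig}}.
#' @param behavior a \code{\link{behaviorParams}}.
#' @param units named list of \code{\link{unitSpec}} objects.
#' @param meta list with \code{rat}, \code{group}, \code{session}.
#' @param seed master integer seed for the bundle.
#' @return a \code{\linkS4class{SessionBundle}}.
#' @examples
#' b <- simulateSession(units = list(u01 = unitSpec()), seed = 7)
#' b
#' @export
simulateSession <- function(config = taskConfig(),
                            behavior = behaviorParams(),
                            units = list(u01 = unitSpec()),
                            meta = list(rat = "r01", group = "Con",
                                        session = "s01"),
                            seed = 1L) {
  if (is.null(names(units))) {
    names(units) <- sprintf("u%02d", seq_along(units))
  }
  schedule <- generateTrialSchedule(config, seed = seed)
  beh <- simulateBehavior(schedule, behavior, config, seed = seed)
  spikes <- lapply(names(units), function(uid) {
    simulateUnit(schedule, units[[uid]], beh$s_true, config,
                 seed = deriveSeed(seed, paste0("unit:", uid)))
  })
  names(spikes) <- names(units)
  unitTruth <- do.call(rbind, lapply(names(units), function(uid) {
    sp <- units[[uid]]
    data.frame(unit_id = uid, label = sp$label,
               baseline_rate_hz = sp$baseline_rate,
               threat_gain = sp$threat_gain, fear_gain = sp$fear_gain,
               uncertainty_weight = sp$internal_uncertainty_weight)
  }))
  meta$seed <- as.integer(seed)
  methods::new("SessionBundle",
    trials = schedule, pokes = beh$pokes, spikes = spikes,
    meta = meta, config = unclass(config),
    truth = list(units = unitTruth, s_true = beh$s_true)
  )
}

#' Simulate a cohort of sessions
#'
#' Generates every rat/session/unit described by a \code{\link{cohortConfig}}
#' from a single master seed (sub-streams keyed by rat, session and unit, so
#' any subset is reproducible). Before simulating, asserts that the group's
#' suppression targets keep the fear-output and threat-probability regressors
#' dissociable (correlation over the trial multiset < 0.95); a behaviorally
#' unrealistic configuration in which the two columns are collinear would
#' make the encoding regression ill-posed.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list of \code{\linkS4class{SessionBundle}} objects, named
#'   \code{rat_session}.
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  task <- config$task
  for (g in names(config$groups)) {
    assertDissociable(config$groups[[g]]$behavior, task)
  }
  bundles <- list()
  ratNum <- 0L
  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    for (r in seq_len(grp$n_rats)) {
      ratNum <- ratNum + 1L
      ratId <- sprintf("r%02d", ratNum)
      for (s in seq_len(config$sessions_per_rat)) {
        sessId <- sprintf("s%02d", s)
        sessSeed <- deriveSeed(config$seed, paste(g, ratId, sessId, sep = ":"))
        units <- drawUnitSpecs(grp, config$units_per_session,
                               seed = deriveSeed(sessSeed, "specs"))
        b <- simulateSession(task, grp$behavior, units,
                             meta = list(rat = ratId, group = g,
                                         session = sessId),
                             seed = sessSeed)
        bundles[[paste(ratId, sessId, sep = "_")]] <- b
      }
    }
  }
  bundles
}

drawUnitSpecs <- function(grp, nUnits, seed) {
  withSeed(seed, {
    specs <- lapply(seq_len(nUnits), function(i) {
      label <- sample(names(grp$label_probs), 1L, prob = grp$label_probs)
      sgn <- switch(label, excited = 1, inhibited = -1, none = 0)
      unitSpec(
        label = label,
        baseline_rate = max(0.5, stats::rnorm(1L, grp$baseline_rate_mean,
                                              grp$baseline_rate_sd)),
        threat_gain = sgn * abs(stats::rnorm(1L, grp$threat_gain_mean,
                                             grp$threat_gain_sd)),
        fear_gain = sgn * abs(stats::rnorm(1L, grp$fear_gain_mean,
                                           grp$fear_gain_sd)),
        internal_uncertainty_weight = grp$uncertainty_weight,
        onset_phasic_fraction = grp$onset_phasic_fraction,
        trial_noise_sd = grp$trial_noise_sd
      )
    })
    names(specs) <- sprintf("u%02d", seq_len(nUnits))
    specs
  })
}

assertDissociable <- function(behavior, task, limit = 0.95) {
  counts <- task$trial_counts
  cue <- rep(c("danger", "uncertainty", "uncertainty", "safety"),
             counts[c("danger", "uncertainty_shock", "uncertainty_omission",
                      "safety")])
  if (length(unique(cue)) < 3) return(invisible(TRUE))
  fear <- behavior$target_suppression[cue]
  threat <- task$shock_probabilities[cue]
  r <- stats::cor(fear, threat)
  if (!is.finite(r) || abs(r) >= limit) {
    stop(sprintf(paste0(
      "fear-output and threat-probability regressors are nearly collinear ",
      "(|r| = %.3f >= %.2f) under these suppression targets; ",
      "beta recovery would be ill-posed"), abs(r), limit), call. = FALSE)
  }
  invisible(TRUE)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
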