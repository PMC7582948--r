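#' Task timing and trial-composition configuration
#'
#' Defines the fear-discrimination task structure: three auditory cues
#' (danger, uncertainty, safety) of 10 s, foot shock delivered 2 s after cue
#' offset on shocked trials, and a 32-trial session of 6 danger, 6
#' uncertainty-shock, 10 uncertainty-omission and 10 safety trials in random
#' order. The uncertainty shock probability is implied by the trial counts
#' (6/16 = 0.375).
#'
#' @param cue_duration cue length, seconds.
#' @param shock_delay_after_offset delay from cue offset to shock, seconds.
#' @param pre_window,post_window peri-event analysis windows before onset /
#'   after offset, seconds. Traces span \code{[-pre, cue + post)}.
#' @param trial_counts named integer vector: \code{danger},
#'   \code{uncertainty_shock}, \code{uncertainty_omission}, \code{safety}.
#' @param shock_probabilities named numeric vector of per-cue shock
#'   probabilities (danger 1.00, uncertainty 0.375, safety 0.00).
#' @param iti_margin extra spacing between the minimum legal inter-onset gap
#'   and the scheduled gap, seconds. The behavioral task uses multi-minute
#'   intervals; the generator compresses them because all analyses live in
#'   the peri-onset window.
#' @param seed integer seed attached to the config.
#' @return A validated list of class \code{"TaskConfig"}.
#' @export
taskConfig <- function(cue_duration = 10,
                       shock_delay_after_offset = 2,
                       pre_window = 20,
                       post_window = 20,
                       trial_counts = c(danger = 6L, uncertainty_shock = 6L,
                                        uncertainty_omission = 10L, safety = 10L),
                       shock_probabilities = c(danger = 1, uncertainty = 0.375,
                                               safety = 0),
                       iti_margin = 5,
                       seed = 1L) {
  durs <- c(cue_duration, shock_delay_after_offset, pre_window, post_window)
  if (any(!is.finite(durs)) || any(durs[-2] <= 0) || shock_delay_after_offset < 0) {
    stop("invalid task config: all durations must be positive", call. = FALSE)
  }
  need <- c("danger", "uncertainty_shock", "uncertainty_omission", "safety")
  if (!all(need %in% names(trial_counts))) {
    stop("trial_counts must name ", paste(need, collapse = ", "), call. = FALSE)
  }
  trial_counts <- as.integer(trial_counts[need])
  names(trial_counts) <- need
  if (any(is.na(trial_counts)) || any(trial_counts < 0)) {
    stop("invalid task config: trial counts must be non-negative integers",
         call. = FALSE)
  }
  if (any(shock_probabilities < 0 | shock_probabilities > 1)) {
    stop("shock probabilities must lie in [0, 1]", call. = FALSE)
  }
  nu <- trial_counts["uncertainty_shock"] + trial_counts["uncertainty_omission"]
  if (nu > 0) {
    pImplied <- trial_counts["uncertainty_shock"] / nu
    if (abs(pImplied - shock_probabilities["uncertainty"]) > 0.5 / max(nu, 1)) {
      stop(sprintf(
        "uncertainty trial counts imply shock probability %.3f, config says %.3f",
        pImplied, shock_probabilities["uncertainty"]), call. = FALSE)
    }
  }
  structure(list(
    cue_duration = cue_duration,
    shock_delay_after_offset = shock_delay_after_offset,
    pre_window = pre_window,
    post_window = post_window,
    trial_counts = trial_counts,
    shock_probabilities = shock_probabilities,
    iti_margin = iti_margin,
    seed = as.integer(seed)
  ), class = "TaskConfig")
}

#' Behavioral (nose-poke) simulation parameters
#'
#' Nose poking is a piecewise-homogeneous Poisson process: rate
#' \code{baseline_poke_rate} everywhere except during cues, where it is
#' thinned by \code{(1 - s)/(1 + s)} with \code{s = clamp(target +
#' N(0, sd), 0, 1)} drawn once per trial, so that the expected measured
#' suppression ratio equals \code{s}. Targets are therefore on the
#' suppression-ratio scale; defaults emulate a trained rat discriminating
#' the three cues (ratios ordered danger > uncertainty > safety).
#'
#' @param baseline_poke_rate baseline poke rate, Hz.
#' @param target_suppression named numeric in [0,1] per cue.
#' @param trial_noise_sd SD of the per-trial suppression perturbation.
#' @param seed integer seed.
#' @return A validated list of class \code{"BehaviorParams"}.
#' @export
behaviorParams <- function(baseline_poke_rate = 1.0,
                           target_suppression = c(danger = 0.9,
                                                  uncertainty = 0.6,
                                                  safety = 0.1),
                           trial_noise_sd = 0.15,
                           seed = 1L) {
  if (baseline_poke_rate < 0) stop("baseline_poke_rate must be >= 0", call. = FALSE)
  if (!all(CUE_LEVELS %in% names(target_suppression))) {
    stop("target_suppression must name danger, uncertainty, safety", call. = FALSE)
  }
  ts <- target_suppression[CUE_LEVELS]
  if (any(ts < 0 | ts > 1)) stop("suppression targets must lie in [0, 1]", call. = FALSE)
  if (!(ts["danger"] >= ts["uncertainty"] && ts["uncertainty"] >= ts["safety"])) {
    warning("suppression targets not ordered danger >= uncertainty >= safety; ",
            "this does not emulate a trained rat", call. = FALSE)
  }
  if (trial_noise_sd < 0) stop("trial_noise_sd must be >= 0", call. = FALSE)
  structure(list(
    baseline_poke_rate = baseline_poke_rate,
    target_suppression = ts,
    trial_noise_sd = trial_noise_sd,
    seed = as.integer(seed)
  ), class = "BehaviorParams")
}

#' Single-unit simulation parameters
#'
#' A unit fires as an inhomogeneous Poisson process with rate
#' \code{max(0, baseline + profile(t) * (threat_gain * p + fear_gain * s + eps))}
#' during the cue and \code{baseline} elsewhere, where \code{p} is the
#' probability the unit's internal tuning assigns to the presented cue
#' (danger 1, safety 0, uncertainty \code{internal_uncertainty_weight}),
#' \code{s} is the trial's true fear level (suppression-ratio scale) and \code{eps} a per-trial
#' Gaussian rate offset. Cue-inhibited units are obtained with negative
#' gains; the instantaneous rate is clamped at zero.
#'
#' @param label intended functional class: \code{"excited"},
#'   \code{"inhibited"} or \code{"none"} (descriptive ground truth only; the
#'   classifier never sees it).
#' @param baseline_rate baseline firing, Hz.
#' @param threat_gain Hz per unit of internally assigned probability.
#' @param fear_gain Hz per unit of trial suppression.
#' @param internal_uncertainty_weight probability the unit's tuning assigns
#'   to the uncertainty cue, in [0, 1].
#' @param onset_phasic_fraction extra multiplicative gain applied during the
#'   first second of the cue (0 = flat profile).
#' @param temporal_profile optional numeric vector, one multiplier per 250 ms
#'   cue bin; overrides \code{onset_phasic_fraction} when supplied.
#' @param trial_noise_sd SD of the per-trial rate offset, Hz.
#' @return A validated list of class \code{"UnitSpec"}.
#' @export
unitSpec <- function(label = c("excited", "inhibited", "none"),
                     baseline_rate = 5,
                     threat_gain = 8,
                     fear_gain = 0,
                     internal_uncertainty_weight = 0.375,
                     onset_phasic_fraction = 0.5,
                     temporal_profile = NULL,
                     trial_noise_sd = 1) {
  label <- match.arg(label)
  if (baseline_rate < 0) stop("baseline_rate must be >= 0", call. = FALSE)
  if (internal_uncertainty_weight < 0 || internal_uncertainty_weight > 1) {
    stop("internal_uncertainty_weight must lie in [0, 1]", call. = FALSE)
  }
  if (trial_noise_sd < 0) stop("trial_noise_sd must be >= 0", call. = FALSE)
  if (label == "inhibited" && (threat_gain > 0 || fear_gain > 0)) {
    warning("inhibited units should have non-positive effective gains",
            call. = FALSE)
  }
  structure(list(
    label = label,
    baseline_rate = baseline_rate,
    threat_gain = threat_gain,
    fear_gain = fear_gain,
    internal_uncertainty_weight = internal_uncertainty_weight,
    onset_phasic_fraction = onset_phasic_fraction,
    temporal_profile = temporal_profile,
    trial_noise_sd = trial_noise_sd
  ), class = "UnitSpec")
}

#' Cohort-level simulation configuration
#'
#' Describes a cohort of rats split into two groups (default 8 Con, 12 EAA)
#' with per-group behavioral parameters and per-group distributions over unit
#' parameters. Group entries may override any \code{\link{unitSpec}} field
#' mean/SD; unit labels are drawn from \code{label_probs}.
#'
#' @param task a \code{\link{taskConfig}}.
#' @param groups named list; each element a list with fields \code{n_rats},
#'   \code{behavior} (a \code{\link{behaviorParams}}), \code{label_probs}
#'   (named probabilities for excited/inhibited/none),
#'   \code{baseline_rate_mean/sd}, \code{threat_gain_mean/sd},
#'   \code{fear_gain_mean/sd}, \code{uncertainty_weight}.
#' @param sessions_per_rat,units_per_session integers.
#' @param seed master integer seed; all per-session randomness is derived
#'   from it by stable keys.
#' @return A list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(task = taskConfig(),
                         groups = list(
                           Con = groupSpec(n_rats = 8),
                           EAA = groupSpec(n_rats = 12)
                         ),
                         sessions_per_rat = 1L,
                         units_per_session = 2L,
                         seed = 1L) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  structure(list(
    task = task, groups = groups,
    sessions_per_rat = as.integer(sessions_per_rat),
    units_per_session = as.integer(units_per_session),
    seed = as.integer(seed)
  ), class = "CohortConfig")
}

#' @rdname cohortConfig
#' @param n_rats rats in the group.
#' @param behavior group \code{\link{behaviorParams}}.
#' @param label_probs named probabilities over unit labels.
#' @param baseline_rate_mean,baseline_rate_sd Hz.
#' @param threat_gain_mean,threat_gain_sd Hz per unit probability (sign is
#'   flipped for inhibited units).
#' @param fear_gain_mean,fear_gain_sd Hz per unit suppression.
#' @param uncertainty_weight internal probability assigned to uncertainty.
#' @param onset_phasic_fraction,trial_noise_sd passed to \code{\link{unitSpec}}.
#' @export
groupSpec <- function(n_rats = 8L,
                      behavior = behaviorParams(),
                      label_probs = c(excited = 0.25, inhibited = 0.35, none = 0.4),
                      baseline_rate_mean = 5, baseline_rate_sd = 1.5,
                      threat_gain_mean = 8, threat_gain_sd = 2,
                      fear_gain_mean = 0, fear_gain_sd = 0,
                      uncertainty_weight = 0.375,
                      onset_phasic_fraction = 0.5,
                      trial_noise_sd = 1) {
  if (abs(sum(label_probs) - 1) > 1e-8 || any(label_probs < 0)) {
    stop("label_probs must be non-negative and sum to 1", call. = FALSE)
  }
  list(n_rats = as.integer(n_rats), behavior = behavior,
       label_probs = label_probs,
       baseline_rate_mean = baseline_rate_mean, baseline_rate_sd = baseline_rate_sd,
       threat_gain_mean = threat_gain_mean, threat_gain_sd = threat_gain_sd,
       fear_gain_mean = fear_gain_mean, fear_gain_sd = fear_gain_sd,
       uncertainty_weight = uncertainty_weight,
       onset_phasic_fraction = onset_phasic_fraction,
       trial_noise_sd = trial_noise_sd)
}

# Stable sub-stream seeds: one master seed per bundle, sub-streams keyed by
# strings such as "unit:u01". Polynomial string hash mod a Mersenne prime
# keeps results identical across platforms and R versions.
deriveSeed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Trial-type labels: collapse = TRUE pools uncertainty-shock and
# uncertainty-omission (rats cannot tell them apart during the cue).
trialTypeLabels <- function(trials, collapse = TRUE) {
  if (collapse) return(trials$cue)
  ifelse(trials$cue == "uncertainty",
         ifelse(trials$shock, "uncertainty_shock", "uncertainty_omission"),
         trials$cue)
}

# Named analysis epochs, seconds relative to cue onset, half-open [a, b).
epochWindow <- function(epoch) {
  switch(epoch,
    baseline20 = c(-20, 0),
    baseline10 = c(-10, 0),
    baseline2  = c(-2, 0),
    first1     = c(0, 1),
    first5     = c(0, 5),
    last5      = c(5, 10),
    cue10      = c(0, 10),
    stop("unknown epoch '", epoch, "'", call. = FALSE)
  )
}
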