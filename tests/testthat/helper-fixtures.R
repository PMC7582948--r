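# Shared fixtures, all built in code at test time.

# A fixed default 32-trial schedule used across tests.
fixedSchedule <- function(seed = 3) {
  generateTrialSchedule(taskConfig(seed = seed), seed = seed)
}

# Stationary Poisson spike train covering a schedule's session span.
stationaryTrain <- function(schedule, rate, margin = 35) {
  Tend <- max(schedule$onset_s) + margin
  sort(stats::runif(stats::rpois(1L, rate * Tend), 0, Tend))
}

# Deterministic spike train: the same within-trial pattern (seconds relative
# to onset) repeated on every trial of each cue; patterns is a named list.
patternedTrain <- function(schedule, patterns) {
  out <- unlist(lapply(seq_len(nrow(schedule)), function(i) {
    schedule$onset_s[i] + patterns[[schedule$cue[i]]]
  }))
  sort(out)
}

# Minimal hand-built bundle with a custom poke stream.
pokeBundle <- function(pokes, onsets = c(25, 80),
                       cues = c("danger", "safety")) {
  tr <- data.frame(trial_index = seq_along(onsets) - 1L, cue = cues,
                   shock = cues == "danger", onset_s = onsets)
  methods::new("SessionBundle", trials = tr, pokes = sort(pokes),
               spikes = list(), meta = list(rat = "rX", group = "Con",
                                            session = "sX"),
               config = unclass(taskConfig()), truth = list())
}

# One simulated unit run through suppression, traces and beta series.
unitThroughPipeline <- function(spec, behavior = behaviorParams(),
                                seed = 1, u = 0.375) {
  b <- simulateSession(behavior = behavior, units = list(u = spec),
                       seed = seed)
  sup <- sessionSuppression(b)
  tr <- znormUnit(trialTypeMeanTraces(spikeTimes(b, "u"), trials(b)), "u")
  list(bundle = b, suppression = sup, traces = tr,
       betas = if (isDegenerate(tr)) NULL else
         unitBetaSeries(tr, spikeTimes(b, "u"), trials(b), sup, u = u))
}
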