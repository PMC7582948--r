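test_that("trial schedules conserve the trial-type multiset under any seed", {
  cfg <- taskConfig()
  for (seed in c(1, 17, 4242, 900001)) {
    sched <- generateTrialSchedule(cfg, seed = seed)
    expect_equal(nrow(sched), 32L)
    ty <- ifelse(sched$cue == "uncertainty",
                 ifelse(sched$shock, "uncertainty_shock", "uncertainty_omission"),
                 sched$cue)
    expect_equal(sort(table(ty)), sort(table(c(
      rep("danger", 6), rep("uncertainty_shock", 6),
      rep("uncertainty_omission", 10), rep("safety", 10)))),
      ignore_attr = TRUE)
    expect_true(all(sched$shock[sched$cue == "danger"]))
    expect_false(any(sched$shock[sched$cue == "safety"]))
    expect_equal(sum(sched$shock[sched$cue == "uncertainty"]), 6L)
  }
})

test_that("schedule onsets respect the peri-event spacing invariant", {
  cfg <- taskConfig()
  sched <- generateTrialSchedule(cfg, seed = 5)
  minGap <- cfg$pre_window + cfg$cue_duration + cfg$post_window
  expect_true(all(diff(sched$onset_s) >= minGap))
  expect_true(min(sched$onset_s) >= cfg$pre_window)
})

test_that("degenerate and invalid schedule configs are handled", {
  empty <- taskConfig(trial_counts = c(danger = 0, uncertainty_shock = 0,
                                       uncertainty_omission = 0, safety = 0),
                      shock_probabilities = c(danger = 1, uncertainty = 0,
                                              safety = 0))
  expect_equal(nrow(generateTrialSchedule(empty)), 0L)
  expect_error(taskConfig(trial_counts = c(danger = -1, uncertainty_shock = 6,
                                           uncertainty_omission = 10,
                                           safety = 10)),
               "non-negative")
  expect_error(taskConfig(cue_duration = -1), "positive")
})

test_that("inconsistent uncertainty counts vs probability are rejected", {
  expect_error(
    taskConfig(trial_counts = c(danger = 6, uncertainty_shock = 2,
                                uncertainty_omission = 14, safety = 10)),
    "imply shock probability")
})

test_that("full suppression with no noise silences poking during danger cues", {
  cfg <- taskConfig()
  sched <- generateTrialSchedule(cfg, seed = 2)
  beh <- behaviorParams(baseline_poke_rate = 2,
                        target_suppression = c(danger = 1, uncertainty = 0.6,
                                               safety = 0.1),
                        trial_noise_sd = 0, seed = 2)
  sim <- simulateBehavior(sched, beh, cfg)
  dOn <- sched$onset_s[sched$cue == "danger"]
  for (on in dOn) {
    expect_equal(sum(sim$pokes >= on & sim$pokes < on + 10), 0L)
  }
  expect_equal(sim$s_true[sched$cue == "danger"], rep(1, 6))
})

test_that("measured suppression converges to the target as baseline rate grows", {
  cfg <- taskConfig()
  beh <- behaviorParams(baseline_poke_rate = 50,
                        target_suppression = c(danger = 0, uncertainty = 0,
                                               safety = 0),
                        trial_noise_sd = 0)
  ratios <- unlist(lapply(1:16, function(s) {
    sched <- generateTrialSchedule(cfg, seed = 300 + s)
    sim <- simulateBehavior(sched, beh, cfg, seed = 300 + s)
    b <- pokeBundle(sim$pokes, onsets = sched$onset_s, cues = sched$cue)
    sessionSuppression(b)$ratio
  }))
  expect_gte(length(ratios), 500)
  expect_lt(abs(mean(ratios)), 0.02)
})

test_that("mean measured ratios are ordered danger > uncertainty > safety", {
  cfg <- taskConfig()
  beh <- behaviorParams(target_suppression = c(danger = 0.9, uncertainty = 0.6,
                                               safety = 0.1))
  allSup <- do.call(rbind, lapply(1:30, function(s) {
    sched <- generateTrialSchedule(cfg, seed = 700 + s)
    sim <- simulateBehavior(sched, beh, cfg, seed = 700 + s)
    sessionSuppression(pokeBundle(sim$pokes, sched$onset_s, sched$cue))
  }))
  m <- tapply(allSup$ratio, allSup$cue, mean, na.rm = TRUE)
  expect_gt(m[["danger"]], m[["uncertainty"]])
  expect_gt(m[["uncertainty"]], m[["safety"]])
})

test_that("zero-rate, zero-gain units emit no spikes", {
  sched <- fixedSchedule()
  spec <- unitSpec(label = "none", baseline_rate = 0, threat_gain = 0,
                   fear_gain = 0, trial_noise_sd = 0)
  expect_length(simulateUnit(sched, spec, seed = 1), 0)
})

test_that("simulated spike counts are Poisson with the nominal rate", {
  # stationary unit; pooled 1 s window counts vs the Poisson pmf
  sched <- fixedSchedule()
  rate <- 5
  spec <- unitSpec(label = "none", baseline_rate = rate, threat_gain = 0,
                   fear_gain = 0, trial_noise_sd = 0)
  counts <- unlist(lapply(1:6, function(s) {
    spk <- simulateUnit(sched, spec, seed = 1000 + s)
    edges <- 0:1764
    tabulate(findInterval(spk, edges), nbins = length(edges) - 1)
  }))
  expect_gte(length(counts), 10000)
  brk <- 0:13
  obs <- c(table(factor(pmin(counts, 13), levels = brk)))
  pr <- dpois(brk, rate); pr[14] <- 1 - ppois(12, rate)
  gof <- suppressWarnings(chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
  expect_lt(abs(mean(counts) - rate), 3 * sqrt(rate / length(counts)))
})

test_that("identical seed and config reproduce a byte-identical bundle", {
  b1 <- simulateSession(units = list(u01 = unitSpec(), u02 = unitSpec()),
                        seed = 99)
  b2 <- simulateSession(units = list(u01 = unitSpec(), u02 = unitSpec()),
                        seed = 99)
  expect_identical(trials(b1), trials(b2))
  expect_identical(pokes(b1), pokes(b2))
  expect_identical(b1@spikes, b2@spikes)
  d1 <- tempfile(); d2 <- tempfile()
  writeSession(b1, d1); writeSession(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("a minimal cohort yields one bundle with one unit plus ground truth", {
  cc <- cohortConfig(groups = list(Con = groupSpec(n_rats = 1)),
                     sessions_per_rat = 1, units_per_session = 1, seed = 4)
  bundles <- generateCohort(cc)
  expect_length(bundles, 1)
  b <- bundles[[1]]
  expect_length(unitIds(b), 1)
  tt <- groundTruth(b)
  expect_equal(nrow(tt$units), 1)
  expect_length(tt$s_true, 32)
})

test_that("group-level gain offsets surface as epoch firing differences", {
  cc <- cohortConfig(
    groups = list(
      lo = groupSpec(n_rats = 3, threat_gain_mean = 3, threat_gain_sd = 0.5,
                     label_probs = c(excited = 1, inhibited = 0, none = 0)),
      hi = groupSpec(n_rats = 3, threat_gain_mean = 12, threat_gain_sd = 0.5,
                     label_probs = c(excited = 1, inhibited = 0, none = 0))),
    units_per_session = 1, seed = 21)
  bundles <- generateCohort(cc)
  meanDiff <- vapply(bundles, function(b) {
    spk <- spikeTimes(b, unitIds(b)[1])
    tr <- trials(b); dtr <- tr[tr$cue == "danger", ]
    mean(vapply(dtr$onset_s, function(on) epochRate(spk, on, "first1"), 0)) -
      mean(vapply(dtr$onset_s, function(on) epochRate(spk, on, "baseline10"), 0))
  }, 0)
  grp <- vapply(bundles, function(b) sessionMeta(b)$group, "")
  expect_gt(mean(meanDiff[grp == "hi"]), mean(meanDiff[grp == "lo"]))
})

test_that("near-collinear suppression targets are rejected by the generator", {
  beh <- behaviorParams(target_suppression = c(danger = 0.8,
                                               uncertainty = 0.3,
                                               safety = 0))
  cc <- cohortConfig(groups = list(Con = groupSpec(n_rats = 1,
                                                   behavior = beh)),
                     seed = 1)
  expect_error(generateCohort(cc), "collinear")
})
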