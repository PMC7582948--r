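test_that("binning covers 200 quarter-second bins with half-open edges", {
  expect_equal(binTrial(numeric(0), 100), rep(0, 200))
  v <- binTrial(25.1, onset = 25)
  expect_equal(which(v > 0), 81L)  # 20 s pre-cue occupies bins 1..80
  expect_equal(v[81], 4)           # one spike / 0.25 s
  # spike exactly at a bin edge belongs to the right-hand bin
  v2 <- binTrial(c(25, 25.25), onset = 25)
  expect_equal(v2[81], 4); expect_equal(v2[82], 4)
})

test_that("per-bin means of a constant-rate train match the nominal rate", {
  rate <- 8; nTrials <- 1000
  set.seed(42)
  traces <- vapply(seq_len(nTrials), function(i) {
    spk <- sort(runif(rpois(1, rate * 50), -20, 30))
    binTrial(spk, onset = 0)
  }, numeric(200))
  binMeans <- rowMeans(traces)
  se <- sqrt(rate / 0.25 / nTrials)
  expect_lt(abs(mean(binMeans) - rate), 3 * se / sqrt(200))
  expect_gte(mean(abs(binMeans - rate) < 3 * se), 0.98)
})

test_that("epoch rates from raw spikes equal rates from tiling bins", {
  set.seed(5)
  spk <- sort(runif(400, 0, 60))
  onset <- 25
  v <- binTrial(spk, onset)
  for (ep in c("baseline10", "first1", "first5", "last5", "cue10")) {
    w <- switch(ep, baseline10 = 41:80, first1 = 81:84, first5 = 81:100,
                last5 = 101:120, cue10 = 81:120)
    expect_identical(epochRate(spk, onset, ep), mean(v[w]))
  }
})

test_that("trial-type mean traces average elementwise within type", {
  sched <- fixedSchedule()
  pat <- list(danger = c(0.1, 0.2), uncertainty = c(0.5), safety = c(5.0))
  spk <- patternedTrain(sched, pat)
  mt <- trialTypeMeanTraces(spk, sched)
  # identical trials per type: the mean equals any single trial's trace
  one <- binTrial(spk, sched$onset_s[sched$cue == "danger"][1])
  expect_equal(mt["danger", ], one, ignore_attr = TRUE)
  # two trials with traces a, b average to (a + b) / 2
  two <- sched[sched$cue == "danger", ][1:2, ]
  a <- binTrial(c(two$onset_s[1] + 0.1), two$onset_s[1])
  b <- binTrial(c(two$onset_s[2] + 0.1, two$onset_s[2] + 3), two$onset_s[2])
  m2 <- trialTypeMeanTraces(c(two$onset_s[1] + 0.1, two$onset_s[2] + 0.1,
                              two$onset_s[2] + 3), two)
  expect_equal(m2["danger", ], (a + b) / 2, ignore_attr = TRUE)
  expect_error(trialTypeMeanTraces(spk, sched[0, ]), "no trials")
})

test_that("the collapse flag pools uncertainty subtypes before averaging", {
  sched <- fixedSchedule()
  # spikes only on uncertainty-shock trials
  us <- sched[sched$cue == "uncertainty" & sched$shock, ]
  spk <- sort(us$onset_s + 0.1)
  pooled <- trialTypeMeanTraces(spk, sched, collapse = TRUE)
  split <- trialTypeMeanTraces(spk, sched, collapse = FALSE)
  expect_setequal(rownames(split),
                  c("danger", "uncertainty_shock", "uncertainty_omission",
                    "safety"))
  # 6 shock + 10 omission trials: pooled mean is 6/16 of the shock-only mean
  expect_equal(unname(pooled["uncertainty", 81]),
               unname(split["uncertainty_shock", 81]) * 6 / 16)
  expect_equal(unname(split["uncertainty_omission", 81]), 0)
})

test_that("a constant-rate unit is flagged degenerate and excluded", {
  mt <- matrix(7, nrow = 3, ncol = 200,
               dimnames = list(c("danger", "uncertainty", "safety"), NULL))
  tr <- znormUnit(mt)
  expect_true(isDegenerate(tr))
  expect_equal(unname(normConstants(tr)[["sigma"]]), 0)
  expect_error(znormTrialFiring(tr, numeric(0), fixedSchedule(), c(0, 1)),
               "degenerate")
})

test_that("concatenated z traces have mean 0 and SD 1 to 1e-9", {
  b <- simulateSession(units = list(u = unitSpec()), seed = 31)
  mt <- trialTypeMeanTraces(spikeTimes(b, "u"), trials(b))
  tr <- znormUnit(mt, "u")
  zz <- as.vector(zTrace(tr))
  expect_lt(abs(mean(zz)), 1e-9)
  expect_lt(abs(sd(zz) - 1), 1e-9)
})

test_that("z traces are exactly invariant to affine rate transforms", {
  b <- simulateSession(units = list(u = unitSpec()), seed = 32)
  mt <- trialTypeMeanTraces(spikeTimes(b, "u"), trials(b))
  z1 <- zTrace(znormUnit(mt))
  z2 <- zTrace(znormUnit(3.7 * mt + 2.1))
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("single-trial z values are consistent with the mean z traces", {
  sched <- fixedSchedule()
  pat <- list(danger = c(-1.5, -0.6, 0.2, 0.3, 1.1, 7.7),
              uncertainty = c(-1.1, 2.5, 2.6), safety = c(12.0, 14.0))
  spk <- patternedTrain(sched, pat)
  tr <- znormUnit(trialTypeMeanTraces(spk, sched))
  for (iv in list(c(0, 1), c(5, 10))) {
    zt <- znormTrialFiring(tr, spk, sched, iv)
    w <- which(-20 + (0:199) * 0.25 >= iv[1] & -20 + (0:199) * 0.25 < iv[2])
    for (cu in c("danger", "uncertainty", "safety")) {
      expect_equal(unname(zt[sched$cue == cu][1]), mean(zTrace(tr, cu)[w]),
                   tolerance = 1e-12)
    }
  }
})

test_that("full-cue z equals the mean of the ten 1 s interval values", {
  b <- simulateSession(units = list(u = unitSpec()), seed = 33)
  tr <- znormUnit(trialTypeMeanTraces(spikeTimes(b, "u"), trials(b)), "u")
  full <- znormTrialFiring(tr, spikeTimes(b, "u"), trials(b), c(0, 10))
  parts <- sapply(0:9, function(k) {
    znormTrialFiring(tr, spikeTimes(b, "u"), trials(b), c(k, k + 1))
  })
  expect_equal(full, rowMeans(parts), tolerance = 1e-9)
})

test_that("null units produce trial z values centered on zero", {
  vals <- unlist(lapply(1:10, function(s) {
    sched <- generateTrialSchedule(taskConfig(), seed = 500 + s)
    set.seed(500 + s)
    spk <- stationaryTrain(sched, rate = 10)
    tr <- znormUnit(trialTypeMeanTraces(spk, sched))
    znormTrialFiring(tr, spk, sched, c(0, 10))
  }))
  expect_length(vals, 320)
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("z normalization is invariant to trial order relabeling", {
  sched <- fixedSchedule()
  set.seed(77)
  spk <- stationaryTrain(sched, rate = 6)
  shuf <- sched[sample(nrow(sched)), ]
  expect_equal(zTrace(znormUnit(trialTypeMeanTraces(spk, sched))),
               zTrace(znormUnit(trialTypeMeanTraces(spk, shuf))))
})
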