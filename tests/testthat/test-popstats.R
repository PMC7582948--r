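test_that("the 2x2 chi-square is uncorrected Pearson on 1 df", {
  r <- chiSquare2x2(matrix(c(50, 50, 50, 50), 2))
  expect_equal(r$chi2, 0)
  expect_equal(r$df, 1)
  set.seed(13)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 40) + 5, 2)
    got <- chiSquare2x2(tab)$chi2
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got, sum((tab - E)^2 / E), tolerance = 1e-10)
    # identity with the squared two-proportion z statistic
    n <- rowSums(tab); p <- tab[, 1] / n; pp <- sum(tab[, 1]) / sum(n)
    z <- (p[1] - p[2]) / sqrt(pp * (1 - pp) * (1 / n[1] + 1 / n[2]))
    expect_equal(got, unname(z^2), tolerance = 1e-9)
  }
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
  expect_error(chiSquare2x2(matrix(1:6, 3)), "2x2")
})

test_that("mixed ANOVA matches a hand-worked balanced decomposition", {
  set.seed(9)
  d <- expand.grid(subj = paste0("s", 1:8), cue = c("a", "b", "c"))
  d$grp <- ifelse(d$subj %in% paste0("s", 1:4), "g1", "g2")
  d$y <- rnorm(24) + as.numeric(d$cue) / 2 + (d$grp == "g2") * 0.5
  res <- mixedAnova(d, "y", "subj", "grp", "cue")
  ybar <- mean(d$y)
  subjMeans <- tapply(d$y, d$subj, mean)
  SS_bs <- 3 * sum((subjMeans - ybar)^2)
  SS_grp <- 12 * sum((tapply(d$y, d$grp, mean) - ybar)^2)
  SS_sw <- SS_bs - SS_grp
  SS_cue <- 8 * sum((tapply(d$y, d$cue, mean) - ybar)^2)
  SS_cells <- 4 * sum((tapply(d$y, list(d$grp, d$cue), mean) - ybar)^2)
  SS_gc <- SS_cells - SS_grp - SS_cue
  SS_err <- sum((d$y - ybar)^2) - SS_bs - SS_cue - SS_gc
  oracle <- data.frame(
    effect = c("grp", "cue", "grp:cue"),
    F = c((SS_grp / 1) / (SS_sw / 6), (SS_cue / 2) / (SS_err / 12),
          (SS_gc / 2) / (SS_err / 12)),
    pes = c(SS_grp / (SS_grp + SS_sw), SS_cue / (SS_cue + SS_err),
            SS_gc / (SS_gc + SS_err)))
  got <- res[match(oracle$effect, res$effect), ]
  expect_equal(got$F, oracle$F, tolerance = 1e-8)
  expect_equal(got$partial_eta_sq, oracle$pes, tolerance = 1e-8)
  expect_equal(got$df_num, c(1, 2, 2))
  expect_equal(got$df_den, c(6, 12, 12))
})

test_that("mixed ANOVA validates its layout", {
  d <- expand.grid(subj = paste0("s", 1:4), cue = c("a", "b"))
  d$grp <- ifelse(d$subj %in% c("s1", "s2"), "g1", "g2")
  d$y <- rnorm(8)
  expect_error(mixedAnova(d[-1, ], "y", "subj", "grp", "cue"), "missing cells")
  d2 <- d; d2$grp <- c("g1", "g2", "g3", "g4")[match(d2$subj, paste0("s", 1:4))]
  expect_error(mixedAnova(d2, "y", "subj", "grp", "cue"), ">= 2 subjects")
})

test_that("group-effect p values are uniform under the null", {
  set.seed(17)
  ps <- replicate(200, {
    d <- expand.grid(subj = paste0("s", 1:12), cue = c("a", "b", "c"))
    d$grp <- ifelse(d$subj %in% paste0("s", 1:6), "g1", "g2")
    subjEff <- rnorm(12)
    d$y <- rnorm(36) + subjEff[match(d$subj, paste0("s", 1:12))]
    res <- mixedAnova(d, "y", "subj", "grp", "cue")
    res$p[res$effect == "grp"]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("an injected group-by-cue interaction is reliably detected", {
  set.seed(18)
  hits <- replicate(120, {
    d <- expand.grid(subj = paste0("s", 1:24), cue = c("a", "b", "c"))
    d$grp <- ifelse(d$subj %in% paste0("s", 1:12), "g1", "g2")
    subjEff <- rnorm(24)
    d$y <- rnorm(72, sd = 1) + subjEff[match(d$subj, paste0("s", 1:24))] +
      (d$grp == "g2") * ((d$cue == "c") - (d$cue == "a")) * 1.5
    res <- mixedAnova(d, "y", "subj", "grp", "cue")
    res$p[res$effect == "grp:cue"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Bonferroni t tests gate significance at 0.05/m", {
  set.seed(19)
  x <- rnorm(20, 1); y <- rnorm(20)
  out <- bonferroniT(list(list(x = x, y = y, name = "a"),
                          list(x = x, y = y + 5, name = "b"),
                          list(x = x, y = x, name = "c")), m = 3)
  expect_equal(out$alpha_corrected, rep(0.05 / 3, 3))
  expect_equal(out$significant, out$p < 0.05 / 3)
  expect_true(out$significant[out$name == "b"])
  # m = 1 reduces to a plain t test
  plain <- bonferroniT(list(list(x = x, y = y)), m = 1)
  expect_equal(plain$p, t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(plain$alpha_corrected, 0.05)
  # paired variant
  pr <- bonferroniT(list(list(x = x, y = y)), m = 1, paired = TRUE)
  expect_equal(pr$p, t.test(x, y, paired = TRUE)$p.value)
})

test_that("Pearson coupling recovers exact lines and its p is calibrated", {
  x <- seq(-2, 2, length.out = 30)
  r <- pearsonCoupling(x, 2 * x + 1)
  expect_equal(r$r2, 1); expect_equal(r$slope, 2); expect_equal(r$intercept, 1)
  expect_error(pearsonCoupling(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearsonCoupling(c(1, 2), c(1, 2)), "n >= 3")
  set.seed(23)
  fp <- mean(replicate(1000, pearsonCoupling(rnorm(50), rnorm(50))$p < 0.05))
  expect_gte(fp, 0.03); expect_lte(fp, 0.07)
})

test_that("coupled populations yield positive slopes almost surely", {
  set.seed(24)
  hits <- replicate(100, {
    gain <- runif(40, 0.5, 2)
    z <- gain + rnorm(40, sd = 0.3)
    beta <- gain + rnorm(40, sd = 0.3)
    pearsonCoupling(z, beta)$slope > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Fisher r-to-z follows the closed form and its symmetries", {
  expect_equal(fisherRtoZ(0.4, 25, 0.4, 40)$Z, 0)
  a <- fisherRtoZ(0.5, 30, 0.1, 20)
  b <- fisherRtoZ(0.1, 20, 0.5, 30)
  expect_equal(a$Z, -b$Z)
  expect_equal(a$p, b$p)
  oracle <- atanh(0.5) / sqrt(1 / 27 + 1 / 27)
  got <- fisherRtoZ(0.5, 30, 0, 30)
  expect_equal(got$Z, oracle, tolerance = 1e-10)
  expect_equal(got$p, 2 * pnorm(-abs(oracle)), tolerance = 1e-10)
  expect_error(fisherRtoZ(1, 30, 0, 30), "< 1")
  expect_error(fisherRtoZ(0.5, 3, 0, 30), "n >= 4")
})

test_that("partial eta squared increases with F at fixed dfs", {
  # two nested datasets with growing effect size
  set.seed(25)
  base <- expand.grid(subj = paste0("s", 1:10), cue = c("a", "b"))
  base$grp <- ifelse(base$subj %in% paste0("s", 1:5), "g1", "g2")
  noise <- rnorm(20)
  out <- sapply(c(0.5, 2), function(eff) {
    d <- base
    d$y <- noise + (d$cue == "b") * eff
    res <- mixedAnova(d, "y", "subj", "grp", "cue")
    unlist(res[res$effect == "cue", c("F", "partial_eta_sq")])
  })
  expect_gt(out["F", 2], out["F", 1])
  expect_gt(out["partial_eta_sq", 2], out["partial_eta_sq", 1])
})
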