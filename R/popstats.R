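#' Pearson chi-square for a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on one
#' degree of freedom, as used to compare cue-responsive unit proportions
#' between groups.
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @examples
#' chiSquare2x2(matrix(c(80, 71, 133, 70), 2, byrow = TRUE))
#' @export
chiSquare2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all margins must be positive", call. = FALSE)
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Mixed-design ANOVA with partial eta squared
#'
#' Standard univariate mixed-design partitioning: one between-subjects
#' factor and one or two within-subjects (repeated) factors. The
#' between-group effect is tested against subjects-within-groups; each
#' within effect (and its interactions) against its own effect-by-subjects
#' error stratum. No sphericity correction is applied. Partial eta squared
#' is \code{SS_effect / (SS_effect + SS_error)} with the error term of the
#' effect's stratum. With unequal group sizes the standard unweighted
#' decomposition is used.
#'
#' @param data long-format data.frame: one row per subject x within-cell.
#' @param dv name of the response column.
#' @param subject name of the subject id column.
#' @param between name of the between-subjects factor column.
#' @param within character vector of one or two within-subjects factor
#'   columns.
#' @return data.frame with one row per effect: \code{effect}, \code{F},
#'   \code{df_num}, \code{df_den}, \code{p}, \code{partial_eta_sq}.
#' @export
mixedAnova <- function(data, dv, subject, between, within) {
  stopifnot(length(within) >= 1, length(within) <= 2)
  cols <- c(dv, subject, between, within)
  if (!all(cols %in% names(data))) {
    stop("missing columns: ", paste(setdiff(cols, names(data)), collapse = ", "),
         call. = FALSE)
  }
  d <- data[, cols]
  names(d) <- c(".dv", ".subj", ".grp", paste0(".w", seq_along(within)))
  for (f in setdiff(names(d), ".dv")) d[[f]] <- factor(d[[f]])
  cells <- table(d$.subj, interaction(d[setdiff(names(d), c(".dv", ".subj", ".grp"))]))
  if (any(cells == 0)) {
    stop("missing cells: every subject must be observed at all within-factor ",
         "levels", call. = FALSE)
  }
  if (min(table(tapply(as.character(d$.grp), d$.subj, `[`, 1))) < 2) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  wTerms <- paste0(".w", seq_along(within))
  rhs <- paste(c(".grp", wTerms), collapse = " * ")
  errTerm <- paste0("Error(.subj/(", paste(wTerms, collapse = " * "), "))")
  form <- stats::as.formula(paste(".dv ~", rhs, "+", errTerm))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)
  out <- do.call(rbind, lapply(sm, function(stratum) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    resid <- rn == "Residuals"
    if (!any(resid) || all(resid)) return(NULL)
    ssErr <- tab[resid, "Sum Sq"]
    dfErr <- tab[resid, "Df"]
    eff <- which(!resid)
    data.frame(
      effect = gsub("\\.grp", between, gsub(
        "\\.w1", within[1], gsub("\\.w2",
        if (length(within) > 1) within[2] else ".w2", rn[eff]))),
      F = tab[eff, "F value"],
      df_num = tab[eff, "Df"],
      df_den = dfErr,
      p = tab[eff, "Pr(>F)"],
      partial_eta_sq = tab[eff, "Sum Sq"] / (tab[eff, "Sum Sq"] + ssErr)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected t tests
#'
#' Runs a two-tailed t test (paired or independent) for each contrast and
#' marks significance at the corrected threshold 0.05/m.
#'
#' @param contrasts list of contrasts; each a list with \code{x}, \code{y}
#'   (numeric vectors) and optionally \code{name}.
#' @param m number of comparisons corrected for (default:
#'   \code{length(contrasts)}).
#' @param paired paired (dependent-samples) or independent t tests.
#' @param var.equal for independent tests, assume equal variances (classic
#'   Student t, the convention in this analysis family).
#' @return data.frame with \code{name}, \code{t}, \code{df}, \code{p},
#'   \code{alpha_corrected}, \code{significant}.
#' @export
bonferroniT <- function(contrasts, m = length(contrasts), paired = FALSE,
                        var.equal = TRUE) {
  stopifnot(m >= 1)
  alpha <- 0.05 / m
  out <- do.call(rbind, lapply(seq_along(contrasts), function(i) {
    ct <- contrasts[[i]]
    tt <- stats::t.test(ct$x, ct$y, paired = paired, var.equal = var.equal)
    data.frame(
      name = if (!is.null(ct$name)) ct$name else paste0("contrast", i),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
      alpha_corrected = alpha, significant = tt$p.value < alpha
    )
  }))
  rownames(out) <- NULL
  out
}

#' Firing/signaling coupling (Pearson)
#'
#' Least-squares line and Pearson correlation between per-unit normalized
#' epoch firing and a per-unit beta coefficient, with the two-tailed p value
#' from \code{t = r * sqrt((n - 2) / (1 - r^2))}.
#'
#' @param x,y numeric vectors (one value per unit), n >= 3, finite, with
#'   positive variance.
#' @return list with \code{slope}, \code{intercept}, \code{r}, \code{r2},
#'   \code{p}, \code{n}.
#' @export
pearsonCoupling <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  slope <- r * stats::sd(y) / stats::sd(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r = r, r2 = r^2, p = ct$p.value, n = length(x))
}

#' Fisher r-to-z comparison of two correlations
#'
#' \code{Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))}, with the
#' two-tailed p from the standard normal. Used to compare firing/signaling
#' coupling between groups.
#'
#' @param r1,r2 sample correlations, |r| < 1.
#' @param n1,n2 sample sizes, each >= 4.
#' @return list with \code{Z} and \code{p}.
#' @export
fisherRtoZ <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each sample", call. = FALSE)
  Z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)))
}
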