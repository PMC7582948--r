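#' Simulate a cohort and write session bundles
#'
#' Deterministic under the seed: the same config and seed produce
#' byte-identical bundle directories. A \code{manifest.json} (config,
#' config hash, seed, package version) is written alongside.
#'
#' @param config a \code{\link{cohortConfig}}, or path to a YAML/JSON file
#'   mirroring its fields.
#' @param out_dir output directory; one subdirectory per session.
#' @param seed optional integer overriding the config's master seed.
#' @return invisibly, the list of written bundle directories.
#' @export
runSimulate <- function(config = cohortConfig(), out_dir, seed = NULL) {
  if (is.character(config)) config <- readCohortConfig(config)
  stopifnot(inherits(config, "CohortConfig"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  bundles <- generateCohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(bundles)) {
    p <- file.path(out_dir, nm)
    writeSession(bundles[[nm]], p)
    paths <- c(paths, p)
  }
  writeManifest(out_dir, config, config$seed)
  invisible(paths)
}

#' Analyze a directory of session bundles
#'
#' Runs the full pipeline — per-trial suppression, peri-event traces and
#' Z-normalization, cue-responsiveness classification, per-interval encoding
#' betas at the programmed uncertainty probability, the nine-assignment
#' threat-tuning curve, and population statistics — writing one CSV per
#' stage plus \code{stats_report.json}. Every exclusion (degenerate unit,
#' rank-deficient design, too few usable trials) is logged with its reason
#' in \code{run.log}.
#'
#' @param in_dir directory of session bundle subdirectories, or a list of
#'   \code{\linkS4class{SessionBundle}} objects.
#' @param out_dir output directory.
#' @param collapse pool uncertainty subtypes (default TRUE).
#' @param scheme classifier epoch scheme (\code{\link{classifyUnit}}).
#' @param baseline_mode per-trial normalization mode
#'   (\code{\link{znormTrialFiring}}).
#' @param u_grid uncertainty assignments for the tuning curve.
#' @param zero_policy suppression 0/0 policy (\code{\link{suppressionRatio}}).
#' @param force overwrite existing outputs.
#' @return invisibly, a list of the result tables.
#' @export
runAnalyze <- function(in_dir, out_dir, collapse = TRUE,
                       scheme = c("classwise", "uniform"),
                       baseline_mode = c("trial", "type"),
                       u_grid = seq(0, 1, by = 0.125),
                       zero_policy = c("na", "zero"),
                       force = FALSE) {
  scheme <- match.arg(scheme)
  baseline_mode <- match.arg(baseline_mode)
  zero_policy <- match.arg(zero_policy)
  bundles <- if (is.list(in_dir) && length(in_dir) > 0 &&
                 methods::is(in_dir[[1]], "SessionBundle")) {
    in_dir
  } else {
    dirs <- list.dirs(in_dir, recursive = FALSE)
    dirs <- dirs[file.exists(file.path(dirs, "trials.csv"))]
    if (length(dirs) == 0) {
      stop("no session bundles found under '", in_dir, "'", call. = FALSE)
    }
    stats::setNames(lapply(dirs, readSession), basename(dirs))
  }
  if (dir.exists(out_dir) &&
      file.exists(file.path(out_dir, "stats_report.json")) && !force) {
    stop("outputs already present in '", out_dir,
         "'; re-run with force = TRUE to overwrite", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character(0)
  logit <- function(...) logLines <<- c(logLines, sprintf(...))

  supRows <- list(); clsRows <- list(); trcRows <- list()
  betaRows <- list(); tunRows <- list(); coupRows <- list()
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    meta <- sessionMeta(b)
    rat <- meta$rat %||% nm; grp <- meta$group %||% "NA"
    sess <- meta$session %||% "s01"
    sup <- sessionSuppression(b, zero_policy)
    supRows[[nm]] <- cbind(rat = rat, group = grp, session = sess, sup)
    nmiss <- sum(is.na(sup$ratio))
    if (nmiss > 0) logit("%s: %d trial(s) with 0/0 suppression recorded NA", nm, nmiss)
    for (uid in unitIds(b)) {
      spk <- spikeTimes(b, uid)
      key <- paste(rat, sess, uid, sep = "_")
      cls <- classifyUnit(spk, trials(b), scheme = scheme)
      tw <- cls$tests
      wide <- stats::setNames(
        as.list(c(tw$t, tw$p)),
        c(paste0("t_", tw$cue, "_", tw$epoch), paste0("p_", tw$cue, "_", tw$epoch)))
      clsRows[[key]] <- data.frame(unit = key, rat = rat, session = sess,
                                   group = grp, label = cls$label, wide)
      mt <- trialTypeMeanTraces(spk, trials(b), collapse = collapse)
      tr <- znormUnit(mt, unit = key)
      nb <- ncol(mt)
      binStart <- -20 + (seq_len(nb) - 1) * 0.25
      trcRows[[key]] <- data.frame(
        rat = rat, session = sess, unit = key, group = grp,
        trial_type = rep(rownames(mt), each = nb),
        bin_index = rep(seq_len(nb) - 1L, times = nrow(mt)),
        bin_start_s = rep(binStart, times = nrow(mt)),
        rate_hz = as.vector(t(mt)),
        diff_hz = as.vector(t(tr@diff)),
        z = as.vector(t(tr@z)))
      if (isDegenerate(tr)) {
        logit("%s: degenerate unit (sigma = 0); excluded from normalized analyses", key)
        next
      }
      bs <- tryCatch(
        unitBetaSeries(tr, spk, trials(b), sup, u = 0.375,
                       baseline_mode = baseline_mode),
        error = function(e) { logit("%s: %s", key, conditionMessage(e)); NULL })
      if (is.null(bs)) next
      if (any(bs$rank_deficient)) {
        logit("%s: rank-deficient encoding design (minimum-norm betas)", key)
      }
      betaRows[[key]] <- cbind(unit = key, group = grp, bs)
      tc <- tuningCurve(tr, spk, trials(b), sup, u_grid = u_grid,
                        baseline_mode = baseline_mode)
      tunRows[[key]] <- cbind(unit = key, group = grp, tc)
      epo <- if (cls$label == "inhibited") "last5" else "first1"
      w <- epochWindow(epo)
      zIdx <- which(binStart >= w[1] - 1e-9 & binStart < w[2] - 1e-9)
      coupRows[[key]] <- data.frame(
        unit = key, group = grp, label = cls$label, epoch = epo,
        z_firing = mean(tr@z[, zIdx]),
        beta_threat = mean(bs$beta_threat), beta_fear = mean(bs$beta_fear))
    }
  }
  tabs <- list(
    suppression = do.call(rbind, supRows),
    classification = do.call(rbind, clsRows),
    traces = do.call(rbind, trcRows),
    betas = do.call(rbind, betaRows),
    tuning = do.call(rbind, tunRows),
    coupling = do.call(rbind, coupRows)
  )
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) tabs[[nm]] <- data.frame()
    rownames(tabs[[nm]]) <- NULL
    writeTable(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  tabs$stats <- populationStats(tabs)
  jsonlite::write_json(tabs$stats, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(if (length(logLines)) logLines else "no exclusions",
             file.path(out_dir, "run.log"))
  invisible(tabs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Group-level statistics assembled from the per-unit tables.
populationStats <- function(tabs) {
  out <- list()
  cls <- tabs$classification
  if (nrow(cls) > 0) {
    out$unit_counts <- as.list(table(cls$label))
    groups <- sort(unique(cls$group))
    if (length(groups) == 2) {
      ct <- responsiveProportions(cls$label, cls$group)
      out$responsive_by_group <- apply(ct, 1, function(r) {
        list(responsive = unname(r[1]), osc = unname(r[2]),
             proportion = unname(r[1] / sum(r)))
      })
      if (all(rowSums(ct) > 0) && all(colSums(ct) > 0)) {
        chi <- chiSquare2x2(ct)
        out$chi_square <- list(test = "responsive proportion, 2x2 Pearson",
                               chi2 = chi$chi2, df = chi$df, p = chi$p)
      }
    }
  }
  tun <- tabs$tuning
  cls <- tabs$classification
  if (!is.null(tun) && nrow(tun) > 0 && nrow(cls) > 0) {
    exc <- cls$unit[cls$label == "excited"]
    sub <- tun[tun$unit %in% exc, , drop = FALSE]
    if (nrow(sub) > 0) {
      curve <- tapply(sub$mean_beta_threat, sub$u, mean)
      out$tuning_curve_excited <- list(
        u = as.numeric(names(curve)), mean_beta_threat = as.numeric(curve),
        argmax_u = as.numeric(names(curve))[which.max(curve)],
        n_units = length(unique(sub$unit)))
    }
  }
  coup <- tabs$coupling
  if (!is.null(coup) && nrow(coup) > 0) {
    out$coupling <- list()
    for (lab in intersect(c("excited", "inhibited"), unique(coup$label))) {
      for (reg in c("beta_threat", "beta_fear")) {
        res <- list()
        for (g in sort(unique(coup$group))) {
          sub <- coup[coup$label == lab & coup$group == g, ]
          if (nrow(sub) >= 3 && stats::sd(sub$z_firing) > 0 &&
              stats::sd(sub[[reg]]) > 0) {
            res[[g]] <- pearsonCoupling(sub$z_firing, sub[[reg]])
          }
        }
        if (length(res) == 2 && all(vapply(res, `[[`, 0, "n") >= 4)) {
          fz <- fisherRtoZ(res[[1]]$r, res[[1]]$n, res[[2]]$r, res[[2]]$n)
          res$fisher <- list(Z = fz$Z, p = fz$p,
                             groups = names(res)[1:2])
        }
        if (length(res) > 0) out$coupling[[paste(lab, reg, sep = ".")]] <- res
      }
    }
  }
  out
}

#' Summarize an analysis directory
#'
#' Deterministic human-readable summary of a completed \code{\link{runAnalyze}}
#' output directory: unit counts per class and group, responsive-proportion
#' chi-square, mean suppression per cue, and the cue-excited tuning-curve
#' peak. Also returns the parsed stats report.
#'
#' @param results_dir directory written by \code{\link{runAnalyze}}.
#' @param file optional path for the text report (default: stdout).
#' @return invisibly, the stats report list.
#' @export
runReport <- function(results_dir, file = "") {
  sj <- file.path(results_dir, "stats_report.json")
  if (!file.exists(sj)) {
    stop("no stats_report.json in '", results_dir,
         "'; run runAnalyze() first", call. = FALSE)
  }
  stats <- jsonlite::read_json(sj, simplifyVector = TRUE)
  sup <- utils::read.csv(file.path(results_dir, "suppression.csv"))
  lines <- c("== threatcode report ==")
  if (nrow(sup) > 0) {
    m <- tapply(sup$ratio, sup$cue, mean, na.rm = TRUE)
    lines <- c(lines, "mean suppression ratio by cue:",
               sprintf("  %-12s %.3f", names(m), m))
  }
  if (!is.null(stats$unit_counts)) {
    lines <- c(lines, paste("units:",
      paste(names(stats$unit_counts), unlist(stats$unit_counts),
            sep = "=", collapse = ", ")))
  } else {
    lines <- c(lines, "units: none classified (zero responsive units)")
  }
  if (!is.null(stats$chi_square)) {
    lines <- c(lines, sprintf(
      "responsive proportion chi-square: chi2 = %.2f, df = %d, p = %.4g",
      stats$chi_square$chi2, stats$chi_square$df, stats$chi_square$p))
  }
  if (!is.null(stats$tuning_curve_excited)) {
    tc <- stats$tuning_curve_excited
    lines <- c(lines, sprintf(
      "cue-excited threat-tuning peak: u = %.3f (n = %d units)",
      tc$argmax_u, tc$n_units))
  }
  writeLines(lines, con = if (identical(file, "")) stdout() else file)
  invisible(stats)
}

stripClass <- function(x) {
  if (is.list(x)) lapply(unclass(x), stripClass) else x
}

writeManifest <- function(out_dir, config, seed) {
  cfgJson <- jsonlite::toJSON(stripClass(config), auto_unbox = TRUE,
                              digits = NA)
  tmp <- file.path(out_dir, ".config.json")
  writeLines(cfgJson, tmp)
  hash <- unname(tools::md5sum(tmp))
  file.remove(tmp)
  jsonlite::write_json(
    list(config = jsonlite::fromJSON(cfgJson, simplifyVector = TRUE),
         config_md5 = hash, seed = seed,
         package = as.character(utils::packageVersion("threatcode"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(hash)
}

#' Read a cohort configuration from YAML or JSON
#'
#' The document mirrors \code{\link{cohortConfig}}: optional \code{task} and
#' per-group blocks (each accepting \code{\link{groupSpec}} fields plus a
#' \code{behavior} block of \code{\link{behaviorParams}} fields), and
#' \code{sessions_per_rat}, \code{units_per_session}, \code{seed}.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a \code{\link{cohortConfig}}.
#' @export
readCohortConfig <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  task <- if (!is.null(doc$task)) {
    args <- doc$task
    if (!is.null(args$trial_counts)) args$trial_counts <- unlist(args$trial_counts)
    if (!is.null(args$shock_probabilities)) {
      args$shock_probabilities <- unlist(args$shock_probabilities)
    }
    do.call(taskConfig, args)
  } else taskConfig()
  groups <- if (!is.null(doc$groups)) {
    lapply(doc$groups, function(g) {
      beh <- if (!is.null(g$behavior)) {
        args <- g$behavior
        if (!is.null(args$target_suppression)) {
          args$target_suppression <- unlist(args$target_suppression)
        }
        do.call(behaviorParams, args)
      } else behaviorParams()
      g$behavior <- beh
      if (!is.null(g$label_probs)) g$label_probs <- unlist(g$label_probs)
      do.call(groupSpec, g)
    })
  } else list(Con = groupSpec(n_rats = 8), EAA = groupSpec(n_rats = 12))
  cohortConfig(task = task, groups = groups,
               sessions_per_rat = doc$sessions_per_rat %||% 1L,
               units_per_session = doc$units_per_session %||% 2L,
               seed = doc$seed %||% 1L)
}
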