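#' Write a session bundle to a directory
#'
#' On-disk dialect: a directory holding \code{trials.csv} (trial_index, cue,
#' shock, onset_s), \code{pokes.csv} (time_s), \code{spikes.csv} (unit_id,
#' time_s), \code{meta.json}, and \code{truth.csv} when simulation ground
#' truth is present. Times are seconds from session start written with 6
#' decimal places; headers are mandatory; row order is deterministic, so
#' re-writing the same bundle is byte-identical.
#'
#' @param bundle a \code{\linkS4class{SessionBundle}}.
#' @param path directory to create/fill.
#' @return \code{path}, invisibly.
#' @export
writeSession <- function(bundle, path) {
  stopifnot(methods::is(bundle, "SessionBundle"))
  methods::validObject(bundle)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr <- bundle@trials
  writeLines(c("trial_index,cue,shock,onset_s",
               sprintf("%d,%s,%s,%.6f", tr$trial_index, tr$cue,
                       ifelse(tr$shock, "true", "false"), tr$onset_s)),
             file.path(path, "trials.csv"))
  writeLines(c("time_s", sprintf("%.6f", bundle@pokes)),
             file.path(path, "pokes.csv"))
  spk <- unlist(lapply(names(bundle@spikes), function(u) {
    sprintf("%s,%.6f", u, bundle@spikes[[u]])
  }))
  writeLines(c("unit_id,time_s", spk), file.path(path, "spikes.csv"))
  meta <- bundle@meta
  meta$config <- bundle@config
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(bundle@truth) > 0) {
    ut <- bundle@truth$units
    urows <- sprintf("unit,%s,NA,%s,%.6f,%.6f,%.6f,%.6f,NA",
                     ut$unit_id, ut$label, ut$baseline_rate_hz,
                     ut$threat_gain, ut$fear_gain, ut$uncertainty_weight)
    st <- bundle@truth$s_true
    trows <- sprintf("trial,NA,%d,NA,NA,NA,NA,NA,%.6f",
                     tr$trial_index, st)
    writeLines(c(paste("record,unit_id,trial_index,label,baseline_rate_hz",
                       "threat_gain,fear_gain,uncertainty_weight,s_true",
                       sep = ","),
                 urows, trows),
               file.path(path, "truth.csv"))
  }
  invisible(path)
}

#' Read a session bundle from a directory
#'
#' Reads the dialect written by \code{\link{writeSession}}, canonicalizes cue
#' labels to lowercase, and validates all \code{SessionBundle} invariants
#' (sorted timestamps, strictly increasing onsets, legal spacing). Violations
#' are reported with the offending file and row.
#'
#' @param path bundle directory.
#' @return a \code{\linkS4class{SessionBundle}}.
#' @export
readSession <- function(path) {
  need <- c("trials.csv", "pokes.csv", "spikes.csv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing) > 0) {
    stop("session bundle at '", path, "' is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tr <- utils::read.csv(file.path(path, "trials.csv"),
                        colClasses = c(trial_index = "integer",
                                       cue = "character",
                                       shock = "character",
                                       onset_s = "numeric"))
  tr$cue <- tolower(tr$cue)
  bad <- which(!(tr$cue %in% CUE_LEVELS))
  if (length(bad) > 0) {
    stop(sprintf("trials.csv row %d: unknown cue label '%s'",
                 bad[1] + 1L, tr$cue[bad[1]]), call. = FALSE)
  }
  tr$shock <- tolower(tr$shock) %in% c("true", "t", "1", "yes")
  assertSortedFile(tr$onset_s, "trials.csv", "onset_s", strict = TRUE)
  pk <- utils::read.csv(file.path(path, "pokes.csv"))$time_s
  if (is.null(pk)) pk <- numeric(0)
  assertSortedFile(pk, "pokes.csv", "time_s")
  sp <- utils::read.csv(file.path(path, "spikes.csv"),
                        colClasses = c(unit_id = "character",
                                       time_s = "numeric"))
  spikes <- lapply(split(seq_len(nrow(sp)), sp$unit_id), function(idx) {
    x <- sp$time_s[idx]
    bad <- idx[which(diff(x) < 0) + 1L]
    if (length(bad) > 0) {
      stop(sprintf("spikes.csv row %d: decreasing spike time for unit '%s'",
                   bad[1] + 1L, sp$unit_id[bad[1]]), call. = FALSE)
    }
    x
  })
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  config <- meta$config
  meta$config <- NULL
  if (!is.null(config$trial_counts)) {
    config$trial_counts <- unlist(config$trial_counts)
  }
  if (!is.null(config$shock_probabilities)) {
    config$shock_probabilities <- unlist(config$shock_probabilities)
  }
  truth <- list()
  tf <- file.path(path, "truth.csv")
  if (file.exists(tf)) {
    tt <- utils::read.csv(tf)
    ut <- tt[tt$record == "unit", c("unit_id", "label", "baseline_rate_hz",
                                    "threat_gain", "fear_gain",
                                    "uncertainty_weight")]
    rownames(ut) <- NULL
    truth <- list(units = ut,
                  s_true = tt$s_true[tt$record == "trial"][order(
                    tt$trial_index[tt$record == "trial"])])
  }
  methods::new("SessionBundle", trials = tr, pokes = as.numeric(pk),
               spikes = spikes, meta = as.list(meta),
               config = if (is.null(config)) list() else as.list(config),
               truth = truth)
}

assertSortedFile <- function(x, file, col, strict = FALSE) {
  if (length(x) < 2) return(invisible(TRUE))
  d <- diff(x)
  bad <- if (strict) which(d <= 0) else which(d < 0)
  if (length(bad) > 0) {
    stop(sprintf("%s row %d: %s not %s", file, bad[1] + 2L, col,
                 if (strict) "strictly increasing" else "sorted"),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a session bundle directory
#'
#' Reads and validates a bundle, returning a short summary. Any dialect or
#' invariant violation raises an error naming the file and row.
#'
#' @param path bundle directory.
#' @return invisibly, the validated \code{\linkS4class{SessionBundle}}.
#' @export
validateSession <- function(path) {
  b <- readSession(path)
  methods::validObject(b)
  message(sprintf("ok: %d trials, %d pokes, %d unit(s)",
                  nrow(b@trials), length(b@pokes), length(b@spikes)))
  invisible(b)
}

#' Write an analysis table as CSV
#'
#' Deterministic column order (as supplied), mandatory header, numeric
#' columns at 6 significant digits. Re-running on identical inputs produces
#' byte-identical files.
#'
#' @param df data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- formatNum(out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

formatNum <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}
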