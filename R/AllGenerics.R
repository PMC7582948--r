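#' @rdname SessionBundle-accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @rdname SessionBundle-accessors
#' @export
setGeneric("pokes", function(x) standardGeneric("pokes"))

#' @rdname SessionBundle-accessors
#' @export
setGeneric("spikeTimes", function(x, unit) standardGeneric("spikeTimes"))

#' @rdname SessionBundle-accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname SessionBundle-accessors
#' @export
setGeneric("sessionMeta", function(x) standardGeneric("sessionMeta"))

#' @rdname SessionBundle-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname UnitTraces-accessors
#' @export
setGeneric("zTrace", function(x, type) standardGeneric("zTrace"))

#' @rdname UnitTraces-accessors
#' @export
setGeneric("diffTrace", function(x, type) standardGeneric("diffTrace"))

#' @rdname UnitTraces-accessors
#' @export
setGeneric("rateTrace", function(x, type) standardGeneric("rateTrace"))

#' @rdname UnitTraces-accessors
#' @export
setGeneric("normConstants", function(x) standardGeneric("normConstants"))

#' @rdname UnitTraces-accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' Accessors for SessionBundle objects
#'
#' \code{trials} returns the trial schedule (data.frame), \code{pokes} the
#' nose-poke timestamps, \code{spikeTimes} one unit's spike timestamps,
#' \code{unitIds} the unit identifiers, \code{sessionMeta} the metadata list
#' and \code{groundTruth} the simulation ground truth (empty list for
#' recorded data).
#'
#' @param x a \code{\linkS4class{SessionBundle}}.
#' @param unit unit id (character) or index.
#' @return See individual descriptions.
#' @name SessionBundle-accessors
#' @aliases trials pokes spikeTimes unitIds sessionMeta groundTruth
NULL

#' @rdname SessionBundle-accessors
#' @export
setMethod("trials", "SessionBundle", function(x) x@trials)

#' @rdname SessionBundle-accessors
#' @export
setMethod("pokes", "SessionBundle", function(x) x@pokes)

#' @rdname SessionBundle-accessors
#' @export
setMethod("spikeTimes", "SessionBundle", function(x, unit) {
  if (is.character(unit) && !unit %in% names(x@spikes)) {
    stop("no unit '", unit, "' in bundle", call. = FALSE)
  }
  x@spikes[[unit]]
})

#' @rdname SessionBundle-accessors
#' @export
setMethod("unitIds", "SessionBundle", function(x) names(x@spikes))

#' @rdname SessionBundle-accessors
#' @export
setMethod("sessionMeta", "SessionBundle", function(x) x@meta)

#' @rdname SessionBundle-accessors
#' @export
setMethod("groundTruth", "SessionBundle", function(x) x@truth)

setMethod("show", "SessionBundle", function(object) {
  m <- object@meta
  cat("SessionBundle:",
      if (!is.null(m$rat)) paste0("rat ", m$rat) else "",
      if (!is.null(m$group)) paste0("(", m$group, ")") else "",
      if (!is.null(m$session)) paste0("session ", m$session) else "", "\n")
  tt <- trialTypeLabels(object@trials, collapse = FALSE)
  cat(sprintf("  %d trials: %s\n", nrow(object@trials),
              paste(names(table(tt)), table(tt), sep = "=", collapse = ", ")))
  cat(sprintf("  %d pokes, %d unit(s): %s\n", length(object@pokes),
              length(object@spikes),
              paste(utils::head(names(object@spikes), 6), collapse = ", ")))
})

#' Accessors for UnitTraces objects
#'
#' \code{rateTrace}, \code{diffTrace} and \code{zTrace} return one trial
#' type's 200-bin trace (or the full matrix when \code{type} is missing);
#' \code{normConstants} returns \code{c(mu, sigma)} and \code{isDegenerate}
#' the degeneracy flag (sigma = 0: the unit never modulated and is excluded
#' from normalized analyses).
#'
#' @param x a \code{\linkS4class{UnitTraces}}.
#' @param type trial-type label; omit for the full matrix.
#' @name UnitTraces-accessors
#' @aliases zTrace diffTrace rateTrace normConstants isDegenerate
NULL

traceRow <- function(x, slotName, type) {
  m <- slot(x, slotName)
  rownames(m) <- x@trialTypes
  if (missing(type) || is.null(type)) return(m)
  if (!type %in% x@trialTypes) stop("no trial type '", type, "'", call. = FALSE)
  m[type, ]
}

#' @rdname UnitTraces-accessors
#' @export
setMethod("zTrace", "UnitTraces", function(x, type) traceRow(x, "z", type))

#' @rdname UnitTraces-accessors
#' @export
setMethod("diffTrace", "UnitTraces", function(x, type) traceRow(x, "diff", type))

#' @rdname UnitTraces-accessors
#' @export
setMethod("rateTrace", "UnitTraces", function(x, type) traceRow(x, "rate", type))

#' @rdname UnitTraces-accessors
#' @export
setMethod("normConstants", "UnitTraces", function(x) c(mu = x@mu, sigma = x@sigma))

#' @rdname UnitTraces-accessors
#' @export
setMethod("isDegenerate", "UnitTraces", function(x) x@degenerate)

setMethod("show", "UnitTraces", function(object) {
  cat(sprintf("UnitTraces for unit '%s': %d trial types x %d bins (%g s)\n",
              object@unit, length(object@trialTypes), ncol(object@rate),
              object@binWidth))
  cat(sprintf("  mu = %.4f Hz, sigma = %.4f Hz%s\n", object@mu, object@sigma,
              if (object@degenerate) " [degenerate]" else ""))
})
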