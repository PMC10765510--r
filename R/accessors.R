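# Accessors and show methods for the S4 containers.

#' Signal matrix of a run (T x N)
#' @param object a \linkS4class{RoiTimeSeries}.
#' @export
setGeneric("roiData", function(object) standardGeneric("roiData"))
#' @export
setMethod("roiData", "RoiTimeSeries", function(object) object@data)

#' ROI labels of an object
#' @param object a \linkS4class{RoiTimeSeries}, \linkS4class{DfcSeries},
#'   \linkS4class{WindowPool} or \linkS4class{StateModel}.
#' @return character vector of ROI labels.
#' @export
setGeneric("roiNames", function(object) standardGeneric("roiNames"))
#' @export
setMethod("roiNames", "RoiTimeSeries", function(object) colnames(object@data))
#' @export
setMethod("roiNames", "DfcSeries", function(object) rownames(object@mats))
#' @export
setMethod("roiNames", "WindowPool", function(object) object@roiNames)
#' @export
setMethod("roiNames", "StateModel", function(object) object@roiNames)

#' Repetition time in seconds
#' @param object a \linkS4class{RoiTimeSeries} or \linkS4class{DfcSeries}.
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @export
setMethod("trSeconds", "RoiTimeSeries", function(object) object@trSeconds)
#' @export
setMethod("trSeconds", "DfcSeries", function(object) object@trSeconds)

#' Run identity accessors
#' @param object an object carrying run provenance.
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
#' @export
setMethod("participantId", "RoiTimeSeries", function(object) object@participantId)
#' @export
setMethod("participantId", "DfcSeries", function(object) object@participantId)

#' @rdname participantId
#' @export
setGeneric("sessionLabel", function(object) standardGeneric("sessionLabel"))
#' @export
setMethod("sessionLabel", "RoiTimeSeries", function(object) object@session)
#' @export
setMethod("sessionLabel", "DfcSeries", function(object) object@session)

#' @rdname participantId
#' @export
setGeneric("runId", function(object) standardGeneric("runId"))
#' @export
setMethod("runId", "RoiTimeSeries", function(object) object@runId)
#' @export
setMethod("runId", "DfcSeries", function(object) object@runId)

#' Number of windows in a dFC series or pool
#' @param object a \linkS4class{DfcSeries} or \linkS4class{WindowPool}.
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))
#' @export
setMethod("nWindows", "DfcSeries", function(object) dim(object@mats)[3])
#' @export
setMethod("nWindows", "WindowPool", function(object) nrow(object@features))

#' Window start TRs (0-based) of a dFC series
#' @param object a \linkS4class{DfcSeries}.
#' @export
setGeneric("windowStarts", function(object) standardGeneric("windowStarts"))
#' @export
setMethod("windowStarts", "DfcSeries", function(object) object@startsTr)

#' Extract one window's correlation matrix
#' @param object a \linkS4class{DfcSeries}.
#' @param i window index (1-based).
#' @return N x N correlation matrix with window provenance attributes
#'   \code{window_index}, \code{start_tr} and \code{end_tr}.
#' @export
setGeneric("windowMatrix", function(object, i) standardGeneric("windowMatrix"))
#' @export
setMethod("windowMatrix", "DfcSeries", function(object, i) {
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= nWindows(object))
  m <- object@mats[, , i]
  dimnames(m) <- list(roiNames(object), roiNames(object))
  attr(m, "window_index") <- i
  attr(m, "start_tr") <- object@startsTr[i]
  attr(m, "end_tr") <- object@startsTr[i] + object@lengthTr
  m
})

#' Window feature matrix of a pool
#' @param object a \linkS4class{WindowPool} or \linkS4class{StateModel}.
#' @export
setGeneric("windowFeatures", function(object) standardGeneric("windowFeatures"))
#' @export
setMethod("windowFeatures", "WindowPool", function(object) object@features)

#' Per-window provenance table
#' @param object a \linkS4class{WindowPool} or \linkS4class{StateModel}.
#' @export
setGeneric("windowProvenance", function(object) standardGeneric("windowProvenance"))
#' @export
setMethod("windowProvenance", "WindowPool", function(object) object@provenance)
#' @export
setMethod("windowProvenance", "StateModel", function(object) object@provenance)

#' State labels of a fitted model
#' @param object a \linkS4class{StateModel}.
#' @return integer vector of per-window state labels (1 = strongest state).
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @export
setMethod("stateLabels", "StateModel", function(object) object@labels)

#' Centroid matrices of a fitted model
#' @param object a \linkS4class{StateModel}.
#' @return N x N x k array of centroid correlation matrices.
#' @export
setGeneric("stateCentroids", function(object) standardGeneric("stateCentroids"))
#' @export
setMethod("stateCentroids", "StateModel", function(object) {
  m <- object@centroids
  if (length(object@roiNames) == dim(m)[1])
    dimnames(m) <- list(object@roiNames, object@roiNames, NULL)
  m
})

#' Centroid strengths (mean upper-triangle r per state)
#' @param object a \linkS4class{StateModel}.
#' @export
setGeneric("stateStrengths", function(object) standardGeneric("stateStrengths"))
#' @export
setMethod("stateStrengths", "StateModel", function(object) object@strengths)

#' Number of states
#' @param object a \linkS4class{StateModel}.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @export
setMethod("nStates", "StateModel", function(object) object@k)

#' Within-cluster sum of squares of the kept restart
#' @param object a \linkS4class{StateModel}.
#' @export
setGeneric("modelInertia", function(object) standardGeneric("modelInertia"))
#' @export
setMethod("modelInertia", "StateModel", function(object) object@inertia)

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries: %d time points x %d ROIs (TR %.3g s)\n",
              nrow(object@data), ncol(object@data), object@trSeconds))
  cat(sprintf("  %s / %s / %s\n", object@participantId, object@session,
              object@runId))
})

setMethod("show", "DfcSeries", function(object) {
  cat(sprintf("DfcSeries: %d windows of %d TR (step %d TR), %d ROIs\n",
              nWindows(object), object@lengthTr, object@stepTr,
              dim(object@mats)[1]))
  cat(sprintf("  %s / %s / %s, TR %.3g s\n", object@participantId,
              object@session, object@runId, object@trSeconds))
})

setMethod("show", "WindowPool", function(object) {
  cat(sprintf("WindowPool: %d windows x %d features (%d ROIs), %d runs\n",
              nrow(object@features), ncol(object@features),
              length(object@roiNames),
              nrow(unique(object@provenance[c("participant_id", "session",
                                              "run_id")]))))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel: k = %d over %d windows (inertia %.4g)\n",
              object@k, length(object@labels), object@inertia))
  cat("  centroid strengths:",
      paste(sprintf("%.3f", object@strengths), collapse = ", "), "\n")
})
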