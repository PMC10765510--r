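#' @import methods
#' @importFrom stats cor sd aggregate approx complete.cases fft lm.fit
#'   median pnorm qnorm quantile rnorm runif setNames shapiro.test var
NULL

VALID_SESSIONS <- c("pre_op", "post_op")

#' Parcellated ROI time series for one acquisition run
#'
#' Holds one run's T x N matrix of parcellated fMRI signals (rows = time
#' points, columns = regions of interest), the repetition time, and run
#' identity. This is the raw input of the whole pipeline.
#'
#' @slot data numeric matrix, T time points x N ROIs; column names are the
#'   ROI labels.
#' @slot trSeconds repetition time in seconds (> 0).
#' @slot participantId participant identifier.
#' @slot session session label, one of \code{"pre_op"} or \code{"post_op"}.
#' @slot runId run identifier.
#'
#' @exportClass RoiTimeSeries
setClass("RoiTimeSeries",
  representation(
    data = "matrix",
    trSeconds = "numeric",
    participantId = "character",
    session = "character",
    runId = "character"
  )
)

setValidity("RoiTimeSeries", function(object) {
  d <- object@data
  msgs <- character()
  if (!is.numeric(d)) msgs <- c(msgs, "data must be a numeric matrix")
  if (nrow(d) < 2L) msgs <- c(msgs, "T >= 2 required (need at least 2 time points)")
  if (ncol(d) < 2L) msgs <- c(msgs, "N >= 2 required (need at least 2 ROIs)")
  if (anyNA(d)) msgs <- c(msgs, "missing values in time-series data")
  nm <- colnames(d)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msgs <- c(msgs, "ROI names must be present and unique")
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    msgs <- c(msgs, "trSeconds must be a single positive number")
  if (!object@session %in% VALID_SESSIONS)
    msgs <- c(msgs, sprintf("session must be one of %s",
                            paste(VALID_SESSIONS, collapse = "/")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param data numeric matrix (time points x ROIs) with ROI names as column
#'   names, or unnamed (names \code{ROI1..ROIN} are generated).
#' @param trSeconds repetition time in seconds.
#' @param participantId,session,runId run identity; \code{session} must be
#'   \code{"pre_op"} or \code{"post_op"}.
#' @return A \linkS4class{RoiTimeSeries} object.
#' @examples
#' x <- RoiTimeSeries(matrix(rnorm(40), 10, 4), trSeconds = 2)
#' dim(roiData(x))
#' @export
RoiTimeSeries <- function(data, trSeconds, participantId = "p01",
                          session = "pre_op", runId = "r01") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(colnames(data)))
    colnames(data) <- paste0("ROI", seq_len(ncol(data)))
  new("RoiTimeSeries", data = data, trSeconds = as.numeric(trSeconds),
      participantId = as.character(participantId),
      session = as.character(session), runId = as.character(runId))
}

#' Sliding-window dynamic functional connectivity series
#'
#' Ordered sequence of per-window N x N Pearson correlation matrices for one
#' run, with window provenance (0-based, half-open TR coordinates).
#'
#' @slot mats numeric array N x N x W of window correlation matrices.
#' @slot startsTr integer vector of 0-based window start TRs.
#' @slot lengthTr window length in TRs.
#' @slot stepTr step between consecutive window starts, in TRs.
#' @slot trSeconds repetition time of the source run (seconds).
#' @slot participantId,session,runId provenance of the source run.
#'
#' @exportClass DfcSeries
setClass("DfcSeries",
  representation(
    mats = "array",
    startsTr = "integer",
    lengthTr = "integer",
    stepTr = "integer",
    trSeconds = "numeric",
    participantId = "character",
    session = "character",
    runId = "character"
  )
)

setValidity("DfcSeries", function(object) {
  d <- dim(object@mats)
  msgs <- character()
  if (length(d) != 3L || d[1] != d[2])
    msgs <- c(msgs, "mats must be an N x N x W array")
  if (length(object@startsTr) != d[3])
    msgs <- c(msgs, "one start TR per window required")
  if (object@lengthTr < 2L) msgs <- c(msgs, "window length must be >= 2 TR")
  if (object@stepTr < 1L) msgs <- c(msgs, "step must be >= 1 TR")
  if (d[3] >= 2L &&
      any(diff(object@startsTr) != object@stepTr))
    msgs <- c(msgs, "consecutive windows must advance by exactly stepTr")
  if (length(msgs)) msgs else TRUE
})

#' Pooled window features across runs
#'
#' Vectorized upper-triangle features of all dFC windows pooled across runs
#' and sessions, with one provenance row per window. This is the input of the
#' state clustering step.
#'
#' @slot features numeric matrix, windows x N(N-1)/2 features.
#' @slot provenance data.frame with one row per window: \code{participant_id},
#'   \code{session}, \code{run_id}, \code{window_index}, \code{start_tr},
#'   \code{tr_seconds}, \code{step_tr}, \code{window_strength} (mean
#'   upper-triangle r of the window).
#' @slot roiNames ROI labels shared by all pooled runs.
#'
#' @exportClass WindowPool
setClass("WindowPool",
  representation(
    features = "matrix",
    provenance = "data.frame",
    roiNames = "character"
  )
)

setValidity("WindowPool", function(object) {
  msgs <- character()
  if (nrow(object@features) != nrow(object@provenance))
    msgs <- c(msgs, "one provenance row per window required")
  p <- ncol(object@features)
  n <- length(object@roiNames)
  if (p != n * (n - 1L) / 2L)
    msgs <- c(msgs, "feature width must be N(N-1)/2")
  need <- c("participant_id", "session", "run_id", "window_index",
            "start_tr", "tr_seconds", "step_tr", "window_strength")
  if (!all(need %in% names(object@provenance)))
    msgs <- c(msgs, "provenance is missing required columns")
  if (length(msgs)) msgs else TRUE
})

#' Fitted connectivity-state model
#'
#' K-means solution over pooled dFC windows: devectorized centroid matrices,
#' per-window state labels aligned with the pool's provenance, and the fit
#' metadata. States are canonically ordered by descending centroid strength,
#' so state 1 is always the most strongly connected state.
#'
#' @slot k number of states.
#' @slot centroids numeric array N x N x k of centroid correlation matrices
#'   (unit diagonal).
#' @slot labels integer vector of per-window state labels in 1..k.
#' @slot strengths mean upper-triangle r of each centroid (descending).
#' @slot inertia within-cluster sum of squared distances of the kept restart.
#' @slot inertiaPath per-Lloyd-iteration inertia of the kept restart.
#' @slot seed,restarts RNG seed and number of random restarts used.
#' @slot provenance per-window provenance copied from the
#'   \linkS4class{WindowPool}.
#' @slot roiNames ROI labels.
#'
#' @exportClass StateModel
setClass("StateModel",
  representation(
    k = "integer",
    centroids = "array",
    labels = "integer",
    strengths = "numeric",
    inertia = "numeric",
    inertiaPath = "numeric",
    seed = "integer",
    restarts = "integer",
    provenance = "data.frame",
    roiNames = "character"
  )
)

setValidity("StateModel", function(object) {
  msgs <- character()
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msgs <- c(msgs, "labels must lie in 1..k")
  if (length(unique(object@labels)) != object@k)
    msgs <- c(msgs, "every state must be nonempty")
  if (dim(object@centroids)[3] != object@k)
    msgs <- c(msgs, "one centroid per state required")
  if (is.unsorted(rev(object@strengths)))
    msgs <- c(msgs, "states must be ordered by descending centroid strength")
  if (nrow(object@provenance) != length(object@labels))
    msgs <- c(msgs, "one provenance row per labelled window required")
  if (length(msgs)) msgs else TRUE
})
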