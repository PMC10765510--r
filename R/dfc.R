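# Static and sliding-window Pearson connectivity. Plain Pearson on boxcar
# (rectangular) windows, no Fisher z, no taper, no within-window detrending:
# anything else would change the clustered centroids. Windows never cross
# run boundaries.

#' Sliding-window specification
#'
#' Window length is given in seconds (the field's convention) and converted
#' to whole TRs by rounding to the nearest integer (ties up); the step is
#' given directly in TRs.
#'
#' @param lengthSeconds window length in seconds (> 0). Default 60 s.
#' @param stepTr step between window starts in TR (>= 1). Default 1.
#' @return object of class \code{WindowSpec}.
#' @export
windowSpec <- function(lengthSeconds = 60, stepTr = 1L) {
  stopifnot(lengthSeconds > 0, stepTr >= 1)
  structure(list(length_seconds = as.numeric(lengthSeconds),
                 step_tr = as.integer(stepTr)),
            class = "WindowSpec")
}

windowLengthTr <- function(spec, trSeconds) {
  len <- as.integer(floor(spec$length_seconds / trSeconds + 0.5))  # ties up
  if (len < 2L)
    stop("window length of ", spec$length_seconds, " s is under 2 TR at TR ",
         trSeconds, " s")
  len
}

checkFcMatrix <- function(m, tol = 1e-12) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol) stop("FC matrix not symmetric")
  if (any(diag(m) != 1)) stop("FC matrix diagonal must be exactly 1")
  if (any(m < -1 - tol) || any(m > 1 + tol)) stop("FC entries outside [-1, 1]")
  invisible(m)
}

pearsonFc <- function(x, context = "series") {
  v <- apply(x, 2, stats::sd)
  if (any(v == 0))
    stop(sprintf("degenerate input: zero-variance ROI '%s' in %s",
                 colnames(x)[which(v == 0)[1]], context))
  m <- stats::cor(x)
  m[m > 1] <- 1; m[m < -1] <- -1
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Static functional connectivity of a run
#'
#' Pairwise Pearson correlation over the entire time series, diagonal forced
#' to exactly 1.
#'
#' @param run a \linkS4class{RoiTimeSeries}.
#' @return N x N correlation matrix with ROI dimnames.
#' @examples
#' x <- RoiTimeSeries(cbind(a = c(0, 1, 2), b = c(0, 1, 3)), trSeconds = 2)
#' staticFC(x)["a", "b"]
#' @export
staticFC <- function(run) {
  m <- pearsonFc(roiData(run), context = sprintf("run %s/%s/%s",
      participantId(run), sessionLabel(run), runId(run)))
  checkFcMatrix(m)
}

#' Sliding-window dFC series of a run
#'
#' Rectangular windows of \code{spec$length_seconds} (rounded to whole TRs)
#' advanced by \code{spec$step_tr}; one Pearson correlation matrix per
#' window. Window coordinates are 0-based and half-open.
#'
#' @param run a \linkS4class{RoiTimeSeries}.
#' @param spec a \code{\link{windowSpec}}.
#' @return a \linkS4class{DfcSeries} with
#'   \code{floor((T - lengthTr)/stepTr) + 1} windows.
#' @export
slidingWindows <- function(run, spec = windowSpec()) {
  x <- roiData(run)
  tPoints <- nrow(x)
  len <- windowLengthTr(spec, trSeconds(run))
  if (tPoints < len)
    stop(sprintf("input too short: run %s/%s/%s has %d TR but the window needs %d",
                 participantId(run), sessionLabel(run), runId(run),
                 tPoints, len))
  step <- spec$step_tr
  w <- (tPoints - len) %/% step + 1L
  starts <- (seq_len(w) - 1L) * step
  n <- ncol(x)
  mats <- array(NA_real_, c(n, n, w),
                dimnames = list(colnames(x), colnames(x), NULL))
  for (i in seq_len(w)) {
    seg <- x[(starts[i] + 1L):(starts[i] + len), , drop = FALSE]
    mats[, , i] <- tryCatch(pearsonFc(seg, context = sprintf("window %d", i)),
                            error = function(e) stop(conditionMessage(e),
                                                     call. = FALSE))
  }
  new("DfcSeries", mats = mats, startsTr = as.integer(starts),
      lengthTr = len, stepTr = as.integer(step),
      trSeconds = trSeconds(run), participantId = participantId(run),
      session = sessionLabel(run), runId = runId(run))
}

#' Vectorize the upper triangle of an FC matrix
#'
#' Row-major upper triangle excluding the diagonal, length N(N-1)/2:
#' (1,2), (1,3), ..., (1,N), (2,3), ... \code{\link{devectorizeUpper}} is
#' the exact inverse.
#'
#' @param fc N x N symmetric matrix.
#' @return numeric feature vector of length N(N-1)/2.
#' @export
vectorizeUpper <- function(fc) {
  n <- nrow(fc)
  t(fc)[lower.tri(fc)]  # row-major upper triangle
}

#' Restore a symmetric unit-diagonal matrix from its upper-triangle vector
#'
#' @param v feature vector of length N(N-1)/2 (row-major upper triangle).
#' @param roiNames optional ROI labels used as dimnames.
#' @return N x N symmetric matrix with unit diagonal.
#' @export
devectorizeUpper <- function(v, roiNames = NULL) {
  p <- length(v)
  n <- as.integer(round((1 + sqrt(1 + 8 * p)) / 2))
  if (n * (n - 1L) / 2L != p)
    stop("vector length ", p, " is not N(N-1)/2 for any integer N")
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- v
  diag(m) <- 1
  if (!is.null(roiNames)) dimnames(m) <- list(roiNames, roiNames)
  m
}

#' Pool dFC windows across runs for clustering
#'
#' Stacks the vectorized upper triangles of every window of every run into
#' one feature matrix with per-window provenance. All runs must share the
#' same ROI set and order.
#'
#' @param dfcList list of \linkS4class{DfcSeries}.
#' @return a \linkS4class{WindowPool}.
#' @export
poolWindows <- function(dfcList) {
  stopifnot(length(dfcList) >= 1L)
  rn <- roiNames(dfcList[[1]])
  feats <- vector("list", length(dfcList))
  provs <- vector("list", length(dfcList))
  for (i in seq_along(dfcList)) {
    d <- dfcList[[i]]
    if (!identical(roiNames(d), rn))
      stop("all pooled runs must share the same ROI names and order")
    w <- nWindows(d)
    n <- length(rn)
    f <- matrix(NA_real_, w, n * (n - 1L) / 2L)
    for (j in seq_len(w)) f[j, ] <- vectorizeUpper(d@mats[, , j])
    feats[[i]] <- f
    provs[[i]] <- data.frame(
      participant_id = d@participantId, session = d@session,
      run_id = d@runId, window_index = seq_len(w),
      start_tr = d@startsTr, tr_seconds = d@trSeconds,
      step_tr = d@stepTr, window_strength = rowMeans(f),
      stringsAsFactors = FALSE)
  }
  new("WindowPool", features = do.call(rbind, feats),
      provenance = do.call(rbind, provs), roiNames = rn)
}
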