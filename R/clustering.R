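# K-means state identification over pooled dFC windows, cluster-quality
# criteria, parameter sweeps, state metrics and lobe-level centroid
# summaries. All windows of all participants and both sessions are clustered
# together; session-level metrics are computed afterwards by slicing labels.

# Squared Euclidean distances from rows of x to rows of centers.
distSqToCenters <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

# At least k distinct rows? Random-projection prefilter, exact fallback.
hasKDistinctRows <- function(x, k) {
  if (nrow(x) < k) return(FALSE)
  proj <- x %*% sin(seq_len(ncol(x)))
  u <- !duplicated(round(proj, 10))
  if (sum(u) >= k) return(TRUE)
  sum(!duplicated(x)) >= k
}

# Lloyd iterations from given initial centroids. Ties in nearest-centroid
# assignment break toward the lower centroid index; an emptied cluster is
# reseeded with the point farthest from its current centroid. Stops when the
# assignment is unchanged or after maxIter iterations. One GEMM per
# iteration: argmin_l ||x - c_l||^2 = argmax_l (x.c_l - ||c_l||^2/2), and
# the within-cluster sum of squares is recovered from the same scores.
lloydKmeans <- function(x, centers, maxIter = 300L) {
  w <- nrow(x)
  k <- nrow(centers)
  xsqTotal <- sum(x^2)
  labels <- integer(w)
  path <- numeric(0)
  for (iter in seq_len(maxIter)) {
    g <- tcrossprod(x, centers)                  # w x k scores
    g <- sweep(g, 2, 0.5 * rowSums(centers^2), "-")
    if (iter > 1L)  # inertia of the previous assignment under updated centers
      path <- c(path, xsqTotal - 2 * sum(g[cbind(seq_len(w), labels)]))
    newLabels <- max.col(g, ties.method = "first")
    for (c in seq_len(k)) {          # reseed emptied clusters deterministically
      if (!any(newLabels == c)) {
        far <- which.min(g[cbind(seq_len(w), newLabels)] -
                           0.5 * rowSums(x^2))   # farthest from its centroid
        centers[c, ] <- x[far, ]
        newLabels[far] <- c
        g[, c] <- tcrossprod(x, centers[c, , drop = FALSE]) -
          0.5 * sum(centers[c, ]^2)
      }
    }
    converged <- identical(newLabels, labels)
    labels <- newLabels
    centers <- rowsum(x, labels, reorder = TRUE) /
      tabulate(labels, k)
    if (converged) break
  }
  g <- tcrossprod(x, centers)
  g <- sweep(g, 2, 0.5 * rowSums(centers^2), "-")
  inertia <- xsqTotal - 2 * sum(g[cbind(seq_len(w), labels)])
  if (!length(path) || inertia != path[length(path)])
    path <- c(path, inertia)
  list(labels = labels, centers = centers,
       inertia = inertia, inertiaPath = path)
}

#' Cluster pooled dFC windows into connectivity states
#'
#' Euclidean K-means over vectorized window upper triangles: initial
#' centroids are drawn uniformly at random from the data points, Lloyd
#' iterations run to convergence (assignment unchanged, cap 300), the best
#' restart by within-cluster sum of squares is kept, and the states are
#' reordered by descending centroid strength so that state 1 is always the
#' strongest.
#'
#' @param pool a \linkS4class{WindowPool} (or a plain feature matrix).
#' @param k number of states; the pool must contain at least k distinct
#'   windows.
#' @param restarts number of random restarts (default 10).
#' @param seed RNG seed recorded on the model.
#' @return a \linkS4class{StateModel}.
#' @export
kmeansStates <- function(pool, k, restarts = 10L, seed = 1L) {
  if (is(pool, "WindowPool")) {
    x <- pool@features
    prov <- pool@provenance
    rn <- pool@roiNames
  } else {
    x <- as.matrix(pool)
    prov <- data.frame(participant_id = "p01", session = "pre_op",
                       run_id = "r01", window_index = seq_len(nrow(x)),
                       start_tr = seq_len(nrow(x)) - 1L, tr_seconds = 1,
                       step_tr = 1L, window_strength = rowMeans(x),
                       stringsAsFactors = FALSE)
    rn <- paste0("V", seq_len(as.integer(round((1 + sqrt(1 + 8 * ncol(x))) / 2))))
  }
  k <- as.integer(k)
  stopifnot(k >= 1L, restarts >= 1L, nrow(x) >= k)
  if (!hasKDistinctRows(x, k))
    stop("degenerate clustering: fewer than k distinct windows")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- sample.int(nrow(x), k)
    fit <- lloydKmeans(x, x[init, , drop = FALSE])
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  strengths <- rowMeans(best$centers)
  ord <- order(strengths, decreasing = TRUE)
  relabel <- match(best$labels, ord)
  n <- length(rn)
  p <- ncol(x)
  if (n * (n - 1L) / 2L == p) {
    centroids <- array(NA_real_, c(n, n, k))
    for (s in seq_len(k))
      centroids[, , s] <- devectorizeUpper(best$centers[ord[s], ], rn)
  } else {
    # raw feature vectors (no FC geometry): keep centroids as 1 x p x k
    rn <- character(0)
    centroids <- array(t(best$centers[ord, , drop = FALSE]), c(1L, p, k))
  }
  new("StateModel", k = k, centroids = centroids,
      labels = as.integer(relabel), strengths = strengths[ord],
      inertia = best$inertia, inertiaPath = best$inertiaPath,
      seed = as.integer(seed), restarts = as.integer(restarts),
      provenance = prov, roiNames = rn)
}

# Squared distances to centers by explicit differencing: slower than the
# BLAS expansion but free of its cancellation error.
distSqToCentersExact <- function(x, centers) {
  k <- nrow(centers)
  d2 <- matrix(0, nrow(x), k)
  for (c in seq_len(k))
    d2[, c] <- rowSums(sweep(x, 2, centers[c, ])^2)
  d2
}

# Mean Euclidean distance from each sample to every cluster (samples x k).
# Small problems use stats::dist (exact differencing); large pools fall back
# to chunked BLAS expansion, whose ~1e-8 relative error is immaterial at
# that scale.
meanDistToClusters <- function(x, labels, k, chunk = 1024L) {
  w <- nrow(x)
  sizes <- tabulate(labels, k)
  ind <- matrix(0, w, k)
  ind[cbind(seq_len(w), labels)] <- 1
  if (w <= 4096L) {
    out <- as.matrix(stats::dist(x)) %*% ind
  } else {
    out <- matrix(0, w, k)
    for (s in seq(1L, w, by = chunk)) {
      e <- min(s + chunk - 1L, w)
      d2 <- distSqToCenters(x[s:e, , drop = FALSE], x)
      out[s:e, ] <- sqrt(d2) %*% ind
    }
  }
  sweep(out, 2, sizes, "/")
}

#' Cluster-quality criteria for one clustering
#'
#' Computes the four quality measures used to pick sliding-window and
#' clustering parameters: inertia (within-cluster sum of squared distances),
#' the mean silhouette coefficient (Euclidean dissimilarity; samples in
#' singleton clusters contribute 0), the Calinski-Harabasz index
#' (between-cluster over within-cluster dispersion, each scaled by its
#' degrees of freedom) and the Davies-Bouldin index (mean over clusters of
#' the worst ratio of summed cluster diameters to centroid separation,
#' where a cluster's diameter is the average member-to-centroid distance).
#'
#' @param features samples x features numeric matrix.
#' @param labels integer cluster labels in 1..k, every cluster nonempty; at
#'   least 2 clusters and at least one cluster with 2 or more members.
#' @param parameter optional (name, value) pair recorded in the report.
#' @return one-row data.frame: \code{k}, \code{inertia}, \code{silhouette},
#'   \code{calinski_harabasz}, \code{davies_bouldin} (plus the parameter
#'   columns when given).
#' @examples
#' x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
#' qualityCriteria(x, c(1, 1, 2, 2))
#' @export
qualityCriteria <- function(features, labels, parameter = NULL) {
  x <- as.matrix(features)
  labels <- as.integer(labels)
  k <- max(labels)
  sizes <- tabulate(labels, k)
  if (k < 2L || any(sizes == 0L))
    stop("need >= 2 nonempty clusters for quality criteria")
  if (all(sizes < 2L))
    stop("silhouette undefined: every cluster is a singleton")
  w <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  for (c in seq_len(k))
    centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
  d2c <- distSqToCentersExact(x, centers)
  inertia <- sum(d2c[cbind(seq_len(w), labels)])

  md <- meanDistToClusters(x, labels, k)
  own <- md[cbind(seq_len(w), labels)]
  nOwn <- sizes[labels]
  a <- ifelse(nOwn > 1L, own * nOwn / (nOwn - 1L), NA_real_)
  md[cbind(seq_len(w), labels)] <- Inf
  b <- apply(md, 1, min)
  s <- ifelse(is.na(a), 0, (b - a) / pmax(a, b))
  s[is.na(a)] <- 0
  silhouette <- mean(s)

  z <- colMeans(x)
  between <- sum(sizes * rowSums(sweep(centers, 2, z)^2))
  ch <- (between / (k - 1)) / (inertia / (w - k))

  diam <- vapply(seq_len(k), function(c)
    mean(sqrt(d2c[labels == c, c])), numeric(1))
  dcent <- as.matrix(stats::dist(centers))
  r <- outer(diam, diam, "+") / dcent
  diag(r) <- -Inf
  db <- mean(apply(r, 1, max))

  out <- data.frame(k = k, inertia = inertia, silhouette = silhouette,
                    calinski_harabasz = ch, davies_bouldin = db)
  if (!is.null(parameter)) {
    out <- cbind(data.frame(parameter = parameter[[1]],
                            value = as.numeric(parameter[[2]])), out)
  }
  out
}

#' Sweep a clustering parameter and report quality criteria
#'
#' Re-runs the pooled clustering over a grid of one parameter --
#' \code{window_seconds}, \code{step_tr} or \code{k} -- holding the others
#' fixed, and reports the four quality criteria per grid value. Elbow/optimum
#' selection is left to the caller. A grid value that violates a component
#' precondition is recorded as an error row and the sweep continues.
#'
#' @param runs list of \linkS4class{RoiTimeSeries}.
#' @param param one of \code{"window_seconds"}, \code{"step_tr"}, \code{"k"}.
#' @param grid numeric vector of parameter values; defaults mirror the
#'   studied ranges (window 30-180 s, step 1-10 TR, k 2-10).
#' @param lengthSeconds,stepTr,k the fixed settings (defaults 60 s, 1 TR, 2).
#' @param restarts,seed K-means settings.
#' @return data.frame with one row per grid value: \code{parameter},
#'   \code{value}, \code{k}, \code{inertia}, \code{silhouette},
#'   \code{calinski_harabasz}, \code{davies_bouldin}, \code{error}.
#' @export
sweepClustering <- function(runs, param = c("k", "window_seconds", "step_tr"),
                            grid = NULL, lengthSeconds = 60, stepTr = 1L,
                            k = 2L, restarts = 10L, seed = 1L) {
  param <- match.arg(param)
  if (is.null(grid))
    grid <- switch(param, k = 2:10, window_seconds = seq(30, 180, by = 10),
                   step_tr = 1:10)
  stopifnot(length(grid) >= 1L)
  poolFor <- function(ls, st) {
    poolWindows(lapply(runs, slidingWindows,
                       spec = windowSpec(ls, st)))
  }
  fixedPool <- if (param == "k") poolFor(lengthSeconds, stepTr) else NULL
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    g <- grid[i]
    rows[[i]] <- tryCatch({
      pool <- switch(param,
        k = fixedPool,
        window_seconds = poolFor(g, stepTr),
        step_tr = poolFor(lengthSeconds, as.integer(g)))
      kk <- if (param == "k") as.integer(g) else as.integer(k)
      model <- kmeansStates(pool, k = kk, restarts = restarts, seed = seed)
      q <- qualityCriteria(pool@features, stateLabels(model),
                           parameter = list(param, g))
      q$inertia <- modelInertia(model)
      q$error <- NA_character_
      q
    }, error = function(e) data.frame(
      parameter = param, value = as.numeric(g), k = NA_integer_,
      inertia = NA_real_, silhouette = NA_real_,
      calinski_harabasz = NA_real_, davies_bouldin = NA_real_,
      error = conditionMessage(e), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' State metrics per participant and session
#'
#' For every (participant, session, state): the occupancy rate (fraction of
#' that participant-session's windows assigned to the state), the dwell time
#' (mean duration of uninterrupted consecutive-window visits, in seconds;
#' visits never cross run boundaries; missing -- not zero -- for a state the
#' participant-session never enters), the transition rate (state-label
#' changes per minute of windowed time, pooled over the session's runs; by
#' construction identical across the session's state rows), and two
#' connectivity strengths: \code{strength}, the mean upper-triangle r of the
#' state centroid (a property of the shared state, constant across
#' sessions), and \code{strength_windows}, the mean upper-triangle r of the
#' member windows of that participant-session (the session-resolved strength
#' used for pre/post comparison).
#'
#' @param model a \linkS4class{StateModel}.
#' @return data.frame with one row per (participant, session, state).
#' @export
stateMetrics <- function(model) {
  prov <- model@provenance
  labels <- model@labels
  k <- model@k
  groups <- split(seq_along(labels),
                  list(prov$participant_id, prov$session), drop = TRUE)
  rows <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    pid <- prov$participant_id[idx[1]]
    sess <- prov$session[idx[1]]
    total <- length(idx)
    visitSeconds <- vector("list", k)
    changes <- 0L
    seconds <- 0
    for (ridx in split(idx, prov$run_id[idx])) {
      ridx <- ridx[order(prov$window_index[ridx])]
      lab <- labels[ridx]
      secPerWin <- prov$step_tr[ridx[1]] * prov$tr_seconds[ridx[1]]
      r <- rle(lab)
      for (s in unique(r$values))
        visitSeconds[[s]] <- c(visitSeconds[[s]],
                               r$lengths[r$values == s] * secPerWin)
      changes <- changes + sum(diff(lab) != 0L)
      seconds <- seconds + length(lab) * secPerWin
    }
    tpm <- changes / (seconds / 60)
    for (s in seq_len(k)) {
      inState <- idx[labels[idx] == s]
      occ <- length(inState) / total
      dwell <- if (length(visitSeconds[[s]])) mean(visitSeconds[[s]]) else NA_real_
      sw <- if (length(inState)) mean(prov$window_strength[inState]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, session = sess, state = s,
        n_windows = length(inState), occupancy_rate = occ,
        dwell_time_seconds = dwell, transitions_per_minute = tpm,
        strength = model@strengths[s], strength_windows = sw,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lobe-level summary of a connectivity matrix
#'
#' Mean of the matrix entries over all ROI pairs spanning each lobe pair
#' (within-lobe pairs use the upper triangle only, so self-correlations are
#' never averaged in). To summarize a pre/post difference, pass the
#' difference matrix.
#'
#' @param mat N x N symmetric matrix with ROI rownames (a state centroid, a
#'   static FC matrix, or a difference of two such matrices).
#' @param lobeMap lobe map from \code{\link{loadLobeMap}} /
#'   \code{\link{defaultLobeMap}}; every ROI in \code{mat} must be mapped.
#' @return data.frame with columns \code{lobe_i}, \code{lobe_j},
#'   \code{mean_r}, one row per unordered lobe pair (including within-lobe).
#' @export
lobeSummary <- function(mat, lobeMap) {
  rois <- rownames(mat)
  if (is.null(rois)) stop("matrix must carry ROI rownames")
  unmapped <- setdiff(rois, names(lobeMap$roi_to_lobe))
  if (length(unmapped))
    stop("mapping error: unmapped ROI(s): ", paste(unmapped, collapse = ", "))
  lobes <- lobeMap$lobes[lobeMap$lobes %in% lobeMap$roi_to_lobe[rois]]
  assign <- lobeMap$roi_to_lobe[rois]
  rows <- list()
  for (i in seq_along(lobes)) for (j in i:length(lobes)) {
    ri <- which(assign == lobes[i])
    rj <- which(assign == lobes[j])
    if (i == j) {
      sub <- mat[ri, ri, drop = FALSE]
      vals <- sub[upper.tri(sub)]
    } else {
      vals <- as.vector(mat[ri, rj, drop = FALSE])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      lobe_i = lobes[i], lobe_j = lobes[j],
      mean_r = if (length(vals)) mean(vals) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
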