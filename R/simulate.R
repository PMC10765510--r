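# Synthetic multi-ROI time series with planted Markov-switching
# connectivity states and a configurable pre/post "stimulation" effect.
# Observations are i.i.d. multivariate normal given the hidden state (an
# optional AR(1) coefficient adds temporal smoothness); the windowed
# correlation structure is what the downstream pipeline consumes, so the
# state-conditional covariance is the planted structure that matters.

#' Block-structured state covariance
#'
#' Builds a unit-diagonal block correlation matrix: within-lobe off-diagonal
#' entries near \code{withinR}, between-lobe entries near \code{betweenR},
#' plus optional symmetric Gaussian jitter; if jitter (or rounding) leaves
#' the matrix non-positive-definite it is projected to the nearest
#' positive-definite correlation matrix.
#'
#' @param nRois number of ROIs.
#' @param lobeSizes integer vector of block sizes; must sum to \code{nRois}.
#' @param withinR,betweenR within-block and between-block correlations;
#'   \code{abs() < 1} and \code{withinR >= betweenR}.
#' @param jitter standard deviation of the symmetric perturbation added to
#'   off-diagonal entries (0 = exact block matrix).
#' @param seed RNG seed for the jitter.
#' @param name state name.
#' @return a state spec: list with \code{name}, \code{covariance} (N x N
#'   symmetric positive-definite), \code{description}.
#' @export
makeBlockCovariance <- function(nRois, lobeSizes, withinR, betweenR,
                                jitter = 0, seed = 1L,
                                name = "state") {
  stopifnot(sum(lobeSizes) == nRois, abs(withinR) < 1, abs(betweenR) < 1,
            withinR >= betweenR, jitter >= 0)
  block <- rep(seq_along(lobeSizes), lobeSizes)
  same <- outer(block, block, "==")
  m <- ifelse(same, withinR, betweenR)
  diag(m) <- 1
  if (jitter > 0) {
    set.seed(as.integer(seed))
    e <- matrix(stats::rnorm(nRois * nRois, sd = jitter), nRois, nRois)
    e <- (e + t(e)) / 2
    diag(e) <- 0
    m <- m + e
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    m <- as.matrix(Matrix::nearPD(m, corr = TRUE)$mat)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("generation error: covariance not positive-definite after projection")
  }
  m <- (m + t(m)) / 2
  structure(list(name = name, covariance = m,
                 description = sprintf("block correlation within %.3g / between %.3g",
                                       withinR, betweenR)),
            class = "StateSpec")
}

checkStateSpec <- function(spec) {
  cv <- spec$covariance
  stopifnot(is.matrix(cv), nrow(cv) == ncol(cv))
  if (max(abs(cv - t(cv))) > 1e-10)
    stop("spec error: state covariance not symmetric")
  if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("spec error: state covariance not positive-definite")
  invisible(spec)
}

#' Markov switching specification
#'
#' @param transitionMatrix K x K row-stochastic matrix of per-TR transition
#'   probabilities.
#' @param initialDistribution length-K probability vector; defaults to the
#'   stationary distribution of the chain.
#' @return a switching spec list.
#' @export
makeSwitchingSpec <- function(transitionMatrix,
                              initialDistribution = NULL) {
  tm <- as.matrix(transitionMatrix)
  stopifnot(nrow(tm) == ncol(tm), all(tm >= 0))
  if (max(abs(rowSums(tm) - 1)) > 1e-12)
    stop("spec error: transition matrix rows must sum to 1")
  if (is.null(initialDistribution))
    initialDistribution <- stationaryDistribution(tm)
  stopifnot(length(initialDistribution) == nrow(tm),
            all(initialDistribution >= 0),
            abs(sum(initialDistribution) - 1) <= 1e-12)
  list(transition_matrix = tm,
       initial_distribution = as.numeric(initialDistribution))
}

#' Stationary distribution of a finite Markov chain
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' a probability vector.
#'
#' @param transitionMatrix K x K row-stochastic matrix.
#' @return length-K stationary probability vector.
#' @export
stationaryDistribution <- function(transitionMatrix) {
  e <- eigen(t(transitionMatrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("no valid stationary distribution found")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Analytic mean sojourn times, in TR
#'
#' Mean uninterrupted stay in each state of a Markov chain,
#' \code{1 / (1 - p_kk)} TR (geometric sojourn).
#'
#' @param transitionMatrix K x K row-stochastic matrix.
#' @return length-K vector of mean sojourn times in TR units.
#' @export
meanSojournTr <- function(transitionMatrix) {
  1 / (1 - diag(as.matrix(transitionMatrix)))
}

sampleMarkovChain <- function(switching, tPoints) {
  tm <- switching$transition_matrix
  k <- nrow(tm)
  cum <- t(apply(tm, 1, cumsum))
  lab <- integer(tPoints)
  u <- stats::runif(tPoints)
  lab[1] <- findInterval(u[1], cumsum(switching$initial_distribution),
                         left.open = TRUE) + 1L
  for (t in 2:tPoints)
    lab[t] <- findInterval(u[t], cum[lab[t - 1L], ], left.open = TRUE) + 1L
  lab
}

#' Simulate one run with Markov-switching connectivity states
#'
#' Draws a hidden per-TR state sequence from the Markov chain, then at each
#' TR draws the N-ROI observation from a zero-mean multivariate normal with
#' the active state's covariance. Ground truth records the label sequence,
#' the analytic stationary occupancy (left unit eigenvector of the
#' transition matrix) and the analytic mean sojourn \code{1/(1 - p_kk)} TR.
#'
#' @param states list of state specs (see \code{\link{makeBlockCovariance}});
#'   all must share the same N.
#' @param switching switching spec (see \code{\link{makeSwitchingSpec}}).
#' @param tPoints number of time points (>= 2).
#' @param trSeconds repetition time in seconds.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @param participantId,session,runId identity recorded on the run.
#' @param ar AR(1) coefficient in [0, 1); 0 (default) gives i.i.d.
#'   observations given the state.
#' @return list with \code{run} (a \linkS4class{RoiTimeSeries}) and
#'   \code{truth} (list: \code{state_labels_per_tr}, \code{true_occupancy},
#'   \code{true_mean_sojourn_tr}, \code{seed}).
#' @examples
#' st <- list(makeBlockCovariance(4, c(2, 2), 0.5, 0.1),
#'            makeBlockCovariance(4, c(2, 2), 0.2, 0.0))
#' sw <- makeSwitchingSpec(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
#' sim <- simulateRun(st, sw, tPoints = 100, trSeconds = 2, seed = 1)
#' sim$truth$true_occupancy
#' @export
simulateRun <- function(states, switching, tPoints, trSeconds, seed,
                        participantId = "sim01", session = "pre_op",
                        runId = "r01", ar = 0) {
  stopifnot(tPoints >= 2, ar >= 0, ar < 1)
  lapply(states, checkStateSpec)
  ns <- vapply(states, function(s) nrow(s$covariance), integer(1))
  if (length(unique(ns)) != 1L)
    stop("spec error: all state covariances must share the same N")
  n <- ns[1]
  if (length(states) != nrow(switching$transition_matrix))
    stop("spec error: switching matrix size must match number of states")
  set.seed(as.integer(seed))
  lab <- sampleMarkovChain(switching, tPoints)
  z <- matrix(stats::rnorm(tPoints * n), tPoints, n)
  x <- matrix(0, tPoints, n)
  chols <- lapply(states, function(s) chol(s$covariance))
  for (k in seq_along(states)) {
    idx <- which(lab == k)
    if (length(idx)) x[idx, ] <- z[idx, , drop = FALSE] %*% chols[[k]]
  }
  if (ar > 0) {
    sc <- sqrt(1 - ar^2)
    for (t in 2:tPoints) x[t, ] <- ar * x[t - 1L, ] + sc * x[t, ]
  }
  colnames(x) <- paste0("ROI", seq_len(n))
  tm <- switching$transition_matrix
  occ <- stationaryDistribution(tm)
  truth <- list(state_labels_per_tr = lab,
                true_occupancy = occ,
                true_mean_sojourn_tr = meanSojournTr(tm),
                seed = as.integer(seed))
  list(run = RoiTimeSeries(x, trSeconds = trSeconds,
                           participantId = participantId,
                           session = session, runId = runId),
       truth = truth)
}

#' Ground-truth window labels by majority rule
#'
#' Maps a per-TR state-label sequence to per-window labels: each window's
#' label is the majority of the per-TR labels it covers; ties break toward
#' the earlier (smaller) state index.
#'
#' @param labelsPerTr integer per-TR state labels.
#' @param lengthTr,stepTr window length and step in TRs.
#' @return integer vector of per-window majority labels.
#' @export
windowMajorityLabels <- function(labelsPerTr, lengthTr, stepTr) {
  tPoints <- length(labelsPerTr)
  stopifnot(tPoints >= lengthTr)
  w <- (tPoints - lengthTr) %/% stepTr + 1L
  starts <- (seq_len(w) - 1L) * stepTr
  vapply(starts, function(s) {
    tab <- tabulate(labelsPerTr[(s + 1L):(s + lengthTr)])
    which.max(tab)  # which.max takes the first maximum: earlier state wins ties
  }, integer(1))
}

#' Built-in simulation scenario mirroring the studied pre/post contrast
#'
#' Two planted connectivity states -- a strongly connected and a sparsely
#' connected one -- switching as a per-TR Markov chain, with the post
#' session's state covariances scaled down and its switching matrix
#' favouring the sparse state. Defaults: 30 ROIs in 6 lobes of 5, TR 2 s,
#' per participant 2 pre-op runs of 144 TR and 2 post-op runs of 300 TR;
#' strong state within/between-lobe r 0.70/0.13 (pronounced lobe-block
#' structure, mean upper-triangle r ~0.21), sparse 0.10/0.075 (weak and
#' diffuse, ~0.079); pre stationary occupancy of the strong state 0.58
#' (mean sojourns 150 and 108.62 TR), post 0.16 (sojourns 30 and 157.5 TR);
#' post connectivity scale 0.85. The within/between contrast and the
#' sojourn lengths are set so that the planted window-level structure is
#' recoverable by the pooled clustering: the generator exists as a
#' ground-truthed test bed, so states distinguishable at the default
#' window length are part of its contract.
#'
#' @param nRois,nLobes parcellation size.
#' @param tr repetition time in seconds.
#' @param tPre,tPost run lengths in TR.
#' @param preRuns,postRuns runs per participant and session.
#' @param postScale multiplicative factor on the post-session state
#'   correlations (< 1 plants a connectivity-strength decrease).
#' @param jitter off-diagonal jitter of the state covariances.
#' @return scenario list consumed by \code{\link{simulateCohort}}.
#' @export
scenarioPaperLike <- function(nRois = 30L, nLobes = 6L, tr = 2,
                              tPre = 144L, tPost = 300L,
                              preRuns = 2L, postRuns = 2L,
                              postScale = 0.85, jitter = 0.02) {
  stopifnot(nRois %% nLobes == 0L)
  lobeSizes <- rep(nRois %/% nLobes, nLobes)
  mkStates <- function(scale, seedBase) list(
    makeBlockCovariance(nRois, lobeSizes, 0.70 * scale, 0.13 * scale,
                        jitter = jitter, seed = seedBase, name = "strong"),
    makeBlockCovariance(nRois, lobeSizes, 0.10 * scale, 0.075 * scale,
                        jitter = jitter, seed = seedBase + 1L,
                        name = "sparse"))
  # sojourns (TR): pre 150 / 108.62 -> stationary 0.58; post 30 / 157.5 -> 0.16
  swPre <- makeSwitchingSpec(rbind(c(1 - 1 / 150, 1 / 150),
                                   c(1 / 108.62, 1 - 1 / 108.62)))
  swPost <- makeSwitchingSpec(rbind(c(1 - 1 / 30, 1 / 30),
                                    c(1 / 157.5, 1 - 1 / 157.5)))
  list(name = "paper_like", nRois = nRois, lobeSizes = lobeSizes, tr = tr,
       pre = list(statesFor = function(seed) mkStates(1, seed),
                  switching = swPre, t = tPre, runs = preRuns),
       post = list(statesFor = function(seed) mkStates(postScale, seed),
                   switching = swPost, t = tPost, runs = postRuns))
}

#' Built-in null scenario with no pre/post effect
#'
#' A single connectivity state, identical generative settings pre and post:
#' used for type-I-error calibration of the group comparison and for
#' cluster-quality behaviour under the absence of state structure.
#'
#' @param nRois,nLobes,tr,tPoints,runsPerSession scenario size settings.
#' @param jitter off-diagonal jitter of the state covariance.
#' @return scenario list consumed by \code{\link{simulateCohort}}.
#' @export
scenarioNullNoEffect <- function(nRois = 12L, nLobes = 6L, tr = 2,
                                 tPoints = 80L, runsPerSession = 1L,
                                 jitter = 0.02) {
  stopifnot(nRois %% nLobes == 0L)
  lobeSizes <- rep(nRois %/% nLobes, nLobes)
  mk <- function(seed) list(
    makeBlockCovariance(nRois, lobeSizes, 0.3, 0.12, jitter = jitter,
                        seed = seed, name = "only"))
  sw <- makeSwitchingSpec(matrix(1, 1, 1))
  side <- function() list(statesFor = mk, switching = sw, t = tPoints,
                          runs = runsPerSession)
  list(name = "null_no_effect", nRois = nRois, lobeSizes = lobeSizes,
       tr = tr, pre = side(), post = side())
}

#' Simulate a pre/post cohort with planted ground truth
#'
#' Generates every participant's pre-op and post-op runs under a scenario
#' (see \code{\link{scenarioPaperLike}}, \code{\link{scenarioNullNoEffect}}),
#' optionally writing per-run CSV files plus a manifest.
#'
#' @param nParticipants number of participants (0 gives an empty cohort).
#' @param scenario scenario list; default \code{scenarioPaperLike()}.
#' @param seed master RNG seed; per-run seeds are derived deterministically.
#' @param outDir if non-NULL, time-series CSVs, \code{manifest.csv} and
#'   per-run ground-truth label CSVs are written there.
#' @return list with \code{runs} (list of \linkS4class{RoiTimeSeries}),
#'   \code{manifest} (data.frame), \code{truths} (per-run ground truth,
#'   named by \code{participant/session/run}), \code{scenario}, \code{seed}.
#' @export
simulateCohort <- function(nParticipants, scenario = scenarioPaperLike(),
                           seed = 1L, outDir = NULL) {
  seed <- as.integer(seed)
  runs <- list(); truths <- list()
  rows <- list()
  counter <- 0L
  for (i in seq_len(nParticipants)) {
    pid <- sprintf("sub%02d", i)
    for (sess in VALID_SESSIONS) {
      side <- if (sess == "pre_op") scenario$pre else scenario$post
      states <- side$statesFor(seed)
      for (r in seq_len(side$runs)) {
        counter <- counter + 1L
        rid <- sprintf("run%02d", r)
        # distinct deterministic sub-seed per run, kept well below 2^31
        # (double arithmetic: products of large seeds overflow integers)
        runSeed <- as.integer((as.numeric(seed) * 10007 + counter * 131) %%
                                2000000011)
        sim <- simulateRun(states, side$switching, side$t, scenario$tr,
                           seed = runSeed, participantId = pid,
                           session = sess, runId = rid)
        key <- paste(pid, sess, rid, sep = "/")
        runs[[key]] <- sim$run
        truths[[key]] <- sim$truth
        path <- NA_character_
        if (!is.null(outDir)) {
          if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
          path <- file.path(outDir, sprintf("%s_%s_%s.csv", pid, sess, rid))
          writeTimeSeries(sim$run, path)
          utils::write.csv(data.frame(tr = seq_len(side$t) - 1L,
                                      state = sim$truth$state_labels_per_tr),
                           file.path(outDir,
                                     sprintf("%s_%s_%s_truth.csv", pid, sess, rid)),
                           row.names = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, session = sess, run_id = rid,
          tr_seconds = scenario$tr, path = path,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(), session = character(),
               run_id = character(), tr_seconds = numeric(),
               path = character(), stringsAsFactors = FALSE)
  if (!is.null(outDir) && nrow(manifest))
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  list(runs = runs, manifest = manifest, truths = truths,
       scenario = scenario, seed = seed)
}
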