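# Shared fixtures built once per test run. The paper-like cohort pipeline is
# expensive, so the recovery and directional-effect tests share one fit.

.fixtures <- new.env(parent = emptyenv())

paperCohortFit <- function() {
  if (!is.null(.fixtures$cohort)) return(.fixtures$cohort)
  coh <- simulateCohort(20, scenarioPaperLike(), seed = 42)
  dfcs <- lapply(coh$runs, slidingWindows, spec = windowSpec(60, 1))
  pool <- poolWindows(dfcs)
  model <- kmeansStates(pool, k = 2, restarts = 10, seed = 42)
  gt <- unlist(lapply(names(coh$runs), function(k)
    windowMajorityLabels(coh$truths[[k]]$state_labels_per_tr,
                         lengthTr = 30L, stepTr = 1L)))
  .fixtures$cohort <- list(coh = coh, pool = pool, model = model, gt = gt)
  .fixtures$cohort
}

# small two-state run for unit tests
smallTwoStateRun <- function(tPoints = 300L, seed = 11L) {
  states <- list(
    makeBlockCovariance(8, c(4, 4), 0.6, 0.1, name = "strong"),
    makeBlockCovariance(8, c(4, 4), 0.1, 0.0, name = "sparse"))
  switching <- makeSwitchingSpec(rbind(c(0.96, 0.04), c(0.04, 0.96)))
  simulateRun(states, switching, tPoints = tPoints, trSeconds = 2,
              seed = seed)
}

metricTable <- function(sm, metric, state) {
  d <- sm[sm$state == state, c("participant_id", "session", metric)]
  names(d)[3] <- "value"
  d
}
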