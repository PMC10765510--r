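# Nonparametric pre/post comparison. The group test is the two-sided
# Mann-Whitney U: exact by complete enumeration of rank arrangements for
# small samples (n1 + n2 <= 12), otherwise the normal approximation with
# tie correction and continuity correction. The reported statistic is the
# standardized (z-scaled) U of the pre sample, so a positive statistic
# means the metric decreased after stimulation.

#' Normality and equal-variance precondition tests
#'
#' Shapiro-Wilk per group and the Levene test (center = median,
#' Brown-Forsythe variant) across the two groups; used to justify the
#' nonparametric route. Groups of fewer than 3 values, or degenerate
#' (constant) data, skip the corresponding test with a reason.
#'
#' @param pre,post numeric samples.
#' @return list: \code{shapiro_p_pre}, \code{shapiro_p_post},
#'   \code{levene_p} (NA when skipped), \code{skipped} (character reasons,
#'   empty when all tests ran).
#' @export
preconditionTests <- function(pre, post) {
  out <- list(shapiro_p_pre = NA_real_, shapiro_p_post = NA_real_,
              levene_p = NA_real_, skipped = character())
  shap <- function(x, which) {
    if (length(x) < 3L)
      out$skipped <<- c(out$skipped, paste0("shapiro_", which, ": n < 3"))
    else if (stats::sd(x) == 0)
      out$skipped <<- c(out$skipped, paste0("shapiro_", which, ": constant sample"))
    else return(stats::shapiro.test(x)$p.value)
    NA_real_
  }
  out$shapiro_p_pre <- shap(pre, "pre")
  out$shapiro_p_post <- shap(post, "post")
  if (length(pre) < 3L || length(post) < 3L) {
    out$skipped <- c(out$skipped, "levene: group n < 3")
  } else {
    y <- c(pre, post)
    g <- factor(rep(c("pre", "post"), c(length(pre), length(post))))
    z <- abs(y - stats::ave(y, g, FUN = stats::median))
    if (stats::sd(z) == 0) {
      out$skipped <- c(out$skipped, "levene: degenerate (no spread about group medians)")
    } else {
      lt <- car::leveneTest(y, g, center = stats::median)
      out$levene_p <- lt[["Pr(>F)"]][1]
    }
  }
  out
}

mwStatistic <- function(pre, post) {
  n1 <- length(pre); n2 <- length(post)
  rk <- rank(c(pre, post))
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  list(u1 = u1, sigma2 = sigma2, mu = n1 * n2 / 2)
}

#' Two-sided Mann-Whitney U test with exact small-sample branch
#'
#' For \code{length(pre) + length(post) <= 12} the two-sided p-value is
#' computed by exhaustive enumeration of all assignments of the pooled
#' (mid)ranks to the two groups, counting arrangements whose U is at least
#' as far from its null mean as the observed one; larger samples use the
#' normal approximation with tie and continuity correction. The reported
#' statistic is the standardized U of the \code{pre} sample (positive when
#' the pre values rank higher). When significant at \code{alpha}, the
#' direction is called by rank comparison: \code{"decreased"} when post
#' ranks below pre, \code{"increased"} otherwise.
#'
#' @param pre,post nonempty numeric samples.
#' @param alpha significance level (default 0.05).
#' @return list: \code{statistic} (z-scaled U), \code{u}, \code{p_value},
#'   \code{direction} (\code{"no_change"} iff \code{p_value >= alpha}),
#'   \code{method} (\code{"exact"} or \code{"normal_approx"}).
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
mannWhitney <- function(pre, post, alpha = 0.05) {
  stopifnot(length(pre) >= 1L, length(post) >= 1L)
  n1 <- length(pre); n2 <- length(post); n <- n1 + n2
  st <- mwStatistic(pre, post)
  if (st$sigma2 == 0) {        # every value tied across both groups
    return(list(statistic = 0, u = st$u1, p_value = 1,
                direction = "no_change", method = "degenerate"))
  }
  z <- (st$u1 - st$mu) / sqrt(st$sigma2)
  if (n <= 12L) {
    rk <- rank(c(pre, post))
    dev <- abs(st$u1 - st$mu)
    combs <- utils::combn(n, n1)
    base <- n1 * (n1 + 1) / 2
    us <- colSums(matrix(rk[combs], nrow = n1)) - base
    p <- mean(abs(us - st$mu) >= dev - 1e-9)
    method <- "exact"
  } else {
    zcc <- (st$u1 - st$mu - sign(st$u1 - st$mu) * 0.5) / sqrt(st$sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(zcc)))
    method <- "normal_approx"
  }
  direction <- if (p >= alpha) "no_change"
    else if (z > 0) "decreased" else "increased"
  list(statistic = z, u = st$u1, p_value = p, direction = direction,
       method = method)
}

#' Group-level pre/post comparison of participant metrics
#'
#' One Mann-Whitney comparison per metric across participants, with group
#' means and the precondition tests, laid out like a summary table (pre
#' mean, post mean, standardized statistic, p). Participants missing a
#' session are excluded from that metric; an optional Benjamini-Hochberg
#' correction and a paired Wilcoxon alternative are available.
#'
#' @param tbl data.frame with columns \code{participant_id}, \code{session}
#'   (pre_op/post_op) and one numeric column per metric; one row per
#'   participant-session (average over runs first).
#' @param metrics character vector of metric column names; default all
#'   numeric columns.
#' @param alpha significance level.
#' @param correction \code{"none"} (default) or \code{"bh"}.
#' @param paired use the paired Wilcoxon signed-rank test instead (off by
#'   default; the unpaired Mann-Whitney is the primary route).
#' @return data.frame with one row per metric: \code{metric},
#'   \code{mean_pre}, \code{mean_post}, \code{statistic}, \code{p_value},
#'   \code{direction}, \code{n_pre}, \code{n_post}, \code{shapiro_p_pre},
#'   \code{shapiro_p_post}, \code{levene_p}.
#' @export
groupCompare <- function(tbl, metrics = NULL, alpha = 0.05,
                         correction = c("none", "bh"), paired = FALSE) {
  correction <- match.arg(correction)
  stopifnot(all(c("participant_id", "session") %in% names(tbl)))
  if (is.null(metrics))
    metrics <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
                       c("participant_id", "state"))
  rows <- list()
  for (m in metrics) {
    pre <- tbl[tbl$session == "pre_op", c("participant_id", m)]
    post <- tbl[tbl$session == "post_op", c("participant_id", m)]
    pre <- pre[is.finite(pre[[m]]), ]
    post <- post[is.finite(post[[m]]), ]
    if (paired) {
      common <- intersect(pre$participant_id, post$participant_id)
      x <- pre[[m]][match(common, pre$participant_id)]
      y <- post[[m]][match(common, post$participant_id)]
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      res <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                  direction = NA_character_)
      res$direction <- if (res$p_value >= alpha) "no_change"
        else if (stats::median(x - y) > 0) "decreased" else "increased"
      preVals <- x; postVals <- y
    } else {
      preVals <- pre[[m]]; postVals <- post[[m]]
      res <- mannWhitney(preVals, postVals, alpha = alpha)
    }
    pc <- preconditionTests(preVals, postVals)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, mean_pre = mean(preVals), mean_post = mean(postVals),
      statistic = res$statistic, p_value = res$p_value,
      direction = res$direction,
      n_pre = length(preVals), n_post = length(postVals),
      shapiro_p_pre = pc$shapiro_p_pre, shapiro_p_post = pc$shapiro_p_post,
      levene_p = pc$levene_p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (correction == "bh") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$direction <- ifelse(out$p_adjusted >= alpha, "no_change",
                            out$direction)
  }
  rownames(out) <- NULL
  out
}

#' Per-participant change tallies for dynamic indicators
#'
#' For each participant and each metric, a Mann-Whitney test on the
#' window-level dynamic indicator values pre vs post; participants are then
#' tallied as increased / decreased / no_change per metric. Participants
#' with fewer than 2 windows in either session are counted as untested.
#'
#' @param dynTbl data.frame of window-level indicator values with columns
#'   \code{participant_id}, \code{session}, plus one numeric column per
#'   metric (e.g. rbind of \code{\link{dynamicIndicators}} outputs).
#' @param metrics metric column names; default the six indicator columns
#'   present.
#' @param alpha significance level.
#' @return data.frame with one row per metric: \code{metric},
#'   \code{n_no_change}, \code{n_increased}, \code{n_decreased},
#'   \code{n_untested}; the first three sum to the participants tested.
#' @export
perParticipantChange <- function(dynTbl, metrics = NULL, alpha = 0.05) {
  if (is.null(metrics))
    metrics <- intersect(c("k_core", "clustering_coefficient", "modularity",
                           "assortativity", "global_efficiency",
                           "local_efficiency"), names(dynTbl))
  participants <- unique(dynTbl$participant_id)
  rows <- list()
  for (m in metrics) {
    tally <- c(no_change = 0L, increased = 0L, decreased = 0L, untested = 0L)
    for (p in participants) {
      pre <- dynTbl[[m]][dynTbl$participant_id == p &
                           dynTbl$session == "pre_op"]
      post <- dynTbl[[m]][dynTbl$participant_id == p &
                            dynTbl$session == "post_op"]
      pre <- pre[is.finite(pre)]; post <- post[is.finite(post)]
      if (length(pre) < 2L || length(post) < 2L) {
        tally["untested"] <- tally["untested"] + 1L
      } else {
        res <- mannWhitney(pre, post, alpha = alpha)
        tally[res$direction] <- tally[res$direction] + 1L
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, n_no_change = tally[["no_change"]],
      n_increased = tally[["increased"]],
      n_decreased = tally[["decreased"]],
      n_untested = tally[["untested"]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
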