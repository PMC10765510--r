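test_that("precondition tests behave on null, non-normal and degenerate input", {
  pc <- preconditionTests(rep(1, 5), rep(1, 5))
  expect_true(any(grepl("levene", pc$skipped)))
  expect_true(is.na(pc$levene_p))

  pc2 <- preconditionTests(c(1, 2), c(1, 2, 3))
  expect_true(any(grepl("shapiro_pre", pc2$skipped)))

  set.seed(41)
  normOk <- 0L; expBad <- 0L
  for (i in 1:100) {
    pcN <- preconditionTests(rnorm(500), rnorm(500))
    if (pcN$shapiro_p_pre >= 0.05) normOk <- normOk + 1L
    pcE <- preconditionTests(rexp(500), rnorm(500))
    if (pcE$shapiro_p_pre < 0.05) expBad <- expBad + 1L
  }
  expect_gte(normOk, 90L)
  expect_gte(expBad, 99L)

  # Levene agrees with direct Brown-Forsythe computation
  set.seed(42)
  x <- rnorm(30); y <- rnorm(30, sd = 3)
  pc3 <- preconditionTests(x, y)
  z <- c(abs(x - median(x)), abs(y - median(y)))
  g <- factor(rep(1:2, each = 30))
  expect_equal(pc3$levene_p, anova(lm(z ~ g))[["Pr(>F)"]][1],
               tolerance = 1e-10)
})

test_that("Mann-Whitney handles identical, separated and tied samples", {
  same <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$direction, "no_change")
  expect_equal(same$statistic, 0)

  sep <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1, tolerance = 1e-12)
  expect_equal(sep$method, "exact")
  expect_equal(sep$u, 0)

  big <- mannWhitney(11:20, 1:10)
  expect_equal(big$method, "normal_approx")
  expect_lt(big$p_value, 0.05)
  expect_equal(big$direction, "decreased")  # pre ranks higher

  tied <- mannWhitney(rep(3, 4), rep(3, 5))
  expect_equal(tied$p_value, 1)
  expect_equal(tied$direction, "no_change")
})

test_that("the exact branch tracks the normal approximation at n = 6 + 6", {
  set.seed(53)
  approxP <- function(pre, post) {
    n1 <- length(pre); n2 <- length(post); n <- n1 + n2
    rk <- rank(c(pre, post))
    u1 <- sum(rk[1:n1]) - n1 * (n1 + 1) / 2
    ties <- table(rk)
    s2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    mu <- n1 * n2 / 2
    z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(s2)
    min(1, 2 * pnorm(-abs(z)))
  }
  for (i in 1:50) {
    pre <- rnorm(6)
    post <- rnorm(6, mean = runif(1, -1, 1))
    res <- mannWhitney(pre, post)
    expect_equal(res$method, "exact")
    expect_lte(abs(res$p_value - approxP(pre, post)), 0.02)
  }
})

test_that("p-values are valid and directions follow the standardized statistic", {
  set.seed(59)
  for (i in 1:40) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    res <- mannWhitney(rnorm(n1), rnorm(n2), alpha = 0.3)
    expect_gte(res$p_value, 0)
    expect_lte(res$p_value, 1)
    if (res$direction == "decreased") expect_gt(res$statistic, 0)
    if (res$direction == "increased") expect_lt(res$statistic, 0)
    if (res$p_value >= 0.3) expect_equal(res$direction, "no_change")
  }
})

test_that("exact p agrees with wilcox.test where both are exact and untied", {
  set.seed(61)
  for (i in 1:20) {
    pre <- rnorm(5); post <- rnorm(6)
    ours <- mannWhitney(pre, post)
    ref <- wilcox.test(pre, post, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("group comparison mirrors a summary-table layout and handles absences", {
  tbl <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:8), 2),
    session = rep(c("pre_op", "post_op"), each = 8),
    m1 = c(rnorm(8, 10), rnorm(8, 10)),
    m2 = c(11:18, 1:8))
  res <- groupCompare(tbl, c("m1", "m2"))
  expect_equal(res$metric, c("m1", "m2"))
  expect_equal(res$direction[2], "decreased")
  expect_lt(res$p_value[2], 0.05)
  expect_equal(res$mean_pre[2], mean(11:18))

  identical_tbl <- tbl
  identical_tbl$m1 <- rep(1:8, 2)
  identical_tbl$m2 <- rep(1:8, 2)
  resI <- groupCompare(identical_tbl)
  expect_true(all(resI$direction == "no_change"))

  missing_tbl <- tbl[-1, ]   # p01 has no pre_op value
  resM <- groupCompare(missing_tbl, "m2")
  expect_equal(resM$n_pre, 7L)
  expect_equal(resM$n_post, 8L)

  resBH <- groupCompare(tbl, c("m1", "m2"), correction = "bh")
  expect_true("p_adjusted" %in% names(resBH))
  resP <- groupCompare(tbl, "m2", paired = TRUE)
  expect_equal(resP$direction, "decreased")
})

test_that("per-participant tallies count directions and untested participants", {
  set.seed(67)
  mkDyn <- function(pid, shift, n = 30) rbind(
    data.frame(participant_id = pid, session = "pre_op",
               global_efficiency = rnorm(n, 0.5, 0.01)),
    data.frame(participant_id = pid, session = "post_op",
               global_efficiency = rnorm(n, 0.5 - shift, 0.01)))
  dyn <- rbind(mkDyn("p1", 0.2), mkDyn("p2", 0.2), mkDyn("p3", 0.2),
               mkDyn("p4", 0))
  tal <- perParticipantChange(dyn, "global_efficiency")
  expect_equal(tal$n_decreased, 3L)
  expect_equal(tal$n_no_change, 1L)
  expect_equal(tal$n_no_change + tal$n_increased + tal$n_decreased, 4L)

  # identical series: everyone lands in no_change
  flat <- rbind(mkDyn("q1", 0), mkDyn("q2", 0))
  talF <- perParticipantChange(flat, "global_efficiency")
  expect_equal(talF$n_no_change, 2L)

  # a participant with one post window is untested, reported separately
  short <- rbind(mkDyn("p1", 0.2),
                 data.frame(participant_id = "p5", session = "pre_op",
                            global_efficiency = rnorm(5, 0.5, 0.01)),
                 data.frame(participant_id = "p5", session = "post_op",
                            global_efficiency = 0.4))
  talS <- perParticipantChange(short, "global_efficiency")
  expect_equal(talS$n_untested, 1L)
  expect_equal(talS$n_decreased, 1L)
})
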