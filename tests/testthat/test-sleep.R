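test_that("stage assignment uses half-open 30-s epochs", {
  hyp <- hypnogram(c("W", "N1", "N2", "N3"))
  expect_identical(assign_stage(45, hyp), "N1")
  expect_identical(assign_stage(30, hyp), "N1")    # boundary -> 2nd epoch
  expect_identical(assign_stage(0, hyp), "W")
  expect_error(assign_stage(130, hyp), "outside")
  expect_error(assign_stage(-1, hyp), "outside")
  # brute-force interval-lookup oracle on random events
  set.seed(1)
  stages <- sample(c("W", "REM", "N1", "N2", "N3"), 40, replace = TRUE)
  hyp2 <- hypnogram(stages)
  t_ev <- runif(100, 0, 40 * 30 - 0.01)
  brute <- vapply(t_ev, function(t) {
    for (e in seq_along(stages))
      if (t >= (e - 1) * 30 && t < e * 30) return(stages[e])
    NA_character_
  }, character(1))
  expect_identical(assign_stage(t_ev, hyp2), brute)
})

test_that("cough rates are duration-normalised with NA for empty stages", {
  hyp <- hypnogram(rep("W", 240))                  # 2 h all wake
  tab <- cough_rate_by_stage(runif(10, 0, 7200), hyp)
  expect_identical(tab$rate[tab$stage == "W"], 5)
  expect_true(all(is.na(tab$rate[tab$stage != "W"])))
  # conservation: sum(rate * duration) = total coughs, for random inputs
  set.seed(2)
  for (i in 1:10) {
    stages <- sample(c("W", "REM", "N1", "N2", "N3"), 60, replace = TRUE)
    hyp2 <- hypnogram(stages)
    t_ev <- runif(50, 0, 60 * 30 - 0.01)
    tb <- cough_rate_by_stage(t_ev, hyp2)
    expect_identical(sum(tb$count), 50L)
    expect_equal(sum(tb$rate * tb$duration_h, na.rm = TRUE), 50,
                 tolerance = 1e-9)
  }
  # lights window restricts both events and epochs
  tab2 <- cough_rate_by_stage(c(100, 4000), hyp, lights = c(0, 3600))
  expect_identical(sum(tab2$count), 1L)
  expect_identical(tab2$duration_h[tab2$stage == "W"], 1)
})

test_that("rank-sum test: exact enumeration and approximation agree", {
  expect_identical(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # most extreme of the C(6,3) = 20 arrangements -> two-sided p = 0.1
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_identical(r$method, "exact")
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  # exact path reproduces the standard exact distribution (tie-free)
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(7)
    ours <- rank_sum_test(x, y)$p_value
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # tie-corrected normal approximation tracks the exact answer at n = 8
  # (every case within 0.02, on average within 0.01; the approximation is
  # bit-identical to the reference continuity-corrected implementation)
  set.seed(4)
  errs <- vapply(1:10, function(i) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    p_ex <- rank_sum_test(x, y)$p_value
    p_ap <- rank_sum_test(x, y, exact_max = 0)$p_value
    expect_equal(p_ap,
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-12)
    abs(p_ex - p_ap)
  }, numeric(1))
  expect_true(all(errs < 0.02))
  expect_lt(mean(errs), 0.01)
})

test_that("correlations follow their definitions", {
  x <- 1:20
  expect_equal(correlate(x, 2 * x + 1)$R, 1, tolerance = 1e-12)
  # monotone nonlinear: Spearman 1, Pearson < 1
  y3 <- x^3
  expect_equal(correlate(x, y3, "spearman")$R, 1, tolerance = 1e-12)
  expect_lt(correlate(x, y3)$R, 1)
  # partial correlation removes a shared confounder
  set.seed(5)
  z <- rnorm(500)
  xa <- z + rnorm(500); ya <- z + rnorm(500)
  expect_gt(correlate(xa, ya)$R, 0.3)
  expect_lt(abs(correlate(xa, ya, "partial", controls = z)$R), 0.1)
  expect_error(correlate(xa, ya, "partial"), "controls")
  expect_warning(correlate(rep(1, 10), rnorm(10)), "zero variance")
  # p-values match the t reference implementation
  set.seed(6)
  a <- rnorm(30); b <- a * 0.5 + rnorm(30)
  ref <- cor.test(a, b)
  ours <- correlate(a, b)
  expect_equal(ours$R, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("post-cough stage transitions are tabulated correctly", {
  hyp <- hypnogram(c("N2", "W"))
  tr <- transition_after_cough(10, hyp)
  expect_identical(tr$counts["N2", "W"], 1L)
  expect_identical(tr$percent["N2", "W"], 100)
  # constant-stage hypnogram: only self transitions
  hyp2 <- hypnogram(rep("N3", 10))
  tr2 <- transition_after_cough(c(5, 50, 200), hyp2)
  expect_identical(sum(tr2$counts), 3L)
  expect_identical(tr2$counts["N3", "N3"], 3L)
  # final-epoch coughs are excluded but counted
  tr3 <- transition_after_cough(c(10, 40), hypnogram(c("W", "N1")))
  expect_identical(tr3$n_excluded_final, 1L)
  expect_identical(sum(tr3$counts), 1L)
  # brute-force pairing oracle on random inputs
  set.seed(7)
  stages <- sample(c("W", "REM", "N1", "N2", "N3"), 50, replace = TRUE)
  hyp3 <- hypnogram(stages)
  t_ev <- runif(200, 0, 50 * 30 - 0.01)
  tr4 <- transition_after_cough(t_ev, hyp3)
  brute <- matrix(0L, 5, 5, dimnames = dimnames(tr4$counts))
  for (t in t_ev) {
    e <- floor(t / 30) + 1
    if (e < 50) brute[stages[e], stages[e + 1]] <-
        brute[stages[e], stages[e + 1]] + 1L
  }
  expect_identical(tr4$counts, brute)
})
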