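test_that("mae matches the scalar-loop oracle", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(0, 0), c(1, -1)), 1)
  expect_error(mae(1:3, 1:2), class = "nf_shape_error")
  set.seed(71)
  for (rep in 1:1000) {
    n <- sample(1:20, 1)
    y <- rnorm(n); yh <- rnorm(n)
    acc <- 0
    for (i in seq_len(n)) acc <- acc + abs(y[i] - yh[i])
    expect_equal(mae(y, yh), acc / n)
  }
})

test_that("r_squared matches the explicit sum-of-squares oracle", {
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_error(r_squared(rep(1, 4), y), class = "nf_undefined_error")
  set.seed(72)
  for (rep in 1:1000) {
    n <- sample(3:30, 1)
    y <- rnorm(n); yh <- y + rnorm(n, sd = 0.5)
    oracle <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
    expect_equal(r_squared(y, yh), oracle)
  }
})

test_that("mAP: perfect, hopeless and hand-enumerated mixed cases", {
  truths <- data.frame(instance = c("i1", "i2", "i3"), code = "n",
                       x = c(10, 50, 90), y = c(10, 50, 90))
  exact <- data.frame(instance = truths$instance, code = "n",
                      x = truths$x, y = truths$y,
                      confidence = c(0.3, 0.9, 0.5))
  expect_equal(mean_average_precision(exact, truths), 1)

  off <- exact; off$x <- off$x + 50
  expect_equal(mean_average_precision(off, truths), 0)

  # one correct high-conf, one wrong mid-conf, one correct low-conf:
  # PR points (1, 1/3), (1/2, 1/3), (2/3, 2/3); 101-point interpolated AP =
  # (34*1 + 33*(2/3)) / 101
  mixed <- data.frame(instance = c("i1", "i2", "i3"), code = "n",
                      x = c(10, 999, 90), y = c(10, 999, 90),
                      confidence = c(0.9, 0.5, 0.2))
  expect_equal(mean_average_precision(mixed, truths),
               (34 + 33 * 2 / 3) / 101, tolerance = 1e-12)

  # invariance under order-preserving confidence rescaling
  mixed2 <- mixed; mixed2$confidence <- mixed$confidence * 7 + 2
  expect_equal(mean_average_precision(mixed2, truths),
               mean_average_precision(mixed, truths))

  # categories without truths are skipped with a warning
  extra <- rbind(mixed, data.frame(instance = "i1", code = "zz", x = 1, y = 1,
                                   confidence = 0.5))
  expect_warning(m <- mean_average_precision(extra, truths,
                   keypoint_eval_config(categories = c("n", "zz"))), "zz")
  expect_equal(m, mean_average_precision(mixed, truths))
  expect_error(keypoint_eval_config(radius = 0), class = "nf_parameter_error")
})

test_that("mAP on detector-style output across many landmarks stays in [0,1]", {
  set.seed(73)
  codes <- view_codes("lateral", include_optional = FALSE)
  truths <- do.call(rbind, lapply(1:5, function(i)
    data.frame(instance = paste0("s", i), code = codes,
               x = runif(length(codes), 0, 200),
               y = runif(length(codes), 0, 200))))
  dets <- truths
  dets$x <- dets$x + rnorm(nrow(dets), sd = 4)
  dets$y <- dets$y + rnorm(nrow(dets), sd = 4)
  dets$confidence <- runif(nrow(dets))
  m <- mean_average_precision(dets, truths, keypoint_eval_config(radius = 5))
  expect_true(m > 0 && m < 1)
  m2 <- mean_average_precision(dets, truths, keypoint_eval_config(radius = 50))
  expect_gt(m2, m)   # a looser radius can only help
})

test_that("pooled_mean reproduces weighted worked examples", {
  expect_equal(round(pooled_mean(data.frame(n = c(18, 15),
                                            mean = c(23.79, 23.83))), 2),
               23.81)
  expect_equal(round(pooled_mean(data.frame(n = c(81, 101),
                                            mean = c(133.89, 138.43))), 2),
               136.41)
  expect_equal(pooled_mean(data.frame(n = c(5, 50), mean = c(7, 7))), 7)
  g <- data.frame(n = c(3, 9), mean = c(1, 5))
  expect_equal(pooled_mean(g), (3 * 1 + 9 * 5) / 12)
  expect_true(pooled_mean(g) >= min(g$mean) && pooled_mean(g) <= max(g$mean))
  expect_equal(pooled_mean(data.frame(n = 4, mean = 2.5)), 2.5)
  expect_error(pooled_mean(data.frame(n = numeric(0), mean = numeric(0))),
               class = "nf_parameter_error")
})

test_that("welch_t_test: identity, symmetry, power, and permutation oracle", {
  a <- c(1, 2, 3, 4, 5)
  r <- welch_t_test(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(welch_t_test(rep(1, 5), a), class = "nf_stat_error")
  expect_error(welch_t_test(1, a), class = "nf_stat_error")

  set.seed(74)
  x <- rnorm(5000); y <- rnorm(5000, mean = 1)
  expect_lt(welch_t_test(x, y)$p, 1e-6)

  # symmetry up to the sign of t
  r1 <- welch_t_test(x[1:20], y[1:25])
  r2 <- welch_t_test(y[1:25], x[1:20])
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)

  # permutation oracle on small samples
  set.seed(75)
  a <- rnorm(8); b <- rnorm(8, mean = 0.8)
  obs <- abs(welch_t_test(a, b)$t)
  pool <- c(a, b)
  nrep <- 100000
  tstat <- function(i) {
    x1 <- pool[i]; x2 <- pool[-i]
    (mean(x1) - mean(x2)) / sqrt(var(x1) / 8 + var(x2) / 8)
  }
  perm <- replicate(nrep, abs(tstat(sample.int(16, 8))))
  p_perm <- mean(perm >= obs - 1e-12)
  p_welch <- welch_t_test(a, b)$p
  mc_err <- 4 * sqrt(p_perm * (1 - p_perm) / nrep)
  # Welch p within Monte-Carlo error + small-sample approximation slack
  expect_lt(abs(p_welch - p_perm), mc_err + 0.02)
})

test_that("kruskal_wallis: degenerate inputs, power, and rank-formula oracle", {
  expect_error(kruskal_wallis(list(rep(2, 4), rep(2, 5))),
               class = "nf_stat_error")
  expect_error(kruskal_wallis(list(1:5)), class = "nf_stat_error")

  # the same sample copied into both groups gives H = 0 (tie-corrected)
  set.seed(76)
  g <- rnorm(10)
  r <- kruskal_wallis(list(g, g))
  expect_equal(r$H, 0)

  # disjoint supports: decisive
  r <- kruskal_wallis(list(rnorm(30), rnorm(30, 10), rnorm(30, 20)))
  expect_lt(r$p, 1e-6)
  expect_equal(r$df, 2)

  # explicit rank-sum formula oracle (no ties)
  for (rep in 1:50) {
    gs <- list(rnorm(6), rnorm(5), rnorm(7))
    allv <- unlist(gs)
    rk <- rank(allv)
    n <- length(allv)
    idx <- rep(seq_along(gs), lengths(gs))
    H <- 12 / (n * (n + 1)) *
      sum(tapply(rk, idx, sum)^2 / lengths(gs)) - 3 * (n + 1)
    expect_equal(kruskal_wallis(gs)$H, H, tolerance = 1e-9)
  }
})

test_that("summarize_classification reports exact fractions and half-up percents", {
  s <- summarize_classification(c("V", "V", "S"))
  expect_equal(sum(s$fraction), 1)
  expect_equal(s$count[s$label == "V"], 2)
  s1 <- summarize_classification("A")
  expect_equal(s1$percent, 100)
  # half-up rounding at one decimal (57.575... -> 57.6)
  s2 <- summarize_classification(rep(c("A", "B"), c(19, 14)))
  expect_equal(s2$percent[s2$label == "A"], 57.6)
  # rounded percentages sum to ~100
  set.seed(77)
  lab <- sample(letters[1:6], 997, replace = TRUE)
  s3 <- summarize_classification(lab)
  expect_lt(abs(sum(s3$percent) - 100), 0.2)
})
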