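test_that("euclidean_distance matches the sum-of-squares oracle on random pairs", {
  expect_equal(euclidean_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(11)
  for (i in 1:1000) {
    p <- rnorm(2, sd = 50); q <- rnorm(2, sd = 50)
    oracle <- sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2)
    expect_equal(euclidean_distance(p, q), oracle)
    expect_equal(euclidean_distance(q, p), oracle)  # symmetry
  }
})

test_that("metric_inner_product equals the componentwise dot product", {
  expect_equal(metric_inner_product(c(1, 0), c(0, 1)), 0)
  expect_equal(metric_inner_product(c(2, 0), c(3, 0)), 6)
  set.seed(12)
  for (i in 1:200) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(metric_inner_product(a, b), sum(a * b))
    # |a||b|cos(theta) identity
    ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    expect_equal(metric_inner_product(a, b),
                 sqrt(sum(a^2)) * sqrt(sum(b^2)) * ct)
  }
})

test_that("angle_at_vertex matches the law-of-cosines oracle and is rigid-motion invariant", {
  expect_equal(angle_at_vertex(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(angle_at_vertex(c(0, 0), c(1, 0), c(2, 0)), 180)
  expect_error(angle_at_vertex(c(1, 1), c(1, 1), c(0, 0)),
               class = "nf_geometry_error")
  set.seed(13)
  for (i in 1:300) {
    a <- rnorm(2); b <- rnorm(2); c_ <- rnorm(2)
    if (isTRUE(all.equal(a, b)) || isTRUE(all.equal(c_, b))) next
    ab <- euclidean_distance(a, b); cb <- euclidean_distance(c_, b)
    ac <- euclidean_distance(a, c_)
    oracle <- acos(min(1, max(-1, (ab^2 + cb^2 - ac^2) / (2 * ab * cb)))) * 180 / pi
    ang <- angle_at_vertex(a, b, c_)
    expect_equal(ang, oracle, tolerance = 1e-9)
    # translation + rotation + uniform scaling invariance
    th <- runif(1, 0, 2 * pi); k <- runif(1, 0.1, 5); t <- rnorm(2)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tf <- function(p) k * drop(R %*% p) + t
    expect_equal(angle_at_vertex(tf(a), tf(b), tf(c_)), ang, tolerance = 1e-8)
  }
})

test_that("calibrate_scale fits tick spacing by least squares", {
  ticks <- cbind(x = c(0, 5, 10, 15), y = 0)
  cal <- calibrate_scale(ticks, 1)
  expect_equal(cal$mm_per_px, 0.2)
  expect_equal(cal$source, "ruler_ticks")

  # jittered ticks stay within 2% of the noiseless scale
  set.seed(14)
  for (i in 1:50) {
    t0 <- cbind(x = seq(0, 60, by = 6) + rnorm(11, sd = 0.1),
                y = rnorm(11, sd = 0.1))
    cal <- calibrate_scale(t0, 2)
    expect_equal(cal$mm_per_px, 2 / 6, tolerance = 0.02)
  }

  expect_error(calibrate_scale(cbind(c(0, 5), 0), 1),
               class = "nf_calibration_error")
  # grossly non-collinear / uneven ticks rejected
  expect_error(calibrate_scale(cbind(c(0, 1, 9, 10), c(0, 5, -4, 2)), 1),
               class = "nf_calibration_error")
})

test_that("calibration is rotation invariant", {
  set.seed(15)
  base <- cbind(seq(0, 50, by = 5), 0)
  for (th in runif(5, 0, 2 * pi)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    cal <- calibrate_scale(base %*% t(R), 2.5)
    expect_equal(cal$mm_per_px, 0.5, tolerance = 1e-9)
  }
})

test_that("measure_subject converts pixels to calibrated units", {
  # alar width from the worked pixel example: 60 px at 0.25 mm/px = 15 mm
  ls <- symmetric_frontal_set()
  ls$points["al_R", ] <- c(100, 200); ls$points["al_L", ] <- c(160, 200)
  cal <- list(frontal = calibration_info("frontal", 0.25))
  defs <- measurement_catalog()
  mt <- measure_subject(list(frontal = ls), cal,
                        defs = defs[defs$code == "al-al", ])
  expect_equal(mt$value, 1.5)   # reported in cm
  expect_equal(mt$units, "cm")
})

test_that("measure_subject errors name the missing landmark and view", {
  ls <- symmetric_frontal_set()
  ls$points <- ls$points[rownames(ls$points) != "al_L", ]
  cal <- list(frontal = calibration_info("frontal", 0.25))
  defs <- measurement_catalog()
  err <- tryCatch(measure_subject(list(frontal = ls), cal,
                                  defs = defs[defs$code == "al-al", ]),
                  error = identity)
  expect_s3_class(err, "nf_measurement_error")
  expect_match(conditionMessage(err), "al_L")
  expect_match(conditionMessage(err), "frontal")
})

test_that("optional kyphion yields an absent entry, not an error", {
  subj <- tiny_population(4)
  subj$has_kyphion <- FALSE
  rv <- render_subject_views(subj[1, ], small_render_cfg(), seed = 1)
  mt <- measure_subject(lapply(rv, `[[`, "landmarks"),
                        lapply(rv, `[[`, "calibration"))
  expect_false("n-k-r" %in% mt$code)
  expect_true("g-n-prn" %in% mt$code)
  # a subject with a kyphion gets the angle
  subj2 <- tiny_population(8)
  subj2 <- subj2[subj2$has_kyphion, ][1, ]
  rv2 <- render_subject_views(subj2, small_render_cfg(), seed = 2)
  mt2 <- measure_subject(lapply(rv2, `[[`, "landmarks"),
                         lapply(rv2, `[[`, "calibration"))
  expect_true("n-k-r" %in% mt2$code)
})

test_that("scale equivariance: k-scaled pixels with mm_per_px/k give identical mm", {
  subj <- tiny_population(2)
  rv <- render_subject_views(subj[1, ], small_render_cfg(), seed = 3)
  sets <- lapply(rv, `[[`, "landmarks")
  cals <- lapply(rv, `[[`, "calibration")
  mt1 <- measure_subject(sets, cals)
  k <- 3.7
  sets2 <- lapply(sets, function(ls) { ls$points <- ls$points * k; ls })
  cals2 <- lapply(cals, function(cl) { cl$mm_per_px <- cl$mm_per_px / k; cl })
  mt2 <- measure_subject(sets2, cals2)
  expect_equal(mt2$value, mt1$value, tolerance = 1e-12)
})

test_that("frontal symmetry ratios behave on symmetric and perturbed sets", {
  ls <- symmetric_frontal_set()
  r <- frontal_symmetry_ratios(ls)
  expect_equal(r$midalar_lr_ratio, 1)
  expect_equal(r$base_lr_ratio, 1)
  expect_equal(r$axis_angle_deg, 0)
  # worked example: g=(112,40), sn=(112,140), mf at +-25 -> height/width = 2
  ls2 <- ls
  ls2$points["g", ] <- c(112, 40); ls2$points["sn", ] <- c(112, 140)
  ls2$points["mf_R", ] <- c(87, 80); ls2$points["mf_L", ] <- c(137, 80)
  expect_equal(frontal_symmetry_ratios(ls2)$height_width_ratio, 2)
  # shifting al/ac right makes the base ratio exceed 1 in the predicted direction
  ls3 <- ls
  ls3$points["ac_R", 1] <- ls3$points["ac_R", 1] - 10   # further from midline
  expect_gt(frontal_symmetry_ratios(ls3)$base_lr_ratio, 1)
  ls4 <- ls
  ls4$points <- ls4$points[rownames(ls4$points) != "mal_L", ]
  expect_error(frontal_symmetry_ratios(ls4), class = "nf_measurement_error")
})

test_that("cross-view consistency: vertical n-sn separation agrees frontal vs lateral", {
  subj <- tiny_population(5, seed = 77)
  for (i in seq_len(nrow(subj))) {
    rv <- render_subject_views(subj[i, ], small_render_cfg(), seed = i)
    vertical_mm <- function(v) {
      p <- rv[[v]]$landmarks$points
      # project the n->sn displacement on the image vertical axis
      abs(metric_inner_product(p["sn", ] - p["n", ], c(0, 1))) *
        rv[[v]]$calibration$mm_per_px
    }
    expect_equal(vertical_mm("frontal"), vertical_mm("lateral"),
                 tolerance = 0.01)
  }
})
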