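# Synthetic morphometric populations. The generator states a world matching
# the published group statistics: sex-specific nasal-bone distances, BMI-
# dependent surface dimensions, sex-specific profile angles, frontal type
# frequencies and kyphion prevalence, tied together by a linear-Gaussian
# surface <- bone link with known coefficients so that bone dimensions are
# recoverable from surface measurements (parameter-recovery testing).

.nf_bone_dims <- c("n_s", "s_k", "k_r", "s_r", "n_r", "d3", "d4", "d5")
.nf_surface_codes <- c("n-prn", "n-sn", "al-al", "ac-ac", "n-r", "en-en", "sn-prn")
.nf_angle_codes <- c("g-n-prn", "n-prn-sn")

# Loadings of standardized bone dims onto surface measures (cm) and angles
# (degrees); rows are unit-normalized then scaled to carry `share` of each
# measure's variance. The direct nasion-rhinion skin distance loads solely on
# the bone length N-R with a high bone share (it is the skin projection of
# the bone), which makes N-R strongly identifiable from the surface.
.nf_link_loadings <- function() {
  dims <- c("n_s", "s_r", "n_r", "d3", "d4", "d5")
  mk <- function(...) {
    v <- setNames(rep(0, 6), dims); l <- list(...); v[names(l)] <- unlist(l); v
  }
  L <- rbind(
    "n-prn"    = mk(n_r = .85, s_r = .527),
    "n-sn"     = mk(n_r = .6, n_s = .6, d4 = .53),
    "al-al"    = mk(d4 = .9, d5 = .436),
    "ac-ac"    = mk(d4 = .8, d3 = .6),
    "n-r"      = mk(n_r = 1),
    "en-en"    = mk(d3 = .8, d5 = .6),
    "sn-prn"   = mk(s_r = .8, d4 = .6),
    "g-n-prn"  = mk(n_s = -.7, n_r = -.714),
    "n-prn-sn" = mk(s_r = .6, n_r = .8))
  share <- c(.85, .85, .85, .85, .92, .85, .85, .5, .5)
  list(L = L / sqrt(rowSums(L^2)), share = share)
}

#' Default population parameters
#'
#' The stated world of the synthetic generator. Defaults reproduce the
#' published group statistics: sex-specific bone distances (mean +/- SD, mm)
#' N-S 5.56/5.89, S-K 14.54/14.08, K-R 4.61/4.52, S-R 18.85/18.22,
#' N-R 23.79/23.83 (male/female); lower bone width d4 17.08 +/- 2.08 mm;
#' surface distances (cm) at the normal-weight baseline with signed BMI
#' slopes reproducing the direction of the published BMI contrasts;
#' profile angles (degrees) g-n-prn 133.89/138.43 and n-prn-sn
#' 103.43/104.91 with per-sex SDs recovered from the reported standard
#' errors; frontal type probabilities A..E = 19,10,1,2,1 out of 33;
#' kyphion prevalence 8/33 with a log-normal hump height whose
#' sub-threshold (< 0.5 mm) mass is 1/8, so that 7 of 8 kyphion-bearing
#' subjects present an S-shaped profile.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; the whole population is deterministic given it.
#' @param sex_ratio Proportion male (default 81/182).
#' @param kyphion_prevalence Probability of a dorsal hump (default 8/33).
#' @param frontal_type_probs Length-5 probability vector for types A..E.
#' @param noise_scale Multiplier on the residual (non-bone) noise SD of the
#'   surface <- bone link; 0 gives a noiseless deterministic link.
#' @param bmi_effects Named vector of signed slopes (units per BMI unit) for
#'   surface measures.
#' @param overrides Named list merged over the remaining internal defaults
#'   (bone means/SDs, surface means/SDs, angle means/SDs, hump distribution,
#'   BMI mixture, type templates).
#' @return An object of class `population_params`.
#' @export
population_params <- function(n, seed = 1L, sex_ratio = 81 / 182,
                              kyphion_prevalence = 8 / 33,
                              frontal_type_probs = c(A = 19, B = 10, C = 1,
                                                     D = 2, E = 1) / 33,
                              noise_scale = 1,
                              bmi_effects = c("n-prn" = -0.020, "n-sn" = 0.005,
                                              "al-al" = 0.022, "ac-ac" = 0.017,
                                              "n-r" = -0.015, "en-en" = 0.008,
                                              "sn-prn" = 0.012),
                              overrides = list()) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n))
    stop_nf("nf_parameter_error", "invalid parameter 'n': must be a non-negative integer")
  if (sex_ratio < 0 || sex_ratio > 1)
    stop_nf("nf_parameter_error", "invalid parameter 'sex_ratio': must be in [0,1]")
  if (kyphion_prevalence < 0 || kyphion_prevalence > 1)
    stop_nf("nf_parameter_error",
            "invalid parameter 'kyphion_prevalence': must be in [0,1]")
  if (length(frontal_type_probs) != 5 ||
      abs(sum(frontal_type_probs) - 1) > 1e-8 || any(frontal_type_probs < 0))
    stop_nf("nf_parameter_error",
            "invalid parameter 'frontal_type_probs': 5 non-negative values summing to 1")
  if (noise_scale < 0)
    stop_nf("nf_parameter_error", "invalid parameter 'noise_scale': must be >= 0")

  p <- list(
    n = as.integer(n), seed = as.integer(seed), sex_ratio = sex_ratio,
    kyphion_prevalence = kyphion_prevalence,
    frontal_type_probs = setNames(frontal_type_probs, c("A", "B", "C", "D", "E")),
    noise_scale = noise_scale, bmi_effects = bmi_effects,
    age = list(M = c(mean = 22.01, sd = 1.39), F = c(mean = 21.88, sd = 1.68)),
    height = list(M = c(mean = 1.68, sd = 0.06), F = c(mean = 1.57, sd = 0.055)),
    # BMI as a 4-component normal mixture (under/normal/over/obese)
    bmi_mix = list(probs = c(0.077, 0.528, 0.192, 0.203),
                   means = c(17.8, 21.7, 27.0, 31.5),
                   sds = c(0.6, 1.8, 1.4, 1.5)),
    bone = list(
      M = list(mean = c(n_s = 5.56, s_k = 14.54, k_r = 4.61, s_r = 18.85,
                        n_r = 23.79, d4 = 17.08),
               sd   = c(n_s = 1.25, s_k = 0.73, k_r = 1.29, s_r = 3.02,
                        n_r = 3.46, d4 = 2.08)),
      F = list(mean = c(n_s = 5.89, s_k = 14.08, k_r = 4.52, s_r = 18.22,
                        n_r = 23.83, d4 = 17.08),
               sd   = c(n_s = 1.19, s_k = 0.93, k_r = 1.08, s_r = 2.29,
                        n_r = 2.29, d4 = 2.08))),
    surface = list(mean = c("n-prn" = 3.85, "n-sn" = 4.91, "al-al" = 4.01,
                            "ac-ac" = 3.23, "n-r" = 1.26, "en-en" = 3.57,
                            "sn-prn" = 1.67),
                   sd   = c("n-prn" = 0.37, "n-sn" = 0.31, "al-al" = 0.31,
                            "ac-ac" = 0.29, "n-r" = 0.21, "en-en" = 0.23,
                            "sn-prn" = 0.19)),
    # per-sex angle SDs are the reported SEs times sqrt(n) (81 M, 101 F)
    angles = list(M = list(mean = c("g-n-prn" = 133.89, "n-prn-sn" = 103.43),
                           sd   = c("g-n-prn" = 1.06 * sqrt(81),
                                    "n-prn-sn" = 0.64 * sqrt(81))),
                  F = list(mean = c("g-n-prn" = 138.43, "n-prn-sn" = 104.91),
                           sd   = c("g-n-prn" = 0.57 * sqrt(101),
                                    "n-prn-sn" = 0.60 * sqrt(101)))),
    # dorsal hump height, mm: lognormal with P(height < 0.5) = 1/8
    hump = c(meanlog = log(1.3), sdlog = (log(1.3) - log(0.5)) / qnorm(7 / 8)),
    tau_k_mm = 0.5,
    # frontal-type templates: uniform ranges for the width ratio w = d3/d4,
    # the concavity c = 1 - d5/min(d3,d4), and the nasomaxillary border
    # slope (degrees from horizontal); margins clear of the classifier
    # thresholds (rho_n 0.45, rho_w 0.80, kappa 0.15, vertical band 80-100).
    type_templates = list(
      A = list(w = c(0.50, 0.75), c = c(0.02, 0.12), slope = c(55, 75)),
      B = list(w = c(0.50, 0.75), c = c(0.18, 0.30), slope = c(55, 75)),
      C = list(w = c(0.30, 0.42), c = c(0.02, 0.12), slope = c(55, 75)),
      D = list(w = c(0.83, 0.95), c = c(0.18, 0.30), slope = c(55, 100)),
      E = list(w = c(0.83, 0.95), c = c(0.02, 0.12), slope = c(82, 98))),
    link = .nf_link_loadings()
  )
  p <- modifyList(p, overrides)
  class(p) <- "population_params"
  p
}

# Expected BMI under the mixture (reference point for BMI slopes so that the
# marginal surface means equal the configured means).
.nf_reference_bmi <- function(p) sum(p$bmi_mix$probs * p$bmi_mix$means)

#' Sample a synthetic subject population
#'
#' Draws `n` subjects from the stated world of `params`: covariates (sex,
#' age, height, weight, BMI), nasal-bone dimensions (sex-specific truncated
#' Gaussians), frontal type (multinomial, with d3/d5 and the nasomaxillary
#' border slope generated from the type's template so the rule-based
#' classifier reproduces the type), kyphion status and hump height (lateral
#' shape is S when a hump of at least `tau_k_mm` is present), and surface
#' measurements/angles generated from the linear-Gaussian surface <- bone
#' link plus BMI effects and residual noise.
#'
#' @param params A [population_params()].
#' @return A `subject_table` data frame, one row per subject, with
#'   covariates, `bone_*` columns (mm), `surf_*` columns (cm), `ang_*`
#'   columns (degrees), `has_kyphion`, `hump_height_mm`, `border_slope_deg`,
#'   `lateral_shape` (V/S) and `frontal_type` (A..E).
#' @export
sample_population <- function(params) {
  stopifnot(inherits(params, "population_params"))
  p <- params
  n <- p$n
  set.seed(p$seed)
  if (n == 0) return(.nf_empty_subject_table())

  sex <- ifelse(runif(n) < p$sex_ratio, "M", "F")
  age <- height <- numeric(n)
  for (s in c("M", "F")) {
    i <- sex == s
    age[i] <- rnorm(sum(i), p$age[[s]]["mean"], p$age[[s]]["sd"])
    height[i] <- rnorm(sum(i), p$height[[s]]["mean"], p$height[[s]]["sd"])
  }
  comp <- sample.int(4, n, replace = TRUE, prob = p$bmi_mix$probs)
  bmi <- rnorm(n, p$bmi_mix$means[comp], p$bmi_mix$sds[comp])
  bmi <- pmax(bmi, 13)
  weight <- bmi * height^2

  # bone dimensions: truncated-at-zero sex-specific Gaussians
  rtrunc <- function(n, mean, sd) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  bone <- matrix(NA_real_, n, length(.nf_bone_dims),
                 dimnames = list(NULL, .nf_bone_dims))
  for (s in c("M", "F")) {
    i <- which(sex == s)
    if (!length(i)) next
    bp <- p$bone[[s]]
    for (d in c("n_s", "s_k", "k_r", "s_r", "n_r", "d4"))
      bone[i, d] <- if (bp$sd[d] == 0) rep(bp$mean[d], length(i))
                    else rtrunc(length(i), bp$mean[d], bp$sd[d])
  }

  # frontal type and the width template it implies
  types <- c("A", "B", "C", "D", "E")
  ft <- types[sample.int(5, n, replace = TRUE, prob = p$frontal_type_probs)]
  w <- cc <- slope <- numeric(n)
  for (t in types) {
    i <- which(ft == t)
    if (!length(i)) next
    tpl <- p$type_templates[[t]]
    w[i] <- runif(length(i), tpl$w[1], tpl$w[2])
    cc[i] <- runif(length(i), tpl$c[1], tpl$c[2])
    slope[i] <- runif(length(i), tpl$slope[1], tpl$slope[2])
  }
  bone[, "d3"] <- w * bone[, "d4"]
  bone[, "d5"] <- (1 - cc) * pmin(bone[, "d3"], bone[, "d4"])

  # kyphion and lateral shape
  has_k <- runif(n) < p$kyphion_prevalence
  hump <- ifelse(has_k, rlnorm(n, p$hump["meanlog"], p$hump["sdlog"]), 0)
  lateral <- ifelse(has_k & hump >= p$tau_k_mm, "S", "V")
  # subjects without a hump have no distinct kyphion point
  bone[!has_k, c("s_k", "k_r")] <- NA_real_

  # surface measurements and angles from the linear-Gaussian link
  zs <- matrix(0, n, 6, dimnames = list(NULL, c("n_s", "s_r", "n_r", "d3", "d4", "d5")))
  for (s in c("M", "F")) {
    i <- which(sex == s)
    if (!length(i)) next
    bp <- p$bone[[s]]
    for (d in c("n_s", "s_r", "n_r"))
      zs[i, d] <- if (bp$sd[d] > 0) (bone[i, d] - bp$mean[d]) / bp$sd[d] else 0
  }
  # width z-scores vs. their marginal template moments (pooled)
  for (d in c("d3", "d4", "d5")) {
    mu <- mean(bone[, d]); sg <- sd(bone[, d])
    zs[, d] <- if (isTRUE(sg > 0)) (bone[, d] - mu) / sg else 0
  }
  L <- p$link$L; share <- p$link$share
  ref_bmi <- .nf_reference_bmi(p)
  surf <- matrix(NA_real_, n, length(.nf_surface_codes),
                 dimnames = list(NULL, .nf_surface_codes))
  for (m in .nf_surface_codes) {
    sd_m <- p$surface$sd[m]
    signal <- drop(zs %*% L[m, ]) * sd_m * sqrt(share[match(m, rownames(L))])
    eps <- rnorm(n, 0, sd_m * sqrt(1 - share[match(m, rownames(L))]) * p$noise_scale)
    dev <- pmin(pmax(signal + eps, -3.5 * sd_m), 3.5 * sd_m)  # keep renderable
    surf[, m] <- p$surface$mean[m] + p$bmi_effects[m] * (bmi - ref_bmi) + dev
  }
  ang <- matrix(NA_real_, n, length(.nf_angle_codes),
                dimnames = list(NULL, .nf_angle_codes))
  for (m in .nf_angle_codes) {
    k <- match(m, rownames(L))
    for (s in c("M", "F")) {
      i <- which(sex == s)
      if (!length(i)) next
      sd_m <- p$angles[[s]]$sd[m]
      signal <- drop(zs[i, , drop = FALSE] %*% L[m, ]) * sd_m * sqrt(share[k])
      eps <- rnorm(length(i), 0, sd_m * sqrt(1 - share[k]) * p$noise_scale)
      ang[i, m] <- p$angles[[s]]$mean[m] + signal + eps
    }
  }
  # angles must stay in a plausible open range for planar construction
  ang[, "g-n-prn"] <- pmin(pmax(ang[, "g-n-prn"], 95), 175)
  ang[, "n-prn-sn"] <- pmin(pmax(ang[, "n-prn-sn"], 70), 160)

  out <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)), sex = sex, age = age,
    height = height, weight = weight, bmi = weight / height^2,
    has_kyphion = has_k, hump_height_mm = hump,
    lateral_shape = lateral, frontal_type = ft, border_slope_deg = slope,
    stringsAsFactors = FALSE)
  colnames(bone) <- paste0("bone_", colnames(bone))
  surf_cols <- gsub("-", "_", paste0("surf_", colnames(surf)))
  ang_cols <- gsub("-", "_", paste0("ang_", colnames(ang)))
  out <- cbind(out, as.data.frame(bone),
               setNames(as.data.frame(surf), surf_cols),
               setNames(as.data.frame(ang), ang_cols))
  attr(out, "params") <- p
  class(out) <- c("subject_table", class(out))
  out
}

.nf_empty_subject_table <- function() {
  out <- data.frame(subject_id = character(0), sex = character(0),
                    age = numeric(0), height = numeric(0), weight = numeric(0),
                    bmi = numeric(0), has_kyphion = logical(0),
                    hump_height_mm = numeric(0), lateral_shape = character(0),
                    frontal_type = character(0), border_slope_deg = numeric(0),
                    stringsAsFactors = FALSE)
  for (d in .nf_bone_dims) out[[paste0("bone_", d)]] <- numeric(0)
  for (m in .nf_surface_codes) out[[gsub("-", "_", paste0("surf_", m))]] <- numeric(0)
  for (m in .nf_angle_codes) out[[gsub("-", "_", paste0("ang_", m))]] <- numeric(0)
  class(out) <- c("subject_table", class(out))
  out
}

#' The 33-cadaver reference fixture
#'
#' Encodes the published 33-cadaver morphology study exactly: 18 male and 15
#' female subjects; frontal types A 9/10, B 6/4, C 1/0, D 1/1, E 1/0
#' (male/female); lateral shapes V = 26, S = 7; 8 kyphion-bearing subjects
#' of which 7 are S-shaped and 1 (a sub-threshold 0.3 mm hump) is V-shaped;
#' per-sex bone-distance means and SDs as published. Bone dimensions and
#' border slopes are drawn reproducibly (fixed internal seed) from the
#' per-sex distributions and the per-type templates, so the rule-based
#' classifiers recover the recorded classes from the geometry.
#'
#' @return A list: `subjects` (a 33-row `subject_table`),
#'   `frontal_counts` (type x sex contingency table) and
#'   `lateral_counts` (shape x kyphion table).
#' @export
cadaver_fixture <- function() {
  # deterministic: local RNG state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  p <- population_params(n = 33, seed = 33L)
  set.seed(2033L)

  sex <- c(rep("M", 18), rep("F", 15))
  ft <- c(rep("A", 9), rep("B", 6), "C", "D", "E",          # 18 males
          rep("A", 10), rep("B", 4), "D")                   # 15 females
  # lateral: S = 7 (4 male, 3 female); kyphion-bearing = 8 (the 7 S plus one
  # male V with a sub-threshold hump)
  lateral <- rep("V", 33)
  lateral[c(1:4, 19:21)] <- "S"
  has_k <- rep(FALSE, 33)
  has_k[c(1:4, 19:21, 5)] <- TRUE
  hump <- numeric(33)
  hump[c(1:4, 19:21)] <- round(rlnorm(7, log(1.8), 0.25), 2)  # >= tau comfortably
  hump[5] <- 0.3                                              # sub-threshold

  rtrunc <- function(n, mean, sd) pmax(rnorm(n, mean, sd), 0.2 * mean)
  bone <- matrix(NA_real_, 33, length(.nf_bone_dims),
                 dimnames = list(NULL, .nf_bone_dims))
  for (s in c("M", "F")) {
    i <- which(sex == s); bp <- p$bone[[s]]
    for (d in c("n_s", "s_k", "k_r", "s_r", "n_r", "d4"))
      bone[i, d] <- rtrunc(length(i), bp$mean[d], bp$sd[d])
  }
  bone[!has_k, c("s_k", "k_r")] <- NA_real_
  w <- cc <- slope <- numeric(33)
  for (t in names(p$type_templates)) {
    i <- which(ft == t)
    if (!length(i)) next
    tpl <- p$type_templates[[t]]
    w[i] <- runif(length(i), tpl$w[1], tpl$w[2])
    cc[i] <- runif(length(i), tpl$c[1], tpl$c[2])
    slope[i] <- runif(length(i), tpl$slope[1], tpl$slope[2])
  }
  bone[, "d3"] <- w * bone[, "d4"]
  bone[, "d5"] <- (1 - cc) * pmin(bone[, "d3"], bone[, "d4"])

  age <- rnorm(33, 64.9, 13.9)
  height <- ifelse(sex == "M", rnorm(33, 1.66, 0.06), rnorm(33, 1.55, 0.05))
  bmi <- rnorm(33, 22, 2.5)
  subjects <- data.frame(
    subject_id = sprintf("C%02d", 1:33), sex = sex, age = age,
    height = height, weight = bmi * height^2, bmi = bmi,
    has_kyphion = has_k, hump_height_mm = hump, lateral_shape = lateral,
    frontal_type = ft, border_slope_deg = slope, stringsAsFactors = FALSE)
  colnames(bone) <- paste0("bone_", colnames(bone))
  subjects <- cbind(subjects, as.data.frame(bone))
  class(subjects) <- c("subject_table", class(subjects))

  list(subjects = subjects,
       frontal_counts = table(type = subjects$frontal_type,
                              sex = factor(subjects$sex, c("M", "F"))),
       lateral_counts = table(shape = subjects$lateral_shape,
                              kyphion = subjects$has_kyphion))
}
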