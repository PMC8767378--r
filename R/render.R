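# Stylized three-view face renderer. Landmark pixel positions are an
# analytic placement of a parametric face template driven by the subject's
# sampled measurements; images carry a schematic profile/outline, a bright
# blob at every landmark, a calibration ruler with ticks at known spacing,
# and additive Gaussian noise. Ground-truth landmark sets match the drawn
# geometry exactly.

#' Rendering configuration
#'
#' @param image_size `c(h, w)` in pixels, at least 64 (default 224 x 224,
#'   the network input size).
#' @param channels 1 (grayscale) or 3.
#' @param mm_per_px Scale at the reference 224-px frame; smaller frames are
#'   scaled proportionally so the whole face still fits.
#' @param tick_px Ruler tick spacing in pixels (>= 2). The physical tick
#'   spacing is `tick_px * mm_per_px` exactly, so ruler calibration is
#'   consistent by construction.
#' @param noise_sd SD of additive Gaussian pixel noise (pixel scale 0..1).
#' @param background Background intensity.
#' @param blob_sigma SD (px) of the landmark blobs.
#' @return An object of class `render_config`.
#' @export
render_config <- function(image_size = c(224, 224), channels = 3,
                          mm_per_px = 0.85, tick_px = 10, noise_sd = 0.02,
                          background = 0.08, blob_sigma = 1.6) {
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  if (any(image_size < 64))
    stop_nf("nf_parameter_error", "image_size must be at least 64 px")
  if (tick_px < 2)
    stop_nf("nf_parameter_error", "ruler tick spacing must be >= 2 px")
  if (!channels %in% c(1, 3))
    stop_nf("nf_parameter_error", "channels must be 1 or 3")
  structure(list(image_size = as.integer(image_size), channels = as.integer(channels),
                 mm_per_px = mm_per_px, tick_px = as.integer(tick_px),
                 noise_sd = noise_sd, background = background,
                 blob_sigma = blob_sigma),
            class = "render_config")
}

# effective mm/px after frame scaling (face occupies the same fraction of
# any frame size)
.nf_eff_scale <- function(cfg) cfg$mm_per_px * 224 / min(cfg$image_size)

# --- drawing primitives (pixel-space, 0-based coordinates) -----------------

.nf_blob <- function(img, x, y, sigma, amp) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3 * sigma)
  xs <- max(0, floor(x - r)):min(w - 1, ceiling(x + r))
  ys <- max(0, floor(y - r)):min(h - 1, ceiling(y + r))
  if (!length(xs) || !length(ys)) return(img)
  g <- outer(exp(-((ys - y)^2) / (2 * sigma^2)),
             exp(-((xs - x)^2) / (2 * sigma^2)))
  img[ys + 1, xs + 1] <- pmin(1, img[ys + 1, xs + 1] + amp * g)
  img
}

.nf_line <- function(img, p, q, val) {
  n <- max(2, ceiling(euclidean_distance(p, q) * 2))
  t <- seq(0, 1, length.out = n)
  xs <- round(p[1] + t * (q[1] - p[1]))
  ys <- round(p[2] + t * (q[2] - p[2]))
  keep <- xs >= 0 & xs < ncol(img) & ys >= 0 & ys < nrow(img)
  img[cbind(ys[keep] + 1, xs[keep] + 1)] <- val
  img
}

.nf_polyline <- function(img, pts, val) {
  for (i in seq_len(nrow(pts) - 1))
    img <- .nf_line(img, pts[i, ], pts[i + 1, ], val)
  img
}

.nf_rot <- function(v, deg) {
  a <- deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

# --- view geometry (all in mm relative to the nasion; y down, x per view) --

.nf_rec_get <- function(rec, col, default = NA_real_) {
  v <- rec[[col]]
  if (is.null(v) || is.na(v)) default else as.numeric(v)
}

# lateral template: subject faces +x, superior is -y
.nf_lateral_geometry <- function(rec) {
  mm <- function(code, d) .nf_rec_get(rec, code, d) * 10  # surface cm -> mm
  n_prn <- mm("surf_n_prn", 3.85); n_sn <- mm("surf_n_sn", 4.91)
  n_r <- mm("surf_n_r", 1.26)        # skin marker over the rhinion, on the dorsum
  sn_prn <- mm("surf_sn_prn", 1.67)
  gnp <- .nf_rec_get(rec, "ang_g_n_prn", 136.4)
  ns_b <- .nf_rec_get(rec, "bone_n_s", 5.71)
  adjusted <- character(0)
  # planar triangle n / prn / sn: distances n-prn, n-sn honoured exactly;
  # sn-prn raised minimally when the sampled triple violates the triangle
  # inequality (geometrically unconstructible)
  if (n_prn + sn_prn <= n_sn + 0.3) {
    sn_prn <- n_sn - n_prn + 0.3
    adjusted <- c(adjusted, "sn-prn")
  }
  theta <- 30                                   # dorsum declination, degrees
  d <- c(cos(theta * pi / 180), sin(theta * pi / 180))
  n <- c(0, 0)
  prn <- n + n_prn * d
  r <- n + n_r * d
  post <- c(-d[2], d[1])                        # posterior-inferior normal
  s <- n + ns_b * d + 1.0 * post
  cosA <- (n_prn^2 + n_sn^2 - sn_prn^2) / (2 * n_prn * n_sn)
  A <- acos(min(1, max(-1, cosA))) * 180 / pi   # angle prn-n-sn at nasion
  sn <- n + n_sn * .nf_rot(d, A)                # rotated toward inferior-posterior
  g <- n + 14 * .nf_rot(d, -gnp)                # realizes the nasofrontal angle
  n_gn <- n_sn / 0.43                           # middle face ~43% of n-gn
  gn <- n + n_gn * c(cos(78 * pi / 180), sin(78 * pi / 180))
  pg <- gn + c(1.5, -8)
  pts <- rbind(g = g, n = n, s = s, r = r, prn = prn, sn = sn, pg = pg, gn = gn,
               po_R = c(-58, 6), or_R = c(-26, -4))
  if (isTRUE(rec$has_kyphion)) {
    # skin hump apex on the visible s -> r dorsum chord, offset anteriorly
    # by the hump height at the along-chord position implied by S-K : K-R
    sk <- .nf_rec_get(rec, "bone_s_k", 14.31)
    kr <- .nf_rec_get(rec, "bone_k_r", 4.56)
    frac <- min(0.8, max(0.2, sk / (sk + kr)))
    chord <- s + frac * (r - s)
    u <- (r - s) / euclidean_distance(s, r)
    ant <- c(u[2], -u[1])                       # anterior normal of the chord
    h <- .nf_rec_get(rec, "hump_height_mm", 0)
    k <- chord + h * ant
    pts <- rbind(pts, k = k)
  }
  list(points = pts, adjusted = adjusted,
       n_sn_vertical = abs(sn[2] - n[2]))
}

# frontal template: subject faces the viewer; midline vertical at x = 0
.nf_frontal_geometry <- function(rec, n_sn_vertical) {
  mm <- function(code, d) .nf_rec_get(rec, code, d) * 10
  al <- mm("surf_al_al", 4.01); ac <- mm("surf_ac_ac", 3.23)
  en <- mm("surf_en_en", 3.57)
  ys <- n_sn_vertical
  yp <- 0.75 * ys
  pts <- rbind(
    g = c(0, -12), n = c(0, 0), prn = c(0, yp), sn = c(0, ys),
    pg = c(0, ys + 30), gn = c(0, ys + 40),
    en_R = c(-en / 2, -8), en_L = c(en / 2, -8),
    ex_R = c(-en / 2 - 28, -9), ex_L = c(en / 2 + 28, -9),
    mf_R = c(-9, -4), mf_L = c(9, -4),
    al_R = c(-al / 2, yp + 2), al_L = c(al / 2, yp + 2),
    mal_R = c(-0.8 * al / 2, (yp + ys) / 2), mal_L = c(0.8 * al / 2, (yp + ys) / 2),
    ac_R = c(-ac / 2, ys - 1), ac_L = c(ac / 2, ys - 1),
    zy_R = c(-64, 8), zy_L = c(64, 8),
    ch_R = c(-24, ys + 16), ch_L = c(24, ys + 16))
  list(points = pts, adjusted = character(0))
}

.nf_basilar_geometry <- function(rec) {
  mm <- function(code, d) .nf_rec_get(rec, code, d) * 10
  al <- mm("surf_al_al", 4.01); ac <- mm("surf_ac_ac", 3.23)
  pts <- rbind(prn = c(0, -12), sn = c(0, 6),
               al_R = c(-al / 2, 0), al_L = c(al / 2, 0),
               ac_R = c(-ac / 2, 4), ac_L = c(ac / 2, 4))
  list(points = pts, adjusted = character(0))
}

# --- rendering -------------------------------------------------------------

.nf_render_view <- function(rec, view, geom, cfg) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  scale <- .nf_eff_scale(cfg)                  # mm per px
  anchor <- switch(view,
    lateral = c(0.42 * w, 0.24 * h),
    frontal = c(0.46 * w, 0.40 * h),
    basilar = c(0.46 * w, 0.50 * h))
  px <- sweep(geom$points / scale, 2, anchor, `+`)
  if (any(px < 2) || any(px[, 1] > w - 3) || any(px[, 2] > h - 3))
    stop_nf("nf_render_error", "subject ", rec$subject_id %||% "?",
            " does not fit in the ", view, " frame: measurements too large ",
            "for image_size/mm_per_px")
  img <- matrix(cfg$background, h, w)
  # schematic structure
  if (view == "lateral") {
    ord <- intersect(c("g", "n", "s", "k", "r", "prn", "sn", "pg", "gn"),
                     rownames(px))
    img <- .nf_polyline(img, px[ord, , drop = FALSE], 0.55)
  } else if (view == "frontal") {
    img <- .nf_polyline(img, px[c("g", "n", "prn", "sn", "pg", "gn"), ], 0.55)
    img <- .nf_polyline(img, px[c("al_R", "prn", "al_L"), ], 0.45)
    img <- .nf_line(img, px["en_R", ], px["ex_R", ], 0.4)
    img <- .nf_line(img, px["en_L", ], px["ex_L", ], 0.4)
  } else {
    img <- .nf_polyline(img, px[c("al_R", "prn", "al_L", "sn", "al_R"), ], 0.5)
  }
  for (i in seq_len(nrow(px)))
    img <- .nf_blob(img, px[i, 1], px[i, 2], cfg$blob_sigma, 0.9)
  # ruler: vertical bar near the right edge, ticks every tick_px
  bar_x <- (w - 9):(w - 7)
  img[, bar_x + 1] <- 0.85
  tick_rows <- seq(6, h - 7, by = cfg$tick_px)
  ticks <- cbind(x = rep(w - 9, length(tick_rows)), y = tick_rows)
  for (ty in tick_rows) img[ty + 1, (w - 13):(w - 7) + 1] <- 1.0
  arr <- array(0, c(h, w, cfg$channels))
  chan_gain <- if (cfg$channels == 3) c(1, 0.85, 0.7) else 1
  for (c in seq_len(cfg$channels))
    arr[, , c] <- pmin(1, img * chan_gain[c] +
                          rnorm(h * w, 0, cfg$noise_sd))
  arr[arr < 0] <- 0
  ls <- landmark_set(rec$subject_id %||% "synthetic", view, px)
  cal <- calibration_info(view, scale, source = "ruler_ticks")
  list(image = arr, landmarks = ls, calibration = cal,
       ruler = list(ticks_px = ticks, tick_spacing_mm = cfg$tick_px * scale),
       adjusted = geom$adjusted)
}

#' Render the three standardized views of a subject
#'
#' Places a parametric face template according to the subject's sampled
#' measurements and draws each view with a calibration ruler. Ground-truth
#' landmark pixel positions match the drawn geometry exactly, and
#' (tick pixel distance) x (mm per px) equals the configured tick spacing
#' exactly. All sampled distances in the measurement catalog are honoured
#' exactly by the geometry except where flagged in the per-view `adjusted`
#' element (a sampled triple that violates the triangle inequality is
#' minimally repaired; see the methods vignette).
#'
#' @param rec A single-row `subject_table` (or equivalent list).
#' @param cfg A [render_config()].
#' @param seed Integer seed for pixel noise.
#' @param views Views to render.
#' @return Named list per view with elements `image` (h x w x c array in
#'   `[0,1]`), `landmarks` ([landmark_set()]), `calibration`
#'   ([calibration_info()]), `ruler` (tick ground truth) and `adjusted`.
#' @export
render_subject_views <- function(rec, cfg = render_config(), seed = 1L,
                                 views = c("frontal", "lateral", "basilar")) {
  if (inherits(rec, "data.frame") && nrow(rec) != 1)
    stop_nf("nf_parameter_error", "rec must be a single subject")
  set.seed(seed)
  lat <- .nf_lateral_geometry(rec)
  out <- list()
  for (v in views) {
    geom <- switch(v,
      lateral = lat,
      frontal = .nf_frontal_geometry(rec, lat$n_sn_vertical),
      basilar = .nf_basilar_geometry(rec))
    out[[v]] <- .nf_render_view(rec, v, geom, cfg)
  }
  out
}

#' Render a landmark-regression training set for one view
#'
#' @param subjects A `subject_table`.
#' @param view View to render.
#' @param cfg A [render_config()].
#' @param seed Integer seed.
#' @return A list of class `keypoint_dataset`: `images` (list of arrays),
#'   `landmark_sets`, `view`, `codes` (landmark order used as the
#'   regression target), `calibration`.
#' @export
render_landmark_dataset <- function(subjects, view = "lateral",
                                    cfg = render_config(), seed = 1L) {
  view <- match.arg(view, .nf_views)
  codes <- view_codes(view, include_optional = FALSE)
  images <- vector("list", nrow(subjects))
  sets <- vector("list", nrow(subjects))
  cal <- NULL
  for (i in seq_len(nrow(subjects))) {
    rv <- render_subject_views(subjects[i, ], cfg, seed = seed + i, views = view)
    images[[i]] <- rv[[view]]$image
    sets[[i]] <- rv[[view]]$landmarks
    cal <- rv[[view]]$calibration
  }
  structure(list(images = images, landmark_sets = sets, view = view,
                 codes = codes, calibration = cal),
            class = "keypoint_dataset")
}

#' Write a complete synthetic fixture dataset to disk
#'
#' Samples a population, renders all three views per subject, and writes
#' images (PNG or plain-text PGM), one landmark JSON per subject-view, the
#' population CSV, and a YAML manifest carrying the seed and parameters.
#' Deterministic: the same seed yields byte-identical landmark JSON.
#'
#' @param n Number of subjects.
#' @param cfg A [render_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @param format `"png"` or `"pgm"` (plain text, grayscale).
#' @return The manifest, invisibly (also written as `manifest.yaml`).
#' @export
make_fixture_dataset <- function(n, cfg = render_config(), seed = 1L,
                                 out_dir, format = c("png", "pgm")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_nf("nf_io_error", "cannot create output directory: ", out_dir)
  subjects <- sample_population(population_params(n, seed = seed))
  files <- character(0)
  for (i in seq_len(nrow(subjects))) {
    rec <- subjects[i, ]
    rv <- render_subject_views(rec, cfg, seed = seed + i)
    for (v in names(rv)) {
      stem <- file.path(out_dir, paste0(rec$subject_id, "_", v))
      imgf <- paste0(stem, ".", format)
      if (format == "png") write_image_png(rv[[v]]$image, imgf)
      else write_image_pgm(rv[[v]]$image, imgf)
      jf <- paste0(stem, ".json")
      write_landmark_file(rv[[v]]$landmarks, jf)
      files <- c(files, basename(imgf), basename(jf))
    }
  }
  csvf <- file.path(out_dir, "population.csv")
  write.csv(subjects, csvf, row.names = FALSE)
  manifest <- list(
    tool = "nasoform", version = as.character(utils::packageVersion("nasoform")),
    n = as.integer(n), seed = as.integer(seed),
    image_size = as.integer(cfg$image_size), channels = cfg$channels,
    mm_per_px_224 = cfg$mm_per_px, tick_px = cfg$tick_px, format = format,
    files = c("population.csv", files))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
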