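# Nasal-bone morphology: the dorsal bone profile, kyphion (dorsal hump)
# detection, the four bone angles (NA, DPA, KA, RA), the lateral V/S shape
# rule and the frontal A-E type decision tree.

#' Construct a lateral bone profile
#'
#' An ordered dorsal polyline from nasion through sellion (optionally
#' kyphion) to rhinion and pronasale, under the lateral orientation
#' contract (subject faces +x, superior is -y).
#'
#' @param points Matrix of `(x, y)` with row names from
#'   `{"n","s","k","r","prn"}` (k optional), in profile order; at least the
#'   four required points.
#' @param mm_per_px Scale; 1 if coordinates are already in mm.
#' @param superior_point Optional point above the nasion giving the
#'   superior profile continuation used by the nasion angle (defaults to
#'   1 unit straight above n).
#' @return `bone_profile` object.
#' @export
bone_profile <- function(points, mm_per_px = 1, superior_point = NULL) {
  need <- c("n", "s", "r", "prn")
  missing <- setdiff(need, rownames(points))
  if (length(missing))
    stop_nf("nf_geometry_error", "bone profile missing point '", missing[1], "'")
  if (nrow(points) < 4)
    stop_nf("nf_geometry_error", "bone profile needs at least 4 points")
  if (is.null(superior_point))
    superior_point <- points["n", ] + c(0, -1 / mm_per_px)
  structure(list(points = points, mm_per_px = mm_per_px,
                 superior_point = superior_point),
            class = "bone_profile")
}

#' Detect the kyphion (dorsal hump apex) on a bone profile
#'
#' The kyphion is the interior profile point (between sellion and rhinion)
#' of maximum perpendicular deviation from the sellion-rhinion chord on the
#' anterior side. It is reported only when that deviation reaches
#' `tau_k_mm` (default 0.5 mm); a straight or posterior-sagging dorsum has
#' no kyphion.
#'
#' @param profile A [bone_profile()].
#' @param tau_k_mm Minimum anterior deviation in mm (> 0).
#' @return `NULL` if no qualifying hump, else a list with `point` (named
#'   `(x, y)`), `code` (row name), and `deviation_mm`.
#' @export
detect_kyphion <- function(profile, tau_k_mm = 0.5) {
  stopifnot(inherits(profile, "bone_profile"))
  if (tau_k_mm <= 0) stop_nf("nf_parameter_error", "tau_k_mm must be > 0")
  pts <- profile$points
  i_s <- match("s", rownames(pts)); i_r <- match("r", rownames(pts))
  interior <- setdiff(seq(i_s, i_r), c(i_s, i_r))
  if (!length(interior)) return(NULL)
  s <- pts[i_s, ]; r <- pts[i_r, ]
  d <- r - s
  u <- d / sqrt(sum(d^2))
  # anterior (dorsal) side: the normal (u_y, -u_x) points toward +x/-y
  best <- NULL
  for (i in interior) {
    v <- pts[i, ] - s
    dev_px <- v[1] * u[2] - v[2] * u[1]       # signed; > 0 is anterior
    dev_mm <- dev_px * profile$mm_per_px
    if (dev_mm >= tau_k_mm && (is.null(best) || dev_mm > best$deviation_mm))
      best <- list(point = pts[i, ], code = rownames(pts)[i],
                   deviation_mm = unname(dev_mm))
  }
  best
}

#' Bone angles on the lateral profile
#'
#' The nasion angle (NA) between the superior profile continuation and the
#' nasion-sellion limb; the dorsal profile angle (DPA) at the sellion
#' between nasion and rhinion; the kyphion angle (KA) at the kyphion
#' between sellion and rhinion, present only when a kyphion is supplied;
#' and the rhinion angle (RA) at the rhinion between the proximal dorsum
#' (kyphion if present, else sellion) and the pronasale.
#'
#' @param profile A [bone_profile()].
#' @param kyphion Optional kyphion point (e.g. from [detect_kyphion()]'s
#'   `$point`).
#' @return Named numeric vector `NA_deg`, `DPA`, `KA` (NA if absent), `RA`,
#'   degrees.
#' @export
bone_angles <- function(profile, kyphion = NULL) {
  stopifnot(inherits(profile, "bone_profile"))
  p <- profile$points
  na_deg <- angle_at_vertex(profile$superior_point, p["n", ], p["s", ])
  dpa <- angle_at_vertex(p["n", ], p["s", ], p["r", ])
  ka <- if (!is.null(kyphion))
    angle_at_vertex(p["s", ], kyphion, p["r", ]) else NA_real_
  prox <- if (!is.null(kyphion)) kyphion else p["s", ]
  ra <- angle_at_vertex(prox, p["r", ], p["prn", ])
  c(NA_deg = na_deg, DPA = dpa, KA = ka, RA = ra)
}

#' Classify the lateral nasal-bone shape (V or S)
#'
#' A V-shaped dorsum runs straight from sellion to rhinion with a single
#' angulation at the dorsal profile angle; an S-shaped dorsum curves
#' through a distinct kyphion, adding a second angulation at the kyphion
#' angle. The rule: S iff a kyphion is present AND its angulation
#' `|180 - KA|` reaches `tau_a_deg`; otherwise V.
#'
#' @param angles Output of [bone_angles()].
#' @param kyphion_present Was a kyphion detected?
#' @param tau_a_deg Minimum kyphion angulation in degrees (default 4).
#' @return `"V"` or `"S"`.
#' @export
classify_lateral_shape <- function(angles, kyphion_present, tau_a_deg = 4) {
  if (tau_a_deg <= 0) stop_nf("nf_parameter_error", "tau_a_deg must be > 0")
  if (kyphion_present && is.na(angles["KA"]))
    stop_nf("nf_logic_error", "kyphion present but KA angle absent")
  if (kyphion_present && abs(180 - angles[["KA"]]) >= tau_a_deg) "S" else "V"
}

#' Frontal type thresholds
#'
#' @param rho_n Narrow frontonasal-suture width ratio bound (d3/d4).
#' @param rho_w Wide bound.
#' @param kappa Concavity bound on `1 - d5/min(d3, d4)`.
#' @param vertical_band_deg Half-width of the vertical-slope band about 90
#'   degrees.
#' @return Named list of thresholds.
#' @export
frontal_type_thresholds <- function(rho_n = 0.45, rho_w = 0.80, kappa = 0.15,
                                    vertical_band_deg = 10) {
  list(rho_n = rho_n, rho_w = rho_w, kappa = kappa,
       vertical_band_deg = vertical_band_deg)
}

#' Classify the frontal nasal-bone type (A-E)
#'
#' Decision tree over the bone widths: `w = d3/d4` (frontonasal-suture
#' width relative to the lower nasomaxillary width), concavity
#' `c = 1 - d5/min(d3, d4)` (narrowest width relative to the smaller
#' boundary width), and whether the nasomaxillary border slope is vertical
#' (within the band about 90 degrees):
#' E if wide, not concave and vertical; D if wide and concave; C if narrow
#' and not concave; B if concave; else A (obliquely descending sutures).
#'
#' @param d3,d4,d5 Upper (frontonasal), lower (nasomaxillary) and narrowest
#'   bone widths, mm.
#' @param border_slope_deg Nasomaxillary border slope, degrees from
#'   horizontal.
#' @param thresholds A [frontal_type_thresholds()].
#' @return One of `"A".."E"`.
#' @export
classify_frontal_type <- function(d3, d4, d5, border_slope_deg,
                                  thresholds = frontal_type_thresholds()) {
  if (any(c(d3, d4, d5) <= 0) || any(!is.finite(c(d3, d4, d5))))
    stop_nf("nf_data_error", "bone widths must be positive and finite")
  th <- thresholds
  w <- d3 / d4
  cc <- 1 - d5 / min(d3, d4)
  vertical <- abs(border_slope_deg - 90) <= th$vertical_band_deg
  if (w >= th$rho_w && !(cc >= th$kappa) && vertical) return("E")
  if (w >= th$rho_w && cc >= th$kappa) return("D")
  if (w < th$rho_n && !(cc >= th$kappa)) return("C")
  if (cc >= th$kappa) return("B")
  "A"
}

#' Build a lateral bone profile from a subject record
#'
#' Reconstructs the dorsal bone polyline (in mm, scale 1) implied by a
#' subject's bone dimensions: nasion at the origin, dorsum declined 30
#' degrees, sellion one mm posterior of the dorsum line at N-S, kyphion
#' (when the subject has one) offset anteriorly by the hump height at S-K
#' along the sellion-rhinion chord.
#'
#' @param rec Single-row `subject_table`.
#' @return A [bone_profile()] with `mm_per_px = 1`.
#' @export
subject_bone_profile <- function(rec) {
  ns <- .nf_rec_get(rec, "bone_n_s", 5.71)
  sr <- .nf_rec_get(rec, "bone_s_r", 18.56)
  theta <- 30 * pi / 180
  d <- c(cos(theta), sin(theta))
  post <- c(-d[2], d[1])
  n <- c(0, 0)
  s <- n + ns * d + 1.0 * post
  r <- s + sr * d
  prn <- r + 8 * c(cos(55 * pi / 180), sin(55 * pi / 180))
  pts <- rbind(n = n, s = s, r = r, prn = prn)
  if (isTRUE(rec$has_kyphion)) {
    sk <- .nf_rec_get(rec, "bone_s_k", 14.31)
    h <- .nf_rec_get(rec, "hump_height_mm", 0)
    u <- d
    ant <- c(u[2], -u[1])
    k <- s + min(sk, 0.9 * sr) * u + h * ant
    pts <- rbind(pts[c("n", "s"), ], k = k, pts[c("r", "prn"), ])
  }
  bone_profile(pts, mm_per_px = 1)
}

#' Rule-based morphology classification of subject records
#'
#' Runs the geometric pipeline on each record: reconstruct the bone
#' profile, detect the kyphion, compute bone angles, and apply the lateral
#' V/S rule and the frontal A-E decision tree.
#'
#' @param subjects A `subject_table`.
#' @param tau_k_mm,tau_a_deg Kyphion detection / angulation thresholds.
#' @param thresholds Frontal [frontal_type_thresholds()].
#' @return Data frame: `subject_id`, `lateral_shape`, `frontal_type`,
#'   `kyphion_detected`, and the four bone angles.
#' @export
classify_subjects <- function(subjects, tau_k_mm = 0.5, tau_a_deg = 4,
                              thresholds = frontal_type_thresholds()) {
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    rec <- subjects[i, ]
    prof <- subject_bone_profile(rec)
    ky <- detect_kyphion(prof, tau_k_mm)
    ang <- bone_angles(prof, kyphion = ky$point)
    data.frame(subject_id = rec$subject_id,
               lateral_shape = classify_lateral_shape(ang, !is.null(ky), tau_a_deg),
               frontal_type = classify_frontal_type(
                 rec$bone_d3, rec$bone_d4, rec$bone_d5,
                 rec$border_slope_deg, thresholds),
               kyphion_detected = !is.null(ky),
               NA_deg = ang[["NA_deg"]], DPA = ang[["DPA"]],
               KA = ang[["KA"]], RA = ang[["RA"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
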