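# Calibrated anthropometry: pixel geometry -> millimetre / degree
# measurements keyed by catalog codes.

#' Euclidean distance between two points
#'
#' Pythagorean distance in pixel (or any Cartesian) coordinates.
#'
#' @param p,q Numeric vectors `c(x, y)` (any common length works).
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  sqrt(sum((q - p)^2))
}

#' Metric inner product of two vectors
#'
#' The scalar product `|g_i||g_j| cos(theta_ij)`, used to project shared axes
#' when checking cross-view consistency of measurements.
#'
#' @param g_i,g_j Numeric vectors of equal length.
#' @return Scalar inner product.
#' @export
metric_inner_product <- function(g_i, g_j) {
  sum(as.numeric(g_i) * as.numeric(g_j))
}

#' Interior angle at a vertex
#'
#' The interior angle `abc` at vertex `b`, in degrees, range `(0, 180]`.
#' Invariant under translation, rotation and uniform scaling.
#'
#' @param a,b,c Points `c(x, y)`; `b` is the vertex.
#' @return Angle in degrees.
#' @export
angle_at_vertex <- function(a, b, c) {
  u <- as.numeric(a) - as.numeric(b)
  v <- as.numeric(c) - as.numeric(b)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_nf("nf_geometry_error", "angle vertex coincides with an endpoint")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Derive a millimetre-per-pixel scale from ruler ticks
#'
#' Fits the mean inter-tick pixel distance by least squares along the ruler
#' axis (principal direction of the tick positions) and converts the known
#' physical tick spacing into a scale. Fits whose residual exceeds 10% of the
#' tick spacing (non-collinear or irregular ticks) are rejected.
#'
#' @param tick_positions_px Matrix (n x 2) or list of `c(x, y)` tick centers,
#'   at least 3, approximately collinear and evenly spaced.
#' @param tick_spacing_mm Physical distance between adjacent ticks, mm.
#' @param view View tag recorded in the result.
#' @return A [calibration_info()] with `mm_per_px = spacing_mm / mean
#'   inter-tick pixel distance`.
#' @export
calibrate_scale <- function(tick_positions_px, tick_spacing_mm, view = "frontal") {
  if (is.list(tick_positions_px))
    tick_positions_px <- do.call(rbind, tick_positions_px)
  pts <- as.matrix(tick_positions_px)
  if (nrow(pts) < 3)
    stop_nf("nf_calibration_error", "at least 3 ruler ticks are required, got ",
            nrow(pts))
  if (!is.numeric(tick_spacing_mm) || tick_spacing_mm <= 0)
    stop_nf("nf_parameter_error", "tick_spacing_mm must be positive")
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)
  axis <- sv$v[, 1]                       # ruler direction
  t <- drop(ctr %*% axis)                 # positions along the ruler
  o <- order(t); t <- t[o]
  # least-squares even-spacing fit: t_i ~ a + d*i
  i <- seq_along(t) - 1
  fit <- stats::lm.fit(cbind(1, i), t)
  d <- abs(fit$coefficients[2])           # mean inter-tick px distance
  off_axis <- sqrt(rowSums((ctr - outer(drop(ctr %*% axis), axis))^2))
  resid <- sqrt(mean(fit$residuals^2) + mean(off_axis^2))
  if (d <= 0 || resid > 0.10 * d)   # residual beyond 10% of a tick spacing
    stop_nf("nf_calibration_error",
            "ruler ticks are not collinear/evenly spaced within 10% of spacing")
  calibration_info(view, unname(tick_spacing_mm / d), source = "ruler_ticks")
}

#' Measurement catalog
#'
#' The measurement definitions computed by [measure_subject()]: projective
#' (linear) distances, angular measurements on the skin surface, and the
#' frontal symmetry ratios. Operand codes resolve in [landmark_catalog()];
#' for angles the vertex is the middle operand.
#'
#' Surface distances are reported in centimetres (the scale on which nasal
#' surface dimensions are conventionally tabulated); angles in degrees.
#' The kyphion angle `n-k-r` is optional: subjects without a dorsal hump
#' simply lack the entry.
#'
#' @return Data frame with columns `code`, `kind` (`distance`, `angle`),
#'   `operands` (comma-separated landmark codes), `view`, `units`,
#'   `optional`, `description`.
#' @export
measurement_catalog <- function() {
  def <- function(code, kind, operands, view, units, optional, description)
    data.frame(code = code, kind = kind, operands = operands, view = view,
               units = units, optional = optional, description = description,
               stringsAsFactors = FALSE)
  out <- rbind(
    def("n-prn",    "distance", "n,prn",      "lateral", "cm", FALSE, "dorsal length"),
    def("n-sn",     "distance", "n,sn",       "lateral", "cm", FALSE, "nasal height"),
    def("n-r",      "distance", "n,r",        "lateral", "cm", FALSE, "nasion to rhinion"),
    def("sn-prn",   "distance", "sn,prn",     "lateral", "cm", FALSE, "tip projection"),
    def("al-al",    "distance", "al_R,al_L",  "frontal", "cm", FALSE, "total nose (alar base) width"),
    def("ac-ac",    "distance", "ac_R,ac_L",  "frontal", "cm", FALSE, "nose swing (subalar) width"),
    def("en-en",    "distance", "en_R,en_L",  "frontal", "cm", FALSE, "intercanthal width"),
    def("g-n-prn",  "angle",    "g,n,prn",    "lateral", "degrees", FALSE, "nasofrontal angle"),
    def("pg-n-prn", "angle",    "pg,n,prn",   "lateral", "degrees", FALSE, "nasofacial angle"),
    def("g-sn-pg",  "angle",    "g,sn,pg",    "lateral", "degrees", FALSE, "facial angle"),
    def("n-prn-sn", "angle",    "n,prn,sn",   "lateral", "degrees", FALSE, "nasomental angle"),
    def("mfh",      "angle",    "g,n,sn",     "lateral", "degrees", FALSE, "middle facial height angle"),
    def("lfh",      "angle",    "n,sn,gn",    "lateral", "degrees", FALSE, "lower facial height angle"),
    def("n-k-r",    "angle",    "n,k,r",      "lateral", "degrees", TRUE,  "nasal kyphion angle")
  )
  rownames(out) <- NULL
  out
}

#' Measure a subject from per-view landmark sets
#'
#' Converts landmark pixel geometry into calibrated measurements: distances
#' are pixel distances times the view's mm-per-px scale (reported in the
#' definition's units); angles are calibration-free. Optional landmarks
#' (kyphion) that are absent yield absent entries, not errors.
#'
#' @param landmark_sets Named list of [landmark_set()]s keyed by view.
#' @param calib Named list of [calibration_info()]s keyed by view (required
#'   for views contributing distance measurements).
#' @param defs Measurement definitions; defaults to [measurement_catalog()].
#' @param subject_id Subject identifier; defaults to the first set's.
#' @param provenance `"ground_truth"` or `"detected"`.
#' @return A `measurement_table` data frame: `subject_id`, `code`, `value`,
#'   `units`, `kind`, `provenance`.
#' @export
measure_subject <- function(landmark_sets, calib = list(),
                            defs = measurement_catalog(),
                            subject_id = NULL,
                            provenance = c("ground_truth", "detected")) {
  provenance <- match.arg(provenance)
  if (inherits(landmark_sets, "landmark_set"))
    landmark_sets <- setNames(list(landmark_sets), landmark_sets$view)
  if (is.null(subject_id)) subject_id <- landmark_sets[[1]]$subject_id
  rows <- list()
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    ls <- landmark_sets[[d$view]]
    if (is.null(ls)) {
      if (d$optional) next
      stop_nf("nf_measurement_error", "no ", d$view,
              " landmark set supplied for measurement '", d$code, "'")
    }
    ops <- strsplit(d$operands, ",")[[1]]
    missing <- setdiff(ops, rownames(ls$points))
    if (length(missing)) {
      if (d$optional) next
      stop_nf("nf_measurement_error", "landmark '", missing[1],
              "' missing from the ", d$view, " view (measurement '", d$code, "')")
    }
    p <- ls$points[ops, , drop = FALSE]
    if (d$kind == "distance") {
      cal <- calib[[d$view]]
      if (is.null(cal))
        stop_nf("nf_measurement_error", "no calibration for the ", d$view,
                " view (measurement '", d$code, "')")
      mm <- euclidean_distance(p[1, ], p[2, ]) * cal$mm_per_px
      value <- if (d$units == "cm") mm / 10 else mm
    } else {
      value <- angle_at_vertex(p[1, ], p[2, ], p[3, ])
    }
    rows[[length(rows) + 1]] <-
      data.frame(subject_id = subject_id, code = d$code, value = value,
                 units = d$units, kind = d$kind, provenance = provenance,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("measurement_table", class(out))
  out
}

#' Frontal symmetry ratios
#'
#' Intranasal symmetry indices from the frontal view: the nasal
#' height-to-width ratio (glabella-to-subnasale over maxillofrontale width),
#' left/right mid-alar and nasal-base width ratios about the dorsum axis,
#' the total nose width, and the angle between the dorsum's long axis and
#' the image vertical (midline).
#'
#' @param ls A frontal [landmark_set()] containing `g`, `n`, `sn`,
#'   `mf_R/L`, `mal_R/L`, `ac_R/L`, `al_R/L`.
#' @return A list: `height_width_ratio`, `midalar_lr_ratio`,
#'   `base_lr_ratio`, `total_width_px`, `axis_angle_deg`.
#' @export
frontal_symmetry_ratios <- function(ls) {
  stopifnot(inherits(ls, "landmark_set"))
  need <- c("g", "n", "sn", "mf_R", "mf_L", "mal_R", "mal_L",
            "ac_R", "ac_L", "al_R", "al_L")
  missing <- setdiff(need, rownames(ls$points))
  if (length(missing))
    stop_nf("nf_measurement_error", "landmark '", missing[1],
            "' missing from the frontal view")
  P <- function(code) ls$points[code, ]
  # dorsum long axis: glabella -> subnasale
  axis <- P("sn") - P("g")
  axis_u <- axis / sqrt(sum(axis^2))
  # signed perpendicular distance of a point from the axis line through g
  perp <- function(p) {
    d <- p - P("g")
    d[1] * axis_u[2] - d[2] * axis_u[1]
  }
  ratio_lr <- function(right, left) abs(perp(P(right))) / abs(perp(P(left)))
  lapply(list(
    height_width_ratio = euclidean_distance(P("g"), P("sn")) /
                         euclidean_distance(P("mf_R"), P("mf_L")),
    midalar_lr_ratio   = ratio_lr("mal_R", "mal_L"),
    base_lr_ratio      = ratio_lr("ac_R", "ac_L"),
    total_width_px     = euclidean_distance(P("al_R"), P("al_L")),
    axis_angle_deg     = atan2(abs(axis[1]), abs(axis[2])) * 180 / pi
  ), unname)
}

#' Reshape a measurement table to wide format
#'
#' One row per subject, one column per measurement code; a `units` attribute
#' maps codes to units.
#'
#' @param mt A `measurement_table` (possibly several subjects row-bound).
#' @return Wide data frame.
#' @export
measurements_wide <- function(mt) {
  codes <- unique(mt$code)
  subjects <- unique(mt$subject_id)
  out <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (code in codes) {
    v <- mt$value[mt$code == code][match(subjects, mt$subject_id[mt$code == code])]
    out[[code]] <- v
  }
  attr(out, "units") <- setNames(mt$units[match(codes, mt$code)], codes)
  out
}
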