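# Canonical landmark catalog: 29 anthropometric points over three standardized
# photographic views. The roster closes the stated "29 points including 10
# pairs" as 9 midline points plus 10 left/right pairs; paired points carry
# _L/_R suffixes on the base code (e.g. al_L, al_R).

.nf_views <- c("frontal", "lateral", "basilar")

# base definitions: code, full name, laterality, views where visible, optional
.nf_landmark_base <- data.frame(
  base      = c("g", "n", "s", "r", "k", "prn", "sn", "pg", "gn",
                "en", "ex", "mf", "al", "mal", "ac", "zy", "ch", "po", "or"),
  full_name = c("glabella", "nasion", "sellion", "rhinion", "kyphion",
                "pronasale", "subnasale", "pogonion", "gnathion",
                "endocanthion", "exocanthion", "maxillofrontale", "alare",
                "mid-alare", "subalare", "zygion", "cheilion", "porion",
                "orbitale"),
  laterality = c(rep("midline", 9), rep("paired", 10)),
  views     = c("frontal,lateral", "frontal,lateral", "lateral", "lateral",
                "lateral", "frontal,lateral,basilar", "frontal,lateral,basilar",
                "frontal,lateral", "frontal,lateral",
                "frontal", "frontal", "frontal", "frontal,basilar", "frontal",
                "frontal,basilar", "frontal", "frontal", "lateral", "lateral"),
  optional  = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                rep(FALSE, 10)),
  stringsAsFactors = FALSE
)

#' Landmark catalog
#'
#' The fixed catalog of the 29 anthropometric landmark points used by the
#' measurement system: 9 midline points and 10 bilateral pairs (each pair
#' contributing a `_L` and `_R` entry). Kyphion (`k`), the apex of a dorsal
#' hump, is flagged optional: it is present only in some subjects.
#'
#' @return A data frame with one row per landmark point (29 rows) and columns
#'   `code` (e.g. `"prn"`, `"al_R"`), `base` (pair base code), `full_name`,
#'   `laterality` (`"midline"` or `"paired"`), `side` (`NA`, `"L"` or `"R"`),
#'   `views` (comma-separated views in which the point is annotated) and
#'   `optional` (not always present).
#' @examples
#' cat(nrow(landmark_catalog()), "landmark points\n")
#' @export
landmark_catalog <- function() {
  base <- .nf_landmark_base
  rows <- lapply(seq_len(nrow(base)), function(i) {
    b <- base[i, ]
    if (b$laterality == "midline") {
      data.frame(code = b$base, base = b$base, full_name = b$full_name,
                 laterality = b$laterality, side = NA_character_,
                 views = b$views, optional = b$optional,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(code = paste0(b$base, c("_R", "_L")), base = b$base,
                 full_name = paste(b$full_name, c("(right)", "(left)")),
                 laterality = b$laterality, side = c("R", "L"),
                 views = b$views, optional = b$optional,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition the catalog into paired and midline base codes
#'
#' Facial anthropometric points are symmetric across the median plane; this
#' returns the disjoint, exhaustive partition of the catalog's base codes.
#'
#' @return A list with elements `paired` (10 base codes) and `midline`
#'   (9 codes).
#' @export
paired_midline_partition <- function() {
  base <- .nf_landmark_base
  list(paired  = base$base[base$laterality == "paired"],
       midline = base$base[base$laterality == "midline"])
}

#' Landmark codes valid for a view
#'
#' @param view One of `"frontal"`, `"lateral"`, `"basilar"`.
#' @param include_optional Include not-always-present landmarks (kyphion)?
#' @return Character vector of point codes in catalog order.
#' @export
view_codes <- function(view, include_optional = TRUE) {
  view <- match.arg(view, .nf_views)
  cat_ <- landmark_catalog()
  keep <- vapply(strsplit(cat_$views, ","), function(v) view %in% v, logical(1))
  if (!include_optional) keep <- keep & !cat_$optional
  # lateral photographs show the camera-side (right) of paired points only
  if (view == "lateral") keep <- keep & !(cat_$side %in% "L")
  cat_$code[keep]
}

#' Construct a landmark set
#'
#' A landmark set holds named 2D pixel coordinates for one view of one
#' subject. Coordinates use image pixel convention: origin top-left, x
#' rightward, y downward, 0-based, sub-pixel values allowed.
#'
#' @param subject_id Subject identifier.
#' @param view One of `"frontal"`, `"lateral"`, `"basilar"`.
#' @param points Named list (or 2-column matrix with row names) of
#'   `c(x, y)` pixel coordinates, names being catalog point codes.
#' @param confidence Optional named numeric vector in `[0, 1]`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(subject_id, view, points, confidence = NULL) {
  view <- match.arg(view, .nf_views)
  if (is.matrix(points)) {
    pts <- points
  } else {
    pts <- do.call(rbind, lapply(points, function(p) as.numeric(p[1:2])))
    rownames(pts) <- names(points)
  }
  colnames(pts) <- c("x", "y")
  structure(list(subject_id = as.character(subject_id), view = view,
                 points = pts, confidence = confidence),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> subject %s, %s view, %d points\n",
              x$subject_id, x$view, nrow(x$points)))
  invisible(x)
}

#' Validate a landmark set against the catalog
#'
#' Checks that every point code is valid for the set's view, that all
#' coordinates are finite, and (when an image shape is supplied) that points
#' lie within the image bounds. Violations are returned as data, not raised.
#'
#' @param ls A [landmark_set()].
#' @param image_shape Optional `c(h, w)` of an attached image.
#' @return A character vector of violation messages, each naming the
#'   offending code and rule; empty if the set is valid.
#' @export
validate_landmark_set <- function(ls, image_shape = NULL) {
  stopifnot(inherits(ls, "landmark_set"))
  ok_codes <- view_codes(ls$view)
  v <- character(0)
  codes <- rownames(ls$points)
  for (code in setdiff(codes, ok_codes))
    v <- c(v, sprintf("code '%s' is not valid for the %s view", code, ls$view))
  bad <- codes[!is.finite(ls$points[, 1]) | !is.finite(ls$points[, 2])]
  for (code in bad) v <- c(v, sprintf("code '%s' has non-finite coordinates", code))
  if (!is.null(image_shape)) {
    h <- image_shape[1]; w <- image_shape[2]
    oob <- codes[is.finite(ls$points[, 1]) & is.finite(ls$points[, 2]) &
                   (ls$points[, 1] < 0 | ls$points[, 1] > w - 1 |
                    ls$points[, 2] < 0 | ls$points[, 2] > h - 1)]
    for (code in oob)
      v <- c(v, sprintf("code '%s' lies outside the %dx%d image bounds", code, h, w))
  }
  if (!is.null(ls$confidence)) {
    bad <- names(ls$confidence)[ls$confidence < 0 | ls$confidence > 1]
    for (code in bad) v <- c(v, sprintf("code '%s' has confidence outside [0,1]", code))
  }
  v
}

#' Calibration information for one view
#'
#' @param view View tag.
#' @param mm_per_px Positive finite millimetres-per-pixel scale.
#' @param source `"ruler_ticks"` or `"metadata"`.
#' @return An object of class `calibration_info`.
#' @export
calibration_info <- function(view, mm_per_px, source = c("ruler_ticks", "metadata")) {
  view <- match.arg(view, .nf_views)
  source <- match.arg(source)
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1 ||
      !is.finite(mm_per_px) || mm_per_px <= 0)
    stop_nf("nf_parameter_error", "mm_per_px must be a positive finite scalar")
  structure(list(view = view, mm_per_px = mm_per_px, source = source),
            class = "calibration_info")
}

#' @export
print.calibration_info <- function(x, ...) {
  cat(sprintf("<calibration_info> %s view: %.6g mm/px (%s)\n",
              x$view, x$mm_per_px, x$source))
  invisible(x)
}
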