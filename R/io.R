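# File formats: landmark JSON (canonical, round-trip safe), PNG / plain-text
# PGM images, measurement CSV.

#' Write a landmark set as canonical JSON
#'
#' Schema: `{subject_id, view, points: {code: [x, y]}, confidence?: {code:
#' value}}`. Output is canonical — points in catalog order, coordinates at
#' fixed precision — so identical sets produce byte-identical files.
#'
#' @param ls A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmark_file <- function(ls, path) {
  stopifnot(inherits(ls, "landmark_set"))
  order_codes <- intersect(view_codes(ls$view), rownames(ls$points))
  pts <- lapply(order_codes, function(code)
    as.numeric(round(ls$points[code, ], 4)))
  names(pts) <- order_codes
  obj <- list(subject_id = ls$subject_id, view = ls$view, points = pts)
  if (!is.null(ls$confidence))
    obj$confidence <- as.list(round(ls$confidence[order_codes], 6))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a landmark set from JSON
#'
#' @param path Path to a landmark JSON file.
#' @return A [landmark_set()].
#' @export
read_landmark_file <- function(path) {
  if (!file.exists(path)) stop_nf("nf_io_error", "no such file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop_nf("nf_parse_error",
                    "invalid JSON in ", path, ": ", conditionMessage(e)))
  for (field in c("subject_id", "view", "points"))
    if (is.null(obj[[field]]))
      stop_nf("nf_parse_error", "missing field '$.", field, "' in ", path)
  if (!obj$view %in% .nf_views)
    stop_nf("nf_parse_error", "invalid view '", obj$view, "' at $.view in ", path)
  ok <- view_codes(obj$view)
  bad <- setdiff(names(obj$points), ok)
  if (length(bad))
    stop_nf("nf_parse_error", "unknown landmark code '", bad[1],
            "' at $.points in ", path)
  for (code in names(obj$points))
    if (length(obj$points[[code]]) != 2 || !all(is.finite(obj$points[[code]])))
      stop_nf("nf_parse_error", "point '$.points.", code,
              "' must be two finite numbers in ", path)
  conf <- if (!is.null(obj$confidence)) unlist(obj$confidence) else NULL
  landmark_set(obj$subject_id, obj$view, obj$points, confidence = conf)
}

#' Write an image array as PNG
#'
#' @param img `h x w` or `h x w x c` array with values in `[0, 1]`.
#' @param path Output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img, target = path)
  invisible(path)
}

#' Read a PNG image as an array
#'
#' @param path PNG path.
#' @return `h x w (x c)` array in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop_nf("nf_io_error", "no such file: ", path)
  png::readPNG(path)
}

#' Write a grayscale image as plain-text PGM (P2)
#'
#' Multichannel input is converted to grayscale by channel averaging.
#' PGM is used for text-only fixtures.
#'
#' @param img Image array in `[0, 1]`.
#' @param path Output path.
#' @param maxval Quantization maximum (default 255).
#' @export
write_image_pgm <- function(img, path, maxval = 255L) {
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(maxval)), con)
  write(t(q), file = con, ncolumns = min(ncol(q), 24))
  invisible(path)
}

#' Read a plain-text PGM (P2) image
#'
#' @param path PGM path.
#' @return `h x w` matrix in `[0, 1]`.
#' @export
read_image_pgm <- function(path) {
  if (!file.exists(path)) stop_nf("nf_io_error", "no such file: ", path)
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop_nf("nf_parse_error", "not an ASCII PGM (P2): ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a measurement table as CSV
#'
#' Long format, one row per subject-measurement, with units carried per row.
#'
#' @param mt A `measurement_table`.
#' @param path Output path.
#' @export
write_measurement_csv <- function(mt, path) {
  write.csv(mt, path, row.names = FALSE)
  invisible(path)
}
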