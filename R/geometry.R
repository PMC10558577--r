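#' Radiographic implant diameter from the platform key points
#'
#' The segment AB spans the implant body at the platform (excluding thread
#' depth), so its Euclidean length is the radiographic diameter in pixels:
#' `D = sqrt((x2 - x1)^2 + (y2 - y1)^2)`.
#'
#' @param a,b Numeric (x, y) pixel coordinates of the two platform points.
#' @return Diameter in pixels (strictly positive).
#' @examples
#' radiographic_diameter(c(0, 0), c(3, 4))  # 5
#' @export
radiographic_diameter <- function(a, b) {
  d <- sqrt(sum((as.numeric(b) - as.numeric(a))^2))
  if (d == 0) {
    isz_error("points A and B coincide: degenerate diameter segment",
              "implant_geometry_error")
  }
  d
}

#' Area of the key-point triangle ABC
#'
#' Absolute shoelace area
#' `S = |x1*y2 + x2*y3 + x3*y1 - x2*y1 - x3*y2 - x1*y3| / 2`,
#' invariant under vertex permutation and rigid motions. Degenerate
#' (collinear) triples give 0; collinearity is rejected upstream when
#' records are constructed.
#'
#' @param a,b,c Numeric (x, y) pixel coordinates.
#' @return Triangle area in square pixels (non-negative).
#' @examples
#' triangle_area(c(0, 0), c(4, 0), c(2, 6))  # 12
#' @export
triangle_area <- function(a, b, c) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  abs(a[1] * b[2] + b[1] * c[2] + c[1] * a[2] -
      b[1] * a[2] - c[1] * b[2] - a[1] * c[2]) / 2
}

#' Radiographic implant length from the three key points
#'
#' With S the triangle area and D the diameter, `L = 2 * S / D`: the
#' perpendicular distance from the apex C to the platform line AB. The apex
#' may project outside the segment AB; only the distance to the line
#' matters.
#'
#' @param a,b Platform key points (pixels).
#' @param c Apex key point (pixels).
#' @return Length in pixels (non-negative).
#' @examples
#' radiographic_length(c(0, 0), c(4, 0), c(2, 6))  # 6
#' @export
radiographic_length <- function(a, b, c) {
  2 * triangle_area(a, b, c) / radiographic_diameter(a, b)
}

#' Extract the millimetre feature vector from an annotation record
#'
#' Applies the three key-point geometry operations and converts pixels to
#' millimetres by the record's imager pixel spacing. The (D_mm, L_mm) pair
#' is the feature vector used by the clustering classifier. All nine
#' catalogue sizes have length > diameter, so a record whose computed
#' radiographic length does not exceed its diameter triggers a validation
#' warning (annotation order or landmark placement is then suspect).
#'
#' @param record An `implant_annotation` with `pixel_spacing_mm` set.
#' @return An object of class `radiographic_measurement`: a list with
#'   `image_id`, `D_px`, `S_px2`, `L_px`, `D_mm`, `L_mm`, `true_code`.
#' @examples
#' rec <- annotation_record("ex", c(0, 0), c(100, 0), c(50, 250),
#'                          pixel_spacing_mm = 0.04)
#' extract_feature(rec)  # D_mm = 4, L_mm = 10
#' @export
extract_feature <- function(record) {
  stopifnot(inherits(record, "implant_annotation"))
  if (is.na(record$pixel_spacing_mm)) {
    isz_error(sprintf("record '%s' has no pixel spacing set", record$image_id),
              "implant_config_error")
  }
  d_px <- radiographic_diameter(record$a, record$b)
  s_px2 <- triangle_area(record$a, record$b, record$c)
  l_px <- 2 * s_px2 / d_px
  if (l_px <= d_px) {
    isz_warning(sprintf(
      "record '%s': radiographic length (%.2f px) <= diameter (%.2f px); all catalogue sizes have length > diameter",
      record$image_id, l_px, d_px), "implant_dimension_warning")
  }
  structure(
    list(image_id = record$image_id,
         D_px = d_px, S_px2 = s_px2, L_px = l_px,
         D_mm = d_px * record$pixel_spacing_mm,
         L_mm = l_px * record$pixel_spacing_mm,
         true_code = record$true_code),
    class = "radiographic_measurement"
  )
}

#' @export
print.radiographic_measurement <- function(x, ...) {
  cat(sprintf(
    "<radiographic_measurement> %s: D = %.3f mm, L = %.3f mm (%.1f px, %.1f px), true code %s\n",
    x$image_id, x$D_mm, x$L_mm, x$D_px, x$L_px, x$true_code))
  invisible(x)
}

#' Extract features for every record of a manifest
#'
#' Reads each annotation and its pixel-spacing source, runs
#' [extract_feature()], and stacks the results into the features table used
#' for training and prediction. Records whose key points are collinear are
#' skipped with a warning (count available as attribute `n_skipped`).
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param base_dir Directory against which relative `annotation_path` /
#'   `spacing_source` entries are resolved.
#' @return Data frame with columns `image_id`, `D_mm`, `L_mm`, `true_code`
#'   (plus `split` when present in the manifest); attribute `n_skipped`.
#' @export
extract_features <- function(manifest, base_dir = ".") {
  validate_manifest(manifest)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  spacing_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(manifest))
  skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    src <- resolve(manifest$spacing_source[i])
    sp <- if (!is.null(spacing_cache[[src]])) spacing_cache[[src]] else {
      spacing_cache[[src]] <- read_pixel_spacing(src)
    }
    rec <- tryCatch(
      read_labelme(resolve(manifest$annotation_path[i]),
                   image_id = manifest$image_id[i]),
      implant_geometry_error = function(e) {
        isz_warning(sprintf("skipping '%s': %s", manifest$image_id[i],
                            conditionMessage(e)), "implant_skip_warning")
        NULL
      })
    if (is.null(rec)) {
      skipped <- skipped + 1L
      next
    }
    rec$pixel_spacing_mm <- sp
    if (!is.na(manifest$true_code[i]) && nzchar(manifest$true_code[i])) {
      rec$true_code <- manifest$true_code[i]
    }
    m <- extract_feature(rec)
    rows[[i]] <- data.frame(image_id = m$image_id, D_mm = m$D_mm, L_mm = m$L_mm,
                            true_code = m$true_code, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(image_id = character(), D_mm = numeric(),
                      L_mm = numeric(), true_code = character(),
                      stringsAsFactors = FALSE)
  }
  if ("split" %in% names(manifest)) {
    out$split <- manifest$split[match(out$image_id, manifest$image_id)]
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}
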