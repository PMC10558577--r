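#' Build an annotation record for one implant image
#'
#' An annotation record holds the three key points labelled on a cropped
#' bone level implant radiograph: `a` and `b` span the implant-body diameter
#' at the platform, `c` marks the implant apex. Coordinates are continuous
#' pixel positions (x right, y down, origin top-left).
#'
#' @param image_id Opaque image identifier.
#' @param a,b,c Numeric length-2 vectors, pixel coordinates of the key points.
#' @param pixel_spacing_mm Physical distance between adjacent pixel centres in
#'   mm, or `NA` if not yet known.
#' @param true_code Optional four-digit ground-truth size code.
#' @return An object of class `implant_annotation`.
#' @export
annotation_record <- function(image_id, a, b, c, pixel_spacing_mm = NA_real_,
                              true_code = NA_character_) {
  pt <- function(p, nm) {
    if (!is.numeric(p) || length(p) != 2L || anyNA(p)) {
      isz_error(sprintf("key point `%s` must be a numeric (x, y) pair", nm),
                "implant_format_error")
    }
    as.numeric(p)
  }
  a <- pt(a, "a"); b <- pt(b, "b"); c <- pt(c, "c")
  if (!is.na(pixel_spacing_mm) && pixel_spacing_mm <= 0) {
    isz_error("pixel_spacing_mm must be positive", "implant_value_error")
  }
  if (triangle_area(a, b, c) < 1e-9) {
    isz_error(sprintf("key points of '%s' are collinear (triangle area ~ 0)",
                      image_id), "implant_geometry_error")
  }
  if (!is.na(true_code)) parse_size_code(true_code)
  structure(
    list(image_id = as.character(image_id), a = a, b = b, c = c,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         true_code = as.character(true_code)),
    class = "implant_annotation"
  )
}

#' @export
print.implant_annotation <- function(x, ...) {
  cat(sprintf("<implant_annotation> %s\n", x$image_id))
  cat(sprintf("  A = (%.2f, %.2f)  B = (%.2f, %.2f)  C = (%.2f, %.2f) [px]\n",
              x$a[1], x$a[2], x$b[1], x$b[2], x$c[1], x$c[2]))
  cat(sprintf("  pixel spacing: %s mm/px   true code: %s\n",
              format(x$pixel_spacing_mm), x$true_code))
  invisible(x)
}

#' Read a LabelMe polygon annotation
#'
#' Reads a LabelMe-style JSON annotation file containing exactly one polygon
#' shape with exactly three vertices. Vertices are taken in file order as
#' (A, B, C): A and B delimit the platform diameter, C the apex. Pixel
#' spacing is left unset; fill it from [read_pixel_spacing()].
#'
#' @param path Path to the annotation JSON file.
#' @param image_id Identifier for the record; defaults to the file's
#'   `imagePath` field, falling back to the file name.
#' @return An `implant_annotation` record (spacing `NA`). The polygon's
#'   `label` field is kept as `true_code` when it is one of the nine size
#'   codes.
#' @export
read_labelme <- function(path, image_id = NULL) {
  if (!file.exists(path)) {
    isz_error(sprintf("annotation file not found: %s", path),
              "implant_format_error")
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    isz_error(sprintf("'%s' is not valid annotation JSON: %s",
                                      path, conditionMessage(e)),
                              "implant_format_error")
                  })
  shapes <- doc$shapes
  polys <- Filter(function(s) identical(s$shape_type, "polygon"),
                  if (is.null(shapes)) list() else shapes)
  if (length(polys) != 1L) {
    isz_error(sprintf("'%s' must contain exactly one polygon shape (found %d)",
                      path, length(polys)), "implant_format_error")
  }
  pts <- polys[[1]]$points
  if (length(pts) != 3L) {
    isz_error(sprintf("polygon in '%s' has %d vertices; expected 3 (A, B, C)",
                      path, length(pts)), "implant_cardinality_error")
  }
  pts <- lapply(pts, function(p) as.numeric(unlist(p)))
  label <- polys[[1]]$label
  true_code <- if (!is.null(label) && label %in% size_codes()) label else NA_character_
  id <- image_id %||% doc$imagePath %||% basename(path)
  annotation_record(id, pts[[1]], pts[[2]], pts[[3]], true_code = true_code)
}

#' Write an annotation record as a LabelMe polygon file
#'
#' Inverse of [read_labelme()]: coordinates round-trip exactly.
#'
#' @param record An `implant_annotation`.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(record, path) {
  stopifnot(inherits(record, "implant_annotation"))
  doc <- list(
    version = "5.0.1",
    flags = structure(list(), names = character()),
    shapes = list(list(
      label = if (is.na(record$true_code)) "implant" else record$true_code,
      points = list(record$a, record$b, record$c),
      group_id = NULL,
      shape_type = "polygon",
      flags = structure(list(), names = character())
    )),
    imagePath = record$image_id,
    imageData = NULL
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}
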