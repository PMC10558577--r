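#' Collapse a (row, column) pixel spacing pair to one scalar
#'
#' The geometry module treats pixel spacing as a single scalar because
#' intraoral sensors have square pixels. A small row/column discrepancy
#' (relative difference at most `tol`) is averaged away; a larger one is an
#' anisotropy error rather than a silent mean.
#'
#' @param row_mm,col_mm Row and column spacing in mm/pixel.
#' @param tol Maximum tolerated relative difference (default 0.5%).
#' @return A single positive spacing in mm/pixel.
#' @examples
#' spacing_from_pair(0.04, 0.04)
#' spacing_from_pair(0.0400, 0.0401)
#' @export
spacing_from_pair <- function(row_mm, col_mm, tol = 0.005) {
  if (!is.finite(row_mm) || !is.finite(col_mm) || row_mm <= 0 || col_mm <= 0) {
    isz_error("pixel spacing values must be positive finite numbers",
              "implant_value_error")
  }
  m <- (row_mm + col_mm) / 2
  if (abs(row_mm - col_mm) / m > tol) {
    isz_error(sprintf(
      "anisotropic pixel spacing (%.6g, %.6g): relative difference %.3g%% exceeds %.3g%%",
      row_mm, col_mm, 100 * abs(row_mm - col_mm) / m, 100 * tol),
      "implant_anisotropy_error")
  }
  m
}

#' Read the imager pixel spacing for one image
#'
#' Accepts either a DICOM file carrying the Imager Pixel Spacing attribute
#' (tag 0018,1164: row and column spacing at the detector front plane, in
#' mm) or a flat key-value sidecar text file with a `pixel_spacing_mm` key.
#' A (row, column) pair is collapsed via [spacing_from_pair()].
#'
#' @param path Path to a DICOM file or a sidecar metadata file.
#' @param tol Anisotropy tolerance passed to [spacing_from_pair()].
#' @return A single positive spacing in mm/pixel.
#' @export
read_pixel_spacing <- function(path, tol = 0.005) {
  if (!file.exists(path)) {
    isz_error(sprintf("spacing source not found: %s", path),
              "implant_format_error")
  }
  if (is_dicom_file(path)) {
    pair <- dicom_imager_pixel_spacing(path)
    if (length(pair) == 1L) pair <- c(pair, pair)
    return(spacing_from_pair(pair[1], pair[2], tol = tol))
  }
  read_spacing_sidecar(path, tol = tol)
}

# Sidecar: flat "key = value" / "key: value" / "key<TAB>value" lines.
read_spacing_sidecar <- function(path, tol = 0.005) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[=:\t]\\s*(.+)$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, "")
  hit <- which(keys == "pixel_spacing_mm")
  if (length(hit) != 1L) {
    isz_error(sprintf("sidecar '%s' must contain exactly one pixel_spacing_mm entry",
                      path), "implant_format_error")
  }
  nums <- suppressWarnings(as.numeric(strsplit(vals[hit], "[,\\\\ ]+")[[1]]))
  nums <- nums[!is.na(nums)]
  if (length(nums) == 1L) {
    if (!is.finite(nums) || nums <= 0) {
      isz_error("pixel_spacing_mm must be positive", "implant_value_error")
    }
    nums
  } else if (length(nums) == 2L) {
    spacing_from_pair(nums[1], nums[2], tol = tol)
  } else {
    isz_error(sprintf("cannot parse pixel_spacing_mm value in '%s'", path),
              "implant_format_error")
  }
}

#' Write a pixel-spacing sidecar file
#'
#' @param spacing_mm Positive scalar spacing in mm/pixel.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_spacing_sidecar <- function(spacing_mm, path) {
  if (!is.finite(spacing_mm) || spacing_mm <= 0) {
    isz_error("pixel_spacing_mm must be positive", "implant_value_error")
  }
  writeLines(sprintf("pixel_spacing_mm = %.17g", spacing_mm), path)
  invisible(path)
}

# ---- Minimal DICOM tag extraction ------------------------------------------
# The package only needs one metadata element, Imager Pixel Spacing
# (0018,1164). This is a deliberately small little-endian tag scanner for
# part-10 files (explicit or implicit VR); it never touches pixel data and
# bails out on constructs it does not need (big endian, undefined-length
# sequences before the target tag).

is_dicom_file <- function(path) {
  if (file.size(path) < 132) return(FALSE)
  hdr <- readBin(path, "raw", n = 132)
  identical(rawToChar(hdr[129:132]), "DICM")
}

dicom_imager_pixel_spacing <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  u16 <- function(i) sum(as.integer(raw[i:(i + 1)]) * c(1L, 256L))
  u32 <- function(i) sum(as.numeric(raw[i:(i + 3)]) * c(1, 256, 65536, 16777216))
  pos <- 133  # first byte after the 128-byte preamble + "DICM"
  explicit <- TRUE          # file meta group is always explicit little endian
  meta_end <- Inf
  transfer_syntax <- "1.2.840.10008.1.2.1"
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  n <- length(raw)
  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2)
    in_meta <- group == 2L
    if (!in_meta && pos >= meta_end && transfer_syntax == "1.2.840.10008.1.2") {
      explicit <- FALSE
    }
    if (in_meta || explicit) {
      vr <- rawToChar(raw[(pos + 4):(pos + 5)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8); data_at <- pos + 12
      } else {
        len <- u16(pos + 6); data_at <- pos + 8
      }
    } else {
      vr <- ""
      len <- u32(pos + 4); data_at <- pos + 8
    }
    if (len == 4294967295) {
      isz_error(sprintf(
        "unsupported undefined-length element (%04x,%04x) before Imager Pixel Spacing in '%s'",
        group, elem, path), "implant_format_error")
    }
    if (group == 2L && elem == 0L) {
      meta_end <- data_at + len + u32(data_at)  # (0002,0000) File Meta group length
    }
    if (group == 2L && elem == 16L) {  # (0002,0010) Transfer Syntax UID
      ts_bytes <- raw[data_at:(data_at + len - 1)]
      transfer_syntax <- trimws(rawToChar(ts_bytes[ts_bytes != as.raw(0)]))
      if (!transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
        isz_error(sprintf("unsupported DICOM transfer syntax '%s' in '%s'",
                          transfer_syntax, path), "implant_format_error")
      }
    }
    if (group == 24L && elem == 4452L) {  # (0018,1164) Imager Pixel Spacing, VR DS
      txt <- rawToChar(raw[data_at:(data_at + len - 1)])
      vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\\\")[[1]]))
      vals <- vals[!is.na(vals)]
      if (!length(vals)) {
        isz_error(sprintf("unparseable Imager Pixel Spacing value in '%s'", path),
                  "implant_format_error")
      }
      return(vals)
    }
    if (group > 24L || (group == 24L && elem > 4452L && !in_meta)) {
      break  # tags are stored in ascending order; target cannot follow
    }
    pos <- data_at + len
  }
  isz_error(sprintf("no Imager Pixel Spacing (0018,1164) attribute in '%s'", path),
            "implant_format_error")
}
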