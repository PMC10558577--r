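# Independent brute-force oracles used to validate the optimisation code.

# All permutations of v, one per row.
all_perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# Cache the 9! permutation matrix: built once per test run.
perms9_cache <- new.env(parent = emptyenv())
perms9 <- function() {
  if (is.null(perms9_cache$p)) perms9_cache$p <- all_perms(1:9)
  perms9_cache$p
}

# Assignment value of every permutation row of P against square matrix M.
perm_values <- function(M, P) {
  n <- ncol(P)
  lin <- sweep((P - 1L) * n, 2, seq_len(n), "+")
  rowSums(matrix(M[as.vector(lin)], nrow(P), n))
}

# Globally optimal k-means inertia by exhaustive assignment enumeration.
# Objective: sum of squared distances to assigned-cluster means.
kmeans_global_optimum <- function(x, k) {
  n <- nrow(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  obj <- rep(sum(x^2), nrow(grid))
  for (cc in seq_len(k)) {
    ind <- grid == cc
    m <- rowSums(ind)
    sx <- as.numeric(ind %*% x[, 1])
    sy <- as.numeric(ind %*% x[, 2])
    obj <- obj - ifelse(m > 0, (sx^2 + sy^2) / m, 0)
  }
  min(obj)
}

# Minimal part-10 DICOM writer (little endian) carrying Imager Pixel
# Spacing; synthetic fixture, built at test time.
write_test_dicom <- function(path, spacing = c(0.04, 0.04), implicit = FALSE,
                             omit_spacing = FALSE) {
  u16r <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32r <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  pad <- function(v, p = as.raw(0)) if (length(v) %% 2) c(v, p) else v
  el_ex <- function(group, elem, vr, value, padding = as.raw(0x20)) {
    value <- pad(value, padding)
    c(u16r(group), u16r(elem), charToRaw(vr), u16r(length(value)), value)
  }
  el_im <- function(group, elem, value, padding = as.raw(0x20)) {
    value <- pad(value, padding)
    c(u16r(group), u16r(elem), u32r(length(value)), value)
  }
  ts <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  meta_body <- el_ex(0x0002, 0x0010, "UI", charToRaw(ts), as.raw(0))
  meta <- c(el_ex(0x0002, 0x0000, "UL", u32r(length(meta_body))), meta_body)
  el <- if (implicit) function(g, e, vr, v) el_im(g, e, v) else el_ex
  ds <- c(
    el(0x0008, 0x0060, "CS", charToRaw("IO")),
    if (!omit_spacing)
      el(0x0018, 0x1164, "DS",
         charToRaw(paste(sprintf("%g", spacing), collapse = "\\"))),
    el(0x0028, 0x0010, "US", u16r(512))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

# Small labelled two-column feature frame builder for classifier tests.
make_features <- function(D, L, code = NULL) {
  data.frame(image_id = sprintf("f%03d", seq_along(D)), D_mm = D, L_mm = L,
             true_code = if (is.null(code)) NA_character_ else code,
             stringsAsFactors = FALSE)
}

# Split a generated feature table the way the study does (train = everything
# not in test; 20 per class in validation and test).
study_split <- function(features, seed, n_val = 20, n_test = 20) {
  man <- data.frame(image_id = features$image_id, annotation_path = "x",
                    spacing_source = "y", true_code = features$true_code,
                    split = "unassigned", stringsAsFactors = FALSE)
  man <- stratified_split(man, n_val, n_test, seed = seed)
  features$split <- man$split
  features
}

# Classify an error pair: same catalogue diameter and adjacent length step?
is_same_diam_adjacent_length <- function(true_code, pred_code) {
  tc <- parse_size_code(true_code)
  pc <- parse_size_code(pred_code)
  tc$diameter_mm == pc$diameter_mm & abs(tc$length_mm - pc$length_mm) == 2
}
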