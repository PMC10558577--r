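#' Scatter-plot table of feature vectors and cluster centroids
#'
#' Flattens a fitted model and a feature set into one long table for the
#' standard feature-plane figure: one row per feature vector (role
#' `"point"`) and one per centroid (role `"centroid"`), with coordinates in
#' the original millimetre plane (centroid D components are divided by the
#' model weight to undo the transform).
#'
#' @param features Features data frame.
#' @param model A fitted `size_km` model.
#' @return Data frame with columns `role`, `image_id`, `D_mm`, `L_mm`,
#'   `cluster`, `code`, `true_code`.
#' @export
scatter_data <- function(features, model) {
  stopifnot(inherits(model, "size_km"))
  cl <- assign_clusters(model, features)
  code <- if (is.null(model$label_map)) rep(NA_character_, model$k) else model$label_map
  pts <- data.frame(
    role = "point",
    image_id = features$image_id %||% sprintf("p%04d", seq_len(nrow(features))),
    D_mm = features$D_mm, L_mm = features$L_mm,
    cluster = cl, code = code[cl],
    true_code = features$true_code %||% NA_character_,
    stringsAsFactors = FALSE
  )
  cents <- data.frame(
    role = "centroid",
    image_id = sprintf("centroid_%d", seq_len(model$k)),
    D_mm = model$centroids[, 1] / model$w, L_mm = model$centroids[, 2],
    cluster = seq_len(model$k), code = code,
    true_code = NA_character_,
    stringsAsFactors = FALSE
  )
  rbind(pts, cents)
}

#' Feature-plane scatter plot with centroids
#'
#' Radiographic diameter on the x-axis, length on the y-axis, points
#' coloured by assigned cluster, cluster centroids overlaid as yellow
#' circles. Every centroid is drawn even if its cluster is empty.
#'
#' @param features Features data frame.
#' @param model A fitted `size_km` model.
#' @return A ggplot object.
#' @export
scatter_plot <- function(features, model) {
  df <- scatter_data(features, model)
  pts <- df[df$role == "point", ]
  cents <- df[df$role == "centroid", ]
  grp <- if (all(is.na(pts$code))) factor(pts$cluster) else factor(pts$code)
  ggplot2::ggplot(pts, ggplot2::aes(x = D_mm, y = L_mm)) +
    ggplot2::geom_point(ggplot2::aes(colour = grp), size = 1.4, alpha = 0.8) +
    ggplot2::geom_point(data = cents, colour = "gold2", fill = "yellow",
                        shape = 21, size = 4, stroke = 1) +
    ggplot2::labs(x = "Radiographic diameter (mm)",
                  y = "Radiographic length (mm)",
                  colour = "Cluster") +
    ggplot2::theme_minimal()
}

#' Export the scatter table and figure
#'
#' @param features Features data frame.
#' @param model A fitted `size_km` model.
#' @param csv_path Destination CSV for the plot table ([scatter_data()]).
#' @param image_path Optional figure path (format by extension, via
#'   [ggplot2::ggsave()]).
#' @param meta Optional comment lines for the CSV header.
#' @return The scatter table, invisibly.
#' @export
scatter_export <- function(features, model, csv_path, image_path = NULL,
                           meta = NULL) {
  df <- scatter_data(features, model)
  write_table_csv(df, csv_path, meta = meta)
  if (!is.null(image_path)) {
    p <- scatter_plot(features, model)
    ggplot2::ggsave(image_path, p, width = 7, height = 6, dpi = 150)
  }
  invisible(df)
}

# Shared deterministic CSV writer (comment header + unquoted rows).
write_table_csv <- function(df, path, meta = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  })
  df[is.na(df)] <- ""
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
  invisible(path)
}

read_table_csv <- function(path, numeric_cols = character()) {
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        stringsAsFactors = FALSE)
  for (col in intersect(numeric_cols, names(df))) df[[col]] <- as.numeric(df[[col]])
  df
}
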