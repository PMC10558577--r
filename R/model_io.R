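#' Serialize a fitted size model to JSON
#'
#' Stores k, w, centroids (transformed plane), the cluster-to-size-code
#' map, inertia and the fitting seed; enough to reload and predict.
#'
#' @param model A `size_km` model.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "size_km"))
  doc <- list(
    format = "implantsize-model",
    version = as.character(utils::packageVersion("implantsize")),
    k = model$k, w = model$w,
    centroids = unname(apply(model$centroids, 1, as.numeric, simplify = FALSE)),
    label_map = if (is.null(model$label_map)) NULL else as.list(model$label_map),
    inertia = model$inertia,
    seed = model$seed, n_init = model$n_init,
    max_iter = model$max_iter, tol = model$tol
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a size model written by [write_model()]
#'
#' @param path Model JSON path.
#' @return A `size_km` model.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    isz_error(sprintf("model file not found: %s", path), "implant_format_error")
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "implantsize-model")) {
    isz_error(sprintf("'%s' is not an implantsize model file", path),
              "implant_format_error")
  }
  centroids <- matrix(as.numeric(doc$centroids), nrow = doc$k,
                      dimnames = list(NULL, c("wD", "L")))
  structure(
    list(k = as.integer(doc$k), w = doc$w, centroids = centroids,
         inertia = doc$inertia, cluster = NULL, n_init = doc$n_init,
         seed = doc$seed, max_iter = doc$max_iter, tol = doc$tol,
         label_map = if (is.null(doc$label_map)) NULL else unlist(doc$label_map)),
    class = "size_km"
  )
}
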