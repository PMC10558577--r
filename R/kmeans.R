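#' Diameter-weighting transform of the feature plane
#'
#' The classifier clusters feature vectors (D, L) after the anisotropic
#' linear map `f(D, L) = (w * D, L)`, `w > 0`: the diameter axis is
#' stretched by `w` while the length axis is untouched. Diameter gaps
#' between catalogue sizes (0.7-0.8 mm) are much smaller than length gaps
#' (2 mm), so up-weighting the diameter lets Euclidean k-means separate
#' diameter groups instead of splitting along length. `w = 1` is the
#' identity.
#'
#' @param features Data frame with columns `D_mm`, `L_mm`, or a 2-column
#'   numeric matrix (D, L).
#' @param w Positive diameter weight.
#' @return An n x 2 numeric matrix of transformed points (columns `wD`, `L`).
#' @examples
#' transform_features(data.frame(D_mm = 3.3, L_mm = 8), w = 2)  # (6.6, 8)
#' @export
transform_features <- function(features, w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w <= 0) {
    isz_error("weight w must be a single positive number", "implant_domain_error")
  }
  x <- feature_matrix(features)
  cbind(wD = w * x[, 1], L = x[, 2])
}

# Accept a features data frame (D_mm, L_mm) or bare 2-column matrix.
feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    if (!all(c("D_mm", "L_mm") %in% names(features))) {
      isz_error("features must have columns D_mm and L_mm", "implant_format_error")
    }
    x <- cbind(features$D_mm, features$L_mm)
  } else {
    x <- as.matrix(features)
    if (ncol(x) != 2L) {
      isz_error("feature matrix must have two columns (D, L)",
                "implant_format_error")
    }
  }
  storage.mode(x) <- "double"
  if (anyNA(x)) isz_error("features contain NA", "implant_value_error")
  x
}

# Squared Euclidean distances between every point and every centre.
dist2 <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
}

#' k-means++ centroid seeding
#'
#' Picks `k` well-spread initial centroids: the first uniformly at random,
#' each subsequent one sampled among the data points with probability
#' proportional to its squared distance to the nearest centroid chosen so
#' far. Uses the current RNG state; seed it (e.g. via [fit_size_model()])
#' for reproducibility.
#'
#' @param x n x 2 numeric matrix of (transformed) points.
#' @param k Number of centroids.
#' @return k x 2 matrix of initial centroids (rows of `x`).
#' @export
kmeanspp_seed <- function(x, k) {
  x <- as.matrix(x)
  k <- stopifnot_scalar_count(k, "k")
  if (nrow(unique(x)) < k) {
    isz_error(sprintf("need at least k = %d distinct points, have %d",
                      k, nrow(unique(x))), "implant_insufficiency_error")
  }
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2min <- rowSums(sweep(x, 2, centers[1, ])^2)
    for (j in 2:k) {
      centers[j, ] <- x[sample.int(n, 1L, prob = d2min), ]
      d2min <- pmin(d2min, rowSums(sweep(x, 2, centers[j, ])^2))
    }
  }
  dimnames(centers) <- list(NULL, colnames(x))
  centers
}

#' Lloyd iterations from given initial centroids
#'
#' Alternates nearest-centroid assignment (Euclidean, ties to the lowest
#' index) and centroid re-estimation as the mean of assigned points, until
#' the relative inertia change drops below `tol` or `max_iter` is reached.
#' A cluster left empty is re-seeded to the point currently farthest from
#' its assigned centroid. Inertia (total within-cluster sum of squares) is
#' non-increasing across iterations.
#'
#' @param x n x d numeric matrix of points.
#' @param centers Initial centroid matrix (k x d).
#' @param max_iter Maximum iterations.
#' @param tol Relative inertia change convergence threshold.
#' @return List with `centers`, `cluster` (assignment), `inertia`,
#'   `inertia_trace`, `iterations`, `converged`.
#' @export
lloyd_fit <- function(x, centers, max_iter = 300, tol = 1e-6) {
  x <- as.matrix(x)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  trace <- numeric(0)
  prev <- Inf
  cl <- integer(nrow(x))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d2m <- dist2(x, centers)
    cl <- max.col(-d2m, ties.method = "first")
    # repair empty clusters before re-estimating means
    repeat {
      empty <- setdiff(seq_len(k), unique(cl))
      if (!length(empty)) break
      j <- empty[1]
      worst <- which.max(d2m[cbind(seq_len(nrow(x)), cl)])
      centers[j, ] <- x[worst, ]
      d2m[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
      cl[worst] <- j
    }
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[cl == j, , drop = FALSE])
    }
    inertia <- sum((x - centers[cl, , drop = FALSE])^2)
    trace <- c(trace, inertia)
    if (is.finite(prev) && (prev - inertia) <= tol * max(prev, .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
    prev <- inertia
  }
  list(centers = centers, cluster = cl, inertia = trace[length(trace)],
       inertia_trace = trace, iterations = iter, converged = converged)
}

#' Fit the weighted k-means size classifier
#'
#' Transforms the training features with weight `w`, then runs k-means++
#' seeding followed by Lloyd iterations `n_init` times under independent
#' sub-seeds derived from `seed`, keeping the run with the lowest inertia.
#' The returned model has no cluster-to-size mapping yet; attach one with
#' [map_clusters_to_labels()] before predicting.
#'
#' @param features Training features (data frame with `D_mm`, `L_mm`).
#' @param k Number of clusters (default 9, one per catalogue size).
#' @param w Positive diameter weight.
#' @param n_init Number of independent restarts.
#' @param seed RNG seed; the fit is bit-reproducible given the seed.
#' @param max_iter,tol Lloyd iteration controls.
#' @return An object of class `size_km`.
#' @export
fit_size_model <- function(features, k = 9, w = 1, n_init = 10, seed = 1,
                           max_iter = 300, tol = 1e-6) {
  k <- stopifnot_scalar_count(k, "k")
  n_init <- max(1L, stopifnot_scalar_count(n_init, "n_init"))
  x <- transform_features(features, w)
  if (nrow(unique(x)) < k) {
    isz_error(sprintf("training set has %d distinct transformed points; k = %d needed",
                      nrow(unique(x)), k), "implant_insufficiency_error")
  }
  best <- NULL
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_init)
    for (s in sub_seeds) {
      run <- with_seed(s, lloyd_fit(x, kmeanspp_seed(x, k),
                                    max_iter = max_iter, tol = tol))
      if (is.null(best) || run$inertia < best$inertia) best <- run
    }
  })
  structure(
    list(k = k, w = w, centroids = best$centers, inertia = best$inertia,
         cluster = best$cluster, n_init = n_init, seed = seed,
         max_iter = max_iter, tol = tol, label_map = NULL),
    class = "size_km"
  )
}

#' @export
print.size_km <- function(x, ...) {
  cat(sprintf("<size_km> k = %d, w = %g, inertia = %.4f, %s\n",
              x$k, x$w, x$inertia,
              if (is.null(x$label_map)) "clusters unmapped" else "clusters mapped to size codes"))
  if (!is.null(x$label_map)) {
    cat("  cluster -> code:", paste(seq_len(x$k), x$label_map, sep = ":",
                                    collapse = "  "), "\n")
  }
  invisible(x)
}

# Nearest-centroid cluster index for features under a fitted model.
assign_clusters <- function(model, features) {
  stopifnot(inherits(model, "size_km"))
  x <- transform_features(features, model$w)
  max.col(-dist2(x, model$centroids), ties.method = "first")
}

#' Map fitted clusters bijectively onto the nine size codes
#'
#' Builds the cluster-by-true-label contingency table of the (labelled)
#' training features and chooses the bijection cluster -> size code that
#' maximises total agreement, via optimal linear assignment
#' ([solve_assignment()]). Ties are broken towards the lexicographically
#' smallest label sequence over cluster indices. One cluster per label is
#' forced: nine clusters must cover nine size groups.
#'
#' @param model A fitted `size_km`.
#' @param features Training features with a `true_code` column.
#' @return The model with `label_map` set (character vector, cluster index
#'   -> size code) and `train_contingency` attached.
#' @export
map_clusters_to_labels <- function(model, features) {
  stopifnot(inherits(model, "size_km"))
  if (!is.data.frame(features) || is.null(features$true_code) ||
      anyNA(features$true_code)) {
    isz_error("map_clusters_to_labels needs features with true_code set",
              "implant_config_error")
  }
  labels <- sort(unique(features$true_code))
  if (length(labels) > model$k) {
    isz_error(sprintf("%d distinct labels but only k = %d clusters",
                      length(labels), model$k), "implant_cardinality_error")
  }
  if (length(labels) < model$k) {
    isz_error(sprintf("k = %d clusters but only %d distinct labels (bijection required)",
                      model$k, length(labels)), "implant_cardinality_error")
  }
  cl <- assign_clusters(model, features)
  cont <- table(factor(cl, levels = seq_len(model$k)),
                factor(features$true_code, levels = labels))
  cont <- unclass(cont)  # clusters x labels count matrix
  chosen <- assign_max_lexicographic(cont)
  model$label_map <- labels[chosen]
  model$train_contingency <- cont
  model
}

#' Predict size codes for new feature vectors
#'
#' Transforms features with the model's weight and assigns each to the
#' Euclidean-nearest centroid; exact distance ties go to the lowest cluster
#' index. Requires a mapped model (see [map_clusters_to_labels()]).
#'
#' @param object A mapped `size_km` model.
#' @param newdata Features (data frame with `D_mm`, `L_mm` or 2-column
#'   matrix).
#' @param ... Unused.
#' @return Character vector of predicted four-digit size codes.
#' @export
predict.size_km <- function(object, newdata, ...) {
  if (is.null(object$label_map)) {
    isz_error("model has no cluster-to-label mapping; run map_clusters_to_labels() first",
              "implant_state_error")
  }
  object$label_map[assign_clusters(object, newdata)]
}

#' Tune the diameter weight over a grid
#'
#' For every candidate weight: fit the clustering model on the training
#' features, map clusters to size codes on the same training features, and
#' score accuracy on the selection features. Returns the weight with the
#' highest selection accuracy (ties towards the smallest weight) together
#' with the full accuracy curve and the winning fitted model. The study
#' design scans integer weights 1..10.
#'
#' @param train Labelled training features.
#' @param selection Labelled features used to score each weight (the study
#'   scores on its test set; a held-out validation set is the conservative
#'   alternative).
#' @param w_grid Positive candidate weights (default `1:10`).
#' @param k,n_init,seed,max_iter,tol Passed to [fit_size_model()]; every
#'   weight is fitted under the same `seed` so the comparison is paired.
#' @return List with `best_w`, `curve` (data frame `w`, `accuracy`) and
#'   `model` (the mapped model fitted at `best_w`).
#' @export
tune_weight <- function(train, selection, w_grid = 1:10, k = 9, n_init = 10,
                        seed = 1, max_iter = 300, tol = 1e-6) {
  if (!length(w_grid) || any(!is.finite(w_grid)) || any(w_grid <= 0)) {
    isz_error("w_grid must be a non-empty vector of positive weights",
              "implant_domain_error")
  }
  w_grid <- sort(unique(as.numeric(w_grid)))
  if (is.null(selection$true_code) || anyNA(selection$true_code)) {
    isz_error("selection features need true_code for accuracy scoring",
              "implant_config_error")
  }
  acc <- numeric(length(w_grid))
  models <- vector("list", length(w_grid))
  for (i in seq_along(w_grid)) {
    m <- fit_size_model(train, k = k, w = w_grid[i], n_init = n_init,
                        seed = seed, max_iter = max_iter, tol = tol)
    m <- map_clusters_to_labels(m, train)
    acc[i] <- mean(predict(m, selection) == selection$true_code)
    models[[i]] <- m
  }
  best <- which.max(acc)  # first maximum = smallest w after sorting
  list(best_w = w_grid[best],
       curve = data.frame(w = w_grid, accuracy = acc),
       model = models[[best]])
}
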