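test_that("the diameter weighting transform scales only the D axis", {
  expect_equal(unname(transform_features(make_features(3.3, 8), 1)),
               matrix(c(3.3, 8), 1))
  expect_equal(unname(transform_features(make_features(3.3, 8), 2)),
               matrix(c(6.6, 8), 1))
  expect_equal(unname(transform_features(make_features(4.1, 10), 10)),
               matrix(c(41, 10), 1))
  # w = 1 is the identity on arbitrary features
  set.seed(5)
  f <- make_features(runif(50, 3, 6), runif(50, 7, 15))
  expect_equal(unname(transform_features(f, 1)), cbind(f$D_mm, f$L_mm))
  expect_error(transform_features(f, 0), class = "implant_domain_error")
  expect_error(transform_features(f, -2), class = "implant_domain_error")
})

test_that("k-means++ seeding honours the squared-distance law", {
  x <- rbind(c(0, 0), c(1, 0), c(3, 0))
  # analytic marginal of the second centroid: average over uniform first pick
  # of D^2 probabilities (enumerated independently of the implementation)
  cond <- function(i) {
    d2 <- colSums((t(x) - x[i, ])^2)
    d2 / sum(d2)
  }
  p2 <- colMeans(rbind(cond(1), cond(2), cond(3)))
  n <- 10000
  picks <- matrix(NA_real_, n, 2)
  set.seed(2024)
  for (i in seq_len(n)) {
    ctr <- kmeanspp_seed(x, 2)
    picks[i, ] <- c(match(ctr[1, 1], x[, 1]), match(ctr[2, 1], x[, 1]))
  }
  emp_first <- tabulate(picks[, 1], 3) / n
  emp_second <- tabulate(picks[, 2], 3) / n
  for (j in 1:3) {
    expect_lt(abs(emp_first[j] - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n))
    expect_lt(abs(emp_second[j] - p2[j]),
              3 * sqrt(p2[j] * (1 - p2[j]) / n) + 1e-12)
  }

  # k = 1: a single centroid equal to some input point
  one <- kmeanspp_seed(x, 1)
  expect_true(any(apply(x, 1, function(r) all(r == one[1, ]))))

  # duplicated points at 9 distinct locations force the 9 locations
  loc <- cbind(rep(1:3, each = 3) * 10, rep(1:3, 3) * 10)
  dup <- loc[rep(1:9, times = 4), ]
  ctr <- kmeanspp_seed(dup, 9)
  expect_equal(nrow(unique(ctr)), 9)
  expect_true(all(apply(ctr, 1, function(r)
    any(loc[, 1] == r[1] & loc[, 2] == r[2]))))

  expect_error(kmeanspp_seed(dup, 10), class = "implant_insufficiency_error")
})

test_that("Lloyd iterations converge monotonically and repair empty clusters", {
  # points already at 9 centroids: zero inertia, assignment unchanged
  loc <- cbind(rep(1:3, each = 3) * 10, rep(1:3, 3) * 10)
  pts <- loc[rep(1:9, times = 3), ]
  res <- lloyd_fit(pts, loc)
  expect_equal(res$inertia, 0)
  expect_equal(res$cluster, rep(1:9, times = 3))

  set.seed(88)
  x <- cbind(runif(60, 0, 10), runif(60, 0, 10))
  ctr0 <- kmeanspp_seed(x, 4)
  res <- lloyd_fit(x, ctr0)
  expect_true(all(diff(res$inertia_trace) <= 1e-12))
  expect_equal(sort(unique(res$cluster)), 1:4)

  # an initial centroid far outside the data is empty and gets re-seeded
  far <- rbind(x[1:3, ], c(1e6, 1e6))
  res2 <- lloyd_fit(x, far)
  expect_equal(sort(unique(res2$cluster)), 1:4)
  expect_true(all(res2$centers[, 1] <= 10))
  expect_true(all(diff(res2$inertia_trace) <= 1e-12))
})

test_that("fitted inertia attains the exhaustive-enumeration optimum on tiny instances", {
  set.seed(301)
  x12 <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  opt <- kmeans_global_optimum(x12, 3)
  fit <- fit_size_model(make_features(x12[, 1], x12[, 2]), k = 3, w = 1,
                        n_init = 20, seed = 17)
  expect_equal(fit$inertia, opt, tolerance = 1e-8)

  x8 <- cbind(runif(8, -5, 5), runif(8, -5, 5))
  opt2 <- kmeans_global_optimum(x8, 2)
  fit2 <- fit_size_model(make_features(x8[, 1], x8[, 2]), k = 2, w = 1,
                         n_init = 20, seed = 17)
  expect_equal(fit2$inertia, opt2, tolerance = 1e-8)

  # more restarts can only improve the best inertia
  fit1 <- fit_size_model(make_features(x12[, 1], x12[, 2]), k = 3, w = 1,
                         n_init = 1, seed = 17)
  expect_lte(fit$inertia, fit1$inertia)
})

test_that("fitting agrees with the stats::kmeans Lloyd cross-check", {
  set.seed(61)
  centers_true <- cbind(c(0, 10, 20), c(0, 8, -5))
  x <- centers_true[rep(1:3, each = 30), ] + matrix(rnorm(180, 0, 0.4), 90)
  ctr0 <- x[c(1, 35, 70), ]
  ours <- lloyd_fit(x, ctr0, tol = 0)
  ref <- stats::kmeans(x, ctr0, iter.max = 300, algorithm = "Lloyd")
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(ours$cluster, unname(ref$cluster))
})

test_that("model fitting is bit-reproducible for a fixed seed", {
  cfg <- sim_preset("full", per_class = 20, seed = 9)
  f <- generate_features(cfg)
  m1 <- fit_size_model(f, k = 9, w = 2, n_init = 5, seed = 4)
  m2 <- fit_size_model(f, k = 9, w = 2, n_init = 5, seed = 4)
  expect_identical(m1$centroids, m2$centroids)
  expect_identical(m1$inertia, m2$inertia)
  expect_identical(m1$cluster, m2$cluster)
})

test_that("cluster-to-label mapping recovers separated classes exactly", {
  cfg <- sim_preset("low_noise", per_class = 30, seed = 21)
  f <- generate_features(cfg)
  m <- fit_size_model(f, k = 9, w = 2, n_init = 10, seed = 3)
  expect_null(m$label_map)
  expect_error(predict(m, f), class = "implant_state_error")
  m <- map_clusters_to_labels(m, f)
  expect_setequal(m$label_map, size_labels()$code)  # bijection
  expect_equal(mean(predict(m, f) == f$true_code), 1.0)
  # centroids sit on the class-wise transformed means
  x <- transform_features(f, 2)
  for (code in size_labels()$code) {
    mu <- colMeans(x[f$true_code == code, , drop = FALSE])
    cen <- m$centroids[match(code, m$label_map), ]
    expect_lt(sqrt(sum((cen - mu)^2)), 0.2)
  }

  skewed <- f
  skewed$true_code[1] <- NA
  expect_error(map_clusters_to_labels(fit_size_model(f, seed = 1), skewed),
               class = "implant_config_error")
  few <- f[f$true_code %in% c("3308", "3310"), ]
  expect_error(map_clusters_to_labels(fit_size_model(f, seed = 1), few),
               class = "implant_cardinality_error")
})

test_that("prediction uses nearest centroid with low-index tie-breaking", {
  model <- structure(list(
    k = 2, w = 1, centroids = rbind(c(0, 0), c(2, 0)), inertia = 0,
    label_map = c("3308", "3310"), seed = 1, n_init = 1,
    max_iter = 300, tol = 1e-6), class = "size_km")
  expect_equal(predict(model, make_features(0, 0)), "3308")
  expect_equal(predict(model, make_features(2, 0)), "3310")
  # exactly equidistant: the lower cluster index wins
  expect_equal(predict(model, make_features(1, 5)), "3308")
})

test_that("weight tuning scores the grid and prefers the smallest tied weight", {
  # trivially separable: every weight reaches accuracy 1 -> smallest w wins
  set.seed(40)
  f <- make_features(rep(c(3.3, 4.8), each = 25) + rnorm(50, 0, 0.01),
                     rep(c(8, 12), each = 25) + rnorm(50, 0, 0.01),
                     rep(c("3308", "4812"), each = 25))
  res <- tune_weight(f, f, w_grid = c(4, 1, 2), k = 2, n_init = 3, seed = 2)
  expect_equal(res$curve$w, c(1, 2, 4))
  expect_equal(res$curve$accuracy, rep(1, 3))
  expect_equal(res$best_w, 1)

  single <- tune_weight(f, f, w_grid = 1, k = 2, n_init = 3, seed = 2)
  expect_equal(single$best_w, 1)
  expect_equal(nrow(single$curve), 1)

  expect_error(tune_weight(f, f, w_grid = numeric(0)),
               class = "implant_domain_error")
  expect_error(tune_weight(f, f, w_grid = c(1, -1)),
               class = "implant_domain_error")
})

test_that("up-weighting the diameter separates diameter-overlapping classes", {
  # diameters differ by 0.8 mm but lengths are noisy: at w = 1 k-means
  # splits along length; stretching D restores the class structure
  set.seed(77)
  n <- 60
  f <- make_features(
    c(rnorm(n, 3.3, 0.05), rnorm(n, 4.1, 0.05)),
    c(rnorm(n, 10, 2.5), rnorm(n, 10, 2.5)),
    rep(c("3310", "4110"), each = n)
  )
  res <- tune_weight(f, f, w_grid = 1:10, k = 2, n_init = 5, seed = 6)
  expect_gt(res$best_w, 1)
  acc_w1 <- res$curve$accuracy[res$curve$w == 1]
  expect_gt(max(res$curve$accuracy), acc_w1)
  expect_gt(max(res$curve$accuracy), 0.95)
})

test_that("models serialize to JSON and reload to identical predictions", {
  cfg <- sim_preset("full", per_class = 15, seed = 19)
  f <- generate_features(cfg)
  m <- map_clusters_to_labels(fit_size_model(f, w = 2, seed = 8), f)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$centroids, m$centroids)
  expect_identical(back$label_map, m$label_map)
  expect_equal(back$w, m$w)
  expect_identical(predict(back, f), predict(m, f))
})
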