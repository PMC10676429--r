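# fabricate a minimal gpa_fit around a given p x 3 x n array of
# "aligned" shapes, bypassing superimposition, to probe the PCA in isolation
fake_alignment <- function(arr, scheme = NULL) {
  n <- dim(arr)[3]
  structure(
    list(aligned = arr,
         consensus = apply(arr, c(1, 2), mean) /
           sqrt(sum(apply(arr, c(1, 2), mean)^2)),
         centroid_sizes = rep(1, n), iterations = 1, final_change = 0,
         tolerance = 1e-8, max_iterations = 100, tangent = FALSE,
         orient = "principal", objective_trace = 0,
         meta = tibble::tibble(specimen_id = paste0("s", seq_len(n)),
                               species = paste0("sp", seq_len(n)),
                               family = NA_character_, group = "synthetic",
                               analyzable = TRUE),
         scheme = scheme),
    class = "gpa_fit")
}

test_that("a sample of mean +/- delta has exactly one shape dimension", {
  set.seed(21)
  base <- center_scale(rand_config(5))
  delta <- matrix(rnorm(15, sd = 0.05), 5, 3)
  arr <- array(0, c(5, 3, 4))
  arr[, , 1] <- arr[, , 3] <- base + delta
  arr[, , 2] <- arr[, , 4] <- base - delta
  model <- fit_pca(fake_alignment(arr))
  expect_gt(model$eigenvalues[1], 0)
  expect_lt(model$eigenvalues[2] / model$eigenvalues[1], 1e-14)
  expect_equal(abs(model$scores[, 1]), rep(sqrt(sum(delta^2)), 4),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(model$variance_fractions[1], 1, tolerance = 1e-12)
})

test_that("eigendecomposition matches an independent PCA oracle", {
  set.seed(22)
  fauna <- generate_fauna(fauna_spec(n_species = c(s = 30), seed = 22))
  fit <- gpa(fauna$dataset)
  model <- fit_pca(fit)

  flat <- t(apply(fit$aligned, 3, function(m) as.vector(t(m))))
  pr <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  k_cmp <- seq_len(min(10, ncol(pr$rotation)))
  expect_equal(model$eigenvalues[k_cmp], unname(pr$sdev[k_cmp]^2),
               tolerance = 1e-8)
  for (k in k_cmp[1:6]) {
    expect_equal(abs(sum(model$vectors[, k] * pr$rotation[, k])), 1,
                 tolerance = 1e-8)
  }
  # variance conservation and score centering
  expect_equal(sum(model$eigenvalues), total_variance_of(fit),
               tolerance = 1e-9)
  expect_equal(max(abs(colMeans(model$scores))), 0, tolerance = 1e-9)
  # unit, orthogonal eigenvectors
  G <- crossprod(model$vectors)
  expect_equal(G, diag(nrow(G)), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("all-component reconstruction reproduces every aligned shape", {
  set.seed(23)
  fauna <- generate_fauna(fauna_spec(n_species = c(s = 8), seed = 23))
  fit <- gpa(fauna$dataset)
  model <- fit_pca(fit)
  flat <- t(apply(fit$aligned, 3, function(m) as.vector(t(m))))
  recon <- sweep(model$scores %*% t(model$vectors), 2, model$center, "+")
  expect_equal(recon, flat, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("scores are invariant to specimen order", {
  set.seed(24)
  fauna <- generate_fauna(fauna_spec(n_species = c(s = 12), seed = 24))
  m0 <- fit_pca(gpa(fauna$dataset))
  perm <- sample(length(fauna$dataset))
  shuffled <- landmark_dataset(fauna$dataset$configs[perm],
                               scheme = fauna$dataset$scheme)
  m1 <- fit_pca(gpa(shuffled))
  k_cmp <- 1:4
  s0 <- m0$scores[order(rownames(m0$scores)), k_cmp]
  s1 <- m1$scores[order(rownames(m1$scores)), k_cmp]
  for (k in k_cmp) {
    expect_equal(abs(s1[, k]), abs(s0[, k]), tolerance = 1e-6)
  }
})

test_that("single-mode noise-free fauna concentrates variance on PC1", {
  fauna <- generate_fauna(fauna_spec(n_species = c(s = 10),
                                     mode_sd = c(0.03, 0, 0, 0),
                                     landmark_noise_sd = 0,
                                     nuisance = FALSE, seed = 25))
  model <- fit_pca(gpa(fauna$dataset))
  expect_gt(model$variance_fractions[1], 0.999)
})

test_that("mean_shape matches the consensus and simple closed forms", {
  set.seed(26)
  fauna <- generate_fauna(fauna_spec(n_species = c(s = 9), seed = 26))
  fit <- gpa(fauna$dataset)
  expect_equal(mean_shape(fit), fit$consensus, tolerance = 1e-9,
               ignore_attr = TRUE)

  base <- center_scale(rand_config(5))
  arr <- array(rep(base, 4), c(5, 3, 4))
  expect_equal(mean_shape(fake_alignment(arr)), base, tolerance = 1e-12,
               ignore_attr = TRUE)
  delta <- matrix(rnorm(15, sd = 0.01), 5, 3)
  arr2 <- array(0, c(5, 3, 4))
  arr2[, , c(1, 3)] <- base + delta
  arr2[, , c(2, 4)] <- base - delta
  expect_equal(mean_shape(fake_alignment(arr2)),
               base / sqrt(sum(base^2)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("nearest_to_mean finds the zero-amplitude species", {
  # species along one growth field, amplitudes centred on zero, one species
  # exactly at the template
  set.seed(27)
  mode1 <- default_modes()$elongation
  amps <- c(-0.06, -0.03, 0, 0.04, 0.05)
  sch <- fish_landmark_scheme()
  configs <- purrr::imap(amps, function(a, i) {
    X <- default_template() + a * mode1
    X <- sweep(X %*% rand_proper_rotation() * runif(1, 0.7, 1.4), 2,
               rnorm(3), "+")
    landmark_config(X, sprintf("sp%02d", i), species = sprintf("species%02d", i),
                    scheme = sch)
  })
  model <- fit_pca(gpa(landmark_dataset(configs)), var_threshold = 0.999)
  hit <- nearest_to_mean(model, "species")
  expect_equal(hit$id, "species03")
  hit2 <- nearest_to_mean(model, "specimen")
  expect_equal(hit2$id, "sp03")
})

test_that("centroid outlier scores follow their definition and rank correctly", {
  expect_equal(centroid_outlier_score(c(0, 0, 0), c(0.5, 0.3, 0.2)), 0)
  expect_equal(centroid_outlier_score(c(1, -1), c(0.5, 0.25), 2), 0.75)
  expect_error(centroid_outlier_score(c(1, 2), c(0.5, 0.2, 0.1)), "length")

  set.seed(28)
  fauna <- generate_fauna(fauna_spec(n_species = c(s = 15), seed = 28))
  fit <- gpa(fauna$dataset)
  model <- fit_pca(fit)
  ranked <- centroid_outlier_scores(model, "specimen")
  # recompute from scratch: scores from aligned coordinates, then the sum
  flat <- t(apply(fit$aligned, 3, function(m) as.vector(t(m))))
  sc <- sweep(flat, 2, colMeans(flat)) %*% model$vectors
  K <- model$K_retained
  manual <- colSums(model$variance_fractions[1:K] * t(abs(sc[, 1:K])))
  names(manual) <- fit$meta$specimen_id
  expect_equal(ranked$outlier_score,
               unname(sort(manual, decreasing = TRUE)), tolerance = 1e-10)
  expect_identical(ranked$specimen_id,
                   names(sort(manual, decreasing = TRUE)))
})

test_that("shapes along a PC behave linearly and project back exactly", {
  set.seed(29)
  fauna <- generate_fauna(fauna_spec(n_species = c(s = 12), seed = 29))
  model <- fit_pca(gpa(fauna$dataset))

  origin <- shape_at_pc(model, 1, 0)
  expect_equal(as.vector(t(origin)), model$center, tolerance = 1e-12)
  plus <- shape_at_pc(model, 2, 0.05)
  minus <- shape_at_pc(model, 2, -0.05)
  expect_equal(plus - origin, origin - minus, tolerance = 1e-12)

  sc <- project_shapes(model, shape_at_pc(model, 2, 0.037))
  expect_equal(sc[1, 2], 0.037, tolerance = 1e-9)
  expect_equal(max(abs(sc[1, -2])), 0, tolerance = 1e-9)

  # sd units place the shape at sd * sqrt(lambda)
  s2 <- shape_at_pc(model, 1, sd = 2)
  expect_equal(project_shapes(model, s2)[1, 1],
               2 * sqrt(model$eigenvalues[1]), tolerance = 1e-9)
  expect_error(shape_at_pc(model, 999), "between")
})

test_that("convex hulls handle canonical and degenerate inputs", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  hull <- convex_hull_2d(sq)
  expect_equal(nrow(hull), 4)
  expect_equal(convex_hull_area(sq), 1, tolerance = 1e-12)
  # counter-clockwise orientation: positive signed area
  x <- hull[, 1]; y <- hull[, 2]; j <- c(2:4, 1)
  expect_gt(sum(x * y[j] - x[j] * y), 0)

  tri <- rbind(c(0, 0), c(2, 0), c(0, 3))
  expect_equal(nrow(convex_hull_2d(tri)), 3)
  expect_equal(convex_hull_area(tri), 3, tolerance = 1e-12)

  expect_equal(convex_hull_2d(rbind(c(1, 2))), rbind(c(1, 2)),
               ignore_attr = TRUE)
  seg <- cbind(seq(0, 1, 0.25), seq(0, 2, 0.5))
  expect_equal(nrow(convex_hull_2d(seg)), 2)
  expect_equal(convex_hull_area(seg), 0)
  expect_error(convex_hull_2d(matrix(numeric(0), 0, 2)), "empty")
})

test_that("hull areas agree with a gift-wrapping oracle on random sets", {
  set.seed(30)
  for (n in c(5, 12, 40)) {
    pts <- matrix(rnorm(2 * n), n, 2)
    expect_equal(convex_hull_area(pts), oracle_hull_area(pts),
                 tolerance = 1e-10)
  }
})

test_that("group occupancy reports hulls per nested group", {
  # two groups pushed apart along the first growth field
  off <- matrix(0, 2, 4, dimnames = list(c("A", "B"), NULL))
  off[1, 1] <- -0.15; off[2, 1] <- 0.15
  fauna <- generate_fauna(fauna_spec(
    n_species = c(A = 8, B = 8), group_offsets = off,
    mode_sd = c(0.02, 0.02, 0.01, 0.01), seed = 31))
  ds <- fauna$dataset
  # group labels live in $family for synthetic data; promote them
  for (id in names(ds$configs)) ds$configs[[id]]$group <-
    if (ds$configs[[id]]$family == "A") "non-teleost" else "ovalentarian acanthomorph"
  model <- fit_pca(gpa(ds))
  occ <- group_occupancy(model, c(1, 2))
  expect_equal(sort(occ$group), sort(c("non-teleost",
                                       "ovalentarian acanthomorph")))
  expect_equal(occ$n_species, c(8, 8))
  # designed offsets separate the groups along PC1
  sp <- pca_scores(model, "species", K = 2)
  a_rng <- range(sp$PC1[sp$group == occ$group[1]])
  b_rng <- range(sp$PC1[sp$group == occ$group[2]])
  expect_true(a_rng[2] < b_rng[1] || b_rng[2] < a_rng[1])
  expect_true(all(occ$area > 0))

  # a 2-species group degenerates to a zero-area segment
  small <- generate_fauna(fauna_spec(n_species = c(A = 2),
                                     specimens_per_species = 2, seed = 32))
  m2 <- fit_pca(gpa(small$dataset))
  occ2 <- group_occupancy(m2, c(1, 2))
  expect_equal(occ2$area, 0)
  expect_warning(group_occupancy(model, c(1, 2),
                                 groups = c("non-teleost", "excluded")),
                 "omitted")
})

test_that("tidy/glance expose the eigenvalue table and autoplot works", {
  set.seed(33)
  fauna <- generate_fauna(fauna_spec(n_species = c(s = 10), seed = 33))
  model <- fit_pca(gpa(fauna$dataset))
  td <- tidy(model)
  expect_equal(td$cumulative_fraction[length(td$cumulative_fraction)], 1,
               tolerance = 1e-9)
  expect_true(all(diff(td$eigenvalue) <= 1e-15))
  expect_equal(sum(td$retained), model$K_retained)
  gg <- autoplot(model)
  expect_s3_class(gg, "ggplot")
})
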