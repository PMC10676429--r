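#' Principal component analysis of Procrustes-aligned shapes
#'
#' Eigendecomposition of the covariance matrix of the flattened aligned
#' coordinates (landmark-major: landmark 1 axis 1..3, landmark 2 axis 1..3,
#' ...), centered at their sample mean. This is a covariance (not
#' correlation) PCA: Procrustes coordinates share a single scale, and the
#' resulting morphospace is metric. Components are sorted by decreasing
#' eigenvalue; each eigenvector is oriented so that its largest-magnitude
#' component is positive (ties broken towards the lowest index), making
#' reported loadings reproducible across numerical backends.
#'
#' All `3p` components are computed and kept; `K_retained` is the smallest
#' number of leading components whose cumulative variance fraction reaches
#' `var_threshold` (default 0.95).
#'
#' @param alignment A [gpa()] fit with at least 3 specimens.
#' @param var_threshold Cumulative variance fraction used to set
#'   `K_retained`.
#'
#' @return An object of class `morphospace_model` with fields `mean_shape`
#'   (unit-size consensus of the aligned sample), `center` (arithmetic mean
#'   of the flattened aligned coordinates — the origin of score space),
#'   `eigenvalues`, `variance_fractions`, `vectors` (3p x 3p, unit columns),
#'   `scores` (n x 3p, zero column means), `K_retained`, `meta`, `scheme`.
#' @export
fit_pca <- function(alignment, var_threshold = 0.95) {
  stopifnot(inherits(alignment, "gpa_fit"))
  flat <- flatten_alignment(alignment)
  n <- nrow(flat)
  if (n < 3) stop("PCA needs at least 3 aligned specimens", call. = FALSE)
  center <- colMeans(flat)
  centered <- sweep(flat, 2, center)
  C <- crossprod(centered) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  vectors <- eig$vectors
  for (k in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, k]))
    if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
  }
  total <- sum(lambda)
  w <- if (total > 0) lambda / total else rep(0, length(lambda))
  scores <- centered %*% vectors
  K <- if (total > 0) which(cumsum(w) >= var_threshold - 1e-12)[1]
       else length(lambda)
  p <- dim(alignment$aligned)[1]
  dimnames(scores) <- list(alignment$meta$specimen_id,
                           paste0("PC", seq_len(ncol(scores))))
  structure(
    list(
      mean_shape = mean_shape(alignment),
      center = center,
      eigenvalues = lambda,
      variance_fractions = w,
      vectors = vectors,
      scores = scores,
      K_retained = K,
      var_threshold = var_threshold,
      p = p,
      meta = alignment$meta,
      scheme = alignment$scheme
    ),
    class = "morphospace_model"
  )
}

#' @export
print.morphospace_model <- function(x, ...) {
  cat("<morphospace_model> ", nrow(x$scores), " specimens, ", x$p,
      " landmarks\n", sep = "")
  K <- min(x$K_retained, 6)
  cat("  variance fractions (PC1..PC", K, "): ",
      paste(sprintf("%.3f", x$variance_fractions[seq_len(K)]),
            collapse = ", "),
      "; K_retained = ", x$K_retained, "\n", sep = "")
  invisible(x)
}

#' Mean (consensus) shape of an aligned sample
#'
#' Arithmetic mean of the aligned configurations, rescaled to unit centroid
#' size so it matches the GPA consensus.
#'
#' @param alignment A [gpa()] fit.
#' @return A p x 3 matrix.
#' @export
mean_shape <- function(alignment) {
  stopifnot(inherits(alignment, "gpa_fit"))
  m <- apply(alignment$aligned, c(1, 2), mean)
  m / sqrt(sum(m^2))
}

#' Eigenvalue table and model summary
#'
#' `tidy()` returns one row per component (eigenvalue, variance fraction,
#' cumulative fraction); `glance()` a one-row model summary.
#'
#' @param x A `morphospace_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.morphospace_model <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fractions,
    cumulative_fraction = cumsum(x$variance_fractions),
    retained = seq_along(x$eigenvalues) <= x$K_retained
  )
}

#' @rdname tidy.morphospace_model
#' @export
glance.morphospace_model <- function(x, ...) {
  tibble::tibble(
    n_specimens = nrow(x$scores), n_landmarks = x$p,
    K_retained = x$K_retained,
    total_variance = sum(x$eigenvalues),
    retained_variance_fraction = sum(x$variance_fractions[seq_len(x$K_retained)])
  )
}

#' PC scores at specimen or species level
#'
#' Species scores are arithmetic means of the member specimens' scores
#' (equivalently, by linearity, scores of the species-mean shapes).
#'
#' @param model A [fit_pca()] model.
#' @param level `"specimen"` or `"species"`.
#' @param K Number of leading components to return (default: all retained).
#' @return A tibble with metadata columns and `PC1..PCK` score columns.
#' @export
pca_scores <- function(model, level = c("specimen", "species"),
                       K = model$K_retained) {
  level <- match.arg(level)
  K <- check_K(model, K)
  sc <- tibble::as_tibble(model$scores[, seq_len(K), drop = FALSE])
  out <- dplyr::bind_cols(model$meta[, c("specimen_id", "species", "group")],
                          sc)
  if (level == "specimen") return(out)
  out |>
    dplyr::group_by(.data$species, .data$group) |>
    dplyr::summarise(
      n_specimens = dplyr::n(),
      dplyr::across(dplyr::starts_with("PC"), mean),
      .groups = "drop"
    )
}

check_K <- function(model, K) {
  K <- as.integer(K)
  if (is.na(K) || K < 1 || K > length(model$eigenvalues)) {
    stop("K must be between 1 and ", length(model$eigenvalues), call. = FALSE)
  }
  K
}

#' Specimen or species closest to the mean shape
#'
#' Finds the specimen (or species mean) with the smallest Euclidean norm in
#' retained score space — the taxon whose shape best approximates the
#' sample's mean body shape. Ties are broken by dataset order with a warning.
#'
#' @inheritParams pca_scores
#' @return A one-row tibble with `level`, `id`, and `distance`.
#' @export
nearest_to_mean <- function(model, level = c("specimen", "species"),
                            K = model$K_retained) {
  level <- match.arg(level)
  sc <- pca_scores(model, level = level, K = K)
  mat <- as.matrix(dplyr::select(sc, dplyr::starts_with("PC")))
  norms <- sqrt(rowSums(mat^2))
  i <- which.min(norms)
  if (sum(abs(norms - norms[i]) < 1e-12) > 1) {
    warning("tie for nearest-to-mean; returning the first in dataset order",
            call. = FALSE)
  }
  id <- if (level == "specimen") sc$specimen_id[i] else sc$species[i]
  tibble::tibble(level = level, id = id, distance = norms[i])
}

#' Variance-weighted centroid outlier score
#'
#' Distance-from-centroid summary of one point in morphospace: the sum over
#' components of the variance fraction times the absolute PC score. Taxa
#' with extreme shapes (long rostra, etc.) rank highest.
#'
#' @param scores Numeric score vector for one specimen or species.
#' @param w Variance fractions (proportions) of the same length.
#' @param K_use Number of leading components to sum over (default: all
#'   supplied).
#' @return Non-negative scalar.
#' @export
centroid_outlier_score <- function(scores, w, K_use = length(scores)) {
  if (length(scores) != length(w)) {
    stop("scores and w must have the same length", call. = FALSE)
  }
  if (K_use > length(scores) || K_use < 1) {
    stop("K_use must be between 1 and length(scores)", call. = FALSE)
  }
  sum(w[seq_len(K_use)] * abs(scores[seq_len(K_use)]))
}

#' Centroid outlier scores for a whole model
#'
#' @inheritParams pca_scores
#' @param K_use Components summed over; defaults to all retained.
#' @return A tibble ranked by decreasing score.
#' @export
centroid_outlier_scores <- function(model, level = c("specimen", "species"),
                                    K_use = model$K_retained) {
  level <- match.arg(level)
  K_use <- check_K(model, K_use)
  sc <- pca_scores(model, level = level, K = K_use)
  mat <- as.matrix(dplyr::select(sc, dplyr::starts_with("PC")))
  w <- model$variance_fractions[seq_len(K_use)]
  sc$outlier_score <- apply(mat, 1, centroid_outlier_score, w = w,
                            K_use = K_use)
  dplyr::arrange(dplyr::select(sc, -dplyr::starts_with("PC")),
                 dplyr::desc(.data$outlier_score))
}

#' Shape along a principal component
#'
#' The configuration at signed position `t` along component `k`: the score
#' origin (arithmetic mean of the aligned configurations) displaced by `t`
#' times the component's per-landmark eigenvector field. `t` is in
#' Procrustes units; alternatively give `sd` to place the shape at
#' `sd * sqrt(eigenvalue_k)`, i.e. in standard deviations along the axis.
#'
#' @param model A [fit_pca()] model.
#' @param k Component index.
#' @param t Displacement in Procrustes units.
#' @param sd Displacement in standard deviations (overrides `t`).
#' @return A p x 3 matrix.
#' @export
shape_at_pc <- function(model, k, t = 0, sd = NULL) {
  k <- check_K(model, k)
  if (!is.null(sd)) t <- sd * sqrt(model$eigenvalues[k])
  flat <- model$center + t * model$vectors[, k]
  matrix(flat, nrow = model$p, ncol = 3, byrow = TRUE,
         dimnames = dimnames(model$mean_shape))
}

#' Project configurations into score space
#'
#' Scores of arbitrary aligned configurations relative to the model's
#' centering point.
#'
#' @param model A [fit_pca()] model.
#' @param shapes A p x 3 matrix, or a p x 3 x n array of aligned shapes.
#' @return An n x 3p score matrix (one row for a single matrix).
#' @export
project_shapes <- function(model, shapes) {
  if (length(dim(shapes)) == 2) {
    flat <- matrix(as.vector(t(shapes)), nrow = 1)
  } else {
    flat <- flatten_alignment(shapes)
  }
  sweep(flat, 2, model$center) %*% model$vectors
}
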