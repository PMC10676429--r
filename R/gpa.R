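#' Centroid size of a landmark configuration
#'
#' The root summed squared distance of the landmarks from their centroid:
#' the size measure removed by Procrustes scaling.
#'
#' @param config A p x 3 numeric matrix or a [landmark_config()].
#' @return A non-negative scalar. Zero only if all landmarks coincide.
#' @export
centroid_size <- function(config) {
  x <- config_coords(config)
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2, ctr)^2))
}

config_coords <- function(config) {
  if (inherits(config, "landmark_config")) return(config$coords)
  x <- as.matrix(config)
  if (ncol(x) != 3 || nrow(x) < 1 || !all(is.finite(x))) {
    stop("expected a finite p x 3 coordinate matrix", call. = FALSE)
  }
  x
}

#' Center a configuration and scale it to unit centroid size
#'
#' @inheritParams centroid_size
#' @return A p x 3 matrix with centroid at the origin and centroid size 1.
#' @export
center_scale <- function(config) {
  x <- config_coords(config)
  ctr <- colMeans(x)
  x <- sweep(x, 2, ctr)
  cs <- sqrt(sum(x^2))
  if (cs <= 0) {
    stop("degenerate configuration: centroid size is zero, cannot scale",
         call. = FALSE)
  }
  x / cs
}

#' Optimal proper rotation between two centered configurations
#'
#' Returns the rotation `R` (with `t(R) %*% R = I`, `det(R) = +1`) minimising
#' the Frobenius norm of `A %*% R - B` over proper rotations, via SVD of
#' `t(A) %*% B` with sign correction on the smallest singular direction.
#' Reflections are disallowed: left and right landmarks are digitised
#' explicitly, so a mirror alignment would be anatomically wrong.
#'
#' @param A,B Centered p x 3 matrices.
#' @return A 3 x 3 rotation matrix.
#' @export
optimal_rotation <- function(A, B) {
  A <- config_coords(A); B <- config_coords(B)
  if (!all(dim(A) == dim(B))) {
    stop("configurations must have identical dimensions", call. = FALSE)
  }
  M <- crossprod(A, B)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  if (sv$d[2] < 1e-12 * max(sv$d[1], .Machine$double.eps)) {
    warning("rank-deficient cross-product matrix: optimal rotation is not ",
            "unique, returning one minimizer", call. = FALSE)
  }
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Euclidean distance between two aligned configurations
#'
#' The Procrustes distance used for convergence checks and nearest-to-mean
#' queries: the square root of the summed squared coordinate differences of
#' two already-aligned configurations.
#'
#' @param A,B Aligned p x 3 matrices of identical dimension.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(A, B) {
  A <- config_coords(A); B <- config_coords(B)
  if (!all(dim(A) == dim(B))) {
    stop("configurations must have identical dimensions", call. = FALSE)
  }
  sqrt(sum((A - B)^2))
}

#' Generalized Procrustes Analysis
#'
#' Superimposes all analyzable configurations of a dataset into a common
#' shape space: every configuration is translated to the origin and scaled to
#' unit centroid size, then iteratively rotated onto the current consensus
#' (initialised as the first configuration), the consensus being re-estimated
#' each round as the arithmetic mean of the rotated configurations rescaled
#' to unit centroid size. Iteration stops when the Procrustes distance
#' between successive consensus shapes falls below `tolerance` or after
#' `max_iterations` rounds. The summed squared distance of the
#' configurations to their mean is non-increasing across iterations.
#'
#' @param dataset A [landmark_dataset()] with at least 2 analyzable
#'   specimens (the `"excluded"` group is dropped), or a p x 3 x n array.
#' @param tolerance Convergence threshold on the change of the consensus
#'   (Procrustes distance between successive consensus estimates).
#' @param max_iterations Iteration cap.
#' @param tangent If `TRUE`, orthogonally project the aligned configurations
#'   onto the tangent space at the consensus after convergence. Off by
#'   default; plain Procrustes coordinates are used downstream.
#' @param orient Output orientation. `"principal"` (default) rotates the
#'   whole aligned sample so the consensus sits in a canonical frame: its
#'   principal axes ordered by decreasing extent (for fish-like
#'   configurations: anteroposterior, then dorsoventral, then mediolateral,
#'   since length > depth > width), axis signs fixed by the skewness of the
#'   consensus coordinates (falling back to the largest-magnitude
#'   coordinate), and the last axis by `det = +1`. This makes the result
#'   deterministic and independent of each specimen's arbitrary original
#'   pose, and gives the coordinate axes an anatomical reading. `"first"`
#'   leaves the sample in the frame of the first configuration.
#'
#' @return An object of class `gpa_fit`: `aligned` (p x 3 x n array),
#'   `consensus` (unit-size p x 3 matrix), `centroid_sizes` (original units),
#'   `iterations`, `final_change`, `objective_trace` (summed squared distance
#'   to the mean after each iteration), `meta`, `scheme`.
#' @export
gpa <- function(dataset, tolerance = 1e-8, max_iterations = 100,
                tangent = FALSE, orient = c("principal", "first")) {
  orient <- match.arg(orient)
  if (inherits(dataset, "landmark_dataset")) {
    dataset <- analyzable_subset(dataset)
    arr <- dataset_array(dataset)
    meta <- dataset_meta(dataset)
    scheme <- dataset$scheme
  } else {
    arr <- dataset
    if (length(dim(arr)) != 3 || dim(arr)[2] != 3) {
      stop("expected a landmark_dataset or a p x 3 x n array", call. = FALSE)
    }
    ids <- dimnames(arr)[[3]]
    if (is.null(ids)) ids <- paste0("spec", seq_len(dim(arr)[3]))
    meta <- tibble::tibble(specimen_id = ids, species = ids,
                           family = NA_character_, group = "synthetic",
                           analyzable = TRUE)
    scheme <- NULL
  }
  n <- dim(arr)[3]
  if (n < 2) stop("GPA needs at least 2 analyzable configurations",
                  call. = FALSE)

  sizes <- apply(arr, 3, centroid_size)
  if (any(sizes <= 0)) {
    stop("zero centroid size for specimen(s): ",
         paste(meta$specimen_id[sizes <= 0], collapse = ", "), call. = FALSE)
  }
  X <- arr
  for (i in seq_len(n)) X[, , i] <- center_scale(arr[, , i])

  consensus <- X[, , 1]
  objective_trace <- numeric(0)
  final_change <- Inf
  iter <- 0
  while (iter < max_iterations) {
    iter <- iter + 1
    for (i in seq_len(n)) {
      X[, , i] <- X[, , i] %*% optimal_rotation(X[, , i], consensus)
    }
    m <- apply(X, c(1, 2), mean)
    objective_trace <- c(objective_trace,
                         sum(sweep(X, c(1, 2), m)^2))
    new_consensus <- m / sqrt(sum(m^2))
    final_change <- procrustes_distance(new_consensus, consensus)
    consensus <- new_consensus
    if (final_change < tolerance) break
  }
  if (orient == "principal") {
    R <- canonical_rotation(consensus)
    consensus <- consensus %*% R
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% R
    if (!is.null(scheme)) {
      scheme$axis_roles <- c("anteroposterior", "dorsoventral", "mediolateral")
    }
  }
  if (tangent) {
    v <- as.vector(consensus)
    for (i in seq_len(n)) {
      xi <- as.vector(X[, , i])
      X[, , i] <- X[, , i] - consensus * (sum(xi * v) - 1)
    }
  }
  dimnames(X) <- list(
    dimnames(arr)[[1]],
    if (orient == "principal" && !is.null(scheme)) scheme$axis_roles
    else dimnames(arr)[[2]],
    dimnames(arr)[[3]]
  )
  structure(
    list(
      aligned = X, consensus = consensus,
      centroid_sizes = stats::setNames(sizes, meta$specimen_id),
      iterations = iter, final_change = final_change,
      tolerance = tolerance, max_iterations = max_iterations,
      tangent = tangent, orient = orient,
      objective_trace = objective_trace,
      meta = meta, scheme = scheme
    ),
    class = "gpa_fit"
  )
}

# rotation taking a centered configuration into its canonical
# principal-axes frame: axes ordered by decreasing extent, signs by
# coordinate skewness (fallback: largest-magnitude coordinate positive),
# last axis by det = +1
canonical_rotation <- function(config) {
  cc <- sweep(config, 2, colMeans(config))
  V <- eigen(crossprod(cc), symmetric = TRUE)$vectors
  proj <- cc %*% V
  for (j in 1:2) {
    sk <- sum(proj[, j]^3)
    s <- if (abs(sk) > 1e-12 * max(abs(proj[, j]))^3) {
      sign(sk)
    } else {
      sign(proj[which.max(abs(proj[, j])), j])
    }
    if (s < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' @export
print.gpa_fit <- function(x, ...) {
  d <- dim(x$aligned)
  cat("<gpa_fit> ", d[3], " specimens, ", d[1], " landmarks; ",
      x$iterations, " iterations, final consensus change ",
      format(x$final_change, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tidy and summarise a GPA fit
#'
#' `tidy()` returns the aligned Procrustes coordinates in long format (one
#' row per specimen/landmark); `glance()` returns a one-row convergence and
#' dispersion summary.
#'
#' @param x A `gpa_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gpa_fit <- function(x, ...) {
  d <- dim(x$aligned)
  lm_names <- dimnames(x$aligned)[[1]]
  if (is.null(lm_names)) lm_names <- paste0("L", seq_len(d[1]))
  axes <- dimnames(x$aligned)[[2]]
  if (is.null(axes)) axes <- c("axis1", "axis2", "axis3")
  purrr::map_dfr(seq_len(d[3]), function(i) {
    out <- tibble::as_tibble(x$aligned[, , i], .name_repair = ~axes)
    tibble::add_column(out, specimen_id = x$meta$specimen_id[i],
                       landmark = lm_names, .before = 1)
  })
}

#' @rdname tidy.gpa_fit
#' @export
glance.gpa_fit <- function(x, ...) {
  d <- dim(x$aligned)
  tibble::tibble(
    n_specimens = d[3], n_landmarks = d[1],
    iterations = x$iterations, final_change = x$final_change,
    converged = x$final_change < x$tolerance,
    total_procrustes_variance = total_shape_variance(x)
  )
}

# total sample variance (trace of the covariance of flattened aligned coords)
total_shape_variance <- function(fit) {
  flat <- flatten_alignment(fit)
  sum(apply(flat, 2, stats::var))
}

# n x 3p matrix, row-major per landmark: (l1 ax1, l1 ax2, l1 ax3, l2 ax1, ...)
flatten_alignment <- function(fit) {
  arr <- if (inherits(fit, "gpa_fit")) fit$aligned else fit
  n <- dim(arr)[3]
  t(apply(arr, 3, function(m) as.vector(t(m))))
}
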