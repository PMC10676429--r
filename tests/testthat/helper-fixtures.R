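# shared fixtures and independent oracles, built in code at test time

# rotation about one coordinate axis
axis_rotation <- function(axis, theta) {
  R <- diag(3)
  ij <- list(c(2, 3), c(1, 3), c(1, 2))[[axis]]
  R[ij[1], ij[1]] <- cos(theta); R[ij[2], ij[2]] <- cos(theta)
  R[ij[1], ij[2]] <- -sin(theta); R[ij[2], ij[1]] <- sin(theta)
  R
}

euler_rotation <- function(a, b, c) {
  axis_rotation(1, a) %*% axis_rotation(2, b) %*% axis_rotation(3, c)
}

rand_proper_rotation <- function() {
  euler_rotation(stats::runif(1, 0, 2 * pi), stats::runif(1, 0, pi),
                 stats::runif(1, 0, 2 * pi))
}

# small scheme for tiny matrix fixtures
tiny_scheme <- function(p) {
  landmark_scheme(paste0("L", seq_len(p)))
}

rand_config <- function(p = 4) {
  matrix(stats::rnorm(p * 3), p, 3)
}

# brute-force optimal rotation: coarse Euler grid followed by Nelder-Mead
# refinement of ||A R - B||_F^2
oracle_rotation_residual <- function(A, B, grid_n = 8) {
  obj <- function(ang) sum((A %*% euler_rotation(ang[1], ang[2], ang[3]) - B)^2)
  gs <- seq(0, 2 * pi, length.out = grid_n + 1)[seq_len(grid_n)]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in gs) for (b in gs) for (c in gs) {
    v <- obj(c(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  opt <- stats::optim(best_ang, obj, control = list(reltol = 1e-14,
                                                    maxit = 5000))
  opt$value
}

# brute-force joint GPA objective on a tiny sample: minimise over all
# per-specimen rotations the summed squared distance to the unit-size
# consensus, from several random starts
oracle_gpa_objective <- function(configs, n_starts = 25) {
  X <- lapply(configs, center_scale)
  n <- length(X)
  obj <- function(angles) {
    rot <- lapply(seq_len(n), function(i) {
      X[[i]] %*% euler_rotation(angles[3 * i - 2], angles[3 * i - 1],
                                angles[3 * i])
    })
    m <- Reduce(`+`, rot) / n
    cons <- m / sqrt(sum(m^2))
    sum(vapply(rot, function(x) sum((x - cons)^2), numeric(1)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- stats::runif(3 * n, 0, 2 * pi)
    opt <- stats::optim(start, obj, control = list(reltol = 1e-15,
                                                   maxit = 20000))
    opt <- stats::optim(opt$par, obj, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 2000))
    best <- min(best, opt$value)
  }
  best
}

# gift-wrapping convex hull (independent of grDevices::chull)
oracle_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts[, 1])
  hull <- start; cur <- start
  repeat {
    cand <- if (length(hull) == 1) setdiff(seq_len(n), cur) else seq_len(n)
    nxt <- cand[1]
    for (j in cand) {
      if (j == cur) next
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      if (nxt == cur || cr < 0) nxt <- j
    }
    if (nxt == start) break
    hull <- c(hull, nxt); cur <- nxt
    if (length(hull) > n) stop("hull oracle failed to terminate")
  }
  poly <- pts[hull, , drop = FALSE]
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# datasets of rigid-motion-plus-scale copies of one shape
copies_dataset <- function(shape, n, scheme = tiny_scheme(nrow(shape))) {
  configs <- lapply(seq_len(n), function(i) {
    X <- shape %*% rand_proper_rotation() * stats::runif(1, 0.5, 3)
    X <- sweep(X, 2, stats::rnorm(3, sd = 2), "+")
    landmark_config(X, specimen_id = paste0("s", i), scheme = scheme)
  })
  landmark_dataset(configs, scheme = scheme)
}

# express a flattened eigenvector field in the template's frame
field_in_template_frame <- function(model, k, alignment,
                                    template = default_template()) {
  R <- optimal_rotation(alignment$consensus, center_scale(template))
  fld <- matrix(model$vectors[, k], nrow = model$p, ncol = 3,
                byrow = TRUE) %*% R
  as.vector(t(fld))
}

flatten_field <- function(m) as.vector(t(m))

# independent of the package internals: total sample variance of the
# flattened aligned coordinates
total_variance_of <- function(fit) {
  flat <- t(apply(fit$aligned, 3, function(m) as.vector(t(m))))
  sum(apply(flat, 2, stats::var))
}

# raw fcsv text with rows in arbitrary order
fcsv_text <- function(coords, labels, coordinate_system = "RAS") {
  rows <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("vtkMRMLMarkupsFiducialNode_%d,%.17g,%.17g,%.17g,0,0,0,1,1,1,0,%s,,",
            i - 1, coords[i, 1], coords[i, 2], coords[i, 3], labels[i])
  }, character(1))
  c("# Markups fiducial file version = 4.11",
    paste0("# CoordinateSystem = ", coordinate_system),
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    rows)
}
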