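#' Minimum convex hull of 2D points
#'
#' Vertices of the minimum convex hull in counter-clockwise order. Degenerate
#' inputs are handled: a single point returns that point, a collinear set
#' returns its two extreme points (the segment).
#'
#' @param points An n x 2 numeric matrix (or data frame) of coordinates.
#' @return An m x 2 matrix of hull vertices, counter-clockwise.
#' @export
convex_hull_2d <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0) stop("empty point set", call. = FALSE)
  if (ncol(pts) != 2 || !all(is.finite(pts))) {
    stop("expected a finite n x 2 matrix", call. = FALSE)
  }
  pts <- unique(pts)
  if (nrow(pts) == 1) return(pts)
  # collinear (or 2-point) sets: return the extreme pair
  d <- sweep(pts, 2, pts[1, ])
  if (nrow(pts) == 2 || all(abs(d[, 1] * d[2, 2] - d[, 2] * d[2, 1]) < 1e-12)) {
    u <- d[which.max(rowSums(d^2)), ]
    proj <- d %*% u
    return(pts[c(which.min(proj), which.max(proj)), , drop = FALSE])
  }
  idx <- grDevices::chull(pts)
  hull <- pts[idx, , drop = FALSE]
  if (polygon_signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), ]
  hull
}

polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a convex hull
#'
#' Shoelace area of the hull of a point set; 0 for degenerate (point or
#' segment) sets.
#'
#' @inheritParams convex_hull_2d
#' @return Non-negative scalar.
#' @export
convex_hull_area <- function(points) {
  hull <- convex_hull_2d(points)
  if (nrow(hull) < 3) return(0)
  abs(polygon_signed_area(hull))
}

#' Morphospace occupancy of nested groups
#'
#' For each nested-clade group, the minimum convex hull of its species-mean
#' scores in a chosen PC plane, with its area. Groups requested but absent
#' from the data are omitted with a warning.
#'
#' @param model A [fit_pca()] model.
#' @param pc_pair Length-2 integer vector of component indices.
#' @param groups Groups to report; defaults to the groups present
#'   (excluding `"excluded"`).
#' @return A tibble with one row per group: `group`, `n_species`, `area`,
#'   and a `hull` list-column of counter-clockwise vertex matrices.
#' @export
group_occupancy <- function(model, pc_pair = c(1, 2), groups = NULL) {
  stopifnot(length(pc_pair) == 2)
  check_K(model, max(pc_pair))
  sp <- pca_scores(model, level = "species", K = max(pc_pair))
  present <- setdiff(unique(sp$group), "excluded")
  if (is.null(groups)) groups <- present
  absent <- setdiff(groups, present)
  if (length(absent) > 0) {
    warning("group(s) with zero species omitted: ",
            paste(absent, collapse = ", "), call. = FALSE)
    groups <- intersect(groups, present)
  }
  cols <- paste0("PC", pc_pair)
  purrr::map_dfr(groups, function(g) {
    pts <- as.matrix(sp[sp$group == g, cols])
    tibble::tibble(
      group = g, n_species = nrow(pts),
      area = convex_hull_area(pts),
      hull = list(convex_hull_2d(pts))
    )
  })
}

#' Morphospace scatter plot
#'
#' Species-mean (large) and specimen (small) points in a PC plane, coloured
#' by nested-clade group, with minimum convex hulls around the species means
#' of each group.
#'
#' @param object A `morphospace_model`.
#' @param pc_pair Components to plot.
#' @param hulls Draw group hulls?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.morphospace_model <- function(object, pc_pair = c(1, 2),
                                       hulls = TRUE, ...) {
  cols <- paste0("PC", pc_pair)
  spec <- pca_scores(object, "specimen", K = max(pc_pair))
  sp <- pca_scores(object, "species", K = max(pc_pair))
  wpc <- 100 * object$variance_fractions[pc_pair]
  gg <- ggplot2::ggplot(
    spec, ggplot2::aes(.data[[cols[1]]], .data[[cols[2]]], colour = .data$group)
  )
  if (hulls) {
    occ <- group_occupancy(object, pc_pair)
    hull_df <- purrr::map_dfr(seq_len(nrow(occ)), function(i) {
      h <- occ$hull[[i]]
      tibble::tibble(group = occ$group[i], x = h[, 1], y = h[, 2])
    })
    gg <- gg + ggplot2::geom_polygon(
      data = hull_df,
      ggplot2::aes(.data$x, .data$y, colour = .data$group, fill = .data$group),
      alpha = 0.15, linewidth = 0.3
    )
  }
  gg +
    ggplot2::geom_point(size = 1, alpha = 0.6) +
    ggplot2::geom_point(data = sp, size = 2.5) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", cols[1], wpc[1]),
      y = sprintf("%s (%.1f%%)", cols[2], wpc[2]),
      colour = "group", fill = "group"
    ) +
    ggplot2::theme_minimal()
}
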