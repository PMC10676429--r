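#' Variance-weighted per-landmark eigenvector magnitudes
#'
#' For each landmark `l` and each of the leading `K` components, the 3D
#' magnitude of the landmark's eigenvector block weighted by the component's
#' variance fraction:
#' `m[l, k] = w_k * sqrt(e_k[l,1]^2 + e_k[l,2]^2 + e_k[l,3]^2)`,
#' where `w_k` is the eigenvalue proportion over the full decomposition.
#' Since each eigenvector has unit norm, `m[l, k] <= w_k` and column sums lie
#' in `[w_k, w_k * sqrt(p)]`.
#'
#' @param model A [fit_pca()] model.
#' @param K Number of leading components to tabulate (default:
#'   `K_retained`).
#' @return A `contribution_table`: a tibble with `landmark`, `number`, and
#'   `PC1..PCK` magnitude columns, plus attributes `w` (the variance
#'   fractions used) and `K`.
#' @export
weighted_landmark_magnitudes <- function(model, K = model$K_retained) {
  K <- check_K(model, K)
  p <- model$p
  w <- model$variance_fractions[seq_len(K)]
  m <- vapply(seq_len(K), function(k) {
    field <- matrix(model$vectors[, k], nrow = p, ncol = 3, byrow = TRUE)
    w[k] * sqrt(rowSums(field^2))
  }, numeric(p))
  colnames(m) <- paste0("PC", seq_len(K))
  scheme <- model$scheme
  tbl <- tibble::tibble(
    landmark = if (!is.null(scheme)) scheme$landmark_names
               else paste0("L", seq_len(p)),
    number = if (!is.null(scheme)) scheme$landmark_numbers else seq_len(p)
  )
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(m))
  structure(tbl, w = w, K = K,
            class = c("contribution_table", class(tbl)))
}

# extract the p x K magnitude matrix from a table, tibble, data frame or matrix
magnitude_matrix <- function(table) {
  if (is.matrix(table)) {
    m <- table
  } else {
    df <- as.data.frame(table)
    pc_cols <- grep("^PC", names(df), value = TRUE)
    if (length(pc_cols) == 0) {
      pc_cols <- names(df)[vapply(df, is.numeric, logical(1)) &
                             !names(df) %in% c("number", "Sum", "sum")]
    }
    m <- as.matrix(df[, pc_cols, drop = FALSE])
    if ("landmark" %in% names(df)) rownames(m) <- df$landmark
  }
  if (!is.numeric(m) || any(m < 0) || !all(is.finite(m))) {
    stop("magnitudes must be a non-negative numeric matrix", call. = FALSE)
  }
  m
}

#' Landmark totals and normalized percentages
#'
#' Row sums of the weighted magnitude table and each landmark's share of the
#' total, as a percentage: `S_l = sum_k m[l,k]`,
#' `N_l = 100 * S_l / sum_l S_l`. The normalization denominator is the total
#' over the displayed components only.
#'
#' @param table A [weighted_landmark_magnitudes()] table, or any data frame /
#'   matrix of non-negative per-landmark, per-PC magnitudes (e.g. a published
#'   summary table).
#' @return A tibble with `landmark`, `sum`, and `norm_pct`.
#' @export
landmark_totals <- function(table) {
  m <- magnitude_matrix(table)
  S <- unname(rowSums(m))
  tot <- sum(S)
  if (tot <= 0) stop("all-zero magnitude table", call. = FALSE)
  tibble::tibble(
    landmark = if (!is.null(rownames(m))) rownames(m)
               else paste0("L", seq_len(nrow(m))),
    sum = S,
    norm_pct = 100 * S / tot
  )
}

#' Share of one component's magnitude carried by a landmark set
#'
#' `100 * sum(m[set, k]) / sum(m[, k])`: the percentage of component `k`'s
#' summed weighted magnitude contributed by the chosen landmarks (e.g. the
#' dorsal-, pectoral- and pelvic-fin insertions).
#'
#' @inheritParams landmark_totals
#' @param k Component (column) index.
#' @param landmarks Integer indices or landmark names (row names) selecting
#'   the set.
#' @return A percentage.
#' @export
group_fraction <- function(table, k, landmarks) {
  m <- magnitude_matrix(table)
  if (k < 1 || k > ncol(m)) {
    stop("component index k out of range", call. = FALSE)
  }
  if (is.character(landmarks)) {
    idx <- match(landmarks, rownames(m))
    if (anyNA(idx)) {
      stop("unknown landmark(s): ",
           paste(landmarks[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- as.integer(landmarks)
    if (length(idx) == 0 || any(idx < 1) || any(idx > nrow(m))) {
      stop("landmark indices out of range", call. = FALSE)
    }
  }
  100 * sum(m[idx, k]) / sum(m[, k])
}

#' Per-column magnitude fractions
#'
#' `f[l, k] = m[l, k] / sum_l m[l, k]`; each column sums to 1.
#'
#' @inheritParams landmark_totals
#' @return A tibble shaped like the input with fractional columns.
#' @export
column_fractions <- function(table) {
  m <- magnitude_matrix(table)
  f <- sweep(m, 2, colSums(m), "/")
  out <- tibble::as_tibble(f)
  tibble::add_column(
    out,
    landmark = if (!is.null(rownames(m))) rownames(m)
               else paste0("L", seq_len(nrow(m))),
    .before = 1
  )
}

#' Anatomical-axis variance decomposition
#'
#' Total shape variance split by coordinate axis and reported under the
#' anatomical role each axis plays (anteroposterior = length, dorsoventral =
#' depth, mediolateral = width): for axis `d`,
#' `V_d = sum_l var_i(aligned[l, d, i])` (sample variance over specimens),
#' and the fractions `V_d / sum(V)`.
#'
#' By default the decomposition is computed from the raw aligned
#' coordinates, i.e. over all components; pass a fitted `model` and `K` to
#' restrict it to the leading `K` components via the identical eigen-route
#' `V_d = sum_k lambda_k sum_l e_k[l, d]^2`.
#'
#' @param alignment A [gpa()] fit.
#' @param scheme A [landmark_scheme()] supplying `axis_roles`; defaults to
#'   the alignment's scheme (or the internal AP/DV/ML column order).
#' @param model Optional [fit_pca()] model for the eigen-route.
#' @param K With `model`: number of leading components to include
#'   (default: all).
#' @return An `axis_decomposition` tibble with `role`, `variance`,
#'   `fraction`, ordered anteroposterior, dorsoventral, mediolateral.
#' @export
axis_variance_decomposition <- function(alignment, scheme = NULL,
                                        model = NULL, K = NULL) {
  if (is.null(scheme)) {
    scheme <- if (inherits(alignment, "gpa_fit")) alignment$scheme else NULL
  }
  roles <- if (!is.null(scheme)) scheme$axis_roles
           else c("anteroposterior", "dorsoventral", "mediolateral")
  if (is.null(model)) {
    stopifnot(inherits(alignment, "gpa_fit"))
    arr <- alignment$aligned
    if (dim(arr)[3] < 2) stop("need at least 2 specimens", call. = FALSE)
    V <- vapply(1:3, function(d) {
      sum(apply(arr[, d, , drop = TRUE], 1, stats::var))
    }, numeric(1))
  } else {
    if (is.null(K)) K <- length(model$eigenvalues)
    K <- check_K(model, K)
    V <- vapply(1:3, function(d) {
      sum(vapply(seq_len(K), function(k) {
        field <- matrix(model$vectors[, k], nrow = model$p, ncol = 3,
                        byrow = TRUE)
        model$eigenvalues[k] * sum(field[, d]^2)
      }, numeric(1)))
    }, numeric(1))
  }
  names(V) <- roles
  ord <- c("anteroposterior", "dorsoventral", "mediolateral")
  V <- V[ord]
  out <- tibble::tibble(
    role = ord,
    variance = unname(V),
    fraction = if (sum(V) > 0) unname(V) / sum(V) else rep(NA_real_, 3)
  )
  class(out) <- c("axis_decomposition", class(out))
  out
}

#' Bar chart of the axis variance decomposition
#'
#' @param object An [axis_variance_decomposition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.axis_decomposition <- function(object, ...) {
  lab <- c(anteroposterior = "length\n(anteroposterior)",
           dorsoventral = "depth\n(dorsoventral)",
           mediolateral = "width\n(mediolateral)")
  df <- dplyr::mutate(object, label = lab[.data$role])
  ggplot2::ggplot(df, ggplot2::aes(.data$label, 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%",
                                                    100 * .data$fraction)),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "% of total shape variance") +
    ggplot2::theme_minimal()
}

#' Ranked contribution report
#'
#' Writes the weighted-magnitude table as a CSV ranked by total magnitude
#' (columns `Landmark`, `L#`, `PC1..PCK`, `Sum`, `Norm(%)`; magnitudes
#' rounded to 3 decimals, percentages to 2) and the axis decomposition as
#' JSON.
#'
#' @param table A [weighted_landmark_magnitudes()] table.
#' @param decomposition An [axis_variance_decomposition()] tibble.
#' @param dir Output directory (created if needed).
#' @param rank_by `"sum"` (descending total, the default) or `"scheme"`
#'   (scheme order).
#' @return Invisibly, the paths written.
#' @export
render_contribution_report <- function(table, decomposition, dir,
                                       rank_by = c("sum", "scheme")) {
  rank_by <- match.arg(rank_by)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- magnitude_matrix(table)
  totals <- landmark_totals(table)
  df <- data.frame(
    Landmark = totals$landmark,
    `L#` = if ("number" %in% names(table)) table$number else seq_len(nrow(m)),
    round(m, 3),
    Sum = round(totals$sum, 3),
    `Norm(%)` = round(totals$norm_pct, 2),
    check.names = FALSE
  )
  if (rank_by == "sum") df <- df[order(-df$Sum), ]
  table_path <- file.path(dir, "contribution_table.csv")
  utils::write.csv(df, table_path, row.names = FALSE)
  axis_path <- file.path(dir, "axis_decomposition.json")
  jsonlite::write_json(
    list(
      variance = as.list(stats::setNames(decomposition$variance,
                                         decomposition$role)),
      fraction = as.list(stats::setNames(decomposition$fraction,
                                         decomposition$role))
    ),
    axis_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(table = table_path, axis = axis_path))
}

#' Published weighted eigenvector-magnitude summary for Lower Mississippi
#' Basin fishes
#'
#' The published 11-landmark by 6-component table of variance-weighted 3D
#' eigenvector magnitudes from a geometric-morphometric survey of adult body
#' shape across the Lower Mississippi Basin fish fauna (232 specimens, 166
#' species; top six components carrying 95% of total shape variance). Useful
#' as a worked example for [landmark_totals()] and [group_fraction()].
#'
#' @return A tibble with `landmark`, `number`, and `PC1..PC6` magnitude
#'   columns, in scheme order.
#' @export
lmb_magnitude_table <- function() {
  tibble::tribble(
    ~landmark, ~number, ~PC1, ~PC2, ~PC3, ~PC4, ~PC5, ~PC6,
    "Tip snout",             1L, 0.121, 0.019, 0.031, 0.031, 0.027, 0.012,
    "Left eye",              2L, 0.074, 0.031, 0.008, 0.005, 0.008, 0.006,
    "Left P1",               3L, 0.136, 0.028, 0.028, 0.018, 0.020, 0.012,
    "Left P2",               4L, 0.189, 0.067, 0.036, 0.015, 0.014, 0.005,
    "AF anterior insertion", 5L, 0.101, 0.041, 0.058, 0.047, 0.018, 0.007,
    "Left Hypural",          6L, 0.099, 0.033, 0.026, 0.014, 0.007, 0.003,
    "DF anterior insertion", 7L, 0.312, 0.093, 0.090, 0.002, 0.011, 0.007,
    "Right eye",             8L, 0.074, 0.032, 0.009, 0.007, 0.008, 0.006,
    "Right P1",              9L, 0.135, 0.029, 0.028, 0.017, 0.021, 0.011,
    "Right P2",             10L, 0.190, 0.066, 0.035, 0.015, 0.014, 0.005,
    "Right Hypural",        11L, 0.099, 0.033, 0.026, 0.014, 0.007, 0.002
  )
}
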