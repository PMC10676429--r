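#' Define a landmark scheme
#'
#' A landmark scheme fixes the identity, order and anatomy of the landmarks
#' digitised on every specimen: the ordered landmark names, their integer
#' labels, which landmarks form bilateral (left/right) pairs, and which
#' anatomical role each of the three coordinate columns plays.
#'
#' Coordinates are never permuted by the package; `axis_roles` is metadata
#' that downstream functions (notably [axis_variance_decomposition()]) use to
#' report per-axis quantities under anatomical names. A dataset digitised in
#' Slicer RAS space typically declares `c("mediolateral", "anteroposterior",
#' "dorsoventral")`, while the synthetic template uses the anteroposterior /
#' dorsoventral / mediolateral column order.
#'
#' @param landmark_names Character vector of unique landmark names, in scheme
#'   order.
#' @param landmark_numbers Integer labels for the landmarks (defaults to
#'   `seq_along(landmark_names)`).
#' @param bilateral_pairs List of length-2 integer vectors, each giving the
#'   (left, right) scheme indices of one bilateral landmark pair.
#' @param axis_roles Character vector of length 3 assigning one anatomical
#'   role to each coordinate column; must be a permutation of
#'   `"anteroposterior"`, `"dorsoventral"`, `"mediolateral"`.
#'
#' @return An object of class `landmark_scheme`.
#' @seealso [fish_landmark_scheme()] for the default 11-landmark fish scheme.
#' @export
landmark_scheme <- function(landmark_names,
                            landmark_numbers = seq_along(landmark_names),
                            bilateral_pairs = list(),
                            axis_roles = c("anteroposterior",
                                           "dorsoventral",
                                           "mediolateral")) {
  landmark_names <- as.character(landmark_names)
  p <- length(landmark_names)
  if (p < 3) {
    stop("a landmark scheme needs at least 3 landmarks, got ", p, call. = FALSE)
  }
  if (anyDuplicated(landmark_names)) {
    stop("landmark names must be unique", call. = FALSE)
  }
  landmark_numbers <- as.integer(landmark_numbers)
  if (length(landmark_numbers) != p) {
    stop("landmark_numbers must match landmark_names in length", call. = FALSE)
  }
  bilateral_pairs <- lapply(bilateral_pairs, function(pr) {
    pr <- as.integer(pr)
    if (length(pr) != 2 || anyNA(pr) || any(pr < 1) || any(pr > p) ||
        pr[1] == pr[2]) {
      stop("each bilateral pair must be two distinct valid landmark indices",
           call. = FALSE)
    }
    pr
  })
  roles <- c("anteroposterior", "dorsoventral", "mediolateral")
  axis_roles <- as.character(axis_roles)
  if (length(axis_roles) != 3 || !setequal(axis_roles, roles)) {
    stop("axis_roles must assign each of anteroposterior, dorsoventral and ",
         "mediolateral to exactly one coordinate column", call. = FALSE)
  }
  structure(
    list(
      landmark_names = landmark_names,
      landmark_numbers = landmark_numbers,
      bilateral_pairs = bilateral_pairs,
      axis_roles = axis_roles
    ),
    class = "landmark_scheme"
  )
}

#' The default 11-landmark fish body scheme
#'
#' Eleven homologous external landmarks spanning the head and post-cranial
#' body of a fish: tip of snout, eyes, pectoral (P1) and pelvic (P2) fin
#' insertions, dorsal-fin (DF) and anal-fin (AF) anterior insertions, and the
#' posterior hypural margins. Eyes, P1, P2 and hypural landmarks form
#' bilateral pairs.
#'
#' @param axis_roles Passed to [landmark_scheme()]; defaults to the internal
#'   anteroposterior / dorsoventral / mediolateral column order used by the
#'   synthetic generator. Datasets digitised in RAS space usually want
#'   `c("mediolateral", "anteroposterior", "dorsoventral")`.
#'
#' @return A `landmark_scheme` with 11 landmarks.
#' @export
#' @examples
#' sch <- fish_landmark_scheme()
#' sch$landmark_names
fish_landmark_scheme <- function(axis_roles = c("anteroposterior",
                                                "dorsoventral",
                                                "mediolateral")) {
  landmark_scheme(
    landmark_names = c(
      "Tip snout", "Left eye", "Left P1", "Left P2",
      "AF anterior insertion", "Left Hypural", "DF anterior insertion",
      "Right eye", "Right P1", "Right P2", "Right Hypural"
    ),
    landmark_numbers = 1:11,
    bilateral_pairs = list(c(2L, 8L), c(3L, 9L), c(4L, 10L), c(6L, 11L)),
    axis_roles = axis_roles
  )
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("<landmark_scheme> ", length(x$landmark_names), " landmarks, ",
      length(x$bilateral_pairs), " bilateral pairs\n", sep = "")
  cat("  axes:", paste(x$axis_roles, collapse = " / "), "\n")
  cat("  ", paste0(x$landmark_numbers, ":", x$landmark_names,
                   collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_landmarks <- function(scheme) length(scheme$landmark_names)

# column index of one anatomical role in a scheme
axis_column <- function(scheme, role) {
  match(role, scheme$axis_roles)
}

schemes_identical <- function(a, b) {
  identical(a$landmark_names, b$landmark_names) &&
    identical(a$landmark_numbers, b$landmark_numbers) &&
    identical(a$bilateral_pairs, b$bilateral_pairs) &&
    identical(a$axis_roles, b$axis_roles)
}
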