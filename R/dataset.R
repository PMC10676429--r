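#' Construct a single-specimen landmark configuration
#'
#' A configuration is one specimen's full set of 3D landmark coordinates,
#' treated as one geometric object, plus identity metadata (specimen, species,
#' family, nested-clade group).
#'
#' @param coords Numeric p x 3 matrix of landmark coordinates, rows in scheme
#'   order. All entries must be finite.
#' @param specimen_id,species,family Character identity metadata.
#' @param group One of `"non-teleost"`, `"non-acanthomorph teleost"`,
#'   `"non-ovalentarian acanthomorph"`, `"ovalentarian acanthomorph"`,
#'   `"excluded"`, `"synthetic"`.
#' @param scheme A [landmark_scheme()].
#'
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(coords, specimen_id, species = specimen_id,
                            family = NA_character_,
                            group = "synthetic",
                            scheme = fish_landmark_scheme()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  p <- n_landmarks(scheme)
  if (nrow(coords) != p || ncol(coords) != 3) {
    stop("specimen '", specimen_id, "': coords must be ", p,
         " x 3 to match the scheme, got ", nrow(coords), " x ", ncol(coords),
         call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    bad <- scheme$landmark_names[!stats::complete.cases(coords) |
                                   rowSums(!is.finite(coords)) > 0]
    stop("specimen '", specimen_id, "': non-finite coordinates at landmark(s) ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  group <- match.arg(group, landmark_groups())
  rownames(coords) <- scheme$landmark_names
  colnames(coords) <- scheme$axis_roles
  structure(
    list(
      specimen_id = as.character(specimen_id),
      species = as.character(species),
      family = as.character(family),
      group = group,
      coords = coords,
      scheme = scheme
    ),
    class = "landmark_config"
  )
}

#' Recognised nested-clade group labels
#'
#' Four nested clade categories used for morphospace occupancy, plus
#' `"excluded"` (loaded but left out of alignment, e.g. taxa lacking
#' homologous fin landmarks) and `"synthetic"` for generated data.
#'
#' @return Character vector of group labels.
#' @export
landmark_groups <- function() {
  c("non-teleost", "non-acanthomorph teleost",
    "non-ovalentarian acanthomorph", "ovalentarian acanthomorph",
    "excluded", "synthetic")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("<landmark_config> ", x$specimen_id, " (", x$species, ", group: ",
      x$group, ")\n", sep = "")
  print(round(x$coords, 4))
  invisible(x)
}

#' Assemble configurations into a dataset
#'
#' @param configs List of [landmark_config()] objects sharing one scheme.
#' @param scheme The shared [landmark_scheme()]; defaults to the first
#'   configuration's scheme.
#' @param provenance Optional free-text provenance note.
#'
#' @return An object of class `landmark_dataset`.
#' @export
landmark_dataset <- function(configs, scheme = NULL, provenance = character()) {
  if (length(configs) < 1) stop("empty dataset", call. = FALSE)
  if (is.null(scheme)) scheme <- configs[[1]]$scheme
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  if (anyDuplicated(ids)) {
    stop("duplicate specimen_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ok <- vapply(configs, function(cf) schemes_identical(cf$scheme, scheme),
               logical(1))
  if (!all(ok)) {
    stop("all configurations must share the identical landmark scheme",
         call. = FALSE)
  }
  names(configs) <- ids
  structure(
    list(scheme = scheme, configs = configs, provenance = provenance),
    class = "landmark_dataset"
  )
}

#' @export
print.landmark_dataset <- function(x, ...) {
  meta <- dataset_meta(x)
  cat("<landmark_dataset> ", length(x$configs), " specimens, ",
      dplyr::n_distinct(meta$species), " species, ",
      n_landmarks(x$scheme), " landmarks\n", sep = "")
  n_excl <- sum(meta$group == "excluded")
  if (n_excl > 0) cat("  (", n_excl, " excluded from alignment)\n", sep = "")
  invisible(x)
}

#' @export
length.landmark_dataset <- function(x) length(x$configs)

#' Specimen metadata as a tibble
#'
#' @param dataset A `landmark_dataset`.
#' @return A tibble with one row per specimen: `specimen_id`, `species`,
#'   `family`, `group`, `analyzable` (FALSE for the `"excluded"` group).
#' @export
dataset_meta <- function(dataset) {
  purrr::map_dfr(dataset$configs, function(cf) {
    tibble::tibble(
      specimen_id = cf$specimen_id, species = cf$species,
      family = cf$family, group = cf$group,
      analyzable = cf$group != "excluded"
    )
  })
}

#' Drop specimens flagged as excluded
#'
#' @param dataset A `landmark_dataset`.
#' @return The dataset restricted to analyzable specimens.
#' @export
analyzable_subset <- function(dataset) {
  keep <- purrr::map_lgl(dataset$configs, ~ .x$group != "excluded")
  if (!any(keep)) stop("no analyzable specimens in dataset", call. = FALSE)
  landmark_dataset(dataset$configs[keep], scheme = dataset$scheme,
                   provenance = dataset$provenance)
}

#' Coordinates of a dataset as a p x 3 x n array
#'
#' @param dataset A `landmark_dataset`.
#' @return Numeric array with dimnames (landmark, axis role, specimen).
#' @export
dataset_array <- function(dataset) {
  p <- n_landmarks(dataset$scheme)
  arr <- array(
    unlist(lapply(dataset$configs, `[[`, "coords"), use.names = FALSE),
    dim = c(p, 3, length(dataset$configs)),
    dimnames = list(dataset$scheme$landmark_names, dataset$scheme$axis_roles,
                    names(dataset$configs))
  )
  arr
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long-format coordinates of a configuration or dataset
#'
#' @param x A `landmark_config` or `landmark_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `specimen_id`, `landmark`, `number`, and one
#'   column per coordinate axis named by its anatomical role.
#' @export
as_tibble.landmark_config <- function(x, ...) {
  out <- tibble::as_tibble(x$coords)
  tibble::add_column(
    out,
    specimen_id = x$specimen_id,
    landmark = x$scheme$landmark_names,
    number = x$scheme$landmark_numbers,
    .before = 1
  )
}

#' @rdname as_tibble.landmark_config
#' @export
as_tibble.landmark_dataset <- function(x, ...) {
  purrr::map_dfr(x$configs, as_tibble)
}
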