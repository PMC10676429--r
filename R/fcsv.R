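#' Read a 3D Slicer markups fiducial (.fcsv) file
#'
#' Parses the Slicer 4.x markups fiducial format: comment header lines
#' beginning with `#` (including an optional `# CoordinateSystem` declaration)
#' followed by CSV rows
#' `id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID`.
#' Rows are matched to the scheme by the `label` column (exact match after
#' whitespace trimming) and reordered to scheme order, so fiducial placement
#' order in Slicer is irrelevant. Files declaring the LPS coordinate system
#' (`# CoordinateSystem = LPS`, or the legacy numeric `= 0`) have their first
#' two coordinate columns negated into the internal RAS-like convention;
#' RAS files pass through unchanged.
#'
#' Missing or duplicated landmark labels, extra labels, a wrong landmark
#' count, or non-finite coordinates are hard errors naming the specimen and
#' the offending labels: specimens lacking homologous landmarks are excluded,
#' never imputed.
#'
#' @param path Path to the `.fcsv` file.
#' @param scheme A [landmark_scheme()]; its `axis_roles` should describe how
#'   the file's RAS axes map onto anatomical roles.
#' @param specimen_id Specimen identifier (default: file name without
#'   extension).
#' @param species,family,group Metadata passed to [landmark_config()].
#'
#' @return A [landmark_config()].
#' @export
read_fcsv <- function(path, scheme = fish_landmark_scheme(),
                      specimen_id = sub("\\.fcsv$", "", basename(path)),
                      species = specimen_id, family = NA_character_,
                      group = "synthetic") {
  if (!file.exists(path)) {
    stop("fcsv file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0) {
    stop("specimen '", specimen_id, "': fcsv file '", path,
         "' contains no fiducial rows", call. = FALSE)
  }
  cs <- fcsv_coordinate_system(header, path)
  df <- utils::read.csv(text = body, header = FALSE,
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 12) {
    stop("specimen '", specimen_id, "': fcsv file '", path,
         "' has fewer than 12 columns; not a markups fiducial file",
         call. = FALSE)
  }
  labels <- trimws(df[[12]])
  coords <- cbind(as.numeric(df[[2]]), as.numeric(df[[3]]),
                  as.numeric(df[[4]]))
  if (cs == "LPS") {
    coords[, 1:2] <- -coords[, 1:2]
  }

  wanted <- scheme$landmark_names
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0) {
    stop("specimen '", specimen_id, "': duplicate landmark label(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(wanted, labels)
  if (length(missing) > 0) {
    stop("specimen '", specimen_id, "': missing landmark label(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(labels, wanted)
  if (length(extra) > 0) {
    stop("specimen '", specimen_id, "': unknown landmark label(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  ord <- match(wanted, labels)
  coords <- coords[ord, , drop = FALSE]
  bad <- wanted[rowSums(!is.finite(coords)) > 0]
  if (length(bad) > 0) {
    stop("specimen '", specimen_id, "': non-finite coordinate at landmark(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  landmark_config(coords, specimen_id = specimen_id, species = species,
                  family = family, group = group, scheme = scheme)
}

fcsv_coordinate_system <- function(header, path) {
  cs_line <- grep("CoordinateSystem", header, value = TRUE)
  if (length(cs_line) == 0) return("RAS")
  val <- trimws(sub(".*=", "", cs_line[1]))
  if (val %in% c("LPS", "0")) return("LPS")
  if (val %in% c("RAS", "1")) return("RAS")
  stop("unrecognised fcsv coordinate system '", val, "' in ", path,
       call. = FALSE)
}

#' Write a configuration as a Slicer markups fiducial file
#'
#' Emits a Slicer 4.11-style `.fcsv` with full-precision coordinates; reading
#' the file back with [read_fcsv()] reproduces the coordinates to 1e-9.
#'
#' @param config A [landmark_config()].
#' @param path Output path.
#' @param coordinate_system `"RAS"` (default) or `"LPS"`; LPS output negates
#'   the first two coordinate columns on write (and [read_fcsv()] negates
#'   them back).
#' @return Invisibly, `path`.
#' @export
write_fcsv <- function(config, path, coordinate_system = c("RAS", "LPS")) {
  if (!inherits(config, "landmark_config")) {
    stop("`config` must be a landmark_config", call. = FALSE)
  }
  coordinate_system <- match.arg(coordinate_system)
  coords <- config$coords
  if (coordinate_system == "LPS") coords[, 1:2] <- -coords[, 1:2]
  rows <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("vtkMRMLMarkupsFiducialNode_%d,%.17g,%.17g,%.17g,0,0,0,1,1,1,0,%s,,",
            i - 1, coords[i, 1], coords[i, 2], coords[i, 3],
            config$scheme$landmark_names[i])
  }, character(1))
  out <- c(
    "# Markups fiducial file version = 4.11",
    paste0("# CoordinateSystem = ", coordinate_system),
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    rows
  )
  ok <- tryCatch({
    writeLines(out, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write fcsv file: ", path, call. = FALSE)
  invisible(path)
}

#' Read a dataset from a manifest CSV
#'
#' The manifest maps specimens to fcsv files and metadata, with columns
#' `specimen_id`, `path`, `species`, `family`, `group`. Relative `path`
#' entries are resolved against the manifest's directory. Rows with group
#' `"excluded"` are loaded but flagged, and dropped from alignment by
#' default (see [analyzable_subset()]).
#'
#' @param manifest Path to the manifest CSV.
#' @param scheme A [landmark_scheme()].
#' @return A [landmark_dataset()].
#' @export
read_dataset <- function(manifest, scheme = fish_landmark_scheme()) {
  if (!file.exists(manifest)) {
    stop("manifest not found: ", manifest, call. = FALSE)
  }
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("specimen_id", "path", "species", "family", "group")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$specimen_id)) {
    stop("manifest has duplicate specimen_id(s): ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]),
               collapse = ", "), call. = FALSE)
  }
  base <- dirname(manifest)
  configs <- lapply(seq_len(nrow(df)), function(i) {
    fp <- df$path[i]
    if (!file.exists(fp)) fp <- file.path(base, df$path[i])
    if (!file.exists(fp)) {
      stop("manifest row ", i, " (specimen '", df$specimen_id[i],
           "'): fcsv file not found: ", df$path[i], call. = FALSE)
    }
    read_fcsv(fp, scheme = scheme, specimen_id = df$specimen_id[i],
              species = df$species[i], family = df$family[i],
              group = df$group[i])
  })
  landmark_dataset(configs, scheme = scheme,
                   provenance = paste0("manifest: ", manifest))
}

#' Read/write the flat one-row-per-specimen coordinate matrix dialect
#'
#' A plain CSV with columns `specimen_id`, `species`, `family`, `group`, then
#' one column per landmark/axis named `<landmark>_<axis role>`.
#'
#' @param dataset A [landmark_dataset()].
#' @param path CSV path.
#' @return `write_flat_csv()` returns `path` invisibly; `read_flat_csv()`
#'   returns a [landmark_dataset()].
#' @export
write_flat_csv <- function(dataset, path) {
  scheme <- dataset$scheme
  arr <- dataset_array(dataset)
  flat <- t(apply(arr, 3, function(m) as.vector(t(m))))
  cn <- as.vector(t(outer(scheme$landmark_names, scheme$axis_roles,
                          paste, sep = "_")))
  meta <- dataset_meta(dataset)
  out <- cbind(meta[, c("specimen_id", "species", "family", "group")],
               as.data.frame(flat))
  names(out) <- c("specimen_id", "species", "family", "group", cn)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flat_csv
#' @param scheme A [landmark_scheme()].
#' @export
read_flat_csv <- function(path, scheme = fish_landmark_scheme()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cn <- as.vector(t(outer(scheme$landmark_names, scheme$axis_roles,
                          paste, sep = "_")))
  miss <- setdiff(cn, names(df))
  if (length(miss) > 0) {
    stop("flat CSV is missing coordinate column(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ...", call. = FALSE)
  }
  p <- n_landmarks(scheme)
  configs <- lapply(seq_len(nrow(df)), function(i) {
    coords <- matrix(as.numeric(df[i, cn]), nrow = p, ncol = 3, byrow = TRUE)
    landmark_config(
      coords,
      specimen_id = df$specimen_id[i],
      species = if ("species" %in% names(df)) df$species[i] else df$specimen_id[i],
      family = if ("family" %in% names(df)) df$family[i] else NA_character_,
      group = if ("group" %in% names(df)) df$group[i] else "synthetic",
      scheme = scheme
    )
  })
  landmark_dataset(configs, scheme = scheme,
                   provenance = paste0("flat csv: ", path))
}
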