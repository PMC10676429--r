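#' Configure an end-to-end analysis run
#'
#' Bundles every choice of a full analysis — input mode, scheme, GPA
#' settings, component-retention policy, report rounding, output directory
#' and seed — into one validated object for [run_pipeline()].
#'
#' @param input `"simulate"`, `"fcsv-manifest"`, or `"flat-csv"`.
#' @param manifest Manifest CSV path (for `"fcsv-manifest"`).
#' @param flat_csv Flat coordinate CSV path (for `"flat-csv"`).
#' @param fauna A [fauna_spec()] (for `"simulate"`; defaults to
#'   `fauna_spec(seed = seed)`).
#' @param scheme A [landmark_scheme()].
#' @param tolerance,max_iterations GPA settings, see [gpa()].
#' @param K Fixed number of retained components, or `NULL` to retain by
#'   cumulative variance.
#' @param var_threshold Cumulative variance threshold when `K` is `NULL`.
#' @param pc_pair Component plane for the occupancy hulls.
#' @param out_dir Output directory.
#' @param seed Integer seed (simulation mode).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = c("simulate", "fcsv-manifest", "flat-csv"),
                            manifest = NULL, flat_csv = NULL, fauna = NULL,
                            scheme = fish_landmark_scheme(),
                            tolerance = 1e-8, max_iterations = 100,
                            K = NULL, var_threshold = 0.95,
                            pc_pair = c(1, 2),
                            out_dir = tempfile("finmorph_run_"),
                            seed = 1L) {
  input <- match.arg(input)
  if (input == "fcsv-manifest" && is.null(manifest)) {
    stop("manifest is required for fcsv-manifest input", call. = FALSE)
  }
  if (input == "flat-csv" && is.null(flat_csv)) {
    stop("flat_csv is required for flat-csv input", call. = FALSE)
  }
  if (input == "simulate" && is.null(fauna)) {
    fauna <- fauna_spec(seed = seed)
  }
  if (!is.null(K)) K <- as.integer(K)
  if (var_threshold <= 0 || var_threshold > 1) {
    stop("var_threshold must be in (0, 1]", call. = FALSE)
  }
  if (tolerance <= 0 || max_iterations < 1) {
    stop("invalid GPA settings", call. = FALSE)
  }
  structure(
    list(input = input, manifest = manifest, flat_csv = flat_csv,
         fauna = fauna, scheme = scheme, tolerance = tolerance,
         max_iterations = max_iterations, K = K,
         var_threshold = var_threshold, pc_pair = pc_pair,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Ingests or simulates a landmark dataset, aligns it with [gpa()], fits the
#' morphospace with [fit_pca()], computes the weighted landmark-magnitude
#' table, the anatomical-axis variance decomposition and the group occupancy
#' hulls, and writes every artifact as plain CSV/JSON/fcsv into the run
#' directory:
#' `aligned.csv`, `consensus.fcsv`, `scores_specimen.csv`,
#' `scores_species.csv`, `eigenvalues.csv`, `contribution_table.csv`,
#' `axis_decomposition.json`, `hulls.json`, and `run_log.json` (settings,
#' seed, convergence, K — enough to reproduce the run exactly). Runs are
#' deterministic given identical config and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `dataset`, `alignment`, `model`, `table`,
#'   `decomposition`, `occupancy`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  dataset <- switch(
    config$input,
    "simulate" = generate_fauna(config$fauna)$dataset,
    "fcsv-manifest" = read_dataset(config$manifest, scheme = config$scheme),
    "flat-csv" = read_flat_csv(config$flat_csv, scheme = config$scheme)
  )

  alignment <- gpa(dataset, tolerance = config$tolerance,
                   max_iterations = config$max_iterations)
  model <- fit_pca(alignment, var_threshold = config$var_threshold)
  K <- if (!is.null(config$K)) check_K(model, config$K) else model$K_retained
  table <- weighted_landmark_magnitudes(model, K = K)
  decomposition <- axis_variance_decomposition(alignment)
  occupancy <- group_occupancy(model, pc_pair = config$pc_pair)

  out <- config$out_dir
  write_flat_csv(aligned_as_dataset(alignment), file.path(out, "aligned.csv"))
  write_fcsv(
    landmark_config(alignment$consensus, specimen_id = "consensus",
                    scheme = dataset$scheme),
    file.path(out, "consensus.fcsv")
  )
  utils::write.csv(pca_scores(model, "specimen", K = K),
                   file.path(out, "scores_specimen.csv"), row.names = FALSE)
  utils::write.csv(pca_scores(model, "species", K = K),
                   file.path(out, "scores_species.csv"), row.names = FALSE)
  utils::write.csv(tidy(model), file.path(out, "eigenvalues.csv"),
                   row.names = FALSE)
  render_contribution_report(table, decomposition, out)
  jsonlite::write_json(
    lapply(seq_len(nrow(occupancy)), function(i) {
      list(group = occupancy$group[i],
           n_species = occupancy$n_species[i],
           area = occupancy$area[i],
           hull = unname(apply(occupancy$hull[[i]], 1, as.list)))
    }),
    file.path(out, "hulls.json"), digits = NA, auto_unbox = TRUE
  )
  jsonlite::write_json(
    list(
      input = config$input, seed = config$seed,
      tolerance = config$tolerance,
      max_iterations = config$max_iterations,
      iterations = alignment$iterations,
      final_change = alignment$final_change,
      K = K, var_threshold = config$var_threshold,
      n_specimens = nrow(model$scores), n_landmarks = model$p,
      package_version = as.character(utils::packageVersion("finmorph"))
    ),
    file.path(out, "run_log.json"), digits = NA, auto_unbox = TRUE
  )

  invisible(list(dataset = dataset, alignment = alignment, model = model,
                 table = table, decomposition = decomposition,
                 occupancy = occupancy, out_dir = out))
}

# re-wrap aligned coordinates as a dataset so they share the writers
aligned_as_dataset <- function(alignment) {
  arr <- alignment$aligned
  scheme <- alignment$scheme
  if (is.null(scheme)) {
    scheme <- landmark_scheme(paste0("L", seq_len(dim(arr)[1])))
  }
  configs <- lapply(seq_len(dim(arr)[3]), function(i) {
    landmark_config(arr[, , i],
                    specimen_id = alignment$meta$specimen_id[i],
                    species = alignment$meta$species[i],
                    family = alignment$meta$family[i],
                    group = alignment$meta$group[i],
                    scheme = scheme)
  })
  landmark_dataset(configs, scheme = scheme, provenance = "aligned")
}
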