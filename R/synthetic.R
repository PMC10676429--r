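#' Template fish configuration
#'
#' An idealised fusiform 11-landmark fish in the internal anatomical axis
#' order (column 1 anteroposterior, 2 dorsoventral, 3 mediolateral): standard
#' length 1.0 from snout tip to the hypural margin, dorsal-fin insertion 0.25
#' standard lengths above the midline near midbody and vertically aligned
#' with the pelvic fins, eyes within a head of ~0.3 standard lengths, and
#' bilateral pairs mirrored across the midsagittal plane.
#'
#' @return A 11 x 3 matrix in [fish_landmark_scheme()] order.
#' @export
default_template <- function() {
  m <- rbind(
    "Tip snout"             = c(0.00,  0.00,  0.00),
    "Left eye"              = c(0.15,  0.08,  0.06),
    "Left P1"               = c(0.30, -0.08,  0.07),
    "Left P2"               = c(0.45, -0.12,  0.05),
    "AF anterior insertion" = c(0.65, -0.10,  0.00),
    "Left Hypural"          = c(1.00,  0.00,  0.02),
    "DF anterior insertion" = c(0.45,  0.25,  0.00),
    "Right eye"             = c(0.15,  0.08, -0.06),
    "Right P1"              = c(0.30, -0.08, -0.07),
    "Right P2"              = c(0.45, -0.12, -0.05),
    "Right Hypural"         = c(1.00,  0.00, -0.02)
  )
  colnames(m) <- c("anteroposterior", "dorsoventral", "mediolateral")
  m
}

#' Default deformation modes
#'
#' Four mutually orthogonal unit-norm displacement fields on the template,
#' interpreted as distinct growth fields:
#' \describe{
#'   \item{elongation}{anteroposterior redistribution of the median and
#'     paired fin landmarks along the body axis;}
#'   \item{deepening}{dorsoventral displacement centred on the dorsal-,
#'     anal- and pelvic-fin insertions (pure depth redistribution);}
#'   \item{widening}{mediolateral displacement of the paired landmarks,
#'     mirror-antisymmetric (anterior body spreads, posterior narrows);}
#'   \item{head}{anteroposterior displacement concentrated on snout and
#'     eyes (snout length / relative head size).}
#' }
#'
#' Each field is built inside a restricted axis/landmark subspace and then
#' projected orthogonal to the similarity group at the template —
#' translations, the scale direction, and the three rotation generators —
#' so the modes are genuine shape (tangent-space) deformations that survive
#' Procrustes superimposition intact; without this, part of a mode would be
#' absorbed by the translation/scale/rotation steps of GPA and amplitude
#' recovery would be biased. The restrictions are chosen so the projection
#' preserves axis purity: the widening mode has exactly zero anteroposterior
#' and dorsoventral components, and the deepening mode's energy is 100%
#' dorsoventral. Mutual orthonormality is enforced by Gram-Schmidt after
#' construction.
#'
#' @return A named list of 11 x 3 unit-norm matrices.
#' @export
default_modes <- function() {
  tpl <- default_template()
  p <- nrow(tpl)
  sch <- fish_landmark_scheme()
  idx <- function(nm) match(nm, sch$landmark_names)
  flat_index <- function(l, d) (l - 1) * 3 + d

  # orthonormal basis of the similarity (translation/scale/rotation) space
  tpl_c <- sweep(tpl, 2, colMeans(tpl))
  sim <- matrix(0, 3 * p, 7)
  for (d in 1:3) sim[flat_index(seq_len(p), d), d] <- 1
  sim[, 4] <- as.vector(t(tpl_c))
  gen <- list(c(2, 3), c(3, 1), c(1, 2))  # rotation generators (axis pairs)
  for (g in 1:3) {
    fld <- matrix(0, p, 3)
    fld[, gen[[g]][1]] <- -tpl_c[, gen[[g]][2]]
    fld[, gen[[g]][2]] <- tpl_c[, gen[[g]][1]]
    sim[, 4 + g] <- as.vector(t(fld))
  }
  Q <- qr.Q(qr(sim))

  # one basis column per (landmark set, axis); pairs move together, except
  # mirror-antisymmetric mediolateral pairs
  pair_field <- function(landmarks, d, signs = rep(1, length(landmarks))) {
    v <- numeric(3 * p)
    v[flat_index(idx(landmarks), d)] <- signs
    v
  }
  sn <- "Tip snout"; ey <- c("Left eye", "Right eye")
  p1 <- c("Left P1", "Right P1"); p2 <- c("Left P2", "Right P2")
  af <- "AF anterior insertion"; df <- "DF anterior insertion"
  hy <- c("Left Hypural", "Right Hypural")

  # project `raw` onto span(basis) minus the similarity space
  shape_field <- function(basis, raw) {
    B <- qr.Q(qr(basis))
    A <- crossprod(Q, B)                       # similarity components of B
    u <- crossprod(B, raw)
    sv <- svd(A)
    pos <- sv$d > 1e-10
    if (any(pos)) {
      # remove the part of u seen by the similarity space
      u <- u - sv$v[, pos, drop = FALSE] %*%
        crossprod(sv$v[, pos, drop = FALSE], u)
    }
    v <- B %*% u
    as.vector(v / sqrt(sum(v^2)))
  }

  ap_fins <- cbind(pair_field(p1, 1), pair_field(p2, 1), pair_field(df, 1),
                   pair_field(af, 1), pair_field(hy, 1))
  dv_all <- cbind(pair_field(sn, 2), pair_field(ey, 2), pair_field(p1, 2),
                  pair_field(p2, 2), pair_field(af, 2), pair_field(df, 2),
                  pair_field(hy, 2))
  ml_anti <- cbind(pair_field(ey, 3, c(1, -1)), pair_field(p1, 3, c(1, -1)),
                   pair_field(p2, 3, c(1, -1)), pair_field(hy, 3, c(1, -1)))
  ap_all <- cbind(pair_field(sn, 1), pair_field(ey, 1), ap_fins)

  raw <- list(
    elongation = ap_fins %*% c(0.5, 1, 1, 1.2, 1.5),
    deepening = dv_all %*% c(0, 0, 0, -1, -1, 1.2, 0),
    widening = ml_anti %*% c(1, 1, -2, -1.5),
    head = ap_all %*% c(-1.5, -0.7, 0, 0, 0, 0, 0)
  )
  basis <- list(elongation = ap_fins, deepening = dv_all,
                widening = ml_anti, head = ap_all)
  flat <- purrr::map2(basis, raw, shape_field)

  # Gram-Schmidt for mutual orthogonality (only elongation/head overlap)
  for (i in seq_along(flat)) {
    v <- flat[[i]]
    if (i > 1) {
      for (j in seq_len(i - 1)) v <- v - sum(v * flat[[j]]) * flat[[j]]
    }
    flat[[i]] <- v / sqrt(sum(v^2))
  }
  lapply(flat, function(v) {
    matrix(v, p, 3, byrow = TRUE, dimnames = dimnames(tpl))
  })
}

#' Specify a synthetic fauna
#'
#' The generative recipe behind [generate_fauna()]: a template configuration
#' deformed by additive shape modes with species-level amplitudes, plus
#' landmark-level noise and optional nuisance rigid motions. For species `s`
#' in group `g`, amplitudes are drawn `a[s, m] ~ Normal(group_offsets[g, m],
#' mode_sd[m])`; specimen `i` of species `s` is
#' `template + sum_m a[s, m] * mode_m + noise`, with iid
#' `Normal(0, landmark_noise_sd)` noise per coordinate, then an independent
#' random proper rotation, translation and positive scale (log-uniform in
#' \[0.5, 2\]) when `nuisance = TRUE`.
#'
#' The defaults emulate the structure of a real temperate fauna: 166 species
#' in four nested clade groups, mode dispersions chosen so the leading shape
#' axes carry variance shares comparable to those reported for fish faunas.
#'
#' @param template p x 3 template matrix.
#' @param modes List of unit-norm p x 3 mode matrices.
#' @param mode_sd Per-mode species-level amplitude standard deviations.
#' @param group_offsets Group x mode matrix of mean amplitudes (default 0).
#' @param n_species Named integer vector of species counts per group.
#' @param specimens_per_species Specimens digitised per species.
#' @param landmark_noise_sd Landmark noise sd (template units).
#' @param nuisance Apply random rigid motion + scale per specimen?
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `fauna_spec` list.
#' @export
fauna_spec <- function(template = default_template(),
                       modes = default_modes(),
                       mode_sd = c(0.072, 0.040, 0.037, 0.025),
                       group_offsets = NULL,
                       n_species = c("non-teleost" = 12,
                                     "non-acanthomorph teleost" = 84,
                                     "non-ovalentarian acanthomorph" = 55,
                                     "ovalentarian acanthomorph" = 15),
                       specimens_per_species = 1,
                       landmark_noise_sd = 0.005,
                       nuisance = TRUE,
                       seed = 1L) {
  M <- length(modes)
  mode_sd <- rep_len(mode_sd, M)
  if (any(mode_sd < 0) || landmark_noise_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (specimens_per_species < 1) {
    stop("specimens_per_species must be >= 1", call. = FALSE)
  }
  G <- length(n_species)
  if (is.null(names(n_species))) {
    names(n_species) <- paste0("group", seq_len(G))
  }
  if (is.null(group_offsets)) {
    group_offsets <- matrix(0, G, M,
                            dimnames = list(names(n_species), names(modes)))
  }
  group_offsets <- as.matrix(group_offsets)
  if (nrow(group_offsets) != G || ncol(group_offsets) != M) {
    stop("group_offsets must be ", G, " groups x ", M, " modes", call. = FALSE)
  }
  for (m in modes) {
    if (!all(dim(m) == dim(template))) {
      stop("every mode must match the template's dimensions", call. = FALSE)
    }
  }
  structure(
    list(template = template, modes = modes, mode_sd = mode_sd,
         group_offsets = group_offsets, n_species = n_species,
         specimens_per_species = as.integer(specimens_per_species),
         landmark_noise_sd = landmark_noise_sd,
         nuisance = isTRUE(nuisance), seed = as.integer(seed)),
    class = "fauna_spec"
  )
}

# deterministic per-unit substream seed, kept below 2^31
substream_seed <- function(seed, stream, index) {
  (as.double(seed %% 65011) * 7919 + stream * 104729 + index * 1009) %% 2147483647
}

random_rotation <- function() {
  # uniform over proper rotations via QR of a Gaussian matrix with sign fix
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Generate a synthetic fauna with ground truth
#'
#' Draws the dataset described by a [fauna_spec()]. Random-number streams
#' are split per species (amplitudes) and per specimen (noise and nuisance
#' transforms), so changing `specimens_per_species` does not perturb the
#' species-level draws.
#'
#' @param spec A [fauna_spec()].
#' @return A list with `dataset` (a [landmark_dataset()]) and `ground_truth`
#'   (species amplitudes as a tibble, per-specimen nuisance transforms, and
#'   the generating recipe itself).
#' @export
generate_fauna <- function(spec) {
  stopifnot(inherits(spec, "fauna_spec"))
  M <- length(spec$modes)
  groups <- names(spec$n_species)
  scheme <- if (nrow(spec$template) == 11) {
    fish_landmark_scheme()
  } else {
    landmark_scheme(paste0("L", seq_len(nrow(spec$template))))
  }

  species_tbl <- purrr::map_dfr(seq_along(groups), function(g) {
    ns <- spec$n_species[g]
    if (ns == 0) return(NULL)
    tibble::tibble(
      species = sprintf("%s_sp%02d", gsub("[^a-zA-Z]", "", groups[g]),
                        seq_len(ns)),
      group = groups[g], group_index = g
    )
  })
  species_tbl$species_index <- seq_len(nrow(species_tbl))

  # species-level amplitude draws, one substream per species
  amp <- matrix(0, nrow(species_tbl), M,
                dimnames = list(species_tbl$species, names(spec$modes)))
  for (s in seq_len(nrow(species_tbl))) {
    set.seed(substream_seed(spec$seed, 1, s))
    g <- species_tbl$group_index[s]
    amp[s, ] <- stats::rnorm(M, mean = spec$group_offsets[g, ],
                             sd = spec$mode_sd)
  }

  p <- nrow(spec$template)
  configs <- list()
  transforms <- list()
  for (s in seq_len(nrow(species_tbl))) {
    shape_s <- spec$template
    for (m in seq_len(M)) shape_s <- shape_s + amp[s, m] * spec$modes[[m]]
    for (i in seq_len(spec$specimens_per_species)) {
      set.seed(substream_seed(spec$seed, 2, (s - 1) * 10000 + i))
      X <- shape_s + matrix(stats::rnorm(p * 3, sd = spec$landmark_noise_sd),
                            p, 3)
      tr <- list(rotation = diag(3), translation = c(0, 0, 0), scale = 1)
      if (spec$nuisance) {
        tr$rotation <- random_rotation()
        tr$translation <- stats::rnorm(3, sd = 0.5)
        tr$scale <- exp(stats::runif(1, log(0.5), log(2)))
        X <- tr$scale * X %*% t(tr$rotation)
        X <- sweep(X, 2, tr$translation, "+")
      }
      id <- sprintf("%s_i%02d", species_tbl$species[s], i)
      configs[[id]] <- landmark_config(
        X, specimen_id = id, species = species_tbl$species[s],
        family = species_tbl$group[s], group = "synthetic", scheme = scheme
      )
      transforms[[id]] <- tr
    }
  }
  dataset <- landmark_dataset(configs, scheme = scheme,
                              provenance = paste0("synthetic fauna, seed ",
                                                  spec$seed))
  ground_truth <- list(
    amplitudes = dplyr::bind_cols(
      species_tbl[, c("species", "group")],
      tibble::as_tibble(amp)
    ),
    transforms = transforms,
    spec = spec
  )
  list(dataset = dataset, ground_truth = ground_truth)
}

#' Write a synthetic fauna to disk as analysis fixtures
#'
#' One fcsv per specimen, a manifest CSV, and a ground-truth JSON, all
#' re-readable with [read_dataset()].
#'
#' @param fauna A [generate_fauna()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_fixtures <- function(fauna, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  dataset <- fauna$dataset
  meta <- dataset_meta(dataset)
  paths <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    cf <- dataset$configs[[meta$specimen_id[i]]]
    paths[i] <- paste0(cf$specimen_id, ".fcsv")
    write_fcsv(cf, file.path(dir, paths[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(
    data.frame(specimen_id = meta$specimen_id, path = paths,
               species = meta$species, family = meta$family,
               group = meta$group),
    manifest, row.names = FALSE
  )
  gt <- fauna$ground_truth
  jsonlite::write_json(
    list(
      amplitudes = gt$amplitudes,
      mode_sd = gt$spec$mode_sd,
      landmark_noise_sd = gt$spec$landmark_noise_sd,
      seed = gt$spec$seed
    ),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(manifest)
}
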