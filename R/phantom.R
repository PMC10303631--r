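#' Synthetic 4D PET phantom configuration
#'
#' Describes a seeded cohort of dynamic PET phantoms with a spherical
#' lesion VOI, a mirrored low-uptake reference VOI, and two response
#' classes whose separation is carried purely by spatial-temporal uptake
#' heterogeneity: the homogeneous class ("CR") uses a single uptake time
#' constant across the lesion, the heterogeneous class ("PR") partitions
#' the lesion into subregions with distinct time constants whose
#' amplitudes are adjusted so the late-window (static) mean uptake
#' matches the homogeneous class in expectation. Static intensity
#' structure is therefore matched between classes and only the temporal
#' dynamics differ.
#'
#' @param grid Grid shape in voxels (default 64 x 64 x 24, a desk-scale
#'   version of the clinical 128 x 128 x 35 matrix; pass the full matrix
#'   to reproduce it).
#' @param spacing Voxel spacing in mm (default 3.9, 3.9, 4.2).
#' @param schedule Frame schedule (default [default_frame_schedule()]).
#' @param lesion_radius Lesion sphere radius in voxels (default 4).
#' @param n_cr,n_pr Subjects per class (defaults 12 and 19, mirroring the
#'   clinical class imbalance).
#' @param tac Lesion time-activity parameters: `K` (plateau amplitude,
#'   SUV), `tau` (uptake time constant, s), `late_slope` (SUV/s).
#' @param background Background uptake parameters `K` and `tau`.
#' @param heterogeneity List: `correlation_length` (voxels) and `cv` of
#'   the shared multiplicative spatial field; `n_subregions` and
#'   `tau_range` (s) of the heterogeneous class; `amplitude_cv`
#'   (subject-level lognormal-free amplitude jitter, applied identically
#'   to both classes).
#' @param noise_scale Additive Gaussian noise scale: per-frame sd is
#'   `noise_scale / sqrt(duration_s)` (SUV), emulating duration-scaled
#'   counting noise.
#' @param dose_range_MBq Injected dose sampled uniformly in this range
#'   (default 110-204 MBq).
#' @param weight_mean_kg,weight_sd_kg Body-weight distribution (normal,
#'   truncated to 45-110 kg).
#' @param seed Cohort seed.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(64, 64, 24),
                           spacing = c(3.9, 3.9, 4.2),
                           schedule = default_frame_schedule(),
                           lesion_radius = 4,
                           n_cr = 12, n_pr = 19,
                           tac = list(K = 6, tau = 300, late_slope = 0),
                           background = list(K = 0.6, tau = 200),
                           heterogeneity = list(correlation_length = 1.5,
                                                cv = 0.3,
                                                n_subregions = 6,
                                                tau_range = c(30, 1200),
                                                amplitude_cv = 0.1),
                           noise_scale = 0.3,
                           dose_range_MBq = c(110, 204),
                           weight_mean_kg = 70, weight_sd_kg = 12,
                           seed = 1) {
  stopifnot(length(grid) == 3, all(grid > 0), all(spacing > 0),
            lesion_radius > 0, n_cr >= 0, n_pr >= 0,
            tac$K >= 0, tac$tau > 0, background$K >= 0, background$tau > 0,
            heterogeneity$cv >= 0, heterogeneity$n_subregions >= 1,
            noise_scale >= 0, all(dose_range_MBq > 0), weight_mean_kg > 0)
  if (!inherits(schedule, "frame_schedule")) {
    stop_dynomics("`schedule` must be a frame_schedule",
                  class = "dynomics_type_error")
  }
  structure(list(grid = as.integer(grid), spacing = spacing,
                 schedule = schedule, lesion_radius = lesion_radius,
                 n_cr = as.integer(n_cr), n_pr = as.integer(n_pr),
                 tac = tac, background = background,
                 heterogeneity = heterogeneity, noise_scale = noise_scale,
                 dose_range_MBq = dose_range_MBq,
                 weight_mean_kg = weight_mean_kg,
                 weight_sd_kg = weight_sd_kg, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Monotone uptake time-activity curve
#'
#' Frame value `K * (1 - exp(-t_mid / tau)) + b * t_mid` at each frame
#' midpoint: a saturating uptake curve with an optional late slope, a
#' phenomenological stand-in for tracer kinetics.
#'
#' @param K Plateau amplitude (SUV), >= 0.
#' @param tau Uptake time constant in seconds, > 0.
#' @param b Late slope in SUV/s.
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of per-frame mean activities.
#' @export
make_tac <- function(K, tau, b, schedule) {
  if (tau <= 0) {
    stop_dynomics("`tau` must be > 0", class = "dynomics_type_error")
  }
  t_mid <- frame_midpoints(schedule)
  K * (1 - exp(-t_mid / tau)) + b * t_mid
}

#' Smooth multiplicative heterogeneity field
#'
#' Seeded Gaussian white noise smoothed to the requested correlation
#' length and rescaled to mean 1 and coefficient of variation `cv`
#' (values are floored at 0.05 to keep the field positive).
#'
#' @param shape Grid shape (length 3).
#' @param correlation_length Smoothing sigma in voxels.
#' @param cv Coefficient of variation (>= 0; 0 returns a constant field).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A 3D array with mean ~1.
#' @export
make_heterogeneity_field <- function(shape, correlation_length = 1.5,
                                     cv = 0.3, seed = NULL) {
  if (cv < 0) stop_dynomics("`cv` must be >= 0", class = "dynomics_type_error")
  if (!is.null(seed)) set.seed(seed)
  if (cv == 0) return(array(1, shape))
  z <- array(rnorm(prod(shape)), shape)
  z <- gaussian_smooth3d(z, sigma = correlation_length)
  z <- (z - mean(z)) / sd(z)
  pmax(1 + cv * z, 0.05)
}

# spherical mask of radius r voxels centered at `center` (voxel units)
sphere_mask <- function(grid, center, radius) {
  x <- seq_len(grid[1]); y <- seq_len(grid[2]); z <- seq_len(grid[3])
  dx2 <- (x - center[1])^2
  dy2 <- (y - center[2])^2
  dz2 <- (z - center[3])^2
  arr <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
  arr
}

#' Generate one synthetic dynamic PET subject
#'
#' Builds a 4D series (stored in activity-concentration units so that
#' [suv_normalize()] recovers the simulated SUV values), a spherical
#' lesion mask placed in one breast position, and a mirrored reference
#' mask. The homogeneous class carries one uptake time constant across
#' the lesion; the heterogeneous class partitions the lesion into
#' seeded subregions (k-means on voxel coordinates) with time constants
#' drawn from `tau_range`, each subregion's amplitude adjusted so its
#' late-window mean uptake equals the subject's target — classes
#' therefore match in static structure and differ in dynamics.
#'
#' @param config A [phantom_config()].
#' @param class_label `"CR"` (homogeneous) or `"PR"` (heterogeneous).
#' @param seed Subject seed.
#' @return A list of class `subject_record`: `subject_id`, `series`,
#'   `lesion`, `reference`, `dose_MBq`, `weight_kg`, `label`.
#' @export
generate_subject <- function(config, class_label = c("CR", "PR"),
                             seed = 1) {
  class_label <- match.arg(class_label)
  set.seed(seed)
  grid <- config$grid
  sched <- config$schedule
  nf <- nrow(sched)
  t_mid <- frame_midpoints(sched)
  late <- tail(seq_len(nf), min(5, nf))
  het <- config$heterogeneity

  # lesion in one breast position (first axis is left-right)
  center <- c(round(grid[1] / 4) + sample(-1:1, 1),
              round(grid[2] / 2) + sample(-1:1, 1),
              round(grid[3] / 2) + sample(-1:1, 1))
  lesion <- voi_mask(sphere_mask(grid, center, config$lesion_radius),
                     config$spacing)
  nles <- sum(lesion$data)

  # subject-level amplitude jitter, identical distribution in both classes
  a_target <- config$tac$K * max(1 + rnorm(1, 0, het$amplitude_cv), 0.2)
  b <- config$tac$late_slope

  # subregion partition and time constants
  if (class_label == "PR" && het$n_subregions > 1) {
    coords <- which(lesion$data, arr.ind = TRUE)
    km <- suppressWarnings(kmeans(coords, centers = min(het$n_subregions,
                                                        nles),
                                  nstart = 1, iter.max = 100))
    region <- km$cluster
    taus <- runif(max(region), het$tau_range[1], het$tau_range[2])
  } else {
    region <- rep(1L, nles)
    taus <- config$tac$tau
  }
  # per-region amplitude so the late-window mean equals the target
  late_t <- mean(t_mid[late])
  tacs <- vapply(taus, function(tau) {
    gain <- mean(1 - exp(-t_mid[late] / tau))
    K <- (a_target - b * late_t) / gain
    K * (1 - exp(-t_mid / tau)) + b * t_mid
  }, numeric(nf)) # nf x n_regions

  field <- make_heterogeneity_field(grid, het$correlation_length, het$cv)
  field_les <- field[lesion$data]

  bg_tac <- make_tac(config$background$K, config$background$tau, 0, sched)

  les_idx <- which(lesion$data)
  data4d <- array(0, c(grid, nf))
  nvox <- prod(grid)
  for (f in seq_len(nf)) {
    frame <- rep(bg_tac[f], nvox)
    frame[les_idx] <- tacs[f, region] * field_les
    if (config$noise_scale > 0) {
      frame <- frame + rnorm(nvox, 0,
                             config$noise_scale / sqrt(sched$duration_s[f]))
    }
    data4d[, , , f] <- frame
  }

  reference <- mirror_reference_mask(lesion)
  dose <- runif(1, config$dose_range_MBq[1], config$dose_range_MBq[2])
  weight <- min(max(rnorm(1, config$weight_mean_kg, config$weight_sd_kg),
                    45), 110)
  # store as activity concentration; SUV normalization inverts this
  data4d <- data4d * (dose / weight)
  series <- dynamic_series(data4d, sched, spacing = config$spacing,
                           units = "concentration")
  structure(list(subject_id = sprintf("subj%08d", seed), series = series,
                 lesion = lesion, reference = reference, dose_MBq = dose,
                 weight_kg = weight, label = class_label),
            class = "subject_record")
}

#' Generate a seeded phantom cohort
#'
#' Generates `n_cr + n_pr` subjects with per-subject seeds derived from
#' the cohort seed. With `dir` given, each subject's 4D series, lesion
#' and reference masks are written as NIfTI together with the schedule
#' CSV and a subject table CSV, and only the manifest is returned (use
#' this for larger cohorts: an in-memory 64 x 64 x 24 x 44 subject is
#' ~35 MB). With `dir = NULL` the full records are returned in memory.
#'
#' @param config A [phantom_config()].
#' @param dir Optional output directory.
#' @return With `dir`: the manifest tibble (columns subject_id,
#'   series_path, lesion_path, reference_path, dose_MBq, weight_kg,
#'   label). Without: list with `subjects` (list of `subject_record`)
#'   and `manifest`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  n <- config$n_cr + config$n_pr
  labels <- c(rep("CR", config$n_cr), rep("PR", config$n_pr))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, n)
  ids <- sprintf("S%03d", seq_len(n))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_frame_schedule(config$schedule, file.path(dir, "schedule.csv"))
  }
  subjects <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- generate_subject(config, labels[i], seeds[i])
    rec$subject_id <- ids[i]
    if (is.null(dir)) {
      subjects[[i]] <- rec
      rows[[i]] <- tibble(subject_id = ids[i], series_path = NA_character_,
                          lesion_path = NA_character_,
                          reference_path = NA_character_,
                          dose_MBq = rec$dose_MBq,
                          weight_kg = rec$weight_kg, label = labels[i])
    } else {
      sp <- file.path(dir, paste0(ids[i], "_series.nii.gz"))
      lp <- file.path(dir, paste0(ids[i], "_lesion.nii.gz"))
      rp <- file.path(dir, paste0(ids[i], "_reference.nii.gz"))
      write_dynamic_series(rec$series, sp)
      write_mask(rec$lesion, lp)
      write_mask(rec$reference, rp)
      rows[[i]] <- tibble(subject_id = ids[i], series_path = sp,
                          lesion_path = lp, reference_path = rp,
                          dose_MBq = rec$dose_MBq,
                          weight_kg = rec$weight_kg, label = labels[i])
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    readr::write_csv(manifest, file.path(dir, "subjects.csv"))
    return(manifest)
  }
  list(subjects = subjects, manifest = manifest)
}

#' Generate a cohort and extract features subject-by-subject
#'
#' Streams the cohort: each subject is generated, SUV-normalized and
#' extracted, then discarded, so arbitrarily large cohorts fit in
#' memory. Static features come from the mean of the last five frames;
#' dynamic features from per-frame extraction.
#'
#' @param config A [phantom_config()].
#' @param scheme A [discretization_scheme()].
#' @param vois VOIs to extract: subset of `c("lesion", "reference")`.
#' @param dynamic If `FALSE`, skip per-frame extraction (static only).
#' @param static_k Trailing frames averaged for the static image.
#' @return List with `static` (tibble: subject_id, voi, class + 107
#'   features) and `dynamic` (long tibble with frame, start_s,
#'   duration_s; `NULL` if `dynamic = FALSE`).
#' @export
cohort_features <- function(config, scheme = discretization_scheme(),
                            vois = c("lesion", "reference"),
                            dynamic = TRUE, static_k = 5) {
  vois <- match.arg(vois, several.ok = TRUE)
  n <- config$n_cr + config$n_pr
  labels <- c(rep("CR", config$n_cr), rep("PR", config$n_pr))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, n)
  ids <- sprintf("S%03d", seq_len(n))
  stat_rows <- list()
  dyn_rows <- list()
  for (i in seq_len(n)) {
    rec <- generate_subject(config, labels[i], seeds[i])
    suv <- suv_normalize(rec$series, rec$dose_MBq, rec$weight_kg)
    static <- make_static_image(suv, k = static_k)
    for (v in vois) {
      mask <- rec[[v]]
      sf <- extract_features(static, mask, scheme)
      stat_rows[[length(stat_rows) + 1]] <- dplyr::bind_cols(
        tibble(subject_id = ids[i], voi = v, class = labels[i]), sf)
      if (dynamic) {
        fts <- extract_per_frame(suv, mask, scheme)
        dyn_rows[[length(dyn_rows) + 1]] <- dplyr::bind_cols(
          tibble(subject_id = ids[i], voi = v, class = labels[i],
                 .rows = nrow(fts)), fts)
      }
    }
  }
  list(static = dplyr::bind_rows(stat_rows),
       dynamic = if (dynamic) dplyr::bind_rows(dyn_rows) else NULL)
}

#' Build a task design matrix from cohort feature tables
#'
#' Maps extracted cohort features onto one of the two classification
#' tasks: `tumor-vs-reference` labels every (subject, VOI) row by its
#' VOI (n = 2 x subjects), `cr-vs-pr` keeps lesion rows and labels them
#' by response class.
#'
#' @param features The list returned by [cohort_features()], or a tibble
#'   shaped like one of its elements.
#' @param task `"tumor-vs-reference"` or `"cr-vs-pr"`.
#' @param mode Design mode, see [assemble_design_matrix()].
#' @return A `design_matrix`.
#' @export
design_from_features <- function(features,
                                 task = c("tumor-vs-reference", "cr-vs-pr"),
                                 mode = c("static", "median", "mad",
                                          "median+mad")) {
  task <- match.arg(task)
  mode <- match.arg(mode)
  x <- if (is.list(features) && !is.data.frame(features)) {
    if (mode == "static") features$static else features$dynamic
  } else features
  if (is.null(x)) {
    stop_dynomics("requested mode not present in `features`",
                  class = "dynomics_design_error")
  }
  if (task == "tumor-vs-reference") {
    x <- dplyr::mutate(x, sample_id = paste(.data$subject_id, .data$voi,
                                            sep = "_"),
                       label = .data$voi)
  } else {
    x <- x |>
      dplyr::filter(.data$voi == "lesion") |>
      dplyr::mutate(sample_id = .data$subject_id, label = .data$class)
  }
  x <- dplyr::select(x, -dplyr::any_of(c("subject_id", "voi", "class")))
  assemble_design_matrix(x, mode)
}
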