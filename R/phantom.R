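#' Scanner acquisition profile
#'
#' Describes the reconstruction grid of a PET scanner as it matters for
#' radiomics reproducibility: voxel spacing, an isotropic Gaussian
#' post-reconstruction filter, and a background noise level. Two named
#' profiles mirror a clinical setting in which an older slice-wise
#' reconstruction (coarse grid, no post-filter) coexists with a newer fully
#' 3D reconstruction (fine grid, 5 mm Gaussian post-filter).
#'
#' @param name profile label, e.g. `"osem2d"`.
#' @param voxel_spacing voxel spacing in mm (length 3, positive).
#' @param post_filter_fwhm FWHM in mm of the isotropic Gaussian
#'   post-reconstruction filter (0 disables it).
#' @param noise_cv coefficient of variation of the multiplicative background
#'   noise (unitless, >= 0).
#' @param grid_shape reconstruction grid in voxels (length 3).
#' @return An object of class `scanner_profile`.
#' @export
scanner_profile <- function(name, voxel_spacing, post_filter_fwhm = 0,
                            noise_cv = 0, grid_shape = c(72L, 72L, 56L)) {
  voxel_spacing <- as.numeric(voxel_spacing)
  stopifnot(length(voxel_spacing) == 3L, all(voxel_spacing > 0),
            post_filter_fwhm >= 0, noise_cv >= 0,
            length(grid_shape) == 3L, all(grid_shape >= 8))
  structure(list(name = as.character(name), voxel_spacing = voxel_spacing,
                 post_filter_fwhm = post_filter_fwhm, noise_cv = noise_cv,
                 grid_shape = as.integer(grid_shape)),
            class = "scanner_profile")
}

#' Built-in scanner profiles
#'
#' `profile_osem2d()` is the coarse-grid profile (2.035 x 2.035 x 2.425 mm
#' voxels, no post-filter); `profile_osem3d()` is the fine-grid profile
#' (1.018 x 1.018 x 2.027 mm voxels with a 5 mm Gaussian post-filter and a
#' somewhat higher noise level). Grid shapes are desk-scale crops covering a
#' comparable ~145 mm field of view rather than full clinical matrices.
#'
#' @param grid_shape override the default grid.
#' @param noise_cv override the default background noise level.
#' @return A [scanner_profile()].
#' @export
profile_osem2d <- function(grid_shape = c(72L, 72L, 56L), noise_cv = 0.10) {
  scanner_profile("osem2d", c(2.035, 2.035, 2.425), 0, noise_cv, grid_shape)
}

#' @rdname profile_osem2d
#' @export
profile_osem3d <- function(grid_shape = c(144L, 144L, 64L), noise_cv = 0.15) {
  scanner_profile("osem3d", c(1.018, 1.018, 2.027), 5, noise_cv, grid_shape)
}

#' Ground-truth tumor geometry and texture
#'
#' An ellipsoidal lesion on a TBR ~ 1 background. `semi_axes` are the
#' ellipsoid semi-axes in mm, sorted descending (a >= b >= c). The uptake
#' profile is either flat at `peak_tbr` or falls off linearly from
#' `peak_tbr` at the centre to 1 at the ellipsoid boundary. A nonzero
#' `rim_fraction` produces a rim-enhanced lesion: the outer `rim_fraction`
#' of the (normalized) radius takes `peak_tbr` while the core is set to
#' 1 + 0.6 (peak_tbr - 1).
#'
#' @param semi_axes mm triplet, sorted descending.
#' @param peak_tbr peak tumor-to-background ratio (> 1).
#' @param center lesion centre in mm, relative to the grid centre.
#' @param orientation rotation angles (radians) about the x, y, z axes.
#' @param texture_amplitude relative amplitude of the multiplicative
#'   intratumoral texture field (>= 0; 0 = homogeneous).
#' @param texture_corr_length correlation length of the texture field, mm.
#' @param rim_fraction fraction of the radius with elevated rim uptake
#'   (0 = solid lesion).
#' @param uptake_profile `"flat"` or `"linear"`.
#' @return An object of class `tumor_spec`.
#' @export
tumor_spec <- function(semi_axes, peak_tbr = 2.5, center = c(0, 0, 0),
                       orientation = c(0, 0, 0), texture_amplitude = 0,
                       texture_corr_length = 6, rim_fraction = 0,
                       uptake_profile = c("flat", "linear")) {
  uptake_profile <- match.arg(uptake_profile)
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stop("tumor_spec: semi_axes must be three positive lengths (mm)")
  }
  if (is.unsorted(rev(semi_axes))) {
    stop("tumor_spec: semi_axes must be sorted descending (a >= b >= c)")
  }
  if (peak_tbr <= 1) stop("tumor_spec: peak_tbr must exceed 1 (background level)")
  if (texture_amplitude < 0) stop("tumor_spec: texture_amplitude must be >= 0")
  if (rim_fraction < 0 || rim_fraction > 1) stop("tumor_spec: rim_fraction in [0, 1]")
  structure(list(semi_axes = semi_axes, peak_tbr = peak_tbr,
                 center = as.numeric(center), orientation = as.numeric(orientation),
                 texture_amplitude = texture_amplitude,
                 texture_corr_length = texture_corr_length,
                 rim_fraction = rim_fraction, uptake_profile = uptake_profile),
            class = "tumor_spec")
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

# Physical coordinates (mm) of voxel centres along each axis, centred on the
# grid midpoint.
grid_axes_mm <- function(grid_shape, spacing) {
  lapply(1:3, function(i) (seq_len(grid_shape[i]) - (grid_shape[i] + 1) / 2) * spacing[i])
}

# Normalized ellipsoidal radius of every voxel (<= 1 inside the lesion).
ellipsoid_radius <- function(spec, scanner) {
  ax <- grid_axes_mm(scanner$grid_shape, scanner$voxel_spacing)
  R <- rotation_matrix(spec$orientation)
  d <- scanner$grid_shape
  x <- array(rep(ax[[1]], times = d[2] * d[3]), d) - spec$center[1]
  y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d) - spec$center[2]
  z <- array(rep(ax[[3]], each = d[1] * d[2]), d) - spec$center[3]
  u1 <- R[1, 1] * x + R[2, 1] * y + R[3, 1] * z
  u2 <- R[1, 2] * x + R[2, 2] * y + R[3, 2] * z
  u3 <- R[1, 3] * x + R[2, 3] * y + R[3, 3] * z
  sqrt((u1 / spec$semi_axes[1])^2 + (u2 / spec$semi_axes[2])^2 +
         (u3 / spec$semi_axes[3])^2)
}

#' Generate one synthetic PET phantom
#'
#' Renders the lesion described by `spec` on the grid of `scanner`:
#' background voxels have mean TBR exactly 1 before filtering (coefficient of
#' variation `scanner$noise_cv`), lesion voxels reach `peak_tbr` modulated by
#' a correlated Gaussian random texture field, and the whole volume is
#' smoothed with the profile's post-reconstruction filter.
#'
#' @param spec a [tumor_spec()].
#' @param scanner a [scanner_profile()].
#' @param seed integer seed controlling texture and noise.
#' @return A list with elements `volume` ([pet_volume()]), `tumor_mask`
#'   (logical array: the true ellipsoid support), and `truth` (named numeric
#'   vector of ground-truth covariates: `major_axis_mm` = 2a, `elongation` =
#'   b/a, `texture_amplitude`, `peak_tbr`, `volume_ml`).
#' @export
generate_phantom <- function(spec, scanner, seed = 1L) {
  stopifnot(inherits(spec, "tumor_spec"), inherits(scanner, "scanner_profile"))
  half_extent <- scanner$grid_shape * scanner$voxel_spacing / 2
  R <- rotation_matrix(spec$orientation)
  extent <- sqrt((R^2) %*% (spec$semi_axes^2))  # lesion extent along grid axes
  if (any(abs(spec$center) + extent > half_extent)) {
    stop("generate_phantom: tumor exceeds grid bounds")
  }
  set.seed(as.integer(seed))
  r <- ellipsoid_radius(spec, scanner)
  inside <- r <= 1
  act <- array(1, scanner$grid_shape)
  if (spec$rim_fraction > 0) {
    core <- inside & r < (1 - spec$rim_fraction)
    rim <- inside & !core
    act[core] <- 1 + 0.6 * (spec$peak_tbr - 1)
    act[rim] <- spec$peak_tbr
  } else if (spec$uptake_profile == "flat") {
    act[inside] <- spec$peak_tbr
  } else {
    act[inside] <- 1 + (spec$peak_tbr - 1) * (1 - r[inside])
  }
  if (spec$texture_amplitude > 0 && any(inside)) {
    fld <- gaussian_random_field(scanner$grid_shape, scanner$voxel_spacing,
                                 spec$texture_corr_length)
    act[inside] <- act[inside] * pmax(0.1, 1 + spec$texture_amplitude * fld[inside])
  }
  if (scanner$noise_cv > 0) {
    z <- array(stats::rnorm(prod(scanner$grid_shape)), scanner$grid_shape)
    act <- act * pmax(0.01, 1 + scanner$noise_cv * z)
  }
  if (scanner$post_filter_fwhm > 0) {
    act <- smooth_gaussian(act, scanner$post_filter_fwhm, scanner$voxel_spacing)
  }
  truth <- c(major_axis_mm = 2 * spec$semi_axes[1],
             elongation = spec$semi_axes[2] / spec$semi_axes[1],
             texture_amplitude = spec$texture_amplitude,
             peak_tbr = spec$peak_tbr,
             volume_ml = 4 / 3 * pi * prod(spec$semi_axes) / 1000)
  list(volume = pet_volume(act, scanner$voxel_spacing, scanner$name),
       tumor_mask = inside, truth = truth)
}

#' Proportional-hazards survival link
#'
#' Survival times are drawn from an exponential distribution whose hazard is
#' `baseline_hazard * exp(sum(coefficients * (covariate - center)))`. All
#' subjects experience the event (no censoring) unless `censor_at_horizon`
#' is set, in which case times beyond `admin_horizon` are administratively
#' censored.
#'
#' @param baseline_hazard events per day at the covariate centres (> 0).
#' @param coefficients named numeric vector of log-hazard slopes on
#'   ground-truth covariates (names must exist in the phantom truth map).
#' @param centers named numeric vector of covariate reference values
#'   (defaults to 0 for covariates not listed).
#' @param admin_horizon administrative horizon in days.
#' @param censor_at_horizon censor (rather than keep) times beyond the
#'   horizon; off by default since the emulated cohort has complete
#'   follow-up to death.
#' @param seed integer seed.
#' @return An object of class `survival_link`.
#' @export
survival_link <- function(baseline_hazard = 1 / 450,
                          coefficients = c(major_axis_mm = 0.10),
                          centers = c(major_axis_mm = 42),
                          admin_horizon = 3650, censor_at_horizon = FALSE,
                          seed = 1L) {
  stopifnot(baseline_hazard > 0, admin_horizon > 0)
  if (is.null(names(coefficients)) && length(coefficients) > 0) {
    stop("survival_link: coefficients must be named by covariate")
  }
  structure(list(baseline_hazard = baseline_hazard, coefficients = coefficients,
                 centers = centers, admin_horizon = admin_horizon,
                 censor_at_horizon = censor_at_horizon, seed = as.integer(seed)),
            class = "survival_link")
}

#' Simulate a survival record from ground-truth covariates
#'
#' @param truth named numeric vector of covariates (as produced by
#'   [generate_phantom()]); every coefficient name in `link` must be present.
#' @param link a [survival_link()].
#' @param seed integer seed for the exponential draw.
#' @return A one-row data.frame with `time_days`, `event`, `label_1yr`
#'   (1 if time >= 365 days) and `hazard`.
#' @export
simulate_survival <- function(truth, link, seed = 1L) {
  stopifnot(inherits(link, "survival_link"))
  miss <- setdiff(names(link$coefficients), names(truth))
  if (length(miss) > 0) {
    stop(sprintf("simulate_survival: covariate(s) missing from truth: %s",
                 paste(miss, collapse = ", ")))
  }
  lp <- 0
  for (nm in names(link$coefficients)) {
    ctr <- if (nm %in% names(link$centers)) link$centers[[nm]] else 0
    lp <- lp + link$coefficients[[nm]] * (truth[[nm]] - ctr)
  }
  hazard <- link$baseline_hazard * exp(lp)
  set.seed(as.integer(seed))
  t <- stats::rexp(1, rate = hazard)
  event <- 1L
  if (link$censor_at_horizon && t > link$admin_horizon) {
    t <- link$admin_horizon
    event <- 0L
  }
  data.frame(time_days = t, event = event,
             label_1yr = as.integer(t >= 365), hazard = hazard)
}

#' Cohort sampling specification
#'
#' Per-subject tumor parameters are drawn uniformly from `tumor_ranges`:
#' `a` (major semi-axis, mm), `b_ratio` and `c_ratio` (axis ratios in (0, 1]),
#' `peak_tbr`, `texture_amplitude`, `texture_corr_length` (mm), and
#' `center_jitter` (mm, uniform cube). Orientation angles are uniform on
#' [0, pi).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param scanner a [scanner_profile()].
#' @param tumor_ranges named list of 2-vectors (or scalars) of sampling
#'   ranges; see Details for defaults.
#' @param ptv_margin mm margin by which the true tumor is dilated to emulate
#'   a planning target volume (default 20, after the 2 cm clinical
#'   target-volume margin convention).
#' @param uptake_profile uptake profile given to every subject
#'   (default "linear": TBR falls off towards the lesion boundary).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, scanner, tumor_ranges = list(),
                        ptv_margin = 20, uptake_profile = "linear", seed = 1L) {
  stopifnot(n_subjects >= 2, inherits(scanner, "scanner_profile"), ptv_margin > 0)
  defaults <- list(a = c(12, 30), b_ratio = c(0.5, 1), c_ratio = c(0.6, 1),
                   peak_tbr = c(2.4, 3.6), texture_amplitude = c(0.05, 0.25),
                   texture_corr_length = c(4, 10), center_jitter = 5)
  for (nm in names(tumor_ranges)) defaults[[nm]] <- tumor_ranges[[nm]]
  structure(list(n_subjects = as.integer(n_subjects), scanner = scanner,
                 tumor_ranges = defaults, ptv_margin = ptv_margin,
                 uptake_profile = uptake_profile, seed = as.integer(seed)),
            class = "cohort_spec")
}

runif_range <- function(r) if (length(r) == 1L) r else stats::runif(1, r[1], r[2])

#' Generate a synthetic phantom cohort with planted survival signal
#'
#' Draws per-subject tumor specifications from the cohort's sampling ranges,
#' renders each phantom, builds a PTV-like mask by dilating the true tumor
#' support by `ptv_margin`, emits a background mask (the PTV complement),
#' and simulates a survival record through the proportional-hazards link.
#' Fully reproducible from `(spec$seed, link$seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param link a [survival_link()].
#' @param ids optional character vector of subject ids.
#' @return A list of class `phantom_cohort` with elements
#'   `subjects` (list of per-subject lists: `id`, `volume`, `tumor_mask`,
#'   `ptv`, `background_mask`, `truth`), `truth_table` (data.frame of
#'   ground-truth covariates), and `survival` (data.frame with columns
#'   `subject_id`, `time_days`, `event`, `scanner`, `label_1yr`).
#' @export
generate_cohort <- function(spec, link, ids = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(link, "survival_link"))
  n <- spec$n_subjects
  if (is.null(ids)) ids <- sprintf("%s_%03d", spec$scanner$name, seq_len(n))
  set.seed(spec$seed)
  tumor_specs <- vector("list", n)
  sub_seeds <- integer(n)
  surv_seeds <- integer(n)
  tr <- spec$tumor_ranges
  for (i in seq_len(n)) {
    a <- runif_range(tr$a)
    b <- a * runif_range(tr$b_ratio)
    cc <- b * runif_range(tr$c_ratio)
    jit <- stats::runif(3, -tr$center_jitter[1], tr$center_jitter[1])
    ang <- stats::runif(3, 0, pi)
    tumor_specs[[i]] <- tumor_spec(
      semi_axes = sort(c(a, b, cc), decreasing = TRUE),
      peak_tbr = runif_range(tr$peak_tbr), center = jit, orientation = ang,
      texture_amplitude = runif_range(tr$texture_amplitude),
      texture_corr_length = runif_range(tr$texture_corr_length),
      uptake_profile = spec$uptake_profile)
    sub_seeds[i] <- derive_seed(spec$seed + i, "phantom")
    surv_seeds[i] <- derive_seed(link$seed + i, "survival")
  }
  subjects <- vector("list", n)
  truth_rows <- vector("list", n)
  surv_rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(tumor_specs[[i]], spec$scanner, sub_seeds[i])
    ptv <- dilate_mask(ph$tumor_mask, spec$ptv_margin, spec$scanner$voxel_spacing)
    sv <- simulate_survival(ph$truth, link, surv_seeds[i])
    subjects[[i]] <- list(
      id = ids[i], volume = ph$volume, tumor_mask = ph$tumor_mask,
      ptv = voi_mask(ptv, "ptv", NA_real_, spec$scanner$voxel_spacing),
      background_mask = !ptv, truth = ph$truth, seed = sub_seeds[i])
    truth_rows[[i]] <- data.frame(subject_id = ids[i], t(ph$truth))
    surv_rows[[i]] <- data.frame(subject_id = ids[i], time_days = sv$time_days,
                                 event = sv$event, scanner = spec$scanner$name,
                                 label_1yr = sv$label_1yr)
  }
  structure(list(subjects = subjects,
                 truth_table = do.call(rbind, truth_rows),
                 survival = do.call(rbind, surv_rows),
                 scanner = spec$scanner, spec = spec, link = link),
            class = "phantom_cohort")
}

#' Generate the two-scanner study cohort
#'
#' Convenience wrapper reproducing the emulated study design: `n_train`
#' subjects on the coarse-grid profile and `n_test` subjects on the
#' fine-grid profile (defaults 25 and 12), sharing one survival link.
#'
#' @param n_train,n_test cohort sizes for the two profiles.
#' @param link a [survival_link()].
#' @param seed integer master seed.
#' @param train_profile,test_profile [scanner_profile()]s.
#' @param ... passed to [cohort_spec()] (e.g. `tumor_ranges`, `ptv_margin`).
#' @return A `phantom_cohort` whose `subjects` concatenates both profiles and
#'   whose `survival` table carries the scanner label per subject.
#' @export
generate_study_cohort <- function(n_train = 25, n_test = 12,
                                  link = survival_link(), seed = 1L,
                                  train_profile = profile_osem2d(),
                                  test_profile = profile_osem3d(), ...) {
  ca <- cohort_spec(n_train, train_profile, seed = derive_seed(seed, "traincohort"), ...)
  cb <- cohort_spec(n_test, test_profile, seed = derive_seed(seed, "testcohort"), ...)
  la <- link; la$seed <- derive_seed(seed, "trainlink")
  lb <- link; lb$seed <- derive_seed(seed, "testlink")
  a <- generate_cohort(ca, la)
  b <- generate_cohort(cb, lb)
  structure(list(subjects = c(a$subjects, b$subjects),
                 truth_table = rbind(a$truth_table, b$truth_table),
                 survival = rbind(a$survival, b$survival),
                 scanner = list(train = train_profile, test = test_profile),
                 spec = list(train = ca, test = cb), link = link),
            class = "phantom_cohort")
}

#' Write a cohort's images, masks and survival table to disk
#'
#' Emits one NIfTI image and two NIfTI masks (true tumor support, PTV) per
#' subject plus a cohort-level CSV survival table and a YAML manifest of
#' seeds and paths.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(subjects = list())
  for (s in cohort$subjects) {
    img <- file.path(dir, paste0(s$id, "_tbr.nii.gz"))
    tm <- file.path(dir, paste0(s$id, "_tumor.nii.gz"))
    pv <- file.path(dir, paste0(s$id, "_ptv.nii.gz"))
    write_pet_volume(s$volume, img)
    write_voi_mask(voi_mask(s$tumor_mask, "tumor", NA_real_, s$volume$spacing), tm)
    write_voi_mask(s$ptv, pv)
    manifest$subjects[[s$id]] <- list(image = img, tumor_mask = tm, ptv = pv,
                                      seed = s$seed)
  }
  surv_path <- file.path(dir, "survival.csv")
  utils::write.csv(cohort$survival, surv_path, row.names = FALSE)
  manifest$survival <- surv_path
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
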