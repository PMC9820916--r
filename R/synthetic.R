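## Synthetic cohort generator -------------------------------------------------
##
## Cohorts are built from the canonical template: per-landmark Gaussian
## jitter creates between-subject anatomical variation, a random rigid pose
## emulates scanner positioning, and airway size is planted as a linear
## model on selected soft/hard-tissue measures so that downstream variable-
## importance analyses have a known ground truth to recover.

#' Specification of a synthetic cohort
#'
#' The defaults emulate a cohort of 60 adults whose measure distributions
#' match published normal-adult ranges: airway volume averages 14,460 mm^3
#' with SD ~7,400 mm^3 and CSAmin averages ~206 mm^2. The planted model is
#'
#' `Vol = beta0 + beta_HSP * HSP + beta_BEP_A * BEP_A + beta_Na_B * Na_B + eps`
#'
#' with `beta_HSP < 0` (a longer horizontal soft palate shrinks the
#' airway); `beta0` is anchored so the expected volume at the template
#' configuration equals `vol_mean`. CSAmin is planted through the waist
#' ratio `u = CSAmin * height / Vol` (in (0, 1) for any realizable tube),
#' itself decreasing in HSP, which keeps every simulated subject
#' geometrically consistent.
#'
#' @param n Number of subjects (>= 2).
#' @param seed Integer RNG seed.
#' @param landmark_sd Per-landmark, per-axis anatomical jitter SD in mm.
#' @param pose_rot_deg Uniform pose rotation half-range per axis, degrees.
#' @param pose_trans_mm Uniform pose translation half-range per axis, mm.
#' @param voxel Isotropic voxel size in mm for generated grids (scanner
#'   resolution, default 0.3 mm).
#' @param beta Named numeric: planted coefficients on `HSP`, `BEP_A`,
#'   `Na_B` in mm^3 per mm.
#' @param vol_mean Expected volume (mm^3) at the template configuration.
#' @param eps_vol_sd Residual SD of the planted volume model, mm^3.
#' @param waist List with `u0` (mean waist ratio), `u_hsp` (per mm of
#'   HSP), `u_sd`, `u_min`, `u_max`.
#' @param vol_min Lower truncation for simulated volumes, mm^3 (redrawn).
#' @param airway_aspect Lateral/anteroposterior semi-axis ratio of the
#'   airway cross-section (> 1: wider than deep).
#' @param female_prob,age_mean,age_sd,age_range Covariate distributions.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 60, seed = 1, landmark_sd = 3,
                        pose_rot_deg = 20, pose_trans_mm = 30, voxel = 0.3,
                        beta = c(HSP = -1000, BEP_A = 350, Na_B = 250),
                        vol_mean = 14460, eps_vol_sd = 5800,
                        waist = list(u0 = 0.88, u_hsp = -0.01, u_sd = 0.06,
                                     u_min = 0.30, u_max = 0.95),
                        vol_min = 2000, airway_aspect = 2.6,
                        female_prob = 0.70, age_mean = 39.5, age_sd = 13.5,
                        age_range = c(22, 72)) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2")
  if (voxel <= 0) stop("voxel size must be > 0")
  if (landmark_sd < 0) stop("landmark noise SD must be >= 0")
  if (pose_rot_deg < 0 || pose_trans_mm < 0) stop("pose ranges must be >= 0")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 landmark_sd = landmark_sd, pose_rot_deg = pose_rot_deg,
                 pose_trans_mm = pose_trans_mm, voxel = voxel, beta = beta,
                 vol_mean = vol_mean, eps_vol_sd = eps_vol_sd, waist = waist,
                 vol_min = vol_min, airway_aspect = airway_aspect,
                 female_prob = female_prob, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n = %d, seed = %d, landmark SD = %g mm\n",
              x$n, x$seed, x$landmark_sd))
  cat("planted volume model: Vol ~", paste(
    sprintf("%+g*%s", x$beta, names(x$beta)), collapse = " "), "\n")
  invisible(x)
}

#' Read / write a cohort spec as JSON
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @export
write_cohort_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$beta <- as.list(obj$beta)   # keep coefficient names as JSON keys
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON integers come back as R integers; the spec is double-valued
  obj <- lapply(obj, function(x)
    if (is.integer(x)) as.numeric(x) else x)
  obj$beta <- stats::setNames(as.numeric(unlist(obj$beta)),
                              names(unlist(obj$beta)))
  obj$waist <- lapply(obj$waist, as.numeric)
  do.call(cohort_spec, obj)
}

random_pose <- function(rot_deg, trans_mm) {
  ang <- stats::runif(3, -rot_deg, rot_deg) * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  Rz <- rot_z(ang[3])
  rigid_transform(Rz %*% Ry %*% Rx, stats::runif(3, -trans_mm, trans_mm))
}

#' Generate a synthetic cohort
#'
#' For each subject: (1) jitter every template landmark with isotropic
#' Gaussian noise of SD `landmark_sd`; (2) reorient the jittered set to
#' the canonical frame and compute its true measurement vector; (3) draw
#' airway volume from the planted linear model and CSAmin through the
#' waist ratio; (4) apply a random rigid pose to produce the raw-frame
#' landmarks a scanner would deliver. Deterministic under a fixed seed.
#'
#' @param spec A `cohort_spec`.
#' @param grids If `TRUE`, also build each subject's binary airway grid at
#'   `spec$voxel` mm (memory-heavy for large cohorts; grids can instead be
#'   built on demand with [subject_airway_grid()]).
#' @return List of `synthetic_subject` objects, each with fields
#'   `id`, `landmarks_raw` (posed), `landmarks_canonical`, `measures`
#'   (named vector incl. age/sex), `vol_true` (mm^3), `csa_true` (mm^2),
#'   `z_sup`, `z_inf`, `pose` (`rigid_transform`), and `grid`
#'   (`voxel_grid` or `NULL`).
#' @export
generate_cohort <- function(spec, grids = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl <- landmark_template()
  tpl_meas <- compute_measures(tpl)
  beta0 <- spec$vol_mean - sum(spec$beta * tpl_meas[names(spec$beta)])

  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, spec$n)

  lapply(seq_len(spec$n), function(i) {
    set.seed(sub_seeds[i])
    ## 1. anatomy
    coords <- template_coords() +
      matrix(stats::rnorm(75, 0, spec$landmark_sd), 25, 3)
    rownames(coords) <- rownames(template_coords())
    jittered <- landmark_set(coords, frame = "raw",
                             subject_id = sprintf("S%03d", i))
    if (spec$landmark_sd == 0) {
      canon <- landmark_set(coords, frame = "reoriented",
                            subject_id = sprintf("S%03d", i))
    } else {
      canon <- apply_transform(jittered, compute_reorientation(jittered))
      canon$subject_id <- sprintf("S%03d", i)
    }

    ## 2. covariates
    age <- min(max(stats::rnorm(1, spec$age_mean, spec$age_sd),
                   spec$age_range[1]), spec$age_range[2])
    sex <- stats::rbinom(1, 1, spec$female_prob)   # 1 = female
    meas <- compute_measures(canon, age = age, sex = sex)

    ## 3. planted airway size
    zb <- suppressWarnings(bounding_planes(canon))
    h <- zb["z_sup"] - zb["z_inf"]
    mu_vol <- beta0 + sum(spec$beta * meas[names(spec$beta)])
    vol <- mu_vol + stats::rnorm(1, 0, spec$eps_vol_sd)
    tries <- 0
    while (spec$eps_vol_sd > 0 && vol < spec$vol_min && tries < 100) {
      vol <- mu_vol + stats::rnorm(1, 0, spec$eps_vol_sd)
      tries <- tries + 1
    }
    w <- spec$waist
    u <- w$u0 + w$u_hsp * (meas[["HSP"]] - tpl_meas[["HSP"]]) +
      stats::rnorm(1, 0, w$u_sd)
    u <- min(max(u, w$u_min), w$u_max)
    csa <- u * vol / h

    ## 4. pose
    pose <- random_pose(spec$pose_rot_deg, spec$pose_trans_mm)
    raw <- apply_transform(canon, pose, frame = "raw")

    subj <- structure(
      list(id = sprintf("S%03d", i), landmarks_raw = raw,
           landmarks_canonical = canon, measures = meas,
           vol_true = unname(vol), csa_true = unname(csa),
           z_sup = unname(zb["z_sup"]), z_inf = unname(zb["z_inf"]),
           pose = pose, aspect = spec$airway_aspect, voxel = spec$voxel,
           grid = NULL),
      class = "synthetic_subject")
    if (grids) subj$grid <- subject_airway_grid(subj)
    subj
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "<synthetic_subject> %s: Vol = %.0f mm^3, CSAmin = %.1f mm^2%s\n",
    x$id, x$vol_true, x$csa_true,
    if (is.null(x$grid)) "" else " (+grid)"))
  invisible(x)
}

#' Build (or rebuild) a subject's airway grid
#'
#' @param subject A `synthetic_subject`.
#' @param voxel Voxel size in mm (defaults to the subject's spec value).
#' @return A `voxel_grid` in the reoriented frame realizing the subject's
#'   true volume and CSAmin.
#' @export
subject_airway_grid <- function(subject, voxel = subject$voxel) {
  generate_airway_grid(subject$vol_true, subject$csa_true,
                       subject$z_sup, subject$z_inf, voxel,
                       aspect = subject$aspect)
}

#' Simulate a repeat measuring session
#'
#' Returns the subject's raw-frame landmarks with independent Gaussian
#' placement error on every coordinate, emulating the same examiner
#' re-placing all landmarks at a later session.
#'
#' @param subject A `synthetic_subject`.
#' @param placement_sd Placement error SD in mm (>= 0).
#' @param seed Integer seed.
#' @return A raw-frame `landmark_set`.
#' @export
generate_repeat_session <- function(subject, placement_sd, seed = 1) {
  if (placement_sd < 0) stop("placement SD must be >= 0")
  set.seed(seed)
  lms <- subject$landmarks_raw
  coords <- lms$coords +
    matrix(stats::rnorm(length(lms$coords), 0, placement_sd),
           nrow(lms$coords), 3)
  rownames(coords) <- rownames(lms$coords)
  landmark_set(coords, frame = "raw", subject_id = lms$subject_id)
}

#' Generate an analytic airway phantom grid
#'
#' Builds a vertically oriented tube with elliptical cross-section whose
#' axial area varies smoothly along z following a cosine profile with a
#' single interior minimum at mid-height (the waist):
#' `A(t) = A_max - (A_max - A_min) * (1 + cos(2*pi*(t - 1/2))) / 2`,
#' `t = (z - z_inf) / height`. Because the profile's mean is
#' `(A_max + A_min)/2`, choosing `A_max = 2*Vol/height - CSAmin` makes the
#' integral between the planes equal the requested volume exactly; a
#' constant-area continuation extends the tube slightly beyond both planes
#' so cropping is meaningful. Voxelization is area-matched: each slice
#' fills the `round(A(z)/voxel^2)` cells closest to the tube axis in the
#' elliptical metric, so per-slice areas are realized to within half a
#' voxel footprint and discretization error shrinks as the voxel halves.
#'
#' @param vol_target Volume between the planes, mm^3.
#' @param csa_min_target Minimal axial area, mm^2.
#' @param z_sup,z_inf Bounding plane heights in mm (`z_sup > z_inf`).
#' @param voxel Isotropic voxel size, mm.
#' @param aspect Ratio of lateral (y) to anteroposterior (x) semi-axis.
#' @param center (x, y) center of the tube, mm.
#' @param overhang Constant-area extension beyond each plane, mm.
#' @return A `voxel_grid` in the reoriented frame.
#' @export
generate_airway_grid <- function(vol_target, csa_min_target, z_sup, z_inf,
                                 voxel, aspect = 2.6, center = c(2, 0),
                                 overhang = 2) {
  if (z_sup <= z_inf) stop("z_sup must exceed z_inf")
  if (vol_target <= 0 || csa_min_target <= 0)
    stop("volume and CSAmin targets must be > 0")
  if (voxel <= 0) stop("voxel size must be > 0")
  h <- z_sup - z_inf
  if (csa_min_target * h > vol_target * (1 + 1e-9))
    stop("incompatible targets: CSAmin x height exceeds the volume")
  a_min <- csa_min_target
  a_max <- 2 * vol_target / h - a_min

  area_at <- function(z) {
    t <- pmin(1, pmax(0, (z - z_inf) / h))
    a_max - (a_max - a_min) * (1 + cos(2 * pi * (t - 0.5))) / 2
  }

  ax_max <- sqrt(a_max / (pi * aspect))     # largest anteroposterior semi-axis
  ay_max <- aspect * ax_max
  margin <- 1.5
  nx <- ceiling(2 * (ax_max + margin) / voxel)
  ny <- ceiling(2 * (ay_max + margin) / voxel)
  zlo <- z_inf - overhang; zhi <- z_sup + overhang
  nz <- floor((zhi - zlo) / voxel) + 1L
  origin <- c(center[1] - (nx - 1) / 2 * voxel,
              center[2] - (ny - 1) / 2 * voxel,
              zlo)
  xc <- origin[1] + (seq_len(nx) - 1) * voxel - center[1]
  yc <- origin[2] + (seq_len(ny) - 1) * voxel - center[2]
  zc <- origin[3] + (seq_len(nz) - 1) * voxel

  ## area-matched voxelization: per slice, fill the round(A / voxel^2)
  ## cells with the smallest elliptical metric, so every slice realizes its
  ## analytic area to within half a voxel footprint (nested-ellipse shape)
  mask <- array(FALSE, c(nx, ny, nz))
  x2 <- matrix(xc^2, nx, ny)
  y2 <- matrix(yc^2, nx, ny, byrow = TRUE)
  q <- x2 / (1 / aspect) + y2 / aspect        # ellipse metric, aspect fixed
  ord <- order(q)
  for (k in seq_len(nz)) {
    A <- area_at(zc[k])
    ncell <- min(round(A / voxel^2), length(ord))
    sl <- matrix(FALSE, nx, ny)
    sl[ord[seq_len(ncell)]] <- TRUE
    mask[, , k] <- sl
  }
  voxel_grid(mask, voxel, origin, frame = "reoriented")
}

#' Measurement table of a synthetic cohort
#'
#' Assembles the per-subject true measures and airway metrics into the
#' standard analysis table. With `from_grids = TRUE` the airway columns
#' are measured from each subject's voxel grid via [airway_metrics()]
#' instead of taken from the generator's analytic truth.
#'
#' @param cohort List of `synthetic_subject`.
#' @param from_grids Measure Vol/CSAmin from voxel grids (builds them on
#'   demand when absent).
#' @return Data frame, one row per subject: `subject_id`, 25 measures,
#'   `age`, `sex`, `Vol`, `CSAmin`, and (when `from_grids`) `Ap`, `Lat`.
#' @export
cohort_measure_table <- function(cohort, from_grids = FALSE) {
  rows <- lapply(cohort, function(s) {
    base <- c(s$measures)
    if (from_grids) {
      g <- if (is.null(s$grid)) subject_airway_grid(s) else s$grid
      am <- airway_metrics(g, s$landmarks_canonical, component_filter = FALSE)
      c(base, Vol = unname(am["Vol"]), CSAmin = unname(am["CSAmin"]),
        Ap = unname(am["Ap"]), Lat = unname(am["Lat"]))
    } else {
      c(base, Vol = s$vol_true, CSAmin = s$csa_true)
    }
  })
  df <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(subject_id = vapply(cohort, `[[`, "", "id"),
                   stringsAsFactors = FALSE), df)
}
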