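#' Synthetic brain phantom atlas
#'
#' Generates a synthetic atlas bundle standing in for a population template:
#' a smooth ellipsoidal "brain" with three tissue intensity levels (CSF-like
#' low, gray-like mid, white-like high), a faint skull shell outside the brain
#' mask, bright hippocampal and anterior-temporal blobs at the segment
#' locations, six distinct landmark structures at the named landmark sites,
#' a smooth random texture for registration contrast, a binary brain mask and
#' segment box definitions centred on the blobs.  Intensities are on the
#' 0..400 scale used throughout the pipeline.  Fully deterministic given
#' `seed`.
#'
#' @param grid_size voxels per axis (>= 64; 128 is the full-scale default,
#'   64 a scaled-down test size with proportionally smaller segment boxes).
#' @param seed RNG seed for the texture field.
#' @param segment_size segment box edge in voxels; defaults to 64 for grids
#'   >= 128 and 32 otherwise.
#' @return an [atlas_bundle()] with attribute `phantom_params`.
#' @export
make_atlas <- function(grid_size = 128L, seed = 1L, segment_size = NULL) {
  if (grid_size < 64) stop("grid_size must be at least 64 per axis")
  if (is.null(segment_size)) segment_size <- if (grid_size >= 128) 64L else 32L
  spacing <- 192 / grid_size
  pp <- phantom_params(grid_size, spacing, seed)
  # segment boxes must fit inside the grid with a margin
  for (off in list(pp$hippo_L, pp$hippo_R, pp$anttemp_L, pp$anttemp_R)) {
    cvox <- round((pp$center_mm + off) / spacing)
    if (any(cvox - segment_size / 2 < 2) ||
        any(cvox + segment_size / 2 > grid_size - 2))
      stop("grid too small to contain ", segment_size,
           "^3 segment boxes with the required margin")
  }
  # the renderer is linear in the hippocampal blob amplitude, so subjects
  # with arbitrary atrophy factors can be composed from two renders
  t0 <- render_phantom_template(pp, atrophy = 0, clamp = FALSE)
  t1 <- render_phantom_template(pp, atrophy = 1, clamp = FALSE)
  img <- pmax(t1, 0)
  mask <- render_phantom_mask(pp)
  aff <- diag(4); aff[1:3, 1:3] <- diag(rep(spacing, 3))
  template <- as_volume(img, spacing = rep(spacing, 3), affine = aff)
  brain_mask <- as_volume(mask, spacing = rep(spacing, 3), affine = aff)
  lm <- landmark_set(lapply(pp$landmarks, function(o) pp$center_mm + o))
  specs <- list(
    segment_spec("hippocampus_L", pp$center_mm + pp$hippo_L, segment_size),
    segment_spec("hippocampus_R", pp$center_mm + pp$hippo_R, segment_size),
    segment_spec("ant_temporal_L", pp$center_mm + pp$anttemp_L, segment_size),
    segment_spec("ant_temporal_R", pp$center_mm + pp$anttemp_R, segment_size))
  out <- atlas_bundle(template, brain_mask, lm, specs)
  attr(out, "phantom_params") <- pp
  attr(out, "phantom_fields") <- list(base = t0, atrophy_unit = t1 - t0)
  attr(out, "cache") <- new.env(parent = emptyenv())
  out
}

phantom_params <- function(grid_size, spacing, seed) {
  center_mm <- rep((grid_size - 1) / 2 * spacing, 3)
  list(
    grid = rep(as.integer(grid_size), 3), spacing = spacing,
    center_mm = center_mm, seed = as.integer(seed),
    semi_axes = c(63, 73, 67),          # mm; brain ellipsoid
    ventricle_semi = c(14, 20, 14), ventricle_off = c(0, 4, 6),
    gray_shell = 0.82,                  # radius fraction where gray starts
    csf_i = 60, gray_i = 160, white_i = 280, skull_i = 100,
    hippo_L = c(-28, -6, -16), hippo_R = c(28, -6, -16),
    anttemp_L = c(-38, 22, -14), anttemp_R = c(38, 22, -14),
    # hippocampal site: a fixed dark (CSF-like) pocket plus a mid-intensity
    # tissue bump whose amplitude carries the atrophy factor; the bump peak
    # stays below the white-matter level so the block histogram range is
    # anchored by white matter and CSF, not by the structure being measured
    hippo_sigma = 9, hippo_amp = 170,
    hippo_dip_sigma = 13, hippo_dip_amp = 200,
    anttemp_sigma = 11, anttemp_amp = 140,
    anttemp_dip_sigma = 14, anttemp_dip_amp = 160,
    landmarks = list(
      eye_left = c(-24, 52, -8), eye_right = c(24, 52, -8),
      fornix_body_front = c(0, 6, 8), midbrain_center = c(0, -4, -10),
      fourth_ventricle_center = c(0, -16, -24),
      corpus_callosum_top = c(0, 10, 34)),
    landmark_amp = c(150, 150, 80, -70, -80, 90),
    landmark_sigma = c(3, 3, 2.5, 4, 2.5, 3),
    texture_amp = 12, texture_spacing_vox = 6)
}

# mm coordinate grids (three vectors) for a phantom grid.
phantom_axes_mm <- function(pp) {
  lapply(1:3, function(a) (seq_len(pp$grid[a]) - 1) * pp$spacing)
}

# squared normalized ellipsoid radius field
ellipsoid_rho2 <- function(pp, semi, offset = c(0, 0, 0)) {
  ax <- phantom_axes_mm(pp)
  cx <- pp$center_mm + offset
  x2 <- ((ax[[1]] - cx[1]) / semi[1])^2
  y2 <- ((ax[[2]] - cx[2]) / semi[2])^2
  z2 <- ((ax[[3]] - cx[3]) / semi[3])^2
  outer(outer(x2, y2, `+`), z2, `+`)
}

gaussian_blob <- function(pp, offset, sigma, amp) {
  ax <- phantom_axes_mm(pp)
  cx <- pp$center_mm + offset
  gx <- exp(-(ax[[1]] - cx[1])^2 / (2 * sigma^2))
  gy <- exp(-(ax[[2]] - cx[2])^2 / (2 * sigma^2))
  gz <- exp(-(ax[[3]] - cx[3])^2 / (2 * sigma^2))
  amp * outer(outer(gx, gy), gz)
}

render_phantom_mask <- function(pp) {
  (ellipsoid_rho2(pp, pp$semi_axes) <= 1) * 1
}

# Template intensities; the hippocampal blob amplitude carries the atrophy
# factor (blob mass scales linearly with it, mimicking volume loss).
render_phantom_template <- function(pp, atrophy = 1, clamp = TRUE) {
  rho2 <- ellipsoid_rho2(pp, pp$semi_axes)
  img <- array(0, pp$grid)
  img[rho2 <= 1.3 & rho2 > 1.05] <- pp$skull_i
  inside <- rho2 <= 1
  img[inside] <- pp$white_i
  img[inside & rho2 > pp$gray_shell^2] <- pp$gray_i
  vent <- ellipsoid_rho2(pp, pp$ventricle_semi, pp$ventricle_off) <= 1
  img[vent & inside] <- pp$csf_i
  for (off in list(pp$hippo_L, pp$hippo_R)) {
    img <- img - gaussian_blob(pp, off, pp$hippo_dip_sigma, pp$hippo_dip_amp)
    img <- img + gaussian_blob(pp, off, pp$hippo_sigma,
                               pp$hippo_amp * atrophy)
  }
  for (off in list(pp$anttemp_L, pp$anttemp_R)) {
    img <- img - gaussian_blob(pp, off, pp$anttemp_dip_sigma,
                               pp$anttemp_dip_amp)
    img <- img + gaussian_blob(pp, off, pp$anttemp_sigma,
                               pp$anttemp_amp * atrophy)
  }
  for (i in seq_along(pp$landmarks))
    img <- img + gaussian_blob(pp, pp$landmarks[[i]], pp$landmark_sigma[i],
                               pp$landmark_amp[i])
  # smooth deterministic texture for registration contrast
  withr_seed(pp$seed, {
    tex <- random_smooth_field(pp$grid, pp$texture_spacing_vox,
                               pp$texture_amp)
  })
  img <- img + tex * inside
  img <- smooth_gauss(img, 0.8)
  if (clamp) img[img < 0] <- 0
  img
}

# evaluate code with a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(code))
}

# Smooth random scalar field: white noise on a coarse B-spline control grid,
# expanded by the cubic spline basis.  sd is the approximate pointwise sd.
random_smooth_field <- function(dims, spacing_vox, sd) {
  nc <- bspline_ncontrol(dims, spacing_vox)
  coef <- array(stats::rnorm(prod(nc), 0, sd * 2.3), nc)
  pos <- lapply(dims, function(n) seq(0, n - 1))
  Bx <- bspline_basis_1d(pos[[1]], nc[1], spacing_vox)
  By <- bspline_basis_1d(pos[[2]], nc[2], spacing_vox)
  Bz <- bspline_basis_1d(pos[[3]], nc[3], spacing_vox)
  tensor3_apply(coef, Bx, By, Bz)
}

#' Default class-effect configuration for the phantom cohort
#'
#' Defines the class-conditional distributions the subject generator draws
#' from: hippocampal atrophy factors (progressive MCI mean below stable MCI),
#' 9-DOF similarity parameter ranges, nonlinear deformation amplitude,
#' intensity bias-field amplitudes, cognitive score distributions (pMCI
#' shifted by MMSE -2, ADAS +4, FAQ +3, CDR-SB +1 relative to sMCI) and APOE
#' genotype frequencies.
#'
#' @return a list of generator settings.
#' @export
default_effect_config <- function() {
  list(
    atrophy = list(sMCI = c(mean = 0.95, sd = 0.05),
                   pMCI = c(mean = 0.70, sd = 0.08),
                   range = c(0.5, 1.0)),
    rotation_deg = 6, scale_range = c(0.92, 1.08), translation_mm = 6,
    deformation_mm = 1.5, deformation_spacing_vox = 8,
    bias_slope_amp = 0.2, bias_offset_amp = 8, bias_spacing_vox = 32,
    scores = list(
      sMCI = list(mmse = c(27.5, 3.5), adas = c(12, 7), faq = c(4, 6),
                  cdr_sb = c(1.5, 2), age = c(73, 7)),
      pMCI = list(mmse = c(25.5, 3.5), adas = c(16, 7), faq = c(7, 6),
                  cdr_sb = c(2.5, 2), age = c(74, 7))),
    apoe = list(
      sMCI = c("e2/e3" = 0.12, "e3/e3" = 0.58, "e2/e4" = 0.07,
               "e4/e2" = 0.07, "e4/e4" = 0.16),
      pMCI = c("e2/e3" = 0.05, "e3/e3" = 0.35, "e2/e4" = 0.12,
               "e4/e2" = 0.12, "e4/e4" = 0.36)))
}

#' Generate one phantom subject
#'
#' Derives a native-space subject volume from the atlas by a known 9-DOF
#' similarity transform, a smooth nonlinear deformation, class-dependent
#' hippocampal atrophy, and a smooth multiplicative/additive intensity bias;
#' emits the matching landmark coordinates analytically from the ground-truth
#' transform, and draws cognitive scores, age and APOE genotype from
#' class-conditional distributions.
#'
#' The generative mapping from native coordinates `y` to atlas coordinates is
#' `x = D(T^{-1}(y))` with `D(x) = x + u(x)`; the native image is the
#' atrophied template evaluated at `x`, then perturbed voxelwise as
#' `a(y) * I + b(y)`.
#'
#' @param atlas [make_atlas()] output.
#' @param label `"sMCI"` or `"pMCI"`.
#' @param effect_config see [default_effect_config()].
#' @param seed RNG seed (one subject = one seed).
#' @param subject_id identifier string.
#' @param keep_fields keep the dense deformation and bias fields in the
#'   returned truth (several MB per subject); cohorts drop them and retain
#'   only the scalar truth plus the seed they can be regenerated from.
#' @return list with elements `volume` (native `mci_volume`), `landmarks`
#'   ([landmark_set()]), and `truth` (similarity, deformation field, bias
#'   fields, atrophy factor, native-space hippocampus centres, and the subject
#'   record row).
#' @export
make_subject <- function(atlas, label = c("sMCI", "pMCI"),
                         effect_config = default_effect_config(), seed = 1L,
                         subject_id = sprintf("sub-%04d", seed %% 10000L),
                         keep_fields = TRUE) {
  label <- match.arg(label)
  pp <- attr(atlas, "phantom_params")
  if (is.null(pp)) stop("atlas must come from make_atlas()")
  ec <- effect_config
  tmpl <- atlas$template
  out <- withr_seed(seed, {
    at <- ec$atrophy[[label]]
    atrophy <- min(max(stats::rnorm(1, at["mean"], at["sd"]),
                       ec$atrophy$range[1]), ec$atrophy$range[2])
    if (atrophy <= 0 || atrophy > 1) stop("atrophy factor outside (0, 1]")
    tr <- similarity9(
      rotation = stats::runif(3, -ec$rotation_deg, ec$rotation_deg),
      scale = stats::runif(3, ec$scale_range[1], ec$scale_range[2]),
      translation = stats::runif(3, -ec$translation_mm, ec$translation_mm),
      center = pp$center_mm)
    u <- array(0, c(pp$grid, 3))
    if (ec$deformation_mm > 0)
      for (c in 1:3)
        u[, , , c] <- random_smooth_field(pp$grid, ec$deformation_spacing_vox,
                                         ec$deformation_mm / 2.3)
    def <- displacement_field(u, tmpl)
    a_fld <- 1 + pmax(pmin(random_smooth_field(pp$grid, ec$bias_spacing_vox,
                                               ec$bias_slope_amp / 2),
                           ec$bias_slope_amp), -ec$bias_slope_amp)
    b_fld <- random_smooth_field(pp$grid, ec$bias_spacing_vox,
                                 ec$bias_offset_amp / 2)
    sc <- ec$scores[[label]]
    rec <- data.frame(
      subject_id = subject_id,
      mmse = min(30, max(0, stats::rnorm(1, sc$mmse[1], sc$mmse[2]))),
      faq = min(30, max(0, stats::rnorm(1, sc$faq[1], sc$faq[2]))),
      cdr_sb = min(18, max(0, stats::rnorm(1, sc$cdr_sb[1], sc$cdr_sb[2]))),
      adas = min(70, max(0, stats::rnorm(1, sc$adas[1], sc$adas[2]))),
      age = min(95, max(55, stats::rnorm(1, sc$age[1], sc$age[2]))),
      apoe = sample(names(ec$apoe[[label]]), 1, prob = ec$apoe[[label]]),
      label = label, stringsAsFactors = FALSE)
    list(atrophy = atrophy, tr = tr, def = def, a_fld = a_fld, b_fld = b_fld,
         rec = rec)
  })
  # native image: evaluate atrophied template at D(T^-1(y))
  pf <- attr(atlas, "phantom_fields")
  tmpl_atr <- if (out$atrophy == 1) tmpl$data else
    pmax(pf$base + out$atrophy * pf$atrophy_unit, 0)
  Y <- grid_world_coords(tmpl)
  x1 <- transform_points(invert_similarity(out$tr), Y)
  x2 <- x1 + field_u_at(out$def, x1)
  native <- interp_trilinear(tmpl_atr, world_to_voxel(tmpl, x2))
  native <- array(native, pp$grid) * out$a_fld + out$b_fld *
    (array(native, pp$grid) > 0)
  vol <- as_volume(native, spacing = tmpl$spacing, affine = tmpl$affine,
                   space = "native")
  # landmarks and hippocampus centres: Q = T(D^-1(P))
  P <- unclass(atlas$landmarks)
  hip <- rbind(pp$center_mm + pp$hippo_L, pp$center_mm + pp$hippo_R)
  allp <- rbind(P, hip)
  pinv <- allp
  for (i in 1:30) pinv <- allp - field_u_at(out$def, pinv)
  Qall <- transform_points(out$tr, pinv)
  lm <- landmark_set(`rownames<-`(Qall[1:6, , drop = FALSE], LANDMARK_NAMES))
  truth <- list(similarity = out$tr,
                deformation = if (keep_fields) out$def,
                bias_slope = if (keep_fields) out$a_fld,
                bias_offset = if (keep_fields) out$b_fld,
                atrophy = out$atrophy,
                hippo_centers_native = Qall[7:8, , drop = FALSE],
                record = out$rec, seed = as.integer(seed))
  list(volume = vol, landmarks = lm, truth = truth)
}

#' Generate a phantom cohort
#'
#' Draws `n_smci` stable and `n_pmci` progressive subjects with per-subject
#' seeds derived deterministically from `seed`.  With `dir` set, writes native
#' volumes (NIfTI), landmark JSONs, the subject CSV and a ground-truth JSON,
#' and returns a manifest of paths; otherwise returns subjects in memory.
#'
#' @param atlas [make_atlas()] output.
#' @param n_smci,n_pmci per-class subject counts (>= 1).
#' @param effect_config see [default_effect_config()].
#' @param seed cohort seed.
#' @param dir optional output directory.
#' @return list with `subjects` (list or paths), `table` (subject records) and
#'   `truth` (per-subject scalar ground truth).
#' @export
make_cohort <- function(atlas, n_smci, n_pmci,
                        effect_config = default_effect_config(), seed = 1L,
                        dir = NULL) {
  stopifnot(n_smci >= 1, n_pmci >= 1)
  labels <- c(rep("sMCI", n_smci), rep("pMCI", n_pmci))
  ids <- sprintf("sub-%04d", seq_along(labels))
  write <- !is.null(dir)
  if (write) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- vector("list", length(labels))
  recs <- vector("list", length(labels))
  truths <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    s <- make_subject(atlas, labels[i], effect_config,
                      seed = seed * 1000L + i, subject_id = ids[i],
                      keep_fields = FALSE)
    recs[[i]] <- s$truth$record
    truths[[i]] <- list(subject_id = ids[i], label = labels[i],
                        atrophy = s$truth$atrophy,
                        similarity = unclass(s$truth$similarity),
                        hippo_centers_native = s$truth$hippo_centers_native,
                        seed = s$truth$seed)
    if (write) {
      vp <- file.path(dir, paste0("vol_", ids[i], ".nii.gz"))
      lp <- file.path(dir, paste0("lm_", ids[i], ".json"))
      write_volume(s$volume, vp)
      write_landmarks(s$landmarks, lp)
      subjects[[i]] <- list(volume = vp, landmarks = lp)
    } else {
      subjects[[i]] <- s
    }
  }
  table <- do.call(rbind, recs)
  if (write) {
    write_subject_table(table, file.path(dir, "subjects.csv"))
    jsonlite::write_json(truths, file.path(dir, "truth.json"), digits = NA,
                         auto_unbox = TRUE)
  }
  list(subjects = subjects, table = table, truth = truths,
       manifest = if (write) list(
         dir = dir, subjects_csv = file.path(dir, "subjects.csv"),
         truth_json = file.path(dir, "truth.json"),
         volumes = vapply(subjects, `[[`, "", "volume"),
         landmarks = vapply(subjects, `[[`, "", "landmarks")) else NULL)
}
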