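#' Analytic optic nerve head phantom parameters
#'
#' Defines a radially symmetric analytic eye used to test the volumetric
#' pipeline against closed-form / quadrature ground truth. Depth `z`
#' increases posteriorly. The phantom surfaces are
#' `BM(r) = baseline_z_mm + bm_bow_mm * (1 - (r/R)^2)` (positive
#' `bm_bow_mm` = posterior bowing) and
#' `ILM(r) = BM(r) - bump_amp_mm * exp(-r^2 / (2 * bump_sigma_mm^2)) +
#' cup_depth_mm * max(0, 1 - (r / cup_radius_mm)^2)` (a Gaussian swelling of
#' the nerve head plus an optional central parabolic cup dip). The BM trace
#' is left unsegmented inside the opening (`r < opening_radius_mm`).
#'
#' @param R_mm truncation radius (half scan width), default 2.795.
#' @param opening_radius_mm BM opening half-width, default 0.75.
#' @param bump_amp_mm,bump_sigma_mm Gaussian ILM swelling amplitude / width.
#' @param bm_bow_mm quadratic BM deflection amplitude (positive posterior).
#' @param cup_depth_mm,cup_radius_mm central parabolic ILM dip.
#' @param baseline_z_mm flat BM reference depth, default 1.
#' @param n_samples_per_scan lateral samples per B-scan, default 1024.
#' @param scale_z_um axial microns per pixel, default 3.87.
#' @param ilm_asym optional `function(r_mm, theta_deg)` returning an additive
#'   anterior ILM elevation (mm), for asymmetry experiments; the quadrature
#'   oracle refuses asymmetric phantoms.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(R_mm = 2.795, opening_radius_mm = 0.75,
                           bump_amp_mm = 0.5, bump_sigma_mm = 0.8,
                           bm_bow_mm = 0, cup_depth_mm = 0,
                           cup_radius_mm = 0.4, baseline_z_mm = 1,
                           n_samples_per_scan = 1024L, scale_z_um = 3.87,
                           ilm_asym = NULL) {
  if (R_mm <= 0 || bump_sigma_mm <= 0 || cup_radius_mm <= 0)
    stop("radii and sigma must be positive")
  if (opening_radius_mm <= 0 || opening_radius_mm >= R_mm)
    stop("opening_radius_mm must lie in (0, R_mm)")
  if (n_samples_per_scan < 16L) stop("need at least 16 samples per scan")
  if (!is.null(ilm_asym) && !is.function(ilm_asym))
    stop("ilm_asym must be a function(r_mm, theta_deg) or NULL")
  structure(list(R_mm = R_mm, opening_radius_mm = opening_radius_mm,
                 bump_amp_mm = bump_amp_mm, bump_sigma_mm = bump_sigma_mm,
                 bm_bow_mm = bm_bow_mm, cup_depth_mm = cup_depth_mm,
                 cup_radius_mm = cup_radius_mm, baseline_z_mm = baseline_z_mm,
                 n_samples_per_scan = as.integer(n_samples_per_scan),
                 scale_z_um = scale_z_um, ilm_asym = ilm_asym),
            class = "phantom_params")
}

phantom_bm_true <- function(p, r) p$baseline_z_mm + p$bm_bow_mm * (1 - (r / p$R_mm)^2)

phantom_ilm <- function(p, r, theta_deg = 0) {
  z <- phantom_bm_true(p, r) -
    p$bump_amp_mm * exp(-r^2 / (2 * p$bump_sigma_mm^2)) +
    p$cup_depth_mm * pmax(0, 1 - (r / p$cup_radius_mm)^2)
  if (!is.null(p$ilm_asym)) z <- z - p$ilm_asym(r, theta_deg)
  z
}

#' Generate a synthetic radial scan set from an analytic phantom
#'
#' Samples the phantom surfaces along 6 diameters at 0, 30, ..., 150 degrees
#' with `n_samples_per_scan` lateral samples each, leaves BM unsegmented
#' strictly inside the opening, marks the opening margins at the samples
#' nearest `±opening_radius_mm`, and returns the set already truncated to
#' its full common width (`2 * R_mm`).
#'
#' @param params a [phantom_params()].
#' @param subject_id,eye_id identifiers for the generated eye.
#' @return A truncated [radial_scan_set()].
#' @export
make_radial_phantom <- function(params, subject_id = "phantom", eye_id = "OD") {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  n <- p$n_samples_per_scan
  scale_x_um <- 2 * p$R_mm * 1000 / (n - 1)
  x_mm <- seq(-p$R_mm, p$R_mm, length.out = n)
  ml <- which.min(abs(x_mm + p$opening_radius_mm)) - 1L  # 0-based
  mr <- which.min(abs(x_mm - p$opening_radius_mm)) - 1L
  scans <- lapply(required_angles(), function(a) {
    theta <- ifelse(x_mm >= 0, a, a + 180)
    r <- abs(x_mm)
    ilm <- phantom_ilm(p, r, theta)
    bm <- phantom_bm_true(p, r)
    open <- seq_along(x_mm) > ml + 1L & seq_along(x_mm) < mr + 1L
    bm[open] <- NA_real_
    segmented_bscan(a, x_px = 0:(n - 1L),
                    ilm_z_px = ilm * 1000 / p$scale_z_um,
                    bm_z_px = bm * 1000 / p$scale_z_um,
                    margin_left_idx = ml, margin_right_idx = mr,
                    scale_x_um = scale_x_um, scale_z_um = p$scale_z_um)
  })
  truncate_scan_set(scans, subject_id = subject_id, eye_id = eye_id)
}

# representation-specific continuous BM depth for the analytic phantom
phantom_bm_rep <- function(p, r, rep) {
  r0 <- p$opening_radius_mm
  chw <- rep$central_half_width_mm
  switch(rep$mode,
    traditional = ifelse(r < r0, phantom_bm_true(p, r0), phantom_bm_true(p, r)),
    estimated   = ifelse(r < chw, phantom_bm_true(p, chw), phantom_bm_true(p, r)),
    excluded    = phantom_bm_true(p, r))
}

phantom_quad <- function(f, lo, hi, breaks) {
  pts <- sort(unique(c(lo, hi, breaks[breaks > lo & breaks < hi])))
  tot <- 0
  for (i in seq_len(length(pts) - 1L))
    tot <- tot + stats::integrate(f, pts[i], pts[i + 1L],
                                  subdivisions = 1000L,
                                  rel.tol = 1e-10, abs.tol = 1e-12)$value
  tot
}

#' Quadrature oracle volumes for a radially symmetric phantom
#'
#' Independent ground truth for [compute_volumes()]: the representation-
#' specific height profiles are integrated as solids of revolution,
#' `2 * pi * integral(r * h(r) dr)`, by adaptive quadrature on the analytic
#' surfaces; in `"chord"` base mode the result is scaled by `3 / pi` (the
#' inscribed-dodecagon to disk area ratio). Refuses asymmetric phantoms.
#'
#' @param params a [phantom_params()] without `ilm_asym`.
#' @param rep a [bm_rep()].
#' @param base_mode `"chord"` or `"sector"`.
#' @return list with `onhv_mm3`, `bmdv_mm3`, `cv_mm3`.
#' @export
phantom_oracle_volumes <- function(params, rep = bm_rep("traditional"),
                                   base_mode = c("chord", "sector")) {
  base_mode <- match.arg(base_mode)
  stopifnot(inherits(params, "phantom_params"))
  if (!is.null(params$ilm_asym))
    stop("the 1-D radial oracle is undefined for asymmetric phantoms")
  p <- params
  R <- p$R_mm
  lo <- if (rep$mode == "excluded") rep$central_half_width_mm else 0
  if (lo >= R) stop("central_half_width_mm must be smaller than R_mm")
  breaks <- c(p$opening_radius_mm, p$cup_radius_mm, rep$central_half_width_mm,
              p$bump_sigma_mm)
  secant_z <- phantom_bm_true(p, R)
  h_onh <- function(r) pmax(0, phantom_bm_rep(p, r, rep) - phantom_ilm(p, r))
  h_bmdv <- function(r) phantom_bm_rep(p, r, rep) - secant_z
  ilm_r0 <- phantom_ilm(p, p$opening_radius_mm)
  h_cup <- function(r)
    ifelse(r <= p$opening_radius_mm, pmax(0, phantom_ilm(p, r) - ilm_r0), 0)
  fac <- if (base_mode == "chord") 3 / pi else 1
  vol <- function(h, lo) fac * 2 * pi * phantom_quad(function(r) r * h(r), lo, R, breaks)
  list(onhv_mm3 = vol(h_onh, lo),
       bmdv_mm3 = vol(h_bmdv, lo),
       cv_mm3 = vol(h_cup, 0))
}

#' Solve for the Gaussian bump amplitude giving a target ONHV
#'
#' The oracle ONHV is affine in the bump amplitude when the cup never clamps
#' the height profile, so the amplitude reproducing any non-negative target
#' volume is recovered exactly from two oracle evaluations.
#'
#' @param target_onhv_mm3 desired oracle ONHV (mm^3), `>= 0`.
#' @param params a [phantom_params()]; its `bump_amp_mm` is ignored.
#' @param rep,base_mode as in [phantom_oracle_volumes()].
#' @return the bump amplitude `A` in mm.
#' @export
calibrate_bump_amplitude <- function(target_onhv_mm3, params,
                                     rep = bm_rep("traditional"),
                                     base_mode = "chord") {
  if (target_onhv_mm3 < 0) stop("target ONHV must be non-negative")
  p0 <- params; p0$bump_amp_mm <- 0
  p1 <- params; p1$bump_amp_mm <- 1
  v0 <- phantom_oracle_volumes(p0, rep, base_mode)$onhv_mm3
  v1 <- phantom_oracle_volumes(p1, rep, base_mode)$onhv_mm3
  if (v1 - v0 <= 0) stop("degenerate phantom: ONHV not increasing in amplitude")
  (target_onhv_mm3 - v0) / (v1 - v0)
}

#' Cohort simulation parameters
#'
#' Generating laws for a synthetic cohort of paired eyes with intracranial
#' pressure (ICP, cm H2O), ganglion cell complex volume (GCCV, mm^3) and the
#' three optic nerve head volumes (mm^3). Default intercepts and slopes are
#' realistic clinical values for the traditional BM representation; each
#' eye-level volume is
#' `intercept + slope * ICP + gcc_coef * GCCV + subject effect + noise`,
#' with a shared-subject random intercept (sd `sd_subject_mm3`) drawn
#' independently per outcome and eye-level residual sd `sd_eye_mm3`.
#'
#' @param n_subjects number of subjects (`>= 2`).
#' @param p_both_eyes probability both eyes are usable (default 0.76; a
#'   single retained eye is OD or OS with equal probability).
#' @param icp_range_cmH2O ICP sampling range, default `c(10, 55)`.
#' @param onhv_intercept_mm3,onhv_slope_mm3_per_cmH2O ONHV generating law
#'   (defaults 4.606, 0.136).
#' @param bmdv_intercept_mm3,bmdv_slope_mm3_per_cmH2O BMDV generating law
#'   (defaults 2.100, -0.038).
#' @param cv_intercept_mm3,cv_slope_mm3_per_cmH2O cup volume law (defaults
#'   0.15, -0.003).
#' @param gcc_mean_mm3,gcc_sd_mm3 GCCV distribution (defaults 0.65, 0.07).
#' @param gcc_coef ONHV response per mm^3 of GCCV (default 0 = univariable
#'   law).
#' @param sd_subject_mm3,sd_eye_mm3 random-intercept and residual sds
#'   (defaults 0.5, 0.3).
#' @param seed optional integer seed consumed by [simulate_cohort()].
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 17L, p_both_eyes = 0.76,
                          icp_range_cmH2O = c(10, 55),
                          onhv_intercept_mm3 = 4.606,
                          onhv_slope_mm3_per_cmH2O = 0.136,
                          bmdv_intercept_mm3 = 2.100,
                          bmdv_slope_mm3_per_cmH2O = -0.038,
                          cv_intercept_mm3 = 0.15,
                          cv_slope_mm3_per_cmH2O = -0.003,
                          gcc_mean_mm3 = 0.65, gcc_sd_mm3 = 0.07,
                          gcc_coef = 0,
                          sd_subject_mm3 = 0.5, sd_eye_mm3 = 0.3,
                          seed = NULL) {
  if (n_subjects < 2L) stop("n_subjects must be at least 2")
  if (p_both_eyes < 0 || p_both_eyes > 1) stop("p_both_eyes must be in [0, 1]")
  if (any(icp_range_cmH2O <= 0) || any(icp_range_cmH2O >= 100) ||
      diff(icp_range_cmH2O) < 0)
    stop("icp_range_cmH2O must be an increasing range within (0, 100)")
  if (sd_subject_mm3 < 0 || sd_eye_mm3 < 0 || gcc_sd_mm3 < 0)
    stop("scales must be non-negative")
  structure(as.list(environment()), class = "cohort_params")
}

#' Simulate a cohort of eyes with known generating laws
#'
#' @param params a [cohort_params()].
#' @return An `onh_cohort` data frame with one row per eye: `subject_id`,
#'   `eye` ("OD"/"OS"), `icp_cmH2O`, `gccv_mm3`, `onhv_mm3`, `bmdv_mm3`,
#'   `cv_mm3`. Reproducible under `params$seed`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(as.integer(p$seed))
  rows <- vector("list", p$n_subjects)
  for (i in seq_len(p$n_subjects)) {
    icp <- stats::runif(1, p$icp_range_cmH2O[1], p$icp_range_cmH2O[2])
    u_onhv <- stats::rnorm(1, 0, p$sd_subject_mm3)
    u_bmdv <- stats::rnorm(1, 0, p$sd_subject_mm3)
    u_cv <- stats::rnorm(1, 0, p$sd_subject_mm3)
    both <- stats::runif(1) < p$p_both_eyes
    eyes <- if (both) c("OD", "OS")
            else if (stats::runif(1) < 0.5) "OD" else "OS"
    sub <- lapply(eyes, function(e) {
      gccv <- stats::rnorm(1, p$gcc_mean_mm3, p$gcc_sd_mm3)
      data.frame(
        subject_id = sprintf("S%03d", i), eye = e, icp_cmH2O = icp,
        gccv_mm3 = gccv,
        onhv_mm3 = p$onhv_intercept_mm3 + p$onhv_slope_mm3_per_cmH2O * icp +
          p$gcc_coef * gccv + u_onhv + stats::rnorm(1, 0, p$sd_eye_mm3),
        bmdv_mm3 = p$bmdv_intercept_mm3 + p$bmdv_slope_mm3_per_cmH2O * icp +
          u_bmdv + stats::rnorm(1, 0, p$sd_eye_mm3),
        cv_mm3 = p$cv_intercept_mm3 + p$cv_slope_mm3_per_cmH2O * icp +
          u_cv + stats::rnorm(1, 0, p$sd_eye_mm3),
        stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("onh_cohort", "data.frame")
  out
}
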