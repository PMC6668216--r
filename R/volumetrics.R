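#' Truncate a set of radial B-scans to a common width
#'
#' All six B-scans are trimmed symmetrically about their center sample so
#' they span a common lateral width. When `width_mm` is omitted it is the
#' width of the shortest scan in the set, which is the rule used when a
#' sample's scans differ in physical length.
#'
#' @param scans a list of 6 [segmented_bscan()] objects at angles
#'   0, 30, ..., 150, or an untruncated [radial_scan_set()].
#' @param width_mm common width in mm; default the minimum scan width.
#' @param subject_id,eye_id identifiers used when `scans` is a bare list.
#' @return A truncated [radial_scan_set()] with `truncated_width_mm` set.
#'   Margins are re-indexed to the retained samples; a margin falling
#'   outside the truncated span is an error.
#' @export
truncate_scan_set <- function(scans, width_mm = NULL,
                              subject_id = "subject", eye_id = "OD") {
  if (inherits(scans, "radial_scan_set")) {
    subject_id <- scans$subject_id; eye_id <- scans$eye_id
    scans <- scans$scans
  }
  set <- radial_scan_set(subject_id, eye_id, scans)  # validates count/angles
  widths <- vapply(set$scans, scan_width_mm, numeric(1))
  if (is.null(width_mm)) width_mm <- min(widths)
  if (width_mm <= 0) stop("width_mm must be positive")
  tol <- 1e-9
  if (width_mm > min(widths) + tol)
    stop(sprintf("width_mm = %.4f mm exceeds the shortest scan width (%.4f mm)",
                 width_mm, min(widths)))
  half <- width_mm / 2
  trimmed <- lapply(set$scans, function(scan) {
    g <- scan_mm(scan)
    keep <- which(abs(g$x_mm) <= half + tol)
    n_left <- keep[1] - 1L
    ml <- scan$margin_left_idx - n_left
    mr <- scan$margin_right_idx - n_left
    if (ml < 0L || mr > length(keep) - 1L)
      stop(sprintf("scan at %g%s: BM opening margin lost by truncation",
                   scan$angle_deg, "°"))
    segmented_bscan(scan$angle_deg,
                    scan$x_px[keep], scan$ilm_z_px[keep], scan$bm_z_px[keep],
                    ml, mr, scan$scale_x_um, scan$scale_z_um)
  })
  radial_scan_set(subject_id, eye_id, trimmed, truncated_width_mm = width_mm)
}

#' Continuous Bruch's membrane boundary under a representation
#'
#' Builds a continuous BM depth curve (mm) per lateral sample of a truncated
#' scan, plus a validity mask, under the chosen representation:
#' * `traditional`: segmented BM joined by a straight chord between the
#'   rater-marked opening margins; every sample valid.
#' * `estimated`: segmented BM outside `central_half_width_mm` of the scan
#'   center; inside, the chord joining the BM depths interpolated at exactly
#'   that distance on either side; every sample valid.
#' * `excluded`: segmented BM outside the central region; samples strictly
#'   inside it (or without segmented BM) marked invalid and excluded from
#'   volume integration downstream.
#'
#' @param scan a truncated [segmented_bscan()].
#' @param rep a [bm_rep()] representation.
#' @return list with `bm_mm` (depth per sample, mm) and `valid` (logical).
#' @export
bm_boundary <- function(scan, rep = bm_rep("traditional")) {
  stopifnot(inherits(scan, "segmented_bscan"), inherits(rep, "bm_representation"))
  g <- scan_mm(scan)
  x <- g$x_mm; bm <- g$bm_mm
  n <- length(x)
  ml <- scan$margin_left_idx + 1L; mr <- scan$margin_right_idx + 1L
  if (rep$mode == "traditional") {
    out <- bm
    inside <- seq_len(n) > ml & seq_len(n) < mr
    if (any(inside))
      out[inside] <- bm[ml] + (bm[mr] - bm[ml]) * (x[inside] - x[ml]) / (x[mr] - x[ml])
    return(list(bm_mm = out, valid = rep(TRUE, n)))
  }
  chw <- rep$central_half_width_mm
  R <- max(abs(x))
  if (chw >= R - 1e-9)
    stop("central_half_width_mm must be smaller than the truncation radius")
  if (rep$mode == "estimated") {
    seg <- !is.na(bm)
    if (!any(x[seg] <= -chw) || !any(x[seg] >= chw))
      stop("estimated representation needs segmented BM at and beyond ±central_half_width_mm")
    zl <- stats::approx(x[seg], bm[seg], xout = -chw, rule = 1)$y
    zr <- stats::approx(x[seg], bm[seg], xout = chw, rule = 1)$y
    out <- bm
    inside <- abs(x) < chw
    out[inside] <- zl + (zr - zl) * (x[inside] + chw) / (2 * chw)
    # samples outside the central region but inside the opening (opening wider
    # than the central region) keep the traditional chord so the curve stays
    # continuous; flag them via NA-fill from the margins chord
    gap <- is.na(out)
    if (any(gap))
      out[gap] <- bm[ml] + (bm[mr] - bm[ml]) * (x[gap] - x[ml]) / (x[mr] - x[ml])
    return(list(bm_mm = out, valid = rep(TRUE, n)))
  }
  # excluded
  valid <- abs(x) >= chw - 1e-9 & !is.na(bm)
  list(bm_mm = bm, valid = valid)
}

#' Secant line through the outermost Bruch's membrane points
#'
#' The per-scan reference line for BM displacement: the straight line through
#' the segmented BM depths at the first and last retained lateral samples of
#' a truncated scan.
#'
#' @param scan a truncated [segmented_bscan()].
#' @return list of class `secant_line` with `z0_mm`, `z1_mm` (depths at the
#'   left/right truncation edges) and `x0_mm`, `x1_mm` (edge positions,
#'   centered coordinates).
#' @export
secant_of_scan <- function(scan) {
  g <- scan_mm(scan)
  n <- length(g$x_mm)
  if (is.na(g$bm_mm[1]) || is.na(g$bm_mm[n]))
    stop("BM must be defined at both outermost retained samples")
  structure(list(z0_mm = g$bm_mm[1], z1_mm = g$bm_mm[n],
                 x0_mm = g$x_mm[1], x1_mm = g$x_mm[n]),
            class = "secant_line")
}

secant_depth <- function(secant, x_mm) {
  secant$z0_mm + (secant$z1_mm - secant$z0_mm) *
    (x_mm - secant$x0_mm) / (secant$x1_mm - secant$x0_mm)
}

#' Optic nerve head height profile of one scan
#'
#' Height above the (representation-specific) BM boundary:
#' `BM depth - ILM depth`, clamped at zero where the ILM dips posterior to
#' the boundary (the optic cup region is excluded from ONHV).
#'
#' @param scan a truncated [segmented_bscan()].
#' @param bm_curve,valid output of [bm_boundary()] for the same scan.
#' @return list with `value` (height per sample, mm, `>= 0`) and `valid`.
#' @export
onh_height <- function(scan, bm_curve, valid) {
  g <- scan_mm(scan)
  if (length(bm_curve) != length(g$ilm_mm) || length(valid) != length(g$ilm_mm))
    stop("bm_curve/valid length does not match the scan")
  h <- bm_curve - g$ilm_mm
  h[!is.na(h) & h < 0] <- 0
  list(value = h, valid = valid & !is.na(h))
}

#' Signed Bruch's membrane displacement profile of one scan
#'
#' `BM depth - secant depth` per sample: positive where BM lies posterior to
#' (deeper than) the secant, negative where it is deflected anteriorly
#' (toward the vitreous). Never clamped.
#'
#' @inheritParams onh_height
#' @param secant a [secant_of_scan()] line for the same scan.
#' @return list with `value` (signed displacement, mm) and `valid`.
#' @export
bm_displacement <- function(scan, bm_curve, valid, secant) {
  g <- scan_mm(scan)
  if (length(bm_curve) != length(g$x_mm) || length(valid) != length(g$x_mm))
    stop("bm_curve/valid length does not match the scan")
  d <- bm_curve - secant_depth(secant, g$x_mm)
  list(value = d, valid = valid & !is.na(d))
}

#' Cup height profile of one scan
#'
#' The cup top is the line joining the ILM points immediately above the BM
#' opening margins. Between the margins the cup height is
#' `max(0, ILM depth - cup-top depth)`; where the ILM lies anterior to the
#' cup top, and everywhere outside the margins, the height is zero.
#'
#' @param scan a truncated [segmented_bscan()].
#' @return list with `value` (cup height, mm, zero outside the margins),
#'   `valid` (all `TRUE`; cup volume has no excluded regions) and `inside`
#'   (logical, the inter-margin region).
#' @export
cup_height <- function(scan) {
  g <- scan_mm(scan)
  n <- length(g$x_mm)
  ml <- scan$margin_left_idx + 1L; mr <- scan$margin_right_idx + 1L
  top <- g$ilm_mm[ml] + (g$ilm_mm[mr] - g$ilm_mm[ml]) *
    (g$x_mm - g$x_mm[ml]) / (g$x_mm[mr] - g$x_mm[ml])
  inside <- seq_len(n) >= ml & seq_len(n) <= mr
  h <- numeric(n)
  h[inside] <- pmax(0, g$ilm_mm[inside] - top[inside])
  list(value = h, valid = rep(TRUE, n), inside = inside)
}

#' Resample one eye's scans into 12 half-scan radial profiles
#'
#' Each truncated B-scan is split at its center into two half-scans (azimuths
#' theta and theta + 180), giving 12 half-scans at 30 degree spacing. The
#' chosen surface (optic nerve head height, BM displacement, or cup height)
#' is linearly interpolated onto a common uniform radial grid of
#' `n_intervals + 1` nodes from the center (`r = 0`) to the truncation radius.
#'
#' @param scan_set a truncated [radial_scan_set()].
#' @param surface one of `"onh_height"`, `"bm_displacement"`, `"cup_height"`.
#' @param rep a [bm_rep()]; ignored by the cup surface, which always uses the
#'   traditional opening geometry.
#' @param n_intervals radial intervals per half-scan (default 510).
#' @return list of 12 `half_scan_profile` objects, each with `theta_deg`,
#'   `r_mm` (length `n_intervals + 1`), `height_mm`, `valid`.
#' @export
build_half_profiles <- function(scan_set,
                                surface = c("onh_height", "bm_displacement",
                                            "cup_height"),
                                rep = bm_rep("traditional"),
                                n_intervals = 510L) {
  surface <- match.arg(surface)
  stopifnot(inherits(scan_set, "radial_scan_set"))
  if (!is_truncated(scan_set))
    stop("scan set must be truncated first (see truncate_scan_set)")
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L) stop("n_intervals must be at least 1")
  R <- scan_set$truncated_width_mm / 2
  r_grid <- seq(0, R, length.out = n_intervals + 1L)
  excluded <- rep$mode == "excluded"
  chw <- rep$central_half_width_mm

  profiles <- vector("list", 12L)
  k <- 1L
  for (scan in scan_set$scans) {
    prof <- switch(surface,
      onh_height = {
        b <- bm_boundary(scan, rep)
        onh_height(scan, b$bm_mm, b$valid)
      },
      bm_displacement = {
        b <- bm_boundary(scan, rep)
        bm_displacement(scan, b$bm_mm, b$valid, secant_of_scan(scan))
      },
      cup_height = cup_height(scan))
    x <- scan_mm(scan)$x_mm
    v <- prof$value
    ok <- !is.na(v)
    for (side in c(1, -1)) {
      xout <- side * r_grid
      h <- stats::approx(x[ok], v[ok], xout = xout, rule = 2)$y
      valid <- rep(TRUE, length(r_grid))
      if (excluded && surface != "cup_height")
        valid <- r_grid >= chw - 1e-9
      theta <- scan$angle_deg + if (side > 0) 0 else 180
      profiles[[k]] <- structure(
        list(theta_deg = theta, r_mm = r_grid, height_mm = h, valid = valid),
        class = "half_scan_profile")
      k <- k + 1L
    }
  }
  profiles[order(vapply(profiles, function(p) p$theta_deg, numeric(1)))]
}

#' Integrate 12 half-scan profiles into a volume by trapezoidal prisms
#'
#' The 12 half-scans at 30 degree spacing bound 12 wedges. Each wedge is
#' filled with one trapezoidal prism per radial interval whose height is the
#' mean of the four corner surface values; a prism with any invalid corner is
#' excluded from the sum. Two base-area conventions are available:
#' `"chord"` uses the planar trapezoid between the two bounding rays,
#' area `(r2^2 - r1^2) * sin(15deg) * cos(15deg)` (a flat surface then
#' integrates to the inscribed dodecagon area, `3 R^2 h`); `"sector"` uses
#' the annular sector, `(pi / 12) * (r2^2 - r1^2)` (a flat surface integrates
#' to the full disk, `pi R^2 h`).
#'
#' @param profiles list of 12 `half_scan_profile` objects on identical radial
#'   grids (see [build_half_profiles()]).
#' @param base_mode `"chord"` (default) or `"sector"`.
#' @return volume in mm^3, with attributes `n_wedges`,
#'   `n_intervals_per_wedge` and `n_prisms_summed` describing the
#'   discretization actually used.
#' @export
integrate_wedges <- function(profiles, base_mode = c("chord", "sector")) {
  base_mode <- match.arg(base_mode)
  if (length(profiles) != 12L) stop("need exactly 12 half-scan profiles")
  thetas <- vapply(profiles, function(p) p$theta_deg, numeric(1))
  o <- order(thetas)
  profiles <- profiles[o]; thetas <- thetas[o]
  if (any(abs(diff(thetas) - 30) > 1e-6))
    stop("half-scan azimuths must be 30 degrees apart")
  r <- profiles[[1]]$r_mm
  for (p in profiles)
    if (length(p$r_mm) != length(r) || any(abs(p$r_mm - r) > 1e-12))
      stop("all profiles must share one radial grid")
  ni <- length(r) - 1L
  r1 <- r[-length(r)]; r2 <- r[-1]
  base <- switch(base_mode,
                 chord  = (r2^2 - r1^2) * sin(pi / 12) * cos(pi / 12),
                 sector = (pi / 12) * (r2^2 - r1^2))
  H <- vapply(profiles, function(p) p$height_mm, numeric(ni + 1L))
  V <- vapply(profiles, function(p) p$valid, logical(ni + 1L))
  vol <- 0
  n_summed <- 0L
  for (w in seq_len(12L)) {
    wn <- if (w == 12L) 1L else w + 1L
    h_mean <- (H[-(ni + 1L), w] + H[-1L, w] + H[-(ni + 1L), wn] + H[-1L, wn]) / 4
    keep <- V[-(ni + 1L), w] & V[-1L, w] & V[-(ni + 1L), wn] & V[-1L, wn]
    vol <- vol + sum(base[keep] * h_mean[keep])
    n_summed <- n_summed + sum(keep)
  }
  structure(vol, n_wedges = 12L, n_intervals_per_wedge = ni,
            n_prisms_summed = n_summed)
}

#' Compute ONHV, BMDV and CV for one eye
#'
#' Orchestrates the full volumetric pipeline on a truncated radial scan set:
#' optic nerve head volume (ONHV) from the clamped height surface above the
#' representation-specific BM boundary; BM displacement volume (BMDV) from
#' the signed displacement between BM and the per-scan secant through the
#' outermost BM points; cup volume (CV) from the cup height surface (CV is
#' representation-independent).
#'
#' @param scan_set a truncated [radial_scan_set()].
#' @param rep a [bm_rep()].
#' @param base_mode `"chord"` or `"sector"` (see [integrate_wedges()]).
#' @param n_intervals radial intervals per half-scan (default 510).
#' @return An object of class `volume_result`: list with `onhv_mm3`,
#'   `bmdv_mm3`, `cv_mm3`, `representation`, `base_mode`, `subject_id`,
#'   `eye_id`.
#' @export
compute_volumes <- function(scan_set, rep = bm_rep("traditional"),
                            base_mode = c("chord", "sector"),
                            n_intervals = 510L) {
  base_mode <- match.arg(base_mode)
  onhv <- integrate_wedges(
    build_half_profiles(scan_set, "onh_height", rep, n_intervals), base_mode)
  bmdv <- integrate_wedges(
    build_half_profiles(scan_set, "bm_displacement", rep, n_intervals), base_mode)
  cv <- integrate_wedges(
    build_half_profiles(scan_set, "cup_height", rep, n_intervals), base_mode)
  structure(
    list(onhv_mm3 = as.numeric(onhv), bmdv_mm3 = as.numeric(bmdv),
         cv_mm3 = as.numeric(cv), representation = rep, base_mode = base_mode,
         subject_id = scan_set$subject_id, eye_id = scan_set$eye_id),
    class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf(
    "<volume_result> %s/%s [%s BM, %s base]\n  ONHV %.4f mm^3  BMDV %+.4f mm^3  CV %.4f mm^3\n",
    x$subject_id, x$eye_id, x$representation$mode, x$base_mode,
    x$onhv_mm3, x$bmdv_mm3, x$cv_mm3))
  invisible(x)
}

#' Macular ganglion cell complex volume in a centered disk
#'
#' Sums thickness times pixel area over all pixels whose centers lie within
#' a disk centered on the fovea (default diameter 3 mm).
#'
#' @param grid a [macula_grid()].
#' @param diameter_mm disk diameter in mm (default 3).
#' @return volume in mm^3.
#' @export
gcc_volume <- function(grid, diameter_mm = 3.0) {
  stopifnot(inherits(grid, "macula_grid"))
  rad <- diameter_mm / 2
  fx <- grid$fovea_xy_mm[1]; fy <- grid$fovea_xy_mm[2]
  ext_x <- ncol(grid$thickness_mm) * grid$pixel_dx_mm
  ext_y <- nrow(grid$thickness_mm) * grid$pixel_dy_mm
  if (fx - rad < 0 || fx + rad > ext_x || fy - rad < 0 || fy + rad > ext_y)
    stop("disk extends beyond the thickness grid")
  xc <- (seq_len(ncol(grid$thickness_mm)) - 0.5) * grid$pixel_dx_mm
  yc <- (seq_len(nrow(grid$thickness_mm)) - 0.5) * grid$pixel_dy_mm
  d2 <- outer((yc - fy)^2, (xc - fx)^2, `+`)
  inside <- d2 <= rad^2
  sum(grid$thickness_mm[inside]) * grid$pixel_dx_mm * grid$pixel_dy_mm
}

#' Flag inter-rater segmentation disagreements
#'
#' Indices (1-based) where two raters' boundary depth traces differ by
#' strictly more than `threshold_px` pixels; such locations are reviewed
#' before re-segmentation.
#'
#' @param seg_a,seg_b equal-length numeric depth traces in pixels.
#' @param threshold_px disagreement threshold in pixels (default 2; strictly
#'   greater differences are flagged).
#' @return integer vector of flagged sample indices (possibly empty).
#' @export
rater_disagreement <- function(seg_a, seg_b, threshold_px = 2) {
  if (length(seg_a) != length(seg_b))
    stop("rater traces must have equal length")
  which(abs(seg_a - seg_b) > threshold_px)
}
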