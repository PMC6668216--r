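#' Segmented radial OCT B-scan
#'
#' Container for one segmented B-scan of the optic nerve head: the internal
#' limiting membrane (ILM) and Bruch's membrane (BM) depth traces in pixels,
#' the rater-marked BM opening margin samples, and the device scaling.
#' Depth (`z`) increases posteriorly, so the ILM has smaller depth than BM
#' wherever tissue is present.
#'
#' @param angle_deg scan orientation in degrees; one of 0, 30, 60, 90, 120,
#'   150.
#' @param x_px integer lateral sample indices (0-based, strictly increasing).
#' @param ilm_z_px ILM depth per sample, in pixels (may be fractional).
#' @param bm_z_px BM depth per sample, in pixels; `NA` inside the BM opening
#'   (strictly between the margin samples).
#' @param margin_left_idx,margin_right_idx 0-based indices into `x_px` of the
#'   rater-marked BM opening margins; BM must be defined at the margins and
#'   everywhere outside them.
#' @param scale_x_um,scale_z_um microns per pixel laterally / axially.
#' @return An object of class `segmented_bscan`.
#' @seealso [radial_scan_set()], [truncate_scan_set()]
#' @export
segmented_bscan <- function(angle_deg, x_px, ilm_z_px, bm_z_px,
                            margin_left_idx, margin_right_idx,
                            scale_x_um, scale_z_um) {
  stopifnot(length(angle_deg) == 1L, length(scale_x_um) == 1L,
            length(scale_z_um) == 1L)
  if (!angle_deg %in% c(0, 30, 60, 90, 120, 150))
    stop("angle_deg must be one of 0, 30, 60, 90, 120, 150; got ", angle_deg)
  n <- length(x_px)
  if (n < 3L) stop("a scan needs at least 3 lateral samples")
  if (length(ilm_z_px) != n || length(bm_z_px) != n)
    stop("x_px, ilm_z_px and bm_z_px must have equal length")
  if (any(diff(x_px) <= 0)) stop("x_px must be strictly increasing")
  if (scale_x_um <= 0 || scale_z_um <= 0) stop("scales must be positive")
  ml <- as.integer(margin_left_idx); mr <- as.integer(margin_right_idx)
  if (is.na(ml) || is.na(mr) || ml >= mr)
    stop("margin_left_idx must be smaller than margin_right_idx")
  if (ml < 0L || mr > n - 1L)
    stop("margin indices must lie inside the lateral sample range")
  outside <- c(seq_len(ml + 1L), seq.int(mr + 1L, n))
  if (anyNA(bm_z_px[outside]))
    stop("bm_z_px must be defined at the margins and everywhere outside the opening")
  if (anyNA(ilm_z_px)) stop("ilm_z_px must be defined at every sample")
  structure(
    list(angle_deg = as.numeric(angle_deg),
         x_px = as.numeric(x_px),
         ilm_z_px = as.numeric(ilm_z_px),
         bm_z_px = as.numeric(bm_z_px),
         margin_left_idx = ml, margin_right_idx = mr,
         scale_x_um = as.numeric(scale_x_um),
         scale_z_um = as.numeric(scale_z_um)),
    class = "segmented_bscan")
}

required_angles <- function() c(0, 30, 60, 90, 120, 150)

#' Physical width of a scan in mm
#' @param scan a `segmented_bscan`.
#' @return lateral extent in mm (first to last sample).
#' @export
scan_width_mm <- function(scan) {
  diff(range(scan$x_px)) * scan$scale_x_um / 1000
}

# lateral positions in mm, centered on the scan midpoint (the assumed optic
# nerve head center), plus depth traces in mm
scan_mm <- function(scan) {
  x <- scan$x_px * scan$scale_x_um / 1000
  x <- x - (x[1] + x[length(x)]) / 2
  list(x_mm = x,
       ilm_mm = scan$ilm_z_px * scan$scale_z_um / 1000,
       bm_mm = scan$bm_z_px * scan$scale_z_um / 1000)
}

#' One eye's set of 6 radial B-scans
#'
#' @param subject_id,eye_id identifiers (`eye_id` conventionally "OD"/"OS").
#' @param scans list of exactly 6 [segmented_bscan()] objects with distinct
#'   angles 0, 30, ..., 150 degrees.
#' @param truncated_width_mm common lateral width after truncation, or `NA`
#'   if the set has not been truncated yet.
#' @return An object of class `radial_scan_set`.
#' @export
radial_scan_set <- function(subject_id, eye_id, scans,
                            truncated_width_mm = NA_real_) {
  if (length(scans) != 6L)
    stop("a radial scan set needs exactly 6 scans, got ", length(scans))
  ok <- vapply(scans, inherits, logical(1), what = "segmented_bscan")
  if (!all(ok)) stop("scans must all be segmented_bscan objects")
  angles <- vapply(scans, function(s) s$angle_deg, numeric(1))
  missing <- setdiff(required_angles(), angles)
  if (length(missing))
    stop("missing scan angle(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(angles)) stop("duplicate scan angles")
  scans <- scans[order(angles)]
  structure(
    list(subject_id = as.character(subject_id),
         eye_id = as.character(eye_id),
         scans = scans,
         truncated_width_mm = as.numeric(truncated_width_mm)),
    class = "radial_scan_set")
}

is_truncated <- function(set) is.finite(set$truncated_width_mm)

#' @export
print.radial_scan_set <- function(x, ...) {
  w <- if (is_truncated(x)) sprintf("%.3f mm (truncated)", x$truncated_width_mm)
       else "not truncated"
  cat(sprintf("<radial_scan_set> subject %s, eye %s: 6 B-scans at 30%s, width %s\n",
              x$subject_id, x$eye_id, "°", w))
  invisible(x)
}

#' Bruch's membrane representation
#'
#' How Bruch's membrane (BM) is represented across the artifact-prone central
#' region of each B-scan: `"traditional"` bridges the rater-marked opening
#' margins with a straight chord; `"estimated"` replaces BM inside
#' `central_half_width_mm` of the scan center with a chord joining the
#' segmented BM at that distance on either side; `"excluded"` drops the
#' central region from volume integration entirely.
#'
#' @param mode one of `"traditional"`, `"estimated"`, `"excluded"`.
#' @param central_half_width_mm half-width of the central region in mm
#'   (default 1.6, i.e. a 3.2 mm region — the maximum BM opening extent).
#' @return An object of class `bm_representation`.
#' @export
bm_rep <- function(mode = c("traditional", "estimated", "excluded"),
                   central_half_width_mm = 1.6) {
  mode <- match.arg(mode)
  if (!is.finite(central_half_width_mm) || central_half_width_mm <= 0)
    stop("central_half_width_mm must be positive")
  structure(list(mode = mode,
                 central_half_width_mm = as.numeric(central_half_width_mm)),
            class = "bm_representation")
}

#' Macular thickness grid
#'
#' A rectangular ganglion-cell-complex (ILM to inner-plexiform/inner-nuclear
#' boundary) thickness map with its pixel spacing and fovea center.
#'
#' @param thickness_mm numeric matrix of thickness in mm (rows = y, cols = x).
#' @param pixel_dx_mm,pixel_dy_mm pixel spacing in mm.
#' @param fovea_xy_mm numeric length-2, fovea center `(x, y)` in mm in grid
#'   coordinates (pixel `(i, j)` center at `((j - 0.5) * dx, (i - 0.5) * dy)`).
#' @return An object of class `macula_grid`.
#' @export
macula_grid <- function(thickness_mm, pixel_dx_mm, pixel_dy_mm, fovea_xy_mm) {
  thickness_mm <- as.matrix(thickness_mm)
  if (any(thickness_mm < 0, na.rm = TRUE)) stop("thickness must be non-negative")
  if (pixel_dx_mm <= 0 || pixel_dy_mm <= 0) stop("pixel spacings must be positive")
  if (length(fovea_xy_mm) != 2L || anyNA(fovea_xy_mm))
    stop("fovea_xy_mm must be a finite (x, y) pair")
  ext_x <- ncol(thickness_mm) * pixel_dx_mm
  ext_y <- nrow(thickness_mm) * pixel_dy_mm
  if (fovea_xy_mm[1] < 0 || fovea_xy_mm[1] > ext_x ||
      fovea_xy_mm[2] < 0 || fovea_xy_mm[2] > ext_y)
    stop("fovea must lie inside the grid")
  structure(list(thickness_mm = thickness_mm,
                 pixel_dx_mm = as.numeric(pixel_dx_mm),
                 pixel_dy_mm = as.numeric(pixel_dy_mm),
                 fovea_xy_mm = as.numeric(fovea_xy_mm)),
            class = "macula_grid")
}
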