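#' Read a radial segmentation set from the JSON interchange format
#'
#' The format is a single JSON object
#' `{subject_id, eye_id, scans: [...6 scans...]}` where each scan carries
#' `angle_deg`, `scale_x_um`, `scale_z_um`, `x_px`, `ilm_z_px`, `bm_z_px`
#' (with `null` inside the BM opening), `margin_left_idx`,
#' `margin_right_idx`; indices are 0-based. A schema description ships in
#' `system.file("extdata", "radial_schema.md", package = "onhvol")`.
#' Violations are reported with a JSON-pointer-style path.
#'
#' @param path path to the JSON file.
#' @return A [radial_scan_set()] (untruncated unless the file says
#'   otherwise via `truncated_width_mm`).
#' @export
read_radial_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("subject_id", "eye_id", "scans"))
    if (is.null(j[[f]])) stop("schema error at /", f, ": missing field")
  sc <- j$scans
  if (is.data.frame(sc)) sc <- split(sc, seq_len(nrow(sc)))
  if (length(sc) != 6L)
    stop("schema error at /scans: expected 6 scans, found ", length(sc),
         "; missing angle(s): ",
         paste(setdiff(required_angles(),
                       vapply(sc, function(s) as.numeric(s$angle_deg)[1],
                              numeric(1))), collapse = ", "))
  scans <- lapply(seq_along(sc), function(i) {
    s <- sc[[i]]
    at <- function(f) paste0("/scans/", i - 1L, "/", f)
    for (f in c("angle_deg", "scale_x_um", "scale_z_um", "x_px", "ilm_z_px",
                "bm_z_px", "margin_left_idx", "margin_right_idx"))
      if (is.null(s[[f]]) || all(is.na(s[[f]])) && f != "bm_z_px")
        stop("schema error at ", at(f), ": missing field")
    unlist_num <- function(v) {
      v <- unlist(lapply(v, function(x) if (is.null(x)) NA_real_ else as.numeric(x)))
      as.numeric(v)
    }
    x <- unlist_num(s$x_px)
    ilm <- unlist_num(s$ilm_z_px); bm <- unlist_num(s$bm_z_px)
    if (length(ilm) != length(x) || length(bm) != length(x))
      stop("schema error at ", at("ilm_z_px"), ": trace length mismatch")
    if (any(diff(x) <= 0))
      stop("schema error at ", at("x_px"), ": not strictly increasing")
    ml <- as.integer(s$margin_left_idx); mr <- as.integer(s$margin_right_idx)
    if (ml < 0L || mr >= length(x) || ml >= mr)
      stop("schema error at ", at("margin_left_idx"),
           ": margins must satisfy 0 <= left < right < trace length")
    tryCatch(
      segmented_bscan(as.numeric(s$angle_deg), x, ilm, bm, ml, mr,
                      as.numeric(s$scale_x_um), as.numeric(s$scale_z_um)),
      error = function(e) stop("schema error at /scans/", i - 1L, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  tw <- if (!is.null(j$truncated_width_mm)) as.numeric(j$truncated_width_mm)
        else NA_real_
  radial_scan_set(j$subject_id, j$eye_id, scans, truncated_width_mm = tw)
}

#' Write a radial scan set to the JSON interchange format
#'
#' @param set a [radial_scan_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_radial_set <- function(set, path) {
  stopifnot(inherits(set, "radial_scan_set"))
  scans <- lapply(set$scans, function(s)
    list(angle_deg = s$angle_deg, scale_x_um = s$scale_x_um,
         scale_z_um = s$scale_z_um, x_px = s$x_px, ilm_z_px = s$ilm_z_px,
         bm_z_px = s$bm_z_px,
         margin_left_idx = s$margin_left_idx,
         margin_right_idx = s$margin_right_idx))
  obj <- list(subject_id = set$subject_id, eye_id = set$eye_id,
              scans = scans)
  if (is_truncated(set)) obj$truncated_width_mm <- set$truncated_width_mm
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Read / write a macular thickness grid (CSV matrix + JSON sidecar)
#'
#' The grid is a headerless CSV of thickness in mm; the sidecar JSON holds
#' `pixel_dx_mm`, `pixel_dy_mm` and `fovea_xy_mm`.
#'
#' @param csv_path path to the thickness CSV.
#' @param sidecar_path path to the metadata JSON; default `csv_path` with
#'   `.json` extension.
#' @return A [macula_grid()].
#' @export
read_macula_grid <- function(csv_path,
                             sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  if (!file.exists(csv_path)) stop("no such file: ", csv_path)
  if (!file.exists(sidecar_path)) stop("no sidecar file: ", sidecar_path)
  m <- as.matrix(utils::read.csv(csv_path, header = FALSE))
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("pixel_dx_mm", "pixel_dy_mm", "fovea_xy_mm"))
    if (is.null(meta[[f]])) stop("schema error at /", f, ": missing field")
  macula_grid(m, meta$pixel_dx_mm, meta$pixel_dy_mm, meta$fovea_xy_mm)
}

#' @rdname read_macula_grid
#' @param grid a [macula_grid()] to write.
#' @export
write_macula_grid <- function(grid, csv_path,
                              sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(grid, "macula_grid"))
  utils::write.table(grid$thickness_mm, csv_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(pixel_dx_mm = grid$pixel_dx_mm,
                            pixel_dy_mm = grid$pixel_dy_mm,
                            fovea_xy_mm = grid$fovea_xy_mm),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Write volume results as a tidy CSV
#'
#' One row per (eye, representation, base mode), volumes at fixed 6-decimal
#' precision (sub-µm^3).
#'
#' @param results a list of `volume_result` objects (see
#'   [compute_volumes()]).
#' @param path output CSV path.
#' @return the data frame written, invisibly.
#' @export
write_volume_table <- function(results, path) {
  if (!length(results)) stop("no volume results to write")
  if (inherits(results, "volume_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(v)
    data.frame(subject_id = v$subject_id, eye_id = v$eye_id,
               representation = v$representation$mode,
               base_mode = v$base_mode,
               onhv_mm3 = sprintf("%.6f", v$onhv_mm3),
               bmdv_mm3 = sprintf("%.6f", v$bmdv_mm3),
               cv_mm3 = sprintf("%.6f", v$cv_mm3),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a cohort table CSV
#'
#' @param path CSV with columns `subject_id`, `eye`, `icp_cmH2O`, and any of
#'   `gccv_mm3`, `onhv_mm3`, `bmdv_mm3`, `cv_mm3`, `rnfl_um`.
#' @return an `onh_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye", "icp_cmH2O")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(table(df$subject_id) > 2L)) stop("more than 2 eyes for a subject")
  if (any(df$icp_cmH2O <= 0)) stop("ICP must be positive")
  class(df) <- c("onh_cohort", "data.frame")
  df
}
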