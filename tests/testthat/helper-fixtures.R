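# Fixture builders shared across the test files. Everything is generated in
# code; no stored data.

# 12 half-scan profiles with an arbitrary height function of (r, theta)
flat_profiles <- function(hfun = function(r, theta) rep(1, length(r)),
                          R = 2.795, n_intervals = 510,
                          valid_fun = NULL) {
  r <- seq(0, R, length.out = n_intervals + 1)
  lapply(seq(0, 330, 30), function(th) {
    valid <- if (is.null(valid_fun)) rep(TRUE, length(r)) else valid_fun(r, th)
    structure(list(theta_deg = th, r_mm = r, height_mm = hfun(r, th),
                   valid = valid),
              class = "half_scan_profile")
  })
}

# one synthetic B-scan with flat BM at depth bm_mm and given ILM offsets;
# x spans [-half_width, half_width] in mm
make_flat_scan <- function(angle = 0, n = 201, half_width = 2.795,
                           bm_mm = 1, ilm_mm = NULL,
                           opening_mm = 0.75, scale_z_um = 2) {
  x_mm <- seq(-half_width, half_width, length.out = n)
  if (is.null(ilm_mm)) ilm_mm <- rep(bm_mm - 0.2, n)
  bm <- rep(bm_mm, n)
  ml <- which.min(abs(x_mm + opening_mm)) - 1L
  mr <- which.min(abs(x_mm - opening_mm)) - 1L
  open <- seq_len(n) > ml + 1L & seq_len(n) < mr + 1L
  bm[open] <- NA
  scale_x_um <- 2 * half_width * 1000 / (n - 1)
  segmented_bscan(angle, 0:(n - 1L), ilm_mm * 1000 / scale_z_um,
                  bm * 1000 / scale_z_um, ml, mr, scale_x_um, scale_z_um)
}

make_flat_set <- function(...) {
  scans <- lapply(c(0, 30, 60, 90, 120, 150), function(a) make_flat_scan(a, ...))
  truncate_scan_set(scans)
}
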