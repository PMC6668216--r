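R_TRUNC <- 2.795

test_that("traditional BM boundary bridges the opening with a straight chord", {
  scan <- make_flat_scan()  # flat BM at 1 mm, opening +-0.75 mm
  b <- bm_boundary(scan, bm_rep("traditional"))
  expect_true(all(b$valid))
  expect_false(anyNA(b$bm_mm))
  n <- length(b$bm_mm)
  expect_equal(b$bm_mm[(n + 1) %/% 2], 1, tolerance = 1e-9)  # horizontal chord
})

test_that("estimated BM boundary is exact when segmented BM is linear", {
  # BM depth linear in x: the +-1.6 mm chord reproduces the line everywhere
  n <- 201
  x_mm <- seq(-R_TRUNC, R_TRUNC, length.out = n)
  bm_mm <- 1 + 0.05 * x_mm
  ml <- which.min(abs(x_mm + 0.75)) - 1L
  mr <- which.min(abs(x_mm - 0.75)) - 1L
  bm_px <- bm_mm * 500; bm_px[seq_len(n) > ml + 1 & seq_len(n) < mr + 1] <- NA
  scan <- segmented_bscan(0, 0:(n - 1), (bm_mm - 0.2) * 500, bm_px,
                          ml, mr, 2 * R_TRUNC * 1000 / (n - 1), 2)
  b <- bm_boundary(scan, bm_rep("estimated"))
  expect_equal(b$bm_mm, bm_mm, tolerance = 1e-9)
  # estimated mode fails when no segmented BM reaches +-central_half_width
  expect_error(bm_boundary(scan, bm_rep("estimated", central_half_width_mm = 2.9)),
               "smaller than the truncation radius")
})

test_that("excluded BM boundary invalidates exactly the central samples", {
  scan <- make_flat_scan(n = 401)
  b <- bm_boundary(scan, bm_rep("excluded"))
  x <- onhvol:::scan_mm(scan)$x_mm
  expect_identical(sum(!b$valid), sum(abs(x) < 1.6 - 1e-9))
})

test_that("secant joins the outermost BM points", {
  scan <- make_flat_scan()
  s <- secant_of_scan(scan)
  expect_equal(s$z0_mm, 1); expect_equal(s$z1_mm, 1)
  # linear BM: the secant coincides with BM everywhere
  n <- 101
  x_mm <- seq(-2, 2, length.out = n)
  bm_mm <- 0.5 + 0.025 * (x_mm + 2)   # 0.4..0.6 style ramp
  scan2 <- segmented_bscan(0, 0:(n - 1), (bm_mm - 0.1) * 500, bm_mm * 500,
                           45, 55, 4000 / (n - 1), 2)
  s2 <- secant_of_scan(scan2)
  expect_equal(onhvol:::secant_depth(s2, x_mm), bm_mm, tolerance = 1e-12)
})

test_that("ONH height clamps cup dips to zero and counts them", {
  n <- 201
  bm <- rep(1, n)
  ilm <- rep(0.8, n)                       # 0.2 mm of tissue everywhere
  dip <- seq((n - 19) %/% 2, length.out = 20)
  ilm[dip] <- 1.1                          # ILM 0.1 mm posterior to BM
  scan <- make_flat_scan(n = n, ilm_mm = ilm)
  b <- bm_boundary(scan, bm_rep("traditional"))
  h <- onh_height(scan, b$bm_mm, b$valid)
  expect_identical(sum(h$value == 0), 20L)
  expect_equal(h$value[-dip], rep(0.2, n - 20), tolerance = 1e-9)
  expect_error(onh_height(scan, b$bm_mm[-1], b$valid[-1]), "length")
})

test_that("BM displacement is signed: posterior positive, anterior negative", {
  scan <- make_flat_scan()
  b <- bm_boundary(scan, bm_rep("traditional"))
  s <- secant_of_scan(scan)
  d0 <- bm_displacement(scan, b$bm_mm, b$valid, s)
  expect_equal(d0$value, rep(0, length(d0$value)), tolerance = 1e-12)
  d_post <- bm_displacement(scan, b$bm_mm + 0.2, b$valid, s)
  expect_equal(unique(round(d_post$value, 10)), 0.2)
  d_ant <- bm_displacement(scan, b$bm_mm - 0.1, b$valid, s)
  expect_equal(unique(round(d_ant$value, 10)), -0.1)
})

test_that("cup height is zero where ILM is anterior to the cup-top line", {
  scan <- make_flat_scan()          # ILM flat, well anterior to BM
  ch <- cup_height(scan)
  expect_true(all(ch$value == 0))
  # parabolic dip of 0.15 mm below the cup top at the center
  n <- 401
  x_mm <- seq(-R_TRUNC, R_TRUNC, length.out = n)
  ilm <- 0.8 + 0.15 * pmax(0, 1 - (x_mm / 0.4)^2)
  scan2 <- make_flat_scan(n = n, ilm_mm = ilm)
  ch2 <- cup_height(scan2)
  expect_equal(max(ch2$value), 0.15, tolerance = 1e-3)
  expect_true(all(ch2$value[!ch2$inside] == 0))
})

test_that("half profiles have n_intervals + 1 nodes at 12 azimuths", {
  set <- make_flat_set(n = 101)
  profs <- build_half_profiles(set, "onh_height", bm_rep("traditional"),
                               n_intervals = 510)
  expect_length(profs, 12)
  expect_equal(sort(vapply(profs, function(p) p$theta_deg, numeric(1))),
               seq(0, 330, 30))
  for (p in profs) expect_length(p$r_mm, 511)
  # constant surface resamples to the constant
  expect_equal(unique(round(profs[[1]]$height_mm, 9)), 0.2)
  # excluded representation masks exactly the nodes with r < 1.6
  pe <- build_half_profiles(set, "onh_height", bm_rep("excluded"), 510)
  expect_identical(sum(!pe[[1]]$valid), sum(pe[[1]]$r_mm < 1.6 - 1e-9))
  expect_error(build_half_profiles(set, "onh_height", n_intervals = 0),
               "n_intervals")
})

test_that("flat-surface integrals hit the closed forms exactly", {
  for (h in c(1, 0.37)) {
    profs <- flat_profiles(function(r, th) rep(h, length(r)))
    expect_equal(as.numeric(integrate_wedges(profs, "chord")),
                 h * 3 * R_TRUNC^2, tolerance = 1e-12)
    expect_equal(as.numeric(integrate_wedges(profs, "sector")),
                 h * pi * R_TRUNC^2, tolerance = 1e-12)
  }
})

test_that("sector-mode volume matches the solid of revolution, chord is 3/pi of it", {
  A <- 0.5; sig <- 0.8
  truth <- 2 * pi * sig^2 * A * (1 - exp(-R_TRUNC^2 / (2 * sig^2)))
  gauss <- function(r, th) A * exp(-r^2 / (2 * sig^2))
  v_sector <- as.numeric(integrate_wedges(flat_profiles(gauss), "sector"))
  expect_equal(v_sector, truth, tolerance = 0.005)
  v_chord <- as.numeric(integrate_wedges(flat_profiles(gauss), "chord"))
  expect_equal(v_chord, truth * 3 / pi, tolerance = 0.005)
  # discretization error decreases with the radial resolution
  err <- sapply(c(50, 510), function(ni)
    abs(as.numeric(integrate_wedges(flat_profiles(gauss, n_intervals = ni),
                                    "sector")) - truth))
  expect_lt(err[2], err[1])
})

test_that("prisms with any invalid corner are excluded from the sum", {
  profs <- flat_profiles(valid_fun = function(r, th) r >= 1.6)
  v <- integrate_wedges(profs, "sector")
  expect_equal(as.numeric(v), pi * (R_TRUNC^2 - 1.6^2), tolerance = 0.005)
  expect_lt(attr(v, "n_prisms_summed"), 12 * 510)
  expect_error(integrate_wedges(profs[-1]), "12")
})

test_that("volumes scale linearly in height and shift linearly in offset", {
  gauss <- function(r, th) 0.3 * exp(-r^2 / 0.9)
  base <- as.numeric(integrate_wedges(flat_profiles(gauss), "chord"))
  scaled <- as.numeric(integrate_wedges(
    flat_profiles(function(r, th) 2.5 * gauss(r, th)), "chord"))
  expect_equal(scaled, 2.5 * base, tolerance = 1e-12)
  # constant posterior offset on a signed surface adds offset x flat volume
  mask <- function(r, th) r >= 1.6
  d0 <- as.numeric(integrate_wedges(flat_profiles(gauss, valid_fun = mask), "sector"))
  d1 <- as.numeric(integrate_wedges(
    flat_profiles(function(r, th) gauss(r, th) + 0.07, valid_fun = mask), "sector"))
  flat_masked <- as.numeric(integrate_wedges(
    flat_profiles(function(r, th) rep(1, length(r)), valid_fun = mask), "sector"))
  expect_equal(d1 - d0, 0.07 * flat_masked, tolerance = 1e-10)
})

test_that("ONHV is invariant to pre-clamping the ILM at the BM boundary", {
  p <- phantom_params(bump_amp_mm = 0.3, cup_depth_mm = 0.5,
                      cup_radius_mm = 0.3, n_samples_per_scan = 601)
  set <- make_radial_phantom(p)
  clamped <- lapply(set$scans, function(s) {
    b <- bm_boundary(s, bm_rep("traditional"))
    ilm_px <- pmin(s$ilm_z_px, b$bm_mm * 1000 / s$scale_z_um)
    segmented_bscan(s$angle_deg, s$x_px, ilm_px, s$bm_z_px,
                    s$margin_left_idx, s$margin_right_idx,
                    s$scale_x_um, s$scale_z_um)
  })
  set2 <- truncate_scan_set(clamped)
  v1 <- compute_volumes(set, bm_rep("traditional"))
  v2 <- compute_volumes(set2, bm_rep("traditional"))
  expect_equal(v1$onhv_mm3, v2$onhv_mm3, tolerance = 1e-10)
  expect_gt(v1$cv_mm3, 0)  # the dip is a real cup
})

test_that("GCC disk volume matches the cylinder closed form", {
  thick <- matrix(0.1, 300, 300)
  g <- macula_grid(thick, 0.02, 0.02, c(3, 3))
  expect_equal(gcc_volume(g), 0.1 * pi * 1.5^2, tolerance = 0.01)
  expect_equal(gcc_volume(g, diameter_mm = 2), 0.1 * pi * 1^2, tolerance = 0.01)
  expect_equal(gcc_volume(macula_grid(matrix(0, 300, 300), 0.02, 0.02, c(3, 3))), 0)
  expect_error(gcc_volume(g, diameter_mm = 7), "beyond")
})

test_that("rater disagreement flags strict >threshold differences only", {
  a <- rep(100, 50); b <- a
  expect_length(rater_disagreement(a, b), 0)
  b[17] <- 103
  expect_identical(rater_disagreement(a, b), 17L)
  b2 <- a + 2
  expect_length(rater_disagreement(a, b2), 0)  # boundary: exactly 2 px
  expect_error(rater_disagreement(a, b2[-1]), "length")
})
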