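test_that("chunk dissection follows floor division and the 80% rule", {
  # 16 planes x 180 x 150 px at default voxel: chunks (8, 36, 36)
  v <- volume(array(0, c(16, 180, 150)))
  ch <- dissect_chunks(v, NULL, 16)
  expect_identical(attr(ch, "grid_dim"), c(2L, 5L, 4L))
  expect_identical(attr(ch, "chunk_px"), c(8L, 36L, 36L))
  expect_equal(nrow(ch), 2 * 5 * 4)

  # tissue fraction strictly below / at the threshold (1000-voxel chunk so
  # 79% and 80% are exactly representable)
  mk <- function(frac) {
    m <- array(FALSE, c(10, 10, 10))
    m[seq_len(frac * 1000)] <- TRUE
    mask_volume(m, voxel = c(1.6, 1.6, 1.6))
  }
  v1 <- volume(array(0, c(10, 10, 10)), voxel = c(1.6, 1.6, 1.6))
  expect_false(dissect_chunks(v1, mk(0.79))$is_tissue)
  expect_true(dissect_chunks(v1, mk(0.80))$is_tissue)

  # all-true mask: every full chunk is tissue
  vall <- volume(array(0, c(16, 72, 72)))
  call <- dissect_chunks(vall, mask_volume(array(TRUE, c(16, 72, 72))))
  expect_true(all(call$is_tissue))

  expect_error(dissect_chunks(volume(array(0, c(4, 36, 36)))), "smaller")
})

test_that("spectrum padding is central, zero elsewhere, energy-conserving", {
  expect_true(all(Mod(pad_spectrum(array(0, c(8, 36, 36)))) == 0))

  ch <- plane_wave_chunk(10, 20, phase = 0.3)
  sp <- pad_spectrum(ch)
  s <- myodisarray:::fftshift3(fft(ch - mean(ch)))
  expect_identical(dim(sp), c(36L, 36L, 36L))
  expect_equal(sp[15:22, , ], s, ignore_attr = TRUE)
  expect_true(all(Mod(sp[c(1:14, 23:36), , ]) == 0))
  expect_equal(sum(Mod(sp)^2), sum(Mod(s)^2))
  expect_error(pad_spectrum(array(0, c(8, 36, 20))), "chunk must be")
})

test_that("padded spectrum inverts to the sinc-interpolated chunk", {
  ch <- plane_wave_chunk(12, -15, phase = 0.1)
  chm <- ch - mean(ch)
  sp <- pad_spectrum(ch)
  rec <- fft(myodisarray:::fftshift3(sp), inverse = TRUE) / length(sp) * (36 / 8)
  # oracle: explicit DFT sum along Z evaluated at the padded sampling comb,
  # independently of any array placement or fftshift bookkeeping
  kz <- c(0:3, -4:-1)                 # natural FFT frequency order, n = 8
  t_new <- (0:35) * 8 / 36            # fractional original-plane positions
  basis <- exp(2i * pi * outer(t_new, kz) / 8)
  oracle <- array(0, c(36, 36, 36))
  for (iy in seq_len(36)) {
    zeta <- stats::mvfft(chm[, iy, ]) # 1D FFT along z for each x column
    oracle[, iy, ] <- Re(basis %*% zeta) / 8
  }
  rec_real <- Re(rec)
  expect_lt(max(abs(rec_real - oracle)), 1e-8)
  # integer sampling positions reproduce the original planes exactly:
  # t = 0, 2, 4, 6 fall at padded planes 1, 10, 19, 28
  for (pair in list(c(1L, 1L), c(10L, 3L), c(19L, 5L), c(28L, 7L))) {
    expect_equal(rec_real[pair[1], , ], chm[pair[2], , ],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("shell filter geometry matches exhaustive lattice enumeration", {
  sf <- make_shell_filter()
  expect_equal(sf$rho, 9)
  expect_equal(sf$rho_inner, 8)
  expect_equal(sf$rho_outer, 10)
  expect_equal(sf$delta_f, 1 / (36 * 0.44))
  ctr <- 19L
  expect_true(sf$mask[ctr, ctr + 9L, ctr])   # offset (0, 9, 0)
  expect_false(sf$mask[ctr, ctr + 5L, ctr])  # radius 5, inside the band
  # brute-force count of lattice points with 8 <= r <= 10 in a 36^3 grid
  cnt <- 0L
  for (a in -18:17) for (b in -18:17) for (c in -18:17) {
    r <- sqrt(a^2 + b^2 + c^2)
    if (r >= 8 && r <= 10) cnt <- cnt + 1L
  }
  expect_equal(sum(sf$mask), cnt)
  # center symmetry
  expect_identical(sf$mask, sf$mask[36:1, 36:1, 36:1][c(36, 1:35), c(36, 1:35), c(36, 1:35)])
  expect_error(make_shell_filter(period_range_um = c(2, 1.6)), "inverted")
})

test_that("smoothed PSDs are non-negative and conserve total energy", {
  sf <- make_shell_filter()
  zero <- smoothed_psds(pad_spectrum(array(0, c(8, 36, 36))), sf)
  expect_true(all(zero$sxx == 0) && all(zero$sxxf == 0))

  ch <- plane_wave_chunk(5, 10)
  sp <- pad_spectrum(ch)
  ps <- smoothed_psds(sp, sf)
  expect_true(all(ps$sxx >= 0) && all(ps$sxxf >= 0))
  # normalized kernel: smoothing preserves the PSD sum (reflect padding is
  # exact away from edges; in-band energy sits well inside)
  expect_equal(sum(ps$sxxf), sum(Mod(sp)^2 * sf$mask), tolerance = 1e-6)
})

test_that("sratio separates gratings, noise and in-shell spectra", {
  sf <- make_shell_filter()
  # in-band grating: band energy dominates once DC is removed
  ps <- smoothed_psds(pad_spectrum(plane_wave_chunk(0, 15)), sf)
  expect_gte(sratio(ps), 0.5)
  # white noise: a flat spectrum puts all its energy in the 8 informative
  # Z-frequency planes, so the expected score is the shell share of those
  set.seed(11)
  scores <- replicate(5, {
    sratio(smoothed_psds(pad_spectrum(array(rnorm(8 * 36 * 36), c(8, 36, 36))), sf))
  })
  flat_expect <- sum(sf$mask[15:22, , ]) / (8 * 36 * 36)
  expect_true(all(scores > flat_expect * 0.5 & scores < flat_expect * 1.5))
  # spectrum entirely inside the shell scores 1
  sp <- pad_spectrum(array(0, c(8, 36, 36)))
  sp[19, 28, 19] <- 3 + 0i   # offset (0, 9, 0): inside the shell
  sp[19, 10, 19] <- 3 + 0i   # symmetric peak
  expect_equal(sratio(smoothed_psds(sp, sf)), 1)
  # all-zero chunk: undefined
  expect_true(is.na(sratio(smoothed_psds(pad_spectrum(array(0, c(8, 36, 36))), sf))))
})

test_that("Sratio normalization is min-max with a strict 14% threshold", {
  fld <- uniform_field(c(1L, 3L, 1L))
  fld$sratio_raw <- c(0.1, 0.2, 0.3)
  out <- normalize_sratio(fld, 0.14)
  expect_equal(out$sratio_norm, c(0, 0.5, 1))
  expect_identical(out$is_reliable, c(FALSE, TRUE, TRUE))

  # boundary: exactly at the threshold is not reliable, just above is
  fld2 <- uniform_field(c(1L, 3L, 1L))
  fld2$sratio_raw <- c(0, 0.14, 1)
  out2 <- normalize_sratio(fld2, 0.14)
  expect_false(out2$is_reliable[2])
  fld2$sratio_raw <- c(0, 0.141, 1)
  expect_true(normalize_sratio(fld2, 0.14)$is_reliable[2])

  # degenerate: single tissue chunk
  fld3 <- uniform_field(c(1L, 1L, 1L))
  fld3$sratio_raw <- 0.4
  expect_warning(out3 <- normalize_sratio(fld3, 0.14), "equal")
  expect_equal(out3$sratio_norm, 0)
  expect_false(out3$is_reliable)
})

test_that("orientation extraction recovers grating axes and flips hemispheres", {
  sf <- make_shell_filter()
  run <- function(theta, phi, phase = 0) {
    ps <- smoothed_psds(pad_spectrum(plane_wave_chunk(theta, phi, phase = phase)), sf)
    extract_orientation(ps$sxxf, sf$delta_f)
  }
  r <- run(0, 0)
  expect_lt(angle_between_deg(r$direction, c(0, 1, 0)), 2)
  expect_gte(r$period_um, 1.6 - 0.44 / 2)
  expect_lte(r$period_um, 2.0 + 0.44 / 2)

  # a phase-reversed grating along -Y maps to the same axis after the flip
  r_neg <- run(0, 180)
  expect_lt(angle_between_deg(r_neg$direction, r$direction), 1e-6)
  expect_gte(r_neg$direction[2], 0)

  # azimuth 15 degrees recovered within the tabulated accuracy
  r15 <- run(0, 15, phase = 0.2)
  ang <- angles_from_dir(r15$direction)
  expect_lte(abs(ang[["phi"]] - 15), 3.9)

  expect_null(extract_orientation(array(0, c(36, 36, 36)), sf$delta_f))
})

test_that("FFT orientation agrees with the brute-force in-band maximizer", {
  # centroid (pipeline) vs grid argmax (oracle) differ slightly on skewed
  # spectral peaks: mean agreement is bounded at 2 degrees, single cases at 4
  set.seed(21)
  ds <- vapply(1:8, function(i) {
    theta <- runif(1, -18, 18)
    phi <- runif(1, -80, 80)
    ch <- plane_wave_chunk(theta, phi, period_um = runif(1, 1.7, 1.9),
                           phase = runif(1))
    sf <- make_shell_filter()
    ps <- smoothed_psds(pad_spectrum(ch), sf)
    fftdir <- extract_orientation(ps$sxxf, sf$delta_f)$direction
    angle_between_deg(fftdir, brute_force_orientation(ch))
  }, 0)
  expect_lt(mean(ds), 2)
  expect_lt(max(ds), 4)
})

test_that("outlier removal demands strong evidence from deviant vectors", {
  center <- c(iz = 2L, iy = 2L, ix = 2L)
  mkfield <- function(sr) {
    fld <- uniform_field(c(3L, 3L, 3L))
    i <- which(fld$iz == 2 & fld$iy == 2 & fld$ix == 2)
    fld$vx[i] <- 1; fld$vy[i] <- 0; fld$vz[i] <- 0
    fld$sratio_norm[i] <- sr
    fld
  }
  weak <- remove_outliers(mkfield(0.2), 0.14)
  i <- which(weak$iz == 2 & weak$iy == 2 & weak$ix == 2)
  expect_true(weak$is_outlier[i])      # 0.2 < 2 x 0.14
  expect_false(weak$is_reliable[i])

  strong <- remove_outliers(mkfield(0.9), 0.14)
  expect_false(strong$is_outlier[i])   # strong evidence retained

  clean <- remove_outliers(uniform_field(c(3L, 3L, 3L)), 0.14)
  expect_equal(sum(clean$is_outlier), 0)
})

test_that("volume analysis recovers a uniform phantom and rejects noise", {
  # a realistic strip has a quality gradient: degrade one edge so min-max
  # normalization anchors there rather than inside the clean bulk
  ph <- make_striated_volume(phantom_spec(extent_um = c(16, 144, 144),
                                          theta = 6, phi = 14, noise_sd = 6,
                                          seed = 3))
  set.seed(33)
  deg <- ph$volume$data[, 1:108, 1:36] +
    rnorm(length(ph$volume$data[, 1:108, 1:36]), sd = 45)
  ph$volume$data[, 1:108, 1:36] <- pmax(0, pmin(255, round(deg)))
  f <- analyze_volume(ph$volume, ph$mask)
  rel <- f[f$is_reliable, ]
  expect_gte(nrow(rel) / sum(f$is_tissue), 0.9)
  mdir <- colMeans(cbind(rel$vx, rel$vy, rel$vz))
  expect_lt(angle_between_deg(mdir, ph$axis), 3)
  # hemisphere invariant and in-band periods
  expect_true(all(rel$vy >= 0))
  bin <- 1 / (36 * 0.44)
  expect_true(all(rel$frequency_um1 >= 8 * bin - bin / 2))
  expect_true(all(rel$frequency_um1 <= 10 * bin + bin / 2))

  # pure noise: low reliable fraction
  set.seed(9)
  nz <- volume(array(pmax(0, pmin(255, 60 + rnorm(16 * 72 * 72, sd = 25))),
                     c(16, 72, 72)))
  fn <- analyze_volume(nz, NULL)
  expect_lte(sum(fn$is_reliable) / sum(fn$is_tissue), 0.2)

  # determinism
  f2 <- analyze_volume(ph$volume, ph$mask)
  expect_identical(as.data.frame(f), as.data.frame(f2))
})
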