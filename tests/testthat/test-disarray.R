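test_that("local disarray matches closed forms and the hemisphere limit", {
  expect_equal(local_disarray(matrix(rep(c(0, 1, 0), 8), ncol = 3, byrow = TRUE)), 0)
  expect_equal(local_disarray(rbind(c(0, 1, 0), c(1, 0, 0))),
               (1 - sqrt(2) / 2) * 100, tolerance = 1e-10)
  # hemisphere-uniform directions: mean resultant length -> 1/2, d -> 50%.
  # Monte-Carlo oracle: uniform on the vy >= 0 hemisphere via normalized
  # Gaussians with the y component reflected.
  set.seed(31)
  n <- 1e5
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  g[, 2] <- abs(g[, 2])
  expect_equal(local_disarray(g), 50, tolerance = 1)
  # non-unit input is normalized first
  expect_equal(local_disarray(rbind(c(0, 5, 0), c(3, 0, 0))),
               (1 - sqrt(2) / 2) * 100, tolerance = 1e-10)
  expect_error(local_disarray(matrix(0, 1, 3)), "zero-length")
})

test_that("local alignment is the mean unit y component", {
  expect_equal(local_alignment(matrix(rep(c(0, 1, 0), 3), ncol = 3, byrow = TRUE)), 1)
  expect_equal(local_alignment(rbind(c(1, 0, 0))), 0)
  expect_equal(local_alignment(rbind(c(0, 1, 0), c(0, 0, 1))), 0.5)
})

test_that("disarray maps tile, validate and summarize macrovoxels", {
  fld <- uniform_field(c(6L, 6L, 6L))
  for (m in 2:6) {
    dm <- disarray_map(fld, m)
    expect_equal(attr(dm, "side_um"), m * 16)
    expect_lt(abs(attr(dm, "D")), 0.5)  # aligned tissue: D ~ 0
    expect_equal(attr(dm, "A"), 1)
    expect_equal(attr(dm, "N_v"), prod(c(6, 6, 6) %/% m))
  }
  # 50% validity rule at m = 2: 3 of 8 reliable slots invalid, 4 of 8 valid
  f3 <- uniform_field(c(2L, 2L, 2L))
  f3$is_reliable <- c(rep(TRUE, 3), rep(FALSE, 5))
  expect_equal(attr(disarray_map(f3, 2), "N_v"), 0)
  f4 <- uniform_field(c(2L, 2L, 2L))
  f4$is_reliable <- c(rep(TRUE, 4), rep(FALSE, 4))
  dm4 <- disarray_map(f4, 2)
  expect_equal(attr(dm4, "N_v"), 1)
  expect_equal(dm4$n_reliable, 4)
  expect_error(disarray_map(uniform_field(c(2L, 2L, 2L)), 3), "smaller")
})

test_that("global statistics are permutation- and rotation-invariant", {
  set.seed(41)
  fld <- uniform_field(c(4L, 4L, 4L))
  # jitter directions around +Y, keep vy > 0
  th <- rnorm(64, 0, 8); ph <- rnorm(64, 0, 8)
  dirs <- t(mapply(dir_from_angles, th, ph))
  fld$vx <- dirs[, 1]; fld$vy <- dirs[, 2]; fld$vz <- dirs[, 3]
  dm <- disarray_map(fld, 2)

  # permutation of macrovoxels: reverse the block order along every axis,
  # carrying each 2x2x2 block's contents intact to its mirrored position
  perm <- fld
  mirror <- function(i) {
    blk <- (i - 1L) %/% 2L
    within <- (i - 1L) %% 2L
    (1L - blk) * 2L + within + 1L
  }
  src <- order(fld$iz, fld$iy, fld$ix)
  dst <- order(mirror(fld$iz), mirror(fld$iy), mirror(fld$ix))
  for (cl in c("vx", "vy", "vz")) perm[[cl]][dst] <- fld[[cl]][src]
  dmp <- disarray_map(perm, 2)
  expect_equal(attr(dmp, "D"), attr(dm, "D"), tolerance = 1e-12)
  expect_equal(attr(dmp, "A"), attr(dm, "A"), tolerance = 1e-12)

  # rotation about the Y axis leaves both D and A unchanged
  a <- 25 * pi / 180
  ry <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
  rot <- fld
  vr <- cbind(fld$vx, fld$vy, fld$vz) %*% t(ry)
  rot$vx <- vr[, 1]; rot$vy <- vr[, 2]; rot$vz <- vr[, 3]
  dmr <- disarray_map(rot, 2)
  expect_equal(attr(dmr, "D"), attr(dm, "D"), tolerance = 1e-10)
  expect_equal(attr(dmr, "A"), attr(dm, "A"), tolerance = 1e-10)

  # a general rotation (tilt about X) preserves D but not A
  b <- 20 * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  tilt <- fld
  vt <- cbind(fld$vx, fld$vy, fld$vz) %*% t(rx)
  tilt$vx <- vt[, 1]; tilt$vy <- vt[, 2]; tilt$vz <- vt[, 3]
  dmt <- disarray_map(tilt, 2)
  expect_equal(attr(dmt, "D"), attr(dm, "D"), tolerance = 1e-10)
  expect_gt(abs(attr(dmt, "A") - attr(dm, "A")), 1e-3)
})

test_that("D'Agostino-Pearson omnibus matches the reference implementation", {
  r1 <- dagostino_pearson(log(1:30))
  expect_equal(r1$statistic, 10.243892527824551, tolerance = 1e-10)
  expect_equal(r1$p_value, 0.005964403288384851, tolerance = 1e-10)
  r2 <- dagostino_pearson(sin((1:60) * 1.7) + (0:59) * 0.05)
  expect_equal(r2$statistic, 1.2362682128699656, tolerance = 1e-10)
  expect_equal(r2$p_value, 0.5389491216844193, tolerance = 1e-10)
  expect_error(dagostino_pearson(1:5), "n >= 8")
})

test_that("log-normal fits recover parameters and honour closed forms", {
  set.seed(51)
  fit <- fit_lognormal(exp(rnorm(10000, 1, 0.5)))
  expect_lt(abs(fit$mu - 1), 0.02)
  expect_lt(abs(fit$sigma - 0.5), 0.02)
  expect_gt(fit$p_value, 0.01)

  # closed-form mode and SD at mu = ln 2, sigma = 0.5
  mu <- log(2); s <- 0.5
  set.seed(52)
  fit2 <- fit_lognormal(exp(rnorm(50000, mu, s)))
  expect_equal(fit2$mode, 2 * exp(-0.25), tolerance = 0.02)
  expect_equal(fit2$std_dev, sqrt((exp(0.25) - 1) * exp(2 * log(2) + 0.25)),
               tolerance = 0.02)

  # sigma -> 0 limit: mode -> exp(mu), sd -> 0
  set.seed(53)
  fit3 <- fit_lognormal(exp(rnorm(1000, 0, 1e-4)))
  expect_equal(fit3$mode, 1, tolerance = 1e-3)
  expect_lt(fit3$std_dev, 1e-3)

  # zeros are excluded and counted; too few positives refuse the fit
  expect_warning(bad <- fit_lognormal(c(rep(0, 30), rlnorm(5))), "refused")
  expect_equal(bad$n_excluded, 30)
  expect_true(is.na(bad$mu))
})

test_that("closed-form mode and SD match numeric moments of the PDF", {
  for (par in list(c(1, 0.5), c(log(2), 0.5), c(2, 0.3))) {
    mu <- par[1]; s <- par[2]
    mode_cf <- exp(mu - s^2)
    sd_cf <- sqrt((exp(s^2) - 1) * exp(2 * mu + s^2))
    # dense numeric evaluation of the PDF
    x <- seq(1e-4, exp(mu + 8 * s), length.out = 2e5)
    p <- dlnorm(x, mu, s)
    mode_num <- x[which.max(p)]
    dx <- diff(x[1:2])
    m1 <- sum(x * p) * dx
    sd_num <- sqrt(sum((x - m1)^2 * p) * dx)
    expect_lt(abs(mode_num - mode_cf) / mode_cf, 0.001)
    expect_lt(abs(sd_num - sd_cf) / sd_cf, 0.001)
  }
})

test_that("multiresolution tables summarize every scale", {
  fld <- uniform_field(c(6L, 6L, 6L))
  set.seed(61)
  th <- rnorm(216, 0, 5); ph <- rnorm(216, 0, 5)
  dirs <- t(mapply(dir_from_angles, th, ph))
  fld$vx <- dirs[, 1]; fld$vy <- dirs[, 2]; fld$vz <- dirs[, 3]
  tb <- multiresolution_table(fld, 2:6)
  expect_equal(tb$side_um, c(32, 48, 64, 80, 96))
  expect_true(all(tb$D >= 0 & tb$D <= 100))

  empty <- uniform_field(c(2L, 2L, 2L))
  empty$is_reliable <- FALSE
  expect_warning(tb0 <- multiresolution_table(empty, 2), "no reliable")
  expect_equal(nrow(tb0), 0)
})

test_that("rendered disarray volumes smooth without creating mass or peaks", {
  fld <- uniform_field(c(6L, 6L, 6L))
  fld$vx[1] <- 1; fld$vy[1] <- 0  # a little variety
  dm <- disarray_map(fld, 2)
  # single valid macrovoxel at d = 10%
  solo <- dm
  solo$valid <- c(TRUE, rep(FALSE, nrow(dm) - 1))
  solo$d <- c(10, rep(NA, nrow(dm) - 1))
  vol <- render_disarray_volume(solo, sigma_um = 10)
  expect_lte(max(vol$data), 10 + 1e-9)

  blocks <- render_disarray_volume(solo, sigma_um = 0)
  expect_setequal(unique(as.vector(blocks$data)), c(0, 10))

  # interior mass conservation: all-valid map, constant d
  full <- dm
  full$valid <- rep(TRUE, nrow(dm))
  full$d <- rep(7, nrow(dm))
  sm <- render_disarray_volume(full, sigma_um = 10)
  expect_equal(sum(sm$data), 7 * length(sm$data), tolerance = 0.01 * 7 * length(sm$data))
})
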