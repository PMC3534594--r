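test_that("hypothetical triggers are continuous across the midpoint", {
  hyp <- TriggerHypothesis(120, 120, t_mid_s = 1)
  expect_equal(hypotheticalTriggers(hyp, 2), c(0, 0.5, 1, 1.5, 2))
  hyp2 <- TriggerHypothesis(120, 150, t_mid_s = 1)
  trig <- hypotheticalTriggers(hyp2, 3)
  d <- diff(trig)
  expect_true(all(abs(d[trig[-length(trig)] < 1 - 1e-9] - 0.5) < 1e-9))
  expect_true(all(abs(d[trig[-length(trig)] >= 1] - 0.4) < 1e-9))
  # no phase jump at the boundary: with a fraction of a cycle pending at
  # t_mid, the next trigger lands where that fraction completes at the new
  # rate, not at t_mid itself
  hyp3 <- TriggerHypothesis(130, 150, t_mid_s = 1)
  trig3 <- hypotheticalTriggers(hyp3, 3)
  pend <- 1 * 130 / 60; frac <- pend - floor(pend)
  expect_equal(min(trig3[trig3 > 1]), 1 + (1 - frac) * 60 / 150,
               tolerance = 1e-12)
  expect_error(TriggerHypothesis(200, 140, t_mid_s = 1))
})

test_that("hypothesis phase matches a brute-force trigger walk", {
  set.seed(42)
  for (rates in list(c(140, 140), c(117, 163), c(171.4, 112.9))) {
    hyp <- TriggerHypothesis(rates[1], rates[2], t_mid_s = 11.3)
    t <- runif(1000, 0, 22.6)
    expect_equal(hypothesisPhase(t, hyp), bruteForcePhase(t, hyp, 22.6),
                 tolerance = 1e-9)
  }
})

test_that("phase binning follows the half-open floor rule", {
  # a measurement at phase fraction 0.999 with 10 bins lands in bin 9
  expect_equal(min(floor(0.999 * 10), 9), 9)
  acq <- toyAcquisition(seed = 3)
  hyp <- TriggerHypothesis(130, 150, t_mid_s = max(acq@time_s) / 2)
  b <- binMeasurements(acq, hyp, 10)
  ph <- hypothesisPhase(acq@time_s, hyp)
  bin <- pmin(floor(ph * 10), 9)
  # conservation: assigned counts sum to the number of measurements,
  # per k-row and encode
  for (e in 1:2) for (r in unique(acq@krow)) {
    sel <- acq@encode == e & acq@krow == r
    expect_equal(sum(b$counts[r + 1L, , e]), sum(sel))
  }
})

test_that("binning matches an independent brute-force assignment", {
  acq <- toyAcquisition(seed = 7, n = 16L, vps = 4L)
  n <- 16L; nph <- 8L
  hyp <- TriggerHypothesis(124, 158, t_mid_s = max(acq@time_s) / 2)
  b <- binMeasurements(acq, hyp, nph)
  # naive loop: per measurement, walk the triggers to find its phase
  ksp <- array(complex(real = 0, imaginary = 0), c(n, n, nph, 2L))
  cnt <- array(0L, c(n, nph, 2L))
  dur <- max(acq@time_s)
  for (m in seq_len(nrow(acq@lines))) {
    ph <- bruteForcePhase(acq@time_s[m], hyp, dur)
    bi <- min(floor(ph * nph), nph - 1L) + 1L
    r <- acq@krow[m] + 1L; e <- acq@encode[m]
    ksp[r, , bi, e] <- ksp[r, , bi, e] + acq@lines[m, ]
    cnt[r, bi, e] <- cnt[r, bi, e] + 1L
  }
  for (e in 1:2) for (r in seq_len(n)) for (bi in seq_len(nph))
    if (cnt[r, bi, e] > 0)
      ksp[r, , bi, e] <- ksp[r, , bi, e] / cnt[r, bi, e]
  occupied <- cnt > 0
  expect_equal(b$counts, cnt)
  for (e in 1:2) for (bi in seq_len(nph)) for (r in seq_len(n))
    if (occupied[r, bi, e])
      expect_equal(b$kspace[r, , bi, e], ksp[r, , bi, e], tolerance = 1e-12)
})

test_that("empty bins are filled from the nearest cyclic neighbour", {
  # toy acquisition whose window covers only part of the hypothetical cycle
  acq <- toyAcquisition(seed = 11, n = 16L, vps = 4L, window = 0.3,
                        tr_ms = 10)
  hyp <- TriggerHypothesis(120, 120, t_mid_s = max(acq@time_s) / 2)
  b <- binMeasurements(acq, hyp, 10)
  expect_gt(b$fill_count, 0)
  expect_true(all(abs(b$kspace) > 0))  # random data: filled cells non-zero
  # complete coverage leaves nothing to fill
  acq2 <- toyAcquisition(seed = 12, n = 16L, vps = 4L, window = 1.0,
                         tr_ms = 10)
  b2 <- binMeasurements(acq2, TriggerHypothesis(120, 120, t_mid_s =
                                                  max(acq2@time_s) / 2), 5)
  expect_equal(b2$fill_count, 0L)
  expect_true(all(b2$counts > 0))
})

test_that("gated reconstruction reproduces the rendered phantom", {
  sim <- studyAcquisition(hr_bpm = 140, seed = 7, snr = Inf)
  hyp <- TriggerHypothesis(140, 140, t_mid_s = max(sim$acq@time_s) / 2)
  nph <- 16L
  cine <- reconstructCine(binMeasurements(sim$acq, hyp, nph), 60000 / 140)
  geom <- mogflow:::phantomGeometry(sim$st$spec)
  nrmse <- vapply(seq_len(nph), function(p) {
    ref <- phantomFrame(sim$st$spec, (p - 0.5) / nph, geom)$enc2
    sqrt(mean(Mod(cine@frames[, , p, 2] - ref)^2)) /
      sqrt(mean(Mod(ref)^2))
  }, numeric(1))
  expect_lt(max(nrmse), 0.05)
})

test_that("single-phase binning reproduces the time-averaged image", {
  acq <- toyAcquisition(seed = 5)
  hyp <- TriggerHypothesis(140, 140, t_mid_s = max(acq@time_s) / 2)
  b <- binMeasurements(acq, hyp, 1)
  for (e in 1:2) for (r in unique(acq@krow)) {
    sel <- acq@encode == e & acq@krow == r
    expect_equal(b$kspace[r + 1L, , 1, e], colMeans(acq@lines[sel, ]),
                 tolerance = 1e-12)
  }
})

test_that("velocity maps decode the phase difference", {
  n <- 8L
  mk <- function(v, venc) {
    fr <- array(complex(real = 0, imaginary = 0), c(n, n, 1, 2))
    fr[, , 1, 1] <- 1
    fr[, , 1, 2] <- exp(1i * pi * v / venc)
    new("CineSeries", frames = fr, phase_times_ms = 10, rr_ms = 400,
        fill_count = 0L)
  }
  expect_equal(unique(as.vector(velocityMaps(mk(0, 150), 150)@velocity_cm_s)), 0)
  expect_equal(unique(as.vector(velocityMaps(mk(75, 150), 150)@velocity_cm_s)),
               75, tolerance = 1e-12)
  # delta-phi = pi maps to VENC itself (up to principal-value sign)
  expect_equal(abs(unique(as.vector(
    velocityMaps(mk(150, 150), 150)@velocity_cm_s))), 150, tolerance = 1e-9)
  expect_error(velocityMaps(mk(0, 150), -1))
})

test_that("rendered parabolic velocities are recovered pixelwise", {
  # lumen-interior pixels of a 10 mm vessel around 75 cm/s
  spec <- PhantomSpec(vessels = list(VesselSpec(center_mm = c(10, -6),
                                                radius_mm = 5,
                                                peak_velocity_cm_s = 37.5)))
  w <- waveformTemplate("arterial_systolic")
  fr <- phantomFrame(spec, 0.12)
  v <- spec@venc_cm_s * Arg(fr$enc2 * Conj(fr$enc1)) / pi
  px <- pixelSpacing(spec)
  centers <- (seq_len(64) - 32.5) * px
  xs <- outer(centers, rep(1, 64)); ys <- outer(rep(1, 64), centers)
  r <- sqrt((xs - 10)^2 + (ys + 6)^2)
  interior <- r <= 5 - 1.5 * px
  vtrue <- 2 * w(0.12) * 37.5 * (1 - (r / 5)^2)
  expect_gt(sum(interior), 10)
  expect_lt(max(abs(v[interior] - vtrue[interior]) / vtrue[interior]), 0.02)
})

test_that("image entropy has the defining metric properties", {
  roi <- maskROI(matrix(TRUE, 4, 4), role = "metric")
  single <- matrix(0, 4, 4); single[2, 3] <- 5
  expect_equal(imageEntropy(single, roi), 0)
  expect_equal(imageEntropy(matrix(2.7, 4, 4), roi), log(16))
  set.seed(8)
  img <- matrix(runif(16), 4, 4)
  expect_equal(imageEntropy(img, roi), imageEntropy(137.2 * img, roi))
  expect_error(imageEntropy(matrix(0, 4, 4), roi), "zero")
  expect_error(imageEntropy(img, maskROI(matrix(TRUE, 3, 3))))
})

test_that("mis-gating strictly raises ROI entropy on pulsatile phantoms", {
  sim <- studyAcquisition(hr_bpm = 141, seed = 17, snr = Inf)
  tmid <- max(sim$acq@time_s) / 2
  e0 <- mogflow:::entropyGrid(sim$acq, sim$st$roi, 141, 141, tmid, 10L)[1, 1]
  set.seed(31)
  for (k in 1:20) {
    off <- runif(2, 1, 10) * sample(c(-1, 1), 2, replace = TRUE)
    hr <- pmin(pmax(141 + off, 110), 180)
    e <- mogflow:::entropyGrid(sim$acq, sim$st$roi, hr[1], hr[2], tmid,
                               10L)[1, 1]
    expect_gt(e, e0)
  }
  # degradation is monotone in the rate error: non-decreasing at 1 bpm
  # steps, with ties (tiny wiggles once the ghosting has saturated)
  # bounded by 1% of the total entropy rise
  es <- vapply(0:10, function(d)
    mogflow:::entropyGrid(sim$acq, sim$st$roi, 141 + d, 141 + d, tmid,
                          10L)[1, 1], numeric(1))
  expect_gt(es[11], es[1])
  expect_true(all(diff(es) >= -0.01 * (es[11] - es[1])))
})

test_that("compiled metric map equals the R reference pipeline", {
  acq <- toyAcquisition(seed = 19, n = 16L, vps = 4L)
  roi <- rectROI(2, 12, 3, 13, dim = c(16, 16))
  tmid <- max(acq@time_s) / 2
  grid <- c(115, 132.5, 150, 171)
  vals <- mogflow:::entropyGrid(acq, roi, grid, grid, tmid, 6L)
  for (i in seq_along(grid)) for (j in seq_along(grid))
    expect_equal(vals[i, j],
                 referenceEntropy(acq, roi, grid[i], grid[j], 6L),
                 tolerance = 1e-10)
  # grid-search argmin equals exhaustive recomputation with the naive path
  ref <- outer(grid, grid, Vectorize(function(a, b)
    referenceEntropy(acq, roi, a, b, 6L)))
  expect_equal(which.min(vals), which.min(ref))
})

test_that("metric map recovers simulated heart rates", {
  sim <- studyAcquisition(hr_bpm = 140, seed = 23, snr = Inf)
  map <- metricMap(sim$acq, sim$st$roi, hr_band_bpm = c(130, 150),
                   step_bpm = 2, n_phases = 10L)
  expect_true(all(abs(map@argmin_bpm - 140) <= 2))
  expect_true(all(is.finite(map@values)))
  expect_equal(min(map@values),
               map@values[match(map@argmin_bpm[1], map@hr1_grid_bpm),
                          match(map@argmin_bpm[2], map@hr2_grid_bpm)])
  # static phantom: flat map flagged uninformative
  spec0 <- PhantomSpec(vessels = list(VesselSpec(center_mm = c(12, -8),
                                                 peak_velocity_cm_s = 0)))
  prof <- HeartRateProfile("constant", 140,
                           duration_s = sim$st$duration_s)
  acq0 <- acquire(spec0, prof, sim$st$protocol, seed = 2)
  expect_warning(m0 <- metricMap(acq0, sim$st$roi, step_bpm = 10),
                 "uninformative")
  expect_lt(m0@flatness, 1e-3)
})

test_that("refinement never worsens the coarse-grid optimum", {
  sim <- studyAcquisition(hr_bpm = 137, seed = 29, snr = Inf)
  res <- mogOptimize(sim$acq, sim$st$roi, hr_band_bpm = c(125, 150))
  expect_lte(res$entropy, min(res$map@values))
  expect_equal(dim(res$cine@velocity_cm_s)[3], 15L)
  # constant noiseless rate recovered to the refinement scale
  expect_lte(max(abs(c(res$hypothesis@hr1_bpm, res$hypothesis@hr2_bpm) -
                       137)), 0.5)
})

test_that("phase interpolation is periodic, linear and mean-preserving", {
  sim <- studyAcquisition(hr_bpm = 140, seed = 7, snr = Inf)
  vc <- reconstructAt(sim$acq,
                      TriggerHypothesis(140, 140,
                                        t_mid_s = max(sim$acq@time_s) / 2),
                      n_phases = 10)
  vi <- interpolatePhases(vc, 15)
  expect_equal(dim(vi@velocity_cm_s)[3], 15L)
  expect_equal(vi@phase_times_ms, (1:15 - 0.5) / 15 * vc@rr_ms)
  # constant-in-time pixels are unchanged
  bgpix <- vc@velocity_cm_s[1, 1, ]
  expect_lt(diff(range(bgpix)), 1e-8)
  expect_equal(unique(round(vi@velocity_cm_s[1, 1, ], 10)),
               round(bgpix[1], 10))
  # cycle-mean preserved within 1% of the velocity scale
  m_in <- apply(vc@velocity_cm_s, c(1, 2), mean)
  m_out <- apply(vi@velocity_cm_s, c(1, 2), mean)
  expect_lt(max(abs(m_in - m_out)), 0.01 * max(abs(m_in)))
  expect_error(interpolatePhases(vc, 5))
})
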