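test_that("temporal resolution follows the two-encode segmented timing", {
  expect_equal(temporalResolution(6.55, 4), 52.4)
  expect_equal(temporalResolution(1, 1), 2)
  expect_equal(temporalResolution(5, 3), 30)
  expect_equal(temporalResolution(AcquisitionProtocol(6.55, 4L, 192L)), 52.4)
  expect_error(temporalResolution(-1, 4))
  expect_error(AcquisitionProtocol(tr_ms = 0))
})

test_that("beat simulation matches each heart-rate model", {
  b <- simulateBeats(HeartRateProfile("constant", 120, duration_s = 2))
  expect_equal(b, c(0, 0.5, 1, 1.5, 2))
  b2 <- simulateBeats(HeartRateProfile("two_level", 120, 150,
                                       duration_s = 4))
  d <- diff(b2)
  expect_true(all(abs(d[b2[-length(b2)] < 2] - 0.5) < 1e-12))
  expect_true(all(abs(d[b2[-length(b2)] >= 2] - 0.4) < 1e-12))
  expect_error(simulateBeats(HeartRateProfile("constant", 90,
                                              duration_s = 2)))
})

test_that("random-walk beats have the configured rate jitter", {
  prof <- HeartRateProfile("random_walk", 140, beat_to_beat_sd_bpm = 2,
                           duration_s = 250)
  b <- simulateBeats(prof, seed = 99)
  expect_identical(b, simulateBeats(prof, seed = 99))
  rates <- 60 / diff(b)
  expect_gt(length(rates), 450)
  expect_true(all(rates >= 110 & rates <= 180))
  sd_inc <- sd(diff(rates))
  expect_lt(abs(sd_inc - 2) / 2, 0.25)
})

test_that("phantom frames implement the velocity-to-phase encoding", {
  # zero velocity: both encodes identical
  spec0 <- PhantomSpec(vessels = list(VesselSpec(center_mm = c(12, -8),
                                                 peak_velocity_cm_s = 0)))
  fr0 <- phantomFrame(spec0, 0.2)
  expect_equal(fr0$enc1, fr0$enc2)
  # uniform velocity v maps to inter-encode phase pi * v / venc: feed a
  # rendered frame pair into velocityMaps and check a lumen-centre pixel
  spec <- PhantomSpec(vessels = list(VesselSpec(center_mm = c(0, 0),
                                                radius_mm = 10,
                                                peak_velocity_cm_s = 37.5)))
  w <- waveformTemplate("arterial_systolic")
  p <- 0.12
  fr <- phantomFrame(spec, p)
  v_centre <- 150 * Arg(fr$enc2[33, 33] * Conj(fr$enc1[33, 33])) / pi
  expect_equal(v_centre, 2 * w(p) * 37.5, tolerance = 0.02)
  # centre-line velocity above VENC wraps and is flagged
  expect_warning(
    phantomFrame(PhantomSpec(vessels = list(
      VesselSpec(center_mm = c(12, -8), peak_velocity_cm_s = 200))), 0.15),
    "aliasing")
})

test_that("lumen-mean velocity of rendered frames tracks the waveform", {
  # radius 5 mm = 4 pixels; estimate = sum of pixel velocities over the
  # lumen footprint divided by the supersampled lumen area
  spec <- PhantomSpec(vessels = list(VesselSpec(center_mm = c(10, -6),
                                                radius_mm = 5,
                                                peak_velocity_cm_s = 60)))
  geom <- mogflow:::phantomGeometry(spec)
  g <- geom$lumens[[1]]
  w <- waveformTemplate("arterial_systolic")
  for (p in c(0.12, 0.3, 0.7)) {
    fr <- phantomFrame(spec, p, geom)
    v <- spec@venc_cm_s * Arg(fr$enc2 * Conj(fr$enc1)) / pi
    est <- sum(v[g$idx]) / sum(g$frac)
    expect_lt(abs(est - w(p) * 60) / abs(w(p) * 60), 0.01)
  }
})

test_that("waveform templates have their defining features", {
  for (nm in waveformNames()) {
    w <- waveformTemplate(nm)
    g <- seq(0, 0.999, length.out = 512)
    expect_equal(max(abs(w(g))), 1, tolerance = 1e-3)
    expect_equal(w(g), w(g + 3))  # periodic
  }
  expect_lt(min(waveformTemplate("svc_biphasic_reversal")(seq(0, 1, 1e-3))), 0)
  expect_gt(min(waveformTemplate("venous_continuous")(seq(0, 1, 1e-3))), 0)
  expect_lt(min(waveformTemplate("branch_pa_retrograde")(seq(0, 1, 1e-3))), 0)
})

test_that("acquisition is deterministic, conservative, and time-consistent", {
  sim <- studyAcquisition(hr_bpm = 140, seed = 5, snr = 20)
  acq <- sim$acq
  acq2 <- studyAcquisition(hr_bpm = 140, seed = 5, snr = 20)$acq
  expect_identical(acq@lines, acq2@lines)
  expect_identical(acq@time_s, acq2@time_s)
  # every (segment, encode, timestamp) tuple appears exactly once
  key <- paste(acq@segment, acq@encode, format(acq@time_s, digits = 15))
  expect_equal(anyDuplicated(key), 0L)
  # timestamps within scan; both encodes per segment; windows fully spanned
  expect_true(all(acq@time_s >= 0 &
                  acq@time_s <= totalScanTime(acq@protocol)))
  spans <- tapply(acq@time_s, acq@segment, function(t) diff(range(t)))
  expect_true(all(spans > 0.9 * acq@protocol@oversample_window_s -
                    2 * acq@protocol@tr_ms / 1000))
  # typical fetal protocol: 48 segments x 0.7 s window is a ~34 s scan
  expect_equal(totalScanTime(AcquisitionProtocol(6.55, 4L, 192L, 0.7)), 33.6)
})

test_that("static phantom acquisition inverts to the rendered image", {
  spec <- PhantomSpec(vessels = list(VesselSpec(center_mm = c(12, -8),
                                                peak_velocity_cm_s = 0)))
  prot <- AcquisitionProtocol(tr_ms = 6.55, views_per_segment = 1L,
                              matrix_size = 64L, oversample_window_s = 0.7)
  prof <- HeartRateProfile("constant", 140,
                           duration_s = totalScanTime(prot))
  acq <- acquire(spec, prof, prot, seed = 2)
  ref <- phantomFrame(spec, 0)
  for (e in 1:2) {
    k <- matrix(complex(real = 0, imaginary = 0), 64, 64)
    sel <- which(acq@encode == e)
    first <- sel[!duplicated(acq@krow[sel])]
    k[acq@krow[first] + 1L, ] <- acq@lines[first, ]
    img <- fft(k, inverse = TRUE) / (64 * 64)
    expect_equal(img, if (e == 1) ref$enc1 else ref$enc2, tolerance = 1e-12)
  }
  # any binning of a static object reproduces the static image
  vc <- reconstructAt(acq, TriggerHypothesis(155, 125,
                                             t_mid_s = max(acq@time_s) / 2),
                      n_phases = 6)
  expect_lt(max(abs(vc@velocity_cm_s)), 1e-8)
  expect_equal(max(apply(vc@magnitude, c(1, 2), function(x) diff(range(x)))),
               0, tolerance = 1e-10)
})

test_that("acquisition text serialisation round-trips", {
  sim <- studyAcquisition(hr_bpm = 132, seed = 9, snr = 40)
  path <- file.path(tempdir(), "acq.csv")
  writeAcquisition(sim$acq, path)
  back <- readAcquisition(path)
  expect_equal(back@lines, sim$acq@lines, tolerance = 1e-12)
  expect_identical(back@krow, sim$acq@krow)
  expect_identical(back@encode, sim$acq@encode)
  expect_equal(back@time_s, sim$acq@time_s, tolerance = 1e-12)
  expect_equal(back@ground_truth$beats, sim$acq@ground_truth$beats,
               tolerance = 1e-12)
  expect_equal(back@protocol@tr_ms, 6.55)
  unlink(c(path, paste0(path, ".meta.yaml")))
})
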