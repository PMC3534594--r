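# Shared fixtures, all generated in code.

# Small acquisition with arbitrary complex content, for oracle-equivalence
# tests that do not need a physically meaningful phantom.
toyAcquisition <- function(seed = 1L, n = 16L, vps = 4L, window = 1.0,
                           tr_ms = 20) {
  set.seed(seed)
  protocol <- AcquisitionProtocol(tr_ms = tr_ms, views_per_segment = vps,
                                  matrix_size = n, oversample_window_s = window)
  nseg <- n %/% vps
  nlines <- floor(window / (tr_ms / 1000))
  l <- rep(seq_len(nlines) - 1L, times = nseg)
  seg <- rep(seq_len(nseg) - 1L, each = nlines)
  encode <- l %% 2L + 1L
  krow <- seg * vps + (l %/% 2L) %% vps
  time_s <- seg * window + l * tr_ms / 1000
  nm <- length(l)
  lines <- matrix(complex(real = rnorm(nm * n), imaginary = rnorm(nm * n)),
                  nm, n)
  new("SegmentedAcquisition", lines = lines, segment = as.integer(seg),
      krow = as.integer(krow), encode = as.integer(encode), time_s = time_s,
      protocol = protocol, ground_truth = list())
}

# Standard simulated acquisition under the package's study conditions.
studyAcquisition <- function(hr_bpm = 140, seed = 1L, snr = Inf,
                             model = "constant", hr2_bpm = hr_bpm) {
  st <- simStudy(snr)
  prof <- HeartRateProfile(model, hr_bpm, hr2_bpm,
                           duration_s = st$duration_s)
  list(acq = acquire(st$spec, prof, st$protocol, seed = seed), st = st)
}

# Independent phase computation by explicit beat walking: advance trigger
# by trigger at the interval-local rate (handling the straddle of the
# midpoint), then accrue phase within the bracketing interval at the
# piecewise rate.
bruteForcePhase <- function(t, hyp, duration_s) {
  r1 <- hyp@hr1_bpm / 60; r2 <- hyp@hr2_bpm / 60
  tm <- hyp@t_mid_s
  trig <- 0
  repeat {
    cur <- trig[length(trig)]
    nxt <- if (cur + 1 / r1 <= tm || cur >= tm) {
      cur + 1 / (if (cur < tm) r1 else r2)
    } else {  # beat straddles the midpoint
      tm + (1 - (tm - cur) * r1) / r2
    }
    trig <- c(trig, nxt)
    if (nxt > duration_s + 1 / r2) break
  }
  vapply(t, function(ti) {
    j <- max(which(trig <= ti))
    a <- trig[j]
    (min(ti, max(tm, a)) - a) * (if (a < tm) r1 else r2) +
      max(0, ti - max(tm, a)) * r2
  }, numeric(1))
}

# Reference entropy of a hypothesis via the exported R pipeline
# (bin -> reconstruct -> entropy of flow-encoded magnitudes).
referenceEntropy <- function(acq, roi, hr1, hr2, n_phases) {
  hyp <- TriggerHypothesis(hr1, hr2, t_mid_s = max(acq@time_s) / 2)
  cine <- reconstructCine(binMeasurements(acq, hyp, n_phases),
                          60000 / hr1)
  imageEntropy(cine@frames[, , , 2], roi)
}
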