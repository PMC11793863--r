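test_that("default cohort composition and label consistency", {
  coh <- small_cohort(seed = 11)
  expect_length(coh$recordings, 20L)
  expect_equal(as.vector(table(factor(coh$labels$label,
                                      c("NR", "PR", "R")))), c(8, 6, 6))
  # every generated HAM-D pair re-annotates to its planted label
  for (i in seq_len(nrow(coh$labels))) {
    lab <- suppressWarnings(annotate_response(coh$labels$hamd_baseline[i],
                                              coh$labels$hamd_post[i]))
    expect_equal(as.character(lab), coh$labels$label[i])
  }
  expect_true(all(coh$truth$age >= 21 & coh$truth$age <= 49))
})

test_that("simulation is deterministic under its seed", {
  cfg <- sim_config(seed = 4)
  a <- simulate_subject(cfg, "PR", "x", seed = 99)
  b <- simulate_subject(cfg, "PR", "x", seed = 99)
  expect_identical(a$recording$intensity, b$recording$intensity)
  expect_identical(a$mirna, b$mirna)
  c2 <- simulate_subject(cfg, "PR", "x", seed = 100)
  expect_false(identical(a$recording$intensity, c2$recording$intensity))
})

test_that("zero motion rate leaves no detectable artifacts", {
  cfg <- sim_config(motion_rate_per_min = 0)
  s <- simulate_subject(cfg, "NR", "x", seed = 5)
  od <- intensity_to_od(s$recording)
  expect_false(any(detect_motion(od)))
})

test_that("noise-free round trip recovers the planted response through the filter", {
  cfg <- sim_config(gain_sdlog = 0, mayer_sdlog = 0, synchrony_sdlog = 0,
                    drift_um = 0, mayer_um = 0, resp_um = 0, cardiac_um = 0,
                    white_um = 1e-9, fluct_um = 0, motion_rate_per_min = 0)
  s <- simulate_subject(cfg, "NR", "x", seed = 3)
  m <- default_montage()
  pp <- preprocess_recording(s$recording, m)
  kept <- intersect(m$in_use, pp$qc$channel[pp$qc$keep])
  expect_length(kept, 32L)
  got <- 1e6 * colMeans(pp$hb$hbo[kept, ])

  # oracle: planted response through an independent frequency-domain
  # Butterworth magnitude-squared filter (zero-phase equivalent), then the
  # same two-point baseline anchoring
  p <- vft_paradigm(); fs <- 10; n <- 1700; t <- (1:n) / fs
  box <- as.numeric(t >= 40 & t < 100)
  h <- nirstreat:::hrf_kernel(seq(0, 32, by = 0.1), s$truth$hrf_peak_s,
                              s$truth$hrf_undershoot)
  resp <- convolve(box, rev(h), type = "open")[1:n] / fs
  planted <- 0.30 * resp / max(resp)
  f <- c(0:(n / 2), -((n / 2 - 1):1)) * fs / n
  H2 <- (1 / (1 + (0.01 / pmax(abs(f), 1e-12))^10)) *
    (1 / (1 + (abs(f) / 0.1)^6))
  filt <- Re(fft(fft(planted) * H2, inverse = TRUE)) / n
  w1 <- nirstreat:::b1_idx(p); w2 <- nirstreat:::b2_idx(p)
  filt <- filt - nirstreat:::two_point_baseline(filt, w1, w2)

  expect_equal(max(got), max(filt), tolerance = 0.05)
  # the band-pass attenuates the sustained block response substantially;
  # the recovered peak must reflect that attenuation, not the raw amplitude
  expect_lt(max(got), 0.30)
})

test_that("planted activation ordering survives extraction when nuisance is off", {
  ok <- 0
  for (sd_ in 1:5) {
    # nuisance off, HRF shape / coupling topology equalized and coupled
    # fluctuations turned down, so amplitude is the only group effect (the
    # band-pass responds to waveform shape, and coupled fluctuations do not
    # average out of the channel-mean trace)
    cfg <- sim_config(group_sizes = c(NR = 6, PR = 5, R = 5), seed = sd_,
                      gain_sdlog = 0, mayer_sdlog = 0, synchrony_sdlog = 0,
                      activation_um = c(NR = 0.2, PR = 0.3, R = 0.4),
                      hrf_peak_s = c(NR = 6, PR = 6, R = 6),
                      hrf_undershoot = c(NR = 0.2, PR = 0.2, R = 0.2),
                      coupling_balance = c(NR = 0.8, PR = 0.8, R = 0.8),
                      fluct_um = 0.02)
    coh <- simulate_cohort(cfg)
    f <- featurize_cohort(coh)$features
    g <- factor(coh$labels$label[match(rownames(f), coh$labels$subject_id)],
                levels = c("NR", "PR", "R"))
    means <- tapply(f[, "mean"], g, mean)
    if (means["NR"] < means["PR"] && means["PR"] < means["R"]) ok <- ok + 1
  }
  expect_equal(ok, 5)
})

test_that("cohorts write to disk and load back as an identical joined cohort", {
  coh <- simulate_cohort(sim_config(group_sizes = c(NR = 2, PR = 2, R = 2),
                                    seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  recs <- lapply(coh$labels$subject_id,
                 function(id) read_recording(file.path(dir, paste0(id, ".csv"))))
  j <- join_cohort(recs, read_mirna(file.path(dir, "mirna.csv")),
                   read_labels(file.path(dir, "labels.csv")))
  expect_length(j$dropped, 0L)
  for (i in seq_along(recs))
    expect_equal(j$recordings[[i]]$intensity, coh$recordings[[i]]$intensity,
                 tolerance = 1e-12)
  expect_equal(j$mirna[[MIRNA_FEATURES[1]]], coh$mirna[[MIRNA_FEATURES[1]]],
               tolerance = 1e-12)
})
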