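#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative model of a synthetic treatment-response cohort with
#' the statistical structure the analysis method assumes. Each subject's
#' prefrontal dHbO is a task-evoked response (double-gamma HRF convolved with
#' the 60 s task boxcar) whose *shape* (peak latency, undershoot depth) and
#' whose inter-channel coupling topology depend on the response group, while
#' its overall scale is dominated by a per-subject multiplicative gain -- the
#' inter-subject nuisance the reference-group PCA routine is designed to
#' remove. The nuisance spread (gain and Mayer-wave amplitude, log-normal) is
#' deliberately much larger than the group effects on amplitude. Physiological
#' noise (linear drift, ~0.1 Hz Mayer waves, 0.25 Hz respiratory, 1.1 Hz
#' cardiac, white noise) and seeded motion spikes are superimposed; dHbR is
#' the typical anticorrelated -1/3 mirror of dHbO plus noise. The forward
#' modified Beer-Lambert model converts concentrations to optical density and
#' then to raw intensities. miRNA values are log-normal with group-shifted
#' means; HAM-D score pairs are generated consistent with each subject's
#' planted group.
#'
#' All amplitudes are in micromolar; durations in seconds.
#'
#' @param group_sizes Named cohort composition (default 24 NR, 15 PR, 13 R).
#' @param seed Master seed; every random draw derives from it.
#' @param activation_um Task-response peak amplitude per group.
#' @param gain_sdlog Log-SD of the per-subject multiplicative gain (dominant
#'   nuisance).
#' @param hrf_peak_s,hrf_undershoot HRF peak latency and undershoot ratio per
#'   group; `hrf_peak_jitter_s`, `hrf_undershoot_jitter` are the (small)
#'   per-subject SDs.
#' @param coupling_total Total variance share of the coupled (global + block)
#'   latent sources; `synchrony_sdlog` is the log-SD of the per-subject
#'   multiplicative synchrony factor applied to it (the second dominant
#'   nuisance, loading on every network metric).
#' @param coupling_balance Fraction of the coupled share carried by the
#'   *global* source, per group -- the group connectivity effect: responders
#'   shift coupling from one global network towards block-structured
#'   subnetworks at similar total synchrony; `balance_jitter` the (small)
#'   per-subject SD.
#' @param fluct_um Amplitude of the coupled low-frequency fluctuations.
#' @param drift_um,mayer_um,resp_um,cardiac_um,white_um Noise amplitudes.
#' @param mayer_sdlog Log-SD of the subject Mayer-wave gain (second nuisance).
#' @param motion_rate_per_min,motion_um Motion-spike rate and amplitude.
#' @param mirna_meanlog Base log-means of the three miRNAs;
#'   `mirna_shift` a 3 x 3 matrix (miRNA x group) of log-mean shifts;
#'   `mirna_sdlog` the within-group log-SD.
#' @param age_range Uniform age range in years.
#' @param hamd_range Baseline HAM-D sampling range.
#' @return A `sim_config` list.
#' @export
sim_config <- function(group_sizes = c(NR = 24, PR = 15, R = 13),
                       seed = 0,
                       activation_um = c(NR = 0.30, PR = 0.33, R = 0.36),
                       gain_sdlog = 0.6,
                       hrf_peak_s = c(NR = 5.5, PR = 7.0, R = 8.5),
                       hrf_peak_jitter_s = 0.25,
                       hrf_undershoot = c(NR = 0.35, PR = 0.20, R = 0.08),
                       hrf_undershoot_jitter = 0.03,
                       coupling_total = 0.65, synchrony_sdlog = 0.5,
                       coupling_balance = c(NR = 0.98, PR = 0.80, R = 0.60),
                       balance_jitter = 0.02,
                       fluct_um = 0.12,
                       drift_um = 0.20, mayer_um = 0.08, mayer_sdlog = 0.5,
                       resp_um = 0.05, cardiac_um = 0.04, white_um = 0.01,
                       motion_rate_per_min = 0.4, motion_um = 3.0,
                       mirna_meanlog = c(0, 0, 0),
                       mirna_shift = rbind(c(0, 0.5, 1.0),
                                           c(0, -0.4, -0.8),
                                           c(0, 0.3, 0.6)),
                       mirna_sdlog = 0.5,
                       age_range = c(21, 49),
                       hamd_range = c(18, 30)) {
  stopifnot(all(group_sizes > 0), identical(names(group_sizes), c("NR", "PR", "R")),
            gain_sdlog >= 0, fluct_um >= 0, white_um >= 0,
            coupling_total > 0, coupling_total <= 1,
            all(coupling_balance >= 0 & coupling_balance <= 1))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Double-gamma HRF with given peak latency and undershoot ratio; unit peak.
hrf_kernel <- function(t, peak_s, undershoot) {
  a1 <- 6; b1 <- (a1 - 1) / peak_s
  a2 <- 16; b2 <- (a2 - 1) / (peak_s + 9)
  h <- stats::dgamma(t, shape = a1, rate = b1) -
    undershoot * stats::dgamma(t, shape = a2, rate = b2)
  h / max(h)
}

# Band-limited (0.02-0.09 Hz) unit-SD random fluctuation of length n.
band_noise <- function(n, fs) {
  t <- seq_len(n) / fs
  freqs <- seq(0.02, 0.09, by = 0.01)
  x <- numeric(n)
  for (f in freqs)
    x <- x + stats::rnorm(1) * cos(2 * pi * f * t) +
      stats::rnorm(1) * sin(2 * pi * f * t)
  x / stats::sd(x)
}

# Block assignment of all 52 channels (4 blocks over the in-use grid,
# lateral channels folded into the nearest block).
channel_blocks <- function(montage) {
  ids <- montage$channels$id
  blk <- integer(length(ids))
  in_use <- match(montage$in_use, ids)
  blk[in_use] <- rep(1:4, length.out = length(in_use))
  blk[blk == 0L] <- rep(1:4, length.out = sum(blk == 0L))
  stats::setNames(blk, ids)
}

#' Simulate one subject
#'
#' @param cfg A [sim_config()].
#' @param group `"NR"`, `"PR"` or `"R"`.
#' @param subject_id Subject identifier.
#' @param seed Seed for this subject's draws.
#' @param montage Montage to simulate (default packaged 52-channel probe).
#' @param paradigm Task paradigm.
#' @return List with `recording` (a `nirs_recording`), `mirna` (named
#'   vector), `label` (one-row data.frame with HAM-D pair), and `truth`
#'   (latent parameters).
#' @export
simulate_subject <- function(cfg, group, subject_id, seed,
                             montage = default_montage(),
                             paradigm = vft_paradigm()) {
  stopifnot(inherits(cfg, "sim_config"), group %in% RESPONSE_LEVELS)
  with_seed(seed, {
    fs <- paradigm$sampling_rate
    n <- paradigm_n_samples(paradigm)
    t <- seq_len(n) / fs
    chans <- montage$channels$id
    nch <- length(chans)
    blocks <- channel_blocks(montage)

    age <- stats::runif(1, cfg$age_range[1], cfg$age_range[2])
    gain <- stats::rlnorm(1, 0, cfg$gain_sdlog)
    mayer_gain <- stats::rlnorm(1, 0, cfg$mayer_sdlog)
    peak_s <- max(3, cfg$hrf_peak_s[group] +
                    stats::rnorm(1, 0, cfg$hrf_peak_jitter_s))
    undershoot <- max(0, cfg$hrf_undershoot[group] +
                        stats::rnorm(1, 0, cfg$hrf_undershoot_jitter))
    synchrony <- stats::rlnorm(1, 0, cfg$synchrony_sdlog)
    total <- min(0.95, max(0.05, cfg$coupling_total * synchrony))
    balance <- min(0.98, max(0.02, cfg$coupling_balance[group] +
                               stats::rnorm(1, 0, cfg$balance_jitter)))
    w0 <- total * balance
    wb <- total * (1 - balance)

    # task-evoked response, unit peak
    box <- as.numeric(t >= task_onset_s(paradigm) & t < task_offset_s(paradigm))
    h <- hrf_kernel(seq(0, 32, by = 1 / fs), peak_s, undershoot)
    resp <- stats::convolve(box, rev(h), type = "open")[seq_len(n)] / fs
    resp <- resp / max(resp)

    amp <- cfg$activation_um[group] * 1e-6
    prof <- pmax(0.2, 1 + stats::rnorm(nch, 0, 0.1))   # spatial profile

    s0 <- band_noise(n, fs)
    sb <- replicate(4, band_noise(n, fs))
    phase <- stats::runif(3, 0, 2 * pi)

    hbo <- matrix(0, nch, n, dimnames = list(chans, NULL))
    for (c in seq_len(nch)) {
      fluct <- sqrt(w0) * s0 + sqrt(wb) * sb[, blocks[c]] +
        sqrt(max(0, 1 - w0 - wb)) * band_noise(n, fs)
      physio <- cfg$drift_um * 1e-6 * (t / max(t) - 0.5) * stats::rnorm(1, 1, 0.3) +
        mayer_gain * cfg$mayer_um * 1e-6 * sin(2 * pi * 0.1 * t + phase[1] +
                                                 stats::runif(1, 0, 2 * pi)) +
        cfg$resp_um * 1e-6 * sin(2 * pi * 0.25 * t + phase[2]) +
        cfg$cardiac_um * 1e-6 * sin(2 * pi * 1.1 * t + phase[3])
      hbo[c, ] <- gain * (amp * prof[c] * resp +
                            cfg$fluct_um * 1e-6 * fluct + physio) +
        stats::rnorm(n, 0, cfg$white_um * 1e-6)
    }
    # seeded motion spikes: brief high-amplitude excursions on random channels
    n_spikes <- stats::rpois(1, cfg$motion_rate_per_min *
                               paradigm_duration(paradigm) / 60)
    if (n_spikes > 0) for (s in seq_len(n_spikes)) {
      ch <- sample(nch, 1)
      at <- sample(n - 2L * fs, 1)
      len <- sample(seq.int(max(2L, round(0.2 * fs)), round(1 * fs)), 1)
      shape <- exp(-((seq_len(len) - len / 2)^2) / (len / 3)^2)
      hbo[ch, at:(at + len - 1L)] <- hbo[ch, at:(at + len - 1L)] +
        sample(c(-1, 1), 1) * cfg$motion_um * 1e-6 * shape
    }
    hbr <- -hbo / 3 + matrix(stats::rnorm(nch * n, 0, cfg$white_um * 1e-6 / 3),
                             nch, n)

    od <- hemoglobin_to_od(hbo, hbr, age, montage)
    i0 <- stats::rlnorm(nch, 0, 0.2)
    intensity <- array(NA_real_, dim = dim(od), dimnames = dimnames(od))
    for (w in 1:2) intensity[, w, ] <- i0 * 10^(-od[, w, ])

    rec <- nirs_recording(subject_id, age, intensity, paradigm)

    # log-normal expression, reported on the log scale (relative expression,
    # the customary qPCR normalization)
    mirna <- stats::rnorm(3,
                          cfg$mirna_meanlog +
                            cfg$mirna_shift[, match(group, RESPONSE_LEVELS)],
                          cfg$mirna_sdlog)
    names(mirna) <- MIRNA_FEATURES

    b <- sample(seq(cfg$hamd_range[1], cfg$hamd_range[2]), 1)
    post_candidates <- switch(group,
      NR = seq(ceiling(0.76 * b), b),
      PR = seq(ceiling(0.50 * b), floor(0.75 * b)),
      R  = seq(0, floor(0.49 * b)))
    post <- post_candidates[sample(length(post_candidates), 1)]

    list(recording = rec,
         mirna = mirna,
         label = data.frame(subject_id = subject_id, label = group,
                            hamd_baseline = b, hamd_post = post,
                            stringsAsFactors = FALSE),
         truth = data.frame(subject_id = subject_id, group = group, age = age,
                            gain = gain, mayer_gain = mayer_gain,
                            activation_um = cfg$activation_um[group],
                            hrf_peak_s = peak_s, hrf_undershoot = undershoot,
                            synchrony = synchrony, coupling_total = total,
                            coupling_balance = balance,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a full cohort
#'
#' Generates `sum(group_sizes)` subjects (default 24 NR + 15 PR + 13 R = 52)
#' with per-subject seeds derived from the master seed, so the cohort is
#' fully reproducible.
#'
#' @inheritParams simulate_subject
#' @return A `nirs_cohort`: `recordings` (list), `mirna` (data.frame),
#'   `labels` (data.frame with HAM-D pairs), `truth` (data.frame),
#'   `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), montage = default_montage(),
                            paradigm = vft_paradigm()) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  ids <- sprintf("sub%02d", seq_along(groups))
  subs <- lapply(seq_along(groups), function(i)
    simulate_subject(cfg, groups[i], ids[i], seed = child_seed(cfg$seed, i),
                     montage = montage, paradigm = paradigm))
  mirna <- data.frame(subject_id = ids,
                      do.call(rbind, lapply(subs, `[[`, "mirna")),
                      check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(recordings = lapply(subs, `[[`, "recording"),
                 mirna = mirna,
                 labels = do.call(rbind, lapply(subs, `[[`, "label")),
                 truth = do.call(rbind, lapply(subs, `[[`, "truth")),
                 config = cfg),
            class = "nirs_cohort")
}

#' @export
print.nirs_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s)\n",
              length(x$recordings),
              paste(names(table(x$labels$label)), table(x$labels$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one intensity CSV (+ JSON sidecar) per subject plus `mirna.csv`,
#' `labels.csv` and `truth.json` into a directory.
#'
#' @param cohort A `nirs_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings)
    write_recording(rec, file.path(dir, paste0(rec$subject_id, ".csv")))
  write_mirna(cohort$mirna, file.path(dir, "mirna.csv"))
  write_labels(cohort$labels, file.path(dir, "labels.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
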