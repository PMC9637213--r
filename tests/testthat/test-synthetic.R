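# Synthetic cohort generator --------------------------------------------------

test_that("null signal and determinism", {
  cfg <- small_config(noise_sigma = 0,
                      erp_amplitude = rbind(control = c(Standard = 0, Novelty = 0,
                                                        Target = 0),
                                            pd = c(Standard = 0, Novelty = 0,
                                                   Target = 0)),
                      source_gain = c(control = 0, pd = 0))
  rec <- generate_record(cfg, "pd", "P1", 99L)
  expect_true(all(rec$data == 0))

  cfg2 <- small_config(seed = 1L)
  a <- generate_record(cfg2, "control", "C1", 55L)
  b <- generate_record(cfg2, "control", "C1", 55L)
  expect_identical(a$data, b$data)
  expect_identical(a$events, b$events)
  c2 <- generate_record(cfg2, "control", "C1", 56L)
  expect_false(identical(a$data, c2$data))
})

test_that("noise-free single-event record is the template at the profile", {
  grid <- toy_grid_3x3()
  amp <- rbind(control = c(Standard = 5, Novelty = 0, Target = 0),
               pd = c(Standard = 5, Novelty = 0, Target = 0))
  cfg <- synthetic_config(n_per_group = 1, grid = grid, duration_s = 20,
                          events_per_task = c(Standard = 1, Novelty = 1,
                                              Target = 1),
                          erp_amplitude = amp, erp_profile_sd = 1e-3,
                          amp_jitter_sd = 0, noise_sigma = 0,
                          source_gain = c(control = 0, pd = 0),
                          erp_center = "B2", mixing = diag(9))
  rec <- generate_record(cfg, "control", "C1", 7L)
  onset <- rec$events$onset_sample[rec$events$task == "Standard"]
  tc_len <- length(eegcsp:::erp_time_course(cfg$fs))
  outside <- rec$data[, -((onset + 1):(onset + tc_len))]
  expect_true(all(outside == 0))
  expect_true(all(rec$data[setdiff(rownames(rec$data), "B2"), ] < 1e-6))
  expect_equal(max(rec$data["B2", ]), 5, tolerance = 1e-6)
})

test_that("event schedule honors gaps and windows; impossible schedules error", {
  cfg <- small_config(seed = 77L)
  for (k in 1:5) {
    rec <- generate_record(cfg, "pd", paste0("P", k), 100L + k)
    on <- rec$events$onset_sample
    expect_true(all(diff(on) >= 4 * cfg$fs))
    expect_true(all(on - 2 * cfg$fs >= 0))
    expect_true(all(on + 2 * cfg$fs <= ncol(rec$data)))
    expect_equal(sum(rec$events$task == "Standard"), 4L)
  }
  expect_error(synthetic_config(duration_s = 20), "cannot be scheduled")
})

test_that("long noise-only record reproduces the mixing covariance", {
  grid <- toy_grid_3x3()
  amp0 <- rbind(control = c(Standard = 0, Novelty = 0, Target = 0),
                pd = c(Standard = 0, Novelty = 0, Target = 0))
  set.seed(81)
  M <- diag(9) + 0.3 * matrix(rnorm(81), 9)
  sigma <- 2
  # white noise (exponent 0) for the quantitative covariance bound; the
  # sample covariance of 1/f noise converges too slowly at test scale
  cfg <- synthetic_config(n_per_group = 1, grid = grid, duration_s = 120,
                          events_per_task = c(Standard = 1, Novelty = 1,
                                              Target = 1),
                          erp_amplitude = amp0, erp_center = "B2",
                          noise_sigma = sigma, noise_exponent = 0,
                          source_gain = c(control = 0, pd = 0), mixing = M)
  dev <- function(dur, seed) {
    cfg$duration_s <- dur
    rec <- generate_record(cfg, "control", "C1", seed)
    emp <- tcrossprod(rec$data) / ncol(rec$data)
    max(abs(emp - sigma^2 * M %*% t(M)))
  }
  d_short <- mean(vapply(1:3, function(s) dev(15, s), numeric(1)))
  d_long <- mean(vapply(1:3, function(s) dev(120, s), numeric(1)))
  expect_lt(d_long, d_short)          # deviation shrinks with duration
  expect_lt(d_long, 0.1 * sigma^2)    # and is small in absolute terms
})

test_that("1/f background noise has the configured spectral slope", {
  set.seed(82)
  x <- eegcsp:::pink_noise(2^15, 1, 1)[, 1]
  p <- Mod(fft(x)[2:2^14])^2
  f <- seq_len(2^14 - 1)
  # average log-power in octave bins and regress on log-frequency
  oct <- floor(log2(f))
  keep <- oct >= 3 & oct <= 12
  mp <- tapply(p[keep], oct[keep], mean)
  log_f <- as.numeric(names(mp)) * log(2)
  slope <- unname(coef(lm(log(mp) ~ log_f))[2])
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("cohorts have the configured size, labels and manifest", {
  cfg <- small_config(seed = 91L)
  coh <- generate_cohort(cfg)
  expect_length(coh$records, 6L)
  expect_equal(sum(coh$manifest$group == "control"), 3L)
  expect_equal(sum(coh$manifest$group == "pd"), 3L)
  expect_equal(vapply(coh$records, `[[`, character(1), "subject_id"),
               coh$manifest$subject_id)
  v <- attr(coh$manifest, "planted_direction")
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  expect_equal(names(which.max(v)), "Fz")

  cfg1 <- synthetic_config(n_per_group = 1, duration_s = 60, seed = 92L)
  expect_length(generate_cohort(cfg1)$records, 2L)
})

test_that("scaled-down parameter recovery: CSP pattern finds the planted direction", {
  cfg <- synthetic_config(
    n_per_group = 4L, duration_s = 30,
    events_per_task = c(Standard = 4L, Novelty = 1L, Target = 1L),
    noise_sigma = 1, source_gain = c(control = 0, pd = 20),
    mixing = diag(60), seed = 93L)
  coh <- generate_cohort(cfg)
  filt <- lapply(coh$records, bandpass, 0.1, 20)
  grp <- coh$manifest$group
  Ec <- do.call(cbind, lapply(filt[grp == "control"], `[[`, "data"))
  Ep <- do.call(cbind, lapply(filt[grp == "pd"], `[[`, "data"))
  m <- csp_fit(Ec, Ep)
  v <- attr(coh$manifest, "planted_direction")
  expect_gte(cosine(m$patterns[, 1], v), 0.95)
  # the filter is the noisier estimate at this reduced scale; the full-size
  # cohort (acceptance suite) holds it to 0.95
  expect_gte(cosine(m$W[1, ], v), 0.7)
  expect_gt(m$ratios[1], m$ratios[2] + 0.1)  # planted component stands out
})
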