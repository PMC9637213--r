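# CSP fitting, projection, features, channel ranking -------------------------

test_that("normalized_covariance matches a loop oracle and has unit trace", {
  expect_equal(normalized_covariance(diag(2)), diag(0.5, 2))
  set.seed(1)
  E <- matrix(rnorm(400), 4, 100)
  C <- normalized_covariance(E)
  # independent elementwise computation
  raw <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) raw[i, j] <- sum(E[i, ] * E[j, ])
  expect_equal(C, raw / sum(diag(raw)), tolerance = 1e-12)
  expect_equal(sum(diag(C)), 1)
  expect_true(isSymmetric(C))
  expect_error(normalized_covariance(matrix(0, 3, 10)), "degenerate")
})

test_that("identical class averages give ratio 1/2 everywhere", {
  set.seed(2)
  E <- matrix(rnorm(5 * 200), 5, 200)
  m <- csp_fit(E, E)
  expect_equal(m$ratios, rep(0.5, 5), tolerance = 1e-10)
})

test_that("axis-aligned 2-channel case: ratios and filters are as computed by hand", {
  # covariances proportional to diag(4, 1) and diag(1, 4)
  Ec <- rbind(c(2, 0, -2, 0), c(0, 1, 0, -1))
  Ep <- rbind(c(1, 0, -1, 0), c(0, 2, 0, -2))
  m <- csp_fit(Ec, Ep)
  expect_equal(m$ratios, c(0.8, 0.2), tolerance = 1e-10)
  # rows of W align with the coordinate axes; first component is channel 2
  expect_equal(cosine(m$W[1, ], c(0, 1)), 1, tolerance = 1e-10)
  expect_equal(cosine(m$W[2, ], c(1, 0)), 1, tolerance = 1e-10)
  expect_equal(cosine(m$patterns[, 1], c(0, 1)), 1, tolerance = 1e-10)
})

test_that("whitening identity, complementary ratios and inverse round trip", {
  set.seed(3)
  for (rep in 1:5) {
    n_ch <- sample(3:8, 1)
    Ec <- matrix(rnorm(n_ch * 300), n_ch, 300)
    Ep <- matrix(rnorm(n_ch * 300), n_ch, 300) * 1.5
    m <- csp_fit(Ec, Ep)
    Cc <- normalized_covariance(Ec) + normalized_covariance(Ep)
    expect_lt(max(abs(m$W %*% Cc %*% t(m$W) - diag(n_ch))), 1e-8)
    # lambda_pd + lambda_control = 1 per component
    Sc <- m$W %*% normalized_covariance(Ec) %*% t(m$W)
    expect_equal(unname(m$ratios + diag(Sc)), rep(1, n_ch), tolerance = 1e-8)
    expect_true(all(diff(m$ratios) <= 1e-12))
    expect_true(all(m$ratios >= -1e-12 & m$ratios <= 1 + 1e-12))
    # W and patterns are mutual inverses
    expect_lt(max(abs(m$W %*% m$patterns - diag(n_ch))), 1e-8)
    # projection round trip
    sig <- matrix(rnorm(n_ch * 50), n_ch, 50)
    Z <- csp_project(m, sig)
    expect_lt(max(abs(m$patterns %*% Z - sig)), 1e-8)
  }
})

test_that("top filter matches a brute-force variance-ratio maximizer", {
  set.seed(4)
  for (n_ch in 2:4) {
    mix_p <- diag(n_ch) + 0.3 * matrix(rnorm(n_ch^2), n_ch)
    Ec <- matrix(rnorm(n_ch * 500), n_ch, 500)
    Ep <- mix_p %*% matrix(rnorm(n_ch * 500), n_ch, 500)
    m <- csp_fit(Ec, Ep)
    oracle <- csp_top_filter_oracle(Ec, Ep)
    expect_gte(cosine(m$W[1, ], oracle$w), 0.999)
    expect_equal(m$ratios[1], oracle$ratio, tolerance = 1e-6)
  }
})

test_that("common rescaling of both averages changes neither filters nor ratios", {
  set.seed(5)
  Ec <- matrix(rnorm(4 * 200), 4, 200)
  Ep <- matrix(rnorm(4 * 200), 4, 200)
  m1 <- csp_fit(Ec, Ep)
  m2 <- csp_fit(17.3 * Ec, 17.3 * Ep)
  expect_equal(m1$ratios, m2$ratios, tolerance = 1e-10)
  for (k in 1:4) expect_gt(cosine(m1$W[k, ], m2$W[k, ]), 1 - 1e-10)
})

test_that("component naming and spatial_patterns slice the six extremes", {
  set.seed(6)
  Ec <- matrix(rnorm(8 * 300), 8, 300)
  Ep <- matrix(rnorm(8 * 300), 8, 300)
  m <- csp_fit(Ec, Ep)
  expect_equal(m$component_names[1:3], c("MxPMnC1", "MxPMnC2", "MxPMnC3"))
  expect_equal(m$component_names[6:8], c("MnPMxC3", "MnPMxC2", "MnPMxC1"))
  sp <- spatial_patterns(m)
  expect_equal(colnames(sp),
               c("MxPMnC1", "MxPMnC2", "MxPMnC3",
                 "MnPMxC1", "MnPMxC2", "MnPMxC3"))
  expect_lt(max(abs(sp - m$patterns[, c(1:3, 8:6)])), 1e-12)
  # orthonormal W (axis-aligned 2-channel case): patterns equal t(W)
  mo <- csp_fit(rbind(c(2, 0, -2, 0), c(0, 1, 0, -1)),
                rbind(c(1, 0, -1, 0), c(0, 2, 0, -2)))
  expect_equal(mo$patterns, t(mo$W), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("log-variance features: unit variance gives 0, both modes agree", {
  cfg <- small_config(seed = 31L)
  rec <- generate_record(cfg, "pd", "P1", 7L)
  recs <- list(generate_record(cfg, "control", "C1", 8L), rec)
  spec <- interval_spec(0, 500)
  ac <- group_pooled_average(recs[1], "Standard", spec)$a
  ap <- group_pooled_average(recs[2], "Standard", spec)$a
  m <- suppressWarnings(csp_fit(ac, ap))
  f1 <- csp_features(m, rec, "Standard", spec, c("MxPMnC2", "MxPMnC3"))
  f2 <- csp_features(m, rec, "Standard", spec, c("MxPMnC2", "MxPMnC3"),
                     mode = "map_then_avg")
  expect_equal(f1, f2, tolerance = 1e-10)  # both modes are linear reductions
  expect_named(f1, c("MxPMnC2", "MxPMnC3"))

  # axis-aligned model + unit-population-variance channel signals in the
  # interval -> features log(1) = 0
  m2 <- csp_fit(rbind(c(2, 0, -2, 0), c(0, 1, 0, -1)),
                rbind(c(1, 0, -1, 0), c(0, 2, 0, -2)))
  rec2 <- constant_record(0, n_ch = 2)
  onset <- rec2$events$onset_sample[1]
  cols <- (onset + 1):(onset + 250)  # the [0, 500) ms interval at fs 500
  for (ch in 1:2) {
    z <- rnorm(250)
    rec2$data[ch, cols] <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  }
  f0 <- csp_features(m2, rec2, "Standard", interval_spec(0, 500), 1:2)
  expect_equal(unname(f0), c(0, 0), tolerance = 1e-10)

  # constant component signal is a feature error
  const_rec <- constant_record(3, n_ch = 2)
  expect_error(csp_features(m2, const_rec, "Standard", interval_spec(0, 250),
                            1L), "zero-variance")
})

test_that("informative-channel ranking: point loadings and ties", {
  g <- toy_grid_3x3()
  labs <- names(g$label_to_cell)
  pat <- matrix(0, 9, 6, dimnames = list(labs, NULL))
  pat["B2", 1] <- 1
  rk <- rank_informative_channels(pat, g)
  expect_equal(rk$channel[1], "B2")
  expect_equal(rk$score[1], 1)

  uniform <- matrix(1, 9, 6, dimnames = list(labs, NULL))
  rk_u <- rank_informative_channels(uniform, g)
  expect_equal(length(unique(rk_u$score)), 1L)  # all tie
})
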