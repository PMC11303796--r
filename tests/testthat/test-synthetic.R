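test_that("all generators are deterministic under a fixed seed", {
  expect_identical(gen_scheme(seed = 9), gen_scheme(seed = 9))
  sch <- test_scheme()
  fit <- benchmark_voxel()
  expect_identical(simulate_voxel(fit, sch, snr = 30, seed = 4),
                   simulate_voxel(fit, sch, snr = 30, seed = 4))
  b1 <- gen_bundle("helix", seed = 12)
  b2 <- gen_bundle("helix", seed = 12)
  expect_identical(b1$streamlines, b2$streamlines)
  s1 <- gen_profiles(profile_sim_spec(seed = 31))
  s2 <- gen_profiles(profile_sim_spec(seed = 31))
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$meta, s2$meta)
  # and generators do not disturb the global RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_profiles(profile_sim_spec(seed = 1)))
  expect_identical(rnorm(1), before)
})

test_that("noise-free simulation equals the forward model", {
  sch <- test_scheme()
  fit <- benchmark_voxel()
  expect_identical(simulate_voxel(fit, sch, snr = Inf), predict_signal(fit, sch))
  expect_error(simulate_voxel(fit, sch, snr = -3), "positive")
})

test_that("Rician noise has the expected moments", {
  # fixed true amplitude 0.5, sigma = 1/30: mean slightly above 0.5 (Rician
  # bias), SD ~ sigma within 10%; oracle = numerical integration of the
  # Rician density
  sch <- gradient_scheme(c(0, rep(1000, 10000)),
                         rbind(c(0, 0, 0),
                               matrix(rep(c(1, 0, 0), 10000), ncol = 3, byrow = TRUE)))
  # attenuation 0.5 at b = 1000 needs adc = log(2)/1000
  adc <- log(2) / 1000
  fit <- mcm_fit(0, list(zeppelin(1, c(1, 0, 0), adc, adc)))
  sig <- simulate_voxel(fit, sch, snr = 30, seed = 2)[-1]
  sigma <- 1 / 30
  x <- seq(0, 2, length.out = 20001)
  # numerically stable Rician density via the exponent-scaled Bessel function
  log_dens <- log(x / sigma^2) - (x^2 + 0.25) / (2 * sigma^2) +
    log(besselI(x * 0.5 / sigma^2, 0, expon.scaled = TRUE)) + x * 0.5 / sigma^2
  dens <- exp(log_dens); dens[1] <- 0
  dx <- x[2] - x[1]
  m1 <- sum(x * dens) * dx
  m2 <- sum(x^2 * dens) * dx
  expect_gt(mean(sig), 0.5)                     # Rician bias direction
  expect_equal(mean(sig), m1, tolerance = 0.002)
  expect_equal(sd(sig), sqrt(m2 - m1^2), tolerance = 0.1 * sigma)
  expect_equal(sd(sig), sigma, tolerance = 0.1 * sigma)
})

test_that("phantoms carry ground truth and reject overlapping regions", {
  sch <- test_scheme()
  dd <- c(2, 2, 1)
  csf <- array(c(TRUE, FALSE, TRUE, FALSE), dd)
  fib <- array(c(FALSE, TRUE, FALSE, TRUE), dd)
  spec <- phantom_spec(dim = dd, regions = list(
    list(mask = csf, fit = mcm_fit(1)),
    list(mask = fib, fit = benchmark_voxel())), snr = Inf, seed = 1)
  ph <- gen_phantom(spec, sch)
  expect_identical(dim(ph$dwi), as.integer(c(dd, nrow(sch))))
  # noise-free CSF voxels equal the free-water decay curve
  expect_equal(ph$dwi[1, 1, 1, ] / 100, predict_signal(mcm_fit(1), sch),
               tolerance = 1e-12)
  expect_identical(ph$truth$n_aniso[1, 1, 1], 0L)
  expect_identical(ph$truth$n_aniso[2, 1, 1], 1L)
  expect_equal(ph$truth$FW[2, 1, 1], 0.3)
  expect_error(phantom_spec(dim = dd, regions = list(
    list(mask = csf, fit = mcm_fit(1)), list(mask = csf, fit = mcm_fit(1)))),
    "overlap")
  # empty region list: pure-noise volume, empty mask
  ph0 <- gen_phantom(phantom_spec(dim = dd, regions = list(), snr = 20, seed = 2), sch)
  expect_false(any(ph0$mask))
  expect_true(all(ph0$dwi > 0))
})

test_that("bundle generator produces the requested geometry", {
  b <- gen_bundle("line", n_streamlines = 5, jitter_sd = 0, spread_sd = 0,
                  seed = 3, scale = 30)
  for (i in 2:5) expect_identical(b$streamlines[[i]], b$streamlines[[1]])
  expect_equal(b$streamlines[[1]][1, ], c(0, 0, 0))
  expect_equal(b$streamlines[[1]][nrow(b$streamlines[[1]]), ], c(30, 0, 0))

  # noisy arc: centroid recovers the true arc within the jitter scale
  ba <- gen_bundle("arc", n_streamlines = 30, jitter_sd = 0.5, spread_sd = 0,
                   seed = 4, scale = 40)
  cl <- compute_centroid(ba, 50)
  tt <- seq(0, pi / 2, length.out = 2001)
  arc <- cbind(40 * cos(tt), 40 * sin(tt), 0)
  rms <- sqrt(mean(vapply(seq_len(50), function(i) {
    min(colSums((t(arc) - cl$nodes[i, ])^2))
  }, numeric(1))))
  expect_lt(rms, 0.5)
})

test_that("profile datasets have the advertised shape and moments", {
  sim <- gen_profiles(profile_sim_spec(seed = 17))
  expect_identical(dim(alongtract:::profiles_to_array(sim$profiles)),
                   c(56L, 100L, 5L))
  expect_identical(nrow(sim$meta), 56L)
  expect_identical(sum(sim$meta$group == "HC"), 21L)
  expect_identical(sum(sim$meta$group == "LLD"), 35L)

  # moments at n = 1000 within standard-error bounds
  big <- gen_profiles(profile_sim_spec(n_group1 = 500, n_group2 = 500, seed = 18))
  expect_equal(mean(big$meta$age), 75, tolerance = 3 * 6 / sqrt(1000))
  expect_equal(sd(big$meta$age), 6, tolerance = 0.5)
  expect_equal(mean(big$meta$AES), 41.78, tolerance = 3 * 8.71 / sqrt(1000))
  expect_equal(sd(big$meta$AES), 8.71, tolerance = 0.9)

  # the latent structure induces the strong negative FA-RD correlation
  arr <- alongtract:::profiles_to_array(sim$profiles)
  fa_rd <- cor(as.numeric(arr[, , "FA"]), as.numeric(arr[, , "RD"]))
  expect_lt(fa_rd, -0.75)

  expect_error(profile_sim_spec(seed = 1, effects = list(list(pc = 5, nodes = 1:5, d = 1))),
               "latent dimension")
  expect_error(profile_sim_spec(seed = 1, effects = list(list(pc = 1, nodes = 90:110, d = 1))),
               "interval")
  expect_error(profile_sim_spec(), "mandatory")
})
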