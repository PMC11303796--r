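test_that("noise-free single-zeppelin signals are recovered almost exactly", {
  sch <- test_scheme()
  truth <- benchmark_voxel()
  fit <- fit_voxel(predict_signal(truth, sch), sch, 1)
  z <- fit$compartments[[1]]
  zt <- truth$compartments[[1]]
  expect_lt(abs(z$lambda_par - zt$lambda_par) / zt$lambda_par, 0.01)
  expect_lt(abs(z$lambda_perp - zt$lambda_perp) / zt$lambda_perp, 0.01)
  expect_lt(abs(fit$fw_weight - truth$fw_weight) / truth$fw_weight, 0.01)
  expect_lt(alongtract:::axis_angle_deg(z$axis, zt$axis), 2)
  # weight conservation after optimization
  expect_equal(fit$fw_weight + z$weight, 1, tolerance = 1e-9)
})

test_that("pure free-water signals give alpha = 1 with near-zero residual", {
  sch <- test_scheme()
  sig <- predict_signal(mcm_fit(1), sch)
  fit <- fit_voxel(sig, sch, 0)
  expect_identical(fit$fw_weight, 1)
  expect_identical(fit$n_aniso, 0L)
  expect_equal(predict_signal(fit, sch), sig, tolerance = 1e-12)
})

test_that("orthogonal two-fiber crossings are resolved", {
  sch <- test_scheme()
  truth <- mcm_fit(0.1, list(zeppelin(0.45, c(1, 0, 0), 1.7e-3, 0.3e-3),
                             zeppelin(0.45, c(0, 1, 0), 1.7e-3, 0.3e-3)))
  fit <- fit_voxel(predict_signal(truth, sch), sch, 2)
  axes <- lapply(fit$compartments, `[[`, "axis")
  ta <- list(c(1, 0, 0), c(0, 1, 0))
  # best assignment over the two possible pairings
  err <- min(
    max(alongtract:::axis_angle_deg(axes[[1]], ta[[1]]),
        alongtract:::axis_angle_deg(axes[[2]], ta[[2]])),
    max(alongtract:::axis_angle_deg(axes[[1]], ta[[2]]),
        alongtract:::axis_angle_deg(axes[[2]], ta[[1]])))
  expect_lt(err, 5)
  w <- vapply(fit$compartments, `[[`, numeric(1), "weight")
  expect_equal(fit$fw_weight + sum(w), 1, tolerance = 1e-9)
})

test_that("degenerate signals are rejected and shape is validated", {
  sch <- test_scheme()
  expect_error(fit_voxel(rep(0, nrow(sch)), sch, 1), "not all zero")
  expect_error(fit_voxel(c(1, NA, rep(0.5, nrow(sch) - 2)), sch, 1), "finite")
  expect_error(fit_voxel(rep(0.5, 10), sch, 1), "match")
})

test_that("compartment-count selection recovers the generating model", {
  sch <- test_scheme()
  gens <- list(
    mcm_fit(1),
    benchmark_voxel(),
    mcm_fit(0.1, list(zeppelin(0.45, c(1, 0, 0), 1.7e-3, 0.3e-3),
                      zeppelin(0.45, c(0, 1, 0), 1.7e-3, 0.3e-3))),
    mcm_fit(0.1, list(zeppelin(0.3, c(1, 0, 0), 1.7e-3, 0.3e-3),
                      zeppelin(0.3, c(0, 1, 0), 1.7e-3, 0.3e-3),
                      zeppelin(0.3, c(0, 0, 1), 1.7e-3, 0.3e-3)))
  )
  for (k in 0:3) {
    sel <- select_n_aniso(predict_signal(gens[[k + 1]], sch), sch)
    expect_identical(sel$n_aniso, k)
    tab <- attr(sel, "selection")
    expect_identical(nrow(tab), 4L)
    expect_equal(sum(tab$akaike_weight), 1, tolerance = 1e-12)
    # criterion of the generating model is no worse than richer models
    expect_true(all(tab$criterion[tab$n_aniso > k] >= tab$criterion[tab$n_aniso == k]))
  }
})

test_that("selection at moderate noise stays accurate", {
  sch <- test_scheme()
  truth <- benchmark_voxel()
  hits <- vapply(1:50, function(s) {
    sig <- simulate_voxel(truth, sch, snr = 50, seed = s)
    select_n_aniso(sig, sch, fit_config(seed = s))$n_aniso == 1L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("metric averaging across candidates is available", {
  sch <- test_scheme()
  sel <- select_n_aniso(predict_signal(benchmark_voxel(), sch), sch,
                        fit_config(metric_averaging = TRUE))
  avg <- attr(sel, "averaged_metrics")
  expect_false(is.null(avg))
  # noise-free: the selected model dominates the Akaike weights, so the
  # averaged metrics agree with the selected model's metrics
  expect_equal(avg$FW, derive_voxel_metrics(sel)$FW, tolerance = 1e-3)
})

test_that("volume driver fits masked voxels only and flags grids", {
  sch <- test_scheme()
  cfg <- fit_config(max_compartments = 1)
  fib <- benchmark_voxel()
  att <- predict_signal(fib, sch)

  dd <- c(2, 2, 1)
  dwi <- array(rep(100 * att, each = prod(dd)), c(dd, nrow(sch)))
  mask <- array(TRUE, dd)
  out <- fit_volume(dwi, mask, sch, cfg)
  fa <- out$metrics$FA
  expect_true(all(abs(fa - fa[1]) < 1e-6))          # spatially constant
  expect_true(all(out$n_aniso == 1L))

  # CSF half / fiber half
  csf_att <- predict_signal(mcm_fit(1), sch)
  dwi[1, , , ] <- rep(100 * csf_att, each = 2)
  out2 <- fit_volume(dwi, mask, sch, cfg)
  expect_true(all(out2$n_aniso[1, , ] == 0L))
  expect_true(all(out2$n_aniso[2, , ] == 1L))
  expect_true(all(is.na(out2$metrics$FA[1, , ])))

  # empty mask: all-undefined maps, no error
  out3 <- fit_volume(dwi, array(FALSE, dd), sch, cfg)
  expect_true(all(is.na(out3$metrics$FW)))
  expect_length(out3$fits, 0)

  expect_error(fit_volume(dwi, array(TRUE, c(3, 2, 1)), sch, cfg), "grid")
  expect_error(fit_volume(dwi[, , , 1:10, drop = FALSE], mask, sch, cfg),
               "4th dimension")
})
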