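# a straight-line bundle safely inside a 1 mm grid
make_test_setup <- function(jitter = 0.2, n_streamlines = 8, seed = 3) {
  b <- gen_bundle("line", n_streamlines = n_streamlines, jitter_sd = jitter,
                  seed = seed, scale = 30, spread_sd = 0.3,
                  offset = c(4, 5, 5), name = "demo")
  cl <- compute_centroid(b, 20)
  list(bundle = b, centroid = cl, affine = diag(4), dim = c(40, 10, 10))
}

test_that("a constant metric field projects to a constant profile, exactly", {
  st <- make_test_setup()
  vols <- list(FA = array(0.43, st$dim), MD = array(7e-4, st$dim))
  tp <- project_metrics(vols, st$affine, st$bundle, st$centroid)
  covered <- tp$weight_sum > 0
  expect_true(any(covered))
  expect_identical(unique(tp$value[covered & tp$metric == "FA"]), 0.43)
  expect_identical(unique(tp$value[covered & tp$metric == "MD"]), 7e-4)
  expect_true(all(is.na(tp$value[!covered])))
})

test_that("projected point counts are conserved over nodes", {
  st <- make_test_setup()
  vols <- list(FA = array(1, st$dim))
  tp <- project_metrics(vols, st$affine, st$bundle, st$centroid)
  n_total <- sum(vapply(st$bundle$streamlines, nrow, integer(1)))
  fa <- tp[tp$metric == "FA", ]
  expect_identical(sum(fa$n_points) + attr(tp, "n_dropped"), n_total)
  expect_identical(attr(tp, "n_dropped"), 0L)
})

test_that("a gradient field projects to an increasing profile tracking x", {
  st <- make_test_setup()
  xvol <- array(rep(seq_len(st$dim[1]) - 1, prod(st$dim[2:3])), st$dim)
  tp <- project_metrics(list(X = xvol), st$affine, st$bundle, st$centroid)
  v <- tp$value[tp$weight_sum > 0]
  nodes_x <- st$centroid$nodes[tp$weight_sum > 0, 1]
  expect_true(all(diff(v) > 0))
  expect_true(all(abs(v - nodes_x) < 1.5))   # within ~a voxel of the node x
})

test_that("projection equals brute-force nearest-node assignment", {
  st <- make_test_setup(jitter = 0.5, n_streamlines = 20, seed = 9)
  xvol <- array(rep(seq_len(st$dim[1]) - 1, prod(st$dim[2:3])), st$dim)
  tp <- project_metrics(list(X = xvol), st$affine, st$bundle, st$centroid)

  # oracle: per-point loop, no vectorized index
  pts <- do.call(rbind, st$bundle$streamlines)
  s <- nrow(st$centroid$nodes)
  h <- st$centroid$spacing
  num <- den <- cnt <- rep(0, s)
  for (i in seq_len(nrow(pts))) {
    ijk <- round(pts[i, ] + 1)           # identity affine, 1-based
    if (any(ijk < 1) || any(ijk > st$dim)) next
    val <- xvol[ijk[1], ijk[2], ijk[3]]
    d <- sqrt(colSums((t(st$centroid$nodes) - pts[i, ])^2))
    j <- which.min(d)
    w <- 1 / (1 + d[j] / h)
    num[j] <- num[j] + w * val
    den[j] <- den[j] + w
    cnt[j] <- cnt[j] + 1
  }
  oracle <- ifelse(den > 0, num / den, NA_real_)
  expect_equal(tp$value, oracle, tolerance = 1e-10)
  expect_equal(tp$n_points, as.integer(cnt))
})

test_that("out-of-bounds points are dropped, all-out errors", {
  st <- make_test_setup()
  vols <- list(FA = array(1, c(10, 10, 10)))  # bundle extends past x = 10
  tp <- project_metrics(vols, st$affine, st$bundle, st$centroid)
  expect_gt(attr(tp, "n_dropped"), 0)

  far <- bundle("far", lapply(st$bundle$streamlines, function(p) {
    sweep(p, 2, c(1000, 0, 0), `+`)
  }))
  expect_error(project_metrics(vols, st$affine, far, st$centroid), "outside")
})

test_that("gaussian kernel and trilinear lookup are accepted options", {
  st <- make_test_setup()
  vols <- list(FA = array(0.5, st$dim))
  tp <- project_metrics(vols, st$affine, st$bundle, st$centroid,
                        projection_config(kernel = "gaussian",
                                          lookup = "trilinear"))
  covered <- tp$weight_sum > 0
  expect_true(all(abs(tp$value[covered] - 0.5) < 1e-9))
})

test_that("subject profile builder filters small bundles and stacks the rest", {
  st <- make_test_setup()
  vols <- list(FA = array(0.5, st$dim), FW = array(0.1, st$dim))
  small <- bundle("tiny", st$bundle$streamlines[1:2])
  expect_warning(
    out <- build_subject_profiles(vols, st$affine, list(st$bundle, small),
                                  subject_id = "s001", s = 20),
    "skipped")
  expect_identical(unique(out$bundle), "demo")
  expect_identical(unique(out$subject), "s001")
  expect_identical(nrow(out), 2L * 20L)
  expect_error(
    suppressWarnings(build_subject_profiles(vols, st$affine, list(small), "s001")),
    "filter")
})
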