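#' Generate a multi-shell cube-and-sphere gradient scheme
#'
#' Emulates a CUSP-style acquisition: half of the gradients sit on the unit
#' sphere at the lowest b-value (spread with a Fibonacci spiral), the other
#' half on the surface of a cube (vertices, edge midpoints, face centers,
#' then seeded random surface points), whose squared radius maps the
#' b-value from `b_range[1]` (face centers) up to `b_range[2]` (vertices).
#'
#' @param n_grad Number of diffusion-weighted gradients (>= 6).
#' @param b_range Length-2 vector, increasing, s/mm^2.
#' @param n_b0 Number of b = 0 entries (>= 1, leading rows).
#' @param seed Integer seed (used for the random cube points).
#' @return A [gradient_scheme()] with `n_grad + n_b0` rows.
#' @export
gen_scheme <- function(n_grad = 60, b_range = c(1000, 3000), n_b0 = 1,
                       seed = 1) {
  if (n_grad < 6) stop("need at least 6 gradients", call. = FALSE)
  if (b_range[1] >= b_range[2]) stop("`b_range` must be increasing", call. = FALSE)
  if (n_b0 < 1) stop("a scheme needs at least one b0 (n_b0 >= 1)", call. = FALSE)

  n_sph <- floor(n_grad / 2)
  i <- seq_len(n_sph)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - (2 * i - 1) / n_sph
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- golden * (i - 1)
  sphere <- cbind(r * cos(phi), r * sin(phi), z)

  verts <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  edges <- unique(do.call(rbind, lapply(1:3, function(ax) {
    g <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
    m <- matrix(0, nrow(g), 3)
    m[, -ax] <- g
    m
  })))
  faces <- rbind(diag(3), -diag(3))
  cube_fixed <- rbind(verts, edges, faces)

  n_cube <- n_grad - n_sph
  if (n_cube <= nrow(cube_fixed)) {
    cube <- cube_fixed[seq_len(n_cube), , drop = FALSE]
  } else {
    rng <- make_rng(seed, 11L)
    extra <- n_cube - nrow(cube_fixed)
    pts <- matrix(rng$runif(3 * extra, -1, 1), extra, 3)
    ax <- rng$sample_int(3, extra, replace = TRUE)
    sgn <- 2 * rng$rbinom(extra, 1, 0.5) - 1
    pts[cbind(seq_len(extra), ax)] <- sgn
    cube <- rbind(cube_fixed, pts)
  }
  r2 <- rowSums(cube^2)
  b_cube <- b_range[1] + (r2 - 1) / 2 * (b_range[2] - b_range[1])
  dirs_cube <- cube / sqrt(r2)

  bval <- c(rep(0, n_b0), rep(b_range[1], n_sph), b_cube)
  dirs <- rbind(matrix(0, n_b0, 3), sphere, dirs_cube)
  gradient_scheme(bval, dirs)
}

#' Simulate a noisy voxel signal
#'
#' Forward-models the attenuation with [predict_signal()] and corrupts it
#' with Rician noise: the magnitude of a complex Gaussian perturbation with
#' `sigma = b0 amplitude / snr` (the attenuation scale has b0 amplitude 1).
#' `snr = Inf` returns the noise-free attenuation. A `"gaussian"` noise
#' model is available for fast tests.
#'
#' @param fit An [mcm_fit()] ground truth.
#' @param scheme A [gradient_scheme()].
#' @param snr Signal-to-noise ratio at b0 (> 0, or `Inf`).
#' @param seed Integer seed.
#' @param noise `"rician"` (default) or `"gaussian"`.
#' @return Attenuation-scale signal vector.
#' @export
simulate_voxel <- function(fit, scheme, snr = Inf, seed = 1,
                           noise = c("rician", "gaussian")) {
  noise <- match.arg(noise)
  att <- predict_signal(fit, scheme)
  if (!is.finite(snr)) return(att)
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  rng <- make_rng(seed, 13L)
  sigma <- 1 / snr
  n <- length(att)
  if (noise == "gaussian") return(att + sigma * rng$rnorm(n))
  sqrt((att + sigma * rng$rnorm(n))^2 + (sigma * rng$rnorm(n))^2)
}

#' Phantom specification and generation
#'
#' A phantom is a small voxel grid with disjoint regions, each carrying a
#' ground-truth mixture fit; [gen_phantom()] simulates the 4-D signal
#' (Rician noise referenced to the b0 amplitude) and emits the ground-truth
#' metric maps for recovery scoring.
#'
#' @param dim Grid dimensions, length 3.
#' @param voxel_size Voxel edge lengths in mm.
#' @param regions List of `list(mask = <3-D logical array>, fit =
#'   <mcm_fit>)`; masks must be pairwise disjoint.
#' @param snr SNR at b0 (`Inf` for noise-free).
#' @param seed Integer seed.
#' @return `phantom_spec()`: a spec object. `gen_phantom()`: list with
#'   `dwi` (4-D array), `mask` (union of regions), `truth` (list: metric
#'   maps `FW, FA, MD, AD, RD` and `n_aniso`), `affine`, `scheme`, `spec`.
#' @export
phantom_spec <- function(dim = c(4, 4, 1), voxel_size = c(2, 2, 2),
                         regions = list(), snr = 30, seed = 1) {
  stopifnot(length(dim) == 3, snr > 0)
  cover <- array(0L, dim)
  for (r in regions) {
    stopifnot(identical(dim(r$mask), as.integer(dim)) || identical(dim(r$mask), dim),
              inherits(r$fit, "mcm_fit"))
    cover <- cover + as.integer(r$mask)
  }
  if (any(cover > 1)) stop("phantom regions overlap", call. = FALSE)
  structure(list(dim = dim, voxel_size = voxel_size, regions = regions,
                 snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param spec A `phantom_spec`.
#' @param scheme A [gradient_scheme()].
#' @export
gen_phantom <- function(spec, scheme) {
  stopifnot(inherits(spec, "phantom_spec"))
  dd <- spec$dim
  ng <- nrow(scheme)
  s0 <- 100
  dwi <- array(0, c(dd, ng))
  mask <- array(FALSE, dd)
  metric_names <- c("FW", "FA", "MD", "AD", "RD")
  truth <- lapply(metric_names, function(m) array(NA_real_, dd))
  names(truth) <- metric_names
  truth$n_aniso <- array(NA_integer_, dd)

  flat <- matrix(dwi, prod(dd), ng)
  for (r in spec$regions) {
    att <- predict_signal(r$fit, scheme)
    met <- derive_voxel_metrics(r$fit)
    idx <- which(r$mask)
    flat[idx, ] <- matrix(s0 * att, length(idx), ng, byrow = TRUE)
    mask[idx] <- TRUE
    for (m in metric_names) truth[[m]][idx] <- met[[m]]
    truth$n_aniso[idx] <- r$fit$n_aniso
  }
  if (is.finite(spec$snr)) {
    rng <- make_rng(spec$seed, 17L)
    sigma <- s0 / spec$snr
    n <- length(flat)
    flat <- sqrt((flat + sigma * rng$rnorm(n))^2 + (sigma * rng$rnorm(n))^2)
  }
  affine <- diag(c(spec$voxel_size, 1))
  list(dwi = array(flat, c(dd, ng)), mask = mask, truth = truth,
       affine = affine, scheme = scheme, spec = spec)
}

#' Generate a geometric streamline bundle
#'
#' Streamlines are a base curve (straight line, circular arc, or helix)
#' plus a constant per-streamline offset (bundle spread) and pointwise
#' Gaussian jitter; everything is deterministic under the seed.
#'
#' @param kind `"line"`, `"arc"` (quarter circle) or `"helix"`.
#' @param n_streamlines Number of streamlines (>= 1).
#' @param jitter_sd Pointwise Gaussian jitter SD, mm.
#' @param seed Integer seed.
#' @param n_points Points per streamline.
#' @param scale Overall size, mm (line length / arc and helix radius).
#' @param spread_sd SD of the constant per-streamline offset, mm.
#' @param offset Translation applied to the whole bundle.
#' @param name Bundle label.
#' @return A [bundle()].
#' @export
gen_bundle <- function(kind = c("line", "arc", "helix"), n_streamlines = 20,
                       jitter_sd = 0.5, seed = 1, n_points = 50, scale = 40,
                       spread_sd = 1, offset = c(0, 0, 0), name = kind[1]) {
  kind <- match.arg(kind)
  stopifnot(n_streamlines >= 1)
  t <- seq(0, 1, length.out = n_points)
  base <- switch(kind,
                 line = cbind(scale * t, 0, 0),
                 arc = cbind(scale * cos(pi / 2 * t), scale * sin(pi / 2 * t), 0),
                 helix = cbind(scale / 2 * cos(3 * pi * t),
                               scale / 2 * sin(3 * pi * t), scale * t))
  rng <- make_rng(seed, 19L)
  sl <- lapply(seq_len(n_streamlines), function(i) {
    off <- rng$rnorm(3, 0, spread_sd)
    jit <- matrix(rng$rnorm(3 * n_points, 0, jitter_sd), n_points, 3)
    sweep(base + jit, 2, off + offset, `+`)
  })
  bundle(name, sl)
}

#' Specification of a synthetic group bundle-profile dataset
#'
#' Describes a subjects x nodes x metrics dataset with realistic
#' inter-metric correlation (shared latent factors), node-smooth variation,
#' covariate effects, and optional planted group shifts and clinical-score
#' associations. The defaults mirror an elderly two-center case-control
#' cohort: 21 + 35 subjects, 100 nodes, 5 metrics (FW, FA, MD, AD, RD)
#' driven by two latent factors whose loadings induce a strong negative
#' FA-RD correlation (about -0.8), age 75 +/- 6 years, and an apathy score
#' of 41.78 +/- 8.71.
#'
#' @param n_group1,n_group2 Group sizes (group 1 = `"HC"`, group 2 =
#'   `"LLD"`).
#' @param n_nodes Nodes per profile.
#' @param loadings Metrics x factors loading matrix (rownames = metrics).
#' @param noise_sd Per-metric residual SD (recycled).
#' @param smooth_width Moving-average width (nodes) of the latent factors.
#' @param effects List of planted group effects, each
#'   `list(pc =, nodes =, d =)`: factor `pc` of group 2 is shifted by `d`
#'   factor-SDs on the node interval.
#' @param aes_effects List of planted score associations, each
#'   `list(pc =, nodes =, slope =)`: the score gains
#'   `slope * mean(factor over the interval)`.
#' @param age_mean,age_sd,p_female,p_center2 Covariate model.
#' @param age_slopes Per-factor slope of age (centered) on the factor.
#' @param aes_mean,aes_sd Clinical score base distribution.
#' @param seed Integer seed (mandatory).
#' @return A list of class `profile_sim_spec`.
#' @export
profile_sim_spec <- function(n_group1 = 21, n_group2 = 35, n_nodes = 100,
                             loadings = default_loadings(),
                             noise_sd = c(FW = 0.6, FA = 0.3, MD = 0.4,
                                          AD = 0.45, RD = 0.3),
                             smooth_width = 5,
                             effects = list(), aes_effects = list(),
                             age_mean = 75, age_sd = 6, p_female = 0.75,
                             p_center2 = 0.5,
                             age_slopes = c(0.02, 0),
                             aes_mean = 41.78, aes_sd = 8.71,
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  loadings <- as.matrix(loadings)
  K <- ncol(loadings)
  noise_sd <- rep_len(noise_sd, nrow(loadings))
  if (any(noise_sd <= 0)) stop("noise SDs must be positive", call. = FALSE)
  for (e in c(effects, aes_effects)) {
    if (e$pc > K) stop("planted effect on a factor beyond the latent dimension",
                       call. = FALSE)
    if (min(e$nodes) < 1 || max(e$nodes) > n_nodes) {
      stop("effect interval outside [1, n_nodes]", call. = FALSE)
    }
  }
  structure(list(n_group1 = n_group1, n_group2 = n_group2, n_nodes = n_nodes,
                 loadings = loadings, noise_sd = noise_sd,
                 smooth_width = smooth_width, effects = effects,
                 aes_effects = aes_effects, age_mean = age_mean,
                 age_sd = age_sd, p_female = p_female, p_center2 = p_center2,
                 age_slopes = rep_len(age_slopes, K),
                 aes_mean = aes_mean, aes_sd = aes_sd,
                 seed = as.integer(seed)),
            class = "profile_sim_spec")
}

#' @rdname profile_sim_spec
#' @export
default_loadings <- function() {
  matrix(c(0.65, 0.00,
           -0.90, 0.25,
           0.30, 0.75,
           0.10, 0.80,
           0.85, 0.15),
         nrow = 5, byrow = TRUE,
         dimnames = list(c("FW", "FA", "MD", "AD", "RD"), c("f1", "f2")))
}

# node-smooth unit-variance random field, n x nodes
smooth_field <- function(rng, n, nodes, width) {
  pad <- width
  raw <- matrix(rng$rnorm(n * (nodes + 2 * pad)), n, nodes + 2 * pad)
  kern <- rep(1 / width, width)
  sm <- t(apply(raw, 1, function(x) {
    stats::filter(x, kern, sides = 2)
  }))
  sm <- sm[, (pad + 1):(pad + nodes), drop = FALSE]
  sm * sqrt(width)                       # restore unit marginal variance
}

#' Generate a synthetic group bundle-profile dataset
#'
#' Builds the profiles as `loadings x latent node-smooth factors +
#' covariate effects + noise`, applies the planted effects of the spec and
#' returns the long profile tibble, the subject metadata and the ground
#' truth (per-node effect mask).
#'
#' @param spec A [profile_sim_spec()].
#' @param bundle_name Bundle label written into the profiles.
#' @return List: `profiles` (tibble `subject, bundle, metric, node, value`),
#'   `meta` (tibble `subject, group, age, sex, center, AES`), `truth`
#'   (list: `effect_nodes` logical per node, `aes_nodes`, spec echo).
#' @export
gen_profiles <- function(spec, bundle_name = "SYN") {
  stopifnot(inherits(spec, "profile_sim_spec"))
  n <- spec$n_group1 + spec$n_group2
  nodes <- spec$n_nodes
  metrics <- rownames(spec$loadings)
  K <- ncol(spec$loadings)
  rng <- make_rng(spec$seed, 23L)

  group <- c(rep("HC", spec$n_group1), rep("LLD", spec$n_group2))
  age <- spec$age_mean + spec$age_sd * rng$rnorm(n)
  sex <- ifelse(rng$runif(n) < spec$p_female, "F", "M")
  center <- ifelse(rng$runif(n) < spec$p_center2, "B", "A")

  fac <- lapply(seq_len(K), function(k) {
    f <- smooth_field(rng, n, nodes, spec$smooth_width)
    f + spec$age_slopes[k] * (age - spec$age_mean)
  })
  for (e in spec$effects) {
    fac[[e$pc]][group == "LLD", e$nodes] <-
      fac[[e$pc]][group == "LLD", e$nodes] + e$d
  }

  aes <- spec$aes_mean + spec$aes_sd * rng$rnorm(n)
  for (e in spec$aes_effects) {
    aes <- aes + e$slope * rowMeans(fac[[e$pc]][, e$nodes, drop = FALSE])
  }

  arr <- array(NA_real_, c(n, nodes, length(metrics)))
  for (m in seq_along(metrics)) {
    y <- matrix(spec$noise_sd[m] * rng$rnorm(n * nodes), n, nodes)
    for (k in seq_len(K)) y <- y + spec$loadings[m, k] * fac[[k]]
    arr[, , m] <- y
  }

  subjects <- sprintf("s%03d", seq_len(n))
  profiles <- tidyr::expand_grid(metric = metrics, node = seq_len(nodes),
                                 subject = subjects)
  # fill in array order: [subject fastest] -> rearrange via indices
  profiles$value <- arr[cbind(match(profiles$subject, subjects),
                              profiles$node,
                              match(profiles$metric, metrics))]
  profiles <- tibble::add_column(profiles, bundle = bundle_name, .after = "subject")
  profiles <- profiles[, c("subject", "bundle", "metric", "node", "value")]
  profiles <- dplyr::arrange(profiles, .data$subject, .data$metric, .data$node)

  effect_nodes <- rep(FALSE, nodes)
  for (e in spec$effects) effect_nodes[e$nodes] <- TRUE
  aes_nodes <- rep(FALSE, nodes)
  for (e in spec$aes_effects) aes_nodes[e$nodes] <- TRUE

  list(profiles = profiles,
       meta = tibble::tibble(subject = subjects, group = group, age = age,
                             sex = sex, center = center, AES = aes),
       truth = list(effect_nodes = effect_nodes, aes_nodes = aes_nodes,
                    spec = spec))
}
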