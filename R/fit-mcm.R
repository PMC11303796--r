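#' Fitting configuration
#'
#' Bundles the tunable parameters of the per-voxel model fit.
#'
#' @param d_iso Fixed free-water diffusivity, mm^2/s.
#' @param lambda_par_min,lambda_par_max Bounds on the axial diffusivity,
#'   mm^2/s (physiological range).
#' @param lambda_perp_min Lower bound on the transverse diffusivity, mm^2/s;
#'   the upper bound is always `lambda_par`.
#' @param n_starts Number of multi-start initializations per candidate model.
#' @param max_compartments Largest number of zeppelins tried by
#'   [select_n_aniso()].
#' @param seed Integer seed controlling the random restarts.
#' @param metric_averaging If `TRUE`, [select_n_aniso()] also reports
#'   Akaike-weight-averaged metrics across the candidate models instead of
#'   only the selected model's metrics.
#' @param noise_floor If `TRUE` (default), the fitted magnitude model is
#'   `sqrt(S^2 + 2 sigma_n^2)` with one shared non-negative floor parameter
#'   `sigma_n`, matching the second moment of Rician-distributed magnitudes.
#'   Without it, the Rician bias at high b-values is absorbed by spurious
#'   extra compartments, corrupting model selection.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(d_iso = 3.0e-3,
                       lambda_par_min = 0.1e-3, lambda_par_max = 3.0e-3,
                       lambda_perp_min = 0.01e-3,
                       n_starts = 5, max_compartments = 3, seed = 1L,
                       metric_averaging = FALSE, noise_floor = TRUE) {
  stopifnot(lambda_par_min > 0, lambda_par_max > lambda_par_min,
            lambda_perp_min > 0, n_starts >= 1,
            max_compartments %in% 0:3)
  structure(list(d_iso = d_iso,
                 lambda_par_min = lambda_par_min,
                 lambda_par_max = lambda_par_max,
                 lambda_perp_min = lambda_perp_min,
                 n_starts = n_starts, max_compartments = max_compartments,
                 seed = as.integer(seed),
                 metric_averaging = isTRUE(metric_averaging),
                 noise_floor = isTRUE(noise_floor)),
            class = "fit_config")
}

# Gaussian ML on attenuations: the concentrated log-likelihood given RSS.
# The variance estimate is floored at (1e-6)^2 attenuation units so that on
# noise-free signals (where the achievable RSS is set by optimizer tolerance,
# not by data) the likelihood of nested models saturates instead of
# diverging, and the parameter penalty decides the comparison.
gaussian_loglik <- function(rss, n) {
  sig2 <- max(rss / n, 1e-12)
  -n / 2 * (log(2 * pi * sig2) + 1)
}

aicc <- function(loglik, k, n) {
  -2 * loglik + 2 * k + if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
}

n_free_params <- function(n_aniso, noise_floor = TRUE) {
  (if (n_aniso == 0) 0L else n_aniso + 4L * n_aniso) + as.integer(noise_floor)
}

# params (n_aniso >= 1), all box-bounded for nlminb:
#   [w_1..w_N]           weight logits, softmax over (0, w_1..w_N); alpha = first
#   per compartment:     theta, phi (axis spherical angles),
#                        dpar (lambda_par * 1e3, in [0.1, 3]),
#                        f    (lambda_perp = perp_min + f * (lambda_par - perp_min))
unpack_params <- function(par, n_aniso, config) {
  w <- c(0, par[seq_len(n_aniso)])
  w <- exp(w - max(w)); w <- w / sum(w)
  comps <- vector("list", n_aniso)
  for (j in seq_len(n_aniso)) {
    p <- par[n_aniso + 4 * (j - 1) + 1:4]
    theta <- p[1]; phi <- p[2]
    axis <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    lpar <- p[3] * 1e-3
    lperp <- config$lambda_perp_min + p[4] * (lpar - config$lambda_perp_min)
    comps[[j]] <- list(weight = w[j + 1], axis = axis,
                       lambda_par = lpar, lambda_perp = max(lperp, config$lambda_perp_min))
  }
  list(alpha = w[1], comps = comps)
}

predict_from_params <- function(par, n_aniso, b, g, config) {
  u <- unpack_params(par, n_aniso, config)
  att <- u$alpha * exp(-b * config$d_iso)
  for (z in u$comps) {
    proj2 <- as.numeric(g %*% z$axis)^2
    adc <- z$lambda_perp + (z$lambda_par - z$lambda_perp) * proj2
    att <- att + z$weight * exp(-b * adc)
  }
  att[b == 0] <- 1
  att
}

# candidate fiber orientations from the data: directions of largest apparent
# diffusivity at the highest shell, thinned to be pairwise > 25 degrees apart
seed_axes <- function(signal, scheme, n_needed) {
  b <- scheme$bval
  g <- scheme_directions(scheme)
  dwi <- b > 0
  adc <- rep(0, length(b))
  s <- pmin(pmax(signal, 1e-6), 1)
  adc[dwi] <- -log(s[dwi]) / b[dwi]
  ord <- order(-adc)
  picked <- matrix(0, 0, 3)
  for (i in ord) {
    if (!dwi[i]) next
    v <- g[i, ]
    if (nrow(picked) == 0 ||
        all(abs(picked %*% v) < cos(25 * pi / 180))) {
      picked <- rbind(picked, v)
    }
    if (nrow(picked) >= n_needed) break
  }
  while (nrow(picked) < n_needed) picked <- rbind(picked, c(0, 0, 1))
  picked
}

axis_to_angles <- function(v) {
  v <- v / sqrt(sum(v^2))
  c(acos(pmin(pmax(v[3], -1), 1)), atan2(v[2], v[1]))
}

#' Fit the free-water + zeppelin mixture to one voxel
#'
#' Maximum-likelihood fit (Gaussian noise on attenuations, so ML reduces to
#' least squares) of a mixture with one fixed-diffusivity free-water
#' compartment and `n_aniso` zeppelins, by bounded local optimization
#' ([stats::nlminb()]) with multi-start initialization: axes seeded from the
#' directions of strongest signal attenuation plus seeded random draws.
#' Weights are parameterized through a softmax so they always lie on the
#' simplex.
#'
#' @param signal Attenuation vector (values of S/S0), one per scheme row.
#' @param scheme A [gradient_scheme()].
#' @param n_aniso Number of zeppelin compartments to fit (0 to 3).
#' @param config A [fit_config()].
#' @return An [mcm_fit()] whose `loglik` is the achieved Gaussian
#'   log-likelihood and `criterion` the AICc; `converged` reports the best
#'   start's optimizer status (the best iterate is returned regardless).
#' @export
fit_voxel <- function(signal, scheme, n_aniso, config = fit_config()) {
  signal <- as.numeric(signal)
  if (length(signal) != nrow(scheme)) {
    stop("signal length must match the scheme", call. = FALSE)
  }
  if (any(!is.finite(signal)) || all(signal == 0)) {
    stop("signal must be finite and not all zero", call. = FALSE)
  }
  stopifnot(n_aniso %in% 0:3)
  n <- length(signal)
  b <- scheme$bval
  g <- scheme_directions(scheme)

  nf <- config$noise_floor
  with_floor <- function(pred, sn) if (nf) sqrt(pred^2 + 2 * sn^2) else pred

  if (n_aniso == 0) {
    pred <- exp(-b * config$d_iso); pred[b == 0] <- 1
    rss <- sum((signal - pred)^2)
    if (nf) {
      opt <- stats::optimize(function(sn) sum((signal - with_floor(pred, sn))^2),
                             c(0, 0.5), tol = 1e-10)
      rss <- min(rss, opt$objective)    # sn = 0 is on the boundary
    }
    ll <- gaussian_loglik(rss, n)
    return(mcm_fit(1, list(), d_iso = config$d_iso, loglik = ll,
                   criterion = aicc(ll, n_free_params(0L, nf) + 1L, n)))
  }

  objective <- function(par) {
    np <- length(par)
    sn <- if (nf) par[np] else 0
    pp <- if (nf) par[-np] else par
    r <- signal - with_floor(predict_from_params(pp, n_aniso, b, g, config), sn)
    sum(r * r)
  }

  lower <- c(rep(-15, n_aniso),
             rep(c(-10, -10, config$lambda_par_min * 1e3, 0), n_aniso),
             if (nf) 0)
  upper <- c(rep(15, n_aniso),
             rep(c(10, 10, config$lambda_par_max * 1e3, 1), n_aniso),
             if (nf) 0.5)

  data_axes <- seed_axes(signal, scheme, n_aniso)
  rng <- make_rng(config$seed, 101L + n_aniso)
  f0 <- (0.3e-3 - config$lambda_perp_min) / (1.7e-3 - config$lambda_perp_min)

  best <- NULL
  for (s in seq_len(config$n_starts)) {
    if (s == 1) {
      axes <- data_axes
      lpar0 <- rep(1.7, n_aniso); ff <- rep(f0, n_aniso)
    } else {
      axes <- matrix(rng$rnorm(3 * n_aniso), n_aniso, 3)
      axes <- axes / sqrt(rowSums(axes^2))
      lpar0 <- rng$runif(n_aniso, 0.8, 2.5)
      ff <- rng$runif(n_aniso, 0.05, 0.6)
    }
    ang <- t(apply(axes, 1, axis_to_angles))
    par0 <- c(rep(0.7, n_aniso),
              as.numeric(t(cbind(ang, lpar0, ff))),
              if (nf) 0.01)
    opt <- stats::nlminb(par0, objective, lower = lower, upper = upper,
                         control = list(iter.max = 500, eval.max = 1500,
                                        rel.tol = 1e-12, x.tol = 1e-10))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }

  u <- unpack_params(if (nf) best$par[-length(best$par)] else best$par,
                     n_aniso, config)
  comps <- lapply(u$comps, function(z) {
    zeppelin(z$weight, z$axis, z$lambda_par, z$lambda_perp)
  })
  # guard against float drift in the softmax weights
  wsum <- u$alpha + sum(vapply(comps, `[[`, numeric(1), "weight"))
  alpha <- u$alpha + (1 - wsum)
  ll <- gaussian_loglik(best$objective, n)
  k <- n_free_params(n_aniso, nf) + 1L
  mcm_fit(alpha, comps, d_iso = config$d_iso, loglik = ll,
          criterion = aicc(ll, k, n),
          converged = best$convergence == 0)
}

#' Select the number of anisotropic compartments for a voxel
#'
#' Fits all candidate models (0 to `max_compartments` zeppelins), scores
#' each with AICc, converts the criteria to Akaike weights and returns the
#' highest-weight model. Ties are broken by lower criterion, then by the
#' smaller compartment count. The full candidate table is attached as the
#' `"selection"` attribute for audit.
#'
#' @inheritParams fit_voxel
#' @return The selected [mcm_fit()]; `attr(, "selection")` is a tibble with
#'   one row per candidate (`n_aniso, loglik, criterion, akaike_weight,
#'   converged`), and with `config$metric_averaging` the attribute
#'   `"averaged_metrics"` holds the Akaike-weight-averaged voxel metrics.
#' @export
select_n_aniso <- function(signal, scheme, config = fit_config()) {
  cands <- lapply(0:config$max_compartments, function(k) {
    fit_voxel(signal, scheme, k, config)
  })
  crit <- vapply(cands, `[[`, numeric(1), "criterion")
  delta <- crit - min(crit)
  aw <- exp(-0.5 * delta); aw <- aw / sum(aw)
  ord <- order(-aw, crit, seq_along(cands))
  chosen <- cands[[ord[1]]]
  tab <- tibble::tibble(
    n_aniso = 0:config$max_compartments,
    loglik = vapply(cands, `[[`, numeric(1), "loglik"),
    criterion = crit,
    akaike_weight = aw,
    converged = vapply(cands, `[[`, logical(1), "converged")
  )
  attr(chosen, "selection") <- tab
  if (config$metric_averaging) {
    mets <- dplyr::bind_rows(lapply(cands, derive_voxel_metrics))
    avg <- lapply(c("FW", "FA", "MD", "AD", "RD"), function(m) {
      v <- mets[[m]]
      ok <- !is.na(v)
      if (!any(ok)) return(NA_real_)
      sum(v[ok] * aw[ok]) / sum(aw[ok])
    })
    names(avg) <- c("FW", "FA", "MD", "AD", "RD")
    attr(chosen, "averaged_metrics") <- tibble::as_tibble(avg)
  }
  chosen
}

#' Fit the mixture model over a masked volume
#'
#' Per-voxel driver: normalizes the 4-D signal by its mean b0, runs
#' [select_n_aniso()] in every voxel inside the mask and assembles scalar
#' metric maps.
#'
#' @param dwi 4-D numeric array (x, y, z, gradient).
#' @param mask 3-D logical (or 0/1) array on the same grid.
#' @param scheme A [gradient_scheme()] matching the 4th dimension.
#' @param config A [fit_config()].
#' @return A list with `metrics` (named list of 3-D arrays `FW, FA, MD, AD,
#'   RD`, `NA` outside the mask), `n_aniso` (3-D integer array, `NA`
#'   outside the mask) and `fits` (list of per-voxel [mcm_fit()]s, named by
#'   linear voxel index).
#' @export
fit_volume <- function(dwi, mask, scheme, config = fit_config()) {
  dd <- dim(dwi)
  if (length(dd) != 4) stop("`dwi` must be a 4-D array", call. = FALSE)
  if (!identical(dim(mask), dd[1:3])) {
    stop("`mask` grid does not match `dwi`", call. = FALSE)
  }
  if (dd[4] != nrow(scheme)) {
    stop("scheme length does not match the 4th dimension of `dwi`", call. = FALSE)
  }
  mask <- array(as.logical(mask), dim = dd[1:3])
  metric_names <- c("FW", "FA", "MD", "AD", "RD")
  maps <- lapply(metric_names, function(m) array(NA_real_, dd[1:3]))
  names(maps) <- metric_names
  nmap <- array(NA_integer_, dd[1:3])
  fits <- list()

  idx <- which(mask)
  b0 <- scheme$bval == 0
  flat <- matrix(dwi, prod(dd[1:3]), dd[4])
  for (i in idx) {
    sig <- flat[i, ]
    s0 <- mean(sig[b0])
    if (!is.finite(s0) || s0 <= 0) next
    att <- sig / s0
    fit <- select_n_aniso(att, scheme, config)
    met <- derive_voxel_metrics(fit)
    for (m in metric_names) maps[[m]][i] <- met[[m]]
    nmap[i] <- fit$n_aniso
    fits[[as.character(i)]] <- fit
  }
  list(metrics = maps, n_aniso = nmap, fits = fits)
}
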