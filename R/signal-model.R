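#' Zeppelin compartment
#'
#' An axially symmetric diffusion tensor (eigenvalues lambda_par,
#' lambda_perp, lambda_perp) with a weight and an orientation. The axis is
#' antipodally symmetric; it is stored with a non-negative z component
#' (canonical sign) so fits are comparable and tests deterministic.
#'
#' @param weight Compartment weight in \[0, 1\].
#' @param axis Unit 3-vector (tolerance 1e-6); sign canonicalized.
#' @param lambda_par Axial diffusivity in mm^2/s.
#' @param lambda_perp Transverse diffusivity in mm^2/s,
#'   `0 < lambda_perp <= lambda_par`.
#' @return A list of class `zeppelin`.
#' @export
zeppelin <- function(weight, axis, lambda_par, lambda_perp) {
  axis <- as.numeric(axis)
  if (length(axis) != 3 || abs(sqrt(sum(axis^2)) - 1) > 1e-6) {
    stop("zeppelin axis must be a unit 3-vector", call. = FALSE)
  }
  if (!(lambda_perp > 0 && lambda_perp <= lambda_par)) {
    stop("need 0 < lambda_perp <= lambda_par", call. = FALSE)
  }
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]", call. = FALSE)
  axis <- canonical_axis(axis)
  structure(list(weight = weight, axis = axis,
                 lambda_par = lambda_par, lambda_perp = lambda_perp),
            class = "zeppelin")
}

canonical_axis <- function(axis) {
  flip <- axis[3] < 0 ||
    (axis[3] == 0 && (axis[2] < 0 || (axis[2] == 0 && axis[1] < 0)))
  if (flip) -axis else axis
}

#' Multi-compartment model fit for one voxel
#'
#' One isotropic free-water compartment (fixed diffusivity `d_iso`) plus
#' 0 to 3 zeppelin compartments. Weights, including the free-water weight,
#' sum to one (tolerance 1e-9). Compartments are stored in descending
#' weight order.
#'
#' @param fw_weight Free-water weight in \[0, 1\].
#' @param compartments List of [zeppelin()] objects (0 to 3).
#' @param d_iso Free-water diffusivity, mm^2/s. Default 3.0e-3
#'   (body-temperature CSF).
#' @param loglik,criterion Optional fit diagnostics (Gaussian log-likelihood
#'   and the information-criterion value used for model selection).
#' @param converged Logical optimizer flag.
#' @return A list of class `mcm_fit`.
#' @examples
#' mcm_fit(0.2, list(zeppelin(0.8, c(1, 0, 0), 1.7e-3, 0.3e-3)))
#' @export
mcm_fit <- function(fw_weight, compartments = list(), d_iso = 3.0e-3,
                    loglik = NA_real_, criterion = NA_real_, converged = TRUE) {
  n_aniso <- length(compartments)
  if (n_aniso > 3) stop("at most 3 anisotropic compartments", call. = FALSE)
  ok <- vapply(compartments, inherits, logical(1), what = "zeppelin")
  if (!all(ok)) stop("`compartments` must be a list of zeppelin objects", call. = FALSE)
  w <- fw_weight + sum(vapply(compartments, `[[`, numeric(1), "weight"))
  if (abs(w - 1) > 1e-9) {
    stop(sprintf("compartment weights must sum to 1 (got %.12f)", w), call. = FALSE)
  }
  if (n_aniso > 1) {
    betas <- vapply(compartments, `[[`, numeric(1), "weight")
    compartments <- compartments[order(-betas)]
  }
  structure(list(fw_weight = fw_weight, d_iso = d_iso,
                 compartments = compartments, n_aniso = n_aniso,
                 loglik = loglik, criterion = criterion, converged = converged),
            class = "mcm_fit")
}

#' @export
print.mcm_fit <- function(x, ...) {
  cat(sprintf("<mcm_fit: FW = %.3f, %d zeppelin(s)%s>\n", x$fw_weight, x$n_aniso,
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  for (z in x$compartments) {
    cat(sprintf("  beta = %.3f  axis = (%+.3f, %+.3f, %+.3f)  l_par = %.2e  l_perp = %.2e\n",
                z$weight, z$axis[1], z$axis[2], z$axis[3], z$lambda_par, z$lambda_perp))
  }
  invisible(x)
}

#' Predict signal attenuation for a fit
#'
#' Evaluates the mixture attenuation
#' `S(b, g) / S0 = alpha * exp(-b * d_iso) + sum_j beta_j * exp(-b * g' D_j g)`
#' where `D_j` is the zeppelin tensor of compartment `j`, so that
#' `g' D_j g = lambda_perp + (lambda_par - lambda_perp) * (g . axis)^2`.
#' Attenuation is exactly 1 at every b = 0 entry.
#'
#' @param fit An [mcm_fit()].
#' @param scheme A [gradient_scheme()].
#' @return Numeric vector of attenuations in (0, 1], one per scheme row.
#' @examples
#' sch <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
#' predict_signal(mcm_fit(1), sch) # c(1, exp(-3))
#' @export
predict_signal <- function(fit, scheme) {
  stopifnot(inherits(fit, "mcm_fit"))
  b <- scheme$bval
  g <- scheme_directions(scheme)
  att <- fit$fw_weight * exp(-b * fit$d_iso)
  for (z in fit$compartments) {
    proj2 <- as.numeric(g %*% z$axis)^2
    adc <- z$lambda_perp + (z$lambda_par - z$lambda_perp) * proj2
    att <- att + z$weight * exp(-b * adc)
  }
  att[b == 0] <- 1
  att
}

#' Scalar tensor metrics of a zeppelin
#'
#' Standard eigenvalue formulas applied to (lambda_par, lambda_perp,
#' lambda_perp): `MD = (l_par + 2 l_perp) / 3`, `AD = l_par`,
#' `RD = l_perp`, and the fractional anisotropy reduces to
#' `FA = (l_par - l_perp) / sqrt(l_par^2 + 2 l_perp^2)`.
#'
#' @param lambda_par,lambda_perp Diffusivities in mm^2/s, vectorized;
#'   `0 < lambda_perp <= lambda_par`.
#' @return A tibble with columns `FA, MD, AD, RD`.
#' @examples
#' zeppelin_scalar_metrics(1.7e-3, 0.3e-3)
#' @export
zeppelin_scalar_metrics <- function(lambda_par, lambda_perp) {
  if (any(!(lambda_perp > 0 & lambda_perp <= lambda_par))) {
    stop("need 0 < lambda_perp <= lambda_par", call. = FALSE)
  }
  tibble::tibble(
    FA = (lambda_par - lambda_perp) /
      sqrt(lambda_par^2 + 2 * lambda_perp^2),
    MD = (lambda_par + 2 * lambda_perp) / 3,
    AD = lambda_par,
    RD = lambda_perp
  )
}

#' Derive voxel microstructure metrics from a fit
#'
#' FW is the free-water weight. FA, MD, AD and RD are computed per zeppelin
#' compartment and averaged (unweighted) across the compartments; with no
#' anisotropic compartment they are `NA` (undefined in pure-isotropic
#' voxels).
#'
#' @param fit An [mcm_fit()].
#' @return A one-row tibble with columns `FW, FA, MD, AD, RD, n_aniso`.
#' @export
derive_voxel_metrics <- function(fit) {
  stopifnot(inherits(fit, "mcm_fit"))
  if (fit$n_aniso == 0) {
    return(tibble::tibble(FW = fit$fw_weight, FA = NA_real_, MD = NA_real_,
                          AD = NA_real_, RD = NA_real_, n_aniso = 0L))
  }
  per <- zeppelin_scalar_metrics(
    vapply(fit$compartments, `[[`, numeric(1), "lambda_par"),
    vapply(fit$compartments, `[[`, numeric(1), "lambda_perp")
  )
  tibble::tibble(FW = fit$fw_weight,
                 FA = mean(per$FA), MD = mean(per$MD),
                 AD = mean(per$AD), RD = mean(per$RD),
                 n_aniso = fit$n_aniso)
}

#' @export
tidy.mcm_fit <- function(x, ...) {
  if (x$n_aniso == 0) {
    return(tibble::tibble(compartment = integer(), weight = numeric(),
                          axis_x = numeric(), axis_y = numeric(), axis_z = numeric(),
                          lambda_par = numeric(), lambda_perp = numeric()))
  }
  tibble::tibble(
    compartment = seq_len(x$n_aniso),
    weight = vapply(x$compartments, `[[`, numeric(1), "weight"),
    axis_x = vapply(x$compartments, function(z) z$axis[1], numeric(1)),
    axis_y = vapply(x$compartments, function(z) z$axis[2], numeric(1)),
    axis_z = vapply(x$compartments, function(z) z$axis[3], numeric(1)),
    lambda_par = vapply(x$compartments, `[[`, numeric(1), "lambda_par"),
    lambda_perp = vapply(x$compartments, `[[`, numeric(1), "lambda_perp")
  )
}

#' @export
glance.mcm_fit <- function(x, ...) {
  tibble::tibble(fw_weight = x$fw_weight, n_aniso = x$n_aniso,
                 loglik = x$loglik, criterion = x$criterion,
                 converged = x$converged)
}
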