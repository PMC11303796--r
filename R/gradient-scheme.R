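#' Build a gradient scheme table
#'
#' A gradient scheme describes a multi-shell diffusion acquisition: one row
#' per volume, with the b-value (s/mm^2) and the unit gradient direction.
#' Every signal operation in the package consumes this table. Directions of
#' b = 0 rows are ignored and stored as zeros.
#'
#' @param bval Numeric vector of b-values in s/mm^2 (>= 0, finite).
#' @param directions Numeric matrix with one row per b-value and columns
#'   `gx, gy, gz`. Rows with `bval > 0` must have unit Euclidean norm
#'   (tolerance 1e-6).
#' @return A tibble of class `gradient_scheme` with columns
#'   `bval, gx, gy, gz`.
#' @examples
#' gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
#' @export
gradient_scheme <- function(bval, directions) {
  bval <- as.numeric(bval)
  directions <- as.matrix(directions)
  if (nrow(directions) != length(bval) || ncol(directions) != 3) {
    stop("`directions` must be a length(bval) x 3 matrix", call. = FALSE)
  }
  if (any(!is.finite(bval)) || any(bval < 0)) {
    stop("b-values must be finite and non-negative", call. = FALSE)
  }
  if (!any(bval == 0)) {
    stop("a gradient scheme needs at least one b = 0 entry", call. = FALSE)
  }
  dwi <- bval > 0
  if (any(dwi)) {
    nrm <- sqrt(rowSums(directions[dwi, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("directions of b > 0 entries must be unit vectors (|norm - 1| <= 1e-6)",
           call. = FALSE)
    }
  }
  directions[!dwi, ] <- 0
  out <- tibble::tibble(
    bval = bval,
    gx = directions[, 1], gy = directions[, 2], gz = directions[, 3]
  )
  class(out) <- c("gradient_scheme", class(out))
  out
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme: %d entries, %d b0, b in [%g, %g] s/mm^2>\n",
              nrow(x), sum(x$bval == 0), min(x$bval), max(x$bval)))
  NextMethod()
}

scheme_directions <- function(scheme) {
  cbind(scheme$gx, scheme$gy, scheme$gz)
}

n_b0 <- function(scheme) sum(scheme$bval == 0)

#' Read a gradient scheme from FSL bval/bvec files or a TSV
#'
#' `read_scheme_fsl()` reads the FSL convention: a one-line whitespace
#' separated bval file and a 3-line bvec file (rows = x, y, z). Vectors are
#' renormalized to unit length when within 1e-3 of it (text round-off);
#' larger deviations are an error. `read_scheme_tsv()` reads a four-column
#' table `bval, gx, gy, gz` with a header.
#'
#' @param bval_file,bvec_file Paths to the FSL pair.
#' @return A [gradient_scheme()] tibble.
#' @export
read_scheme_fsl <- function(bval_file, bvec_file) {
  bval <- scan(bval_file, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(bvec_file))
  if (nrow(bvec) != 3) stop("bvec file must have 3 rows (x, y, z)", call. = FALSE)
  dirs <- t(bvec)
  dwi <- bval > 0
  nrm <- sqrt(rowSums(dirs^2))
  bad <- dwi & abs(nrm - 1) > 1e-3
  if (any(bad)) stop("bvec columns for b > 0 entries are not unit vectors", call. = FALSE)
  dirs[dwi, ] <- dirs[dwi, , drop = FALSE] / nrm[dwi]
  gradient_scheme(bval, dirs)
}

#' @rdname read_scheme_fsl
#' @param file Path of the TSV variant.
#' @export
read_scheme_tsv <- function(file) {
  tab <- utils::read.delim(file, sep = "\t")
  need <- c("bval", "gx", "gy", "gz")
  if (!all(need %in% names(tab))) {
    stop("scheme TSV needs columns bval, gx, gy, gz", call. = FALSE)
  }
  gradient_scheme(tab$bval, as.matrix(tab[, c("gx", "gy", "gz")]))
}

#' Write a gradient scheme
#'
#' `write_scheme_fsl()` writes the FSL bval/bvec pair; `write_scheme_tsv()`
#' writes the single-table form.
#'
#' @param scheme A [gradient_scheme()].
#' @param bval_file,bvec_file,file Output paths.
#' @return The input, invisibly.
#' @export
write_scheme_fsl <- function(scheme, bval_file, bvec_file) {
  writeLines(paste(format(scheme$bval, trim = TRUE, scientific = FALSE,
                          digits = 15),
                   collapse = " "), bval_file)
  bvec <- t(scheme_directions(scheme))
  writeLines(apply(bvec, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                              collapse = " ")), bvec_file)
  invisible(scheme)
}

#' @rdname write_scheme_fsl
#' @export
write_scheme_tsv <- function(scheme, file) {
  readr::write_tsv(tibble::as_tibble(scheme)[, c("bval", "gx", "gy", "gz")], file)
  invisible(scheme)
}
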