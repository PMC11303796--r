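#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Derive a child seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 32749 + stream * 7919) %% 2147483562L
}

# A self-contained RNG stream: draws do not touch (and are not touched by)
# the global generator state, so seeded components compose deterministically.
make_rng <- function(seed, stream = 0L) {
  state <- NULL
  local({
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
    set.seed(derive_seed(seed, stream))
    state <<- get(".Random.seed", globalenv())
  })
  draw <- function(fn) {
    function(...) {
      old <- get0(".Random.seed", globalenv(), inherits = FALSE)
      on.exit(if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv()))
      assign(".Random.seed", state, envir = globalenv())
      out <- fn(...)
      state <<- get(".Random.seed", globalenv())
      out
    }
  }
  list(
    rnorm = draw(stats::rnorm),
    runif = draw(stats::runif),
    rbinom = draw(stats::rbinom),
    sample_int = draw(function(n, size = n, replace = FALSE) {
      sample.int(n, size = size, replace = replace)
    })
  )
}

# angle in degrees between two axes, modulo sign (antipodal symmetry)
axis_angle_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(pmin(abs(sum(a * b)), 1)) * 180 / pi
}

# maximal runs of TRUE along a logical vector; NA breaks a run
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- as.integer(cumsum(r$lengths))
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], end = ends[keep],
                 length = r$lengths[keep])
}
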