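#' @keywords internal
"_PACKAGE"

## Small shared helpers: seeded evaluation, circular arithmetic, axis math.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state
#'
#' All stochastic stages in the package draw from one owned generator via
#' this helper, so a lattice or dataset is reproducible from its seed without
#' disturbing the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Wrap angles into a half-open interval
#'
#' @param x Angles in degrees.
#' @param period Full period in degrees (default 360).
#' @param center Centre of the target interval; the result lies in
#'   `(center - period/2, center + period/2]`.
#' @return Wrapped angles in degrees.
#' @export
wrap_angle <- function(x, period = 360, center = 0) {
  y <- (x - center + period / 2) %% period
  y[y == 0] <- period
  y + center - period / 2
}

## Minimal circular distance between two angle sets, degrees.
circ_dist <- function(a, b, period = 360) {
  abs(wrap_angle(a - b, period = period))
}

## Unwrap an ordered angle series: successive differences are mapped into
## (-period/2, period/2] and re-accumulated, so slopes much smaller than the
## period survive the branch cuts.
unwrap_series <- function(phi, period = 360) {
  if (length(phi) < 2) return(phi)
  d <- wrap_angle(diff(phi), period = period)
  phi[1] + c(0, cumsum(d))
}

## Rotation matrix about an arbitrary unit axis (Rodrigues), angle in degrees.
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_z <- function(angle_deg) rotation_about_axis(c(0, 0, 1), angle_deg)

`%||%` <- function(a, b) if (is.null(a)) b else a
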