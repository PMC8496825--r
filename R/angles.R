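#' Wrap angles to [-180, 180)
#'
#' All directions in hdring are allocentric or egocentric angles in degrees,
#' anticlockwise positive, wrapped to the half-open interval \[-180, 180).
#'
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles in \[-180, 180).
#' @export
#' @examples
#' wrap_angle(c(180, -180, 360, 725))
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Preferred-direction grid
#'
#' Equally spaced preferred directions on \[-180, 180), the common grid shared
#' by the attractor ring, the retrosplenial layers and every visual channel.
#'
#' @param n number of directions (neurons per layer).
#' @return numeric vector of length `n`, starting at -180.
#' @export
theta_grid <- function(n) {
  stopifnot(n >= 1)
  -180 + (seq_len(n) - 1) * 360 / n
}

# degrees -> radians
deg2rad <- function(x) x * pi / 180

# signed circular difference a - b in [-180, 180)
circ_diff <- function(a, b) wrap_angle(a - b)

# circular mean of angles in degrees; NA if resultant ~ 0
circ_mean <- function(x) {
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  atan2(s, c) * 180 / pi
}

# circularly shift a vector by k positions (k > 0 moves entries to higher
# indices, i.e. rotates the profile anticlockwise on the theta grid)
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# seed-scoped evaluation: run expr with a temporary RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
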