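#' Visual cue
#'
#' One feature-specific cue in a scenery. The `profile` describes how the
#' corresponding visual channel responds as a function of egocentric bearing:
#' \describe{
#'   \item{unimodal}{a scaled von Mises bump, `fmax * exp(kappa * (cos(theta - phi) - 1))`.}
#'   \item{broad}{a plateau of width `width` built by tiling unimodal bumps
#'     across \[phi - width/2, phi + width/2\] and rescaling to `fmax`
#'     (the cumulative-von-Mises shape of a wide, directionally unspecific cue).}
#'   \item{bimodal}{two unimodal bumps at two allocentric centers
#'     (an ambiguous cue such as two identical posters on opposite walls).}
#'   \item{constant}{a direction-independent channel, used for odor-like
#'     contextual signals spanning 360 degrees.}
#' }
#'
#' Cue dynamics: `static`, `rotate` (center advances at `speed` deg/s,
#' anticlockwise positive), `teleport` (center jumps to a uniformly random
#' direction every `period` seconds), `window` (cue present only for
#' `t_on <= t < t_off`).
#'
#' @param feature channel label, e.g. `"red"`.
#' @param profile one of `"unimodal"`, `"broad"`, `"bimodal"`, `"constant"`.
#' @param centers allocentric center(s) in degrees; exactly 2 for `bimodal`.
#' @param kappa von Mises encoding precision (>= 0).
#' @param fmax peak rate in (0, 1].
#' @param width plateau width in degrees (broad profile only).
#' @param dynamics one of `"static"`, `"rotate"`, `"teleport"`, `"window"`.
#' @param speed rotation speed in deg/s (rotate dynamics).
#' @param period teleport period in seconds (teleport dynamics).
#' @param t_on,t_off presence window in seconds (window dynamics).
#' @return an object of class `hd_cue`.
#' @export
#' @examples
#' cue("blue", "broad", centers = 0, kappa = 20, width = 90)
#' cue("red", "bimodal", centers = c(90, -90), kappa = 20)
cue <- function(feature, profile = c("unimodal", "broad", "bimodal", "constant"),
                centers = 0, kappa = 20, fmax = 1, width = 90,
                dynamics = c("static", "rotate", "teleport", "window"),
                speed = 0, period = 10, t_on = 0, t_off = Inf) {
  profile <- match.arg(profile)
  dynamics <- match.arg(dynamics)
  centers <- wrap_angle(centers)
  if (profile == "bimodal" && length(centers) != 2) {
    stop("bimodal cue needs exactly 2 centers")
  }
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (fmax <= 0 || fmax > 1) stop("`fmax` must be in (0, 1]")
  if (profile == "broad" && width <= 0) stop("`width` must be > 0")
  structure(
    list(
      feature = feature, profile = profile, centers = centers,
      kappa = kappa, fmax = fmax, width = width,
      dynamics = dynamics, speed = speed, period = period,
      t_on = t_on, t_off = t_off
    ),
    class = "hd_cue"
  )
}

#' Scenery: a named set of cues
#'
#' A scenery is one environment's cue configuration plus the layout of the
#' feature-specific visual channels (all channels share one egocentric
#' direction grid). Channels are created for `features` (default: the union
#' of cue features), so a scenery can declare silent channels.
#'
#' All cues are treated as distal: a channel's response depends on head
#' direction only, never on position.
#'
#' @param name scenery name.
#' @param cues list of [cue] objects.
#' @param n_dirs neurons per channel (egocentric grid resolution).
#' @param features channel labels; defaults to the cue features in order of
#'   first appearance.
#' @return an object of class `hd_scenery`.
#' @export
scenery <- function(name, cues, n_dirs = 120, features = NULL) {
  stopifnot(length(cues) >= 0)
  cue_feats <- vapply(cues, function(x) x$feature, character(1))
  if (is.null(features)) features <- unique(cue_feats)
  if (!all(cue_feats %in% features)) {
    stop("every cue feature must map to a declared channel")
  }
  structure(
    list(
      name = name, cues = cues, n_dirs = n_dirs, features = features,
      theta = theta_grid(n_dirs)
    ),
    class = "hd_scenery"
  )
}

#' @export
print.hd_scenery <- function(x, ...) {
  cat(sprintf("<hd_scenery> \"%s\": %d cue(s), %d channel(s) x %d neurons\n",
              x$name, length(x$cues), length(x$features), x$n_dirs))
  for (cu in x$cues) {
    cat(sprintf("  %-8s %-8s centers %s  kappa %.3g  fmax %.2f  [%s]\n",
                cu$feature, cu$profile,
                paste(round(cu$centers, 1), collapse = "/"),
                cu$kappa, cu$fmax, cu$dynamics))
  }
  invisible(x)
}

#' Unimodal von Mises rate profile
#'
#' `f(theta) = fmax * exp(kappa * (cos(theta - phi) - 1))`: peak `fmax` at
#' `theta = phi`, flat at `fmax` when `kappa = 0`.
#'
#' @param theta egocentric direction grid in degrees.
#' @param phi center in degrees.
#' @param kappa encoding precision.
#' @param fmax peak rate.
#' @return rate vector over `theta`.
#' @export
unimodal_profile <- function(theta, phi, kappa, fmax = 1) {
  fmax * exp(kappa * (cos(deg2rad(theta - phi)) - 1))
}

#' Broad (plateau) rate profile
#'
#' Sum of unimodal profiles with precision `kappa` whose centers tile
#' \[phi - width/2, phi + width/2\] at 1 degree steps, rescaled so the
#' maximum equals `fmax`. Yields a plateau of near-maximal rate of extent
#' about `width`, symmetric about `phi`.
#'
#' @inheritParams unimodal_profile
#' @param width plateau width in degrees (> 0).
#' @export
broad_profile <- function(theta, phi, kappa, width, fmax = 1) {
  stopifnot(width > 0)
  tiles <- seq(phi - width / 2, phi + width / 2, by = 1)
  f <- rowSums(vapply(tiles, function(p) unimodal_profile(theta, p, kappa, 1),
                      numeric(length(theta))))
  f * (fmax / max(f))
}

# memoised cue shapes: profile of a center-0 cue on a 1-degree grid; the
# response at any head direction is a circular shift of this shape
.shape_cache <- new.env(parent = emptyenv())
cue_shape <- function(cu) {
  key <- paste(cu$profile, cu$kappa, cu$fmax, cu$width, sep = "|")
  s <- .shape_cache[[key]]
  if (is.null(s)) {
    grid <- -180:179
    s <- switch(cu$profile,
      unimodal = ,
      bimodal = unimodal_profile(grid, 0, cu$kappa, cu$fmax),
      broad = broad_profile(grid, 0, cu$kappa, cu$width, cu$fmax),
      constant = rep(cu$fmax, length(grid))
    )
    .shape_cache[[key]] <- s
  }
  s
}

# sample a cached 1-degree shape at arbitrary angles (circular linear
# interpolation)
sample_shape <- function(shape, ang) {
  pos <- (ang + 180) %% 360          # in [0, 360), grid step 1 degree
  i0 <- floor(pos)
  w <- pos - i0
  i0 <- i0 %% 360
  i1 <- (i0 + 1) %% 360
  shape[i0 + 1] * (1 - w) + shape[i1 + 1] * w
}

# raw (pre-normalization) egocentric response of one cue at head direction hd
cue_response <- function(cu, theta, hd, t = 0) {
  if (cu$dynamics == "window" && !(t >= cu$t_on && t < cu$t_off)) {
    return(numeric(length(theta)))
  }
  shape <- cue_shape(cu)
  out <- numeric(length(theta))
  for (ctr in cu$centers) {
    out <- out + sample_shape(shape, theta - (ctr - hd))
  }
  if (cu$profile == "constant") out <- out / length(cu$centers)
  out
}

#' Feature-specific channel responses
#'
#' Computes the per-channel visual rates for a scenery at a given true head
#' direction: each cue's allocentric center is converted to an egocentric
#' bearing `wrap(center - hd)`, per-cue profiles are summed within each
#' channel, optional low-amplitude background noise is added, and every
#' channel that is not everywhere zero is rescaled to the common target mean
#' (silent channels stay zero). Rates are clamped to \[0, 1\].
#'
#' The mean normalization implements upstream sensory adaptation: every
#' active feature channel fluctuates about the same overall intensity, so
#' narrow cues end up with higher peaks (higher saliency) than broad ones.
#'
#' @param scn an [hd_scenery].
#' @param hd true head direction in degrees.
#' @param t simulation time in seconds (for windowed cues).
#' @param target_mean common post-normalization channel mean.
#' @param noise_amp amplitude of the fixed broad background-noise profile
#'   (0 disables it).
#' @param noise_kappa precision of the background-noise profile.
#' @param noise_phi center of the background-noise profile (egocentric).
#' @param jitter_frac if > 0, adds uniformly random noise redrawn on every
#'   call, scaled so its 1-norm is `jitter_frac` of the channel signal's
#'   1-norm (the stochastic input-noise condition of the capacity
#'   experiments).
#' @return `n_dirs x n_channels` matrix of rates in \[0, 1\], channels in
#'   `scn$features` order.
#' @export
channel_response <- function(scn, hd, t = 0, target_mean = 0.08,
                             noise_amp = 0.02, noise_kappa = 0.5,
                             noise_phi = 0, jitter_frac = 0) {
  theta <- scn$theta
  out <- matrix(0, length(theta), length(scn$features),
                dimnames = list(NULL, scn$features))
  for (cu in scn$cues) {
    out[, cu$feature] <- out[, cu$feature] + cue_response(cu, theta, hd, t)
  }
  active <- colSums(out) > 0 # channels carrying cue signal
  if (noise_amp > 0) {
    bg <- noise_amp * unimodal_profile(theta, noise_phi, noise_kappa, 1)
    out <- out + bg
  }
  if (jitter_frac > 0) {
    for (j in which(active)) {
      s <- sum(out[, j])
      u <- stats::runif(length(theta))
      out[, j] <- out[, j] + u * (jitter_frac * s / sum(u))
    }
  }
  # adaptation: every channel with cue signal fluctuates about the same
  # mean intensity; channels carrying only background noise stay weak.
  # The common mean is set so the summed intensity over active channels is
  # constant (divisive normalization across features): target_mean is the
  # per-channel mean when three channels are active.
  n_act <- sum(active)
  if (n_act > 0) {
    per_mean <- target_mean * 3 / n_act
    means <- colMeans(out)
    out[, active] <- sweep(out[, active, drop = FALSE], 2,
                           per_mean / means[active], `*`)
  }
  pmin(pmax(out, 0), 1)
}

#' Advance cue dynamics by one time step
#'
#' Rotating cues advance their centers by `speed * dt` (anticlockwise
#' positive); teleporting cues jump to a uniformly random direction whenever
#' a period boundary falls in `(t, t + dt]` (using the current RNG stream,
#' so runs are reproducible under a fixed seed); static and windowed cues are
#' unchanged (windowed presence is evaluated in [channel_response]).
#'
#' @param scn an [hd_scenery].
#' @param t current time in seconds.
#' @param dt time step in seconds.
#' @return the scenery with updated cue centers.
#' @export
advance_cues <- function(scn, t, dt) {
  for (i in seq_along(scn$cues)) {
    cu <- scn$cues[[i]]
    if (cu$dynamics == "rotate") {
      cu$centers <- wrap_angle(cu$centers + cu$speed * dt)
    } else if (cu$dynamics == "teleport") {
      if (floor((t + dt) / cu$period) > floor(t / cu$period)) {
        cu$centers <- stats::runif(length(cu$centers), -180, 180)
      }
    }
    scn$cues[[i]] <- cu
  }
  scn
}

#' Rotate a whole scenery
#'
#' Shifts every cue center by `angle` degrees anticlockwise; used for the
#' scene-rotation experiments.
#'
#' @param scn an [hd_scenery].
#' @param angle rotation in degrees, anticlockwise positive.
#' @return the rotated scenery.
#' @export
rotate_scenery <- function(scn, angle) {
  scn$cues <- lapply(scn$cues, function(cu) {
    if (cu$profile != "constant") cu$centers <- wrap_angle(cu$centers + angle)
    cu
  })
  scn
}

#' Constant (odor-like) channel response
#'
#' The response of a scenery's constant-profile channel: a direction-independent
#' rate vector, normalized like any other channel. Errors if the scenery has
#' no constant cue.
#'
#' @inheritParams channel_response
#' @return rate vector over the egocentric grid.
#' @export
odor_channel <- function(scn, hd = 0, target_mean = 0.08) {
  const <- vapply(scn$cues, function(cu) cu$profile == "constant", logical(1))
  if (!any(const)) stop("scenery declares no constant-profile cue")
  feat <- scn$cues[[which(const)[1]]]$feature
  channel_response(scn, hd, noise_amp = 0, target_mean = target_mean)[, feat]
}
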