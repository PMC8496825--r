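#' Assemble the full network
#'
#' Builds all layer states and plastic weights for one model variant:
#' \describe{
#'   \item{full}{visual channels -> aLB (mOSA or an alternative rule) ->
#'     dRSC, plus the attractor/gRSC/dRSC loop and dRSC feedback.}
#'   \item{direct}{no aLB layer; per-channel visual -> dRSC connections under
#'     classic Hebbian learning with norm capping, everything else unchanged.}
#' }
#'
#' @param n_dirs ring size (attractor, gRSC, dRSC and visual channels).
#' @param n_alb number of aLB cells (default `3 * n_dirs`, matching the
#'   360-cell layer used with a 120-neuron ring at full scale).
#' @param features visual channel labels.
#' @param params parameter list from [hd_params].
#' @param variant `"full"` or `"direct"`.
#' @param rule plasticity rule for the visual->aLB weights: `"mosa"` or one
#'   of the [alt_rule_update] rules.
#' @param seed integer seed for all random initialization.
#' @param start_hd initial represented head direction.
#' @param hetero_frac fraction of dRSC cells whose Hebbian learning rate is
#'   reduced to near zero (the heterogeneous-learning-rate variant; 0
#'   disables it).
#' @param calibrate if `TRUE` (default) calibrate the attractor velocity
#'   gain for this ring size (cached per size/parameter set).
#' @return an object of class `hd_network`.
#' @export
hd_network <- function(n_dirs = 120, n_alb = NULL,
                       features = c("red", "green", "blue"),
                       params = hd_params(), variant = c("full", "direct"),
                       rule = "mosa", seed = 1, start_hd = 0,
                       hetero_frac = 0, calibrate = TRUE) {
  variant <- match.arg(variant)
  if (is.null(n_alb)) n_alb <- 3 * n_dirs
  if (calibrate && is.na(params$attractor$vel_gain)) {
    params$attractor$vel_gain <- cached_velocity_gain(params$attractor, n_dirs)
  }
  net <- list(
    n_dirs = n_dirs, n_alb = n_alb, features = features,
    params = params, variant = variant, rule = rule,
    theta = theta_grid(n_dirs)
  )
  net$hd <- attractor_init(n_dirs, start_hd, params$attractor)
  net$rsc <- rsc_init(n_dirs, n_alb, params, seed = seed)
  if (variant == "full") {
    net$alb <- alb_layer(n_alb, n_dirs, length(features),
                         w_lo = params$alb$w_lo, w_hi = params$alb$w_hi,
                         seed = seed + 1)
  } else {
    net$W_v2d <- lapply(seq_along(features), function(j) {
      matrix(0, n_dirs, n_dirs)
    })
  }
  eta_mask <- rep(1, n_dirs)
  if (hetero_frac > 0) {
    n_slow <- round(hetero_frac * n_dirs)
    eta_mask[seq_len(n_slow) * floor(n_dirs / n_slow)] <- 0.01
  }
  net$eta_mask <- eta_mask
  class(net) <- "hd_network"
  net
}

#' @export
print.hd_network <- function(x, ...) {
  cat(sprintf(
    "<hd_network> %s model, ring %d, %s, channels: %s\n",
    x$variant, x$n_dirs,
    if (x$variant == "full") sprintf("%d aLB cells (%s rule)", x$n_alb, x$rule)
    else "direct visual->dRSC",
    paste(x$features, collapse = ", ")
  ))
  invisible(x)
}

# velocity-gain cache (per ring size and attractor parameters)
.gain_cache <- new.env(parent = emptyenv())
cached_velocity_gain <- function(apars, n) {
  key <- paste(n, apars$kappa, apars$amp, apars$inhib, apars$tau,
               apars$alpha, apars$beta, sep = "|")
  if (is.null(.gain_cache[[key]])) {
    g <- calibrate_velocity_gain(apars, n = n)
    .gain_cache[[key]] <- as.numeric(g)
  }
  .gain_cache[[key]]
}

#' Experiment protocols
#'
#' A protocol is an ordered list of environment visits with dwell times,
#' plus the trajectory source and the tests to run. Each visit is a list
#' with elements `scenery`, `duration` (s), `learn` (logical, default TRUE),
#' `feedback` (logical, default TRUE), `jitter_frac` (per-step uniform input
#' noise, default taken from the protocol) and `tests`, a list of test
#' specifications from [test_spec] executed right after the visit.
#'
#' @param visits list of visit lists (see above).
#' @param trajectory either an [hd_trajectory] covering the summed visit
#'   durations, or `NULL` to generate a synthetic trajectory
#'   (mean speed 72.88 deg/s) from `seed`.
#' @param final_tests tests run after all visits.
#' @param seed master seed for the run (network initialization, synthetic
#'   trajectory, cue teleports, input noise).
#' @param dt integration step in seconds.
#' @param jitter_frac default per-step uniform visual input noise fraction.
#' @param noise_amp background-noise amplitude override (`NULL`: parameter
#'   default).
#' @param test_revs number of full revolutions of the standard test rotation
#'   (60 deg/s); 10 reproduces the canonical 60-s test.
#' @param name protocol name.
#' @return an object of class `hd_protocol`.
#' @export
hd_protocol <- function(visits, trajectory = NULL, final_tests = list(),
                        seed = 1, dt = hd_params()$dt, jitter_frac = 0,
                        noise_amp = NULL, test_revs = 2,
                        name = "protocol") {
  for (i in seq_along(visits)) {
    v <- visits[[i]]
    stopifnot(inherits(v$scenery, "hd_scenery"), v$duration > 0)
    if (is.null(v$learn)) v$learn <- TRUE
    if (is.null(v$feedback)) v$feedback <- TRUE
    if (is.null(v$tests)) v$tests <- list()
    visits[[i]] <- v
  }
  structure(
    list(visits = visits, trajectory = trajectory,
         final_tests = final_tests, seed = seed, dt = dt,
         jitter_frac = jitter_frac, noise_amp = noise_amp,
         test_revs = test_revs, name = name),
    class = "hd_protocol"
  )
}

#' @rdname hd_protocol
#' @param scenery scenery to test in (`NULL`: the current visit's scenery,
#'   with cue dynamics stopped).
#' @param label test label.
#' @param weights `"current"` or the index of an earlier visit whose weight
#'   snapshot should be loaded (weights are always frozen during tests).
#' @param layers which rate logs to keep: subset of
#'   `c("alb", "hd", "grsc", "drsc")`.
#' @param epsilon recruitment threshold for the aLB representation.
#' @export
test_spec <- function(scenery = NULL, label = "test", weights = "current",
                      layers = "alb", epsilon = 0.5) {
  list(scenery = scenery, label = label, weights = weights,
       layers = layers, epsilon = epsilon)
}

#' @export
print.hd_protocol <- function(x, ...) {
  cat(sprintf("<hd_protocol> \"%s\": %d visit(s), %.0f s total learning, seed %d\n",
              x$name, length(x$visits),
              sum(vapply(x$visits, `[[`, numeric(1), "duration")), x$seed))
  invisible(x)
}
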