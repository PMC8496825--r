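#' Default model parameters
#'
#' Returns the full nested parameter list for the network, with the shipped
#' calibrated defaults. Any entry can be overridden by passing a nested list
#' in `...` (e.g. `hd_params(alb = list(eta = 0.1))`), which is merged over
#' the defaults.
#'
#' Layers share the thresholded-tanh rate transfer; `alpha` is the activation
#' threshold, `beta` the slope, `tau` the membrane time constant in seconds,
#' and gains `g_*` scale each projection. See the package vignette for the
#' rationale behind each value.
#'
#' @param ... nested overrides merged over the defaults.
#' @return nested parameter list with entries `dt`, `visual`, `alb`,
#'   `attractor`, `grsc`, `drsc`, `direct`.
#' @export
#' @examples
#' p <- hd_params(alb = list(eta = 0.05))
#' p$alb$eta
hd_params <- function(...) {
  p <- list(
    # global integration step: 2.5 ms so the fastest layer (aLB, tau 5 ms)
    # is resolved by at least two Euler steps
    dt = 0.0025,
    visual = list(
      target_mean = 0.08,  # common channel mean after normalization
      noise_amp = 0.005,   # background-noise amplitude (small, on all channels)
      noise_kappa = 0.5,
      kappa_narrow = 10,   # precision of narrow (unimodal/bimodal) cues
      kappa_green = 14,    # precision of the distinguishing (green) cue
      kappa_broad = 20,    # per-tile precision of the broad cue
      broad_width = 90
    ),
    alb = list(
      tau = 0.005, alpha = 71.5, beta = 6,
      noise_sd = 0,        # Gaussian activation noise (off by default)
      kick_size = 5,       # recruitment-search boost (activation units)
      kick_len = 0.5,      # duration of each single-cell boost (seconds)
      g_alb = -12,         # per-source lateral-inhibition weight (negative)
      g_vis = 8,           # feed-forward gain, per 120-neuron channel
      n_ref = 120,         # reference channel size for g_vis
      eta = 0.005,         # mOSA learning rate (per step)
      zeta = 1,
      w_lo = 0.28,         # uniform weight-initialization interval
      w_hi = 0.32
    ),
    attractor = list(
      tau = 0.05, alpha = 0, beta = 3,
      kappa = 8, amp = 1, inhib = 0.4,
      seed_amp = 0.5,      # amplitude of the initial seeded bump
      pi_gain = 1,         # path-integration gain (1 = veridical)
      vel_gain = NA,       # set by calibrate_velocity_gain
      g_fb = 0.5,          # dRSC one-to-one feedback gain
      g_fb_inh = 4         # dRSC global-inhibition feedback gain
    ),
    grsc = list(
      tau = 0.0025, alpha = 0.05, beta = 4,
      g_in = 1, g_inh = 0.5
    ),
    drsc = list(
      tau = 0.0025, alpha = 1.1, beta = 4,
      g_g2d = 0.3, g_a2d = 12, g_inh = 4,
      eta_g2d = 5e-4, eta_a2d = 2.5e-4,
      wmax_g2d = 1, wmax_a2d = 0.5,
      init_rand = 0.02,    # random component of initial gRSC->dRSC rows
      init_topo = 0.3,     # topographic bias amplitude
      topo_kappa = 8
    ),
    direct = list(
      g_v2d = 3,           # per-channel visual->dRSC gain (direct variant)
      eta = 2e-5, wmax = 1
    )
  )
  merge_pars(p, list(...))
}

#' @rdname hd_params
#' @details `hd_params_capacity()` returns the parameter set used for the
#'   sequential multi-environment (capacity) simulations: a larger
#'   recruitment search step (`kick_len` 1.5 s) so the reservoir of
#'   uncommitted aLB cells is consumed slowly enough to cover ten
#'   environments. Pair it with a proportionally larger aLB population
#'   (e.g. `n_alb = 720` on a 120-neuron ring).
#'
#'   `hd_params_direct()` returns the parameter set for the
#'   alternative network without aLB cells (direct visual-to-dRSC Hebbian
#'   pathway). The two models carry separate hyperparameter columns: the
#'   direct pathway uses per-channel gains that weight narrow
#'   (directionally specific) cues above broad ones, softer dRSC
#'   competition, and a weak, slide-style corrective feedback, so the
#'   attractor resolves cue ambiguity by ring proximity rather than by
#'   re-anchoring to the strongest match.
#' @export
#' @export
hd_params_capacity <- function(...) {
  p <- hd_params(alb = list(kick_len = 2))
  merge_pars(p, list(...))
}

#' @rdname hd_params
#' @export
hd_params_direct <- function(...) {
  p <- hd_params(
    direct = list(g_v2d = c(3, 3, 1), eta = 2e-5, wmax = 1),
    drsc = list(g_inh = 4, alpha = 0.4),
    attractor = list(g_fb = 0.05, g_fb_inh = 0.05)
  )
  merge_pars(p, list(...))
}

# recursive merge of override list over defaults
merge_pars <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_pars(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}
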