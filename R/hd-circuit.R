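#' Ring-attractor connectivity
#'
#' Builds the fixed attractor weights from a circular kernel: a symmetric
#' (even) component `amp * exp(kappa * (cos(d) - 1)) - inhib` that sustains a
#' stationary activity bump, and an antisymmetric (odd) component equal to
#' the discrete circular derivative of the symmetric kernel. Scaling the odd
#' component by angular velocity translates the bump at a speed proportional
#' to the velocity (the derivative-coupling construction of velocity-driven
#' bump attractors), which [calibrate_velocity_gain] pins to deg-for-deg
#' path integration.
#'
#' @param n number of ring neurons.
#' @param kappa concentration of the excitatory kernel (sets bump width).
#' @param amp peak recurrent excitation.
#' @param inhib uniform recurrent inhibition subtracted from the kernel.
#' @return list with circulant matrices `sym` and `asym` (the latter the
#'   derivative kernel, per radian).
#' @export
build_attractor_weights <- function(n, kappa = 8, amp = 1, inhib = 0.45) {
  d <- 2 * pi * (seq_len(n) - 1) / n    # offsets, starting at 0
  # kernel scaled inversely with ring size so total recurrent drive is
  # independent of n (amp/inhib are per 12 neighbours at reference scale)
  k <- (amp * exp(kappa * (cos(d) - 1)) - inhib) * (12 / n)
  # circulant from kernel of offsets: W[i, j] = k(theta_i - theta_j)
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1)
  sym <- matrix(k[idx], n, n)
  h <- 2 * pi / n
  kd <- (circ_shift(k, -1) - circ_shift(k, 1)) / (2 * h) # dk/d(offset)
  asym <- matrix(kd[idx], n, n)
  list(sym = sym, asym = asym)
}

#' Head-direction attractor state
#'
#' Initializes the ring with a bump of activation centered on `start_hd`.
#'
#' @param n ring size.
#' @param start_hd initial represented direction in degrees.
#' @param pars attractor parameter list (see [hd_params]).
#' @return list with `a`, `f`, `theta`, the weight matrices and parameters.
#' @export
attractor_init <- function(n, start_hd = 0, pars = hd_params()$attractor) {
  w <- build_attractor_weights(n, pars$kappa, pars$amp, pars$inhib)
  theta <- theta_grid(n)
  a <- pars$seed_amp * exp(pars$kappa * (cos(deg2rad(theta - start_hd)) - 1))
  st <- list(a = a, f = rate_transfer(a, pars$alpha, pars$beta),
             theta = theta, W = w, pars = pars)
  st
}

#' One attractor integration step
#'
#' Drive = symmetric recurrent input + angular-velocity-scaled antisymmetric
#' input (velocity multiplied by the path-integration gain and the calibrated
#' velocity gain) + optional corrective feedback (one-to-one excitation minus
#' global inhibition from dRSC rates), Euler-integrated with the attractor's
#' time constant.
#'
#' @param st attractor state from [attractor_init].
#' @param omega angular velocity in deg/s.
#' @param feedback dRSC rate vector (same length as the ring) or `NULL`.
#' @param dt time step in seconds.
#' @return updated state.
#' @export
attractor_step <- function(st, omega, feedback = NULL, dt) {
  p <- st$pars
  om <- deg2rad(omega) * p$pi_gain * p$vel_gain
  drive <- as.numeric(st$W$sym %*% st$f) + om * as.numeric(st$W$asym %*% st$f)
  if (!is.null(feedback)) {
    drive <- drive + p$g_fb * feedback - p$g_fb_inh * mean(feedback)
  }
  st$a <- st$a + (dt / p$tau) * (-st$a + drive)
  st$f <- rate_transfer(st$a, p$alpha, p$beta)
  st
}

# decode bump speed (deg/s) at constant omega over t_sim seconds
bump_speed <- function(pars, n, omega, t_sim = 2, dt = 0.005, settle = 0.5) {
  st <- attractor_init(n, 0, pars)
  n_settle <- round(settle / dt)
  n_sim <- round(t_sim / dt)
  for (k in seq_len(n_settle)) st <- attractor_step(st, 0, NULL, dt)
  ang <- numeric(n_sim)
  for (k in seq_len(n_sim)) {
    st <- attractor_step(st, omega, NULL, dt)
    ang[k] <- population_vector(st$f, st$theta)
  }
  unwrapped <- cumsum(c(ang[1], circ_diff(ang[-1], ang[-n_sim])))
  tt <- seq_len(n_sim) * dt
  unname(stats::coef(stats::lm(unwrapped ~ tt))[2])
}

#' Calibrate the velocity gain
#'
#' Finds the scalar multiplier on the antisymmetric kernel such that the
#' decoded bump speed matches the commanded angular velocity across
#' `omega_grid`. With the derivative-kernel construction the speed is linear
#' in the gain, so a single measurement fixes it; the full grid is then
#' checked and the worst relative error reported in
#' `attr(gain, "max_rel_error")`.
#'
#' @param pars attractor parameter list (`vel_gain` is ignored on entry).
#' @param n ring size.
#' @param omega_grid velocities (deg/s) to verify; 0 entries are skipped.
#' @param dt integration step for the calibration runs.
#' @return the calibrated gain (numeric scalar) with attribute
#'   `max_rel_error`.
#' @export
calibrate_velocity_gain <- function(pars, n = 120,
                                    omega_grid = c(-120, -60, -30, 30, 60, 120),
                                    dt = 0.00125) {
  pars$pi_gain <- 1 # calibration is of the veridical integrator
  pars$vel_gain <- pars$tau
  st <- attractor_init(n, 0, pars)
  for (k in seq_len(round(1 / dt))) st <- attractor_step(st, 0, NULL, dt)
  if (max(st$f) < 0.1) stop("calibration failure: no stable bump")
  ref <- 60
  v <- bump_speed(pars, n, ref, dt = dt)
  if (abs(v) < 1e-6) stop("calibration failure: bump does not move")
  gain <- pars$tau * ref / v
  # center the residual speed-ratio band across the grid (the integrator's
  # first-order error grows with |omega| dt, so a ref-only fit sits at one
  # edge of the band)
  pars$vel_gain <- gain
  grid <- omega_grid[omega_grid != 0]
  ratios <- vapply(grid, function(om) bump_speed(pars, n, om, dt = dt) / om,
                   numeric(1))
  gain <- gain * 2 / (max(ratios) + min(ratios))
  pars$vel_gain <- gain
  errs <- vapply(grid, function(om) {
    abs(bump_speed(pars, n, om, dt = dt) / om - 1)
  }, numeric(1))
  attr(gain, "max_rel_error") <- max(errs)
  gain
}

#' Retrosplenial layer states and Hebbian plasticity
#'
#' `rsc_init` builds the granular (gRSC) and dysgranular (dRSC) layer states
#' and the plastic weight matrices. gRSC receives the attractor bump through
#' a one-to-one projection; dRSC receives full gRSC->dRSC and aLB->dRSC
#' matrices, both Hebbian with per-row norm capping. The gRSC->dRSC matrix
#' starts from random positive weights with a weak topographic bias toward
#' the index-matched gRSC cell, realizing the inherited initial preferred
#' directions of dRSC cells that the one-to-one feedback to the attractor
#' relies on; Hebbian learning then amplifies the bias into the learned
#' association structure.
#'
#' @param n layer size (same as the attractor ring).
#' @param n_alb number of aLB cells.
#' @param pars parameter list (see [hd_params], entries `grsc`, `drsc`).
#' @param seed optional seed for the random initial connectivity.
#' @return list with states `grsc`, `drsc` (each `a`, `f`) and weights
#'   `W_g2d`, `W_a2d`.
#' @export
rsc_init <- function(n, n_alb, pars = hd_params(), seed = NULL) {
  pd <- pars$drsc
  W_g2d <- with_seed(seed, {
    base <- matrix(stats::runif(n * n, 0, pd$init_rand), n, n)
    d <- 2 * pi * (seq_len(n) - 1) / n
    topo <- pd$init_topo * exp(pd$topo_kappa * (cos(d) - 1))
    idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1)
    base + matrix(topo[idx], n, n)
  })
  W_g2d <- normalize_rows(W_g2d, pd$wmax_g2d)
  list(
    grsc = list(a = numeric(n), f = numeric(n)),
    drsc = list(a = numeric(n), f = numeric(n)),
    W_g2d = W_g2d,
    W_a2d = matrix(0, n, n_alb)
  )
}

#' @rdname rsc_init
#' @param rsc layer bundle from [rsc_init].
#' @param f_hd attractor rate vector.
#' @param dt time step in seconds.
#' @export
grsc_step <- function(rsc, f_hd, pars, dt) {
  p <- pars$grsc
  drive <- p$g_in * f_hd - p$g_inh * mean(rsc$grsc$f)
  rsc$grsc$a <- rsc$grsc$a + (dt / p$tau) * (-rsc$grsc$a + drive)
  rsc$grsc$f <- rate_transfer(rsc$grsc$a, p$alpha, p$beta)
  rsc
}

#' @rdname rsc_init
#' @param f_alb aLB rate vector (or an already weighted visual drive for the
#'   direct model variant, passed through `extra_drive`).
#' @param extra_drive optional additional drive vector added to dRSC (used by
#'   the direct visual-to-dRSC model variant).
#' @export
drsc_step <- function(rsc, f_alb, pars, dt, extra_drive = NULL) {
  p <- pars$drsc
  drive <- p$g_g2d * as.numeric(rsc$W_g2d %*% rsc$grsc$f) +
    p$g_a2d * as.numeric(rsc$W_a2d %*% f_alb) -
    p$g_inh * mean(rsc$drsc$f)
  if (!is.null(extra_drive)) drive <- drive + extra_drive
  rsc$drsc$a <- rsc$drsc$a + (dt / p$tau) * (-rsc$drsc$a + drive)
  rsc$drsc$f <- rate_transfer(rsc$drsc$a, p$alpha, p$beta)
  rsc
}

#' Hebbian update with norm capping
#'
#' `hebbian_update` adds the outer product `eta * post %o% pre` (optionally
#' with a per-post-neuron learning-rate vector for heterogeneous plasticity);
#' `normalize_rows` then rescales any row whose two-norm exceeds `w_max`
#' back to `w_max` (rows at or below the cap are unchanged). The printed
#' floor semantics (scaling sub-cap rows *up* to `w_max`) is available via
#' `mode = "floor"`, but the cap is the default since `w_max` is the maximum
#' total connection strength.
#'
#' @param W weight matrix (`n_post x n_pre`).
#' @param post,pre rate vectors.
#' @param eta learning rate, scalar or per-post-neuron vector (>= 0).
#' @return updated matrix.
#' @export
hebbian_update <- function(W, post, pre, eta) {
  if (any(eta < 0)) stop("`eta` must be >= 0")
  if (length(eta) > 1) post <- eta * post else post <- eta[1] * post
  W + tcrossprod(post, pre)
}

#' @rdname hebbian_update
#' @param w_max maximum row two-norm.
#' @param mode `"cap"` (default) or `"floor"` (the printed max semantics).
#' @export
normalize_rows <- function(W, w_max, mode = c("cap", "floor")) {
  mode <- match.arg(mode)
  nrm <- sqrt(rowSums(W^2))
  scale <- rep(1, nrow(W))
  if (mode == "cap") {
    over <- nrm > w_max
    scale[over] <- w_max / nrm[over]
  } else {
    under <- nrm < w_max & nrm > 0
    scale[under] <- w_max / nrm[under]
  }
  W * scale
}
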