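#' Abstract landmark-bearing (aLB) layer
#'
#' aLB cells receive feed-forward drive from every feature-specific visual
#' channel and inhibit each other laterally, giving winner-take-all dynamics:
#' each active cell ends up encoding one egocentric view of the whole cue
#' array (a conjunction of cues), not any single cue.
#'
#' `alb_layer()` builds the layer state and its plastic weights. Weights are
#' initialized i.i.d. uniform on the small positive interval
#' `(w_lo, w_hi)` (seeded). The interval is narrow and bounded away from
#' zero: every untrained cell then carries nearly the same total drive,
#' which places the whole reservoir in the competitive window between a
#' partially matched incumbent (which loses it) and a fully matched one
#' (which keeps it), while the residual jitter ties winner selection
#' reproducibly to the seed.
#'
#' @param n_alb number of aLB cells.
#' @param n_vis neurons per visual channel.
#' @param n_features number of visual channels.
#' @param w_lo,w_hi bounds of the uniform weight initialization.
#' @param seed optional integer seed for the initialization.
#' @return a list with elements `a`, `f` (activation/rate vectors), `W`
#'   (list of `n_alb x n_vis` non-negative matrices, one per channel) and
#'   `L` (the fixed lateral-inhibition matrix).
#' @export
alb_layer <- function(n_alb, n_vis, n_features, w_lo = 0.28, w_hi = 0.32,
                      seed = NULL) {
  W <- with_seed(seed, lapply(seq_len(n_features), function(j) {
    matrix(stats::runif(n_alb * n_vis, w_lo, w_hi), n_alb, n_vis)
  }))
  kick_order <- with_seed(if (is.null(seed)) NULL else seed + 7,
                          sample.int(n_alb))
  list(
    a = numeric(n_alb), f = numeric(n_alb),
    W = W, L = lateral_inhibition_matrix(n_alb),
    kick_order = kick_order, kick_pos = 0L, kick_ttl = 0L
  )
}

#' One integration step of the aLB layer
#'
#' Euler step of the aLB decay dynamics: leaky decay, inhibitory lateral
#' drive (`g_alb < 0`) and the summed feed-forward drive from all visual
#' channels, followed by the rate transfer.
#'
#' @param st aLB layer state from [alb_layer].
#' @param vis `n_vis x n_features` matrix of visual channel rates.
#' @param pars parameter list with `tau`, `alpha`, `beta`, `g_alb`
#'   (lateral-inhibition gain, negative) and `g_vis` (feed-forward gain,
#'   scalar or per-channel vector).
#' @param dt time step in seconds.
#' @param noise_sd standard deviation (per sqrt-second) of Gaussian
#'   stochastic drive added to every activation (0 disables it).
#' @param kicks if `TRUE`, apply the learning-phase recruitment search: at
#'   any moment one cell receives a sustained activation boost of size
#'   `kick_size` lasting `kick_len` seconds (parameters in `pars`), after
#'   which the next cell of a seeded random permutation is boosted. The
#'   kick lets a single reservoir cell probe the passing views for long
#'   enough to consolidate through the subspace rule: at unencoded views it
#'   crosses threshold, wins and specializes, while inside an encoded tile
#'   the winner's inhibition keeps it silent and the kick is harmless.
#'   Boosting one cell at a time avoids mass-activation transients, and
#'   visiting cells in permutation order gives each cell a single coherent
#'   firing locus per sweep, so downstream Hebbian associations stay
#'   consistent.
#' @return the updated layer state.
#' @export
alb_step <- function(st, vis, pars, dt, noise_sd = 0, kicks = FALSE) {
  if (is.null(st$kick_ttl)) {
    st$kick_ttl <- 0L
    st$kick_pos <- 0L
  }
  if (ncol(vis) != length(st$W)) {
    stop("visual channel count does not match weight count")
  }
  # the feed-forward gain is specified per reference channel size so the
  # total visual drive is independent of the grid resolution
  n_ref <- if (is.null(pars$n_ref)) nrow(vis) else pars$n_ref
  g_vis <- rep_len(pars$g_vis, ncol(vis)) * n_ref / nrow(vis)
  # g_alb is the per-source inhibitory weight; the total gain on the
  # row-stochastic lateral matrix scales with layer size so one winner
  # suppresses the rest regardless of N_aLB. The lateral drive
  # (N-1) * L f = sum(f) - f is computed directly.
  drive <- pars$g_alb * (sum(st$f) - st$f)
  for (j in seq_along(st$W)) {
    drive <- drive + g_vis[j] * as.numeric(st$W[[j]] %*% vis[, j])
  }
  st$a <- st$a + (dt / pars$tau) * (-st$a + drive)
  if (noise_sd > 0) {
    st$a <- st$a + noise_sd * sqrt(dt) * stats::rnorm(length(st$a))
  }
  if (kicks && pars$kick_size > 0) {
    if (st$kick_ttl <= 0L) {
      st$kick_pos <- (st$kick_pos %% length(st$kick_order)) + 1L
      st$kick_ttl <- as.integer(round(pars$kick_len / dt))
    }
    idx <- st$kick_order[st$kick_pos]
    st$a[idx] <- st$a[idx] + pars$kick_size
    st$kick_ttl <- st$kick_ttl - 1L
  }
  st$f <- rate_transfer(st$a, pars$alpha, pars$beta)
  st
}

#' Modified Oja's Subspace Algorithm (mOSA) update
#'
#' Per channel `j`, updates `W <- [W + eta * f_alb (f_vis_j - zeta W' f_alb)']_+`
#' where `[.]_+` clips negative entries to zero. The feedback term
#' `W' f_alb` is the visual pattern expected from the current aLB firing;
#' weights grow in proportion to the difference between real and expected
#' input, so an active aLB cell is depressed away from silent visual cells
#' (the mechanism that disconnects cells from moved or vanished cues).
#' Setting `zeta > 1` strengthens the feedback term; its effect can be
#' compensated by scaling `eta` down and the feed-forward gain up.
#'
#' @param W list of per-channel weight matrices (`n_alb x n_vis`).
#' @param f_alb aLB rate vector.
#' @param vis `n_vis x n_features` visual rate matrix.
#' @param eta learning rate.
#' @param zeta feedback prefactor (>= 1).
#' @return the updated (entry-wise non-negative) weight list.
#' @export
mosa_update <- function(W, f_alb, vis, eta, zeta = 1) {
  act <- which(f_alb > 0)
  if (length(act) == 0) return(W)
  f_act <- f_alb[act]
  for (j in seq_along(W)) {
    # only rows of active cells change (the update carries a factor f_alb),
    # and untouched rows are already non-negative
    Wa <- W[[j]][act, , drop = FALSE]
    expected <- as.numeric(crossprod(Wa, f_act))
    Wa <- Wa + eta * tcrossprod(f_act, vis[, j] - zeta * expected)
    Wa[Wa < 0] <- 0
    W[[j]][act, ] <- Wa
  }
  W
}

#' Alternative plasticity rules for the comparison study
#'
#' Applies one of the published alternatives to the mOSA rule with the same
#' interface. `osa_original` is the subspace rule without the non-negativity
#' clip (weights may go negative); `hebb` is the pure outer-product term
#' (entries clipped to \[0, 1\] for numerical boundedness); `hebb_covariance`
#' centers both factors on running means (time constant `tau_mean`);
#' `intrator_bcm` uses the BCM form `f (f - theta_m) vis'` with a sliding
#' threshold `theta_m` tracking `<f^2>`.
#'
#' Rules with running state (`hebb_covariance`, `intrator_bcm`) keep it in
#' `attr(W, "rule_state")`.
#'
#' @param rule one of `"hebb"`, `"hebb_covariance"`, `"intrator_bcm"`,
#'   `"osa_original"`.
#' @inheritParams mosa_update
#' @param pars optional list: `tau_mean` (running-mean time constant in
#'   updates, default 200), `dt` ignored.
#' @return the updated weight list.
#' @export
alt_rule_update <- function(rule, W, f_alb, vis, eta, pars = list()) {
  rules <- c("hebb", "hebb_covariance", "intrator_bcm", "osa_original")
  if (!rule %in% rules) {
    stop("unknown rule; registered rules: ", paste(rules, collapse = ", "))
  }
  tau_mean <- if (is.null(pars$tau_mean)) 200 else pars$tau_mean
  st <- attr(W, "rule_state")
  if (rule == "osa_original") {
    for (j in seq_along(W)) {
      expected <- as.numeric(crossprod(W[[j]], f_alb))
      W[[j]] <- W[[j]] + eta * tcrossprod(f_alb, vis[, j] - expected)
    }
  } else if (rule == "hebb") {
    for (j in seq_along(W)) {
      W[[j]] <- pmin(pmax(W[[j]] + eta * tcrossprod(f_alb, vis[, j]), 0), 1)
    }
  } else if (rule == "hebb_covariance") {
    if (is.null(st)) {
      st <- list(f_mean = f_alb, v_mean = vis)
    }
    st$f_mean <- st$f_mean + (f_alb - st$f_mean) / tau_mean
    st$v_mean <- st$v_mean + (vis - st$v_mean) / tau_mean
    df <- f_alb - st$f_mean
    for (j in seq_along(W)) {
      W[[j]] <- pmin(pmax(W[[j]] + eta * tcrossprod(df, vis[, j] - st$v_mean[, j]), 0), 1)
    }
  } else { # intrator_bcm
    if (is.null(st)) st <- list(theta_m = rep(0.1, length(f_alb)))
    st$theta_m <- st$theta_m + (f_alb^2 - st$theta_m) / tau_mean
    phi <- f_alb * (f_alb - st$theta_m)
    for (j in seq_along(W)) {
      W[[j]] <- pmin(pmax(W[[j]] + eta * tcrossprod(phi, vis[, j]), 0), 1)
    }
  }
  attr(W, "rule_state") <- st
  W
}

#' Recruited cells from a rate log
#'
#' A cell is *recruited* during a test phase if its maximum firing rate
#' reaches the threshold `epsilon` (default 0.5).
#'
#' @param rate_log `n_steps x n_cells` matrix of rates.
#' @param epsilon recruitment threshold in \[0, 1\].
#' @return integer vector of recruited cell ids (possibly empty).
#' @export
recruit_report <- function(rate_log, epsilon = 0.5) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  peak <- apply(rate_log, 2, max)
  which(peak >= epsilon & peak > 0)
}
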