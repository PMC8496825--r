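# Protocol execution. The per-step loop exists twice: a compiled engine
# (src/run_phase.cpp) used for the standard mOSA/direct variants, and an R
# loop built from the exported primitives, used for the pluggable
# alternative learning rules and as a cross-check of the engine. Both paths
# draw from the RNG in the same order, so runs are reproducible either way.

# fused Hebbian update + row cap restricted to active postsynaptic rows
# (rows with zero post rate are unchanged and already satisfy the cap)
hebb_cap <- function(W, post, pre, eta, w_max) {
  ep <- eta * post
  act <- which(ep > 0)
  if (length(act) == 0) return(W)
  Wa <- W[act, , drop = FALSE] + tcrossprod(ep[act], pre)
  nrm <- sqrt(rowSums(Wa^2))
  over <- nrm > w_max
  if (any(over)) Wa[over, ] <- Wa[over, , drop = FALSE] * (w_max / nrm[over])
  W[act, ] <- Wa
  W
}

# one network step (R path); returns the updated network
network_step <- function(net, vis, omega, dt, learn = TRUE, feedback = TRUE) {
  p <- net$params
  extra <- NULL
  if (net$variant == "full") {
    net$alb <- alb_step(net$alb, vis, p$alb, dt,
                        noise_sd = if (learn) p$alb$noise_sd else 0,
                        kicks = learn)
    if (learn) {
      if (net$rule == "mosa") {
        net$alb$W <- mosa_update(net$alb$W, net$alb$f, vis,
                                 eta = p$alb$eta, zeta = p$alb$zeta)
      } else {
        net$alb$W <- alt_rule_update(net$rule, net$alb$W, net$alb$f, vis,
                                     eta = p$alb$eta)
      }
    }
    f_alb <- net$alb$f
  } else {
    f_alb <- numeric(net$n_alb)
    extra <- numeric(net$n_dirs)
    gv2d <- rep_len(p$direct$g_v2d, length(net$W_v2d))
    for (j in seq_along(net$W_v2d)) {
      extra <- extra + gv2d[j] * as.numeric(net$W_v2d[[j]] %*% vis[, j])
    }
  }
  fb <- if (feedback) net$rsc$drsc$f else NULL
  net$hd <- attractor_step(net$hd, omega, fb, dt)
  net$rsc <- grsc_step(net$rsc, net$hd$f, p, dt)
  net$rsc <- drsc_step(net$rsc, f_alb, p, dt, extra_drive = extra)
  if (learn) {
    pd <- p$drsc
    net$rsc$W_g2d <- hebb_cap(net$rsc$W_g2d, net$rsc$drsc$f, net$rsc$grsc$f,
                              pd$eta_g2d * net$eta_mask, pd$wmax_g2d)
    if (net$variant == "full") {
      net$rsc$W_a2d <- hebb_cap(net$rsc$W_a2d, net$rsc$drsc$f, f_alb,
                                pd$eta_a2d * net$eta_mask, pd$wmax_a2d)
    } else {
      # each per-channel connection matrix is capped separately
      for (j in seq_along(net$W_v2d)) {
        net$W_v2d[[j]] <- hebb_cap(net$W_v2d[[j]], net$rsc$drsc$f, vis[, j],
                                   p$direct$eta * net$eta_mask,
                                   p$direct$wmax)
      }
    }
  }
  net
}

# scene descriptor for the compiled engine
scene_spec <- function(net, scn, noise_amp) {
  p <- net$params$visual
  chan <- match(vapply(scn$cues, `[[`, character(1), "feature"),
                scn$features) - 1L
  dyn_code <- c(static = 0L, rotate = 1L, teleport = 2L, window = 3L)
  cues <- lapply(seq_along(scn$cues), function(i) {
    cu <- scn$cues[[i]]
    shape <- cue_shape(cu)
    if (cu$profile == "constant") shape <- shape / length(cu$centers)
    list(channel = chan[i], shape = shape, centers = cu$centers,
         dyn = dyn_code[[cu$dynamics]], speed = cu$speed,
         period = cu$period, t_on = cu$t_on, t_off = cu$t_off)
  })
  bg <- if (noise_amp > 0) {
    noise_amp * unimodal_profile(scn$theta, 0, p$noise_kappa, 1)
  } else {
    numeric(length(scn$theta))
  }
  list(cues = cues, n_channels = length(scn$features), bg = bg,
       target_mean = p$target_mean)
}

# run one phase over a trajectory slice; dispatches to the compiled engine
# unless an alternative aLB learning rule is active
run_phase <- function(net, scn, hd, omega, t0, dt, learn, feedback,
                      jitter_frac, noise_amp, log_every = 0,
                      keep = character(0), engine = c("auto", "cpp", "r")) {
  engine <- match.arg(engine)
  use_cpp <- engine == "cpp" ||
    (engine == "auto" && (net$variant == "direct" || net$rule == "mosa" ||
                            !learn))
  keep_flags <- c("alb", "hd", "grsc", "drsc") %in% keep
  if (use_cpp) {
    state <- list(
      a_alb = if (net$variant == "full") net$alb$a else numeric(net$n_alb),
      f_alb = if (net$variant == "full") net$alb$f else numeric(net$n_alb),
      a_hd = net$hd$a, f_hd = net$hd$f,
      a_g = net$rsc$grsc$a, f_g = net$rsc$grsc$f,
      a_d = net$rsc$drsc$a, f_d = net$rsc$drsc$f,
      W_g2d = net$rsc$W_g2d, W_a2d = net$rsc$W_a2d,
      Wsym = net$hd$W$sym, Wasym = net$hd$W$asym,
      # fresh list containers: the engine replaces their elements in place,
      # so they must not share a list SEXP with snapshots or the caller
      W_alb = if (net$variant == "full") lapply(net$alb$W, identity) else list(),
      W_v2d = if (net$variant == "direct") lapply(net$W_v2d, identity) else list(),
      eta_mask = net$eta_mask, theta = net$theta,
      kick_order = if (net$variant == "full") net$alb$kick_order else integer(0),
      kick_pos = if (net$variant == "full") net$alb$kick_pos else 0L,
      kick_ttl = if (net$variant == "full") net$alb$kick_ttl else 0L
    )
    res <- .cpp_run_phase(state, scene_spec(net, scn, noise_amp),
                          net$params, hd, omega, t0, dt, learn, feedback,
                          net$variant == "full", jitter_frac, noise_amp,
                          as.integer(log_every), keep_flags)
    if (net$variant == "full") {
      net$alb$a <- as.numeric(res$a_alb)
      net$alb$f <- as.numeric(res$f_alb)
      net$alb$W <- res$W_alb
      if (learn) {
        net$alb$kick_pos <- res$kick_pos
        net$alb$kick_ttl <- res$kick_ttl
      }
    } else {
      net$W_v2d <- res$W_v2d
    }
    net$hd$a <- as.numeric(res$a_hd)
    net$hd$f <- as.numeric(res$f_hd)
    net$rsc$grsc$a <- as.numeric(res$a_g)
    net$rsc$grsc$f <- as.numeric(res$f_g)
    net$rsc$drsc$a <- as.numeric(res$a_d)
    net$rsc$drsc$f <- as.numeric(res$f_d)
    net$rsc$W_g2d <- res$W_g2d
    net$rsc$W_a2d <- res$W_a2d
    for (i in seq_along(scn$cues)) {
      scn$cues[[i]]$centers <- as.numeric(res$cue_centers[[i]])
    }
    logs <- list()
    if (keep_flags[1]) logs$alb <- res$log_alb
    if (keep_flags[2]) logs$hd <- res$log_hd
    if (keep_flags[3]) logs$grsc <- res$log_g
    if (keep_flags[4]) logs$drsc <- res$log_d
    return(list(net = net, scn = scn, logs = logs,
                dec = data.frame(t = as.numeric(res$dec_t),
                                 true_hd = as.numeric(res$dec_true),
                                 decoded_hd = as.numeric(res$dec_hd))))
  }
  # R path
  p <- net$params
  T_ <- length(hd)
  logs <- list()
  if (keep_flags[1]) logs$alb <- matrix(0, T_, net$n_alb)
  if (keep_flags[2]) logs$hd <- matrix(0, T_, net$n_dirs)
  if (keep_flags[3]) logs$grsc <- matrix(0, T_, net$n_dirs)
  if (keep_flags[4]) logs$drsc <- matrix(0, T_, net$n_dirs)
  dec_t <- c(); dec_true <- c(); dec_hd <- c()
  for (k in seq_len(T_)) {
    t_now <- t0 + (k - 1) * dt
    scn <- advance_cues(scn, t_now, dt)
    vis <- channel_response(scn, hd[k], t = t_now,
                            target_mean = p$visual$target_mean,
                            noise_amp = noise_amp,
                            noise_kappa = p$visual$noise_kappa,
                            jitter_frac = jitter_frac)
    net <- network_step(net, vis, omega[k], dt, learn = learn,
                        feedback = feedback)
    if (keep_flags[1]) logs$alb[k, ] <- net$alb$f
    if (keep_flags[2]) logs$hd[k, ] <- net$hd$f
    if (keep_flags[3]) logs$grsc[k, ] <- net$rsc$grsc$f
    if (keep_flags[4]) logs$drsc[k, ] <- net$rsc$drsc$f
    if (log_every > 0 && k %% log_every == 0) {
      dec_t <- c(dec_t, t_now)
      dec_true <- c(dec_true, hd[k])
      dec_hd <- c(dec_hd,
                  tryCatch(population_vector(net$hd$f, net$theta),
                           error = function(e) NA_real_))
    }
  }
  list(net = net, scn = scn, logs = logs,
       dec = data.frame(t = dec_t, true_hd = dec_true, decoded_hd = dec_hd))
}

# extract the plastic weights
weight_snapshot <- function(net) {
  s <- list(W_g2d = net$rsc$W_g2d, W_a2d = net$rsc$W_a2d)
  if (net$variant == "full") s$W_alb <- net$alb$W else s$W_v2d <- net$W_v2d
  s
}

restore_weights <- function(net, snap) {
  net$rsc$W_g2d <- snap$W_g2d
  net$rsc$W_a2d <- snap$W_a2d
  if (net$variant == "full") net$alb$W <- snap$W_alb else net$W_v2d <- snap$W_v2d
  net
}

# frozen test phase on a copy of the network; returns representations.
# One warmup revolution lets the frozen network settle into its periodic
# response; the representation is built from the steady passes only.
run_test_phase <- function(net, scn, start_hd, spec, proto) {
  dt <- proto$dt
  warm <- 360 / 60
  duration <- proto$test_revs * warm + warm
  traj <- test_rotation(start_hd, speed = 60, duration = duration, dt = dt)
  noise_amp <- if (is.null(proto$noise_amp)) {
    net$params$visual$noise_amp
  } else {
    proto$noise_amp
  }
  res <- run_phase(net, scn, traj$hd, traj$omega, 0, dt,
                   learn = FALSE, feedback = TRUE, jitter_frac = 0,
                   noise_amp = noise_amp, log_every = 10,
                   keep = spec$layers)
  steady <- (round(warm / dt) + 1):length(traj$hd)
  logs <- lapply(res$logs, function(m) m[steady, , drop = FALSE])
  hd_steady <- traj$hd[steady]
  reps <- lapply(logs, build_representation, true_hd = hd_steady,
                 bins = net$n_dirs, epsilon = spec$epsilon)
  dec <- res$dec[res$dec$t >= warm, ]
  ok <- !is.na(dec$decoded_hd)
  he <- if (any(ok)) {
    heading_error(dec$decoded_hd[ok], dec$true_hd[ok])
  } else {
    c(mean = NA_real_, sem = NA_real_)
  }
  list(
    label = spec$label, scenery = scn$name, epsilon = spec$epsilon,
    reps = reps,
    recruited = if ("alb" %in% spec$layers) reps$alb$recruited else integer(0),
    heading = he
  )
}

#' Run a protocol
#'
#' Executes the learning/testing loop: for every step the trajectory
#' advances, cue dynamics advance, visual channels are computed, the aLB
#' layer (or the direct pathway) is updated with plasticity if the visit is
#' a learning phase, and the attractor/gRSC/dRSC loop is integrated with
#' dRSC feedback. After each visit its tests run on a frozen copy of the
#' network (so weights are bit-identical before and after every test), and
#' a weight snapshot is stored. All randomness derives from the protocol
#' seed, so a repeated run is exactly reproducible.
#'
#' @param proto an [hd_protocol].
#' @param network an [hd_network], or `NULL` to build one from `...`.
#' @param ... arguments passed to [hd_network] when `network` is `NULL`.
#' @param log_every keep every `log_every`-th step in the learning log.
#' @param engine `"auto"` (compiled engine where available), `"cpp"` or
#'   `"r"` (the reference loop built from the exported primitives).
#' @return an object of class `hd_run`: list with `tests` (named list of
#'   test results: representations, recruited sets, heading errors),
#'   `snapshots` (per-visit weight snapshots), `learn_log` (data frame of
#'   time, true and decoded HD during learning), `network` (final state)
#'   and `protocol`.
#' @export
run_protocol <- function(proto, network = NULL, ..., log_every = 20,
                         engine = "auto") {
  stopifnot(inherits(proto, "hd_protocol"))
  total <- sum(vapply(proto$visits, `[[`, numeric(1), "duration"))
  set.seed(proto$seed)
  if (is.null(network)) {
    network <- hd_network(..., seed = proto$seed)
  }
  net <- network
  dt <- proto$dt
  traj <- proto$trajectory
  if (is.null(traj)) {
    traj <- synth_trajectory(total, dt = dt, seed = proto$seed + 1000)
  }
  if (length(traj$hd) < round(total / dt)) {
    stop("trajectory shorter than the summed visit durations")
  }
  noise_amp <- if (is.null(proto$noise_amp)) {
    net$params$visual$noise_amp
  } else {
    proto$noise_amp
  }
  snapshots <- list()
  tests <- list()
  learn_log <- list()
  step0 <- 0
  for (vi in seq_along(proto$visits)) {
    v <- proto$visits[[vi]]
    scn <- v$scenery
    jit <- if (is.null(v$jitter_frac)) proto$jitter_frac else v$jitter_frac
    n_steps <- round(v$duration / dt)
    idx <- step0 + seq_len(n_steps)
    res <- run_phase(net, scn, traj$hd[idx], traj$omega[idx],
                     t0 = step0 * dt, dt = dt, learn = v$learn,
                     feedback = v$feedback, jitter_frac = jit,
                     noise_amp = noise_amp, log_every = log_every,
                     engine = engine)
    net <- res$net
    learn_log[[vi]] <- res$dec
    step0 <- step0 + n_steps
    snapshots[[vi]] <- weight_snapshot(net)
    hd_now <- traj$hd[step0]
    for (ts in v$tests) {
      out <- execute_test(net, ts, res$scn, hd_now, snapshots, proto)
      tests[[out$label]] <- out
    }
  }
  hd_end <- traj$hd[min(step0, length(traj$hd))]
  last_scn <- proto$visits[[length(proto$visits)]]$scenery
  for (ts in proto$final_tests) {
    out <- execute_test(net, ts, last_scn, hd_end, snapshots, proto)
    tests[[out$label]] <- out
  }
  structure(
    list(tests = tests, snapshots = snapshots,
         learn_log = do.call(rbind, learn_log),
         network = net, protocol = proto),
    class = "hd_run"
  )
}

# resolve a test spec (scenery default + snapshot weights) and run it
execute_test <- function(net, ts, current_scn, hd_now, snapshots, proto) {
  scn <- if (is.null(ts$scenery)) freeze_cues(current_scn) else ts$scenery
  if (!identical(ts$weights, "current")) {
    net <- restore_weights(net, snapshots[[ts$weights]])
  }
  run_test_phase(net, scn, hd_now, ts, proto)
}

# stop all cue dynamics at the current centers
freeze_cues <- function(scn) {
  scn$cues <- lapply(scn$cues, function(cu) {
    cu$dynamics <- "static"
    cu
  })
  scn
}

#' @export
print.hd_run <- function(x, ...) {
  cat(sprintf("<hd_run> \"%s\": %d visit(s), %d test(s)\n",
              x$protocol$name, length(x$snapshots), length(x$tests)))
  for (nm in names(x$tests)) {
    tst <- x$tests[[nm]]
    cat(sprintf("  %-24s scenery %-16s recruited %3d  heading %6.2f deg\n",
                nm, tst$scenery, length(tst$recruited),
                tst$heading[["mean"]]))
  }
  invisible(x)
}

#' @export
summary.hd_run <- function(object, ...) {
  res <- lapply(names(object$tests), function(nm) {
    tst <- object$tests[[nm]]
    lobes <- NA_integer_
    uni <- NA
    if (!is.null(tst$reps$alb) && length(tst$recruited) > 0) {
      sc <- lapply(tst$recruited, function(i) {
        unimodality_score(tst$reps$alb$tuning[i, ], tst$epsilon)
      })
      lobes <- mean(vapply(sc, `[[`, integer(1), "n_lobes"))
      uni <- all(vapply(sc, `[[`, logical(1), "is_unimodal"))
    }
    data.frame(test = nm, scenery = tst$scenery,
               recruited = length(tst$recruited),
               mean_lobes = lobes, all_unimodal = uni,
               heading_mean = tst$heading[["mean"]],
               heading_sem = tst$heading[["sem"]])
  })
  do.call(rbind, res)
}
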