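# Builders for the standard experiment sceneries and protocols.
# Allocentric convention: 0 = East, 90 = North, -90 = South, +-180 = West,
# anticlockwise positive.

#' Standard sceneries
#'
#' `scenery_conflict()` is the canonical complex scenery: an ambiguous
#' narrow "red" cue pair due North and due South (indistinguishable at the
#' sensory level, hence a bimodal channel) plus a broad, unambiguous "blue"
#' cue due East; a "green" channel is declared but silent. It is the setting
#' in which only the laterally inhibited subspace rule extracts a unimodal
#' landmark-bearing code.
#'
#' @param n_dirs neurons per channel.
#' @param pars visual parameter list (see [hd_params]).
#' @return an [scenery].
#' @export
scenery_conflict <- function(n_dirs = 120, pars = hd_params()$visual) {
  scenery(
    "conflict", list(
      cue("red", "bimodal", centers = c(90, -90), kappa = pars$kappa_narrow),
      cue("blue", "broad", centers = 0, kappa = pars$kappa_broad,
          width = pars$broad_width)
    ),
    n_dirs = n_dirs, features = c("red", "green", "blue")
  )
}

#' @rdname scenery_conflict
#' @param green_at allocentric direction of the distinguishing green cue.
#' @export
scenery_capacity <- function(green_at = 180, n_dirs = 120,
                             pars = hd_params()$visual) {
  scenery(
    sprintf("capacity@%d", round(wrap_angle(green_at))), list(
      cue("red", "unimodal", centers = 90, kappa = pars$kappa_narrow),
      cue("blue", "broad", centers = 0, kappa = pars$kappa_broad,
          width = pars$broad_width),
      cue("green", "unimodal", centers = green_at, kappa = pars$kappa_green)
    ),
    n_dirs = n_dirs, features = c("red", "green", "blue")
  )
}

#' @rdname scenery_conflict
#' @export
scenery_dark <- function(n_dirs = 120) {
  scenery("darkness", list(), n_dirs = n_dirs,
          features = c("red", "green", "blue"))
}

#' Scenario library
#'
#' Returns a fully parameterized protocol for one of the named experiment
#' scenarios. Durations default to scaled-down values that preserve the
#' dynamical regime (see the vignette); pass `dwell`/`duration` to change
#' them. HD continuity across environment transitions is inherent: one
#' continuous trajectory spans all visits.
#'
#' Registered scenarios:
#' \describe{
#'   \item{conflict_scene}{single complex scenery, learn then standard test.}
#'   \item{moving_cue}{blue cue rotating at 90 deg/s during learning;
#'     tests on the unstable scenery (eps = 0) and on the frozen scenery.}
#'   \item{teleporting_cue}{blue cue teleporting every 10 s; same tests.}
#'   \item{novel_cue}{red-blue, then red-blue-green, then red-blue again;
#'     final tests on all three cue configurations.}
#'   \item{capacity}{`n_env` environments sharing red/blue, green cue
#'     advanced 36 deg anticlockwise per environment; intermediate test
#'     after each visit plus final tests on every environment.}
#'   \item{mirrored}{two 180-degree-mirrored sceneries alternated.}
#'   \item{darkness}{no visual input; run open loop to expose path
#'     integration drift (use a path-integration gain != 1).}
#'   \item{scene_rotation}{conflict scenery, then the whole scenery rotated
#'     120 deg anticlockwise; HD-layer tests after each phase.}
#'   \item{multi_env_retrieval}{the capacity sequence with HD-layer tests per
#'     environment (heading-retrieval errors).}
#'   \item{rich_capacity}{`n_env` (default 20) environments, 3 cues drawn
#'     from 6 features at random directions.}
#'   \item{capacity_noise}{capacity with 5 percent uniform input noise.}
#' }
#'
#' @param name scenario name (see above).
#' @param n_dirs ring / channel size.
#' @param dwell dwell time per environment visit in seconds (scenario-
#'   specific default when `NULL`).
#' @param n_env number of environments (capacity scenarios).
#' @param seed protocol seed.
#' @param test_revs revolutions per test rotation.
#' @param pars parameter list, for scenery construction defaults.
#' @return an [hd_protocol].
#' @export
scenario_library <- function(name, n_dirs = 120, dwell = NULL, n_env = 10,
                             seed = 1, test_revs = 2, pars = hd_params()) {
  pv <- pars$visual
  reg <- c("conflict_scene", "moving_cue", "teleporting_cue", "novel_cue",
           "capacity", "mirrored", "darkness",
           "scene_rotation", "multi_env_retrieval", "rich_capacity", "capacity_noise")
  if (!name %in% reg) {
    stop("unknown scenario \"", name, "\"; registered: ",
         paste(reg, collapse = ", "))
  }
  base <- scenery_conflict(n_dirs, pv)
  proto <- switch(name,
    conflict_scene = {
      d <- if (is.null(dwell)) 300 else dwell
      hd_protocol(list(list(
        scenery = base, duration = d,
        tests = list(test_spec(label = "conflict"))
      )), seed = seed, test_revs = test_revs, name = name)
    },
    moving_cue = ,
    teleporting_cue = {
      d <- if (is.null(dwell)) 60 else dwell
      blue <- if (name == "moving_cue") {
        cue("blue", "broad", centers = 0, kappa = pv$kappa_broad,
            width = pv$broad_width, dynamics = "rotate", speed = 90)
      } else {
        cue("blue", "broad", centers = 0, kappa = pv$kappa_broad,
            width = pv$broad_width, dynamics = "teleport", period = 10)
      }
      scn <- scenery("unstable-blue", list(
        cue("red", "bimodal", centers = c(90, -90), kappa = pv$kappa_narrow),
        blue
      ), n_dirs = n_dirs, features = c("red", "green", "blue"))
      hd_protocol(list(
        list(scenery = scn, duration = d,
             tests = list(test_spec(label = "early_frozen"))),
        list(scenery = scn, duration = d,
             tests = list(
               test_spec(label = "unstable", scenery = scn, epsilon = 0),
               test_spec(label = "frozen")
             ))
      ), seed = seed, test_revs = test_revs, name = name)
    },
    novel_cue = {
      d <- if (is.null(dwell)) 120 else dwell
      rb <- base
      rbg <- scenery("red-blue-green", c(base$cues, list(
        cue("green", "unimodal", centers = 180, kappa = pv$kappa_green)
      )), n_dirs = n_dirs, features = base$features)
      gonly <- scenery("green-only", list(
        cue("green", "unimodal", centers = 180, kappa = pv$kappa_green)
      ), n_dirs = n_dirs, features = base$features)
      hd_protocol(list(
        list(scenery = rb, duration = d),
        list(scenery = rbg, duration = d),
        list(scenery = rb, duration = d)
      ), final_tests = list(
        test_spec(scenery = rb, label = "red_blue"),
        test_spec(scenery = rbg, label = "red_blue_green"),
        test_spec(scenery = gonly, label = "green_only")
      ), seed = seed, test_revs = test_revs, name = name)
    },
    capacity = ,
    capacity_noise = ,
    multi_env_retrieval = {
      d <- if (is.null(dwell)) 60 else dwell
      layers <- if (name == "multi_env_retrieval") c("alb", "hd", "drsc") else "alb"
      envs <- lapply(seq_len(n_env), function(k) {
        scenery_capacity(180 + (k - 1) * 36, n_dirs, pv)
      })
      visits <- lapply(seq_len(n_env), function(k) {
        list(scenery = envs[[k]], duration = d,
             tests = list(test_spec(
               label = sprintf("intermediate_%02d", k), layers = layers)))
      })
      finals <- lapply(seq_len(n_env), function(k) {
        test_spec(scenery = envs[[k]], label = sprintf("final_%02d", k),
                  layers = layers)
      })
      hd_protocol(visits, final_tests = finals, seed = seed,
                  jitter_frac = if (name == "capacity_noise") 0.05 else 0,
                  test_revs = test_revs, name = name)
    },
    mirrored = {
      d <- if (is.null(dwell)) 30 else dwell
      env2 <- rotate_scenery(base, 180)
      env2$name <- "conflict-mirrored"
      n_alt <- 8
      visits <- lapply(seq_len(n_alt), function(k) {
        list(scenery = if (k %% 2 == 1) base else env2, duration = d)
      })
      visits[[n_alt]]$tests <- list(
        test_spec(scenery = base, label = "single_env",
                  layers = c("alb", "grsc", "drsc"))
      )
      hd_protocol(visits, seed = seed, test_revs = test_revs, name = name)
    },
    darkness = {
      d <- if (is.null(dwell)) 120 else dwell
      hd_protocol(list(list(
        scenery = scenery_dark(n_dirs), duration = d, feedback = FALSE
      )), noise_amp = 0, seed = seed, test_revs = test_revs, name = name)
    },
    scene_rotation = {
      d <- if (is.null(dwell)) 300 else dwell
      env2 <- rotate_scenery(base, 120)
      env2$name <- "conflict+120"
      hd_protocol(list(
        list(scenery = base, duration = d,
             tests = list(test_spec(label = "env1",
                                    layers = c("alb", "hd", "drsc")))),
        list(scenery = env2, duration = d,
             tests = list(test_spec(label = "env2",
                                    layers = c("alb", "hd", "drsc"))))
      ), seed = seed, test_revs = test_revs, name = name)
    },
    rich_capacity = {
      d <- if (is.null(dwell)) 60 else dwell
      if (missing(n_env)) n_env <- 20
      feats <- c("red", "green", "blue", "yellow", "cyan", "magenta")
      envs <- with_seed(seed * 131 + 7, lapply(seq_len(n_env), function(k) {
        picked <- sample(feats, 3)
        dirs <- stats::runif(3, -180, 180)
        scenery(sprintf("rich%02d", k), lapply(1:3, function(i) {
          cue(picked[i], "unimodal", centers = dirs[i],
              kappa = pv$kappa_narrow)
        }), n_dirs = n_dirs, features = feats)
      }))
      visits <- lapply(seq_len(n_env), function(k) {
        list(scenery = envs[[k]], duration = d,
             tests = list(test_spec(label = sprintf("intermediate_%02d", k))))
      })
      finals <- lapply(seq_len(n_env), function(k) {
        test_spec(scenery = envs[[k]], label = sprintf("final_%02d", k))
      })
      hd_protocol(visits, final_tests = finals, seed = seed,
                  test_revs = test_revs, name = name)
    }
  )
  proto
}

#' @rdname scenario_library
#' @export
list_scenarios <- function() {
  c("conflict_scene", "moving_cue", "teleporting_cue", "novel_cue",
    "capacity", "mirrored", "darkness", "scene_rotation",
    "multi_env_retrieval", "rich_capacity", "capacity_noise")
}
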