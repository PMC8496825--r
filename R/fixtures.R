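# Miniature deterministic inputs and run digests for fast testing.

#' Miniature world
#'
#' A scaled-down twin of the canonical conflict experiment: 36-neuron
#' channels (10-degree resolution), the bimodal-red + broad-blue scenery and
#' a short synthetic trajectory. Runs the full pipeline in seconds while
#' preserving the dynamical regime (dt and gains unchanged).
#'
#' @param seed integer seed.
#' @param duration trajectory length in seconds.
#' @param n_dirs channel size (>= 36).
#' @return list with elements `scenery`, `trajectory`, `protocol`.
#' @export
mini_world <- function(seed = 1, duration = 60, n_dirs = 36) {
  stopifnot(n_dirs >= 36)
  scn <- scenery_conflict(n_dirs)
  proto <- hd_protocol(list(list(
    scenery = scn, duration = duration,
    tests = list(test_spec(label = "conflict"))
  )), seed = seed, test_revs = 1, name = "mini_world")
  list(
    scenery = scn,
    trajectory = synth_trajectory(duration, dt = proto$dt,
                                  seed = seed + 1000),
    protocol = proto
  )
}

#' Similarity map over recruited sets
#'
#' IoU matrix between two lists of recruited-cell sets, e.g. the
#' environment-by-environment similarity maps of the capacity experiments.
#'
#' @param sets_a,sets_b lists of integer vectors (recruited cell ids).
#' @return `length(sets_a) x length(sets_b)` matrix of IoU values.
#' @export
iou_map <- function(sets_a, sets_b = sets_a) {
  m <- matrix(0, length(sets_a), length(sets_b))
  for (i in seq_along(sets_a)) {
    for (j in seq_along(sets_b)) {
      m[i, j] <- iou(sets_a[[i]], sets_b[[j]])
    }
  }
  m
}

# recruited sets from a run's tests whose labels match a prefix
recruited_sets <- function(run, prefix) {
  labs <- grep(paste0("^", prefix), names(run$tests), value = TRUE)
  lapply(run$tests[sort(labs)], `[[`, "recruited")
}

#' Compact digest of a run
#'
#' A JSON-serializable summary for regression comparison: per-test recruited
#' counts, lobe counts and heading errors, plus the IoU diagonal and
#' off-diagonal means where the run contains intermediate/final capacity
#' tests. The digest of a seeded run equals the digest of its repeat.
#'
#' @param run an `hd_run`.
#' @return a named list (digest).
#' @export
golden_summary <- function(run) {
  s <- summary(run)
  per_test <- lapply(seq_len(nrow(s)), function(i) {
    list(
      test = s$test[i], scenery = s$scenery[i],
      recruited = s$recruited[i],
      mean_lobes = if (is.na(s$mean_lobes[i])) NULL else s$mean_lobes[i],
      all_unimodal = if (is.na(s$all_unimodal[i])) NULL else s$all_unimodal[i],
      heading_mean = if (is.na(s$heading_mean[i])) NULL else round(s$heading_mean[i], 4)
    )
  })
  digest <- list(protocol = run$protocol$name, seed = run$protocol$seed,
                 tests = per_test)
  inter <- recruited_sets(run, "intermediate_")
  fin <- recruited_sets(run, "final_")
  if (length(inter) > 0 && length(fin) == length(inter)) {
    m_ff <- iou_map(fin)
    digest$iou <- list(
      final_diag_mean = mean(diag(m_ff)),
      final_offdiag_mean = mean(m_ff[row(m_ff) != col(m_ff)]),
      intermediate_vs_final_diag = diag(iou_map(inter, fin))
    )
  }
  digest
}

#' @rdname golden_summary
#' @param digest a digest from `golden_summary`.
#' @param path output JSON path.
#' @export
write_golden_summary <- function(digest, path) {
  jsonlite::write_json(digest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
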