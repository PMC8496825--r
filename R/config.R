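# Declarative scenery / protocol configuration (YAML).

#' Read a scenery from a YAML configuration
#'
#' The YAML layout mirrors the [scenery]/[cue] constructors:
#' ```yaml
#' name: conflict
#' n_dirs: 120
#' features: [red, green, blue]
#' cues:
#'   - {feature: red, profile: bimodal, centers: [90, -90], kappa: 20}
#'   - {feature: blue, profile: broad, centers: 0, kappa: 20, width: 90}
#' ```
#'
#' @param path YAML file path.
#' @return an [scenery].
#' @export
read_scenery <- function(path) {
  cfg <- yaml::read_yaml(path)
  cues <- lapply(cfg$cues, function(cu) do.call(cue, cu))
  scenery(
    name = if (is.null(cfg$name)) basename(path) else cfg$name,
    cues = cues,
    n_dirs = if (is.null(cfg$n_dirs)) 120 else cfg$n_dirs,
    features = if (is.null(cfg$features)) NULL else unlist(cfg$features)
  )
}

#' @rdname read_scenery
#' @param scn an [scenery].
#' @export
write_scenery <- function(scn, path) {
  cfg <- list(
    name = scn$name, n_dirs = scn$n_dirs, features = as.list(scn$features),
    cues = lapply(scn$cues, function(cu) {
      cu <- unclass(cu)
      cu[!vapply(cu, is.null, logical(1))]
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
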