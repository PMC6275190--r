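#' Read a network specification from a YAML file
#'
#' The file is a key-value tree with `step_ms`, `populations` (list of
#' `id`, `size`, `model`, `params`) and `projections` (list of `name`,
#' `src`, `tgt`, `pre`, `post`, `weight`, `delay`, `plasticity`, `w_max`);
#' see `inst/extdata/example-network.yaml` for a worked example.
#'
#' @param path YAML file path.
#' @return a `cabot_network` built with [build_network()].
#' @export
read_network_config <- function(path) {
  build_network(yaml::read_yaml(path))
}

#' Read / write a world specification as YAML
#'
#' @param path YAML file path.
#' @param spec a [world_spec()] list.
#' @return `read_world_config` returns a `cabot_world`;
#'   `write_world_config` returns `path` invisibly.
#' @export
read_world_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- world_spec()
  for (nm in intersect(names(raw), c("width", "height", "corridor_color",
                                     "start")))
    spec[[nm]] <- raw[[nm]]
  if (!is.null(raw$rooms))
    spec$rooms <- lapply(raw$rooms, function(r) unlist(r)[c("x0", "y0", "x1", "y1")])
  if (!is.null(raw$corridors))
    spec$corridors <- lapply(raw$corridors, function(r) unlist(r)[c("x0", "y0", "x1", "y1")])
  if (!is.null(raw$shapes))
    spec$shapes <- do.call(rbind, lapply(raw$shapes, as.data.frame))
  build_world(spec)
}

#' @rdname read_world_config
#' @export
write_world_config <- function(spec, path) {
  if (inherits(spec, "cabot_world")) spec <- spec$spec
  out <- list(width = spec$width, height = spec$height,
              rooms = lapply(spec$rooms, as.list),
              corridors = lapply(spec$corridors, as.list),
              shapes = lapply(seq_len(nrow(spec$shapes)), function(i)
                as.list(spec$shapes[i, ])),
              corridor_color = spec$corridor_color,
              start = spec$start)
  yaml::write_yaml(out, path)
  invisible(path)
}
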