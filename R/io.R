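# Plain-text readers/writers for cubes, trajectories and signals, plus the
# YAML pipeline configuration.

cube_header_marker <- "# jvpradar_cube v1"
signal_header_marker <- "# jvpradar_signal v1"

#' Write a radar data cube to a self-describing text file
#'
#' Comment header carrying the radar configuration (JSON) and cube shape,
#' followed by one flattened sample per line in [flatten_cube()] order.
#'
#' @param cube a [radar_cube()].
#' @param path output file.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "radar_cube"))
  cfg_json <- jsonlite::toJSON(unclass(cube$config), auto_unbox = TRUE, digits = NA)
  header <- c(cube_header_marker,
              paste0("# config: ", cfg_json),
              paste0("# frames: ", dim(cube$values)[1]))
  writeLines(header, path)
  data.table::fwrite(data.table::data.table(value = flatten_cube(cube)),
                     path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a radar data cube written by [write_cube()]
#'
#' @param path input file.
#' @return A [radar_cube()].
#' @export
read_cube <- function(path) {
  head_lines <- readLines(path, n = 3L)
  if (length(head_lines) < 3L || head_lines[1] != cube_header_marker)
    stop(sprintf("'%s' is not a jvpradar cube file (missing '%s' marker)",
                 path, cube_header_marker), call. = FALSE)
  if (!startsWith(head_lines[2], "# config: "))
    stop(sprintf("malformed cube file '%s': missing config header", path),
         call. = FALSE)
  cfg <- jsonlite::fromJSON(sub("^# config: ", "", head_lines[2]))
  config <- do.call(radar_config, cfg)
  dt <- data.table::fread(path, skip = 3L, header = TRUE)
  if (!"value" %in% names(dt))
    stop(sprintf("malformed cube file '%s': missing 'value' column", path),
         call. = FALSE)
  reshape_raw(dt$value, config)
}

#' Write a 1-D signal or trajectory to CSV
#'
#' Two columns (`time_s`, `value_m`) under a comment header recording the
#' sample rate.
#'
#' @param sig a `displacement_signal` or [displacement_trajectory()].
#' @param path output file.
#' @export
write_signal <- function(sig, path) {
  if (!inherits(sig, c("displacement_signal", "displacement_trajectory")))
    stop("sig must be a displacement_signal or displacement_trajectory",
         call. = FALSE)
  writeLines(c(signal_header_marker,
               paste0("# sample_rate: ", format(sig$sample_rate, digits = 15))),
             path)
  n <- length(sig$values)
  data.table::fwrite(
    data.table::data.table(time_s = (seq_len(n) - 1) / sig$sample_rate,
                           value_m = sig$values),
    path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a signal written by [write_signal()]
#'
#' @param path input file.
#' @return A [displacement_trajectory()].
#' @export
read_signal <- function(path) {
  head_lines <- readLines(path, n = 2L)
  if (length(head_lines) < 2L || head_lines[1] != signal_header_marker)
    stop(sprintf("'%s' is not a jvpradar signal file (missing '%s' marker)",
                 path, signal_header_marker), call. = FALSE)
  if (!startsWith(head_lines[2], "# sample_rate: "))
    stop(sprintf("malformed signal file '%s': missing sample_rate header", path),
         call. = FALSE)
  rate <- as.numeric(sub("^# sample_rate: ", "", head_lines[2]))
  dt <- data.table::fread(path, skip = 2L, header = TRUE,
                          colClasses = list(character = 1:2))
  vals <- suppressWarnings(as.numeric(dt$value_m))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric value in '%s' at data line %d", path, bad),
         call. = FALSE)
  }
  displacement_trajectory(rate, vals)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; the nested `radar`,
#' `scene`, `jvp` and `filters` maps take the corresponding constructor
#' arguments.  Unknown keys at any level are rejected rather than silently
#' dropped.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys <- function(got, fn, where) {
    allowed <- names(formals(fn))
    unknown <- setdiff(names(got), allowed)
    if (length(unknown) > 0L)
      stop(sprintf("unknown key%s in %s config: %s",
                   if (length(unknown) > 1) "s" else "", where,
                   paste(unknown, collapse = ", ")), call. = FALSE)
  }
  check_keys(raw, pipeline_config, "pipeline")
  args <- raw
  for (nm in c(radar = "radar", scene = "scene", jvp = "jvp",
               filters = "filters")) {
    if (!is.null(raw[[nm]])) {
      fn <- switch(nm, radar = radar_config, scene = scene_spec,
                   jvp = jvp_waveform_spec, filters = filter_spec)
      check_keys(raw[[nm]], fn, nm)
      sub <- raw[[nm]]
      # named numeric vectors arrive as YAML maps
      sub <- lapply(sub, function(v) if (is.list(v)) unlist(v) else v)
      args[[nm]] <- do.call(fn, sub)
    }
  }
  do.call(pipeline_config, args)
}
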