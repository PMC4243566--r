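# Plain-text interchange formats: spike-event CSV (`time,channel`), label CSV
# (`onset,pattern_id`), YAML run configs keyed by the reference parameter
# names, and a JSON run manifest. Round trips are bit-exact because every
# field is an integer.

#' Write / read spike events as CSV
#'
#' The event format is a two-column CSV with header `time,channel`:
#' non-negative integer step index and 1-based channel, one event per row.
#' Reading sorts by time and validates every field; writing then reading
#' recovers the stream's events exactly.
#'
#' @param stream a `skan_stream` (or bare data.frame with `time`, `channel`).
#' @param path file path.
#' @return `read_events()` returns a `skan_stream`; `write_events()` returns
#'   `path` invisibly.
#' @param T presentation period to attach to the read stream.
#' @param n_channels channel count; inferred from the data when `NULL`.
#' @param duration total steps; inferred when `NULL`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' set.seed(1)
#' st <- build_sequence(list(make_target_pattern(2, 20)), 1, 5, T = 100)
#' write_events(st, f)
#' st2 <- read_events(f, T = 100)
#' identical(st$events, st2$events)
#' @export
write_events <- function(stream, path) {
  ev <- if (inherits(stream, "skan_stream")) stream$events else stream
  stopifnot(is.data.frame(ev), all(c("time", "channel") %in% names(ev)))
  write.csv(ev[, c("time", "channel")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, T = 400L, n_channels = NULL, duration = NULL) {
  df <- read.csv(path, colClasses = "character")
  if (!identical(names(df), c("time", "channel")))
    stop("expected CSV header 'time,channel'")
  bad <- which(!grepl("^[0-9]+$", df$time) | !grepl("^[0-9]+$", df$channel))
  if (length(bad))
    stop(sprintf("non-integer or negative field at row %d", bad[1]))
  ev <- data.frame(time = as.integer(df$time), channel = as.integer(df$channel))
  if (nrow(ev) && any(ev$channel < 1L))
    stop("channels are 1-based; found channel < 1")
  ev <- ev[order(ev$time, ev$channel), , drop = FALSE]
  rownames(ev) <- NULL
  if (is.null(n_channels)) n_channels <- if (nrow(ev)) max(ev$channel) else 1L
  if (is.null(duration)) {
    duration <- if (nrow(ev)) {
      as.integer(ceiling((max(ev$time) + 1L) / T) * T)
    } else {
      as.integer(T)
    }
  }
  .new_stream(ev, NULL, T, duration, n_channels)
}

#' Write / read presentation labels as CSV
#'
#' Ground-truth labels in a CSV with header `onset,pattern_id`.
#'
#' @param labels data.frame with columns `onset` and `pattern_id` (a
#'   `skan_stream` is also accepted).
#' @param path file path.
#' @return `read_labels()` returns the data.frame; `write_labels()` returns
#'   `path` invisibly.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "skan_stream")) labels <- labels$labels
  stopifnot(is.data.frame(labels),
            all(c("onset", "pattern_id") %in% names(labels)))
  write.csv(labels[, c("onset", "pattern_id")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read.csv(path)
  if (!all(c("onset", "pattern_id") %in% names(df)))
    stop("expected CSV header 'onset,pattern_id'")
  data.frame(onset = as.integer(df$onset),
             pattern_id = as.integer(df$pattern_id))
}

#' Read a run configuration
#'
#' Flat YAML file keyed by the reference parameter names (`w`, `ddr`,
#' `dr_max`, `theta_rise`, `theta_fall`, `inh_max`, `inh_decay`, `T`,
#' `n_inputs`, `n_neurons`, `PW`, noise fields `sigma`, `p_signal`,
#' `noise_rate`, and experiment sizes). Unspecified keys take the package
#' defaults; `theta_rise`/`theta_fall` default to their per-input scaling.
#'
#' @param path YAML file path.
#' @return list with elements `params` ([skan_params()]), `net`
#'   ([net_params()]), and the remaining scalar settings.
#' @export
read_skan_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed config: expected a YAML mapping")
  n_inputs <- as.integer(cfg$n_inputs %||% 2L)
  args <- list(n_inputs = n_inputs)
  for (f in c("w", "ddr", "dr_max", "dr_floor", "theta_rise", "theta_fall",
              "theta_init"))
    if (!is.null(cfg[[f]])) args[[f]] <- as.integer(cfg[[f]])
  if (!is.null(cfg$dr_init)) args$dr_init <- as.integer(cfg$dr_init)
  params <- do.call(skan_params, args)
  net <- net_params(as.integer(cfg$n_neurons %||% 1L),
                    as.integer(cfg$inh_max %||% 100L),
                    as.integer(cfg$inh_decay %||% 1L))
  rest <- cfg[setdiff(names(cfg), c("w", "ddr", "dr_max", "dr_floor",
                                    "theta_rise", "theta_fall", "theta_init",
                                    "dr_init", "n_inputs", "n_neurons",
                                    "inh_max", "inh_decay"))]
  defaults <- list(T = 400L, PW = 20L, sigma = 0, p_signal = 1,
                   noise_rate = 0, n_presentations = 300L, n_simulations = 100L)
  for (nm in names(defaults))
    if (is.null(rest[[nm]])) rest[[nm]] <- defaults[[nm]]
  c(list(params = params, net = net), rest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run bit-exactly: configuration
#' snapshot, master seed, package version, timestamps and the output file
#' inventory.
#'
#' @param path output JSON path.
#' @param config list of configuration values (serialisable).
#' @param seed master seed used for the run.
#' @param files character vector of output files written.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, files = character(0)) {
  man <- list(config = config, seed = seed,
              package = "skan",
              version = as.character(utils::packageVersion("skan")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              files = files)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
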