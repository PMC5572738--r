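#' Fluorescence assay trace
#'
#' A time-stamped fluorescence series with labelled event markers
#' (dithionite addition, light on/off, reagent additions).
#'
#' @param time Strictly increasing time grid in seconds.
#' @param fluorescence Fluorescence in arbitrary units, finite, same length
#'   as `time`.
#' @param events Data frame with columns `label` (character) and `time`
#'   (seconds, within the trace time range), or NULL.
#' @param meta Optional named list of provenance/quality information
#'   (e.g. out-of-calibration flags set by simulators or converters).
#' @return An object of class `assay_trace`.
#' @export
assay_trace <- function(time, fluorescence, events = NULL, meta = list()) {
  stopifnot(is.numeric(time), is.numeric(fluorescence))
  if (length(time) != length(fluorescence)) {
    stop("time and fluorescence must have the same length", call. = FALSE)
  }
  if (length(time) < 2L || any(diff(time) <= 0)) {
    stop("time must be a strictly increasing grid", call. = FALSE)
  }
  if (!all(is.finite(fluorescence))) {
    stop("fluorescence must be finite", call. = FALSE)
  }
  if (is.null(events)) {
    events <- data.frame(label = character(), time = numeric())
  }
  stopifnot(is.data.frame(events), all(c("label", "time") %in% names(events)))
  if (nrow(events) > 0 &&
      (any(events$time < min(time)) || any(events$time > max(time)))) {
    stop("event times must lie within the trace time range", call. = FALSE)
  }
  structure(list(time = time, fluorescence = fluorescence,
                 events = events, meta = meta),
            class = "assay_trace")
}

#' @export
print.assay_trace <- function(x, ...) {
  cat(sprintf("Assay trace: %d samples, t = [%.1f, %.1f] s\n",
              length(x$time), min(x$time), max(x$time)))
  if (nrow(x$events) > 0) {
    cat("Events:\n")
    for (i in seq_len(nrow(x$events))) {
      cat(sprintf("  %-22s t = %.1f s\n", x$events$label[i], x$events$time[i]))
    }
  }
  invisible(x)
}

#' Look up an event time on a trace
#'
#' @param trace An [assay_trace()].
#' @param label Event label to find (e.g. "dithionite_addition").
#' @return The event time in seconds; errors if the label is absent.
#' @export
event_time <- function(trace, label) {
  stopifnot(inherits(trace, "assay_trace"))
  hit <- trace$events$time[trace$events$label == label]
  if (length(hit) == 0) {
    stop(sprintf("trace has no '%s' event marker", label), call. = FALSE)
  }
  hit[1]
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations route
# through this so no generator mutates global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
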