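#' Read and write assay traces and titrations as CSV
#'
#' Traces are stored as a two-column CSV (`time_s`, `fluorescence_au`)
#' with event markers in a JSON sidecar named `<path>` with the `.csv`
#' extension replaced by `.events.json`. Titrations use columns
#' `ppr_g_per_mol` and `reduction_pct`.
#'
#' @param trace An [assay_trace()].
#' @param path Output CSV path.
#' @return `write_assay_trace()` invisibly returns `path`;
#'   `read_assay_trace()` returns an [assay_trace()].
#' @name trace_io
NULL

events_sidecar <- function(path) sub("\\.csv$", "", path) |>
  paste0(".events.json")

#' @rdname trace_io
#' @export
write_assay_trace <- function(trace, path) {
  stopifnot(inherits(trace, "assay_trace"))
  utils::write.csv(
    data.frame(time_s = trace$time, fluorescence_au = trace$fluorescence),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(events = trace$events, meta = trace$meta),
    events_sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_assay_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- utils::read.csv(path)
  need <- c("time_s", "fluorescence_au")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop(sprintf("trace CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  events <- NULL
  meta <- list()
  sc <- events_sidecar(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(side$events) && length(side$events) > 0) {
      events <- as.data.frame(side$events)
    }
    if (!is.null(side$meta)) meta <- as.list(side$meta)
  }
  assay_trace(d$time_s, d$fluorescence_au, events = events, meta = meta)
}

#' @rdname trace_io
#' @param titration Data frame with columns `ppr` and `F` (percent
#'   reduction), e.g. from [generate_ppr_series()].
#' @export
write_titration <- function(titration, path) {
  stopifnot(is.data.frame(titration), all(c("ppr", "F") %in% names(titration)))
  utils::write.csv(
    data.frame(ppr_g_per_mol = titration$ppr, reduction_pct = titration$F),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- utils::read.csv(path)
  need <- c("ppr_g_per_mol", "reduction_pct")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop(sprintf("titration CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  data.frame(ppr = d$ppr_g_per_mol, F = d$reduction_pct)
}

#' @rdname trace_io
#' @param radii Numeric radius samples (nm).
#' @export
write_dls <- function(radii, path) {
  utils::write.csv(data.frame(radius_nm = radii), path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_dls <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- utils::read.csv(path)
  if (!"radius_nm" %in% names(d)) {
    stop("DLS CSV is missing column(s): radius_nm", call. = FALSE)
  }
  d$radius_nm
}
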