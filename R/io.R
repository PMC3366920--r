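# Sweep file format: delimited text with time_ms in column 1 and one
# sweep per remaining column (header row names the sweeps), plus a JSON
# sidecar (<path>.json) carrying unit, varied-parameter values, protocol
# and metadata. Values are printed with 9 significant digits so a
# write/read/write cycle is bit-identical.

#' Write a sweep set to CSV with a JSON sidecar
#'
#' @param set A [sweep_set()].
#' @param path CSV file path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(set, path) {
  stopifnot(inherits(set, "sweep_set"))
  lens <- vapply(set$traces, nrow, integer(1))
  if (length(unique(lens)) != 1) {
    stop("all sweeps must share a time base to be written together")
  }
  tab <- do.call(cbind, c(list(set$traces[[1]]$time_ms),
                          lapply(set$traces, `[[`, "current")))
  colnames(tab) <- c("time_ms", names(set$traces))
  txt <- apply(tab, 1, function(row)
    paste(formatC(row, digits = 9, format = "g"), collapse = ","))
  writeLines(c(paste(colnames(tab), collapse = ","), txt), path)

  tr1 <- set$traces[[1]]
  sidecar <- list(
    varied_param = set$varied_param,
    varied_values = stats::setNames(as.list(set$values),
                                    names(set$traces)),
    sampling_ms = attr(tr1, "sampling_ms"),
    unit = attr(tr1, "unit"),
    metadata = trace_meta(tr1),
    protocol = if (!is.null(attr(tr1, "protocol"))) {
      p <- attr(tr1, "protocol")
      list(segments = p$segments, inter_episode_ms = p$inter_episode_ms,
           junction_corrected = p$junction_corrected)
    })
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a sweep set written by [write_sweeps()]
#'
#' @param path CSV file path (sidecar expected at `<path>.json`).
#' @return A [sweep_set()].
#' @export
read_sweeps <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop("missing JSON sidecar: ", side_path)
  }
  side <- jsonlite::fromJSON(side_path, simplifyDataFrame = TRUE)
  sweep_names <- setdiff(colnames(tab), "time_ms")
  protocol <- if (!is.null(side$protocol)) {
    p <- voltage_protocol(side$protocol$segments,
                          side$protocol$inter_episode_ms)
    p$junction_corrected <- isTRUE(side$protocol$junction_corrected)
    p
  }
  traces <- lapply(sweep_names, function(nm)
    current_trace(tab[[nm]], side$sampling_ms, side$unit, protocol,
                  as.list(side$metadata)))
  names(traces) <- sweep_names
  sweep_set(traces,
            as.numeric(unlist(side$varied_values[sweep_names])),
            side$varied_param)
}
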