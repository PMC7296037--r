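#' Read a delimited trace table with its JSON sidecar
#'
#' Reads a CSV/TSV trace file with a header whose first column is time
#' (`time_s` or `time_ms`) followed by one or more value columns, and
#' merges the metadata from the sidecar JSON `<path>.json` when present
#' (or an explicit `sidecar` path). The sampling rate is taken from the
#' sidecar `fs` when available, otherwise inferred as the reciprocal of
#' the median time step.
#'
#' @param path path to the delimited file (`.csv` or `.tsv`).
#' @param sidecar optional path to the metadata JSON.
#' @return An object of class `trace_table`: `data` (data.frame),
#'   `metadata` (named list), `fs` (Hz), `time_unit` (`"s"` or `"ms"`).
#' @export
read_trace <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE)
  if (ncol(df) < 2L) stop("trace table needs a time column and at least one value column",
                          call. = FALSE)
  tcol <- names(df)[1]
  if (!tcol %in% c("time_s", "time_ms")) {
    stop(sprintf("missing time column: first column must be `time_s` or `time_ms`, got `%s`",
                 tcol), call. = FALSE)
  }
  tv <- df[[1]]
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0)
    stop(sprintf("malformed rows (NA values) at line(s): %s",
                 paste(head(bad + 1L, 10), collapse = ", ")), call. = FALSE)
  }
  if (is.unsorted(tv, strictly = TRUE)) {
    bad <- which(diff(tv) <= 0)[1]
    stop(sprintf("non-monotone time at data row %d", bad + 1L), call. = FALSE)
  }

  if (is.null(sidecar)) {
    cand <- paste0(path, ".json")
    sidecar <- if (file.exists(cand)) cand else NA_character_
  }
  meta <- list()
  if (!is.na(sidecar)) {
    meta <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                     error = function(e) {
                       stop(sprintf("unreadable sidecar %s: %s", sidecar,
                                    conditionMessage(e)), call. = FALSE)
                     })
  }
  unit <- if (tcol == "time_ms") "ms" else "s"
  scale <- if (unit == "ms") 1e-3 else 1
  fs <- if (!is.null(meta$fs)) as.numeric(meta$fs)
        else 1 / (median(diff(tv)) * scale)
  structure(
    list(data = df, metadata = meta, fs = fs, time_unit = unit),
    class = "trace_table"
  )
}

#' @export
print.trace_table <- function(x, ...) {
  cat(sprintf("<trace_table> %d rows x %d cols, fs = %g Hz, %d metadata field(s)\n",
              nrow(x$data), ncol(x$data), x$fs, length(x$metadata)))
  invisible(x)
}

# atomic write: temp file in the destination directory, then rename
atomic_write <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fn(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Write a trace table and its JSON sidecar
#'
#' Writes the data as CSV and the metadata as `<path>.json`. Both writes
#' are atomic (temp file + rename), so partial outputs never masquerade
#' as complete.
#'
#' @param x a `trace_table`, or a data.frame (metadata then via `metadata`).
#' @param path output CSV path.
#' @param metadata named list written to the sidecar (merged over
#'   `x$metadata` for trace tables).
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, metadata = list()) {
  if (inherits(x, "trace_table")) {
    df <- x$data
    meta <- utils::modifyList(x$metadata, metadata)
  } else if (is.data.frame(x)) {
    df <- x
    meta <- metadata
  } else {
    stop("`x` must be a trace_table or data.frame", call. = FALSE)
  }
  atomic_write(function(tmp) {
    write.csv(df, tmp, row.names = FALSE)
  }, path)
  if (length(meta)) {
    atomic_write(function(tmp) {
      jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }, paste0(path, ".json"))
  }
  invisible(path)
}

#' Convert a trace table to an lfp_signal
#'
#' @param x a `trace_table` with a single value column.
#' @param column value column name; default the second column.
#' @return an [lfp_signal()].
#' @export
as_lfp_signal <- function(x, column = NULL) {
  stopifnot(inherits(x, "trace_table"))
  if (is.null(column)) column <- names(x$data)[2]
  scale <- if (x$time_unit == "ms") 1e-3 else 1
  lfp_signal(x$data[[column]], fs = x$fs, t0 = x$data[[1]][1] * scale)
}
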