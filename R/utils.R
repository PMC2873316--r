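## internal helpers shared across modules

#' Evaluate an expression under a fixed RNG seed, restoring caller state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Abort with a classed condition so callers/tests can discriminate errors
#' @noRd
nr_abort <- function(msg, class = "netreg_error", ...) {
  stop(structure(
    class = c(class, "netreg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

nr_validation_error <- function(msg, ...) {
  nr_abort(msg, class = "netreg_validation_error", ...)
}

nr_parse_error <- function(msg, ...) {
  nr_abort(msg, class = "netreg_parse_error", ...)
}

nr_lookup_error <- function(msg, ...) {
  nr_abort(msg, class = "netreg_lookup_error", ...)
}

nr_io_error <- function(msg, ...) {
  nr_abort(msg, class = "netreg_io_error", ...)
}

#' Write a report table as UTF-8 TSV with header, stable column order
#'
#' @param rows data.frame of report rows
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_tsv_report <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  write.table(rows, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_file <- function(path, what = "file") {
  if (!file.exists(path)) nr_io_error(sprintf("%s not found: %s", what, path))
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, fileEncoding = "UTF-8")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
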