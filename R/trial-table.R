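#' Trial tables of two-exit escape counts
#'
#' A trial table records one row per escape repetition: a unique trial id and
#' the number of ants that left through each exit. It is a plain data.frame
#' with class `"trial_table"` so analysis functions can validate their input
#' once.
#'
#' @param trial_id Character vector of unique trial identifiers. Defaults to
#'   `"t1", "t2", ...`.
#' @param n_left,n_right Non-negative integer counts per trial; every trial
#'   must have at least one escaped ant.
#' @return A `trial_table` (data.frame with columns `trial_id`, `n_left`,
#'   `n_right`).
#' @examples
#' tt <- trial_table(n_left = c(3, 1, 2), n_right = c(1, 3, 2))
#' sign_counts(tt)
#' @export
trial_table <- function(n_left, n_right,
                        trial_id = paste0("t", seq_along(n_left))) {
  if (length(n_left) != length(n_right))
    stop("`n_left` and `n_right` must have the same length", call. = FALSE)
  df <- data.frame(trial_id = as.character(trial_id),
                   n_left = as.integer(n_left),
                   n_right = as.integer(n_right),
                   stringsAsFactors = FALSE)
  as_trial_table(df)
}

#' @param x A data.frame with columns `trial_id`, `n_left`, `n_right`.
#' @rdname trial_table
#' @export
as_trial_table <- function(x) {
  req <- c("trial_id", "n_left", "n_right")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x)[req]
  x$trial_id <- as.character(x$trial_id)
  validate_trial_rows(x)
  x$n_left <- as.integer(x$n_left)
  x$n_right <- as.integer(x$n_right)
  class(x) <- c("trial_table", "data.frame")
  x
}

validate_trial_rows <- function(x) {
  if (nrow(x) == 0L) stop("trial table is empty", call. = FALSE)
  nl <- suppressWarnings(as.numeric(x$n_left))
  nr <- suppressWarnings(as.numeric(x$n_right))
  bad <- which(!is.finite(nl) | !is.finite(nr) | nl < 0 | nr < 0 |
                 nl != round(nl) | nr != round(nr) | nl + nr < 1)
  if (length(bad))
    stop(sprintf("invalid escape counts in row %d (trial '%s')",
                 bad[1], x$trial_id[bad[1]]), call. = FALSE)
  if (anyDuplicated(x$trial_id))
    stop("trial ids must be unique", call. = FALSE)
  invisible(NULL)
}

#' @export
print.trial_table <- function(x, ...) {
  n <- x$n_left + x$n_right
  cat(sprintf("Trial table: %d trials, total escaped N in [%d, %d]\n",
              nrow(x), min(n), max(n)))
  NextMethod()
}

#' Read and write trial-table CSV files
#'
#' The interchange format is a UTF-8 CSV with a header row and columns
#' `trial_id`, `n_left`, `n_right`. Reading validates every row and reports
#' the first offending row on failure; `read_trial_table(write_trial_table(t))`
#' is the identity.
#'
#' @param path File path.
#' @param table A [trial_table()].
#' @return `read_trial_table()` returns a `trial_table`;
#'   `write_trial_table()` invisibly returns `path`.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("trial_id", "n_left", "n_right")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  nl <- suppressWarnings(as.numeric(df$n_left))
  nr <- suppressWarnings(as.numeric(df$n_right))
  bad <- which(is.na(nl) | is.na(nr))
  if (length(bad))
    stop(sprintf("non-numeric escape count in row %d (trial '%s') of %s",
                 bad[1], df$trial_id[bad[1]], path), call. = FALSE)
  df$n_left <- nl
  df$n_right <- nr
  as_trial_table(df)
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
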