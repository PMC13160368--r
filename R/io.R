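#' Read functional data from wide-format delimited text
#'
#' First column `t` holds the time grid; every further column is one
#' function. The grid must be strictly increasing from 0 to 1. Warping files
#' use the same layout.
#'
#' @param path File path.
#' @param sep Field separator (default any whitespace, as written by
#'   [write_functional_data]).
#' @return List of [fsample]s, named by column.
#' @export
read_functional_data <- function(path, sep = "") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (ncol(df) < 2) stop("expected a time column plus functions", call. = FALSE)
  grid <- df[[1]]
  validate_grid(grid)
  out <- lapply(df[-1], function(v) fsample(grid, v))
  names(out) <- names(df)[-1]
  out
}

#' Write functional data as wide-format delimited text
#'
#' @param functions List of [fsample]s on a common grid.
#' @param path Output path.
#' @export
write_functional_data <- function(functions, path) {
  fm <- fsample_matrix(functions)
  df <- data.frame(t = fm$grid, fm$values)
  names(df) <- c("t", if (!is.null(names(functions)) &&
                          all(nzchar(names(functions)))) {
    names(functions)
  } else {
    paste0("f", seq_along(functions))
  })
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a prediction band as delimited text
#'
#' Columns: `t`, `lower`, `upper`, `length` (empty intervals have `NA`
#' bounds and zero length).
#'
#' @param band A `prediction_band`.
#' @param path Output path.
#' @export
write_band <- function(band, path) {
  stopifnot(inherits(band, "prediction_band"))
  utils::write.table(
    data.frame(t = band$grid, lower = band$lower, upper = band$upper,
               length = band$lengths),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a distance matrix as delimited text with the metric in the header
#'
#' @param D Distance matrix with a `metric` attribute (see
#'   [distance_matrix]).
#' @param path Output path.
#' @export
write_distance_matrix <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s", attr(D, "metric")), con)
  utils::write.table(D, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
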