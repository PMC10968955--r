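#' Mixed continuous/binary dataset
#'
#' The typed data matrix fed to network estimation: each column is declared
#' continuous or binary, binary columns hold only 0/1, and no missing
#' values are allowed (complete cases are enforced upstream by
#' [read_cohort()]).
#'
#' @param x Numeric matrix or all-numeric data frame (n rows, p >= 2
#'   columns, named).
#' @param types Character vector of `"continuous"`/`"binary"`, one per
#'   column (recycled names allowed if named).
#' @return A `mixed_data` object: list with `values` (numeric matrix),
#'   `nodes`, `types`.
#' @export
mixed_data <- function(x, types) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("x must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  p <- ncol(x)
  if (p < 2) stop("need at least 2 columns", call. = FALSE)
  if (!is.null(names(types))) types <- types[colnames(x)]
  types <- as.character(types)
  if (length(types) != p || !all(types %in% c("continuous", "binary"))) {
    stop("types must be one of continuous/binary per column", call. = FALSE)
  }
  if (anyNA(x)) stop("mixed_data does not allow missing values", call. = FALSE)
  for (j in which(types == "binary")) {
    if (!all(x[, j] %in% c(0, 1))) {
      stop("binary column ", colnames(x)[j], " contains values outside {0,1}",
           call. = FALSE)
    }
  }
  structure(list(values = x, nodes = colnames(x), types = types),
            class = "mixed_data")
}

#' @export
print.mixed_data <- function(x, ...) {
  cat("mixed_data:", nrow(x$values), "rows,", length(x$nodes), "nodes (",
      sum(x$types == "continuous"), "continuous,",
      sum(x$types == "binary"), "binary )\n")
  invisible(x)
}

#' @export
dim.mixed_data <- function(x) dim(x$values)

#' @export
as.data.frame.mixed_data <- function(x, ...) as.data.frame(x$values)
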