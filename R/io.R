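#' Read a predictor matrix from CSV
#'
#' Loads a samples x predictors design matrix from a comma-separated file.
#' The file must have a header row of unique column names, no row-name
#' column, and every cell must parse as a finite number: missing values
#' are not permitted anywhere in the design. Methylation beta values,
#' clinical covariates and indicator-coded categorical variables are all
#' acceptable columns, but categorical text must be recoded to 0/1
#' indicators before loading.
#'
#' @param path Path to a CSV file (comma delimiter, `.` decimal mark,
#'   optional double quotes, UTF-8).
#' @return A numeric matrix with column names in file order.
#' @export
read_design_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_ragged_csv(path)
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE,
                          colClasses = NULL, showProgress = FALSE)
  if (ncol(dt) < 1L) stop("format error: no columns in ", path)
  nms <- colnames(dt)
  if (anyDuplicated(nms)) {
    stop("format error: duplicate column names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  bad <- which(!vapply(dt, is.numeric, logical(1)))
  if (length(bad)) {
    hint <- if (1L %in% bad)
      " (if the first column holds sample identifiers, remove the row names; categorical variables must be converted to 0/1 indicators)"
    else
      " (categorical variables must be converted to 0/1 indicators)"
    stop("format error: non-numeric column(s): ",
         paste(nms[bad], collapse = ", "), hint)
  }
  m <- as.matrix(dt)
  storage.mode(m) <- "double"
  bad <- first_nonfinite(m)
  if (!is.null(bad)) {
    stop("validation error: missing or non-finite value at data row ",
         bad[1L], ", column '", nms[bad[2L]],
         "' -- there can be no missing values in the predictor matrix")
  }
  rownames(m) <- NULL
  m
}

# fread silently recycles/fills some malformed layouts; enforce a strict
# rectangular contract up front with 1-based row positions in the message.
check_ragged_csv <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (!length(nf)) stop("format error: empty file: ", path)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("format error: ragged row ", bad, " has ", nf[bad],
         " fields but the header has ", nf[1L])
  }
  invisible(nf[1L])
}

#' Read an outcome vector from CSV
#'
#' The outcome file must contain exactly one column with a header naming
#' the outcome (e.g. `age`), and no missing values.
#'
#' @param path Path to a single-column CSV file.
#' @return A numeric vector in file order, with the column header attached
#'   as attribute `"label"`.
#' @export
read_outcome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  width <- check_ragged_csv(path)
  if (width != 1L) {
    stop("format error: outcome file must have exactly one column, found ",
         width)
  }
  first <- readLines(path, n = 1L)
  if (!nzchar(trimws(first)) ||
      !is.na(suppressWarnings(as.numeric(gsub('"', "", trimws(first)))))) {
    stop("format error: outcome file has no header row -- column names are required")
  }
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE,
                          showProgress = FALSE)
  v <- dt[[1L]]
  if (!is.numeric(v)) stop("format error: non-numeric outcome column")
  v <- as.double(v)
  if (any(!is.finite(v))) {
    stop("validation error: missing or non-finite outcome value at data row ",
         which(!is.finite(v))[1L])
  }
  structure(v, label = colnames(dt)[1L])
}

#' Validate a predictor matrix / outcome pair
#'
#' Collects every contract violation (rather than stopping at the first):
#' dimension mismatch between matrix and outcome, missing or non-finite
#' entries, too few samples, missing or duplicated column names.
#'
#' @param m Numeric predictor matrix with column names.
#' @param y Numeric outcome vector.
#' @return An object of class `slim_validation`: list with `ok` (logical)
#'   and `violations` (character vector, empty when `ok`).
#' @export
validate_pair <- function(m, y) {
  v <- character(0)
  if (!is.matrix(m) || !is.numeric(m)) {
    v <- c(v, "predictor matrix is not a numeric matrix")
  } else {
    if (is.null(colnames(m)) || any(!nzchar(colnames(m)))) {
      v <- c(v, "predictor matrix lacks column names")
    } else if (anyDuplicated(colnames(m))) {
      v <- c(v, "duplicate predictor column names")
    }
    if (nrow(m) < 3L) v <- c(v, "fewer than 3 samples")
    bad <- first_nonfinite(m)
    if (!is.null(bad)) {
      v <- c(v, sprintf("missing or non-finite value at row %d, column %d",
                        bad[1L], bad[2L]))
    }
    if (is.numeric(y) && length(y) != nrow(m)) {
      v <- c(v, sprintf("length mismatch: %d samples in matrix, %d in outcome",
                        nrow(m), length(y)))
    }
  }
  if (!is.numeric(y)) {
    v <- c(v, "outcome is not numeric")
  } else if (any(!is.finite(y))) {
    v <- c(v, sprintf("missing or non-finite outcome value at position %d",
                      which(!is.finite(y))[1L]))
  }
  structure(list(ok = length(v) == 0L, violations = v),
            class = "slim_validation")
}

#' @export
print.slim_validation <- function(x, ...) {
  if (x$ok) cat("ok: matrix and outcome pass all checks\n")
  else cat("violations:\n", paste0("  - ", x$violations, "\n"), sep = "")
  invisible(x)
}

# Finiteness scan sized for multi-gigabyte matrices: anyNA() walks the
# data without a temporary and catches NA/NaN; given neither is present,
# sum() is finite iff no Inf is (is.finite() or range() on the whole
# matrix would allocate copies of its size). Only a dirty input pays for
# the block-wise localization.
first_nonfinite <- function(m, block_size = 10000L) {
  if (!anyNA(m) && is.finite(sum(m))) return(NULL)
  p <- ncol(m)
  for (s in seq(1L, max(p, 1L), by = block_size)) {
    e <- min(p, s + block_size - 1L)
    blk <- m[, s:e, drop = FALSE]
    if (any(!is.finite(blk))) {
      idx <- which(!is.finite(blk), arr.ind = TRUE)[1L, ]
      return(c(idx[1L], s + idx[2L] - 1L))
    }
  }
  NULL
}

stop_on_invalid <- function(m, y) {
  rep <- validate_pair(m, y)
  if (!rep$ok) {
    stop("invalid input:\n", paste0("  - ", rep$violations, collapse = "\n"))
  }
  invisible(TRUE)
}

#' Construct a fitted linear model specification
#'
#' A `slim_model` holds an intercept plus named slopes in the order the
#' terms were accepted during selection, together with the final adjusted
#' R-squared and the selection configuration that produced it.
#'
#' @param intercept Numeric scalar.
#' @param coefficients Named numeric vector of slopes (may be empty for an
#'   intercept-only model); names must be unique.
#' @param adjusted_r2 Final adjusted R-squared of the fit (default `NA`).
#' @param config The [selection_config()] used, or `NULL`.
#' @return An object of class `slim_model`.
#' @export
slim_model <- function(intercept, coefficients = numeric(0),
                       adjusted_r2 = NA_real_, config = NULL) {
  coefficients <- unlist(coefficients)
  if (length(coefficients) == 0L) coefficients <- setNames(numeric(0), character(0))
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    stop("all slopes must be named by their predictor column")
  }
  if (anyDuplicated(names(coefficients))) stop("duplicate term names in model")
  if (!is.finite(intercept) || any(!is.finite(coefficients))) {
    stop("model estimates must be finite")
  }
  structure(list(intercept = as.double(intercept),
                 coefficients = coefficients,
                 adjusted_r2 = adjusted_r2,
                 config = config),
            class = "slim_model")
}

#' @export
print.slim_model <- function(x, ...) {
  cat("Linear prediction model:", length(x$coefficients), "term(s)\n")
  cat("  (Intercept) ", format(x$intercept, digits = 6), "\n")
  for (nm in names(x$coefficients)) {
    cat("  ", nm, " ", format(x$coefficients[[nm]], digits = 6), "\n", sep = "")
  }
  if (is.finite(x$adjusted_r2)) {
    cat("  adjusted R-squared:", format(x$adjusted_r2, digits = 4), "\n")
  }
  invisible(x)
}

#' Write a model to a two-column CSV
#'
#' The file holds one `term,estimate` pair per row; the first data row is
#' always the intercept under the reserved name `(Intercept)`. Estimates
#' are written with full precision so that [read_model()] round-trips
#' exactly.
#'
#' @param model A [slim_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "slim_model"))
  df <- data.frame(term = c("(Intercept)", names(model$coefficients)),
                   estimate = format(c(model$intercept, unname(model$coefficients)),
                                     digits = 17, scientific = TRUE, trim = TRUE),
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, quote = "auto")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path Path to a `term,estimate` CSV.
#' @return A [slim_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE,
                          colClasses = list(character = 1L), showProgress = FALSE)
  if (!identical(colnames(dt), c("term", "estimate"))) {
    stop("format error: expected header 'term,estimate', found '",
         paste(colnames(dt), collapse = ","), "'")
  }
  est <- suppressWarnings(as.double(dt$estimate))
  if (any(is.na(est))) {
    stop("format error: malformed estimate at data row ", which(is.na(est))[1L])
  }
  if (nrow(dt) < 1L || dt$term[1L] != "(Intercept)") {
    stop("format error: first data row must be the '(Intercept)' term")
  }
  terms <- dt$term[-1L]
  if (anyDuplicated(terms)) {
    stop("format error: duplicate term name '", terms[duplicated(terms)][1L], "'")
  }
  slim_model(intercept = est[1L],
             coefficients = setNames(est[-1L], terms))
}

#' Predict from a fitted model
#'
#' Applies the linear model to new data, matching terms to columns of
#' `newdata` by NAME (never by position), so a permuted or wider matrix
#' predicts identically as long as every model term is present.
#'
#' @param object A [slim_model()].
#' @param newdata Numeric matrix with named columns covering all model terms.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.slim_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  terms <- names(object$coefficients)
  if (length(terms)) {
    missing <- setdiff(terms, colnames(newdata))
    if (length(missing)) {
      stop("prediction error: model term(s) absent from new data: ",
           paste(missing, collapse = ", "))
    }
    drop(newdata[, terms, drop = FALSE] %*% object$coefficients) + object$intercept
  } else {
    rep(object$intercept, nrow(newdata))
  }
}

#' Write a predictor matrix to CSV
#'
#' Counterpart of [read_design_matrix()]; full-precision numeric output.
#'
#' @param m Numeric matrix with column names.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_design_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  data.table::fwrite(as.data.frame(m), path, quote = "auto")
  invisible(path)
}

#' Write an outcome vector to a single-column CSV
#'
#' @param y Numeric vector; its `"label"` attribute (or `name`) becomes the
#'   header.
#' @param path Output file path.
#' @param name Column header; defaults to the vector's `"label"` attribute
#'   or `"y"`.
#' @return Invisibly, `path`.
#' @export
write_outcome <- function(y, path, name = NULL) {
  if (is.null(name)) name <- attr(y, "label")
  if (is.null(name)) name <- "y"
  df <- data.frame(x = as.double(y))
  colnames(df) <- name
  data.table::fwrite(df, path, quote = "auto")
  invisible(path)
}
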