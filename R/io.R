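#' Column-role schema for long-format CSV files
#'
#' Declares which columns play which role in a long-format file (one row
#' per subject-visit). The fixed covariates are listed with the
#' missing-prone ones first, in the order of the sequential covariate
#' models; that ordering is part of the model specification.
#'
#' @param id,time,response column names of the subject identifier, the
#'   spline covariate (e.g. visit time), and the semicontinuous response.
#' @param covariates character vector of fixed-effect covariate columns,
#'   missing-prone first.
#' @param n_missing number of leading missing-prone covariates.
#' @param random optional random-effect covariate columns (default: a
#'   random intercept).
#' @param sentinel string marking a missing cell (empty cells are always
#'   treated as missing too).
#' @return An object of class `data_schema`.
#' @export
data_schema <- function(id, time, response, covariates, n_missing = 0,
                        random = NULL, sentinel = "NA") {
  stopifnot(length(id) == 1, length(time) == 1, length(response) == 1,
            n_missing >= 0, n_missing <= length(covariates))
  structure(list(id = id, time = time, response = response,
                 covariates = covariates, n_missing = as.integer(n_missing),
                 random = random, sentinel = sentinel),
            class = "data_schema")
}

#' Read a long-format CSV into a longitudinal dataset
#'
#' Cells equal to the schema's sentinel (or empty) become missing values.
#' Rows are grouped by subject (in order of first appearance) with the
#' file's within-subject order preserved; responses below 1e-12 are
#' coerced to exact zeros. Non-numeric cells, negative responses, and
#' unknown columns raise errors naming the offending rows.
#'
#' @param path CSV file path.
#' @param schema a [data_schema()].
#' @return A [long_data()] object.
#' @export
read_long_csv <- function(path, schema) {
  stopifnot(inherits(schema, "data_schema"))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) stop("no data rows in ", path)
  need <- c(schema$id, schema$time, schema$response, schema$covariates,
            schema$random)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  num <- function(col) {
    v <- trimws(raw[[col]])
    v[v == schema$sentinel | v == ""] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("non-numeric values in column '", col, "' at rows ",
           paste(utils::head(bad, 5), collapse = ", "))
    out
  }
  time <- num(schema$time)
  y <- num(schema$response)
  neg <- which(!is.na(y) & y < 0)
  if (length(neg))
    stop("negative responses at rows ", paste(utils::head(neg, 5), collapse = ", "))
  X <- sapply(schema$covariates, num)
  Z <- if (is.null(schema$random)) NULL else
    as.matrix(sapply(schema$random, num))
  id <- raw[[schema$id]]
  # stable: group rows by subject in order of first appearance, preserving
  # the file's within-subject row order (round trips are lossless)
  ord <- order(match(id, unique(id)))
  dat <- long_data(id = id[ord], time = time[ord],
                   y = y[ord], X = as.matrix(X)[ord, , drop = FALSE],
                   m = schema$n_missing,
                   Z = if (is.null(Z)) NULL else Z[ord, , drop = FALSE])
  message(sprintf("read %d rows, %d subjects; missing: y %.1f%%%s",
                  dat$n_obs, dat$n, 100 * mean(dat$r_y),
                  if (dat$m > 0) paste0(", ", paste(
                    sprintf("%s %.1f%%", schema$covariates[seq_len(dat$m)],
                            100 * colMeans(dat$r_x)), collapse = ", "))
                  else ""))
  dat
}

#' Write a longitudinal dataset to a long-format CSV
#'
#' The round trip through [read_long_csv()] is lossless for complete data.
#'
#' @param data a [long_data()] object.
#' @param path destination file.
#' @param sentinel string written for missing cells.
#' @return Invisibly, the schema describing the written file.
#' @export
write_long_csv <- function(data, path, sentinel = "NA") {
  stopifnot(inherits(data, "long_data"))
  xn <- colnames(data$X)
  if (is.null(xn)) xn <- paste0("x", seq_len(ncol(data$X)))
  df <- data.frame(id = data$subjects[data$id], time = data$time,
                   y = data$y)
  df[xn] <- data$X
  intercept_only <- ncol(data$Z) == 1 && all(data$Z == 1)
  if (!intercept_only) {
    zn <- paste0("z", seq_len(ncol(data$Z)))
    df[zn] <- data$Z
  }
  mat <- as.matrix(format(df, trim = TRUE, digits = 15))
  mat[is.na(df)] <- sentinel
  write.csv(as.data.frame(mat), path, row.names = FALSE, quote = FALSE)
  invisible(data_schema(id = "id", time = "time", response = "y",
                        covariates = xn, n_missing = data$m,
                        random = if (intercept_only) NULL else zn,
                        sentinel = sentinel))
}
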