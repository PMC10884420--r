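#' Competing-risks dataset
#'
#' Bundle subject-level right-censored survival data with two competing causes
#' of death into a validated container. Status is coded 0 (censored), 1
#' (cause-1 death) and 2 (cause-2 death). Covariates must be numeric with no
#' missing entries; an optional categorical group label (e.g. gender) may be
#' attached. An administrative censoring time, when supplied, is a single
#' scalar cutoff for the whole dataset.
#'
#' @param data a data.frame holding one row per subject.
#' @param time,status,id names of the observed-time, status and id columns.
#' @param covariates character vector of covariate column names; defaults to
#'   every numeric column other than time/status/id/group.
#' @param group optional name of a categorical grouping column.
#' @param censor_time optional administrative censoring time (same units as
#'   `time`); every censored subject must satisfy `time <= censor_time`.
#' @return an object of class `crdata`: the data.frame restricted to the
#'   canonical columns, with attributes `covariates`, `group`, `censor_time`.
#' @examples
#' d <- data.frame(id = 1:3, time = c(2, 5, 1.5), status = c(1, 0, 2),
#'                 x1 = rnorm(3))
#' crdata(d, censor_time = 5)
#' @export
crdata <- function(data, time = "time", status = "status", id = "id",
                   covariates = NULL, group = NULL, censor_time = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(time, status)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!id %in% names(data)) data[[id]] <- seq_len(nrow(data))
  if (is.null(covariates)) {
    drop <- c(time, status, id, group)
    covariates <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], drop)
  }
  if (anyDuplicated(covariates))
    stop("covariate column names must be unique")
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
  if (nrow(data) < 1L) stop("need at least one subject")
  if (length(covariates) < 1L) stop("need at least one covariate column")

  out <- data.frame(id = data[[id]],
                    time = as.numeric(data[[time]]),
                    status = as.integer(data[[status]]),
                    stringsAsFactors = FALSE)
  if (!is.null(group)) {
    if (!group %in% names(data)) stop("group column not found: ", group)
    out$group <- as.character(data[[group]])
  }
  for (v in covariates) {
    if (!is.numeric(data[[v]]))
      stop("covariate column '", v, "' is not numeric")
    out[[v]] <- as.numeric(data[[v]])
  }

  bad <- which(!(out$time > 0) | is.na(out$time))
  if (length(bad))
    stop("non-positive or missing time in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!(out$status %in% 0:2))
  if (length(bad))
    stop("status outside {0,1,2} in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  X <- as.matrix(out[covariates])
  if (anyNA(X)) {
    bad <- which(rowSums(is.na(X)) > 0L)
    stop("missing covariate value(s) in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!is.null(censor_time)) {
    stopifnot(is.numeric(censor_time), length(censor_time) == 1L,
              censor_time > 0)
    bad <- which(out$status == 0L & out$time > censor_time + 1e-12)
    if (length(bad))
      stop("censored subject(s) with time beyond the administrative cutoff: row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }

  structure(out,
            covariates = covariates,
            group = if (is.null(group)) NULL else "group",
            censor_time = if (is.null(censor_time)) NA_real_ else censor_time,
            class = c("crdata", "data.frame"))
}

#' @export
print.crdata <- function(x, ...) {
  n <- nrow(x)
  tab <- table(factor(x$status, levels = 0:2))
  cat("Competing-risks dataset: ", n, " subjects, ",
      length(attr(x, "covariates")), " covariate(s)\n", sep = "")
  cat("  events: cause 1 = ", tab[["1"]], ", cause 2 = ", tab[["2"]],
      ", censored = ", tab[["0"]], "\n", sep = "")
  if (!is.na(attr(x, "censor_time")))
    cat("  administrative censoring at t = ", attr(x, "censor_time"), "\n",
        sep = "")
  if (!is.null(attr(x, "group")))
    cat("  groups: ", paste(names(table(x$group)), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Covariate matrix of a crdata object
#' @param x a `crdata` object.
#' @return numeric matrix, one row per subject, covariate columns.
#' @export
covariate_matrix <- function(x) {
  stopifnot(inherits(x, "crdata"))
  as.matrix(as.data.frame(x)[attr(x, "covariates")])
}

#' Read a competing-risks dataset from CSV
#'
#' Expects a header row with columns id, time, status, optionally a group
#' column, and numeric covariates. Column names other than the defaults can be
#' mapped through the arguments.
#'
#' @inheritParams crdata
#' @param path path to a comma-separated file with header.
#' @return a [crdata] object; row order of the file is preserved.
#' @export
read_crdata <- function(path, time = "time", status = "status", id = "id",
                        covariates = NULL, group = NULL, censor_time = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  crdata(raw, time = time, status = status, id = id,
         covariates = covariates, group = group, censor_time = censor_time)
}

#' Write a competing-risks dataset to CSV
#'
#' Columns are written in canonical order id, time, status, group (if any),
#' then covariates, at full precision so that a read/write round trip is
#' lossless.
#'
#' @param x a [crdata] object.
#' @param path output file path.
#' @export
write_crdata <- function(x, path) {
  stopifnot(inherits(x, "crdata"))
  cols <- c("id", "time", "status", attr(x, "group"), attr(x, "covariates"))
  df <- as.data.frame(x)[cols]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
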