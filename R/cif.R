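#' Aalen-Johansen cumulative incidence functions
#'
#' Nonparametric estimate of the probability of failing from each competing
#' cause by time t: F_k(t) = sum over event times t_j <= t of
#' S(t_j-) * d_kj / n_j, with S the all-cause Kaplan-Meier survival and n_j
#' the number at risk. Subjects censored at an event time are kept in the
#' risk set at that time (events precede censorings). When a group label is
#' given, one estimate is returned per level.
#'
#' @param data a [crdata] object (statuses 0/1/2).
#' @param group optional name of the grouping column (use `"group"` for the
#'   label attached by [crdata()]), or `NULL` for a single overall estimate.
#' @return object of class `cif_aj` (or a named list of them, class
#'   `cif_aj_list`, when grouped): `time` (sorted distinct event times),
#'   `cif1`, `cif2` (step values at those times), `surv` (all-cause KM),
#'   `n_risk`, and step functions `F1`, `F2`.
#' @examples
#' d <- crdata(data.frame(id = 1:4, time = 1:4, status = c(1, 0, 2, 1),
#'                        x = rnorm(4)))
#' cuminc_aj(d)
#' @export
cuminc_aj <- function(data, group = NULL) {
  stopifnot(inherits(data, "crdata"))
  if (!is.null(group)) {
    g <- as.data.frame(data)[[group]]
    lv <- unique(g)
    out <- lapply(lv, function(l) {
      idx <- which(g == l)
      if (!length(idx)) return(NULL)
      est <- cif_engine(data$time[idx], data$status[idx])
      est$group <- l
      est
    })
    names(out) <- lv
    keep <- !vapply(out, is.null, TRUE)
    if (any(!keep)) warning("empty group level(s) skipped")
    return(structure(out[keep], class = "cif_aj_list"))
  }
  cif_engine(data$time, data$status)
}

cif_engine <- function(time, status) {
  if (!any(status > 0L)) stop("no events in the data")
  ord <- order(time)
  time <- time[ord]; status <- status[ord]
  n <- length(time)
  ut <- unique(time[status > 0L])          # distinct event times
  surv_prev <- 1                            # S(t-)
  S <- F1 <- F2 <- numeric(length(ut))
  nr <- integer(length(ut))
  f1 <- f2 <- 0
  for (j in seq_along(ut)) {
    tt <- ut[j]
    at_risk <- sum(time >= tt)
    d1 <- sum(status == 1L & time == tt)
    d2 <- sum(status == 2L & time == tt)
    f1 <- f1 + surv_prev * d1 / at_risk
    f2 <- f2 + surv_prev * d2 / at_risk
    surv_prev <- surv_prev * (1 - (d1 + d2) / at_risk)
    S[j] <- surv_prev; F1[j] <- f1; F2[j] <- f2; nr[j] <- at_risk
  }
  structure(list(time = ut, cif1 = F1, cif2 = F2, surv = S, n_risk = nr,
                 F1 = stats::stepfun(ut, c(0, F1), right = FALSE),
                 F2 = stats::stepfun(ut, c(0, F2), right = FALSE),
                 group = NULL),
            class = "cif_aj")
}

#' @export
print.cif_aj <- function(x, ...) {
  cat("Aalen-Johansen cumulative incidence",
      if (!is.null(x$group)) paste0(" (group ", x$group, ")"), ": ",
      length(x$time), " event times; F1(max) = ",
      round(max(x$cif1), 4), ", F2(max) = ", round(max(x$cif2), 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.cif_aj_list <- function(x, ...) {
  for (e in x) print(e)
  invisible(x)
}

#' Plot cumulative incidence curves before and after the censoring update
#'
#' One panel per group level (a single panel when ungrouped), with one step
#' curve per cause, solid before the update and dashed after.
#'
#' @param before,after `cif_aj` or `cif_aj_list` objects on matching group
#'   levels.
#' @param file optional path; when given the plot is written there as a PDF.
#' @param main title prefix.
#' @return invisibly, the file path (or NULL when drawn on the active
#'   device).
#' @export
plot_cif_compare <- function(before, after, file = NULL,
                             main = "Cumulative incidence") {
  as_list <- function(z) if (inherits(z, "cif_aj")) list(overall = z) else z
  b <- as_list(before); a <- as_list(after)
  if (!identical(sort(names(b)), sort(names(a))))
    stop("group levels of 'before' and 'after' do not match")
  if (!is.null(file)) {
    grDevices::pdf(file, width = 4.5 * length(b), height = 4.5)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, length(b)))
  on.exit(graphics::par(op), add = TRUE)
  for (g in names(b)) {
    xmax <- max(b[[g]]$time, a[[g]]$time)
    graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 1),
                   xlab = "time", ylab = expression(F[k](t)),
                   main = paste(main, "-", g))
    graphics::lines(b[[g]]$F1, col = 1, lty = 1, do.points = FALSE)
    graphics::lines(b[[g]]$F2, col = 2, lty = 1, do.points = FALSE)
    graphics::lines(a[[g]]$F1, col = 1, lty = 2, do.points = FALSE)
    graphics::lines(a[[g]]$F2, col = 2, lty = 2, do.points = FALSE)
    graphics::legend("topleft", bty = "n", col = c(1, 2, 1, 2),
                     lty = c(1, 1, 2, 2),
                     legend = c("cause 1, before", "cause 2, before",
                                "cause 1, after", "cause 2, after"))
  }
  invisible(file)
}
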