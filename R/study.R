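#' Monte-Carlo mean, bias and mean squared error
#'
#' @param estimates vector of estimates over replicates.
#' @param truth true parameter value.
#' @return named vector: mean, bias = mean - truth, mse = mean of squared
#'   deviations from truth.
#' @export
bias_mse <- function(estimates, truth) {
  if (length(estimates) < 1L) stop("no estimates supplied")
  m <- mean(estimates)
  c(mean = m, bias = m - truth, mse = mean((estimates - truth)^2))
}

#' Monte-Carlo study of the propensity update
#'
#' Simulates `reps` competing-risks datasets from the Weibull
#' proportional-hazards design, fits both cause-specific Cox models on each,
#' applies the propensity-score censoring update separately per cause, refits,
#' and aggregates mean, bias and MSE of every coefficient before and after
#' the update. Replicate r uses seed `seed + r`, so individual replicates are
#' independently reproducible.
#'
#' @inheritParams simulate_crdata
#' @param reps number of replicate datasets.
#' @param p threshold probability for the update.
#' @param signs_method `"mple"` (default) or `"mcmc"`.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param max_fail_frac abort when more than this fraction of replicates
#'   fails to converge.
#' @return object of class `psm_study`: `summary` (data.frame with columns
#'   cause, parameter, condition, mean, bias, mse), `estimates` (reps x
#'   parameter x cause x condition array), `truth`, `config`, `n_failed`,
#'   `failed_reps`.
#' @examples
#' st <- run_simulation_study(n = 100, reps = 5, seed = 1)
#' st
#' @export
run_simulation_study <- function(n = 200, reps = 100,
                                 beta1 = c(-0.5, 0.01, 0.02),
                                 beta2 = c(-0.5, 0.43, 0.03),
                                 gamma = 1.5, lambda = 0.1, censor_time = 5,
                                 p = 0.9, signs_method = c("mple", "mcmc"),
                                 seed = 1, max_fail_frac = 0.1) {
  signs_method <- match.arg(signs_method)
  m <- length(beta1)
  pn <- paste0("beta", seq_len(m))
  est <- array(NA_real_,
               dim = c(reps, m, 2L, 2L),
               dimnames = list(NULL, pn, c("cause1", "cause2"),
                               c("without_psm", "with_psm")))
  failed <- integer(0)
  for (r in seq_len(reps)) {
    d <- simulate_crdata(n = n, beta1 = beta1, beta2 = beta2,
                         gamma = gamma, lambda = lambda,
                         censor_time = censor_time, seed = seed + r)
    ok <- TRUE
    res <- tryCatch({
      for (k in 1:2) {
        fit <- psmcox(d, cause = k, p = p, signs_method = signs_method,
                      seed = seed + r)
        if (!fit$fit_before$converged || !fit$fit_after$converged)
          stop("non-convergence")
        est[r, , k, "without_psm"] <- coef(fit$fit_before)
        est[r, , k, "with_psm"] <- coef(fit$fit_after)
      }
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!isTRUE(res)) {
      failed <- c(failed, r)
      est[r, , , ] <- NA_real_
    }
  }
  if (length(failed) > max_fail_frac * reps)
    stop(length(failed), " of ", reps,
         " replicates failed to converge; study aborted")

  truth <- list(cause1 = beta1, cause2 = beta2)
  rows <- list()
  for (k in 1:2) for (cond in c("without_psm", "with_psm"))
    for (j in seq_len(m)) {
      v <- est[, j, k, cond]
      v <- v[!is.na(v)]
      bm <- bias_mse(v, truth[[k]][j])
      rows[[length(rows) + 1L]] <- data.frame(
        cause = k, parameter = pn[j], condition = cond,
        mean = bm[["mean"]], bias = bm[["bias"]], mse = bm[["mse"]])
    }
  structure(list(summary = do.call(rbind, rows), estimates = est,
                 truth = truth,
                 config = list(n = n, reps = reps, beta1 = beta1,
                               beta2 = beta2, gamma = gamma,
                               lambda = lambda, censor_time = censor_time,
                               p = p, signs_method = signs_method,
                               seed = seed),
                 n_failed = length(failed), failed_reps = failed),
            class = "psm_study")
}

#' @export
print.psm_study <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat("Monte-Carlo study: ", cfg$reps, " replicates x ", cfg$n,
      " subjects (p = ", cfg$p, ", signs = ", cfg$signs_method, ")\n",
      sep = "")
  if (x$n_failed)
    cat("  ", x$n_failed, " replicate(s) excluded (non-convergence)\n",
        sep = "")
  print(format_study_table(x, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Arrange a study summary in the two-cause report layout
#'
#' One row per parameter and condition, columns holding mean/bias/MSE for
#' each cause side by side.
#'
#' @param x a `psm_study` object.
#' @param digits rounding for display.
#' @return data.frame with columns condition, parameter, then
#'   mean/bias/mse for cause 1 and cause 2.
#' @export
format_study_table <- function(x, digits = 4) {
  s <- x$summary
  out <- NULL
  for (cond in unique(s$condition)) {
    a <- s[s$condition == cond & s$cause == 1, ]
    b <- s[s$condition == cond & s$cause == 2, ]
    out <- rbind(out, data.frame(
      condition = cond, parameter = a$parameter,
      mean1 = round(a$mean, digits), bias1 = round(a$bias, digits),
      mse1 = round(a$mse, digits),
      mean2 = round(b$mean, digits), bias2 = round(b$bias, digits),
      mse2 = round(b$mse, digits)))
  }
  out
}

#' Write the study summary and per-replicate estimates to CSV
#' @param x a `psm_study` object.
#' @param summary_path,estimates_path output file paths (either may be NULL
#'   to skip).
#' @export
write_study <- function(x, summary_path = NULL, estimates_path = NULL) {
  if (!is.null(summary_path))
    utils::write.csv(x$summary, summary_path, row.names = FALSE)
  if (!is.null(estimates_path)) {
    e <- x$estimates
    long <- expand.grid(rep = seq_len(dim(e)[1]),
                        parameter = dimnames(e)[[2]],
                        cause = dimnames(e)[[3]],
                        condition = dimnames(e)[[4]],
                        stringsAsFactors = FALSE)
    long$estimate <- as.vector(e)
    utils::write.csv(long, estimates_path, row.names = FALSE)
  }
  invisible(x)
}
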