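# Cause-specific Cox proportional hazards by Newton-Raphson maximization of
# the Breslow partial likelihood. Events of the other cause and censorings are
# treated as censored at their observed times; no intercept is estimable.

# Shared internal engine. time/event are vectors, X a numeric matrix.
# Returns beta, se, vcov, loglik trace, score, baseline ingredients.
cox_engine <- function(time, event, X, tol = 1e-8, max_iter = 100L) {
  n <- length(time)
  m <- ncol(X)
  if (sum(event) < 1L) stop("no events for the requested cause/transition")
  sdX <- apply(X, 2L, stats::sd)
  if (any(sdX == 0))
    stop("constant covariate column: coefficient not identifiable")

  ord <- order(time)           # increasing; risk set = suffix
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]

  loglik_grad_hess <- function(beta, want_hess = TRUE) {
    eta <- drop(X %*% beta)
    eta <- eta - max(eta)                       # guard overflow
    w <- exp(eta)
    # reverse cumulative sums over the suffix risk sets
    S0 <- rev(cumsum(rev(w)))
    S1 <- apply(w * X, 2L, function(col) rev(cumsum(rev(col))))
    if (is.null(dim(S1))) S1 <- matrix(S1, nrow = n)
    # group tied times: risk set taken at the first index of each tie block
    first <- !duplicated(time)
    blk <- cumsum(first)                        # block index per row
    ll <- 0; grad <- numeric(m)
    hess <- matrix(0, m, m)
    ev_idx <- which(event == 1L)
    # per event: eta_i - log S0(block start); Breslow
    starts <- which(first)
    bstart <- starts[blk]
    ll <- sum(eta[ev_idx] - log(S0[bstart[ev_idx]]))
    xbar <- S1 / S0                             # n x m (per row start)
    grad <- colSums(X[ev_idx, , drop = FALSE] -
                    xbar[bstart[ev_idx], , drop = FALSE])
    if (want_hess) {
      # second risk-set moments via reverse cumulative sums: the Breslow
      # hessian is -sum_events [S2/S0 - (S1/S0)(S1/S0)']
      pairs <- which(upper.tri(hess, diag = TRUE), arr.ind = TRUE)
      S2 <- apply(pairs, 1L, function(ab)
        rev(cumsum(rev(w * X[, ab[1]] * X[, ab[2]]))))
      idx <- bstart[ev_idx]
      e2 <- colSums(S2[idx, , drop = FALSE] / S0[idx])
      hess[pairs] <- -e2
      hess[pairs[, 2:1, drop = FALSE]] <- -e2
      M <- xbar[idx, , drop = FALSE]
      hess <- hess + crossprod(M)
    }
    list(ll = ll, grad = grad, hess = hess)
  }

  beta <- numeric(m)
  cur <- loglik_grad_hess(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$hess, cur$grad),
                     error = function(e) stop("singular information matrix"))
    step <- -step
    halve <- 0L
    repeat {
      cand <- beta + step
      new <- loglik_grad_hess(cand)
      if (new$ll >= cur$ll - 1e-12 || halve >= 20L) break
      step <- step / 2
      halve <- halve + 1L
    }
    beta <- cand
    cur <- new
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    if (max(abs(beta) / (sdX + 1e-12)) > 50)  # monotone likelihood escape
      break
  }
  # a huge standardized coefficient means the likelihood is still climbing
  # toward an infinite maximizer even if the score already looks flat
  if (converged && max(abs(beta) * sdX) > 15) converged <- FALSE
  info <- -cur$hess
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, m, m))
  list(beta = beta, se = sqrt(diag(vcov)), vcov = vcov,
       loglik = cur$ll, score = cur$grad,
       converged = converged, iterations = iter,
       ord_time = time, ord_event = event, ord_X = X)
}

#' Cause-specific Cox proportional-hazards model
#'
#' Fits the Cox model for one competing cause by Newton-Raphson maximization
#' of the Breslow partial likelihood, treating the other cause's events and
#' censorings as censored observations. Standard errors come from the inverse
#' observed information; the cumulative baseline hazard is the Nelson-Aalen
#' (Breslow) step estimator evaluated at the fitted coefficients.
#'
#' @param data a [crdata] object (or data.frame with time/status/covariates).
#' @param cause which competing cause to fit, 1 or 2.
#' @param formula optional right-hand-side formula selecting covariates,
#'   e.g. `~ x1 + x2`; default uses every covariate column.
#' @param tol convergence tolerance on the max-norm of the score.
#' @param max_iter Newton-Raphson iteration cap.
#' @return an object of class `cscox` with components `coefficients`, `se`,
#'   `vcov`, `loglik` (length 2: at zero and at the optimum), `baseline`
#'   (right-continuous step function H0(t)), `cause`, `n`, `n_events`,
#'   `converged`, `iterations`.
#' @examples
#' d <- simulate_crdata(n = 100, seed = 42)
#' fit <- cscox(d, cause = 1)
#' summary(fit)
#' @export
cscox <- function(data, cause = 1, formula = NULL, tol = 1e-8,
                  max_iter = 100L) {
  stopifnot(cause %in% 1:2)
  if (!inherits(data, "crdata")) data <- crdata(data)
  X <- covariate_matrix(data)
  if (!is.null(formula)) {
    X <- stats::model.matrix(stats::update(formula, ~ . - 1),
                             as.data.frame(data))
  }
  event <- as.integer(data$status == cause)
  ll0 <- cox_loglik_raw(data$time, event, X, numeric(ncol(X)))
  eng <- cox_engine(data$time, event, X, tol = tol, max_iter = max_iter)
  if (!eng$converged)
    warning("Newton-Raphson did not converge (possibly monotone likelihood)")
  names(eng$beta) <- names(eng$se) <- colnames(X)
  base <- nelson_aalen_baseline(data, cause = cause, beta = eng$beta,
                                X = X)
  structure(list(coefficients = eng$beta, se = eng$se, vcov = eng$vcov,
                 loglik = c(null = ll0, fitted = eng$loglik),
                 score = eng$score, baseline = base,
                 cause = cause, n = nrow(data), n_events = sum(event),
                 converged = eng$converged, iterations = eng$iterations,
                 call = match.call()),
            class = "cscox")
}

# plain Breslow log partial likelihood at a given beta
cox_loglik_raw <- function(time, event, X, beta) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  eta <- drop(X %*% beta)
  w <- exp(eta)
  S0 <- rev(cumsum(rev(w)))
  first <- !duplicated(time)
  bstart <- which(first)[cumsum(first)]
  ev <- which(event == 1L)
  sum(eta[ev] - log(S0[bstart[ev]]))
}

#' Log partial likelihood of a cause-specific Cox model
#'
#' Breslow form: the sum over cause-k events of the linear predictor minus the
#' log of the risk-set sum of exponentiated linear predictors.
#'
#' @inheritParams cscox
#' @param beta coefficient vector at which to evaluate.
#' @return scalar log partial likelihood.
#' @export
cox_loglik <- function(data, cause, beta) {
  if (!inherits(data, "crdata")) data <- crdata(data)
  X <- covariate_matrix(data)
  cox_loglik_raw(data$time, as.integer(data$status == cause), X, beta)
}

#' Nelson-Aalen cumulative baseline hazard
#'
#' Step estimator H0(t) = sum over event times <= t of d_j divided by the
#' risk-set sum of exp(x'beta).
#'
#' @inheritParams cox_loglik
#' @param X optional covariate matrix override.
#' @return a right-continuous step function of class `stepfun`, 0 at t = 0.
#' @export
nelson_aalen_baseline <- function(data, cause, beta, X = NULL) {
  if (!inherits(data, "crdata") && is.null(X)) data <- crdata(data)
  if (is.null(X)) X <- covariate_matrix(data)
  time <- data$time
  event <- as.integer(data$status == cause)
  if (sum(event) == 0L)
    return(stats::stepfun(c(0, max(time)), c(0, 0, 0), right = FALSE))
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  w <- exp(drop(X %*% beta))
  S0 <- rev(cumsum(rev(w)))
  first <- !duplicated(time)
  bstart <- which(first)[cumsum(first)]
  ev_times <- unique(time[event == 1L])
  inc <- vapply(ev_times, function(tt) {
    d <- sum(event == 1L & time == tt)
    d / S0[bstart[match(tt, time)]]
  }, numeric(1))
  stats::stepfun(ev_times, c(0, cumsum(inc)), right = FALSE)
}

#' Transition-specific Cox model on long-format multistate records
#'
#' Fits the Cox model for a single transition of the illness-death topology
#' on the long-format output of [to_long_transitions()]. The joint partial
#' likelihood over transitions factorises, so each transition is fitted on
#' its own rows; the time scale is the sojourn time in the originating state.
#'
#' @param long long-format data.frame from [to_long_transitions()].
#' @param from,to states defining the transition.
#' @param covariates character vector of covariate columns; default: all
#'   numeric columns besides the structural ones.
#' @inheritParams cscox
#' @return a `cscox` object (cause field records the transition label).
#' @export
cscox_transition <- function(long, from, to, covariates = NULL,
                             tol = 1e-8, max_iter = 100L) {
  sub <- long[long$from == from & long$to == to, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for transition ", from, "->", to)
  if (sum(sub$status) == 0L)
    stop("no events for transition ", from, "->", to)
  if (is.null(covariates)) {
    covariates <- setdiff(
      names(sub)[vapply(sub, is.numeric, TRUE)],
      c("id", "from", "to", "entry", "exit", "status", "cause"))
  }
  df <- data.frame(id = sub$id, time = sub$exit - sub$entry,
                   status = sub$status)
  df$time[df$time <= 0] <- 1e-10       # zero sojourn guarded
  for (v in covariates) df[[v]] <- sub[[v]]
  fit <- cscox(crdata(df), cause = 1, tol = tol, max_iter = max_iter)
  fit$transition <- paste0(from, "->", to)
  fit
}

#' @export
print.cscox <- function(x, digits = 4, ...) {
  lab <- if (is.null(x$transition)) paste("cause", x$cause) else
    paste("transition", x$transition)
  cat("Cause-specific Cox model (", lab, "), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  print(round(rbind(coef = x$coefficients, `se` = x$se), digits))
  invisible(x)
}

#' @export
summary.cscox <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(coef = object$coefficients,
               `exp(coef)` = exp(object$coefficients),
               se = object$se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  structure(list(table = tab, loglik = object$loglik, cause = object$cause,
                 n = object$n, n_events = object$n_events,
                 converged = object$converged,
                 iterations = object$iterations),
            class = "summary.cscox")
}

#' @export
print.summary.cscox <- function(x, digits = 4, ...) {
  cat("Cause-specific Cox model, cause ", x$cause, ": n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  stats::printCoefmat(x$table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("log partial likelihood: ", format(x$loglik[["fitted"]], digits = 6),
      " (null ", format(x$loglik[["null"]], digits = 6), "), ",
      x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @export
coef.cscox <- function(object, ...) object$coefficients

#' @export
vcov.cscox <- function(object, ...) object$vcov

#' @export
logLik.cscox <- function(object, ...) {
  structure(object$loglik[["fitted"]], df = length(object$coefficients),
            class = "logLik")
}

#' Linear predictor or relative risk for a fitted cause-specific Cox model
#' @param object a `cscox` fit.
#' @param newdata data.frame or `crdata` with the model's covariate columns;
#'   defaults to refusing (the fit does not store its data).
#' @param type `"lp"` for the linear predictor, `"risk"` for exp(lp).
#' @param ... unused.
#' @export
predict.cscox <- function(object, newdata,
                          type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[names(object$coefficients)])
  lp <- drop(X %*% object$coefficients)
  if (type == "lp") lp else exp(lp)
}

#' Martingale residuals of a cause-specific Cox fit
#' @param object a `cscox` fit.
#' @param data the dataset the model was fitted to.
#' @param ... unused.
#' @return numeric vector delta_i - H0(t_i) exp(x_i'beta).
#' @export
residuals.cscox <- function(object, data, ...) {
  if (!inherits(data, "crdata")) data <- crdata(data)
  X <- as.matrix(as.data.frame(data)[names(object$coefficients)])
  H <- object$baseline(data$time)
  as.integer(data$status == object$cause) -
    H * exp(drop(X %*% object$coefficients))
}
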