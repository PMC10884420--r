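#' Draw baseline covariates
#'
#' Independent standard-normal baseline covariates, one row per subject.
#'
#' @param n number of subjects.
#' @param m number of covariates.
#' @param seed optional RNG seed for reproducibility.
#' @return n x m numeric matrix with columns x1..xm.
#' @export
draw_covariates <- function(n, m, seed = NULL) {
  stopifnot(n >= 1, m >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n * m), nrow = n, ncol = m,
         dimnames = list(NULL, paste0("x", seq_len(m))))
}

#' Invert the Weibull cumulative hazard to an event time
#'
#' Under a proportional-hazards model with Weibull cumulative baseline hazard
#' H(t) = lambda * t^gamma, a uniform draw u maps to the event time
#' t = (-log(u) / (lambda * exp(x'beta)))^(1/gamma).
#'
#' @param u uniform draw(s) in (0, 1].
#' @param x covariate row vector, or a matrix with one row per subject.
#' @param beta coefficient vector.
#' @param lambda,gamma Weibull scale and shape, both > 0.
#' @return simulated event time(s), >= 0.
#' @export
weibull_event_time <- function(u, x, beta, lambda, gamma) {
  stopifnot(lambda > 0, gamma > 0)
  if (any(u <= 0) || any(u > 1)) stop("u must lie in (0, 1]")
  eta <- drop(if (is.matrix(x)) x %*% beta else sum(x * beta))
  (-log(u) / (lambda * exp(eta)))^(1 / gamma)
}

#' Resolve two latent cause-specific times into an observed record
#'
#' Compares the two latent survival times with the administrative censoring
#' time c: if the earlier latent time is within c the subject fails from that
#' cause (exact ties go to cause 1); otherwise the subject is censored at c.
#'
#' @param s1,s2 latent event times for causes 1 and 2 (vectors allowed).
#' @param censor_time administrative censoring time c > 0.
#' @return data.frame with columns `time` and `status`.
#' @export
assign_final_status <- function(s1, s2, censor_time) {
  stopifnot(all(s1 > 0), all(s2 > 0), censor_time > 0)
  s <- pmin(s1, s2)
  obs <- s <= censor_time
  data.frame(time = ifelse(obs, s, censor_time),
             status = ifelse(obs, ifelse(s1 <= s2, 1L, 2L), 0L))
}

#' Simulate a two-cause competing-risks dataset
#'
#' Latent times for the two causes are drawn independently per subject by
#' cumulative-hazard inversion from Weibull proportional-hazards models
#' sharing the covariates but with cause-specific coefficients, then resolved
#' against the administrative censoring time.
#'
#' Defaults are the desk-study configuration: 200 subjects, three N(0,1)
#' covariates, beta^(1) = (-0.5, 0.01, 0.02), beta^(2) = (-0.5, 0.43, 0.03),
#' gamma = 1.5, lambda = 0.1, censoring at 5 years.
#'
#' @param n subjects.
#' @param beta1,beta2 coefficient vectors for causes 1 and 2 (equal length).
#' @param gamma,lambda Weibull shape and scale of both cause-specific
#'   baseline hazards.
#' @param censor_time administrative censoring time (years).
#' @param seed optional RNG seed.
#' @return a [crdata] object with attribute `censor_time` set.
#' @examples
#' d <- simulate_crdata(n = 50, seed = 1)
#' table(d$status)
#' @export
simulate_crdata <- function(n = 200,
                            beta1 = c(-0.5, 0.01, 0.02),
                            beta2 = c(-0.5, 0.43, 0.03),
                            gamma = 1.5, lambda = 0.1,
                            censor_time = 5, seed = NULL) {
  stopifnot(n >= 2, length(beta1) == length(beta2))
  if (!is.null(seed)) set.seed(seed)
  m <- length(beta1)
  X <- draw_covariates(n, m)
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  s1 <- weibull_event_time(u1, X, beta1, lambda, gamma)
  s2 <- weibull_event_time(u2, X, beta2, lambda, gamma)
  fin <- assign_final_status(s1, s2, censor_time)
  df <- data.frame(id = seq_len(n), time = fin$time, status = fin$status)
  df <- cbind(df, as.data.frame(X))
  crdata(df, censor_time = censor_time)
}

#' Simulate a chemoradiotherapy-like four-state cohort
#'
#' Synthetic analogue of a head-and-neck chemoradiotherapy cohort: 536
#' subjects followed over an illness-death topology LRC -> FP -> DP -> Death
#' with direct LRC -> Death allowed. Six continuous baseline labs
#' (hemoglobin, sugar, creatinine, albumin, sodium, potassium) and a binary
#' gender label are generated; transition times are Weibull with rates chosen
#' so the two competing death counts land near 154 (death after progression,
#' cause 1) and 75 (direct death, cause 2) out of 536, with roughly 307
#' censored. The real cohort is not public; this fixture only emulates its
#' shape and makes no numerical claims about it.
#'
#' @param n cohort size.
#' @param seed optional RNG seed.
#' @param rates named list of Weibull (shape, rate) pairs per transition
#'   `t12`, `t14`, `t23`, `t24`, `t34`; see Details for defaults.
#' @param followup_range administrative follow-up window (years); each
#'   subject's last follow-up is uniform on this interval.
#' @return wide data.frame: id, lrc_time, fp_time, dp_time, death_time,
#'   cause, last_followup, cov1..cov6, gender.
#' @export
simulate_chemo_analog <- function(n = 536, seed = NULL,
                                  rates = list(t12 = c(1.2, 0.14),
                                               t14 = c(1.2, 0.043),
                                               t23 = c(1.1, 0.35),
                                               t24 = c(1.1, 0.42),
                                               t34 = c(1.1, 0.80)),
                                  followup_range = c(2, 6)) {
  if (!is.null(seed)) set.seed(seed)
  rweib <- function(n, par) {
    # inversion of H(t) = rate * t^shape
    (-log(stats::runif(n)) / par[2])^(1 / par[1])
  }
  covs <- cbind(cov1 = stats::rnorm(n, 12.5, 1.6),   # hemoglobin g/dL
                cov2 = stats::rnorm(n, 105, 22),     # sugar mg/dL
                cov3 = stats::rnorm(n, 0.9, 0.22),   # creatinine mg/dL
                cov4 = stats::rnorm(n, 4.0, 0.45),   # albumin g/dL
                cov5 = stats::rnorm(n, 138, 3.1),    # sodium mmol/L
                cov6 = stats::rnorm(n, 4.2, 0.42))   # potassium mmol/L
  gender <- ifelse(stats::runif(n) < 0.72, "male", "female")
  fu <- stats::runif(n, followup_range[1], followup_range[2])

  t12 <- rweib(n, rates$t12); t14 <- rweib(n, rates$t14)
  fp_time <- death_time <- dp_time <- rep(NA_real_, n)
  cause <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (t14[i] <= t12[i] && t14[i] <= fu[i]) {        # direct death
      death_time[i] <- t14[i]; cause[i] <- 2L
    } else if (t12[i] < t14[i] && t12[i] <= fu[i]) {  # first progression
      fp_time[i] <- t12[i]
      t23 <- fp_time[i] + rweib(1L, rates$t23)
      t24 <- fp_time[i] + rweib(1L, rates$t24)
      if (t24 <= t23 && t24 <= fu[i]) {
        death_time[i] <- t24; cause[i] <- 1L
      } else if (t23 < t24 && t23 <= fu[i]) {         # distant progression
        dp_time[i] <- t23
        t34 <- dp_time[i] + rweib(1L, rates$t34)
        if (t34 <= fu[i]) { death_time[i] <- t34; cause[i] <- 1L }
      }
    }
  }
  data.frame(id = seq_len(n), lrc_time = 0,
             fp_time = fp_time, dp_time = dp_time,
             death_time = death_time, cause = cause,
             last_followup = fu,
             as.data.frame(covs), gender = gender,
             stringsAsFactors = FALSE)
}
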