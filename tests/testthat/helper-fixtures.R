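# Small fixture builders shared across the suite. All data are generated in
# code; nothing is read from disk.

tiny_crdata <- function() {
  crdata(data.frame(id = 1:3, time = c(2, 5, 1.5), status = c(1, 0, 2),
                    x1 = c(0.3, -1.2, 0.8)),
         censor_time = 5)
}

# random competing-risks dataset with unstructured times, for oracle checks
random_crdata <- function(n = 50, m = 3, p_cens = 0.3) {
  status <- sample(0:2, n, replace = TRUE, prob = c(p_cens,
                                                    (1 - p_cens) / 2,
                                                    (1 - p_cens) / 2))
  if (!any(status == 1L)) status[1] <- 1L
  if (!any(status == 2L)) status[2] <- 2L
  df <- data.frame(id = seq_len(n),
                   time = round(rexp(n, 0.5), 4) + 0.01,
                   status = status)
  for (j in seq_len(m)) df[[paste0("x", j)]] <- rnorm(n)
  crdata(df)
}

# four-subject single-cause worked example: all events, covariate 1,0,1,0
four_subject_crdata <- function() {
  crdata(data.frame(id = 1:4, time = 1:4, status = 1L,
                    z = c(1, 0, 1, 0)))
}
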