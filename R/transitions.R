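#' Expand a wide four-state record table into long transition format
#'
#' The illness-death topology has states 1 = loco-regional control (LRC),
#' 2 = first progression (FP), 3 = distant progression (DP), 4 = death, with
#' forward-only transitions 1->2, 1->4, 2->3, 2->4, 3->4. Death reached
#' directly from state 1 is competing cause 2; death after any progression is
#' competing cause 1.
#'
#' Each subject contributes one row per transition they were at risk for:
#' `status = 1` for the realized transition, 0 for the competing ones, with
#' `entry`/`exit` giving the sojourn interval in the originating state.
#'
#' @param wide data.frame with columns `id`, `lrc_time` (entry into state 1,
#'   usually 0), optional `fp_time`, `dp_time`, `death_time`, `cause`
#'   (1 or 2, for deaths), `last_followup`, plus any covariate columns, which
#'   are carried through unchanged.
#' @return data.frame in long format: id, from, to, entry, exit, status,
#'   cause (1/2 for rows into state 4, NA otherwise), then covariates.
#' @export
to_long_transitions <- function(wide) {
  stopifnot(is.data.frame(wide),
            all(c("id", "lrc_time", "last_followup") %in% names(wide)))
  opt <- c("fp_time", "dp_time", "death_time", "cause")
  for (v in opt) if (!v %in% names(wide)) wide[[v]] <- NA_real_
  covs <- setdiff(names(wide), c("id", "lrc_time", opt, "last_followup"))

  rows <- vector("list", nrow(wide))
  for (i in seq_len(nrow(wide))) {
    r <- wide[i, ]
    tt <- c(lrc = r$lrc_time, fp = r$fp_time, dp = r$dp_time,
            death = r$death_time, fu = r$last_followup)
    seen <- tt[!is.na(tt)]
    if (is.unsorted(c(r$lrc_time, seen[setdiff(names(seen), "lrc")]),
                    strictly = FALSE) ||
        any(seen < r$lrc_time))
      stop("event dates out of order for subject ", r$id)
    dead <- !is.na(r$death_time)
    out <- list()
    add <- function(from, to, entry, exit, status, cause = NA_integer_) {
      out[[length(out) + 1L]] <<- data.frame(
        id = r$id, from = from, to = to,
        entry = entry, exit = exit, status = status, cause = cause)
    }
    # state 1 occupancy
    exit1 <- min(c(r$fp_time, r$death_time, r$last_followup), na.rm = TRUE)
    to_fp <- !is.na(r$fp_time) && r$fp_time <= exit1
    died1 <- dead && !to_fp && r$death_time <= exit1
    add(1L, 2L, r$lrc_time, exit1, as.integer(to_fp))
    add(1L, 4L, r$lrc_time, exit1, as.integer(died1),
        if (died1) 2L else NA_integer_)
    if (to_fp) {
      exit2 <- min(c(r$dp_time, r$death_time, r$last_followup), na.rm = TRUE)
      to_dp <- !is.na(r$dp_time) && r$dp_time <= exit2
      died2 <- dead && !to_dp && r$death_time <= exit2
      add(2L, 3L, r$fp_time, exit2, as.integer(to_dp))
      add(2L, 4L, r$fp_time, exit2, as.integer(died2),
          if (died2) 1L else NA_integer_)
      if (to_dp) {
        exit3 <- min(c(r$death_time, r$last_followup), na.rm = TRUE)
        died3 <- dead && r$death_time <= exit3
        add(3L, 4L, r$dp_time, exit3, as.integer(died3),
            if (died3) 1L else NA_integer_)
      }
    }
    blk <- do.call(rbind, out)
    if (any(blk$exit < blk$entry))
      stop("event dates out of order for subject ", r$id)
    for (v in covs) blk[[v]] <- r[[v]]
    rows[[i]] <- blk
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Collapse a wide four-state table to a competing-risks dataset
#'
#' Maps each subject to the two-cause competing-risks view used by the
#' cause-specific Cox machinery: observed time is the death time (status =
#' recorded cause) or the last follow-up (status = 0).
#'
#' @inheritParams to_long_transitions
#' @param group optional name of a column to attach as group label.
#' @return a [crdata] object.
#' @export
wide_to_crdata <- function(wide, group = NULL) {
  dead <- !is.na(wide$death_time)
  df <- data.frame(id = wide$id,
                   time = ifelse(dead, wide$death_time, wide$last_followup),
                   status = ifelse(dead, wide$cause, 0L))
  covs <- setdiff(names(wide),
                  c("id", "lrc_time", "fp_time", "dp_time", "death_time",
                    "cause", "last_followup"))
  for (v in covs) df[[v]] <- wide[[v]]
  num <- covs[vapply(wide[covs], is.numeric, TRUE)]
  crdata(df, covariates = setdiff(num, group), group = group)
}
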