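#' Default activity parameters for free-play sessions
#'
#' Per-activity mean and SD of total in-session duration (minutes, from the
#' observed 20-minute free-play sessions: energetic play 11.7 +/- 4.0,
#' walking 2.8 +/- 1.9, running 2.4 +/- 1.1, seated 4.3 +/- 2.3) and the MET
#' target driving the generator's EE model (seated 1.3, walking 3.7, running
#' 6.0, energetic play 4.5).
#'
#' @return data.frame with columns `activity`, `total_mean_min`,
#'   `total_sd_min`, `target_met`.
#' @export
activity_defaults <- function() {
  data.frame(
    activity = c("seated", "walking", "running", "energetic_play"),
    total_mean_min = c(4.3, 2.8, 2.4, 11.7),
    total_sd_min = c(2.3, 1.9, 1.1, 4.0),
    target_met = c(1.3, 3.7, 6.0, 4.5),
    stringsAsFactors = FALSE
  )
}

#' Generate a randomized free-play activity schedule
#'
#' Draws per-activity total durations from truncated normals with the
#' [activity_defaults()] means/SDs, rescales them so the totals sum exactly to
#' `session_length` (keeping expected totals proportional to the configured
#' means), splits each active behaviour into 1-3 bouts, and interleaves the
#' active bouts in random order with seated segments between them. Bout
#' durations are integer seconds and conserve `session_length` exactly.
#'
#' @param seed integer seed.
#' @param session_length session length in seconds (> 0; default 1200, the
#'   20-minute play session).
#' @param activities data.frame as returned by [activity_defaults()].
#' @return data.frame with columns `activity`, `duration_s`, `target_met`,
#'   `start_s`; durations sum to `session_length`.
#' @export
default_schedule <- function(seed = 1L, session_length = 1200,
                             activities = activity_defaults()) {
  if (!is.numeric(session_length) || session_length <= 0)
    stop("`session_length` must be positive")
  min_bout <- 10
  if (session_length < min_bout * nrow(activities))
    stop("`session_length` shorter than the minimum schedulable bouts")
  with_seed(seed, {
    tot <- stats::rnorm(nrow(activities),
                        activities$total_mean_min * 60,
                        activities$total_sd_min * 60)
    tot <- pmax(tot, min_bout)
    tot <- tot / sum(tot) * session_length
    # split each active behaviour into 1-3 bouts
    bouts <- list()
    for (i in seq_len(nrow(activities))) {
      act <- activities$activity[i]
      if (act == "seated") next
      k <- sample(1:3, 1)
      w <- stats::rgamma(k, shape = 2)
      d <- tot[i] * w / sum(w)
      keep <- d >= min_bout / 2
      if (!any(keep)) { d <- sum(d); keep <- TRUE }
      d <- d[keep] * tot[i] / sum(d[keep])
      bouts[[act]] <- d
    }
    active <- data.frame(
      activity = rep(names(bouts), lengths(bouts)),
      duration_s = unlist(bouts, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    active <- active[sample.int(nrow(active)), , drop = FALSE]
    # seated total split across the gaps: before, between and after active bouts
    seated_tot <- tot[activities$activity == "seated"]
    ngap <- nrow(active) + 1L
    gw <- stats::rgamma(ngap, shape = 1.5)
    seated <- seated_tot * gw / sum(gw)
    out <- data.frame(activity = character(0), duration_s = numeric(0))
    for (j in seq_len(nrow(active))) {
      out <- rbind(out, data.frame(activity = "seated", duration_s = seated[j]),
                   active[j, c("activity", "duration_s")])
    }
    out <- rbind(out, data.frame(activity = "seated", duration_s = seated[ngap]))
    out <- out[out$duration_s >= 1, , drop = FALSE]
    # integer seconds conserving the session length exactly
    d <- floor(out$duration_s)
    rem <- session_length - sum(d)
    if (rem != 0) {
      ord <- order(out$duration_s - d, decreasing = rem > 0)
      bump <- ord[seq_len(min(abs(rem), length(d)))]
      d[bump] <- d[bump] + sign(rem)
      d[which.max(d)] <- d[which.max(d)] + (session_length - sum(d))
    }
    out$duration_s <- d
    out <- out[out$duration_s > 0, , drop = FALSE]
    out$target_met <- activities$target_met[match(out$activity,
                                                  activities$activity)]
    out$start_s <- cumsum(c(0, out$duration_s[-nrow(out)]))
    rownames(out) <- NULL
    stopifnot(sum(out$duration_s) == session_length)
    out
  })
}
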