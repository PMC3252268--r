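# Half-life estimation from transcription-shutoff (actinomycin D chase)
# decay time courses, with censoring of slow decays.

#' Fit an mRNA half-life from a decay time course
#'
#' Models first-order decay: abundance is normalised to the value at time 0
#' and its natural log regressed on time by ordinary least squares; the
#' half-life is `ln(2) / |slope|`. Decays too slow to quantify inside the
#' chase window — a non-negative slope, or a fitted half-life beyond
#' `censor_limit` — are reported as censored ("> censor_limit"), the standard
#' treatment when the signal has not fallen far enough for an accurate rate.
#'
#' @param times Numeric vector of time points in minutes, strictly
#'   increasing, starting at 0 (length >= 3).
#' @param abundance Positive relative abundances at `times` (units are
#'   irrelevant; the log-linear fit has an intercept).
#' @param censor_limit Censoring threshold in minutes (default 240, a typical
#'   2-hour chase quantification limit).
#' @return An object of class `half_life`: list with `value` (minutes; equal
#'   to `censor_limit` when censored), `censored` (logical), and `slope`
#'   (per-minute log-decay rate).
#' @examples
#' fit_half_life(c(0, 30, 60, 120), 2^(-c(0, 30, 60, 120) / 60))  # 60 min
#' @export
fit_half_life <- function(times, abundance, censor_limit = 240) {
  if (length(times) != length(abundance) || length(times) < 3L) {
    stop("need >= 3 matched (time, abundance) points", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (times[1L] != 0) stop("time course must include t = 0", call. = FALSE)
  if (any(abundance <= 0)) {
    stop("abundance must be positive", call. = FALSE)
  }
  slope <- unname(coef(lm(log(abundance) ~ times))[2L])
  if (slope >= 0) {
    return(structure(list(value = censor_limit, censored = TRUE,
                          slope = slope), class = "half_life"))
  }
  hl <- log(2) / abs(slope)
  structure(list(value = if (hl > censor_limit) censor_limit else hl,
                 censored = hl > censor_limit, slope = slope),
            class = "half_life")
}

#' @export
print.half_life <- function(x, ...) {
  if (x$censored) cat(sprintf("half-life > %g min (censored)\n", x$value))
  else cat(sprintf("half-life %.4g min\n", x$value))
  invisible(x)
}

#' @export
format.half_life <- function(x, ...) {
  if (x$censored) paste0(">", format(x$value, ...)) else format(x$value, ...)
}

#' Fit half-lives for a table of decay time courses
#'
#' @param tc A data.frame with columns `id`, `time_min`, `abundance` (one row
#'   per measurement; several transcripts may share the table).
#' @inheritParams fit_half_life
#' @return A data.frame with one row per `id`: `id`, `half_life` (minutes),
#'   `censored`.
#' @export
fit_half_lives <- function(tc, censor_limit = 240) {
  need <- c("id", "time_min", "abundance")
  if (!is.data.frame(tc) || !all(need %in% names(tc))) {
    stop("`tc` needs columns id, time_min, abundance", call. = FALSE)
  }
  ids <- unique(tc$id)
  rows <- lapply(ids, function(i) {
    sub <- tc[tc$id == i, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    hl <- fit_half_life(sub$time_min, sub$abundance, censor_limit)
    data.frame(id = i, half_life = hl$value, censored = hl$censored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
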