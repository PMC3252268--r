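#' Scoring parameters
#'
#' Bundles every tunable parameter of the ARE scorer. The defaults are the
#' standard setting: each AUUUA pentamer contributes `pentamer_value` to the
#' basal score; neighbouring pentamers add `overlap_bonus` when they overlap,
#' `gap0_3_bonus` when separated by 0-3 nt, `gap4_6_bonus` for 4-6 nt and
#' `gap7_9_bonus` for 7-9 nt; a pentamer lying inside an AU-block adds
#' `block_bonus`. An AU-block opens where a `block_word`-nt window reaches an
#' A+U fraction of at least `block_start_au` and persists while subsequent
#' windows stay at or above `block_end_au`.
#'
#' @param pentamer_value Score units added per AUUUA pentamer (default 1).
#' @param overlap_bonus Bonus for overlapping neighbouring pentamers (1.5).
#' @param gap0_3_bonus Bonus when 0-3 nt separate neighbouring pentamers (0.75).
#' @param gap4_6_bonus Bonus for a 4-6 nt separation (0.4).
#' @param gap7_9_bonus Bonus for a 7-9 nt separation (0.2).
#' @param block_bonus Bonus per pentamer inside an AU-block (0.3).
#' @param block_word Sliding-window width in nt (default 20).
#' @param block_start_au A+U fraction opening a block (default 0.80).
#' @param block_end_au A+U fraction below which a block ends (default 0.55).
#'
#' @return An object of class `score_config` (a named list).
#' @examples
#' cfg <- score_config()
#' score_config(overlap_bonus = 0)
#' @export
score_config <- function(pentamer_value = 1,
                         overlap_bonus = 1.5,
                         gap0_3_bonus = 0.75,
                         gap4_6_bonus = 0.4,
                         gap7_9_bonus = 0.2,
                         block_bonus = 0.3,
                         block_word = 20L,
                         block_start_au = 0.80,
                         block_end_au = 0.55) {
  cfg <- list(
    pentamer_value = as.numeric(pentamer_value),
    overlap_bonus = as.numeric(overlap_bonus),
    gap0_3_bonus = as.numeric(gap0_3_bonus),
    gap4_6_bonus = as.numeric(gap4_6_bonus),
    gap7_9_bonus = as.numeric(gap7_9_bonus),
    block_bonus = as.numeric(block_bonus),
    block_word = as.integer(block_word),
    block_start_au = as.numeric(block_start_au),
    block_end_au = as.numeric(block_end_au)
  )
  bonuses <- unlist(cfg[c("overlap_bonus", "gap0_3_bonus", "gap4_6_bonus",
                          "gap7_9_bonus", "block_bonus")])
  if (any(!is.finite(bonuses)) || any(bonuses < 0)) {
    stop("all bonuses must be finite and >= 0", call. = FALSE)
  }
  if (cfg$block_word < 5L) {
    stop("block_word must be >= 5 nt", call. = FALSE)
  }
  if (!(cfg$block_end_au > 0 && cfg$block_end_au <= cfg$block_start_au &&
        cfg$block_start_au <= 1)) {
    stop("need 0 < block_end_au <= block_start_au <= 1", call. = FALSE)
  }
  structure(cfg, class = "score_config")
}

#' @export
print.score_config <- function(x, ...) {
  cat("ARE scoring configuration\n")
  cat(sprintf("  pentamer value     %.3g\n", x$pentamer_value))
  cat(sprintf("  proximity bonuses  overlap %.3g | 0-3 nt %.3g | 4-6 nt %.3g | 7-9 nt %.3g\n",
              x$overlap_bonus, x$gap0_3_bonus, x$gap4_6_bonus, x$gap7_9_bonus))
  cat(sprintf("  AU-block           bonus %.3g | word %d nt | start >= %.0f%% | end >= %.0f%%\n",
              x$block_bonus, x$block_word, 100 * x$block_start_au,
              100 * x$block_end_au))
  invisible(x)
}

as_score_config <- function(cfg) {
  if (is.null(cfg)) return(score_config())
  if (inherits(cfg, "score_config")) return(cfg)
  if (is.list(cfg)) return(do.call(score_config, cfg))
  stop("`cfg` must be a score_config or a named list", call. = FALSE)
}
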