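# Analysis statistics: distributions, 2x2 enrichment, ROC/AUC, censored
# rank correlation, grouped summaries.

#' Bin a score distribution
#'
#' Tallies scores into half-open bins `[lo, hi)` given by `bin_edges` and
#' returns per-bin frequencies plus the cumulative distribution. The last edge
#' may be `Inf` for an open-ended top bin.
#'
#' @param scores Numeric vector of scores (non-empty).
#' @param bin_edges Increasing numeric vector of bin edges covering all
#'   scores.
#' @return A data.frame with `lo`, `hi`, `count`, `frequency`, `cumulative`.
#' @export
score_distribution <- function(scores, bin_edges) {
  if (length(scores) == 0L) stop("`scores` is empty", call. = FALSE)
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be strictly increasing with >= 2 values",
         call. = FALSE)
  }
  if (any(scores < bin_edges[1L]) || any(scores >= bin_edges[length(bin_edges)])) {
    stop("scores fall outside [first edge, last edge)", call. = FALSE)
  }
  bin <- findInterval(scores, bin_edges, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(bin_edges) - 1L)
  freq <- counts / length(scores)
  data.frame(lo = head(bin_edges, -1L), hi = tail(bin_edges, -1L),
             count = counts, frequency = freq, cumulative = cumsum(freq))
}

#' ARE enrichment at a score threshold
#'
#' Builds the 2x2 table of scores at/above versus below `thresh` in a real
#' group against a control group, and tests whether high scores are enriched
#' in the real group: Pearson chi-squared without continuity correction,
#' two-sided Fisher's exact test, and the phi association coefficient
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`. Positive phi means high scores
#' are over-represented in the real group.
#'
#' @param real_scores Numeric scores of the group under test.
#' @param control_scores Numeric scores of the control/null group.
#' @param thresh Score threshold (default 4, a practical cut between
#'   ARE-poor and ARE-bearing transcripts; enrichment of strong AREs is often
#'   assessed at 10).
#' @return An object of class `contingency_result`: list with the counts
#'   `a` (real >= thresh), `b` (real < thresh), `c` (control >= thresh),
#'   `d` (control < thresh), `chi2_p` (NA when a table margin is zero),
#'   `fisher_p`, and `phi` (NA when a margin is zero).
#' @export
enrichment_at_threshold <- function(real_scores, control_scores, thresh = 4) {
  if (length(real_scores) == 0L || length(control_scores) == 0L) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  a <- sum(real_scores >= thresh); b <- sum(real_scores < thresh)
  cc <- sum(control_scores >= thresh); d <- sum(control_scores < thresh)
  contingency_result(a, b, cc, d)
}

#' 2x2 contingency statistics from raw counts
#'
#' @param a,b,c,d Counts of the table `[[a, b], [c, d]]` (rows: real/control,
#'   columns: at/above threshold, below threshold).
#' @return See [enrichment_at_threshold()].
#' @export
contingency_result <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  margins_ok <- all(rowSums(tab) > 0L) && all(colSums(tab) > 0L)
  chi2_p <- NA_real_
  phi <- NA_real_
  if (margins_ok) {
    chi2_p <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value)
    phi <- (a * d - b * c) /
      sqrt(prod(c(a + b, c + d, a + c, b + d)))
  }
  fisher_p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  structure(list(a = a, b = b, c = c, d = d,
                 chi2_p = chi2_p, fisher_p = fisher_p, phi = phi),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 enrichment\n")
  cat(sprintf("  real:    %d >= thresh, %d below\n", x$a, x$b))
  cat(sprintf("  control: %d >= thresh, %d below\n", x$c, x$d))
  cat(sprintf("  phi = %s, chi2 p = %s, Fisher p = %.3g\n",
              format(x$phi, digits = 3), format(x$chi2_p, digits = 3),
              x$fisher_p))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps every unique observed score as a threshold, predicting "positive"
#' (e.g. labile mRNA) when score >= threshold, and computes the area under
#' the resulting curve by the trapezoid rule. With ties counted as half, this
#' equals the Mann-Whitney U statistic divided by `n_pos * n_neg`: the
#' probability that a random positive outscores a random negative.
#'
#' @param pos_scores Scores of the positive class (non-empty).
#' @param neg_scores Scores of the negative class (non-empty).
#' @return An object of class `roc_result`: list with `thresholds` (swept
#'   descending, including `Inf` and `-Inf` endpoints), `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both score groups must be non-empty", call. = FALSE)
  }
  th <- c(Inf, sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE),
          -Inf)
  tpr <- vapply(th, function(t) mean(pos_scores >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(neg_scores >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Spearman rank correlation with optional censoring
#'
#' Computes the Spearman correlation as the Pearson correlation of
#' average-rank vectors. Censored observations (e.g. half-lives only known to
#' exceed 240 minutes) are treated as mutually tied at the largest rank,
#' which uses their ordering information without inventing a magnitude.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param x_censored,y_censored Optional logical vectors flagging censored
#'   ("greater than") entries of `x`/`y`.
#' @return The correlation coefficient in `[-1, 1]`; `NA` with a warning when
#'   either rank vector has zero variance.
#' @export
spearman_censored <- function(x, y, x_censored = NULL, y_censored = NULL) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("`x` and `y` must have equal length >= 3", call. = FALSE)
  }
  rank_with_censoring <- function(v, cens) {
    if (!is.null(cens)) {
      stopifnot(length(cens) == length(v))
      v[cens] <- Inf  # censored entries tie above every observed value
    }
    rank(v, ties.method = "average")
  }
  rx <- rank_with_censoring(x, x_censored)
  ry <- rank_with_censoring(y, y_censored)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("zero variance in ranks; correlation undefined")
    return(NA_real_)
  }
  cor(rx, ry)
}

#' Grouped mean, standard error and t-test against the pooled mean
#'
#' Summarises a numeric outcome (e.g. log2 expression level) within groups
#' (e.g. score bins): per-group mean, standard error, and a two-sided
#' one-sample t-test of the group against the pooled mean of all values.
#' Groups of size 1 report `NA` for the SE and p-value.
#'
#' @param values Numeric vector.
#' @param group_labels Vector of group labels, same length as `values`.
#' @return A data.frame with `group`, `n`, `mean`, `se`, `p_vs_pooled`;
#'   the pooled mean is in `attr(, "pooled_mean")`. Groups appear in order of
#'   first appearance.
#' @export
group_summary <- function(values, group_labels) {
  if (length(values) != length(group_labels) || length(values) == 0L) {
    stop("`values` and `group_labels` must be non-empty and equal length",
         call. = FALSE)
  }
  pooled <- mean(values)
  labels <- unique(group_labels)
  rows <- lapply(labels, function(g) {
    v <- values[group_labels == g]
    n <- length(v)
    se <- if (n > 1L) sd(v) / sqrt(n) else NA_real_
    p <- if (n > 1L && sd(v) > 0) t.test(v, mu = pooled)$p.value else NA_real_
    data.frame(group = as.character(g), n = n, mean = mean(v), se = se,
               p_vs_pooled = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pooled_mean") <- pooled
  out
}
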