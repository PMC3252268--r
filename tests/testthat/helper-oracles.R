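# Independent brute-force oracles. These apply the scoring rules literally
# (per-position loops, exhaustive enumeration) and share no code with the
# package implementation.

oracle_normalize <- function(seq) chartr("Uu", "TT", toupper(seq))

# every 5-mer compared against ATTTA, one position at a time
oracle_pentamers <- function(seq) {
  s <- oracle_normalize(seq)
  n <- nchar(s)
  hits <- integer(0)
  if (n >= 5L) {
    for (i in 1:(n - 4L)) {
      if (substr(s, i, i + 4L) == "ATTTA") hits <- c(hits, i)
    }
  }
  hits
}

# literal open/extend/close state machine over window starts, then merge
oracle_blocks <- function(seq, word = 20L, start_au = 0.80, end_au = 0.55) {
  s <- oracle_normalize(seq)
  n <- nchar(s)
  if (n < word) return(data.frame(start = integer(0), end = integer(0)))
  win_au <- function(i) {
    chars <- strsplit(substr(s, i, i + word - 1L), "")[[1]]
    mean(chars %in% c("A", "T"))
  }
  open <- FALSE
  bs <- integer(0); be <- integer(0)
  cur_start <- NA_integer_; cur_end <- NA_integer_
  for (i in 1:(n - word + 1L)) {
    f <- win_au(i)
    if (!open) {
      if (f >= start_au) {
        open <- TRUE
        cur_start <- i
        cur_end <- i + word - 1L
      }
    } else {
      if (f >= end_au) {
        cur_end <- i + word - 1L
      } else {
        bs <- c(bs, cur_start); be <- c(be, cur_end)
        open <- FALSE
      }
    }
  }
  if (open) { bs <- c(bs, cur_start); be <- c(be, cur_end) }
  if (length(bs) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  # merge overlapping/adjacent
  out_s <- bs[1]; out_e <- be[1]
  if (length(bs) > 1L) {
    for (j in 2:length(bs)) {
      if (bs[j] <= out_e[length(out_e)] + 1L) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], be[j])
      } else {
        out_s <- c(out_s, bs[j]); out_e <- c(out_e, be[j])
      }
    }
  }
  data.frame(start = out_s, end = out_e)
}

# literal rule application for the full score; per-pair bonuses are collected
# and summed as one vector so the component totals are bit-reproducible
oracle_total <- function(seq, pentamer_value = 1, overlap = 1.5,
                         g03 = 0.75, g46 = 0.4, g79 = 0.2, blockb = 0.3,
                         word = 20L, start_au = 0.80, end_au = 0.55) {
  hits <- oracle_pentamers(seq)
  pair <- numeric(0)
  if (length(hits) > 1L) {
    for (j in 2:length(hits)) {
      gap <- hits[j] - hits[j - 1L] - 5L
      pair <- c(pair,
        if (gap < 0) overlap
        else if (gap <= 3) g03
        else if (gap <= 6) g46
        else if (gap <= 9) g79
        else 0)
    }
  }
  blocks <- oracle_blocks(seq, word, start_au, end_au)
  contained <- 0L
  for (h in hits) {
    if (nrow(blocks) > 0L &&
        any(blocks$start <= h & h + 4L <= blocks$end)) {
      contained <- contained + 1L
    }
  }
  length(hits) * pentamer_value + sum(pair) + blockb * contained
}

# random test sequence with a target AU fraction
random_seq <- function(len, au = 0.6) {
  paste(sample(c("A", "U", "G", "C"), len, replace = TRUE,
               prob = c(au / 2, au / 2, (1 - au) / 2, (1 - au) / 2)),
        collapse = "")
}

# exhaustive two-sided Fisher p: enumerate all 2x2 tables with the observed
# margins, sum hypergeometric probabilities <= that of the observed table
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  p_of <- function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }
  p_obs <- p_of(a)
  total <- 0
  for (x in lo:hi) {
    px <- p_of(x)
    if (px <= p_obs * (1 + 1e-7)) total <- total + px
  }
  total
}

# AUC by exhaustive pair counting, ties as half
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Spearman by direct rank-Pearson with average ranks
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mean((rx - mean(rx)) * (ry - mean(ry))) / (sd2(rx) * sd2(ry))
}
sd2 <- function(v) sqrt(mean((v - mean(v))^2))
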