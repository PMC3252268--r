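# Core scorer. Sequences are normalised once (uppercase, U -> T) and scored on
# the DNA alphabet; all user-facing coordinates are 1-based inclusive.

normalize_seq <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) {
    stop("`seq` must be a single character string", call. = FALSE)
  }
  chartr("Uu", "TT", toupper(seq))
}

# logical vector: TRUE where the base is A or T/U (ambiguity letters and
# anything else count as non-AU)
au_mask <- function(chars) chars == "A" | chars == "T"

#' Locate AUUUA pentamers
#'
#' Finds every occurrence of the AUUUA pentamer, including overlapping ones
#' (AUUUAUUUA carries two). Matching is case-insensitive and treats T and U
#' identically; IUPAC ambiguity letters never match.
#'
#' @param seq A single nucleotide string (DNA or RNA alphabet, any case).
#' @return Integer vector of 1-based start positions, ascending.
#' @examples
#' find_pentamers("AUUUAUUUA")
#' find_pentamers("atttagcgcATTTA")
#' @export
find_pentamers <- function(seq) {
  s <- normalize_seq(seq)
  n <- nchar(s)
  if (n < 5L) return(integer(0))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  isA <- chars == "A"
  isT <- chars == "T"
  i <- seq_len(n - 4L)
  which(isA[i] & isT[i + 1L] & isT[i + 2L] & isT[i + 3L] & isA[i + 4L])
}

#' Locate AU-blocks
#'
#' Slides a `block_word`-nt window along the sequence. A block opens at the
#' start of the first window whose A+U fraction reaches `block_start_au`; it
#' then extends while each subsequent window keeps an A+U fraction of at least
#' `block_end_au`, and closes at the end of the last qualifying window.
#' Overlapping or adjacent blocks are merged, so the returned blocks are
#' disjoint, sorted and maximal.
#'
#' @inheritParams find_pentamers
#' @param cfg A [score_config()].
#' @return A data.frame with 1-based inclusive `start` and `end` columns; zero
#'   rows when the sequence is shorter than `block_word` or no window opens a
#'   block.
#' @examples
#' find_au_blocks(strrep("AU", 15))
#' @export
find_au_blocks <- function(seq, cfg = score_config()) {
  cfg <- as_score_config(cfg)
  s <- normalize_seq(seq)
  n <- nchar(s)
  w <- cfg$block_word
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < w) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  cs <- cumsum(au_mask(chars))
  starts <- seq_len(n - w + 1L)
  win_au <- (cs[starts + w - 1L] - c(0, cs)[starts]) / w

  keep <- win_au >= cfg$block_end_au     # window can sustain an open block
  open <- win_au >= cfg$block_start_au   # window can open a block
  if (!any(open)) return(empty)

  # runs of consecutive sustaining windows; a run yields a block iff it
  # contains an opening window, spanning from that window's start to the end
  # of the run's last window
  r <- rle(keep)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  bs <- integer(0); be <- integer(0)
  for (k in which(r$values)) {
    idx <- run_start[k]:run_end[k]
    first_open <- idx[open[idx]][1L]
    if (!is.na(first_open)) {
      bs <- c(bs, first_open)
      be <- c(be, run_end[k] + w - 1L)
    }
  }
  if (length(bs) == 0L) return(empty)

  # merge overlapping/adjacent blocks (runs are window-disjoint but the +w-1
  # extension can make blocks touch)
  ms <- bs[1L]; me <- be[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (j in seq_along(bs)[-1L]) {
    if (bs[j] <= me + 1L) {
      me <- max(me, be[j])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- bs[j]; me <- be[j]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Proximity bonuses between neighbouring pentamers
#'
#' For each consecutive pair of pentamer hits the gap is the number of
#' nucleotides strictly between the two pentamers
#' (`next_start - prev_start - 5`). A negative gap means the pentamers
#' overlap. Only neighbouring pairs contribute, so three tandem overlapping
#' pentamers earn two overlap bonuses.
#'
#' @param hits Integer vector of 1-based pentamer starts, ascending.
#' @inheritParams find_au_blocks
#' @return Total proximity bonus in score units.
#' @examples
#' proximity_bonuses(c(1L, 5L))   # overlapping -> 1.5
#' proximity_bonuses(c(1L, 10L))  # 4 nt apart  -> 0.4
#' @export
proximity_bonuses <- function(hits, cfg = score_config()) {
  cfg <- as_score_config(cfg)
  if (length(hits) < 2L) return(0)
  if (is.unsorted(hits, strictly = TRUE)) {
    stop("`hits` must be strictly ascending", call. = FALSE)
  }
  gaps <- diff(hits) - 5L
  sum(ifelse(gaps < 0L, cfg$overlap_bonus,
      ifelse(gaps <= 3L, cfg$gap0_3_bonus,
      ifelse(gaps <= 6L, cfg$gap4_6_bonus,
      ifelse(gaps <= 9L, cfg$gap7_9_bonus, 0)))))
}

#' AU-block bonuses for pentamers
#'
#' A pentamer earns `block_bonus` once when its full 5-nt span lies inside a
#' single AU-block; a pentamer straddling a block boundary earns nothing.
#'
#' @inheritParams proximity_bonuses
#' @param blocks A data.frame of disjoint sorted blocks as returned by
#'   [find_au_blocks()].
#' @return Total block bonus in score units.
#' @export
block_bonuses <- function(hits, blocks, cfg = score_config()) {
  cfg <- as_score_config(cfg)
  cfg$block_bonus * sum(pentamer_in_block(hits, blocks))
}

pentamer_in_block <- function(hits, blocks) {
  if (length(hits) == 0L || nrow(blocks) == 0L) {
    return(rep(FALSE, length(hits)))
  }
  vapply(hits, function(h) {
    any(blocks$start <= h & h + 4L <= blocks$end)
  }, logical(1))
}

#' Score one sequence
#'
#' Computes the full ARE score breakdown of a sequence: the basal score
#' (`pentamer_value` per AUUUA pentamer), the proximity bonus over
#' neighbouring pentamer pairs, and the AU-block bonus for pentamers embedded
#' in AU-rich context. A sequence without any pentamer scores 0 regardless of
#' its AU content.
#'
#' @inheritParams find_au_blocks
#' @param id Optional identifier carried into the result.
#' @return An object of class `arescore_result`: a list with `id`, `length`,
#'   `hits` (1-based pentamer starts), `blocks` (data.frame), `n_pentamers`,
#'   `n_blocks`, `basal`, `proximity_bonus`, `block_bonus` and `total`.
#' @examples
#' score_sequence("AUUUAUUUA")$total        # 3.5
#' score_sequence("AUUUAGCGCAUUUA")$total   # 2.4
#' @export
score_sequence <- function(seq, cfg = score_config(), id = NA_character_) {
  cfg <- as_score_config(cfg)
  hits <- find_pentamers(seq)
  blocks <- find_au_blocks(seq, cfg)
  basal <- length(hits) * cfg$pentamer_value
  prox <- proximity_bonuses(hits, cfg)
  blk <- block_bonuses(hits, blocks, cfg)
  structure(list(
    id = id,
    length = nchar(seq),
    hits = hits,
    blocks = blocks,
    n_pentamers = length(hits),
    n_blocks = nrow(blocks),
    basal = basal,
    proximity_bonus = prox,
    block_bonus = blk,
    total = basal + prox + blk
  ), class = "arescore_result")
}

#' @export
print.arescore_result <- function(x, ...) {
  cat(sprintf("ARE score %.4g  (%s, %d nt)\n", x$total,
              if (is.na(x$id)) "unnamed" else x$id, x$length))
  cat(sprintf("  %d pentamer(s), %d AU-block(s)\n", x$n_pentamers, x$n_blocks))
  cat(sprintf("  basal %.4g + proximity %.4g + block %.4g\n",
              x$basal, x$proximity_bonus, x$block_bonus))
  invisible(x)
}

#' Score a batch of sequences
#'
#' Applies [score_sequence()] to every record at least `min_len` nt long.
#' Shorter records are excluded (the default 10 nt floor drops 3'UTR
#' annotations too short to be meaningful) and reported via the `skipped`
#' attribute.
#'
#' @param records A data.frame with columns `id` and `seq` (as returned by
#'   [read_fasta()]), or a named character vector of sequences.
#' @inheritParams find_au_blocks
#' @param min_len Minimum sequence length in nt to score (default 10).
#' @return A data.frame with one row per retained record, in input order:
#'   `id`, `length`, `n_pentamers`, `n_blocks`, `basal`, `proximity_bonus`,
#'   `block_bonus`, `arescore`. The ids of skipped records are in
#'   `attr(, "skipped")`.
#' @examples
#' score_batch(c(a = "AUUUAUUUAG", b = "GGGGGGGGGG"))
#' @export
score_batch <- function(records, cfg = score_config(), min_len = 10L) {
  cfg <- as_score_config(cfg)
  records <- as_records(records)
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    stop("duplicate record id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  keep <- nchar(records$seq) >= min_len
  skipped <- records$id[!keep]
  records <- records[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- score_sequence(records$seq[i], cfg, id = records$id[i])
    data.frame(id = r$id, length = r$length, n_pentamers = r$n_pentamers,
               n_blocks = r$n_blocks, basal = r$basal,
               proximity_bonus = r$proximity_bonus,
               block_bonus = r$block_bonus, arescore = r$total,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id = character(0), length = integer(0),
               n_pentamers = integer(0), n_blocks = integer(0),
               basal = numeric(0), proximity_bonus = numeric(0),
               block_bonus = numeric(0), arescore = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Per-hit detail table
#'
#' Expands a batch into one row per pentamer hit, reporting 1-based start,
#' AU-block membership, and the gap and bonus relative to the previous hit of
#' the same record.
#'
#' @inheritParams score_batch
#' @return A data.frame with columns `id`, `hit_start`, `in_block`,
#'   `pair_gap`, `pair_bonus` (`pair_gap`/`pair_bonus` are `NA` for the first
#'   hit of a record).
#' @export
hit_details <- function(records, cfg = score_config(), min_len = 10L) {
  cfg <- as_score_config(cfg)
  records <- as_records(records)
  records <- records[nchar(records$seq) >= min_len, , drop = FALSE]
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- score_sequence(records$seq[i], cfg, id = records$id[i])
    if (r$n_pentamers == 0L) return(NULL)
    gaps <- c(NA_integer_, diff(r$hits) - 5L)
    bonus <- vapply(gaps, function(g) {
      if (is.na(g)) NA_real_
      else if (g < 0L) cfg$overlap_bonus
      else if (g <= 3L) cfg$gap0_3_bonus
      else if (g <= 6L) cfg$gap4_6_bonus
      else if (g <= 9L) cfg$gap7_9_bonus
      else 0
    }, numeric(1))
    data.frame(id = r$id, hit_start = r$hits,
               in_block = pentamer_in_block(r$hits, r$blocks),
               pair_gap = gaps, pair_bonus = bonus,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), hit_start = integer(0),
                      in_block = logical(0), pair_gap = integer(0),
                      pair_bonus = numeric(0))
  }
  rownames(out) <- NULL
  out
}

# coerce a named character vector or data.frame to the (id, seq) contract
as_records <- function(records) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq", seq_along(records))
    return(data.frame(id = ids, seq = unname(records),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(records) && all(c("id", "seq") %in% names(records))) {
    return(data.frame(id = as.character(records$id),
                      seq = as.character(records$seq),
                      stringsAsFactors = FALSE))
  }
  stop("`records` must be a data.frame with `id` and `seq` columns, ",
       "or a named character vector", call. = FALSE)
}
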