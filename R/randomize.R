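# Null sequence sets: composition-matched randomization and size-matched
# concatemers. All randomness is governed by an explicit integer seed.

with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Composition-matched randomized control set
#'
#' Pools every nucleotide of the input sequences into one multiset, applies a
#' seeded uniform permutation, and partitions the permuted pool back into
#' sequences whose lengths match the inputs one by one. The total
#' mononucleotide composition and the length multiset of the output are
#' therefore *exactly* those of the input — the fully adjusted null against
#' which ARE enrichment in a real transcriptome is judged.
#'
#' @param records A data.frame with `id` and `seq` columns, or a named
#'   character vector.
#' @param seed Integer seed; the same seed reproduces the same set.
#' @return A data.frame with `id` (input id prefixed `rnd_`) and `seq`.
#' @export
composition_matched_set <- function(records, seed = NULL) {
  records <- as_records(records)
  lens <- nchar(records$seq)
  if (nrow(records) == 0L || sum(lens) == 0L) {
    stop("need at least one non-empty record", call. = FALSE)
  }
  pool <- unlist(strsplit(toupper(records$seq), "", fixed = TRUE),
                 use.names = FALSE)
  shuffled <- with_seed_if(seed, sample(pool, length(pool), replace = FALSE))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seqs <- vapply(seq_along(lens), function(i) {
    if (lens[i] == 0L) "" else
      paste(shuffled[starts[i]:ends[i]], collapse = "")
  }, character(1))
  data.frame(id = paste0("rnd_", records$id), seq = seqs,
             stringsAsFactors = FALSE)
}

#' Size-matched concatemer control set
#'
#' For each target length, draws sequences from the pool uniformly with
#' replacement, concatenates them until the target is reached or exceeded,
#' and truncates the tail so each output length matches its target exactly.
#' This is the stricter null used to ask whether a set of 3'UTRs is more
#' ARE-rich than same-sized chunks of real 3'UTR sequence.
#'
#' @param pool_records Pool of sequences to draw from (data.frame with
#'   `id`/`seq`, or named character vector).
#' @param target_lengths Positive integer vector of output lengths in nt.
#' @param seed Integer seed.
#' @return A data.frame with `id` (`concat_1`, `concat_2`, ...) and `seq`;
#'   output lengths equal `target_lengths` exactly.
#' @export
concatemer_set <- function(pool_records, target_lengths, seed = NULL) {
  pool_records <- as_records(pool_records)
  pool <- pool_records$seq[nchar(pool_records$seq) > 0L]
  if (length(pool) == 0L) stop("pool is empty", call. = FALSE)
  target_lengths <- as.integer(target_lengths)
  if (length(target_lengths) == 0L || any(target_lengths <= 0L)) {
    stop("target_lengths must be positive", call. = FALSE)
  }
  seqs <- with_seed_if(seed, vapply(target_lengths, function(tl) {
    parts <- character(0)
    total <- 0L
    while (total < tl) {
      p <- pool[[sample.int(length(pool), 1L)]]
      parts <- c(parts, p)
      total <- total + nchar(p)
    }
    substr(paste(parts, collapse = ""), 1L, tl)
  }, character(1)))
  data.frame(id = paste0("concat_", seq_along(target_lengths)), seq = seqs,
             stringsAsFactors = FALSE)
}
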