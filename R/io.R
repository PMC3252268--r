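# FASTA and tabular I/O. Parsing and writing delegate to Biostrings; a light
# pre-scan supplies the line-number diagnostic Biostrings does not give.

#' Read a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines, DNA or RNA
#' alphabet, any case). The record id is the header token up to the first
#' whitespace; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with character columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA: sequence before first header at line %d",
                 first), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  data.frame(id = ids, seq = gsub("[[:space:]]", "", as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTA file
#'
#' @param records A data.frame with `id` and `seq` columns, or a named
#'   character vector.
#' @param path Output path.
#' @param width Line-wrap width in nt.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_records(records)
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gene/transcript/3'UTR table
#'
#' Reads a TSV with columns `gene_id`, `transcript_id` and `seq` (one 3'UTR
#' per transcript). Blank lines are skipped. `transcript_id` must be unique;
#' a `gene_id` may repeat across its transcripts.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data.frame with the three character columns, in file order.
#' @export
read_utr_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", blank.lines.skip = TRUE)
  need <- c("gene_id", "transcript_id", "seq")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[, need]
  if (anyDuplicated(tab$transcript_id)) {
    dup <- unique(tab$transcript_id[duplicated(tab$transcript_id)])
    stop("duplicate transcript_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Collapse scored transcripts to one per gene
#'
#' When several transcripts map to the same gene, keeps for each gene the
#' transcript with the highest score — the convention for transcriptome-wide
#' per-gene ARE assessment. Score ties are broken deterministically by the
#' lexicographically smallest `transcript_id`.
#'
#' @param scored A data.frame with columns `gene_id`, `transcript_id` and
#'   `score` (extra columns are carried along).
#' @return A data.frame with one row per distinct `gene_id`, ordered by first
#'   appearance of the gene.
#' @export
collapse_by_gene <- function(scored) {
  need <- c("gene_id", "transcript_id", "score")
  if (!is.data.frame(scored) || !all(need %in% names(scored))) {
    stop("`scored` needs columns gene_id, transcript_id, score",
         call. = FALSE)
  }
  pick <- vapply(split(seq_len(nrow(scored)), scored$gene_id), function(idx) {
    best <- idx[scored$score[idx] == max(scored$score[idx])]
    best[order(scored$transcript_id[best])][1L]
  }, integer(1))
  out <- scored[sort(pick), , drop = FALSE]  # preserve first-appearance order
  rownames(out) <- NULL
  out
}

#' Write a score table as TSV
#'
#' @param scores A data.frame, e.g. from [score_batch()].
#' @param path Output path (use `""` for standard output).
#' @param cfg Optional [score_config()] echoed into `#`-prefixed header lines
#'   for provenance.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, cfg = NULL) {
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  if (!is.null(cfg)) {
    cfg <- as_score_config(cfg)
    writeLines(sprintf("# %s = %s", names(unclass(cfg)),
                       vapply(unclass(cfg), format, character(1))), con)
  }
  write.table(scores, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
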