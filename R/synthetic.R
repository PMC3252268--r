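# Synthetic transcriptome with planted AREs: background 3'UTR-like sequences
# with a controlled fraction carrying a class-II-like pentamer cluster inside
# an AU-rich span. Used to exercise scoring/enrichment end to end without any
# genome download.

#' Specification for a synthetic transcriptome
#'
#' Describes a set of 3'UTR-like background sequences of log-normally
#' distributed length, a fraction of which carry a planted ARE: a cluster of
#' closely spaced/overlapping AUUUA pentamers embedded in an AU-rich pad
#' (the class-II-like configuration of strong AREs). Defaults emulate a
#' compact invertebrate 3'UTR complement: median length 207 nt, background
#' A+U fraction 0.60.
#'
#' @param n_genes Number of sequences (default 2000).
#' @param length_meanlog,length_sdlog Log-normal length parameters (defaults
#'   `log(207)` and 0.7; lengths are rounded and floored at `min_length`).
#' @param min_length Minimum sequence length in nt (default 30).
#' @param background_au Background A+U fraction (default 0.60; A and U
#'   equiprobable, likewise G and C).
#' @param planted_fraction Fraction of sequences given a planted ARE
#'   (default 0.05).
#' @param pentamer_range Integer range of pentamers per planted cluster
#'   (default `c(4, 7)`).
#' @param spacing_range Range of gaps in nt between neighbouring planted
#'   pentamers; a gap of -1 overlaps them on the shared A, the only
#'   self-overlap the AUUUA motif admits (default `c(-1, 3)`).
#' @param pad AU-rich padding in nt on each side of the cluster (default 20).
#' @param pad_au A+U fraction of the padding (default 0.90).
#' @return An object of class `synth_spec` (a named list).
#' @export
synth_spec <- function(n_genes = 2000L,
                       length_meanlog = log(207),
                       length_sdlog = 0.7,
                       min_length = 30L,
                       background_au = 0.60,
                       planted_fraction = 0.05,
                       pentamer_range = c(4L, 7L),
                       spacing_range = c(-1L, 3L),
                       pad = 20L,
                       pad_au = 0.90) {
  spec <- list(n_genes = as.integer(n_genes),
               length_meanlog = length_meanlog,
               length_sdlog = length_sdlog,
               min_length = as.integer(min_length),
               background_au = background_au,
               planted_fraction = planted_fraction,
               pentamer_range = as.integer(pentamer_range),
               spacing_range = as.integer(spacing_range),
               pad = as.integer(pad),
               pad_au = pad_au)
  if (spec$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (spec$planted_fraction < 0 || spec$planted_fraction > 1) {
    stop("planted_fraction must be in [0, 1]", call. = FALSE)
  }
  if (spec$background_au <= 0 || spec$background_au >= 1 ||
      spec$pad_au <= 0 || spec$pad_au > 1) {
    stop("AU fractions must lie in (0, 1)", call. = FALSE)
  }
  if (spec$pentamer_range[1L] < 1L ||
      spec$pentamer_range[2L] < spec$pentamer_range[1L]) {
    stop("invalid pentamer_range", call. = FALSE)
  }
  if (spec$spacing_range[2L] < spec$spacing_range[1L] ||
      spec$spacing_range[1L] < -1L) {
    stop("invalid spacing_range (gaps must be >= -1 nt)", call. = FALSE)
  }
  structure(spec, class = "synth_spec")
}

random_bases <- function(n, au) {
  if (n == 0L) return(character(0))
  sample(c("A", "U", "G", "C"), n, replace = TRUE,
         prob = c(au / 2, au / 2, (1 - au) / 2, (1 - au) / 2))
}

# one planted cassette: pentamers at the drawn spacings inside an AU-rich pad
build_cassette <- function(spec) {
  # index-based draws: sample(x, ...) on a length-1 vector would resample 1:x
  krange <- spec$pentamer_range[1L]:spec$pentamer_range[2L]
  k <- krange[sample.int(length(krange), 1L)]
  grange <- spec$spacing_range[1L]:spec$spacing_range[2L]
  gaps <- if (k > 1L) {
    grange[sample.int(length(grange), k - 1L, replace = TRUE)]
  } else integer(0)
  core <- "AUUUA"
  for (g in gaps) {
    if (g < 0L) {
      # g = -1: next pentamer shares its leading A with the previous one
      core <- paste0(core, "UUUA")
    } else {
      core <- paste0(core, paste(random_bases(g, spec$pad_au), collapse = ""),
                     "AUUUA")
    }
  }
  paste0(paste(random_bases(spec$pad, spec$pad_au), collapse = ""), core,
         paste(random_bases(spec$pad, spec$pad_au), collapse = ""))
}

#' Generate a synthetic transcriptome with planted AREs
#'
#' Draws `n_genes` background sequences at the spec's base composition and
#' length distribution, then replaces a central slice of a `planted_fraction`
#' subset with an ARE cassette (pentamer cluster inside an AU-rich pad).
#' Output is byte-identical for a fixed seed.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed (required for reproducibility).
#' @return A list with `records` (data.frame `id`, `seq`) and `truth`
#'   (data.frame `id`, `length`, `planted`, `n_planted_pentamers`,
#'   `cassette_start`, `cassette_end`; coordinates 1-based inclusive, NA for
#'   unplanted records).
#' @export
generate_synthetic_transcriptome <- function(spec = synth_spec(),
                                             seed = NULL) {
  if (!inherits(spec, "synth_spec")) spec <- do.call(synth_spec, spec)
  with_seed_if(seed, {
    lens <- pmax(spec$min_length,
                 as.integer(round(stats::rlnorm(spec$n_genes,
                                                spec$length_meanlog,
                                                spec$length_sdlog))))
    n_planted <- as.integer(round(spec$planted_fraction * spec$n_genes))
    # worst-case cassette: max pentamers at max spacing plus both pads
    worst <- 2L * spec$pad + 5L * spec$pentamer_range[2L] +
      max(0L, spec$spacing_range[2L]) * (spec$pentamer_range[2L] - 1L)
    eligible <- which(lens >= worst)
    if (length(eligible) < n_planted) {
      stop(sprintf(paste0("infeasible spec: %d records of >= %d nt needed ",
                          "to hold the planted cassettes, only %d available"),
                   n_planted, worst, length(eligible)), call. = FALSE)
    }
    planted_idx <- sort(eligible[sample.int(length(eligible), n_planted)])

    seqs <- character(spec$n_genes)
    cass_start <- rep(NA_integer_, spec$n_genes)
    cass_end <- rep(NA_integer_, spec$n_genes)
    n_pent <- rep(NA_integer_, spec$n_genes)
    for (i in seq_len(spec$n_genes)) {
      s <- paste(random_bases(lens[i], spec$background_au), collapse = "")
      if (i %in% planted_idx) {
        cassette <- build_cassette(spec)
        cl <- nchar(cassette)
        at <- sample.int(lens[i] - cl + 1L, 1L)
        s <- paste0(substr(s, 1L, at - 1L), cassette,
                    substr(s, at + cl, lens[i]))
        cass_start[i] <- at
        cass_end[i] <- at + cl - 1L
        n_pent[i] <- length(find_pentamers(cassette))
      }
      seqs[i] <- s
    }
    ids <- sprintf("synth_%05d", seq_len(spec$n_genes))
    list(
      records = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
      truth = data.frame(id = ids, length = lens,
                         planted = seq_len(spec$n_genes) %in% planted_idx,
                         n_planted_pentamers = n_pent,
                         cassette_start = cass_start,
                         cassette_end = cass_end,
                         stringsAsFactors = FALSE)
    )
  })
}
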