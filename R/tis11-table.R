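# The 26-mRNA fly decay panel: half-lives measured by qPCR in SL2 cells after
# transcription shutoff, under control (GFP dsRNA) and Tis11 knock-down
# conditions, with the 3'UTR length and ARE score of each transcript.
# Half-lives beyond 240 minutes could not be quantified and are censored.

#' Drosophila SL2 mRNA decay panel
#'
#' A panel of 26 fly mRNAs — 12 sensitive to Tis11 knock-down and 14
#' controls — with half-lives (minutes) measured by qPCR after actinomycin D
#' transcription shutoff under control (GFP dsRNA) and Tis11 dsRNA
#' conditions, the annotated 3'UTR length, and the ARE score of each
#' transcript. Half-lives that exceeded the 240-minute quantification window
#' are censored: the `*_censored` flag is `TRUE` and the value column holds
#' 240.
#'
#' @return A data.frame with 26 rows and columns `name`, `cg`, `group`
#'   (`"tis11_sensitive"` or `"control"`), `half_life_gfp`,
#'   `half_life_gfp_censored`, `half_life_tis11`,
#'   `half_life_tis11_censored`, `utr_length`, `arescore`.
#' @export
tis11_decay_table <- function() {
  # name, CG id, group, t1/2 GFP (min, NA = censored), t1/2 Tis11, UTR nt, score
  rows <- list(
    list("Pxn",         "CG12002", "tis11_sensitive", 163,  NA, 180, 0),
    list("TotA",        "CG31509", "tis11_sensitive",  NA,  NA, 153, 2.6),
    list("Vir-1",       "CG31764", "tis11_sensitive",  NA,  NA, 311, 4),
    list("Lectin-28C",  "CG7106",  "tis11_sensitive",  NA,  NA,  53, 0),
    list("CG8239",      "CG8239",  "tis11_sensitive", 134, 199, 287, 10.8),
    list("NimB2",       "CG31839", "tis11_sensitive",  NA,  NA,  81, 0),
    list("Ric",         "CG8418",  "tis11_sensitive", 229, 200, 1317, 10.1),
    list("CG15435",     "CG15435", "tis11_sensitive",  46,  60, 191, 11.55),
    list("CG7115",      "CG7115",  "tis11_sensitive",  63,  85, 493, 6.15),
    list("CG10249",     "CG10249", "tis11_sensitive",  49,  44, 822, 6.5),
    list("CG2915",      "CG2915",  "tis11_sensitive",  NA,  NA,  83, 0),
    list("NimB1",       "CG33119", "tis11_sensitive",  NA,  NA,  36, 0),
    list("Reck",        "CG5392",  "control",          39,  35, 582, 11.2),
    list("Pax",         "CG31794", "control",         158, 120, 325, 4.65),
    list("CG32512",     "CG32512", "control",         114,  78, 583, 9.55),
    list("Ho",          "CG14716", "control",          77,  65, 104, 4.1),
    list("CG5026",      "CG5026",  "control",         183, 128, 572, 6.5),
    list("CG7787",      "CG7787",  "control",          NA, 168, 438, 3.2),
    list("Ef1\u03b148D", "CG8280", "control",     NA,  NA, 554, 4.9),
    list("CG17184",     "CG17184", "control",          66, 107, 653, 3.9),
    list("CG31997",     "CG31997", "control",          NA,  NA,  70, 0),
    list("CG10131",     "CG10131", "control",          NA,  NA,  97, 0),
    list("CG8135",      "CG8135",  "control",          NA, 170, 148, 0),
    list("dUTPase",     "CG4584",  "control",          NA,  NA, 131, 0),
    list("Mod(mdg4)",   "CG32491", "control",          93,  74,  44, 5.2),
    list("eEF1\u03b4", "CG4912", "control",       NA,  NA,  91, 0)
  )
  gfp <- vapply(rows, function(r) as.numeric(r[[4]]), numeric(1))
  tis <- vapply(rows, function(r) as.numeric(r[[5]]), numeric(1))
  data.frame(
    name = vapply(rows, `[[`, character(1), 1L),
    cg = vapply(rows, `[[`, character(1), 2L),
    group = vapply(rows, `[[`, character(1), 3L),
    half_life_gfp = ifelse(is.na(gfp), 240, gfp),
    half_life_gfp_censored = is.na(gfp),
    half_life_tis11 = ifelse(is.na(tis), 240, tis),
    half_life_tis11_censored = is.na(tis),
    utr_length = vapply(rows, function(r) as.numeric(r[[6]]), numeric(1)),
    arescore = vapply(rows, function(r) as.numeric(r[[7]]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Summary analysis of the SL2 decay panel
#'
#' Runs the standard validation battery over the 26-mRNA decay panel (or a
#' table of the same shape): score-bin counts, the stability of score-0
#' transcripts, censoring-aware rank correlations of half-life against score
#' and against 3'UTR length, and ROC discrimination of labile from stable
#' transcripts by score and by length.
#'
#' @param tab A data.frame shaped like [tis11_decay_table()] (the default).
#' @param labile_below Labile class: uncensored control half-life strictly
#'   below this many minutes (default 140).
#' @param bin_edges Score bin edges (default `c(0, 4, 8, Inf)`, i.e. low
#'   `<4`, medium 4-7.99, high `>=8`).
#' @return A list with
#'   `bin_counts` (named integer vector per score bin),
#'   `score_zero_total` and `score_zero_censored` (score-0 transcripts and
#'   how many of them have a censored control half-life),
#'   `spearman_score` / `spearman_length` (rank correlation of control
#'   half-life with ARE score / 3'UTR length, censored values tied at the
#'   top),
#'   `n_labile`, `n_stable`, and
#'   `roc_score` / `roc_length` ([roc_auc()] results for discriminating
#'   labile from stable transcripts).
#' @export
analyze_tis11_decay <- function(tab = tis11_decay_table(),
                                labile_below = 140,
                                bin_edges = c(0, 4, 8, Inf)) {
  dist <- score_distribution(tab$arescore, bin_edges)
  bin_counts <- setNames(dist$count,
                         paste0("[", dist$lo, ",", dist$hi, ")"))

  zero <- tab[tab$arescore == 0, , drop = FALSE]

  sp_score <- spearman_censored(tab$arescore, tab$half_life_gfp,
                                y_censored = tab$half_life_gfp_censored)
  sp_len <- spearman_censored(tab$utr_length, tab$half_life_gfp,
                              y_censored = tab$half_life_gfp_censored)

  labile <- !tab$half_life_gfp_censored & tab$half_life_gfp < labile_below
  stable <- tab$half_life_gfp_censored
  list(
    bin_counts = bin_counts,
    score_zero_total = nrow(zero),
    score_zero_censored = sum(zero$half_life_gfp_censored),
    spearman_score = sp_score,
    spearman_length = sp_len,
    n_labile = sum(labile),
    n_stable = sum(stable),
    roc_score = roc_auc(tab$arescore[labile], tab$arescore[stable]),
    roc_length = roc_auc(tab$utr_length[labile], tab$utr_length[stable])
  )
}
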