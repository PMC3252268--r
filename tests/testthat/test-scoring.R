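# Core scorer: pentamer detection, AU-blocks, bonuses, full score.

test_that("pentamer detection finds overlapping hits and normalizes case/T-U", {
  expect_identical(find_pentamers("GGGCCCGGG"), integer(0))
  expect_identical(find_pentamers(""), integer(0))
  expect_identical(find_pentamers("AUUUAUUUA"), c(1L, 5L))
  expect_identical(find_pentamers("atttagcgcATTTA"), c(1L, 10L))
  # ambiguity letters never match
  expect_identical(find_pentamers("ANUUA"), integer(0))

  set.seed(11)
  for (i in 1:50) {
    s <- random_seq(sample(5:120, 1), au = runif(1, 0.3, 0.9))
    expect_identical(find_pentamers(s), oracle_pentamers(s))
  }
})

test_that("AU-block detection follows the open/extend/close window rule", {
  # shorter than the word size: no block possible
  expect_identical(nrow(find_au_blocks(strrep("A", 19))), 0L)
  # pure-AU sequence: one maximal block covering everything
  expect_equal(find_au_blocks(strrep("AU", 15)),
               data.frame(start = 1L, end = 30L))
  # block opened by the all-A window extends while windows stay >= 55% AU
  expect_equal(find_au_blocks(paste0(strrep("A", 20), strrep("G", 20))),
               oracle_blocks(paste0(strrep("A", 20), strrep("G", 20))))
  # high-AU island inside GC background
  s <- paste0(strrep("GC", 15), strrep("AU", 12), strrep("GC", 15))
  expect_equal(find_au_blocks(s), oracle_blocks(s))

  set.seed(22)
  for (i in 1:100) {
    s <- random_seq(sample(20:200, 1), au = runif(1, 0.4, 0.95))
    expect_equal(find_au_blocks(s), oracle_blocks(s))
  }
})

test_that("block boundaries respect non-default thresholds and word size", {
  cfg <- score_config(block_word = 10L, block_start_au = 0.7,
                      block_end_au = 0.5)
  set.seed(33)
  for (i in 1:50) {
    s <- random_seq(sample(10:150, 1), au = runif(1, 0.3, 0.9))
    expect_equal(find_au_blocks(s, cfg),
                 oracle_blocks(s, word = 10L, start_au = 0.7, end_au = 0.5))
  }
})

test_that("proximity bonuses use the gap between neighbouring pentamers", {
  expect_equal(proximity_bonuses(integer(0)), 0)
  expect_equal(proximity_bonuses(1L), 0)
  expect_equal(proximity_bonuses(c(1L, 5L)), 1.5)    # gap -1: overlap
  expect_equal(proximity_bonuses(c(1L, 6L)), 0.75)   # gap 0
  expect_equal(proximity_bonuses(c(1L, 9L)), 0.75)   # gap 3
  expect_equal(proximity_bonuses(c(1L, 10L)), 0.4)   # gap 4
  expect_equal(proximity_bonuses(c(1L, 12L)), 0.4)   # gap 6
  expect_equal(proximity_bonuses(c(1L, 13L)), 0.2)   # gap 7
  expect_equal(proximity_bonuses(c(1L, 15L)), 0.2)   # gap 9
  expect_equal(proximity_bonuses(c(1L, 16L)), 0)     # gap 10
  # only neighbouring pairs: three tandem overlaps earn 2 x 1.5
  expect_equal(proximity_bonuses(c(1L, 5L, 9L)), 3)
  expect_error(proximity_bonuses(c(5L, 1L)), "ascending")
})

test_that("block bonus requires full containment of the pentamer", {
  none <- data.frame(start = integer(0), end = integer(0))
  blk <- data.frame(start = 10L, end = 40L)
  expect_equal(block_bonuses(c(12L), none), 0)
  expect_equal(block_bonuses(c(12L), blk), 0.3)
  expect_equal(block_bonuses(c(37L), blk), 0)  # spans 37..41, straddles end
  expect_equal(block_bonuses(c(36L), blk), 0.3)
  expect_equal(block_bonuses(c(8L), blk), 0)   # straddles the start
})

test_that("worked examples score as the rules dictate", {
  expect_equal(score_sequence("GCGCGCGCGC")$total, 0)
  expect_equal(score_sequence("")$total, 0)
  expect_equal(score_sequence("AUUUAUUUA")$total, 3.5)
  expect_equal(score_sequence("AUUUAGCGCAUUUA")$total, 2.4)
  expect_equal(score_sequence("AAUAAUUUAAUAAUAAUAAUAAUAA")$total, 1.3)
})

test_that("score equals the brute-force oracle on random sequences", {
  set.seed(44)
  for (i in 1:200) {
    s <- random_seq(sample(20:500, 1), au = runif(1, 0.3, 0.9))
    expect_identical(score_sequence(s)$total, oracle_total(s))
  }
})

test_that("score respects non-default parameter settings", {
  cfg0 <- score_config(overlap_bonus = 0, gap0_3_bonus = 0, gap4_6_bonus = 0,
                       gap7_9_bonus = 0, block_bonus = 0)
  set.seed(55)
  for (i in 1:50) {
    s <- random_seq(sample(20:300, 1), au = runif(1, 0.4, 0.9))
    # with all bonuses off, the total is the exact pentamer count
    expect_equal(score_sequence(s, cfg0)$total, length(oracle_pentamers(s)))
  }
  cfg <- score_config(pentamer_value = 2, overlap_bonus = 1, block_bonus = 0.5,
                      block_word = 10L, block_start_au = 0.9,
                      block_end_au = 0.6)
  for (i in 1:50) {
    s <- random_seq(sample(20:300, 1), au = runif(1, 0.4, 0.9))
    expect_equal(score_sequence(s, cfg)$total,
                 oracle_total(s, pentamer_value = 2, overlap = 1,
                              blockb = 0.5, word = 10L, start_au = 0.9,
                              end_au = 0.6))
  }
})

test_that("score is invariant to case and T/U and zero iff no pentamer", {
  set.seed(66)
  for (i in 1:50) {
    s <- random_seq(sample(20:300, 1), au = runif(1, 0.3, 0.9))
    r <- score_sequence(s)
    expect_equal(score_sequence(tolower(s))$total, r$total)
    expect_equal(score_sequence(chartr("U", "T", s))$total, r$total)
    expect_gte(r$total, 0)
    expect_identical(r$total == 0, r$n_pentamers == 0L)
    expect_equal(r$total, r$basal + r$proximity_bonus + r$block_bonus)
  }
})

test_that("appending a far-downstream pentamer adds exactly one unit", {
  set.seed(77)
  for (i in 1:20) {
    s <- random_seq(sample(30:200, 1), au = runif(1, 0.3, 0.7))
    # GC spacer destroys any window continuation and exceeds the 9-nt band
    s2 <- paste0(s, strrep("GC", 10), "AUUUA")
    expect_equal(score_sequence(s2)$total, score_sequence(s)$total + 1)
  }
})

test_that("batch scoring filters, preserves order, matches single scoring", {
  recs <- data.frame(id = c("a", "b", "c"),
                     seq = c("AUUUG", "GCGCGCGCG", "AUUUAUUUAG"))
  out <- score_batch(recs, min_len = 10L)
  expect_identical(out$id, "c")
  expect_identical(attr(out, "skipped"), c("a", "b"))
  expect_equal(out$arescore, 3.5)

  set.seed(88)
  recs <- data.frame(id = paste0("s", 1:30),
                     seq = replicate(30, random_seq(sample(5:100, 1), 0.6)))
  out <- score_batch(recs, min_len = 10L)
  keep <- recs[nchar(recs$seq) >= 10L, ]
  expect_identical(out$id, keep$id)
  expect_equal(out$arescore,
               vapply(keep$seq, function(s) score_sequence(s)$total,
                      numeric(1), USE.NAMES = FALSE))

  expect_error(score_batch(data.frame(id = c("x", "x"),
                                      seq = c(strrep("A", 12),
                                              strrep("C", 12)))),
               "duplicate.*x")
})

test_that("config validation rejects bad parameters", {
  expect_error(score_config(overlap_bonus = -1), "bonuses")
  expect_error(score_config(block_word = 3), "block_word")
  expect_error(score_config(block_start_au = 0.5, block_end_au = 0.8),
               "block_end_au")
})

test_that("hit details report block membership and pair bonuses", {
  d <- hit_details(c(x = "AUUUAGCGCAUUUA"))
  expect_equal(d$hit_start, c(1L, 10L))
  expect_equal(d$pair_gap, c(NA_integer_, 4L))
  expect_equal(d$pair_bonus, c(NA_real_, 0.4))
  expect_false(any(d$in_block))
  d2 <- hit_details(c(y = strrep("AAUAAUUUAAUAAUAAUAAUAAUAA", 1)))
  expect_true(all(d2$in_block))
})
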