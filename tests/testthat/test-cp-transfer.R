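test_that("planted plastid-derived segments are detected, short ones not", {
  cfg <- synth_config(n_isoforms = 2, isoform_length_range = c(3e4, 4e4),
                      seed = 23,
                      repeat_plan = default_repeat_plan()[0, ],
                      mtpt_plan = data.frame(length = c(1500L, 150L),
                                             identity = c(95, 98)),
                      ssr_plan = default_ssr_plan()[0, ],
                      gene_plan = list())
  sim <- generate_mitogenome(cfg)
  segs <- detect_cp_segments(sim$genome, sim$plastome)
  tr <- sim$truth$mtpt
  big <- tr[tr$length == 1500, ]
  m <- segs[segs$isoform == big$isoform, ]
  expect_equal(nrow(m), 1L)
  cover <- (min(m$end, big$end) - max(m$start, big$start)) / 1500
  expect_gte(cover, 0.95)
  expect_gt(m$identity, 80)
  # the 150 bp transfer is below the 200 bp threshold
  small <- tr[tr$length == 150, ]
  expect_false(any(segs$isoform == small$isoform &
                     segs$start < small$end & segs$end > small$start))
  expect_equal(attr(segs, "total_bp"), sum(segs$length))
})

test_that("mito-side hit merging is idempotent and length-weighted", {
  hits <- data.frame(
    query_id = "iso1", subject_id = "pl", strand = "+",
    q_start = c(100L, 300L, 900L), q_end = c(400L, 600L, 1000L),
    s_start = c(1000L, 1200L, 5000L), s_end = c(1300L, 1500L, 5100L),
    score = 1, matches = 1, length = c(300L, 300L, 100L), gaps = 0L,
    identity = c(90, 100, 80), evalue = 0, stringsAsFactors = FALSE)
  m1 <- mitokit:::merge_cp_hits(hits)
  expect_equal(nrow(m1), 2L)
  expect_equal(m1$start, c(100L, 900L))
  expect_equal(m1$end, c(600L, 1000L))
  expect_equal(m1$identity[1], (90 * 300 + 100 * 300) / 600)
  expect_equal(m1$p_start[1], 1000L)
  expect_equal(m1$p_end[1], 1500L)
  # merging the merged segments changes nothing
  hits2 <- data.frame(
    query_id = "iso1", subject_id = "pl", strand = "+",
    q_start = m1$start, q_end = m1$end, s_start = m1$p_start,
    s_end = m1$p_end, score = 1, matches = 1,
    length = m1$end - m1$start, gaps = 0L, identity = m1$identity,
    evalue = 0, stringsAsFactors = FALSE)
  m2 <- mitokit:::merge_cp_hits(hits2)
  expect_equal(m2$start, m1$start)
  expect_equal(m2$end, m1$end)
  expect_equal(m2$identity, m1$identity)
})

test_that("intact donor genes are containment-based, fragments separate", {
  pl <- generate_plastome(lsc = 20000, ir = 2000, ssc = 3000, seed = 29)
  genes <- pl$truth$genes[order(pl$truth$genes$start), ]
  g2 <- genes[1:2, ]
  g3 <- genes[3, ]
  gap_ok <- g3$start - g2$start[1] < 9000
  skip_if(!gap_ok, "gene layout unsuitable for this seed")
  # donor window: genes 1-2 complete, gene 3 cut in half
  donor_start <- max(0, g2$start[1] - 50)
  donor_end <- g3$start + floor((g3$end - g3$start) / 2)
  cfg <- synth_config(n_isoforms = 1, isoform_length_range = c(3e4, 3e4),
                      seed = 31,
                      repeat_plan = default_repeat_plan()[0, ],
                      mtpt_plan = data.frame(
                        length = donor_end - donor_start, identity = 97,
                        p_start = donor_start),
                      ssr_plan = default_ssr_plan()[0, ],
                      gene_plan = list())
  sim <- generate_mitogenome(cfg, plastome = pl)
  segs <- detect_cp_segments(sim$genome, pl$genome)
  ann <- annotate_intact_genes(segs, pl$truth$genes)
  expect_setequal(ann$gene[ann$status == "intact"], g2$gene)
  expect_true(g3$gene %in% ann$gene[ann$status == "fragment"])
})

test_that("segment length histograms and per-isoform counts are exact", {
  g <- organelle_genome("g", c(i1 = strrep("A", 100), i2 = strrep("C", 100)))
  segs <- data.frame(isoform = c("i1", "i1", "i2"),
                     start = 0L, end = 1L,
                     length = c(250L, 800L, 800L),
                     stringsAsFactors = FALSE)
  sm <- segment_summaries(segs, g)
  expect_equal(sm$histogram$count, c(1L, 2L, 0L, 0L, 0L))
  expect_equal(sm$histogram$bin,
               c("200-500", "501-1000", "1001-1500", "1501-3000", ">3000"))
  expect_equal(sm$per_isoform$count, c(2L, 1L))
  empty <- segment_summaries(segs[0, ], g)
  expect_true(all(empty$histogram$count == 0L))
  expect_true(all(empty$per_isoform$count == 0L))
})

test_that("bins count overlapping features and drop the trailing stub", {
  set.seed(61)
  g <- organelle_genome("g", c(i1 = random_dna(7000)))
  cp <- data.frame(isoform = "i1", start = 2900L, end = 3100L,
                   length = 200L)
  rp <- data.frame(isoform = "i1", start = 100L, end = 200L)
  bt <- bin_table(g, cp, rp, bin_size = 3000)
  expect_equal(nrow(bt), 2L)               # 7000 -> 2 full bins
  expect_equal(bt$n_cp, c(1L, 1L))         # the segment straddles both
  expect_equal(bt$n_repeat, c(1L, 0L))
  bt2 <- bin_table(g, cp, rp, bin_size = 3000, count_mode = "start")
  expect_equal(bt2$n_cp, c(1L, 0L))
})

test_that("a construction forcing transfers into low-GC bins gives r < 0", {
  set.seed(62)
  lo <- random_dna(30000, gc = 0.35)
  hi <- random_dna(30000, gc = 0.50)
  g <- organelle_genome("g", c(lo = lo, hi = hi))
  cp <- data.frame(isoform = "lo",
                   start = seq(1000L, 25000L, by = 3000L),
                   end = seq(1000L, 25000L, by = 3000L) + 400L)
  cp$length <- cp$end - cp$start
  rep_iv <- data.frame(isoform = character(), start = integer(),
                       end = integer())
  res <- binned_feature_correlation(g, cp, rep_iv)
  expect_lt(res$r_cp_gc, 0)
  # Pearson r identical to the independent two-pass formula
  expect_equal(res$r_cp_gc,
               pearson_oracle(res$bins$n_cp, res$bins$gc),
               tolerance = 1e-12)
  expect_true(is.na(res$r_cp_repeat))      # zero repeat variance
})

test_that("degenerate bin tables are rejected or flagged", {
  bins <- data.frame(gc = c(0.4, 0.5), n_repeat = c(1, 2), n_cp = c(0, 1))
  expect_error(binned_feature_correlation(bins), "3 bins")
  bins3 <- data.frame(gc = c(0.4, 0.5, 0.45), n_repeat = c(1, 2, 3),
                      n_cp = c(1, 1, 1))
  expect_message(res <- binned_feature_correlation(bins3),
                 "zero variance")
  expect_true(is.na(res$r_cp_gc))
})

test_that("total transfer bp is invariant under isoform reordering", {
  sim <- small_sim(seed = 33, ssr_rows = integer(0),
                   gene_templates = integer(0))
  segs1 <- detect_cp_segments(sim$genome, sim$plastome)
  g_rev <- organelle_genome("rev", rev(sim$genome$seq),
                            rev(sim$genome$circular))
  segs2 <- detect_cp_segments(g_rev, sim$plastome)
  expect_equal(attr(segs1, "total_bp"), attr(segs2, "total_bp"))
})
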