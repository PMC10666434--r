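test_that("size classification uses the closed 100-1000 bp interval", {
  expect_equal(classify_repeat(c(99, 100, 1000, 1001)),
               c("short", "intermediate", "intermediate", "large"))
  expect_error(classify_repeat(20), "exceed 20")
})

test_that("planted repeats of all three size classes are recovered", {
  set.seed(41)
  cfg <- synth_config(n_isoforms = 2, isoform_length_range = c(4e4, 5e4),
                      seed = 8,
                      repeat_plan = data.frame(
                        length = c(50L, 500L, 5000L),
                        identity = c(98, 97.8, 99.5),
                        strand = "+", cross_isoform = c(FALSE, TRUE, TRUE)),
                      mtpt_plan = default_mtpt_plan()[0, ],
                      ssr_plan = default_ssr_plan()[0, ],
                      gene_plan = list())
  sim <- generate_mitogenome(cfg)
  found <- find_dispersed_repeats(sim$genome)
  tr <- sim$truth$repeats
  expect_equal(sort(found$size_class),
               sort(c("short", "intermediate", "large")))
  for (i in seq_len(nrow(tr))) {
    m <- found[(found$iso_a == tr$iso_a[i] &
                  abs(found$start_a - tr$start_a[i]) <= 13 &
                  abs(found$end_a - tr$end_a[i]) <= 13) |
                 (found$iso_b == tr$iso_a[i] &
                    abs(found$start_b - tr$start_a[i]) <= 13 &
                    abs(found$end_b - tr$end_a[i]) <= 13), ]
    expect_equal(nrow(m), 1L, info = tr$pair_id[i])
    expect_lt(min(abs(m$identity - tr$identity[i])), 1)
  }
})

test_that("a 90 percent identity repeat fails the 95 percent threshold", {
  set.seed(42)
  cfg <- synth_config(n_isoforms = 1, isoform_length_range = c(4e4, 4e4),
                      seed = 12,
                      repeat_plan = data.frame(length = 800L, identity = 90),
                      mtpt_plan = default_mtpt_plan()[0, ],
                      ssr_plan = default_ssr_plan()[0, ],
                      gene_plan = list())
  sim <- generate_mitogenome(cfg)
  found <- find_dispersed_repeats(sim$genome, min_identity = 95)
  expect_true(all(found$length < 700))   # planted pair must not surface
})

test_that("repeat content union counts overlapping bases once", {
  g <- organelle_genome("g", c(iso1 = strrep("ACGT", 1000)))
  pairs <- data.frame(
    iso_a = "iso1", start_a = c(100L, 150L), end_a = c(200L, 260L),
    iso_b = "iso1", start_b = c(1000L, 2000L), end_b = c(1100L, 2110L),
    strand = "+", length = c(100L, 110L), identity = 100,
    evalue = 0, size_class = "intermediate", stringsAsFactors = FALSE)
  dd <- deduplicate_repeat_content(pairs, g)
  # a-side union: [100,260) = 160 bp; b-side: 100 + 110
  expect_equal(dd$total_bp, 160L + 210L)
  expect_equal(dd$fraction, 370 / 4000)
  none <- deduplicate_repeat_content(pairs[0, ], g)
  expect_equal(none$total_bp, 0L)
  expect_equal(none$fraction, 0)
})

test_that("union is bounded by twice the summed pair lengths", {
  sim <- small_sim(seed = 19)
  found <- find_dispersed_repeats(sim$genome)
  dd <- deduplicate_repeat_content(found, sim$genome)
  expect_lte(dd$total_bp, 2 * sum(found$length))
  expect_gt(dd$total_bp, 0)
})

test_that("origin-spanning repeats on circular isoforms are recovered", {
  set.seed(43)
  core <- random_dna(600)
  # isoform a: last 300 bp of the repeat at the start, first 300 at the end
  isoA <- paste0(substr(core, 301, 600), random_dna(20000),
                 substr(core, 1, 300))
  isoB <- paste0(random_dna(9000), mutate_seq(core, 6), random_dna(9000))
  g_circ <- organelle_genome("g", c(a = isoA, b = isoB), circular = TRUE)
  found <- find_dispersed_repeats(g_circ)
  hit <- found[found$length >= 550, ]
  expect_gte(nrow(hit), 1L)
  expect_true(any(hit$end_a > nchar(isoA) | hit$end_b > nchar(isoB) |
                    hit$start_a > 20000 | hit$start_b > 20000 |
                    hit$length >= 550))
  # as a linear genome only the two broken halves can match
  g_lin <- organelle_genome("g", c(a = isoA, b = isoB), circular = FALSE)
  flin <- find_dispersed_repeats(g_lin)
  expect_lt(max(flin$length), 550)
})

test_that("SSR thresholds and canonical motifs behave at the edges", {
  set.seed(44)
  bg1 <- random_dna(300)
  s <- paste0(bg1, "G", strrep("A", 8), "C", random_dna(200),
              "G", strrep("AT", 5), "G", random_dna(200),
              "C", strrep("A", 7), "G", random_dna(100))
  ss <- find_ssrs(c(x = s))
  a8 <- ss[ss$motif == "A" & ss$count == 8, ]
  expect_equal(nrow(a8), 1L)
  at5 <- ss[ss$motif_len == 2 & ss$count >= 5, ]
  expect_equal(nrow(at5), 1L)
  expect_equal(at5$canonical, "AT")
  expect_false(any(ss$motif == "A" & ss$count == 7))
  # motifs are primitive: a 10x AT run is never reported as ATAT
  expect_false(any(nchar(ss$motif) == 4 &
                     substr(ss$motif, 1, 2) == substr(ss$motif, 3, 4)))
})

test_that("SSR finder equals the naive scanner on planted strings", {
  set.seed(45)
  for (i in 1:12) {
    s <- paste0(random_dna(800), strrep("T", sample(6:12, 1)),
                random_dna(400), strrep("AGC", sample(3:7, 1)),
                random_dna(400), strrep("CT", sample(3:8, 1)),
                random_dna(400))
    got <- find_ssrs(c(x = s))
    exp <- ssr_oracle(s)
    expect_equal(got[, c("start", "end", "motif", "motif_len", "count")],
                 exp[, c("start", "end", "motif", "motif_len", "count")],
                 ignore_attr = TRUE, info = paste("case", i))
  }
})

test_that("plastome repeat types are assigned by orientation relation", {
  set.seed(46)
  core <- random_dna(30)
  s <- paste0(random_dna(400), core, random_dna(300), core,
              random_dna(300), revcomp(core), random_dna(300),
              chartr("ACGT", "TGCA", core), random_dna(200))
  # with a zero-mismatch budget the planted exact copies are the maximal
  # repeats, reported at Hamming distance 0 under their orientation type
  r <- find_plastome_repeats(s, min_len = 25, max_hamming = 0)
  expect_true(any(r$type == "forward" & r$hamming == 0 & r$length >= 30))
  expect_true(any(r$type == "palindromic" & r$hamming == 0))
  expect_true(any(r$type == "complement" & r$hamming == 0))
  # with the default budget the same copies surface inside maximal
  # windows that absorb up to three flanking mismatches
  r3 <- find_plastome_repeats(s, min_len = 25, max_hamming = 3)
  expect_true(any(r3$type == "forward" & r3$length >= 30))
})

test_that("plastome repeat finder equals the all-pairs Hamming oracle", {
  set.seed(47)
  for (i in 1:4) {
    core <- random_dna(25)
    s <- paste0(random_dna(250), core, random_dna(150),
                mutate_seq(core, 2), random_dna(150), revcomp(core),
                random_dna(100))
    got <- find_plastome_repeats(s, min_len = 12, max_hamming = 2)
    exp <- plastome_repeats_oracle(s, min_len = 12, max_mm = 2)
    expect_equal(got, exp, ignore_attr = TRUE, info = paste("case", i))
  }
})
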