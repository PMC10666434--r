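# one shared synthetic genome with a single clean repeat pair
recomb_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(
        n_isoforms = 2, isoform_length_range = c(40000, 50000), seed = 7,
        repeat_plan = data.frame(length = 1000L, identity = 99,
                                 strand = "+", cross_isoform = TRUE),
        mtpt_plan = default_mtpt_plan()[0, ],
        ssr_plan = default_ssr_plan()[0, ], gene_plan = list())
      sim <- generate_mitogenome(cfg)
      pairs <- find_dispersed_repeats(sim$genome)
      pairs$pair_id <- "rep_01"
      cfgs <- build_configurations(pairs[1, ], sim$genome, pairs)
      cache <<- list(sim = sim, pairs = pairs, cfgs = cfgs)
    }
    cache
  }
})

test_that("configurations have the expected layout and composition", {
  fx <- recomb_fixture()
  cfgs <- fx$cfgs
  pair <- fx$pairs[1, ]
  expect_equal(unname(nchar(cfgs$sequences)),
               rep(2 * 2000 + pair$length, 4))
  expect_equal(cfgs$meta$class,
               c("original", "original", "alternative", "alternative"))
  # alt_1 is left flank of A + repeat + right flank of B, by construction
  g <- fx$sim$genome
  la <- substr(g$seq[[pair$iso_a]], pair$start_a - 2000 + 1, pair$start_a)
  ra <- substr(g$seq[[pair$iso_a]], pair$end_a + 1, pair$end_a + 2000)
  rb <- substr(g$seq[[pair$iso_b]], pair$end_b + 1, pair$end_b + 2000)
  rep_a <- substr(g$seq[[pair$iso_a]], pair$start_a + 1, pair$end_a)
  expect_identical(cfgs$sequences[["original_1"]], paste0(la, rep_a, ra))
  expect_identical(cfgs$sequences[["alt_1"]], paste0(la, rep_a, rb))
})

test_that("flanks are truncated at linear isoform ends and flagged", {
  set.seed(51)
  core <- random_dna(400)
  isoA <- paste0(substr(random_dna(500), 1, 500), core, random_dna(3000))
  isoB <- paste0(random_dna(3000), core, random_dna(3000))
  g <- organelle_genome("g", c(a = isoA, b = isoB), circular = FALSE)
  pair <- data.frame(iso_a = "a", start_a = 500L, end_a = 900L,
                     iso_b = "b", start_b = 3000L, end_b = 3400L,
                     strand = "+", length = 400L, stringsAsFactors = FALSE)
  cfgs <- build_configurations(pair, g, flank = 2000)
  expect_equal(cfgs$meta$left_flank[1], 500L)
  expect_true(cfgs$meta$truncated[1])
  expect_false(cfgs$meta$truncated[2])
})

test_that("flanks stop at neighbouring repeat copies", {
  fx <- recomb_fixture()
  pair <- fx$pairs[1, ]
  # fabricate a second repeat interval 800 bp left of copy A
  fake <- pair
  fake$start_a <- pair$start_a - 800L
  fake$end_a <- pair$start_a - 700L
  fake$start_b <- 100L
  fake$end_b <- 200L
  both <- rbind(fx$pairs, fake)
  cfgs <- build_configurations(pair, fx$sim$genome, both)
  expect_equal(cfgs$meta$left_flank[1], 700L)
})

test_that("an error-free read from a configuration supports it", {
  fx <- recomb_fixture()
  r <- substr(fx$cfgs$sequences[["original_1"]], 1500, 4200)
  sup <- assign_reads(c(read1 = r), fx$cfgs)
  expect_equal(sup$n_original, 1L)
  expect_equal(sup$n_alternative, 0L)
  ra <- substr(fx$cfgs$sequences[["alt_2"]], 1500, 4200)
  supa <- assign_reads(c(read1 = ra), fx$cfgs)
  expect_equal(supa$n_alternative, 1L)
})

test_that("reads not anchored in both flanks are ambiguous", {
  fx <- recomb_fixture()
  m <- fx$cfgs$meta[1, ]
  # repeat copy only, no flank anchor
  r <- substr(fx$cfgs$sequences[["original_1"]], m$rep_start + 1, m$rep_end)
  sup <- assign_reads(c(read1 = r), fx$cfgs)
  expect_equal(sup$n_ambiguous, 1L)
  # repeat plus one flank only
  r1 <- substr(fx$cfgs$sequences[["original_1"]], 1200, m$rep_end)
  sup1 <- assign_reads(c(read1 = r1), fx$cfgs)
  expect_equal(sup1$n_ambiguous, 1L)
})

test_that("an incomplete configuration set is rejected", {
  fx <- recomb_fixture()
  broken <- fx$cfgs
  broken$sequences <- broken$sequences[1:3]
  expect_error(assign_reads(c(r = "ACGT"), broken), "incomplete")
})

test_that("the frequency formula and its degenerate case are exact", {
  f <- function(o, a) recombination_frequency(
    list(pair_id = "p", n_original = o, n_alternative = a,
         n_ambiguous = 0L))$frequency
  expect_equal(f(90L, 10L), 0.10)
  expect_equal(f(50L, 50L), 0.50)
  expect_true(is.na(f(0L, 0L)))
  expect_error(recombination_frequency(
    list(pair_id = "p", n_original = -1L, n_alternative = 0L,
         n_ambiguous = 0L)), "negative")
})

test_that("simulated recombinant fractions are recovered within 3 SE", {
  fx <- recomb_fixture()
  tpl <- list(original = fx$cfgs$sequences[c("original_1", "original_2")],
              alternative = fx$cfgs$sequences[c("alt_1", "alt_2")])
  ests <- c()
  for (f in c(0, 0.4)) {
    rd <- suppressWarnings(
      simulate_reads(tpl, 500, error_rate = 0.05,
                     recombinant_fraction = f,
                     seed = 60 + round(100 * f)))
    sup <- assign_reads(rd$reads, fx$cfgs)
    fr <- recombination_frequency(sup)
    n_inf <- fr$n_original + fr$n_alternative
    est <- if (is.na(fr$frequency)) 0 else fr$frequency
    se <- sqrt(f * (1 - f) / max(n_inf, 1))
    expect_lte(abs(est - f), max(3 * se, 1e-9), label = paste("f =", f))
    ests <- c(ests, est)
  }
  expect_true(ests[1] < ests[2])
})

test_that("pairs no read can span are reported unassessable", {
  fx <- recomb_fixture()
  reads <- c(r1 = random_dna(900))       # shorter than repeat + anchors
  res <- recombination_scan(fx$sim$genome, fx$pairs, reads)
  expect_equal(res$status, "unassessable")
  expect_true(is.na(res$frequency))
})
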