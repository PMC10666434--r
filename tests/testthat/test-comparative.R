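test_that("self-similarity is exactly 1 and random genomes share ~nothing", {
  set.seed(71)
  g <- organelle_genome("a", c(i1 = random_dna(20000),
                               i2 = random_dna(15000)))
  self <- pairwise_similarity(g, g)
  expect_equal(self$fraction_a, 1.0)
  expect_equal(self$fraction_b, 1.0)
  h <- organelle_genome("b", c(j1 = random_dna(20000)))
  cross <- pairwise_similarity(g, h)
  expect_lt(cross$fraction_a, 0.02)
})

test_that("similarity is invariant under isoform reordering", {
  set.seed(72)
  shared <- random_dna(12000)
  ga <- organelle_genome("a", c(i1 = paste0(random_dna(5000), shared),
                                i2 = random_dna(8000)))
  gb <- organelle_genome("b", c(j1 = random_dna(6000),
                                j2 = paste0(shared, random_dna(4000))))
  s1 <- pairwise_similarity(ga, gb)
  ga_r <- organelle_genome("a", rev(ga$seq))
  s2 <- pairwise_similarity(ga_r, gb)
  expect_equal(s1$covered_bp_a, s2$covered_bp_a, tolerance = 0.001)
  expect_gt(s1$fraction_a, 12000 / 25000 * 0.95)
})

test_that("gene clusters are maximal gap-bounded runs, singletons excluded", {
  ann <- data.frame(
    gene = c("nad1", "nad2", "nad3", "cox1", "atp9"),
    isoform = c("i1", "i1", "i1", "i1", "i2"),
    start = c(0L, 1500L, 3000L, 20000L, 100L),
    end = c(1000L, 2500L, 4000L, 21000L, 1100L),
    strand = "+", kind = "protein_coding", stringsAsFactors = FALSE)
  cl <- gene_clusters(ann, max_gap = 5000)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$genes, c("nad1", "nad2", "nad3"))
  # tighter gap cap splits the run
  cl2 <- gene_clusters(ann, max_gap = 400)
  expect_length(cl2, 0L)
})

test_that("planted cluster templates are recovered and shared", {
  simA <- small_sim(seed = 81, gene_templates = 1:6, mtpt_rows = integer(0),
                    ssr_rows = integer(0), repeat_rows = integer(0))
  simB <- small_sim(seed = 82, gene_templates = 1:6, mtpt_rows = integer(0),
                    ssr_rows = integer(0), repeat_rows = integer(0))
  clA <- gene_clusters(simA$truth$genes)
  clB <- gene_clusters(simB$truth$genes)
  tmpl <- Filter(function(x) length(x) >= 2, default_gene_plan()[1:6])
  expect_length(clA, length(tmpl))
  got <- lapply(clA, `[[`, "genes")
  expect_setequal(vapply(got, paste, character(1), collapse = "-"),
                  vapply(tmpl, paste, character(1), collapse = "-"))
  sh <- shared_clusters(clA, clB)
  expect_equal(nrow(sh), length(tmpl))
  expect_equal(nrow(shared_clusters(clA, clB)),
               nrow(shared_clusters(clB, clA)))
})

test_that("cluster matching allows exact reversal only", {
  mk <- function(genes, iso) structure(
    list(genes = genes, isoform = iso, strands = rep("+", length(genes)),
         start = 0L, end = 1L), class = "gene_cluster")
  a <- list(mk(c("nad3", "rps12"), "i1"), mk(c("atp9", "rps7"), "i1"))
  b <- list(mk(c("rps12", "nad3"), "j1"), mk(c("atp9", "rps13"), "j2"))
  sh <- shared_clusters(a, b)
  expect_equal(nrow(sh), 1L)
  expect_true(sh$reversed)
  expect_equal(sh$genes, "nad3-rps12")
})

test_that("RSCU is 1 under uniform usage and normalizes to family size", {
  code <- Biostrings::GENETIC_CODE
  uni <- paste(names(code)[code != "*"], collapse = "")
  r <- rscu(c(g = paste0(uni, "TAA")))
  expect_true(all(abs(r$rscu - 1) < 1e-12))
  # every amino-acid family sums to its codon count k
  set.seed(83)
  cds <- vapply(1:5, function(i) {
    paste(c("ATG", sample(names(code)[code != "*" & names(code) != "ATG"],
                          200, replace = TRUE), "TAG"), collapse = "")
  }, character(1))
  names(cds) <- paste0("g", 1:5)
  rt <- rscu(cds)
  sums <- tapply(rt$rscu, rt$amino_acid, sum)
  ks <- tapply(rt$codon, rt$amino_acid, length)
  ok <- !is.na(sums)
  expect_equal(as.numeric(sums[ok]), as.numeric(ks[ok]),
               tolerance = 1e-12)
})

test_that("a 3:1 His codon bias gives RSCU 1.5 and 0.5 exactly", {
  r <- rscu(c(g1 = paste0("ATG", strrep("CAT", 3), "CAC", "TAA")))
  expect_equal(r$rscu[r$codon == "CAT"], 1.5)
  expect_equal(r$rscu[r$codon == "CAC"], 0.5)
})

test_that("RSCU equals the per-codon tally oracle on random gene sets", {
  set.seed(84)
  code <- Biostrings::GENETIC_CODE
  cds <- vapply(1:4, function(i) {
    paste(c("ATG", sample(names(code)[code != "*"], 150, replace = TRUE),
            "TAA"), collapse = "")
  }, character(1))
  names(cds) <- paste0("g", 1:4)
  # drop genes with internal stops the same way the implementation warns
  keep <- !vapply(cds, function(s) {
    cods <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 3, 3))
    any(code[cods] == "*", na.rm = TRUE)
  }, logical(1))
  got <- suppressWarnings(rscu(cds))
  exp <- rscu_oracle(unname(cds[keep]))
  m <- merge(got, exp, by = "codon")
  expect_equal(m$count.x, m$count.y)
  expect_equal(m$rscu.x, m$rscu.y, tolerance = 1e-12)
})

test_that("RSCU cross-checks against seqinr and skips broken CDS", {
  skip_if_not_installed("seqinr")
  set.seed(85)
  code <- Biostrings::GENETIC_CODE
  cds <- paste(c("ATG", sample(names(code)[code != "*"], 300,
                               replace = TRUE), "TAA"), collapse = "")
  got <- rscu(c(g = cds))
  uco <- seqinr::uco(seqinr::s2c(tolower(cds)), index = "rscu")
  names(uco) <- toupper(chartr("u", "t", names(uco)))
  cmp <- got[!is.na(got$rscu) & got$codon %in% names(uco), ]
  expect_equal(cmp$rscu, unname(uco[cmp$codon]), tolerance = 1e-9)
  expect_warning(rscu(c(bad = "ATGTAACATTAA")), "internal stop")
})

test_that("duplicate gene copies are counted once by default", {
  cds <- c(nad1 = paste0("ATG", strrep("CAT", 4), "TAA"),
           nad1 = paste0("ATG", strrep("CAC", 4), "TAA"))
  r1 <- rscu(cds)
  expect_equal(r1$count[r1$codon == "CAC"], 0L)
  r2 <- rscu(cds, dedupe_genes = FALSE)
  expect_equal(r2$count[r2$codon == "CAC"], 4L)
})

test_that("start/stop codon boundaries are tabulated and flagged", {
  cds <- c(nad1 = "ATGAAATAA", mttB = "ATAAAATGA")
  cb <- codon_boundary_summary(cds)
  expect_equal(cb$start_codon, c("ATG", "ATA"))
  expect_equal(cb$stop_codon, c("TAA", "TGA"))
  expect_equal(sum(!cb$canonical_start), 1L)
})

test_that("ORFs are found at exact planted coordinates across strands", {
  set.seed(86)
  code <- Biostrings::GENETIC_CODE
  body <- paste(sample(names(code)[code != "*" & names(code) != "ATG"],
                       133, replace = TRUE), collapse = "")
  orf <- paste0("ATG", body, "TAA")       # 405 bp
  bg1 <- random_dna(2001)
  sfwd <- paste0(bg1, "TAA", orf, random_dna(1500))
  res <- find_orfs(c(x = sfwd))
  expect_true(any(res$start == 2004 & res$end == 2004 + 405 &
                    res$strand == "+"))
  # same ORF on the reverse strand (revcomp of stop + ORF keeps the
  # reverse-frame stop adjacent, so the planted start is exact)
  srev <- paste0(bg1, revcomp(paste0("TAA", orf)), random_dna(1500))
  resr <- find_orfs(c(x = srev))
  expect_true(any(resr$start == 2001 & resr$end == 2001 + 405 &
                    resr$strand == "-"))
})

test_that("the 300 bp ORF bound is exclusive and ATG is required", {
  set.seed(87)
  code <- Biostrings::GENETIC_CODE
  mk_orf <- function(ncod) {
    paste0("ATG", paste(sample(names(code)[code != "*" &
                                             names(code) != "ATG"],
                               ncod, replace = TRUE), collapse = ""), "TAA")
  }
  short <- mk_orf(98)                      # exactly 300 bp
  long <- mk_orf(99)                       # 303 bp
  s <- paste0("TAA", short, "TAA", long, "TAA")
  res <- find_orfs(c(x = s), min_len = 300)
  expect_equal(nrow(res[res$strand == "+" & res$frame == 0, ]), 1L)
  expect_equal(res$length[res$strand == "+" & res$frame == 0], 303L)
  no_atg <- paste(rep("CCC", 200), collapse = "")
  expect_equal(nrow(find_orfs(c(x = no_atg))), 0L)
})
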