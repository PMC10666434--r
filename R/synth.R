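#' Configuration for the synthetic mitogenome generator
#'
#' Defaults emulate the organisation of a multichromosomal orchid
#' mitogenome: ~22 circular isoforms of 20-125 kb, background GC ~0.43,
#' dispersed repeat pairs in three size classes at > 95 percent identity,
#' plastid-derived inserts of 0.2-10 kb at > 80 percent identity, SSR loci,
#' and genes arranged in conserved clusters.
#'
#' @param n_isoforms number of isoforms.
#' @param isoform_length_range bp range (min, max) for isoform lengths.
#' @param gc_target background GC fraction.
#' @param repeat_plan data.frame(length, identity, strand, cross_isoform):
#'   dispersed repeat pairs to plant (identity in percent; substitutions
#'   only, so planted identity is exact).
#' @param mtpt_plan data.frame(length, identity) of plastid-derived inserts
#'   to plant; optional column p_start pins the donor interval.
#' @param ssr_plan data.frame(motif, count) of SSR loci to plant.
#' @param gene_plan list of character vectors; each vector is a cluster
#'   template of gene names planted as consecutive features (singletons
#'   allowed).
#' @param circular circularity flag(s) for the isoforms.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(n_isoforms = 22L,
                         isoform_length_range = c(20000L, 125000L),
                         gc_target = 0.43,
                         repeat_plan = default_repeat_plan(),
                         mtpt_plan = default_mtpt_plan(),
                         ssr_plan = default_ssr_plan(),
                         gene_plan = default_gene_plan(),
                         circular = TRUE,
                         seed = 1L) {
  stopifnot(n_isoforms >= 1, all(isoform_length_range > 0),
            gc_target > 0, gc_target < 1)
  if (nrow(repeat_plan) > 0 &&
      (any(repeat_plan$identity <= 0) || any(repeat_plan$identity > 100))) {
    stop("repeat identities must be in (0, 100]")
  }
  structure(list(n_isoforms = as.integer(n_isoforms),
                 isoform_length_range = as.integer(isoform_length_range),
                 gc_target = gc_target, repeat_plan = repeat_plan,
                 mtpt_plan = mtpt_plan, ssr_plan = ssr_plan,
                 gene_plan = gene_plan, circular = circular,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_repeat_plan <- function() {
  data.frame(
    length = c(8000L, 5000L, 2000L, 800L, 500L, 300L, 150L, 60L, 45L, 30L),
    identity = c(99.5, 99, 98.5, 98, 97, 96, 98, 100, 97.8, 96.7),
    strand = c("+", "+", "-", "+", "+", "+", "-", "+", "+", "+"),
    cross_isoform = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
                      FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname synth_config
#' @export
default_mtpt_plan <- function() {
  data.frame(length = c(300L, 500L, 900L, 1500L, 3000L, 6000L),
             identity = c(85, 88, 92, 95, 97, 99))
}

#' @rdname synth_config
#' @export
default_ssr_plan <- function() {
  data.frame(motif = c("A", "T", "AT", "AG", "TA", "AAT", "AGC"),
             count = c(10L, 9L, 6L, 5L, 7L, 5L, 6L),
             stringsAsFactors = FALSE)
}

#' @rdname synth_config
#' @export
default_gene_plan <- function() {
  list(c("rps3", "rpl16", "rpl2", "rps19"),
       c("atp8", "nad4L", "atp4"),
       c("nad3", "rps12"),
       c("rrn5", "rrn18"),
       c("rps14", "rpl5"),
       c("atp9", "rps7"),
       "cox1", "nad5", "mttB")
}

BASES <- c("A", "C", "G", "T")

random_dna_chars <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

other_base <- function(b) {
  idx <- match(b, BASES)
  BASES[((idx - 1L + sample.int(3L, length(b), replace = TRUE)) %% 4L) + 1L]
}

# TRUE when every terminal prefix/suffix window of the feature stays above
# the +1/-2 score break-even density (fewer than t/3 substitutions in the
# outer t bases).  A terminal window below break-even is trimmed off any
# score-optimal local alignment, so the planted boundary would be
# unrecoverable by construction rather than by detector error.
edges_alignable <- function(pos, n, w = 60L) {
  for (t in seq_len(min(w, n))) {
    lim <- (t - 1L) %/% 3L
    if (sum(pos <= t) > lim) return(FALSE)
    if (sum(pos > n - t) > lim) return(FALSE)
  }
  TRUE
}

# Substitute exactly n_mut positions to different bases.  Positions are
# i.i.d. uniform (so long exact runs remain for k-mer seeding), re-drawn
# when a terminal window falls below the alignment break-even density;
# edge_buffer additionally keeps the outermost bases intact.
mutate_substitutions <- function(chars, n_mut, edge_buffer = 0L) {
  if (n_mut == 0L) return(chars)
  n <- length(chars)
  buf <- min(edge_buffer, max(0L, (n - n_mut) %/% 2L))
  pool <- (buf + 1L):(n - buf)
  pos <- pool[sample.int(length(pool), n_mut)]
  for (try in seq_len(200L)) {
    if (edges_alignable(pos, n)) break
    pos <- pool[sample.int(length(pool), n_mut)]
  }
  chars[pos] <- other_base(chars[pos])
  chars
}

# occupied-interval registry: sample a free interval on a random isoform
new_registry <- function(lens) {
  lapply(lens, function(L) data.frame(start = integer(), end = integer()))
}

sample_free_interval <- function(reg, lens, len, margin = 60L,
                                 isoform = NULL, tries = 500L) {
  for (t in seq_len(tries)) {
    iso <- if (is.null(isoform)) sample(names(lens), 1L) else isoform
    L <- lens[[iso]]
    if (L < len + 2L * margin) next
    start <- sample.int(L - len - 2L * margin, 1L) + margin
    occ <- reg[[iso]]
    if (nrow(occ) == 0L ||
        !any(occ$start < start + len + margin &
               occ$end > start - margin)) {
      return(list(isoform = iso, start = start, end = start + len))
    }
  }
  stop("could not place a ", len, " bp feature: plan exceeds isoform ",
       "capacity", call. = FALSE)
}

mark_occupied <- function(reg, iso, start, end) {
  reg[[iso]] <- rbind(reg[[iso]], data.frame(start = start, end = end))
  reg
}

# random CDS: ATG + non-stop codons + stop
random_cds_chars <- function(n_codons, gc) {
  stops <- c("TAA", "TAG", "TGA")
  body <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(random_dna_chars(3L, gc), collapse = "")
      if (!cd %in% stops) break
    }
    body[i] <- cd
  }
  strsplit(paste0("ATG", paste(body, collapse = ""),
                  sample(stops, 1L)), "", fixed = TRUE)[[1]]
}

#' Generate a synthetic quadripartite plastome
#'
#' One circular isoform structured LSC + IR_A + SSC + IR_B where IR_B is
#' exactly the reverse complement of IR_A, with genes planted in the single
#' copy regions.
#'
#' @param lsc,ir,ssc region lengths in bp.
#' @param gc named GC targets for the three distinct regions.
#' @param genes character vector of plastid gene names to plant (in LSC and
#'   SSC).
#' @param name genome label.
#' @param seed integer seed.
#' @return list with \code{genome} (an \code{organelle_genome}) and
#'   \code{truth} (regions and genes data.frames, internal coordinates).
#' @export
generate_plastome <- function(lsc = 84962L, ir = 26128L, ssc = 14001L,
                              gc = c(lsc = 0.36, ir = 0.43, ssc = 0.30),
                              genes = c("psbA", "rbcL", "matK", "atpB",
                                        "rpoB", "psbB", "petA", "ndhF",
                                        "ccsA", "rpl32"),
                              name = "synth_plastome", seed = 1L) {
  set.seed(seed)
  lsc_ch <- random_dna_chars(lsc, gc[["lsc"]])
  ira_ch <- random_dna_chars(ir, gc[["ir"]])
  ssc_ch <- random_dna_chars(ssc, gc[["ssc"]])
  feats <- empty_features()
  reg <- list(LSC = data.frame(start = integer(), end = integer()),
              SSC = data.frame(start = integer(), end = integer()))
  lens <- c(LSC = lsc, SSC = ssc)
  for (g in genes) {
    n_codons <- sample(100:400, 1L)
    cds <- random_cds_chars(n_codons, gc[["lsc"]])
    region <- if (lsc >= ssc) "LSC" else "SSC"
    pl <- sample_free_interval(reg, lens, length(cds), isoform = region)
    reg <- mark_occupied(reg, pl$isoform, pl$start, pl$end)
    if (pl$isoform == "LSC") {
      lsc_ch[(pl$start + 1L):pl$end] <- cds
      gstart <- pl$start
    } else {
      ssc_ch[(pl$start + 1L):pl$end] <- cds
      gstart <- lsc + ir + pl$start
    }
    feats <- rbind(feats, data.frame(
      gene = g, isoform = name, start = gstart,
      end = gstart + length(cds), strand = "+",
      kind = "protein_coding", stringsAsFactors = FALSE
    ))
  }
  ira <- paste(ira_ch, collapse = "")
  seq <- paste0(paste(lsc_ch, collapse = ""), ira,
                paste(ssc_ch, collapse = ""), revcomp_cpp(ira))
  regions <- data.frame(
    region = c("LSC", "IR_A", "SSC", "IR_B"),
    start = c(0L, lsc, lsc + ir, lsc + ir + ssc),
    end = c(lsc, lsc + ir, lsc + ir + ssc, lsc + 2L * ir + ssc),
    stringsAsFactors = FALSE
  )
  genome <- organelle_genome(name, stats::setNames(seq, name),
                             circular = TRUE)
  list(genome = genome,
       truth = list(regions = regions, genes = validate_features(feats)))
}

#' Generate a synthetic multi-isoform mitogenome with planted ground truth
#'
#' Background sequence is i.i.d. at the target GC.  Dispersed repeats are
#' planted as second copies mutated (substitutions only) to the requested
#' identity; plastid-derived segments are copied from a donor plastome and
#' mutated likewise; SSR loci and clustered gene features are planted at
#' recorded positions.  No two planted features overlap.  A fixed seed gives
#' byte-identical output.
#'
#' @param config a \code{\link{synth_config}}.
#' @param plastome optional donor \code{organelle_genome} with its truth (a
#'   list as returned by \code{\link{generate_plastome}}); generated
#'   internally when MTPTs are planned and none is supplied.
#' @param name genome label.
#' @return list with \code{genome}, \code{truth} (repeats, mtpt, ssr,
#'   genes), \code{plastome} and \code{plastome_truth}.
#' @export
generate_mitogenome <- function(config, plastome = NULL,
                                name = "synth_mito") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  rng <- config$isoform_length_range
  lens <- rng[1] + sample.int(rng[2] - rng[1] + 1L, config$n_isoforms,
                              replace = TRUE) - 1L
  ids <- sprintf("isoform_%02d", seq_len(config$n_isoforms))
  names(lens) <- ids
  planted_bp <- sum(config$repeat_plan$length) * 2 +
    sum(config$mtpt_plan$length) +
    sum(nchar(config$ssr_plan$motif) * config$ssr_plan$count) +
    length(unlist(config$gene_plan)) * 1500
  if (planted_bp * 1.3 > sum(lens)) {
    stop("planted-feature plan exceeds genome capacity (",
         planted_bp, " bp planned, ", sum(lens), " bp available)")
  }
  chars <- lapply(lens, random_dna_chars, gc = config$gc_target)
  reg <- new_registry(lens)
  truth <- list()
  # --- genes in cluster templates ---------------------------------------
  feats <- empty_features()
  for (tmpl in config$gene_plan) {
    tmpl <- as.character(tmpl)
    blocks <- lapply(tmpl, function(g) {
      if (startsWith(g, "trn")) {
        list(kind = "tRNA", chars = random_dna_chars(
          sample(70:90, 1L), config$gc_target))
      } else if (startsWith(g, "rrn")) {
        list(kind = "rRNA", chars = random_dna_chars(
          sample(900:1800, 1L), config$gc_target))
      } else {
        list(kind = "protein_coding",
             chars = random_cds_chars(sample(100:300, 1L),
                                      config$gc_target))
      }
    })
    gaps <- sample(80:400, length(tmpl))
    block_len <- sum(vapply(blocks, function(b) length(b$chars),
                            integer(1))) + sum(gaps[-1])
    # wide margin keeps distinct cluster templates from chaining under the
    # default 5 kb adjacency rule
    pl <- sample_free_interval(reg, lens, block_len, margin = 5100L)
    reg <- mark_occupied(reg, pl$isoform, pl$start, pl$end)
    pos <- pl$start
    for (i in seq_along(tmpl)) {
      glen <- length(blocks[[i]]$chars)
      chars[[pl$isoform]][(pos + 1L):(pos + glen)] <- blocks[[i]]$chars
      feats <- rbind(feats, data.frame(
        gene = tmpl[i], isoform = pl$isoform, start = pos,
        end = pos + glen, strand = "+", kind = blocks[[i]]$kind,
        stringsAsFactors = FALSE
      ))
      pos <- pos + glen + if (i < length(tmpl)) gaps[i + 1L] else 0L
    }
  }
  truth$genes <- feats
  truth$gene_clusters <- lapply(config$gene_plan, as.character)
  # --- dispersed repeat pairs -------------------------------------------
  rp <- config$repeat_plan
  rp_truth <- NULL
  if (nrow(rp) > 0) {
    for (i in seq_len(nrow(rp))) {
      len <- rp$length[i]
      strand <- if ("strand" %in% names(rp)) rp$strand[i] else "+"
      cross <- if ("cross_isoform" %in% names(rp)) rp$cross_isoform[i]
               else FALSE
      a <- sample_free_interval(reg, lens, len)
      reg <- mark_occupied(reg, a$isoform, a$start, a$end)
      iso_b <- if (cross && config$n_isoforms > 1L) {
        sample(setdiff(ids, a$isoform), 1L)
      } else NULL
      b <- sample_free_interval(reg, lens, len, isoform = iso_b)
      reg <- mark_occupied(reg, b$isoform, b$start, b$end)
      src <- chars[[a$isoform]][(a$start + 1L):a$end]
      cp <- if (strand == "-") {
        strsplit(revcomp_cpp(paste(src, collapse = "")), "",
                 fixed = TRUE)[[1]]
      } else src
      n_mut <- round(len * (100 - rp$identity[i]) / 100)
      cp <- mutate_substitutions(cp, n_mut, edge_buffer = 3L)
      chars[[b$isoform]][(b$start + 1L):b$end] <- cp
      rp_truth <- rbind(rp_truth, data.frame(
        pair_id = sprintf("rep_%02d", i),
        iso_a = a$isoform, start_a = a$start, end_a = a$end,
        iso_b = b$isoform, start_b = b$start, end_b = b$end,
        strand = strand, length = len,
        identity = 100 * (len - n_mut) / len,
        size_class = classify_repeat(max(len, 21L)),
        stringsAsFactors = FALSE
      ))
    }
  }
  truth$repeats <- rp_truth %||% data.frame()
  # --- plastid-derived inserts ------------------------------------------
  mp <- config$mtpt_plan
  pl_out <- plastome
  mt_truth <- NULL
  if (nrow(mp) > 0) {
    if (is.null(pl_out)) {
      pl_out <- generate_plastome(seed = derive_seed(config$seed, 17L))
    }
    pseq <- pl_out$genome$seq[[1]]
    pn <- nchar(pseq)
    for (i in seq_len(nrow(mp))) {
      len <- mp$length[i]
      p_start <- if ("p_start" %in% names(mp) && !is.na(mp$p_start[i])) {
        mp$p_start[i]
      } else sample.int(pn - len, 1L)
      donor <- substr(pseq, p_start + 1L, p_start + len)
      strand <- sample(c("+", "-"), 1L)
      cp <- strsplit(if (strand == "-") revcomp_cpp(donor) else donor, "",
                     fixed = TRUE)[[1]]
      n_mut <- round(len * (100 - mp$identity[i]) / 100)
      cp <- mutate_substitutions(cp, n_mut)
      m <- sample_free_interval(reg, lens, len)
      reg <- mark_occupied(reg, m$isoform, m$start, m$end)
      chars[[m$isoform]][(m$start + 1L):m$end] <- cp
      mt_truth <- rbind(mt_truth, data.frame(
        mtpt_id = sprintf("mtpt_%02d", i),
        isoform = m$isoform, start = m$start, end = m$end,
        p_start = p_start, p_end = p_start + len, strand = strand,
        length = len, identity = 100 * (len - n_mut) / len,
        stringsAsFactors = FALSE
      ))
    }
  }
  truth$mtpt <- mt_truth %||% data.frame()
  # --- SSR loci ----------------------------------------------------------
  sp <- config$ssr_plan
  ssr_truth <- NULL
  if (nrow(sp) > 0) {
    for (i in seq_len(nrow(sp))) {
      motif <- toupper(sp$motif[i])
      len <- nchar(motif) * sp$count[i]
      run <- strsplit(strrep(motif, sp$count[i]), "", fixed = TRUE)[[1]]
      s <- sample_free_interval(reg, lens, len + 2L)
      reg <- mark_occupied(reg, s$isoform, s$start, s$end)
      # guard bases stop the run extending into the background
      first <- substr(motif, nchar(motif), nchar(motif))
      chars[[s$isoform]][s$start + 1L] <- other_base(substr(motif, 1L, 1L))
      chars[[s$isoform]][(s$start + 2L):(s$start + 1L + len)] <- run
      chars[[s$isoform]][s$end] <- other_base(first)
      ssr_truth <- rbind(ssr_truth, data.frame(
        isoform = s$isoform, start = s$start + 1L,
        end = s$start + 1L + len, motif = motif,
        count = sp$count[i], stringsAsFactors = FALSE
      ))
    }
  }
  truth$ssr <- ssr_truth %||% data.frame()
  seqs <- vapply(chars, paste, character(1), collapse = "")
  genome <- organelle_genome(name, seqs, circular = config$circular)
  list(genome = genome, truth = truth,
       plastome = if (!is.null(pl_out)) pl_out$genome else NULL,
       plastome_truth = if (!is.null(pl_out)) pl_out$truth else NULL)
}

# apply substitutions/indels to one read sequence
mutate_read <- function(seq, rate) {
  n <- nchar(seq)
  nerr <- stats::rbinom(1L, n, rate)
  if (nerr == 0L) return(seq)
  pos <- sort(sample.int(n, nerr))
  type <- sample.int(3L, nerr, replace = TRUE, prob = c(0.5, 0.25, 0.25))
  pieces <- character(2L * nerr + 1L)
  prev <- 1L
  for (t in seq_len(nerr)) {
    p <- pos[t]
    pieces[2L * t - 1L] <- substr(seq, prev, p - 1L)
    cur <- substr(seq, p, p)
    pieces[2L * t] <- switch(type[t],
                             other_base(cur),
                             paste0(cur, sample(BASES, 1L)),
                             "")
    prev <- p + 1L
  }
  pieces[2L * nerr + 1L] <- substr(seq, prev, n)
  paste(pieces, collapse = "")
}

#' Simulate Nanopore-like long reads with a recombinant fraction
#'
#' Each read is drawn from an "original" template with probability
#' \code{1 - recombinant_fraction} and from an "alternative" (recombinant)
#' template otherwise, at a uniform start position and random strand.  Read
#' lengths are log-normal truncated to \code{[min_len, max_len]};
#' substitutions and indels (50/25/25) are applied at \code{error_rate}.
#' Reads longer than their template are truncated (one summary warning).
#'
#' @param templates either an \code{organelle_genome} (all reads labelled
#'   "original") or a list with character vectors \code{original} and
#'   \code{alternative}.
#' @param n_reads number of reads.
#' @param error_rate per-base error rate in [0, 0.2].
#' @param recombinant_fraction fraction of reads drawn from alternative
#'   templates, in [0, 1].
#' @param meanlog,sdlog log-normal read-length parameters (default mode
#'   ~3 kb, long tail, 10-kb-library-like).
#' @param min_len,max_len truncation bounds for read length (bp).
#' @param seed integer seed.
#' @return list with \code{reads} (named character vector) and \code{truth}
#'   (read, class, template, strand, start, length).
#' @export
simulate_reads <- function(templates, n_reads, error_rate = 0.05,
                           recombinant_fraction = 0,
                           meanlog = log(3000), sdlog = 0.45,
                           min_len = 1000L, max_len = 50000L, seed = 1L) {
  stopifnot(recombinant_fraction >= 0, recombinant_fraction <= 1,
            error_rate >= 0, error_rate <= 0.2, n_reads >= 1)
  set.seed(seed)
  if (inherits(templates, "organelle_genome")) {
    templates <- list(original = templates$seq,
                      alternative = character(0))
    if (recombinant_fraction > 0) {
      stop("recombinant_fraction > 0 needs alternative templates")
    }
  }
  orig <- templates$original
  alt <- templates$alternative
  cls <- ifelse(stats::runif(n_reads) < recombinant_fraction,
                "alternative", "original")
  lens <- round(stats::rlnorm(n_reads, meanlog, sdlog))
  lens <- pmin(pmax(lens, min_len), max_len)
  reads <- character(n_reads)
  truth <- data.frame(read = sprintf("read_%05d", seq_len(n_reads)),
                      class = cls, template = NA_character_,
                      strand = NA_character_, start = NA_integer_,
                      length = NA_integer_, stringsAsFactors = FALSE)
  n_trunc <- 0L
  for (i in seq_len(n_reads)) {
    pool <- if (cls[i] == "alternative") alt else orig
    ti <- sample.int(length(pool), 1L)
    tmpl <- pool[[ti]]
    tl <- nchar(tmpl)
    start <- sample.int(tl, 1L) - 1L
    end <- start + lens[i]
    if (end > tl) { end <- tl; n_trunc <- n_trunc + 1L }
    frag <- substr(tmpl, start + 1L, end)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") frag <- revcomp_cpp(frag)
    reads[i] <- mutate_read(frag, error_rate)
    truth$template[i] <- names(pool)[ti] %||% as.character(ti)
    truth$strand[i] <- strand
    truth$start[i] <- start
    truth$length[i] <- end - start
  }
  if (n_trunc > 0L) {
    warning(n_trunc, " read(s) exceeded their template and were truncated")
  }
  names(reads) <- truth$read
  list(reads = reads, truth = truth)
}

#' Write reads as FASTQ (constant quality)
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  ss <- Biostrings::DNAStringSet(reads)
  names(qual) <- names(ss)
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}
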