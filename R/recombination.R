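#' Build original and alternative repeat-flank configurations
#'
#' For one detected repeat pair, extracts the +-\code{flank} bp single-copy
#' flanking regions of each copy as the two original configurations and
#' builds the two expected recombinant (alternative) configurations that
#' exchange the flanks.  Flanks are truncated at isoform ends (or wrapped on
#' circular isoforms) and shortened to their single-copy portion when they
#' overlap any other detected repeat interval; shortened flanks are flagged.
#'
#' For a direct pair (strand \code{+}): \code{alt_1 = left(A) + repeat +
#' right(B)} and \code{alt_2 = left(B) + repeat + right(A)}.  For an
#' inverted pair (strand \code{-}) the crossover inverts the intervening
#' segment, so \code{alt_1 = left(A) + repeat + revcomp(left(B))} and
#' \code{alt_2 = revcomp(right(A)) + repeat_B + right(B)}.
#'
#' @param pair one row of a repeat-pair table
#'   (\code{\link{find_dispersed_repeats}} layout).
#' @param genome the \code{organelle_genome}.
#' @param detected_repeats full repeat-pair table; other pairs' intervals
#'   bound the single-copy flanks.
#' @param flank flank length in bp.
#' @return a \code{repeat_configurations} list: \code{sequences} (named:
#'   original_1, original_2, alt_1, alt_2), \code{meta} (per configuration:
#'   repeat span inside the configuration sequence and flank lengths), and
#'   \code{pair}.
#' @export
build_configurations <- function(pair, genome, detected_repeats = NULL,
                                 flank = 2000L) {
  stopifnot(flank > 0)
  lens <- isoform_lengths(genome)
  if (pair$end_a - pair$start_a > lens[[pair$iso_a]] ||
      pair$end_b - pair$start_b > lens[[pair$iso_b]]) {
    stop("repeat copy longer than its isoform")
  }
  other <- NULL
  if (!is.null(detected_repeats) && nrow(detected_repeats) > 0) {
    dr <- detected_repeats
    own <- (dr$iso_a == pair$iso_a & dr$start_a == pair$start_a &
              dr$iso_b == pair$iso_b & dr$start_b == pair$start_b)
    other <- repeat_pair_intervals(dr[!own, , drop = FALSE], genome)
    # the pair's own two copies also bound each other's flanks
    own_iv <- data.frame(
      isoform = c(pair$iso_a, pair$iso_b),
      start = c(pair$start_a, pair$start_b),
      end = c(pair$end_a, pair$end_b), stringsAsFactors = FALSE
    )
    other <- rbind(other, own_iv)
  }
  get_flank <- function(iso, pos, side, exclude_start, exclude_end) {
    seq <- genome$seq[[iso]]
    L <- lens[[iso]]
    circ <- genome$circular[[iso]]
    if (side == "left") {
      lo <- pos - flank
      hi <- pos
      if (!is.null(other)) {
        oi <- other[other$isoform == iso &
                      !(other$start == exclude_start &
                          other$end == exclude_end), , drop = FALSE]
        blk <- oi$end[oi$end <= hi & oi$end > lo]
        if (length(blk) > 0) lo <- max(blk)
      }
      truncated <- FALSE
      if (lo < 0) {
        if (circ) {
          s <- paste0(substr(seq, L + lo + 1L, L), substr(seq, 1L, hi))
          return(list(seq = s, len = hi - lo, truncated = FALSE))
        }
        lo <- 0L; truncated <- TRUE
      }
      list(seq = substr(seq, lo + 1L, hi), len = hi - lo,
           truncated = truncated)
    } else {
      lo <- pos
      hi <- pos + flank
      if (!is.null(other)) {
        oi <- other[other$isoform == iso &
                      !(other$start == exclude_start &
                          other$end == exclude_end), , drop = FALSE]
        blk <- oi$start[oi$start >= lo & oi$start < hi]
        if (length(blk) > 0) hi <- min(blk)
      }
      truncated <- FALSE
      if (hi > L) {
        if (circ) {
          s <- paste0(substr(seq, lo + 1L, L), substr(seq, 1L, hi - L))
          return(list(seq = s, len = hi - lo, truncated = FALSE))
        }
        hi <- L; truncated <- TRUE
      }
      list(seq = substr(seq, lo + 1L, hi), len = hi - lo,
           truncated = truncated)
    }
  }
  la <- get_flank(pair$iso_a, pair$start_a, "left", pair$start_a,
                  pair$end_a)
  ra <- get_flank(pair$iso_a, pair$end_a, "right", pair$start_a,
                  pair$end_a)
  lb <- get_flank(pair$iso_b, pair$start_b, "left", pair$start_b,
                  pair$end_b)
  rb <- get_flank(pair$iso_b, pair$end_b, "right", pair$start_b,
                  pair$end_b)
  rep_a <- substr(genome$seq[[pair$iso_a]], pair$start_a + 1L, pair$end_a)
  rep_b <- substr(genome$seq[[pair$iso_b]], pair$start_b + 1L, pair$end_b)
  inverted <- !is.null(pair$strand) && pair$strand == "-"
  if (inverted) {
    seqs <- c(original_1 = paste0(la$seq, rep_a, ra$seq),
              original_2 = paste0(lb$seq, rep_b, rb$seq),
              alt_1 = paste0(la$seq, rep_a, revcomp_cpp(lb$seq)),
              alt_2 = paste0(revcomp_cpp(ra$seq), rep_b, rb$seq))
    lefts <- c(la$len, lb$len, la$len, ra$len)
    rights <- c(ra$len, rb$len, lb$len, rb$len)
  } else {
    seqs <- c(original_1 = paste0(la$seq, rep_a, ra$seq),
              original_2 = paste0(lb$seq, rep_b, rb$seq),
              alt_1 = paste0(la$seq, rep_a, rb$seq),
              alt_2 = paste0(lb$seq, rep_b, ra$seq))
    lefts <- c(la$len, lb$len, la$len, lb$len)
    rights <- c(ra$len, rb$len, rb$len, ra$len)
  }
  rep_len <- c(nchar(rep_a), nchar(rep_b), nchar(rep_a), nchar(rep_b))
  meta <- data.frame(
    config = names(seqs),
    class = c("original", "original", "alternative", "alternative"),
    left_flank = lefts, rep_start = lefts, rep_end = lefts + rep_len,
    right_flank = rights,
    truncated = c(la$truncated | ra$truncated,
                  lb$truncated | rb$truncated,
                  la$truncated | rb$truncated,
                  lb$truncated | ra$truncated),
    stringsAsFactors = FALSE
  )
  structure(list(sequences = seqs, meta = meta, pair = pair,
                 flank = flank),
            class = "repeat_configurations")
}

#' Assign long reads to repeat-flank configurations
#'
#' Each read is aligned (both strands) against all four configurations with
#' the seed-and-extend aligner.  A read supports a configuration iff its
#' best alignment there spans the full repeat copy plus at least
#' \code{min_anchor} bp into both flanks (or the full flank when a flank is
#' shorter than the anchor) at identity >= \code{min_read_identity}.  Reads
#' qualifying for no configuration, spanning only one flank, or whose best
#' original-class and alternative-class scores tie, are counted ambiguous.
#'
#' @param reads character vector of read sequences.
#' @param configurations a \code{repeat_configurations} object.
#' @param min_anchor minimum bp a read must extend into each flank.
#' @param min_read_identity minimum alignment identity (fraction).
#' @param k seed length for read mapping.
#' @param scoring a \code{scoring_scheme}.
#' @return list of class \code{read_support}: n_original, n_alternative,
#'   n_ambiguous, and \code{calls} (per-read class).
#' @export
assign_reads <- function(reads, configurations, min_anchor = 100L,
                         min_read_identity = 0.8, k = 13L,
                         scoring = scoring_scheme()) {
  if (length(reads) < 1L) stop("no reads")
  if (!inherits(configurations, "repeat_configurations") ||
      length(configurations$sequences) != 4L) {
    stop("configuration set incomplete: need the 4 configurations")
  }
  meta <- configurations$meta
  n <- length(reads)
  best <- matrix(-Inf, nrow = n, ncol = 4L,
                 dimnames = list(NULL, meta$config))
  ok <- matrix(FALSE, nrow = n, ncol = 4L)
  for (ci in seq_len(4L)) {
    subj <- configurations$sequences[[ci]]
    h <- chain_align_cpp(unname(reads), subj, as.integer(k), 400L, 30L,
                         500L, 120L, as.integer(k) + 2L, 50L,
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, FALSE, TRUE)
    if (nrow(h) == 0L) next
    h$identity <- ifelse(h$length > 0, h$matches / h$length, 0)
    need_lo <- meta$rep_start[ci] -
      min(min_anchor, meta$left_flank[ci])
    need_hi <- meta$rep_end[ci] +
      min(min_anchor, meta$right_flank[ci])
    h$qual <- h$s_start <= need_lo & h$s_end >= need_hi &
      h$identity >= min_read_identity
    # best alignment per read; qualification judged on that alignment
    o <- order(h$query, -h$score)
    h <- h[o, , drop = FALSE]
    first <- !duplicated(h$query)
    hb <- h[first, , drop = FALSE]
    best[hb$query, ci] <- hb$score
    ok[hb$query, ci] <- hb$qual
  }
  is_orig <- meta$class == "original"
  score_if <- function(scores, qual, sel) {
    s <- ifelse(qual[, sel, drop = FALSE],
                scores[, sel, drop = FALSE], -Inf)
    apply(s, 1L, max)
  }
  bo <- score_if(best, ok, is_orig)
  ba <- score_if(best, ok, !is_orig)
  calls <- ifelse(bo == -Inf & ba == -Inf, "ambiguous",
                  ifelse(bo == ba, "ambiguous",
                         ifelse(bo > ba, "original", "alternative")))
  structure(list(pair_id = configurations$pair$pair_id %||% NA_character_,
                 n_original = sum(calls == "original"),
                 n_alternative = sum(calls == "alternative"),
                 n_ambiguous = sum(calls == "ambiguous"),
                 calls = calls),
            class = "read_support")
}

#' Repeat-mediated recombination frequency
#'
#' \code{frequency = n_alternative / (n_original + n_alternative)}.
#' Ambiguous reads are excluded by construction; a zero denominator gives
#' \code{NA} (never 0).
#'
#' @param support a \code{read_support} (or any list with counts
#'   n_original, n_alternative, n_ambiguous).
#' @return one-row data.frame: pair_id, n_original, n_alternative,
#'   n_ambiguous, frequency.
#' @export
recombination_frequency <- function(support) {
  no <- support$n_original
  na_ <- support$n_alternative
  if (any(c(no, na_, support$n_ambiguous %||% 0L) < 0)) {
    stop("negative read counts")
  }
  den <- no + na_
  data.frame(pair_id = support$pair_id %||% NA_character_,
             n_original = no, n_alternative = na_,
             n_ambiguous = support$n_ambiguous %||% NA_integer_,
             frequency = if (den > 0) na_ / den else NA_real_,
             stringsAsFactors = FALSE)
}

#' Recombination activity scan over all repeat pairs
#'
#' Builds flank configurations for every detected repeat pair, assigns the
#' reads, and reports per-pair support counts and recombination frequency.
#' Pairs too long for any read to span (repeat length + 2 anchors exceeding
#' the longest read) are reported with status "unassessable" rather than
#' frequency 0.  A pair is flagged recombinationally active when it has at
#' least \code{min_alt_reads} alternative-supporting reads and frequency
#' above \code{min_freq} (tunable; single chimeric reads do not qualify).
#'
#' @param genome the \code{organelle_genome}.
#' @param pairs repeat-pair table.
#' @param reads character vector of read sequences.
#' @param flank,min_anchor,min_read_identity,k,scoring see
#'   \code{\link{build_configurations}} and \code{\link{assign_reads}}.
#' @param min_alt_reads,min_freq activity-call thresholds.
#' @return data.frame: pair_id, size_class, n_original, n_alternative,
#'   n_ambiguous, frequency, status, active.
#' @export
recombination_scan <- function(genome, pairs, reads, flank = 2000L,
                               min_anchor = 100L, min_read_identity = 0.8,
                               k = 13L, scoring = scoring_scheme(),
                               min_alt_reads = 2L, min_freq = 0.01) {
  max_read <- max(nchar(reads))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    pair <- pairs[i, , drop = FALSE]
    pair$pair_id <- pair$pair_id %||% sprintf("pair_%03d", i)
    if (pair$length + 2L * min_anchor > max_read) {
      return(data.frame(pair_id = pair$pair_id,
                        size_class = pair$size_class %||% NA_character_,
                        n_original = NA_integer_,
                        n_alternative = NA_integer_,
                        n_ambiguous = NA_integer_, frequency = NA_real_,
                        status = "unassessable", active = NA,
                        stringsAsFactors = FALSE))
    }
    cfg <- build_configurations(pair, genome, pairs, flank = flank)
    sup <- assign_reads(reads, cfg, min_anchor = min_anchor,
                        min_read_identity = min_read_identity, k = k,
                        scoring = scoring)
    fr <- recombination_frequency(sup)
    fr$size_class <- pair$size_class %||% NA_character_
    fr$status <- "assessed"
    fr$active <- !is.na(fr$frequency) &
      fr$n_alternative >= min_alt_reads & fr$frequency > min_freq
    fr[, c("pair_id", "size_class", "n_original", "n_alternative",
           "n_ambiguous", "frequency", "status", "active")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
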