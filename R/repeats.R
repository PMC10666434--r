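#' Classify dispersed repeats by length
#'
#' Size classes: short (< 100 bp), intermediate (100-1000 bp, closed
#' interval), large (> 1000 bp).
#'
#' @param length integer vector of repeat lengths (> 20 bp).
#' @return character vector of size classes.
#' @export
classify_repeat <- function(length) {
  if (any(length <= 20)) stop("repeat length must exceed 20 bp")
  ifelse(length < 100, "short",
         ifelse(length <= 1000, "intermediate", "large"))
}

# extend a circular isoform sequence past the origin so origin-spanning
# repeats are seen by the linear scan
circular_extend <- function(seq, circular, max_ext = 20000L) {
  if (!circular) return(list(seq = seq, ext = 0L))
  n <- nchar(seq)
  ext <- min(n - 1L, max_ext)
  list(seq = paste0(seq, substr(seq, 1L, ext)), ext = ext)
}

#' Find dispersed repeat pairs in a multi-isoform genome
#'
#' The genome is aligned against itself (every isoform pair including
#' self-alignment, both strands) with the seed-and-extend aligner; trivial
#' full-length self-hits and mirror duplicates are removed, and each pair is
#' classified by length.  Circular isoforms are scanned with an
#' origin-extended copy so origin-spanning repeats are recovered; their
#' coordinates are normalized back and intervals with \code{end > length}
#' wrap past the origin.
#'
#' @param genome an \code{organelle_genome}.
#' @param min_len minimum aligned length (bp).
#' @param min_identity minimum percent identity.
#' @param max_evalue expectation-value cutoff.
#' @param k seed length.
#' @param scoring a \code{scoring_scheme}.
#' @return data.frame of repeat pairs: iso_a, start_a, end_a, iso_b,
#'   start_b, end_b, strand, length (aligned columns), identity, evalue,
#'   size_class.  Interval a is the lexicographically smaller
#'   (isoform, start).
#' @export
find_dispersed_repeats <- function(genome, min_len = 20L, min_identity = 95,
                                   max_evalue = 1e-5, k = 13L,
                                   scoring = scoring_scheme()) {
  ids <- names(genome$seq)
  out <- list()
  for (ia in seq_along(ids)) {
    ea <- circular_extend(genome$seq[[ia]], genome$circular[[ia]])
    La <- nchar(genome$seq[[ia]])
    for (ib in ia:length(ids)) {
      eb <- circular_extend(genome$seq[[ib]], genome$circular[[ib]])
      Lb <- nchar(genome$seq[[ib]])
      h <- seed_extend_align(ea$seq, eb$seq, k = k, min_len = min_len,
                             min_identity = min_identity,
                             max_evalue = max_evalue, scoring = scoring,
                             skip_self = (ia == ib),
                             query_id = ids[ia], subject_id = ids[ib])
      if (nrow(h) == 0L) next
      # drop copies living entirely in the circular extension
      h <- h[h$q_start < La & h$s_start < Lb, , drop = FALSE]
      # self pair: drop hits where both intervals are identical (trivial)
      if (ia == ib) {
        h <- h[!(h$q_start == h$s_start & h$q_end == h$s_end &
                   h$strand == "+"), , drop = FALSE]
      }
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L) return(empty_repeat_pairs())
  h <- do.call(rbind, out)
  # canonical order within each pair: smaller (isoform, start) first
  a_first <- (match(h$query_id, ids) < match(h$subject_id, ids)) |
    (h$query_id == h$subject_id &
       (h$q_start < h$s_start |
          (h$q_start == h$s_start & h$q_end <= h$s_end)))
  pairs <- data.frame(
    iso_a = ifelse(a_first, h$query_id, h$subject_id),
    start_a = ifelse(a_first, h$q_start, h$s_start),
    end_a = ifelse(a_first, h$q_end, h$s_end),
    iso_b = ifelse(a_first, h$subject_id, h$query_id),
    start_b = ifelse(a_first, h$s_start, h$q_start),
    end_b = ifelse(a_first, h$s_end, h$q_end),
    strand = h$strand, length = h$length, identity = h$identity,
    evalue = h$evalue, stringsAsFactors = FALSE
  )
  # normalize origin-wrapped duplicate placements and drop mirrors
  key <- sprintf("%s:%d-%d|%s:%d-%d|%s", pairs$iso_a, pairs$start_a,
                 pairs$end_a, pairs$iso_b, pairs$start_b, pairs$end_b,
                 pairs$strand)
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  pairs$size_class <- classify_repeat(pmax(pairs$length, 21L))
  pairs <- pairs[order(pairs$iso_a, pairs$start_a, pairs$iso_b,
                       pairs$start_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

empty_repeat_pairs <- function() {
  data.frame(iso_a = character(), start_a = integer(), end_a = integer(),
             iso_b = character(), start_b = integer(), end_b = integer(),
             strand = character(), length = integer(), identity = numeric(),
             evalue = numeric(), size_class = character(),
             stringsAsFactors = FALSE)
}

# repeat pair table -> one interval row per copy, wrapping split at origin
repeat_pair_intervals <- function(pairs, genome = NULL) {
  iv <- data.frame(
    isoform = c(pairs$iso_a, pairs$iso_b),
    start = c(pairs$start_a, pairs$start_b),
    end = c(pairs$end_a, pairs$end_b), stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    lens <- isoform_lengths(genome)
    L <- lens[iv$isoform]
    wrap <- iv$end > L
    if (any(wrap)) {
      extra <- data.frame(isoform = iv$isoform[wrap], start = 0L,
                          end = iv$end[wrap] - L[wrap],
                          stringsAsFactors = FALSE)
      iv$end[wrap] <- L[wrap]
      iv <- rbind(iv, extra)
    }
  }
  iv
}

#' Non-redundant repeat content of a genome
#'
#' Projects every repeat-pair interval onto the genome, unions overlapping
#' intervals per isoform, and reports the union size in bp and as a fraction
#' of the genome length.
#'
#' @param pairs repeat pairs from \code{\link{find_dispersed_repeats}}.
#' @param genome the \code{organelle_genome} the pairs were detected on.
#' @return list with \code{intervals} (merged, per isoform),
#'   \code{total_bp}, and \code{fraction}.
#' @export
deduplicate_repeat_content <- function(pairs, genome) {
  if (nrow(pairs) == 0L) {
    return(list(intervals = data.frame(isoform = character(),
                                       start = integer(), end = integer()),
                total_bp = 0L, fraction = 0))
  }
  iv <- repeat_pair_intervals(pairs, genome)
  merged <- merge_intervals(iv)
  total <- sum(merged$end - merged$start)
  list(intervals = merged, total_bp = total,
       fraction = total / total_length(genome))
}

# union of [start, end) intervals per isoform via IRanges
merge_intervals <- function(iv, gap = 0L) {
  if (nrow(iv) == 0L) {
    return(data.frame(isoform = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(iv, iv$isoform), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end),
                         min.gapwidth = gap + 1L)
    data.frame(isoform = d$isoform[1], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$isoform, out$start), , drop = FALSE]
}

# lexicographically minimal rotation of a motif
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    rot <- vapply(seq_len(n) - 1L, function(r) {
      paste0(substr(m, r + 1L, n), substr(m, 1L, r))
    }, character(1))
    min(rot)
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if motif is a repetition of a shorter motif
motif_is_periodic <- function(m) {
  n <- nchar(m)
  if (n == 1L) return(FALSE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        strrep(substr(m, 1L, d), n / d) == m) return(TRUE)
  }
  FALSE
}

#' Find simple sequence repeats (microsatellites)
#'
#' Maximal perfect tandem runs of 1-6 bp motifs.  Mononucleotide runs need
#' at least \code{mono_min} copies, longer motifs at least \code{poly_min}.
#' Runs whose motif is itself periodic are reported only at the primitive
#' motif; overlapping candidate loci are resolved in favour of the longer
#' locus.  Only full motif copies count towards the locus, so the locus
#' sequence is exactly \code{motif} repeated \code{count} times.
#'
#' @param genome an \code{organelle_genome} (or a single DNA string).
#' @param mono_min minimum copies for 1-bp motifs.
#' @param poly_min minimum copies for 2-6 bp motifs.
#' @param max_motif maximum motif length (<= 6).
#' @return data.frame: isoform, start, end, motif (as observed), canonical
#'   (lexicographically minimal rotation), motif_len, count.
#' @export
find_ssrs <- function(genome, mono_min = 8L, poly_min = 5L, max_motif = 6L) {
  stopifnot(mono_min > 0, poly_min > 0, max_motif >= 1, max_motif <= 6)
  seqs <- if (inherits(genome, "organelle_genome")) genome$seq
          else stats::setNames(as.character(genome),
                               names(genome) %||%
                                 paste0("seq", seq_along(genome)))
  out <- lapply(names(seqs), function(id) {
    loci <- ssr_scan_one(seqs[[id]], mono_min, poly_min, max_motif)
    if (nrow(loci) > 0L) loci$isoform <- id
    loci
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(isoform = character(), start = integer(),
                      end = integer(), motif = character(),
                      canonical = character(), motif_len = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  out[, c("isoform", "start", "end", "motif", "canonical", "motif_len",
          "count")]
}

ssr_scan_one <- function(seq, mono_min, poly_min, max_motif) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cand <- list()
  for (m in seq_len(min(max_motif, max(0L, n - 1L)))) {
    if (n <= m) break
    eq <- chars[seq_len(n - m)] == chars[(m + 1L):n] &
      chars[seq_len(n - m)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run <- which(r$values)
    thr <- if (m == 1L) mono_min else poly_min
    for (w in run) {
      count <- (r$lengths[w] + m) %/% m
      if (count < thr) next
      p <- starts[w]                       # 1-based start of the run
      motif <- substr(seq, p, p + m - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      if (motif_is_periodic(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = p - 1L, end = p - 1L + count * m, motif = motif,
        motif_len = m, count = count, stringsAsFactors = FALSE
      )
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), canonical = character(),
                      motif_len = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  loci <- do.call(rbind, cand)
  # resolve overlaps: prefer longer loci, then earlier start
  loci <- loci[order(-(loci$end - loci$start), loci$start,
                     loci$motif_len), , drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(loci$start[prior] < loci$end[i] &
              loci$end[prior] > loci$start[i])) keep[i] <- FALSE
  }
  loci <- loci[keep, , drop = FALSE]
  loci$canonical <- canonical_motif(loci$motif)
  loci[order(loci$start), , drop = FALSE]
}

#' Find forward, reverse, complement and palindromic repeats
#'
#' All maximal pairs of equal-length substrings (>= \code{min_len} bp) of a
#' single sequence lying within Hamming distance \code{max_hamming} under
#' the four orientation relations: forward (copy B equals copy A), reverse
#' (B is A reversed), complement (B is A complemented, not reversed), and
#' palindromic (B is the reverse complement of A).  Maximal means not
#' extendable on either side without exceeding the distance budget.  Each
#' unordered copy pair is reported once; pairs whose two copies coincide are
#' dropped.
#'
#' The scan is quadratic in the sequence length (every diagonal of every
#' orientation is walked once), intended for plastome-scale and smaller
#' sequences.
#'
#' @param sequence one DNA string.
#' @param min_len minimum copy length (bp).
#' @param max_hamming Hamming-distance budget.
#' @return data.frame: type, start_a, end_a, start_b, end_b, length,
#'   hamming.
#' @export
find_plastome_repeats <- function(sequence, min_len = 20L, max_hamming = 3L) {
  s <- toupper(sequence)
  n <- nchar(s)
  res <- list()
  add <- function(type, i, j, len, mm) {
    if (length(i) == 0L) return()
    res[[length(res) + 1L]] <<- data.frame(
      type = type, start_a = i, end_a = i + len, start_b = j,
      end_b = j + len, length = len, hamming = mm, stringsAsFactors = FALSE
    )
  }
  # forward: s vs s, j > i
  f <- hamming_pairs_cpp(s, s, min_len, max_hamming, TRUE)
  add("forward", f$i, f$j, f$len, f$mismatches)
  # complement: s vs complement(s), keep i < j (relation is symmetric)
  co <- hamming_pairs_cpp(s, complement_seq(s), min_len, max_hamming, FALSE)
  keep <- co$i < co$j
  add("complement", co$i[keep], co$j[keep], co$len[keep],
      co$mismatches[keep])
  # reverse / palindromic: s vs transformed s, map B back, dedupe mirrors
  for (ty in c("reverse", "palindromic")) {
    t <- if (ty == "reverse") {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    } else revcomp_cpp(s)
    h <- hamming_pairs_cpp(s, t, min_len, max_hamming, FALSE)
    if (nrow(h) == 0L) next
    b_start <- n - h$j - h$len
    a1 <- pmin(h$i, b_start); b1 <- pmax(h$i, b_start)
    ident <- h$i == b_start
    key <- sprintf("%d:%d:%d", a1, b1, h$len)
    keep <- !ident & !duplicated(key)
    add(ty, a1[keep], b1[keep], h$len[keep], h$mismatches[keep])
  }
  if (length(res) == 0L) {
    return(data.frame(type = character(), start_a = integer(),
                      end_a = integer(), start_b = integer(),
                      end_b = integer(), length = integer(),
                      hamming = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$type, out$start_a, out$start_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
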