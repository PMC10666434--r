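#' Alignment scoring scheme
#'
#' Match/mismatch scores, affine gap penalties and the Karlin-Altschul
#' calibration constants used to convert raw scores into expectation values.
#' The defaults are megablast-like (+1/-2, gap open 2, gap extend 1) with the
#' ungapped Karlin-Altschul constants for that matrix (lambda = 1.28,
#' K = 0.46).
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open gap opening penalty (>= 0, applied as a cost).
#' @param gap_extend gap extension penalty (>= 0, per base, applied as a
#'   cost; a gap of length L costs gap_open + L * gap_extend).
#' @param lambda,K Karlin-Altschul calibration constants.
#' @return a \code{scoring_scheme} list.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = 2L,
                           gap_extend = 1L, lambda = 1.28, K = 0.46) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            lambda > 0, K > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Karlin-Altschul expectation value
#'
#' \code{E = K * m * n * exp(-lambda * score)}.  Effective lengths are taken
#' as the raw sequence lengths (no edge correction).
#'
#' @param score alignment raw score.
#' @param m,n (effective) lengths of the two sequences.
#' @param scoring a \code{scoring_scheme}.
#' @return numeric expectation value(s).
#' @export
evalue <- function(score, m, n, scoring = scoring_scheme()) {
  if (any(m <= 0) || any(n <= 0)) stop("non-positive sequence length")
  scoring$K * as.numeric(m) * as.numeric(n) * exp(-scoring$lambda * score)
}

#' Exact Smith-Waterman local alignment (oracle scale)
#'
#' Optimal local alignment with affine gaps by full dynamic programming.
#' Quadratic time and memory: both sequences must be <= 5000 bp.  Used as
#' the validation oracle for the seed-and-extend aligner.
#'
#' @param a,b DNA strings.
#' @param scoring a \code{scoring_scheme}.
#' @return one-row data.frame: q_start, q_end, s_start, s_end (0-based
#'   half-open), score, matches, length (aligned columns), gaps, identity
#'   (percent).  Score 0 (no positive-scoring alignment) gives NA
#'   coordinates.
#' @export
local_align <- function(a, b, scoring = scoring_scheme()) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  if (nchar(a) > 5000L || nchar(b) > 5000L) {
    stop("local_align is the quadratic oracle; sequences must be <= 5000 bp")
  }
  r <- sw_align_cpp(toupper(a), toupper(b), scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_extend)
  data.frame(q_start = r$q_start, q_end = r$q_end, s_start = r$s_start,
             s_end = r$s_end, score = r$score, matches = r$matches,
             length = r$length, gaps = r$gaps,
             identity = if (r$length > 0) 100 * r$matches / r$length
                        else NA_real_)
}

#' Seed-and-extend local alignment
#'
#' BLASTN-like search: exact k-mer seeds against an indexed subject,
#' same-diagonal seed merging, collinear chaining, piecewise gap filling by
#' small exact alignments, and ungapped X-drop end extension.  Both strands
#' of the query are searched; coordinates are always reported on the forward
#' strands with a strand flag.
#'
#' @param query,subject DNA strings (query may be a named character vector).
#' @param k seed length, 9..15.
#' @param min_len minimum aligned length to report.
#' @param min_identity minimum percent identity to report.
#' @param max_evalue expectation-value cutoff.
#' @param scoring a \code{scoring_scheme}.
#' @param both_strands search the reverse complement of the query too.
#' @param skip_self when query and subject are the same sequence, suppress
#'   the trivial full-length self-match.
#' @param query_id,subject_id labels stored in the hit table.
#' @param max_occ k-mers occurring more often than this in the subject are
#'   not used as seeds.
#' @param chain_gap maximum gap bridged within one chain (bp).
#' @param xdrop X-drop threshold for ungapped end extension (a generous
#'   budget lets extension cross local mismatch clusters inside diverged
#'   homologies; the endpoint is still the running score maximum).
#' @return data.frame of hits: query_id, subject_id, strand, q_start, q_end,
#'   s_start, s_end (0-based half-open, forward strands), score, matches,
#'   length, gaps, identity, evalue.
#' @export
seed_extend_align <- function(query, subject, k = 13L, min_len = 20L,
                              min_identity = 0, max_evalue = 1e-5,
                              scoring = scoring_scheme(),
                              both_strands = TRUE, skip_self = FALSE,
                              query_id = NULL, subject_id = "subject",
                              max_occ = 400L, chain_gap = 500L,
                              xdrop = 50L) {
  k <- as.integer(k)
  if (k < 9L || k > 15L) stop("k must be in [9, 15]")
  qv <- if (is.character(query)) query else as.character(query)
  qids <- query_id %||% (names(qv) %||% paste0("q", seq_along(qv)))
  hits <- chain_align_cpp(unname(qv), subject, k, as.integer(max_occ), 30L,
                          as.integer(chain_gap), 120L, k + 2L,
                          as.integer(xdrop), scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend,
                          isTRUE(skip_self), isTRUE(both_strands))
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      strand = character(), q_start = integer(),
                      q_end = integer(), s_start = integer(),
                      s_end = integer(), score = integer(),
                      matches = integer(), length = integer(),
                      gaps = integer(), identity = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  hits$query_id <- qids[hits$query]
  hits$subject_id <- subject_id
  hits$identity <- ifelse(hits$length > 0, 100 * hits$matches / hits$length,
                          0)
  if (min_identity > 0) {
    hits <- trim_hits_to_identity(hits, qv, subject, min_identity, min_len,
                                  scoring)
  }
  hits$evalue <- evalue(hits$score, nchar(qv)[hits$query], nchar(subject),
                        scoring)
  hits <- hits[hits$length >= min_len & hits$identity >= min_identity &
                 hits$evalue <= max_evalue, , drop = FALSE]
  hits <- dedup_contained_hits(hits)
  rownames(hits) <- NULL
  hits[, c("query_id", "subject_id", "strand", "q_start", "q_end",
           "s_start", "s_end", "score", "matches", "length", "gaps",
           "identity", "evalue")]
}

# Decompose a match vector into identity-passing windows: find the longest
# window whose identity is >= pid percent (prefix sums of 100*match - pid;
# a window qualifies iff its prefix-sum difference is >= 0; the longest one
# comes from a prefix-minimum sweep), then recurse on both remainders.
# Returns 1-based inclusive (lo, hi) pairs of length >= min_len.
identity_subsegments <- function(mv, pid, min_len) {
  segs <- list()
  rec <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < min_len) return()
    P <- c(0, cumsum(100 * mv[lo:hi] - pid))
    minP <- cummin(P)
    best_len <- 0L; ba <- 0L; bb <- 0L
    for (b1 in 2:(n + 1L)) {
      if (minP[b1 - 1L] > P[b1]) next
      loi <- 1L; hii <- b1 - 1L
      while (loi < hii) {
        mid <- (loi + hii) %/% 2L
        if (minP[mid] <= P[b1]) hii <- mid else loi <- mid + 1L
      }
      if (b1 - loi > best_len) {
        best_len <- b1 - loi; ba <- loi; bb <- b1 - 1L
      }
    }
    if (best_len < min_len) return()
    segs[[length(segs) + 1L]] <<- c(lo + ba - 1L, lo + bb - 1L)
    rec(lo, lo + ba - 2L)
    rec(lo + bb, hi)
  }
  rec(1L, length(mv))
  segs
}

# Two ways a raw hit can fail the identity threshold although a planted
# homology is present: X-drop extension appends chance-matching background
# to a short hit, and the chainer bridges two same-diagonal homologies (the
# arms of a close inverted repeat are always co-diagonal on the minus
# strand) across a random spacer.  Gapless failing hits are decomposed into
# their maximal identity-passing sub-segments, each reported as its own hit
# "trimmed to aligned columns".
trim_hits_to_identity <- function(hits, qv, subject, min_identity, min_len,
                                  scoring) {
  fail <- which(hits$identity < min_identity & hits$length >= min_len)
  if (length(fail) == 0L) return(hits)
  drop <- rep(FALSE, nrow(hits))
  extra <- list()
  for (i in fail) {
    qseg <- substr(qv[hits$query[i]], hits$q_start[i] + 1L, hits$q_end[i])
    if (hits$strand[i] == "-") qseg <- revcomp_cpp(qseg)
    sseg <- substr(subject, hits$s_start[i] + 1L, hits$s_end[i])
    if (hits$gaps[i] == 0L && nchar(qseg) == nchar(sseg)) {
      qc <- strsplit(qseg, "", fixed = TRUE)[[1]]
      sc <- strsplit(sseg, "", fixed = TRUE)[[1]]
      mv <- qc == sc & qc != "N"
      segs <- identity_subsegments(mv, min_identity, min_len)
      drop[i] <- TRUE
      for (sg in segs) {
        lo <- sg[1L]; hi <- sg[2L]
        len <- hi - lo + 1L
        mt <- sum(mv[lo:hi])
        row <- hits[i, , drop = FALSE]
        if (row$strand == "+") {
          row$q_start <- hits$q_start[i] + lo - 1L
          row$q_end <- row$q_start + len
        } else {
          qe <- hits$q_end[i] - (lo - 1L)
          row$q_start <- qe - len
          row$q_end <- qe
        }
        row$s_start <- hits$s_start[i] + lo - 1L
        row$s_end <- row$s_start + len
        row$length <- len
        row$matches <- mt
        row$score <- mt * scoring$match + (len - mt) * scoring$mismatch
        row$identity <- 100 * mt / len
        extra[[length(extra) + 1L]] <- row
      }
    } else if (nchar(qseg) <= 5000L && nchar(sseg) <= 5000L) {
      # gapped merge (e.g. two co-diagonal homologies bridged across a
      # spacer, which even the exact local alignment keeps joined when the
      # bridge costs less than an arm scores): re-align exactly, then
      # decompose the alignment columns into identity-passing windows and
      # map each window back through the per-column operations
      r <- sw_align_cpp(qseg, sseg, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
      drop[i] <- TRUE
      if (r$score > 0 && r$length >= min_len) {
        ops <- r$ops
        mvo <- ops == 0L
        segs <- identity_subsegments(mvo, min_identity, min_len)
        dq <- c(0L, cumsum(ops != 2L))   # query bases consumed before col
        ds <- c(0L, cumsum(ops != 3L))   # subject bases consumed
        Lq <- nchar(qseg)
        for (sg in segs) {
          lo <- sg[1L]; hi <- sg[2L]
          len <- hi - lo + 1L
          q0 <- r$q_start + dq[lo]; q1 <- r$q_start + dq[hi + 1L]
          s0 <- r$s_start + ds[lo]; s1 <- r$s_start + ds[hi + 1L]
          if (q1 <= q0 || s1 <= s0) next
          mt <- sum(mvo[lo:hi])
          gp <- sum(ops[lo:hi] >= 2L)
          row <- hits[i, , drop = FALSE]
          if (row$strand == "+") {
            row$q_start <- hits$q_start[i] + q0
            row$q_end <- hits$q_start[i] + q1
          } else {
            row$q_start <- hits$q_start[i] + (Lq - q1)
            row$q_end <- hits$q_start[i] + (Lq - q0)
          }
          row$s_start <- hits$s_start[i] + s0
          row$s_end <- hits$s_start[i] + s1
          row$length <- len
          row$matches <- mt
          row$gaps <- gp
          row$score <- mt * scoring$match +
            (len - mt - gp) * scoring$mismatch -
            (scoring$gap_open + scoring$gap_extend) * gp
          row$identity <- 100 * mt / len
          extra[[length(extra) + 1L]] <- row
        }
      }
    }
  }
  out <- rbind(hits[!drop, , drop = FALSE], do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

# drop hits whose query and subject intervals are both contained in a
# higher-scoring kept hit of the same query/strand
dedup_contained_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$score, hits$q_start, hits$s_start)
  hits <- hits[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    prior <- which(keep[seq_len(i - 1L)])
    same <- hits$query[prior] == hits$query[i] &
      hits$strand[prior] == hits$strand[i]
    contained <- same &
      hits$q_start[prior] <= hits$q_start[i] &
      hits$q_end[prior] >= hits$q_end[i] &
      hits$s_start[prior] <= hits$s_start[i] &
      hits$s_end[prior] >= hits$s_end[i]
    if (any(contained)) keep[i] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Adapter for replicating accession-based numbers with hits produced by an
#' external BLASTN run.  Converts 1-based inclusive coordinates (with
#' sstart > send on the minus strand) to the internal 0-based half-open
#' forward-strand convention.
#'
#' @param path tabular file with the standard 12 columns.
#' @return hit data.frame in the same layout as
#'   \code{\link{seed_extend_align}} (score column holds the bit score).
#' @export
read_blast_tab <- function(path) {
  tb <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tb) < 12L) stop("expected 12 outfmt-6 columns")
  names(tb)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  minus <- tb$sstart > tb$send
  s_lo <- ifelse(minus, tb$send, tb$sstart)
  s_hi <- ifelse(minus, tb$sstart, tb$send)
  data.frame(
    query_id = tb$qseqid, subject_id = tb$sseqid,
    strand = ifelse(minus, "-", "+"),
    q_start = tb$qstart - 1L, q_end = tb$qend,
    s_start = s_lo - 1L, s_end = s_hi,
    score = tb$bitscore,
    matches = round(tb$length * tb$pident / 100),
    length = tb$length, gaps = tb$gapopen,
    identity = tb$pident, evalue = tb$evalue,
    stringsAsFactors = FALSE
  )
}

#' Write hits as BLAST tabular (outfmt 6)
#' @param hits hit data.frame from \code{\link{seed_extend_align}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  minus <- hits$strand == "-"
  sstart <- ifelse(minus, hits$s_end, hits$s_start + 1L)
  send <- ifelse(minus, hits$s_start + 1L, hits$s_end)
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
                   hits$query_id, hits$subject_id, hits$identity,
                   as.integer(hits$length),
                   as.integer(hits$length - hits$matches - hits$gaps),
                   as.integer(hits$gaps), hits$q_start + 1L, hits$q_end,
                   as.integer(sstart), as.integer(send), hits$evalue,
                   as.numeric(hits$score))
  writeLines(lines, path)
  invisible(path)
}
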