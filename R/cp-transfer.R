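#' Detect plastid-derived segments (MTPTs) in a mitogenome
#'
#' Each mitochondrial isoform is aligned against the plastome (both
#' strands); hits passing the identity/length/E-value thresholds are merged
#' on the mitochondrial side into maximal segments (strict
#' overlap/adjacency by default, tolerance configurable).  A merged
#' segment's identity is the length-weighted mean of its component hits and
#' its plastome interval is the span of their donor intervals.
#'
#' @param mitogenome,plastome \code{organelle_genome} objects (the plastome
#'   may have several records; the first is used).
#' @param min_identity minimum percent identity (default 80).
#' @param min_len minimum segment length in bp (default 200).
#' @param max_evalue expectation-value cutoff.
#' @param merge_gap bp tolerance for merging adjacent hits (0 = strict).
#' @param k seed length.
#' @param scoring a \code{scoring_scheme}.
#' @return data.frame of class \code{cp_segments}: isoform, start, end,
#'   length, p_start, p_end, strand, identity; attributes \code{total_bp}
#'   and \code{fraction} hold the merged totals.
#' @export
detect_cp_segments <- function(mitogenome, plastome, min_identity = 80,
                               min_len = 200L, max_evalue = 1e-5,
                               merge_gap = 0L, k = 13L,
                               scoring = scoring_scheme()) {
  pseq <- plastome$seq[[1]]
  hits <- seed_extend_align(mitogenome$seq, pseq, k = k,
                            min_len = 30L, min_identity = min_identity,
                            max_evalue = max_evalue, scoring = scoring,
                            query_id = names(mitogenome$seq),
                            subject_id = plastome$name)
  segs <- merge_cp_hits(hits, merge_gap = merge_gap)
  segs <- segs[segs$length > min_len & segs$identity > min_identity, ,
               drop = FALSE]
  rownames(segs) <- NULL
  total <- sum(segs$length)
  structure(segs, total_bp = total,
            fraction = total / total_length(mitogenome),
            class = c("cp_segments", "data.frame"))
}

# merge hit intervals on the mito (query) side; identity length-weighted
merge_cp_hits <- function(hits, merge_gap = 0L) {
  empty <- data.frame(isoform = character(), start = integer(),
                      end = integer(), length = integer(),
                      p_start = integer(), p_end = integer(),
                      strand = character(), identity = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  out <- lapply(split(hits, hits$query_id), function(d) {
    ir <- IRanges::IRanges(start = d$q_start + 1L, end = d$q_end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    grp <- IRanges::findOverlaps(ir, red, select = "first")
    do.call(rbind, lapply(seq_along(red), function(g) {
      comp <- d[grp == g, , drop = FALSE]
      w <- comp$q_end - comp$q_start
      maj <- names(sort(table(comp$strand), decreasing = TRUE))[1]
      data.frame(isoform = comp$query_id[1],
                 start = IRanges::start(red)[g] - 1L,
                 end = IRanges::end(red)[g],
                 length = IRanges::width(red)[g],
                 p_start = min(comp$s_start), p_end = max(comp$s_end),
                 strand = maj,
                 identity = sum(comp$identity * w) / sum(w),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$isoform, out$start), , drop = FALSE]
}

#' Intact plastid genes within plastid-derived segments
#'
#' A plastid gene is intact in a segment iff its full donor interval lies
#' within the segment's plastome interval; genes overlapping a segment edge
#' are listed separately as fragments.
#'
#' @param segments a \code{cp_segments} table.
#' @param plastome_annotations plastid gene features (internal convention).
#' @return data.frame: segment index, isoform, gene, status
#'   ("intact"/"fragment").
#' @export
annotate_intact_genes <- function(segments, plastome_annotations) {
  ann <- plastome_annotations
  out <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    inside <- ann$start >= s$p_start & ann$end <= s$p_end
    partial <- !inside & ann$start < s$p_end & ann$end > s$p_start
    if (!any(inside | partial)) return(NULL)
    data.frame(segment = i, isoform = s$isoform,
               gene = ann$gene[inside | partial],
               status = ifelse(inside[inside | partial], "intact",
                               "fragment"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(segment = integer(), isoform = character(),
                      gene = character(), status = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Length histogram and per-isoform counts of plastid-derived segments
#'
#' @param segments a \code{cp_segments} table.
#' @param genome the mitogenome (fixes the isoform order; isoforms without
#'   segments get zero counts).
#' @param length_breaks inner bin edges; the default reproduces the
#'   200-500 / 501-1000 / 1001-1500 / 1501-3000 / >3000 bp bins.
#' @return list with \code{histogram} (bin, count) and \code{per_isoform}
#'   (isoform, count).
#' @export
segment_summaries <- function(segments, genome,
                              length_breaks = c(200, 500, 1000, 1500,
                                                3000)) {
  br <- c(length_breaks, Inf)
  labs <- character(length(br) - 1)
  for (i in seq_along(labs)) {
    lo <- if (i == 1) br[1] else br[i] + 1
    labs[i] <- if (is.finite(br[i + 1])) paste0(lo, "-", br[i + 1])
               else paste0(">", br[i])
  }
  cnt <- integer(length(labs))
  if (nrow(segments) > 0) {
    idx <- findInterval(segments$length, br[-1] + 1) + 1L
    tab <- table(factor(idx, levels = seq_along(labs)))
    cnt <- as.integer(tab)
  }
  iso <- names(genome$seq)
  per <- data.frame(isoform = iso,
                    count = as.integer(table(factor(segments$isoform,
                                                    levels = iso))),
                    stringsAsFactors = FALSE)
  list(histogram = data.frame(bin = labs, count = cnt,
                              stringsAsFactors = FALSE),
       per_isoform = per)
}

#' Per-bin GC, repeat and plastid-transfer counts on the concatenated genome
#'
#' Isoforms are concatenated, cut into non-overlapping bins of
#' \code{bin_size} bp (a trailing shorter bin is dropped), and each feature
#' increments every bin it overlaps (\code{count_mode = "overlap"}) or only
#' its start bin (\code{"start"}).
#'
#' @param genome an \code{organelle_genome}.
#' @param cp_segments \code{cp_segments} table (columns isoform, start,
#'   end).
#' @param repeat_intervals repeat interval table (columns isoform, start,
#'   end), e.g. \code{deduplicate_repeat_content(...)$intervals} or the raw
#'   pair copies.
#' @param bin_size bin width in bp.
#' @param count_mode "overlap" or "start".
#' @return data.frame: bin, global_start, gc, n_repeat, n_cp.
#' @export
bin_table <- function(genome, cp_segments, repeat_intervals,
                      bin_size = 3000L, count_mode = c("overlap", "start")) {
  count_mode <- match.arg(count_mode)
  cc <- concatenate_isoforms(genome)
  n_bins <- nchar(cc$sequence) %/% bin_size
  if (n_bins < 1L) stop("genome shorter than one bin")
  starts <- (seq_len(n_bins) - 1L) * bin_size
  gc <- vapply(starts, function(s) {
    gc_content(substr(cc$sequence, s + 1L, s + bin_size))
  }, numeric(1))
  off <- stats::setNames(cc$offsets$offset, cc$offsets$isoform)
  count_feats <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(integer(n_bins))
    gs <- off[iv$isoform] + iv$start
    ge <- off[iv$isoform] + iv$end
    if (count_mode == "start") { ge <- gs + 1L }
    q <- IRanges::IRanges(start = gs + 1L, end = ge)
    b <- IRanges::IRanges(start = starts + 1L, end = starts + bin_size)
    IRanges::countOverlaps(b, q)
  }
  data.frame(bin = seq_len(n_bins), global_start = starts, gc = gc,
             n_repeat = count_feats(repeat_intervals),
             n_cp = count_feats(cp_segments))
}

#' Correlation of plastid-derived content with GC and repeat density
#'
#' Pearson correlation (two-sided) of per-bin transfer counts against
#' per-bin GC and repeat counts.  Bin tables from several genomes may be
#' pooled by passing them pre-bound, or by giving lists of genomes and
#' feature tables.
#'
#' @param genome an \code{organelle_genome}, a list of them, or a
#'   ready-made bin table (data.frame with gc, n_repeat, n_cp).
#' @param cp_segments,repeat_intervals feature tables (or lists parallel to
#'   \code{genome}).
#' @param bin_size,count_mode see \code{\link{bin_table}}.
#' @return list of class \code{cp_correlation}: r_cp_gc, r_cp_repeat,
#'   p_cp_gc, p_cp_repeat, n_bins, and the pooled \code{bins} table.
#'   Zero variance in a variable gives r = NA with a diagnostic message.
#' @export
binned_feature_correlation <- function(genome, cp_segments = NULL,
                                       repeat_intervals = NULL,
                                       bin_size = 3000L,
                                       count_mode = "overlap") {
  bins <- if (is.data.frame(genome)) {
    genome
  } else if (inherits(genome, "organelle_genome")) {
    bin_table(genome, cp_segments, repeat_intervals, bin_size, count_mode)
  } else {
    do.call(rbind, lapply(seq_along(genome), function(i) {
      bin_table(genome[[i]], cp_segments[[i]], repeat_intervals[[i]],
                bin_size, count_mode)
    }))
  }
  if (nrow(bins) < 3L) stop("need at least 3 bins for a correlation")
  cor_pair <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      message("zero variance; correlation undefined")
      return(list(r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  g <- cor_pair(bins$n_cp, bins$gc)
  r <- cor_pair(bins$n_cp, bins$n_repeat)
  structure(list(r_cp_gc = g$r, p_cp_gc = g$p, r_cp_repeat = r$r,
                 p_cp_repeat = r$p, n_bins = nrow(bins), bins = bins),
            class = "cp_correlation")
}

#' @export
print.cp_correlation <- function(x, ...) {
  cat("Binned correlation over", x$n_bins, "bins\n")
  cat(sprintf("  cp-derived vs GC:      r = %.3f (p = %.3g)\n",
              x$r_cp_gc, x$p_cp_gc))
  cat(sprintf("  cp-derived vs repeats: r = %.3f (p = %.3g)\n",
              x$r_cp_repeat, x$p_cp_repeat))
  invisible(x)
}
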