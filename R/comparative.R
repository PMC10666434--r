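#' Inter-genome sequence similarity
#'
#' All hits of genome A against genome B below the E-value cutoff are
#' projected onto each genome; overlapping hit intervals are merged
#' (redundancy exclusion) so no base is counted twice.  The shared fraction
#' of A is the merged coverage divided by the length of A, and symmetrically
#' for B; the two fractions differ when the genome sizes differ.
#'
#' @param genome_a,genome_b \code{organelle_genome} objects.
#' @param max_evalue expectation-value cutoff.
#' @param min_len minimum hit length considered.
#' @param k seed length.
#' @param scoring a \code{scoring_scheme}.
#' @return one-row data.frame: genome_a, genome_b, covered_bp_a,
#'   fraction_a, covered_bp_b, fraction_b.
#' @export
pairwise_similarity <- function(genome_a, genome_b, max_evalue = 1e-5,
                                min_len = 50L, k = 13L,
                                scoring = scoring_scheme()) {
  ca <- concatenate_isoforms(genome_a)
  cb <- concatenate_isoforms(genome_b)
  hits <- seed_extend_align(ca$sequence, cb$sequence, k = k,
                            min_len = min_len, min_identity = 0,
                            max_evalue = max_evalue, scoring = scoring,
                            query_id = genome_a$name,
                            subject_id = genome_b$name)
  la <- total_length(genome_a)
  lb <- total_length(genome_b)
  cov <- function(starts, ends, L) {
    if (length(starts) == 0L) return(0L)
    r <- IRanges::reduce(IRanges::IRanges(start = starts + 1L,
                                          end = pmin(ends, L)))
    sum(IRanges::width(r))
  }
  cba <- cov(hits$q_start, hits$q_end, la)
  cbb <- cov(hits$s_start, hits$s_end, lb)
  data.frame(genome_a = genome_a$name, genome_b = genome_b$name,
             covered_bp_a = cba, fraction_a = cba / la,
             covered_bp_b = cbb, fraction_b = cbb / lb,
             stringsAsFactors = FALSE)
}

#' Gene clusters: maximal runs of adjacent genes
#'
#' Genes are taken in annotation order per isoform; consecutive genes whose
#' intergenic gap is at most \code{max_gap} belong to one cluster.  Runs of
#' fewer than \code{min_genes} genes (singletons by default) are excluded.
#' Without a gap cap, pure adjacency would chain entire isoforms.
#'
#' @param annotations feature data.frame (internal convention).
#' @param min_genes minimum genes per cluster.
#' @param max_gap maximum intergenic gap in bp.
#' @return list of \code{gene_cluster} lists: genes (ordered names),
#'   isoform, strands, start, end.
#' @export
gene_clusters <- function(annotations, min_genes = 2L, max_gap = 5000L) {
  ann <- annotations[order(annotations$isoform, annotations$start), ,
                     drop = FALSE]
  out <- list()
  for (iso in unique(ann$isoform)) {
    d <- ann[ann$isoform == iso, , drop = FALSE]
    if (nrow(d) == 0L) next
    gap_ok <- c(FALSE, d$start[-1] - d$end[-nrow(d)] <= max_gap)
    grp <- cumsum(!gap_ok)
    for (g in split(seq_len(nrow(d)), grp)) {
      if (length(g) < min_genes) next
      out[[length(out) + 1L]] <- structure(
        list(genes = d$gene[g], isoform = iso, strands = d$strand[g],
             start = d$start[g[1]], end = d$end[g[length(g)]]),
        class = "gene_cluster")
    }
  }
  out
}

#' Gene clusters shared between two genomes
#'
#' A cluster of A matches a cluster of B iff the ordered gene-name lists
#' are identical or exactly reversed (orientation-insensitive).  Each
#' cluster is matched at most once.
#'
#' @param clusters_a,clusters_b cluster lists from
#'   \code{\link{gene_clusters}}.
#' @return data.frame of matched clusters: genes (collapsed with "-"),
#'   isoform_a, isoform_b, reversed.
#' @export
shared_clusters <- function(clusters_a, clusters_b) {
  used <- logical(length(clusters_b))
  rows <- list()
  for (ca in clusters_a) {
    for (j in seq_along(clusters_b)) {
      if (used[j]) next
      gb <- clusters_b[[j]]$genes
      if (identical(ca$genes, gb)) {
        rows[[length(rows) + 1L]] <- data.frame(
          genes = paste(ca$genes, collapse = "-"),
          isoform_a = ca$isoform, isoform_b = clusters_b[[j]]$isoform,
          reversed = FALSE, stringsAsFactors = FALSE)
        used[j] <- TRUE
        break
      }
      if (identical(ca$genes, rev(gb))) {
        rows[[length(rows) + 1L]] <- data.frame(
          genes = paste(ca$genes, collapse = "-"),
          isoform_a = ca$isoform, isoform_b = clusters_b[[j]]$isoform,
          reversed = TRUE, stringsAsFactors = FALSE)
        used[j] <- TRUE
        break
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(genes = character(), isoform_a = character(),
                      isoform_b = character(), reversed = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Relative synonymous codon usage (RSCU)
#'
#' \code{rscu(c) = count(c) * k / sum(counts)} over the \code{k} synonymous
#' codons of c's amino acid; uniform usage gives 1 for every codon.  Stop
#' codons are excluded by default.  Duplicate gene copies (identical names)
#' are counted once by default.  CDS with an internal in-frame stop are
#' skipped with a warning.
#'
#' @param cds_sequences named character vector of CDS (length divisible by
#'   3, start to stop).
#' @param dedupe_genes count each distinct gene name once.
#' @param include_stops include stop codons as a 3-codon family.
#' @return data.frame of class \code{rscu_table}: codon, amino_acid, count,
#'   rscu (NA for amino acids with zero total).
#' @export
rscu <- function(cds_sequences, dedupe_genes = TRUE,
                 include_stops = FALSE) {
  code <- Biostrings::GENETIC_CODE
  if (dedupe_genes && !is.null(names(cds_sequences))) {
    cds_sequences <- cds_sequences[!duplicated(names(cds_sequences))]
  }
  counts <- stats::setNames(integer(length(code)), names(code))
  for (gi in seq_along(cds_sequences)) {
    s <- toupper(cds_sequences[[gi]])
    n <- nchar(s)
    if (n %% 3 != 0) {
      warning("CDS ", names(cds_sequences)[gi] %||% gi,
              " length not divisible by 3; skipped")
      next
    }
    cods <- substring(s, seq(1, n, 3), seq(3, n, 3))
    aa <- code[cods]
    internal_stop <- which(aa == "*")
    internal_stop <- internal_stop[internal_stop < length(cods)]
    if (length(internal_stop) > 0) {
      warning("CDS ", names(cds_sequences)[gi] %||% gi,
              " has an internal stop codon; skipped")
      next
    }
    tb <- table(cods[!is.na(aa)])
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  if (!include_stops) {
    counts <- counts[code[names(counts)] != "*"]
  }
  aa <- code[names(counts)]
  fam_tot <- tapply(counts, aa, sum)[aa]
  fam_k <- table(aa)[aa]
  val <- ifelse(fam_tot > 0, counts * as.numeric(fam_k) / fam_tot,
                NA_real_)
  structure(data.frame(codon = names(counts), amino_acid = unname(aa),
                       count = unname(counts), rscu = unname(val),
                       stringsAsFactors = FALSE),
            class = c("rscu_table", "data.frame"))
}

#' Start and stop codons of annotated CDS
#'
#' Tabulates the first and last codon of each CDS and flags non-canonical
#' starts (not ATG) and stops (not TAA/TAG/TGA).
#'
#' @param cds_sequences named character vector of CDS.
#' @return data.frame: gene, start_codon, stop_codon, canonical_start,
#'   canonical_stop.
#' @export
codon_boundary_summary <- function(cds_sequences) {
  nm <- names(cds_sequences) %||% paste0("cds", seq_along(cds_sequences))
  s <- toupper(cds_sequences)
  n <- nchar(s)
  start <- substr(s, 1L, 3L)
  stop_ <- substr(s, n - 2L, n)
  data.frame(gene = nm, start_codon = start, stop_codon = stop_,
             canonical_start = start == "ATG",
             canonical_stop = stop_ %in% c("TAA", "TAG", "TGA"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Identify open reading frames
#'
#' Scans all six frames of every isoform for ATG-to-stop spans without
#' internal in-frame stops, longer than \code{min_len} bp (stop codon
#' included).  Only the longest ORF per stop codon and frame is reported.
#' Coordinates are on the forward strand in the internal convention.
#'
#' @param genome an \code{organelle_genome} (or a single DNA string).
#' @param min_len minimum ORF length in bp (exclusive bound).
#' @return data.frame: isoform, start, end, strand, frame, length.
#' @export
find_orfs <- function(genome, min_len = 300L) {
  seqs <- if (inherits(genome, "organelle_genome")) genome$seq
          else stats::setNames(as.character(genome),
                               names(genome) %||%
                                 paste0("seq", seq_along(genome)))
  out <- list()
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[id]] else revcomp_cpp(seqs[[id]])
      for (fr in 0:2) {
        n_cod <- (nchar(s) - fr) %/% 3
        if (n_cod < 2) next
        cods <- substring(s, fr + seq(1, by = 3, length.out = n_cod),
                          fr + seq(3, by = 3, length.out = n_cod))
        is_stop <- cods %in% c("TAA", "TAG", "TGA")
        is_atg <- cods == "ATG"
        prev_stop <- 0L
        for (st in which(is_stop)) {
          if (st - prev_stop < 2L) { prev_stop <- st; next }
          atg <- which(is_atg[(prev_stop + 1L):(st - 1L)])
          if (length(atg) > 0L) {
            a <- prev_stop + atg[1L]      # longest ORF for this stop
            start0 <- fr + (a - 1L) * 3L  # 0-based on strand s
            end0 <- fr + st * 3L
            if (end0 - start0 > min_len) {
              if (strand == "+") {
                fs <- start0; fe <- end0
              } else {
                fs <- L - end0; fe <- L - start0
              }
              out[[length(out) + 1L]] <- data.frame(
                isoform = id, start = fs, end = fe, strand = strand,
                frame = fr, length = end0 - start0,
                stringsAsFactors = FALSE)
            }
          }
          prev_stop <- st
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(isoform = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$isoform, res$start), , drop = FALSE]
}
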