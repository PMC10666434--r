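#' Multi-isoform organelle genome container
#'
#' A plant mitogenome (or plastome) is represented as an ordered set of named
#' isoform sequences, each with a circularity flag.  Sequences are stored
#' linearized as deposited; circularity is honoured by the operations that
#' need it (repeat detection, flank extraction).  All internal coordinates are
#' 0-based half-open on the forward strand.
#'
#' @param name genome label.
#' @param sequences named character vector of DNA sequences over
#'   \code{A,C,G,T,N}.
#' @param circular logical scalar or vector (recycled) of circularity flags.
#' @return an object of class \code{organelle_genome}.
#' @export
organelle_genome <- function(name, sequences, circular = FALSE) {
  if (length(sequences) < 1L) stop("a genome needs at least one isoform")
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every isoform needs a name")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate isoform ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(sequences) == 0L)) stop("empty isoform sequence")
  circular <- rep_len(as.logical(circular), length(sequences))
  names(circular) <- ids
  structure(list(name = name, seq = sequences, circular = circular),
            class = "organelle_genome")
}

#' @export
print.organelle_genome <- function(x, ...) {
  cat("<organelle_genome> ", x$name, "\n", sep = "")
  cat("  isoforms: ", length(x$seq), ",  total length: ",
      total_length(x), " bp\n", sep = "")
  st <- genome_stats(x)
  print(utils::head(st, 10), row.names = FALSE)
  if (nrow(st) > 10) cat("  ... ", nrow(st) - 10, " more\n", sep = "")
  invisible(x)
}

#' Total genome length in bp
#' @param genome an \code{organelle_genome}.
#' @return integer total length.
#' @export
total_length <- function(genome) {
  sum(isoform_lengths(genome))
}

#' Per-isoform lengths
#' @param genome an \code{organelle_genome}.
#' @return named integer vector of isoform lengths.
#' @export
isoform_lengths <- function(genome) {
  vapply(genome$seq, nchar, integer(1))
}

#' Per-isoform length, GC and circularity table
#' @param genome an \code{organelle_genome}.
#' @return data.frame with columns isoform, length, gc, circular.
#' @export
genome_stats <- function(genome) {
  data.frame(
    isoform = names(genome$seq),
    length = unname(isoform_lengths(genome)),
    gc = unname(vapply(genome$seq, gc_content, numeric(1))),
    circular = unname(genome$circular),
    stringsAsFactors = FALSE
  )
}

#' Read a multi-record FASTA file as an organelle genome
#'
#' One isoform per record, order preserved.  Characters outside
#' \code{A,C,G,T,N} are rejected in strict mode (the default) or normalized
#' to \code{N}.
#'
#' @param path FASTA file.
#' @param name genome label (default: file name without extension).
#' @param circular circularity flag(s), recycled across isoforms.
#' @param normalize_ambiguous convert IUPAC ambiguity codes to N instead of
#'   erroring.
#' @return an \code{organelle_genome}.
#' @export
read_fasta <- function(path, name = NULL, circular = FALSE,
                       normalize_ambiguous = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(ss)
  names(seqs) <- ids
  seqs <- vapply(ids, function(i) {
    normalize_dna(seqs[[i]], normalize_ambiguous, id = i)
  }, character(1))
  organelle_genome(name %||% sub("\\.[^.]*$", "", basename(path)),
                   seqs, circular)
}

#' Write an organelle genome as multi-record FASTA
#' @param genome an \code{organelle_genome}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read gene annotations from GFF3 or a feature TSV
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention.  The TSV format is 5 columns (gene, isoform, start,
#' end, strand), already in the internal convention.
#'
#' @param path annotation file.
#' @param format \code{"gff3"} or \code{"tsv"}.
#' @param genome optional \code{organelle_genome}; if given, features are
#'   validated against its isoform ids and lengths.
#' @return data.frame with columns gene, isoform, start, end, strand, kind,
#'   sorted by (isoform, start).
#' @export
read_annotations <- function(path, format = c("gff3", "tsv"), genome = NULL) {
  format <- match.arg(format)
  if (format == "gff3") {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(body) == 0L) {
      feats <- empty_features()
    } else {
      g <- rtracklayer::readGFF(path)
      g <- as.data.frame(g, stringsAsFactors = FALSE)
      keep <- g$type %in% c("gene", "CDS", "tRNA", "rRNA", "ORF", "orf")
      g <- g[keep, , drop = FALSE]
      kind <- c(gene = "protein_coding", CDS = "protein_coding",
                tRNA = "tRNA", rRNA = "rRNA", ORF = "orf",
                orf = "orf")[as.character(g$type)]
      nm <- g$Name
      if (is.null(nm)) nm <- rep(NA_character_, nrow(g))
      if ("gene" %in% names(g)) nm <- ifelse(is.na(nm), g$gene, nm)
      if ("ID" %in% names(g)) nm <- ifelse(is.na(nm), g$ID, nm)
      feats <- data.frame(
        gene = as.character(nm), isoform = as.character(g$seqid),
        start = as.integer(g$start) - 1L, end = as.integer(g$end),
        strand = as.character(g$strand), kind = unname(kind),
        stringsAsFactors = FALSE
      )
    }
  } else {
    tb <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (ncol(tb) < 5L) stop("feature TSV needs 5 columns: ",
                            "gene, isoform, start, end, strand")
    feats <- data.frame(
      gene = as.character(tb[[1]]), isoform = as.character(tb[[2]]),
      start = as.integer(tb[[3]]), end = as.integer(tb[[4]]),
      strand = as.character(tb[[5]]),
      kind = if (ncol(tb) >= 6) as.character(tb[[6]]) else "protein_coding",
      stringsAsFactors = FALSE
    )
  }
  validate_features(feats, genome)
}

empty_features <- function() {
  data.frame(gene = character(), isoform = character(), start = integer(),
             end = integer(), strand = character(), kind = character(),
             stringsAsFactors = FALSE)
}

validate_features <- function(feats, genome = NULL) {
  if (nrow(feats) == 0L) return(feats)
  bad <- feats$end <= feats$start
  if (any(bad)) {
    stop("feature(s) with end <= start: ",
         paste(feats$gene[bad], collapse = ", "))
  }
  if (any(feats$start < 0L)) stop("negative feature start")
  if (!is.null(genome)) {
    lens <- isoform_lengths(genome)
    unknown <- setdiff(unique(feats$isoform), names(lens))
    if (length(unknown) > 0L) {
      stop("features reference unknown isoform(s): ",
           paste(unknown, collapse = ", "))
    }
    over <- feats$end > lens[feats$isoform]
    if (any(over)) {
      stop("feature(s) extend past isoform end: ",
           paste(feats$gene[over], collapse = ", "))
    }
  }
  feats[order(feats$isoform, feats$start, method = "radix"), , drop = FALSE]
}

#' Write gene features as GFF3
#' @param features feature data.frame (internal convention).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_annotations_gff3 <- function(features, path) {
  type <- c(protein_coding = "gene", tRNA = "tRNA", rRNA = "rRNA",
            orf = "ORF")[features$kind]
  type[is.na(type)] <- "gene"
  lines <- c("##gff-version 3",
             sprintf("%s\tmitokit\t%s\t%d\t%d\t.\t%s\t.\tName=%s",
                     features$isoform, type, features$start + 1L,
                     features$end, features$strand, features$gene))
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#' @param intervals data.frame with columns isoform, start, end and
#'   optionally name.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(intervals, path) {
  nm <- if ("name" %in% names(intervals)) intervals$name else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$isoform,
                     intervals$start, intervals$end, nm), path)
  invisible(path)
}

#' Concatenate isoforms into one sequence with an offset map
#'
#' Isoforms are joined in order with no separator.  The offset map supports
#' unique inverse mapping from any global coordinate back to
#' (isoform, local coordinate).
#'
#' @param genome an \code{organelle_genome}.
#' @return list with elements \code{sequence} (one string) and
#'   \code{offsets} (data.frame isoform, offset, length).
#' @export
concatenate_isoforms <- function(genome) {
  lens <- isoform_lengths(genome)
  offs <- cumsum(c(0L, unname(lens)))[seq_along(lens)]
  list(
    sequence = paste(genome$seq, collapse = ""),
    offsets = data.frame(isoform = names(lens), offset = offs,
                         length = unname(lens), stringsAsFactors = FALSE)
  )
}

#' Map global (concatenated) coordinates back to isoform coordinates
#' @param offsets offset map from \code{concatenate_isoforms}.
#' @param pos integer vector of global 0-based positions.
#' @return data.frame with columns isoform, local.
#' @export
global_to_local <- function(offsets, pos) {
  tot <- offsets$offset[nrow(offsets)] + offsets$length[nrow(offsets)]
  if (any(pos < 0L | pos >= tot)) stop("global position out of range")
  idx <- findInterval(pos, offsets$offset)
  data.frame(isoform = offsets$isoform[idx],
             local = pos - offsets$offset[idx], stringsAsFactors = FALSE)
}

#' GC content of a DNA string
#'
#' Computed as (G + C) / (A + C + G + T); N and other characters are excluded
#' from the denominator.  Returns \code{NA} when no unambiguous base is
#' present.
#'
#' @param seq one DNA string.
#' @return fraction in [0, 1], or NA.
#' @export
gc_content <- function(seq) {
  if (nchar(seq) == 0L) stop("empty sequence")
  cnt <- base_counts(seq)
  den <- sum(cnt[c("A", "C", "G", "T")])
  if (den == 0L) return(NA_real_)
  sum(cnt[c("G", "C")]) / den
}

#' GC content in non-overlapping windows
#'
#' @param seq one DNA string.
#' @param window window size in bp; a trailing partial window is kept and
#'   flagged.
#' @return data.frame with columns start, end, gc (NA for all-N windows),
#'   partial.
#' @export
gc_content_windows <- function(seq, window) {
  n <- nchar(seq)
  starts <- seq.int(0L, n - 1L, by = window)
  ends <- pmin(starts + window, n)
  gc <- vapply(seq_along(starts), function(i) {
    gc_content(substr(seq, starts[i] + 1L, ends[i]))
  }, numeric(1))
  data.frame(start = starts, end = ends, gc = gc,
             partial = (ends - starts) < window)
}
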