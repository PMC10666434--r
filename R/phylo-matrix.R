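#' Aligned locus block
#'
#' A multiple sequence alignment for one locus: equal-length rows over
#' \code{A,C,G,T,N,-} with unique taxon names.
#'
#' @param locus_id locus label.
#' @param rows named character vector of aligned sequences.
#' @return an \code{msa_block}.
#' @export
msa_block <- function(locus_id, rows) {
  if (length(rows) < 1L) stop("empty alignment block")
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    stop("rows need unique taxon names")
  }
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("rows of unequal length in locus ", locus_id)
  bad <- grepl("[^ACGTN-]", rows)
  if (any(bad)) {
    stop("characters outside {A,C,G,T,N,-} in taxa: ",
         paste(names(rows)[bad], collapse = ", "))
  }
  structure(list(locus_id = locus_id, rows = rows, width = w),
            class = "msa_block")
}

#' Read one aligned FASTA file as an msa_block
#' @param path aligned FASTA.
#' @param locus_id locus label (default: file name).
#' @return an \code{msa_block}.
#' @export
read_msa_fasta <- function(path, locus_id = NULL) {
  ss <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  msa_block(locus_id %||% sub("\\.[^.]*$", "", basename(path)), rows)
}

#' Remove plastid-derived segments from a mitogenome
#'
#' Excises every (merged) cp-derived interval from its isoform and
#' re-derives coordinates, so downstream alignments are free of foreign
#' sequence.  The removed total equals the merged segment total, and an
#' old-to-new coordinate map for the retained blocks is returned.
#'
#' @param genome an \code{organelle_genome}.
#' @param cp_segments segments table (columns isoform, start, end).
#' @return list: \code{genome} (masked), \code{map} (isoform, old_start,
#'   old_end, new_start), \code{removed_bp}.
#' @export
mask_cp_derived <- function(genome, cp_segments) {
  lens <- isoform_lengths(genome)
  if (!is.null(cp_segments) && nrow(cp_segments) > 0) {
    unknown <- setdiff(unique(cp_segments$isoform), names(lens))
    if (length(unknown) > 0) {
      stop("segments on unknown isoform(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(cp_segments$end > lens[cp_segments$isoform]) ||
        any(cp_segments$start < 0)) {
      stop("segment outside its isoform")
    }
  }
  merged <- if (is.null(cp_segments) || nrow(cp_segments) == 0L) {
    data.frame(isoform = character(), start = integer(), end = integer())
  } else {
    merge_intervals(as.data.frame(cp_segments)[, c("isoform", "start",
                                                   "end")])
  }
  seqs <- genome$seq
  map <- list()
  removed <- 0L
  for (iso in names(seqs)) {
    mi <- merged[merged$isoform == iso, , drop = FALSE]
    if (nrow(mi) == 0L) {
      map[[iso]] <- data.frame(isoform = iso, old_start = 0L,
                               old_end = lens[[iso]], new_start = 0L,
                               stringsAsFactors = FALSE)
      next
    }
    keep_start <- c(0L, mi$end)
    keep_end <- c(mi$start, lens[[iso]])
    w <- keep_end > keep_start
    keep_start <- keep_start[w]; keep_end <- keep_end[w]
    pieces <- substring(seqs[[iso]], keep_start + 1L, keep_end)
    removed <- removed + sum(mi$end - mi$start)
    seqs[[iso]] <- paste(pieces, collapse = "")
    if (length(keep_start) > 0L) {
      new_start <- cumsum(c(0L, (keep_end - keep_start)[-length(keep_start)]))
      map[[iso]] <- data.frame(isoform = iso, old_start = keep_start,
                               old_end = keep_end, new_start = new_start,
                               stringsAsFactors = FALSE)
    }
  }
  seqs <- seqs[nchar(seqs) > 0L]
  masked <- organelle_genome(paste0(genome$name, "_cpmasked"), seqs,
                             genome$circular[names(seqs)])
  list(genome = masked, map = do.call(rbind, unname(map)),
       removed_bp = removed)
}

#' Remove alignment columns with excess missing data
#'
#' Missing data per column is the fraction of gap (\code{-}) plus \code{N}
#' characters; columns strictly above \code{max_missing} are removed, row
#' order preserved.  The operation is idempotent.
#'
#' @param msa an \code{msa_block}.
#' @param max_missing maximum tolerated missing fraction per column.
#' @return filtered \code{msa_block} (empty blocks yield a warning).
#' @export
filter_columns <- function(msa, max_missing = 0.5) {
  m <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  miss <- colMeans(m == "-" | m == "N")
  keep <- miss <= max_missing
  if (!any(keep)) {
    warning("all columns removed from locus ", msa$locus_id)
    rows <- stats::setNames(rep("", nrow(m)), names(msa$rows))
    out <- structure(list(locus_id = msa$locus_id, rows = rows,
                          width = 0L), class = "msa_block")
    return(out)
  }
  rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  msa_block(msa$locus_id, stats::setNames(rows, names(msa$rows)))
}

#' Overall missing-data fraction of a block
#' @param msa an \code{msa_block}.
#' @return fraction of gap + N characters over all cells.
#' @export
block_missing_fraction <- function(msa) {
  ch <- paste(msa$rows, collapse = "")
  cnt <- base_counts(ch)
  (nchar(ch) - sum(cnt[c("A", "C", "G", "T")])) / nchar(ch)
}

#' Concatenate locus alignments into a supermatrix
#'
#' Blocks are concatenated in the given order; taxa missing from a block
#' are filled with all-gap rows.  The partition map records each locus'
#' column range (0-based half-open) and tiles the matrix exactly.
#'
#' @param blocks list of \code{msa_block}s (unique locus ids).
#' @param taxa_order character vector of taxa; defaults to the union in
#'   first-appearance order.
#' @return a \code{supermatrix}: taxa, rows (named character vector),
#'   partitions (locus, start, end).
#' @export
build_supermatrix <- function(blocks, taxa_order = NULL) {
  ids <- vapply(blocks, function(b) b$locus_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate locus ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  taxa <- taxa_order %||%
    unique(unlist(lapply(blocks, function(b) names(b$rows))))
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- data.frame(locus = ids, start = NA_integer_,
                      end = NA_integer_, stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    extra <- setdiff(names(b$rows), taxa)
    if (length(extra) > 0) {
      stop("block ", b$locus_id, " has taxa outside taxa_order: ",
           paste(extra, collapse = ", "))
    }
    fill <- strrep("-", b$width)
    add <- vapply(taxa, function(tx) {
      if (tx %in% names(b$rows)) b$rows[[tx]] else fill
    }, character(1))
    rows <- paste0(rows, add)
    names(rows) <- taxa
    parts$start[i] <- pos
    parts$end[i] <- pos + b$width
    pos <- pos + b$width
  }
  structure(list(taxa = taxa, rows = rows, partitions = parts,
                 width = pos), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$taxa), " taxa x ", x$width,
      " columns, ", nrow(x$partitions), " partitions\n", sep = "")
  invisible(x)
}

#' Write a supermatrix as FASTA
#' @param sm a \code{supermatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in sm$taxa) {
    writeLines(c(paste0(">", tx), sm$rows[[tx]]), con)
  }
  invisible(path)
}

#' Read a supermatrix written as FASTA
#' @param path FASTA file.
#' @param partitions optional partition table to reattach.
#' @return a \code{supermatrix} (single partition when none supplied).
#' @export
read_supermatrix_fasta <- function(path, partitions = NULL) {
  ss <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("rows of unequal length")
  structure(list(taxa = names(rows), rows = rows,
                 partitions = partitions %||%
                   data.frame(locus = "all", start = 0L, end = w,
                              stringsAsFactors = FALSE),
                 width = w), class = "supermatrix")
}

#' Write a supermatrix as relaxed PHYLIP
#' @param sm a \code{supermatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_supermatrix_phylip <- function(sm, path) {
  lines <- c(paste(length(sm$taxa), sm$width),
             paste(sm$taxa, sm$rows[sm$taxa]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a supermatrix as NEXUS with a partition (charset) block
#' @param sm a \code{supermatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_supermatrix_nexus <- function(sm, path) {
  lines <- c(
    "#NEXUS", "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa), sm$width),
    "  FORMAT DATATYPE=DNA MISSING=N GAP=-;",
    "  MATRIX",
    sprintf("    %s %s", sm$taxa, sm$rows[sm$taxa]),
    "  ;", "END;", "BEGIN SETS;",
    sprintf("  CHARSET %s = %d-%d;", sm$partitions$locus,
            sm$partitions$start + 1L, sm$partitions$end),
    "END;"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Robinson-Foulds distance between two trees
#'
#' Convenience wrapper for comparing inferred topologies: reads newick
#' (file or string) and returns the unrooted Robinson-Foulds distance.
#'
#' @param tree_a,tree_b newick strings, file paths, or \code{phylo}
#'   objects.
#' @return integer RF distance.
#' @export
rf_distance <- function(tree_a, tree_b) {
  as_tree <- function(x) {
    if (inherits(x, "phylo")) return(x)
    if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  }
  phangorn::RF.dist(as_tree(tree_a), as_tree(tree_b))
}
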