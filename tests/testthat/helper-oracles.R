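# Independent oracle implementations used to validate the package's
# primitives.  These deliberately use different mechanics (full matrices,
# naive scans, two-pass formulas) from the implementation under test.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# plant a mutated copy of src inside a background string at position pos
# (1-based); substitutions only
mutate_seq <- function(seq, n_mut) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (n_mut > 0) {
    pos <- sample(length(ch), n_mut)
    bases <- c("A", "C", "G", "T")
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

# --- quadratic affine-gap Smith-Waterman score, full-matrix formulation ---
sw_score_oracle <- function(a, b, match = 1, mismatch = -2, go = 2,
                            ge = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A); n <- length(B)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  FF <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      FF[i, j] <- max(H[i - 1, j] - go - ge, FF[i - 1, j] - ge)
      sc <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], FF[i, j])
    }
  }
  max(H)
}

# --- naive SSR scanner: per-position extension with while loops ----------
ssr_oracle <- function(seq, mono_min = 8, poly_min = 5, max_motif = 6) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cand <- list()
  for (m in seq_len(max_motif)) {
    i <- 1L
    while (i + m <= n) {
      # run must be maximal on the left
      if (i > m && ch[i - 1] == ch[i - 1 + m] && ch[i - 1] != "N") {
        i <- i + 1L
        next
      }
      j <- i
      while (j + m <= n && ch[j] == ch[j + m] && ch[j] != "N") j <- j + 1L
      r <- j - i                      # equalities
      count <- (r + m) %/% m
      thr <- if (m == 1) mono_min else poly_min
      motif <- paste(ch[i:(i + m - 1)], collapse = "")
      ok <- count >= thr && !grepl("N", motif, fixed = TRUE)
      if (ok) {
        # primitive motif check
        for (d in seq_len(m - 1)) {
          if (m %% d == 0 &&
              strrep(substr(motif, 1, d), m / d) == motif) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + count * m, motif = motif,
          motif_len = m, count = count, stringsAsFactors = FALSE)
      }
      i <- if (r > 0) j else i + 1L
    }
  }
  if (length(cand) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), motif_len = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  loci <- do.call(rbind, cand)
  loci <- loci[order(-(loci$end - loci$start), loci$start,
                     loci$motif_len), , drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))[-1]) {
    prior <- which(keep[seq_len(i - 1)])
    if (any(loci$start[prior] < loci$end[i] &
              loci$end[prior] > loci$start[i])) keep[i] <- FALSE
  }
  loci <- loci[keep, , drop = FALSE]
  loci <- loci[order(loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

# --- diagonal Hamming scan in R: maximal windows from mismatch vectors ---
hamming_oracle <- function(s, t, min_len, max_mm, same = FALSE) {
  S <- strsplit(s, "", fixed = TRUE)[[1]]
  T_ <- strsplit(t, "", fixed = TRUE)[[1]]
  ns <- length(S); nt <- length(T_)
  rows <- list()
  offs <- if (same) seq_len(nt - 1) else (-(ns - 1)):(nt - 1)
  for (off in offs) {
    i0 <- max(-off, 0); j0 <- i0 + off
    L <- min(ns - i0, nt - j0)
    if (L < min_len) next
    a <- S[(i0 + 1):(i0 + L)]
    b <- T_[(j0 + 1):(j0 + L)]
    mm <- which(a != b | a == "N")
    if (length(mm) <= max_mm) {
      rows[[length(rows) + 1L]] <- data.frame(
        i = i0, j = j0, len = L, mismatches = length(mm))
      next
    }
    M <- c(0L, mm, L + 1L)
    for (aidx in seq_len(length(M) - max_mm - 1L)) {
      b_ <- aidx + max_mm + 1L
      st <- M[aidx] + 1L
      en <- M[b_] - 1L
      len <- en - st + 1L
      if (len >= min_len) {
        rows[[length(rows) + 1L]] <- data.frame(
          i = i0 + st - 1L, j = j0 + st - 1L, len = len,
          mismatches = max_mm)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(i = integer(), j = integer(), len = integer(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# full four-orientation plastome-repeat oracle built on hamming_oracle
plastome_repeats_oracle <- function(s, min_len = 20, max_mm = 3) {
  n <- nchar(s)
  rows <- list()
  emit <- function(type, i, j, len, mm) {
    if (length(i) == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, start_a = i, end_a = i + len, start_b = j,
      end_b = j + len, length = len, hamming = mm,
      stringsAsFactors = FALSE)
  }
  f <- hamming_oracle(s, s, min_len, max_mm, same = TRUE)
  emit("forward", f$i, f$j, f$len, f$mismatches)
  co <- hamming_oracle(s, chartr("ACGT", "TGCA", s), min_len, max_mm)
  k <- co$i < co$j
  emit("complement", co$i[k], co$j[k], co$len[k], co$mismatches[k])
  rev_str <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = "")
  for (ty in c("reverse", "palindromic")) {
    t <- if (ty == "reverse") rev_str(s) else rev_str(chartr("ACGT",
                                                             "TGCA", s))
    h <- hamming_oracle(s, t, min_len, max_mm)
    if (nrow(h) == 0) next
    bs <- n - h$j - h$len
    a1 <- pmin(h$i, bs); b1 <- pmax(h$i, bs)
    keep <- h$i != bs & !duplicated(sprintf("%d:%d:%d", a1, b1, h$len))
    emit(ty, a1[keep], b1[keep], h$len[keep], h$mismatches[keep])
  }
  if (length(rows) == 0) {
    return(data.frame(type = character(), start_a = integer(),
                      end_a = integer(), start_b = integer(),
                      end_b = integer(), length = integer(),
                      hamming = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$type, out$start_a, out$start_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- two-pass Pearson correlation ---------------------------------------
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# --- per-codon tally RSCU oracle ----------------------------------------
rscu_oracle <- function(cds_vec) {
  code <- Biostrings::GENETIC_CODE
  tally <- integer(0)
  for (s in cds_vec) {
    n <- nchar(s)
    for (p in seq(1, n - 2, by = 3)) {
      cd <- substr(s, p, p + 2)
      tally[cd] <- (if (is.na(tally[cd])) 0L else tally[cd]) + 1L
    }
  }
  out <- list()
  for (aa in unique(code[code != "*"])) {
    fam <- names(code)[code == aa]
    cnts <- vapply(fam, function(cd) {
      v <- tally[cd]; if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
    tot <- sum(cnts)
    for (cd in fam) {
      out[[length(out) + 1L]] <- data.frame(
        codon = cd, amino_acid = aa, count = cnts[[cd]],
        rscu = if (tot > 0) cnts[[cd]] * length(fam) / tot else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# small synthetic genome helper used across tests
small_sim <- function(seed = 42, n_isoforms = 3,
                      len_range = c(40000, 60000),
                      repeat_rows = c(2, 5, 8), mtpt_rows = c(2, 4),
                      ssr_rows = 1:3, gene_templates = c(1, 3)) {
  cfg <- synth_config(
    n_isoforms = n_isoforms, isoform_length_range = len_range,
    seed = seed,
    repeat_plan = default_repeat_plan()[repeat_rows, , drop = FALSE],
    mtpt_plan = default_mtpt_plan()[mtpt_rows, , drop = FALSE],
    ssr_plan = default_ssr_plan()[ssr_rows, , drop = FALSE],
    gene_plan = default_gene_plan()[gene_templates]
  )
  generate_mitogenome(cfg)
}
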