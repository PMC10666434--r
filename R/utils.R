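#' Reverse complement of a DNA string
#'
#' Bases outside \code{A,C,G,T} become \code{N}.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, revcomp_cpp, character(1), USE.NAMES = FALSE)
}

#' Complement (without reversal) of a DNA string
#' @param x character vector of DNA strings.
#' @return character vector of complements.
#' @export
complement_seq <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# counts of A, C, G, T, N and other characters in one string
base_counts <- function(seq) {
  r <- charToRaw(seq)
  n <- length(r)
  cnt <- c(
    A = sum(r == as.raw(65L)), C = sum(r == as.raw(67L)),
    G = sum(r == as.raw(71L)), T = sum(r == as.raw(84L)),
    N = sum(r == as.raw(78L))
  )
  c(cnt, other = n - sum(cnt))
}

# validate/normalize a DNA string; strict mode rejects non-ACGTN
normalize_dna <- function(seq, normalize_ambiguous = FALSE, id = "") {
  seq <- toupper(seq)
  cnt <- base_counts(seq)
  if (cnt[["other"]] > 0L) {
    if (!normalize_ambiguous) {
      stop("sequence ", id, " contains ", cnt[["other"]],
           " characters outside {A,C,G,T,N}; set normalize_ambiguous = TRUE ",
           "to convert them to N", call. = FALSE)
    }
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[!chars %in% c("A", "C", "G", "T", "N")] <- "N"
    seq <- paste(chars, collapse = "")
  }
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derived from a user seed (kept below 2^31)
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt) %% 2147483647)
}
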