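BASES <- c("A", "C", "G", "T")

base_digits <- function(seq) {
  # A=0, C=1, G=2, T=3; any other symbol (N, IUPAC ambiguity, gap) = -1
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  d <- match(chars, BASES) - 1L
  d[is.na(d)] <- -1L
  d
}

#' Base-4 index of a k-mer
#'
#' Maps a canonical-base word to its row in the k-mer table: A, C, G, T encode
#' the base-4 digits 0-3, leftmost base most significant, so `"ACGT"` has index
#' `0*64 + 1*16 + 2*4 + 3 = 27`. Windows containing non-ACGT symbols are
#' invalid and signal an error (callers scanning a sequence skip them).
#'
#' @param window A single string of length `k` over A/C/G/T.
#' @return Zero-based integer index in `[0, 4^k)`.
#' @export
#' @examples
#' kmer_index("ACGT")  # 27
kmer_index <- function(window) {
  d <- base_digits(window)
  if (any(d < 0)) stop("invalid window (non-ACGT base): ", window, call. = FALSE)
  k <- length(d)
  sum(d * 4^((k - 1):0))
}

#' Global k-mer feature vector of a sequence
#'
#' Counts every length-`k` window whose bases are all canonical, scanning the
#' sequence once with a rolling Horner update (each slide drops the most
#' significant base-4 digit and appends the new base, so the per-window cost is
#' constant instead of O(k)). Windows touching an ambiguous base contribute
#' nothing. The result has length `4^k`; with `normalize = TRUE` (default)
#' counts are divided by their total so the vector is a length-invariant
#' frequency profile.
#'
#' @param seq Nucleotide string (case-insensitive).
#' @param k Word size (default 7).
#' @param normalize Divide counts by their sum when at least one valid window
#'   exists (default `TRUE`).
#' @return Numeric vector of length `4^k`, named by k-mer word.
#' @export
#' @examples
#' kmer_vector("ACGT", k = 2, normalize = FALSE)[c("AC", "CG", "GT")]
kmer_vector <- function(seq, k = 7, normalize = TRUE) {
  stopifnot(k >= 1)
  counts <- .kmer_count_horner(base_digits(seq), as.integer(k))
  names(counts) <- kmer_words(k)
  if (normalize) {
    tot <- sum(counts)
    if (tot > 0) counts <- counts / tot
  }
  counts
}

kmer_words <- function(k) {
  words <- BASES
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      words <- as.vector(t(outer(words, BASES, paste0)))
    }
  }
  words
}

#' Extract the both-end (BE) sequence
#'
#' The terminal regions of TEs carry the discriminative structure (LTRs, TIRs,
#' poly-A/T tails), so the local branch looks only at the first and last `L`
#' bases: left segment = first `min(L, len)` bases right-padded with N to
#' length `L`; right segment = last `min(L, len)` bases left-padded with N;
#' the BE sequence is their concatenation (length exactly `2L`). For
#' sequences shorter than `2L` the two segments overlap — every base is still
#' seen, none is invented (padding N one-hot encodes to a zero row).
#'
#' @param seq Nucleotide string.
#' @param L Per-end length in bp (default 600).
#' @return String of length `2L`.
#' @export
extract_both_ends <- function(seq, L = 600) {
  stopifnot(L >= 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0) {
    warning("empty sequence: both-end extraction returns all-N padding")
    return(strrep("N", 2 * L))
  }
  m <- min(L, n)
  left <- paste0(substr(seq, 1, m), strrep("N", L - m))
  right <- paste0(strrep("N", L - m), substr(seq, n - m + 1, n))
  paste0(left, right)
}

#' One-hot encode a nucleotide string
#'
#' @param seq Nucleotide string (typically the output of
#'   [extract_both_ends()]).
#' @return Integer matrix with `nchar(seq)` rows and 4 columns (A, C, G, T);
#'   A maps to `(1,0,0,0)` and so on, any other symbol (including N padding)
#'   to the all-zero row, so padding is signal-free.
#' @export
one_hot <- function(seq) {
  d <- base_digits(seq)
  m <- matrix(0L, nrow = length(d), ncol = 4,
              dimnames = list(NULL, BASES))
  ok <- d >= 0
  m[cbind(which(ok), d[ok] + 1L)] <- 1L
  m
}

#' Compute both feature representations for a table of sequences
#'
#' Adds a `kmer` list-column (length-`4^k` frequency vectors) and a `onehot`
#' list-column (`2L` x 4 matrices over the both-end sequence) to a records
#' tibble, the pair of inputs every node classifier consumes.
#'
#' @param records Tibble with at least `id` and `seq` columns (see
#'   [read_fasta()] / [simulate_dataset()]).
#' @param k k-mer word size (default 7).
#' @param L per-end length in bp (default 600).
#' @param normalize Normalize k-mer counts to frequencies (default `TRUE`).
#' @return The input tibble with `kmer` and `onehot` list-columns.
#' @export
featurize <- function(records, k = 7, L = 600, normalize = TRUE) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  records <- tibble::as_tibble(records)
  records$kmer <- lapply(records$seq, kmer_vector, k = k, normalize = normalize)
  records$onehot <- lapply(records$seq, function(s) one_hot(extract_both_ends(s, L)))
  attr(records, "k") <- k
  attr(records, "L") <- L
  records
}

#' Reverse complement of a nucleotide string
#' @param seq Nucleotide string; non-ACGT symbols are preserved (N stays N).
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, "", USE.NAMES = FALSE))
}
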