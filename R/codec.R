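# 2-bit k-mer codec: A=00, C=01, G=10, T=11, first base most significant.
# Under this key the complement of a base is the bitwise NOT of its 2-bit
# field (A<->T, C<->G), so reverse complementation of a code is field-wise
# inversion plus field reversal -- no string round-trip needed.

.KMER_MAX_K <- 15L
.BASES <- c("A", "C", "G", "T")

# lookup from UTF-8 code point to base code; NA for anything not ACGT/acgt
.base_lookup <- local({
  v <- rep(NA_real_, 127L)
  v[utf8ToInt("A")] <- 0; v[utf8ToInt("C")] <- 1
  v[utf8ToInt("G")] <- 2; v[utf8ToInt("T")] <- 3
  v[utf8ToInt("a")] <- 0; v[utf8ToInt("c")] <- 1
  v[utf8ToInt("g")] <- 2; v[utf8ToInt("t")] <- 3
  v
})

.check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k > .KMER_MAX_K || k != round(k))
    stop("k must be a single integer in 1..", .KMER_MAX_K, call. = FALSE)
  as.integer(k)
}

.check_codes <- function(code, k) {
  if (length(code) == 0L) stop("no codes supplied", call. = FALSE)
  if (anyNA(code) || any(code < 0) || any(code >= 4^k) || any(code != round(code)))
    stop("codes must be integers in [0, 4^k)", call. = FALSE)
  as.numeric(code)
}

#' Encode k-mers as integers
#'
#' Maps each DNA word to its integer code under the fixed 2-bit-per-base
#' encoding A=00, C=01, G=10, T=11, concatenated left to right with the
#' first base in the most significant position. Codes are returned as
#' doubles so that k up to 15 (4^15 codes) stays exact.
#'
#' @param x character vector of k-mers, all of the same length k
#'   (1 <= k <= 15). Lowercase is accepted and uppercased; any character
#'   outside ACGT is an error -- callers must pre-split sequences on
#'   ambiguity codes.
#' @return numeric vector of codes in `[0, 4^k)`.
#' @examples
#' kmer_encode("ACGT")  # 27
#' @seealso [kmer_decode()], [kmer_revcomp()]
#' @export
kmer_encode <- function(x) {
  if (!is.character(x) || length(x) == 0L) stop("x must be a non-empty character vector")
  k <- unique(nchar(x))
  if (length(k) != 1L) stop("all k-mers must have the same length")
  if (k == 0L) stop("empty k-mer")
  k <- .check_k(k)
  ints <- utf8ToInt(paste(x, collapse = ""))
  ints[ints > 127L | ints < 1L] <- 1L  # out-of-table code points -> NA lookup
  b <- .base_lookup[ints]
  if (anyNA(b)) stop("sequence contains characters outside A/C/G/T")
  m <- matrix(b, nrow = k)
  as.numeric(colSums(m * 4^((k - 1):0)))
}

#' Decode integer codes back to k-mer strings
#'
#' Exact inverse of [kmer_encode()] for a given word length.
#'
#' @param code numeric vector of codes in `[0, 4^k)`.
#' @param k word length in bases.
#' @return character vector of uppercase DNA words of length `k`.
#' @examples
#' kmer_decode(27, 4)  # "ACGT"
#' @export
kmer_decode <- function(code, k) {
  k <- .check_k(k)
  code <- .check_codes(code, k)
  parts <- lapply(seq_len(k), function(j) .BASES[(code %/% 4^(k - j)) %% 4 + 1])
  do.call(paste0, parts)
}

#' Reverse complement in code space
#'
#' Complements each 2-bit base field (equivalent to XOR with all ones under
#' this encoding) and reverses the field order, yielding the code of the
#' reverse-complement word without decoding. Vectorised over `code`.
#'
#' @inheritParams kmer_decode
#' @return numeric vector of codes, `kmer_encode(revcomp(kmer_decode(code)))`.
#' @examples
#' kmer_revcomp(kmer_encode("AAAA"), 4) == kmer_encode("TTTT")
#' @export
kmer_revcomp <- function(code, k) {
  k <- .check_k(k)
  code <- .check_codes(code, k)
  rc <- numeric(length(code))
  for (j in seq_len(k)) {
    d <- (code %/% 4^(k - j)) %% 4
    rc <- rc + (3 - d) * 4^(j - 1)
  }
  rc
}

# reverse complement of plain character sequences (ACGT only)
.revcomp_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s)))),
         character(1), USE.NAMES = FALSE)
}
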