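# k-mer profiles: the dense vector of 4^k counts indexed by 2-bit code,
# plus construction from sequence data and the single-profile algebra
# (merge, shrink, balance, shuffle, info, spectrum).

#' Construct a k-mer profile
#'
#' A profile is the dense vector of occurrence counts of all 4^k possible
#' DNA words of length k, indexed by their 2-bit code (see [kmer_encode()]).
#' Counts are integral after counting but may become non-integral after
#' scaling transforms.
#'
#' @param counts numeric vector of length 4^k, non-negative.
#' @param k word length in bases (1..15).
#' @param label dataset name carried through transforms and into distance
#'   matrices.
#' @return an object of class `kmer_profile`: a list with elements `k`,
#'   `counts` and `label`.
#' @export
kmer_profile <- function(counts, k, label = "profile") {
  k <- .check_k(k)
  counts <- as.numeric(counts)
  if (length(counts) != 4^k)
    stop("counts must have length 4^k = ", 4^k, call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA", call. = FALSE)
  structure(list(k = k, counts = counts, label = as.character(label)[1]),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat("k-mer profile '", x$label, "': k=", x$k,
      ", total=", format(sum(x$counts), big.mark = ","),
      ", non-zero=", nz, ", nullomers=", 4^x$k - nz, "\n", sep = "")
  invisible(x)
}

.check_profile <- function(p) {
  if (!inherits(p, "kmer_profile")) stop("not a kmer_profile", call. = FALSE)
  p
}

.check_same_k <- function(a, b) {
  .check_profile(a); .check_profile(b)
  if (a$k != b$k) stop("profiles have different k (", a$k, " vs ", b$k, ")", call. = FALSE)
  invisible(NULL)
}

# windows of one sequence as 1-based profile indices; windows containing
# any non-ACGT character are dropped; sequences shorter than k yield none
.window_indices <- function(s, k) {
  ints <- utf8ToInt(s)
  ints[ints > 127L | ints < 1L] <- 1L
  b <- .base_lookup[ints]
  L <- length(b)
  if (L < k) return(numeric(0))
  n <- L - k + 1
  bad <- is.na(b)
  b[bad] <- 0
  code <- numeric(n)
  for (j in 0:(k - 1)) code <- code + b[(1 + j):(n + j)] * 4^(k - 1 - j)
  cb <- cumsum(bad)
  ok <- (cb[k:L] - c(0, cb)[1:n]) == 0
  code[ok] + 1
}

#' Count k-mers in sequences
#'
#' Slides a window of size k over every record and increments the count of
#' the window's code. Windows never span record boundaries, and windows
#' containing any character outside A/C/G/T (case-insensitive) contribute
#' nothing -- each record is effectively split into maximal ACGT-only
#' fragments, a fragment of length L contributing max(0, L-k+1) windows.
#'
#' @param x character vector of sequences (named or not), or an
#'   `XStringSet`. Use [read_fasta()] to obtain records from a file.
#' @param k word length in bases.
#' @param label dataset name for the resulting profile.
#' @return a [kmer_profile()] with integral counts.
#' @examples
#' p <- count_kmers("ACGTACGT", 4)
#' sum(p$counts)  # 5 windows
#' @export
count_kmers <- function(x, k, label = "profile") {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("x must be a character vector or XStringSet")
  k <- .check_k(k)
  idx <- unlist(lapply(x, .window_indices, k = k), use.names = FALSE)
  counts <- if (length(idx)) as.numeric(tabulate(idx, nbins = 4^k)) else numeric(4^k)
  kmer_profile(counts, k, label)
}

#' Merge two profiles
#'
#' Element-wise sum of counts; used e.g. to pool the two mates of a
#' paired-end library into one profile before assessing strand balance.
#'
#' @param a,b profiles with the same k.
#' @param label label of the merged profile; defaults to the two labels
#'   joined with "+".
#' @return a [kmer_profile()].
#' @export
profile_merge <- function(a, b, label = NULL) {
  .check_same_k(a, b)
  kmer_profile(a$counts + b$counts, a$k,
               label %||% paste(a$label, b$label, sep = "+"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Shrink a profile to a smaller word length
#'
#' Collapses k to k-1 by summing the four counts that share the same
#' (k-1)-base prefix (consecutive blocks of 4 in code order), repeating
#' until word length `m`. The total count is conserved; note that counting
#' directly at the smaller k from reads would see one extra terminal window
#' per read, so shrinking a read profile slightly under-represents read
#' ends relative to re-counting.
#'
#' @param p a profile.
#' @param m target word length, `1 <= m < p$k`.
#' @return a [kmer_profile()] with word length `m`.
#' @export
profile_shrink <- function(p, m) {
  .check_profile(p)
  m <- .check_k(m)
  if (m >= p$k) stop("m must be smaller than the profile's k", call. = FALSE)
  counts <- p$counts
  for (kk in p$k:(m + 1)) counts <- colSums(matrix(counts, nrow = 4))
  kmer_profile(counts, m, p$label)
}

#' Enforce strand symmetry on a profile
#'
#' Replaces each count by the sum of the word's count and its reverse
#' complement's count; palindromic words (even k only) are doubled. The
#' result satisfies counts\[w\] == counts\[revcomp(w)\] for every w, so its
#' [strand_balance()] is exactly 0.
#'
#' @param p a profile.
#' @return a strand-symmetric [kmer_profile()].
#' @export
profile_balance <- function(p) {
  .check_profile(p)
  rc <- kmer_revcomp(0:(4^p$k - 1), p$k)
  kmer_profile(p$counts + p$counts[rc + 1], p$k, p$label)
}

#' Randomly permute the counts of a profile
#'
#' Shuffles the full counts vector (zeros included) with a seeded
#' generator, producing a random profile with exactly the same distribution
#' of count values -- total, spectrum and nullomer number are preserved,
#' while any association between count and word identity is destroyed.
#'
#' @param p a profile.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @return a [kmer_profile()].
#' @export
profile_shuffle <- function(p, seed = NULL) {
  .check_profile(p)
  counts <- with_seed(seed, p$counts[sample.int(length(p$counts))])
  kmer_profile(counts, p$k, p$label)
}

#' Summary statistics of a profile
#'
#' @param p a profile.
#' @return a list with `k`, `total`, `non_zero`, `nullomers` (absent
#'   words), and the `mean`, `median` and `sd` of the counts vector.
#' @export
profile_info <- function(p) {
  .check_profile(p)
  nz <- sum(p$counts > 0)
  list(k = p$k,
       total = sum(p$counts),
       non_zero = nz,
       nullomers = 4^p$k - nz,
       mean = mean(p$counts),
       median = stats::median(p$counts),
       sd = stats::sd(p$counts))
}

#' k-mer spectrum (frequency of frequencies)
#'
#' Tallies how many distinct words occur at each count value; the modality
#' of this distribution reflects the complexity of the sequenced genome(s)
#' and library. Requires integral counts (profiles that have been scaled
#' are rejected).
#'
#' @param p a profile with integral counts.
#' @param include_zero if `TRUE`, include the count-0 bin (the nullomers).
#' @return a data.frame with columns `count` and `n_kmers`, sorted by
#'   `count`.
#' @export
kmer_spectrum <- function(p, include_zero = FALSE) {
  .check_profile(p)
  if (any(p$counts != round(p$counts)))
    stop("spectrum requires integral counts (profile appears scaled)", call. = FALSE)
  cts <- p$counts[p$counts > 0]
  tab <- table(cts)
  out <- data.frame(count = as.numeric(names(tab)), n_kmers = as.numeric(tab))
  if (include_zero)
    out <- rbind(data.frame(count = 0, n_kmers = sum(p$counts == 0)), out)
  out[order(out$count), , drop = FALSE]
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}
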