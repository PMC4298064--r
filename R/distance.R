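# Multiset distance between k-mer profiles, strand balance, and the
# all-vs-all distance matrix.

#' Default per-word pairwise distance
#'
#' The distance between the two counts x and y of one word in two
#' profiles:
#'
#'   f(x, y) = |x - y| / ((x + 1)(y + 1))
#'
#' It is symmetric, zero at x == y, lies in \[0, 1), and discounts
#' differences between large counts relative to the same absolute
#' difference between small counts -- a disagreement about a rare word
#' weighs more than the same disagreement about an abundant one.
#'
#' @param x,y non-negative numeric vectors (recycled).
#' @return numeric vector of distances in `[0, 1)`.
#' @examples
#' pairwise_default(1, 0)  # 0.5
#' pairwise_default(3, 1)  # 0.25
#' @export
pairwise_default <- function(x, y) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  abs(x - y) / ((x + 1) * (y + 1))
}

# multiset distance between two aligned count vectors: mean of f over
# positions nonzero in either vector, with a +1 in the denominator so the
# empty set is safe and values stay below 1 for the default f
.multiset_dist <- function(x, y, f = pairwise_default) {
  s <- x > 0 | y > 0
  ns <- sum(s)
  if (ns == 0) return(0)
  sum(f(x[s], y[s])) / (ns + 1)
}

#' Multiset distance between two profiles
#'
#' Sums a per-word pairwise function f over all words that are present
#' (nonzero) in at least one of the two profiles, normalised by the number
#' of such words plus one. With the default f the distance lies in
#' \[0, 1), is symmetric, and is zero exactly when the two count vectors
#' are identical.
#'
#' @param a,b profiles with the same k.
#' @param f pairwise function, a vectorised function of two non-negative
#'   numerics; defaults to [pairwise_default()].
#' @return a single non-negative number.
#' @examples
#' a <- count_kmers("ACGTACGT", 4)
#' multiset_distance(a, a)  # 0
#' @export
multiset_distance <- function(a, b, f = pairwise_default) {
  .check_same_k(a, b)
  .multiset_dist(a$counts, b$counts, f)
}

#' Strand balance of a profile
#'
#' Splits the profile into two sub-profiles that are reverse complements
#' of each other -- for every non-palindromic word pair (w, revcomp(w)) the
#' lexicographically smaller code goes in the forward vector, its mirror
#' in the reverse vector -- and returns the multiset distance between the
#' two vectors. 0 means coverage is perfectly balanced between strands;
#' values grow with strand bias and shrink as sequencing depth increases
#' on a strand-symmetric source. Palindromic words are excluded: they
#' would contribute f(c, c) = 0 while inflating the normalising set size.
#'
#' @param p a profile.
#' @param f pairwise function, as in [multiset_distance()].
#' @return a single non-negative number.
#' @export
strand_balance <- function(p, f = pairwise_default) {
  .check_profile(p)
  codes <- 0:(4^p$k - 1)
  rc <- kmer_revcomp(codes, p$k)
  w <- codes < rc
  .multiset_dist(p$counts[w], p$counts[rc[w] + 1], f)
}

#' All-vs-all distance matrix
#'
#' For every unordered pair of profiles, applies [prepare_pair()] to fresh
#' copies (pairwise transforms never mutate the originals or leak between
#' pairs) and computes the [multiset_distance()]. The result is symmetric
#' with a zero diagonal.
#'
#' @param profiles a list of at least two profiles, all with the same k.
#'   Row/column labels are taken from the list names if set, else from the
#'   profile labels.
#' @inheritParams prepare_pair
#' @param f pairwise function, as in [multiset_distance()].
#' @return a symmetric numeric matrix of class `kmer_distmat` with
#'   dimnames set to the labels.
#' @export
distance_matrix <- function(profiles, do_balance = FALSE, do_smooth = FALSE,
                            do_scale = FALSE, policy = smoothing_policy(),
                            f = pairwise_default) {
  if (!is.list(profiles) || length(profiles) < 2)
    stop("need at least two profiles", call. = FALSE)
  lapply(profiles, .check_profile)
  ks <- vapply(profiles, function(p) p$k, numeric(1))
  if (length(unique(ks)) != 1) stop("profiles have mixed k", call. = FALSE)
  labels <- names(profiles) %||% vapply(profiles, function(p) p$label, character(1))
  if (is.null(names(profiles)))
    labels <- make.unique(labels)
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pr <- prepare_pair(profiles[[i]], profiles[[j]], do_balance = do_balance,
                         do_smooth = do_smooth, do_scale = do_scale, policy = policy)
      m[i, j] <- m[j, i] <- multiset_distance(pr$a, pr$b, f)
    }
  }
  structure(m, class = c("kmer_distmat", "matrix", "array"))
}

#' Per-sample median pairwise distance
#'
#' For each label, the median of its off-diagonal row entries. Samples
#' with an unusually high median distance to everything else are quality
#' outliers.
#'
#' @param m a `kmer_distmat` (or any symmetric labelled matrix) with at
#'   least 3 samples.
#' @return named numeric vector of medians, one per label.
#' @export
median_pairwise_distance <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  out <- vapply(seq_len(n), function(i) stats::median(m[i, -i]), numeric(1))
  names(out) <- rownames(m)
  out
}
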