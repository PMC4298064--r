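# Independent oracles used across the suite. They deliberately avoid the
# package's codec: k-mers are handled as strings in ACGT-lexicographic
# order, windows are extracted with substring().

ORACLE_BASES <- c("A", "C", "G", "T")

# all k-mers in lexicographic order (prefix slow, last base fast)
all_kmers <- function(k) {
  out <- ORACLE_BASES
  while (k > 1) {
    out <- as.vector(t(outer(out, ORACLE_BASES, paste0)))
    k <- k - 1
  }
  out
}

# naive sliding-window tally by string matching; windows with non-ACGT
# characters are dropped
naive_count <- function(seqs, k) {
  universe <- all_kmers(k)
  counts <- numeric(length(universe))
  for (s in toupper(seqs)) {
    L <- nchar(s)
    if (L < k) next
    w <- substring(s, 1:(L - k + 1), k:L)
    w <- w[grepl("^[ACGT]+$", w)]
    if (length(w)) counts <- counts + tabulate(match(w, universe), nbins = length(universe))
  }
  counts
}

# string-level reverse complement
string_revcomp <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

# brute-force multiset distance: explicit loop over every position
brute_multiset <- function(x, y, f = function(a, b) abs(a - b) / ((a + 1) * (b + 1))) {
  total <- 0
  ns <- 0
  for (i in seq_along(x)) {
    if (x[i] > 0 || y[i] > 0) {
      total <- total + f(x[i], y[i])
      ns <- ns + 1
    }
  }
  if (ns == 0) 0 else total / (ns + 1)
}

# random integer profile with controllable sparsity
random_profile <- function(k, lambda = 1, label = "rand") {
  kmer_profile(stats::rpois(4^k, lambda), k, label)
}

# random ACGT sequence of given length (plain base R, no package code)
random_acgt <- function(n) paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
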