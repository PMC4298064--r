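# Seeded generators for the study conditions: random genomes, mutated
# relatives, metagenome mixtures at specified copy numbers, substitution-
# error read simulation, composition-preserving permutation controls, and
# the k-scan that uses them to choose a word length.

#' Generate a random genome sequence
#'
#' I.i.d. bases with the G+C probability split evenly between G and C (and
#' A+T likewise).
#'
#' @param length sequence length in bases (>= 1).
#' @param gc_fraction expected GC content in \[0, 1\].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a single character string over ACGT.
#' @export
random_genome <- function(length, gc_fraction = 0.5, seed = NULL) {
  if (length < 1 || length != round(length)) stop("length must be a positive integer")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2, (1 - gc_fraction) / 2)
  with_seed(seed,
            paste(sample(.BASES, length, replace = TRUE, prob = prob), collapse = ""))
}

#' Randomly permute the bases of a sequence
#'
#' A composition-preserving permutation control: the base composition (and
#' hence the 1-mer profile) is exactly that of the input, but all word
#' structure at k >= 2 is destroyed.
#'
#' @param x a single non-empty sequence string.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a permuted sequence of the same length and composition.
#' @export
permute_sequence <- function(x, seed = NULL) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0) stop("x must be one non-empty string")
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  with_seed(seed, paste(sample(ch), collapse = ""))
}

#' Mutate a fraction of positions
#'
#' Emulates homology between related genomes: copies the input and
#' substitutes a given fraction of positions with a uniformly chosen
#' different base (default 10%, i.e. ~90% identity).
#'
#' @param x a single sequence string over ACGT.
#' @param rate fraction of positions to substitute, in \[0, 1\].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(x, rate = 0.1, seed = NULL) {
  if (!is.character(x) || length(x) != 1L) stop("x must be one string")
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  with_seed(seed, {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    n <- round(rate * length(ch))
    if (n > 0) {
      pos <- sample.int(length(ch), n)
      for (p in pos) ch[p] <- sample(setdiff(.BASES, ch[p]), 1)
    }
    paste(ch, collapse = "")
  })
}

#' Build a metagenome mixture at specified copy numbers
#'
#' Emits each genome repeated `copies` times as independent records, so
#' the mixture's k-mer profile is exactly the integer combination
#' sum(copies\[i\] * profile(genome\[i\])).
#'
#' @param genomes named character vector of genome sequences.
#' @param copies non-negative integer copy numbers, one per genome, at
#'   least one positive.
#' @return named character vector of records, names suffixed with the
#'   copy index.
#' @export
build_mixture <- function(genomes, copies) {
  if (length(genomes) != length(copies)) stop("genomes and copies must have equal length")
  if (any(copies < 0) || any(copies != round(copies))) stop("copies must be non-negative integers")
  if (all(copies == 0)) stop("at least one copy number must be positive")
  nm <- names(genomes) %||% paste0("genome", seq_along(genomes))
  out <- character(0)
  for (i in seq_along(genomes)) {
    if (copies[i] == 0) next
    rec <- rep(genomes[[i]], copies[i])
    names(rec) <- paste0(nm[i], "_copy", seq_len(copies[i]))
    out <- c(out, rec)
  }
  out
}

#' Simulate sequencing reads with substitution errors
#'
#' Reads are drawn uniformly over valid start positions (sources weighted
#' by their number of valid positions) and, in `strands = "both"` mode,
#' assigned to a strand by a fair coin (reverse-strand reads are the
#' reverse complement of the sampled window). Substitution errors are
#' i.i.d. per base. In paired mode each fragment emits two mates from
#' opposite strands at the given insert size.
#'
#' @param genomes character vector of source sequences (each at least
#'   `read_length`, or `insert_size` in paired mode).
#' @param n_reads number of reads (fragments, in paired mode) to draw.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param strands `"both"` (fair coin) or `"forward"` (plus strand only).
#' @param paired emit mate pairs from fragment ends.
#' @param insert_size outer fragment length for paired mode.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return named character vector of reads (`read<i>` or
#'   `frag<i>/1`, `frag<i>/2`).
#' @export
simulate_reads <- function(genomes, n_reads, read_length = 100, error_rate = 0,
                           strands = c("both", "forward"), paired = FALSE,
                           insert_size = 300, seed = NULL) {
  strands <- match.arg(strands)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  span <- if (paired) insert_size else read_length
  if (paired && insert_size < read_length) stop("insert_size must be >= read_length")
  lens <- nchar(genomes)
  if (any(lens < span)) stop("every source sequence must be at least ", span, " bases")
  with_seed(seed, {
    npos <- lens - span + 1
    src <- sample.int(length(genomes), n_reads, replace = TRUE, prob = npos)
    start <- floor(stats::runif(n_reads) * npos[src]) + 1
    minus <- if (strands == "both") stats::runif(n_reads) < 0.5 else rep(FALSE, n_reads)
    if (!paired) {
      reads <- substr(genomes[src], start, start + read_length - 1)
      reads[minus] <- .revcomp_string(reads[minus])
      reads <- .apply_errors(reads, error_rate)
      stats::setNames(reads, paste0("read", seq_len(n_reads)))
    } else {
      frag <- substr(genomes[src], start, start + insert_size - 1)
      frag[minus] <- .revcomp_string(frag[minus])
      m1 <- substr(frag, 1, read_length)
      m2 <- .revcomp_string(substr(frag, insert_size - read_length + 1, insert_size))
      reads <- .apply_errors(c(rbind(m1, m2)), error_rate)
      stats::setNames(reads, paste0("frag", rep(seq_len(n_reads), each = 2),
                                    "/", rep(1:2, n_reads)))
    }
  })
}

# i.i.d. substitutions; an erroneous base is replaced by one of the other 3
.apply_errors <- function(reads, error_rate) {
  if (error_rate == 0) return(unname(reads))
  vapply(reads, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < error_rate)
    for (p in hit) ch[p] <- sample(setdiff(.BASES, ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Scan word lengths against permutation controls
#'
#' For each k in the range, profiles the data and `n_permutations`
#' composition-preserving permutations of it (each record's bases shuffled
#' independently; the same permuted datasets are reused across all k), and
#' summarises the scaled multiset distances between the data profile and
#' each permuted profile. The word length at which the mean distance
#' levels off is the one that best separates real word structure from
#' composition alone.
#'
#' @param x character vector of sequences (the dataset).
#' @param k_min,k_max inclusive range of word lengths (1..15).
#' @param n_permutations number of permuted control datasets (>= 2).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return data.frame with columns `k`, `mean_distance`, `sd_distance`.
#' @export
scan_k <- function(x, k_min = 1, k_max = 10, n_permutations = 10, seed = NULL) {
  k_min <- .check_k(k_min); k_max <- .check_k(k_max)
  if (k_min > k_max) stop("k_min must not exceed k_max")
  if (n_permutations < 2) stop("need at least 2 permutations")
  with_seed(seed, {
    perms <- lapply(seq_len(n_permutations), function(i)
      vapply(x, permute_sequence, character(1), USE.NAMES = FALSE))
    res <- lapply(k_min:k_max, function(k) {
      p0 <- count_kmers(x, k, "data")
      d <- vapply(perms, function(px) {
        pp <- count_kmers(px, k, "permuted")
        sc <- scale_pair(p0, pp)
        multiset_distance(sc$a, sc$b)
      }, numeric(1))
      data.frame(k = k, mean_distance = mean(d), sd_distance = stats::sd(d))
    })
    do.call(rbind, res)
  })
}
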