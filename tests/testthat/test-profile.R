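test_that("counting enumerates sliding windows and skips ambiguity codes", {
  p <- count_kmers("ACGTACGT", 4)
  expect_equal(sum(p$counts), 5)
  expect_equal(p$counts[kmer_encode("ACGT") + 1], 2)
  expect_equal(p$counts[kmer_encode(c("CGTA", "GTAC", "TACG")) + 1], c(1, 1, 1))

  q <- count_kmers("ACGNACG", 3)
  expect_equal(sum(q$counts), 2)
  expect_equal(q$counts[kmer_encode("ACG") + 1], 2)

  expect_equal(sum(count_kmers("ACG", 4)$counts), 0)  # record shorter than k
})

test_that("a 12-nt record yields 1 window at k=12 and 7 at k=6", {
  rec <- "ACGTACGTACGT"
  expect_equal(sum(count_kmers(rec, 12)$counts), 1)
  expect_equal(sum(count_kmers(rec, 6)$counts), 7)
})

test_that("counting matches the naive substring oracle and Biostrings", {
  set.seed(41)
  reads <- replicate(50, random_acgt(sample(20:60, 1)))
  for (k in 1:6) {
    expect_equal(count_kmers(reads, k)$counts, naive_count(reads, k))
  }
  # independent library cross-check: oligonucleotideFrequency uses the same
  # ACGT-lexicographic order as the 2-bit code
  bs <- Biostrings::DNAStringSet(reads)
  for (k in c(2, 5)) {
    expect_equal(count_kmers(reads, k)$counts,
                 unname(colSums(Biostrings::oligonucleotideFrequency(bs, k))))
  }
})

test_that("windows containing ambiguity codes are skipped, fragment-wise", {
  set.seed(42)
  s <- random_acgt(300)
  # inject Ns, then compare against counting the maximal ACGT fragments
  sN <- paste0(substr(s, 1, 100), "N", substr(s, 101, 200), "NN", substr(s, 201, 300))
  frags <- c(substr(s, 1, 100), substr(s, 101, 200), substr(s, 201, 300))
  for (k in c(3, 7)) {
    expect_equal(count_kmers(sN, k)$counts, count_kmers(frags, k)$counts)
  }
})

test_that("merge is element-wise addition with the zero profile as identity", {
  set.seed(7)
  a <- random_profile(3); b <- random_profile(3)
  zero <- kmer_profile(numeric(64), 3)
  expect_equal(profile_merge(a, zero)$counts, a$counts)
  m <- profile_merge(a, b)
  expect_equal(sum(m$counts), sum(a$counts) + sum(b$counts))
  expect_equal(m$counts, a$counts + b$counts)
  expect_error(profile_merge(a, random_profile(4)), "different k")
})

test_that("merging paired mates equals counting both mates in one pass", {
  set.seed(8)
  g <- random_genome(2000)
  reads <- simulate_reads(g, 40, 50, paired = TRUE, insert_size = 150, seed = 9)
  mate1 <- reads[grepl("/1$", names(reads))]
  mate2 <- reads[grepl("/2$", names(reads))]
  merged <- profile_merge(count_kmers(mate1, 4), count_kmers(mate2, 4))
  expect_equal(merged$counts, count_kmers(reads, 4)$counts)
})

test_that("shrink groups by prefix and conserves totals", {
  counts <- numeric(16)
  counts[kmer_encode(c("AA", "AC", "GA")) + 1] <- c(1, 2, 3)
  s <- profile_shrink(kmer_profile(counts, 2), 1)
  expect_equal(s$counts, c(3, 0, 3, 0))  # A=3, G=3

  set.seed(11)
  p <- random_profile(5)
  for (m in 4:1) expect_equal(sum(profile_shrink(p, m)$counts), sum(p$counts))
  expect_error(profile_shrink(p, 5), "smaller")
})

test_that("shrinking a read profile loses one terminal window per read", {
  set.seed(12)
  for (L in c(30, 57)) {
    read <- random_acgt(L)
    k <- 8
    direct <- sum(count_kmers(read, k - 1)$counts)
    shrunk <- sum(profile_shrink(count_kmers(read, k), k - 1)$counts)
    expect_equal(direct - shrunk, 1)
  }
})

test_that("balance symmetrises counts across strands", {
  p <- count_kmers(c("AA", "AA"), 2)       # {AA:2}
  b <- profile_balance(p)
  expect_equal(b$counts[kmer_encode("AA") + 1], 2)
  expect_equal(b$counts[kmer_encode("TT") + 1], 2)

  pal <- kmer_profile(tabulate(kmer_encode("AT") + 1, 16), 2)
  expect_equal(profile_balance(pal)$counts[kmer_encode("AT") + 1], 2)  # self-pair doubles

  set.seed(13)
  q <- random_profile(4)
  bq <- profile_balance(q)
  rc <- kmer_revcomp(0:255, 4)
  expect_equal(bq$counts, bq$counts[rc + 1])              # strand-symmetric
  expect_equal(profile_balance(bq)$counts, 2 * bq$counts) # linearity
  expect_equal(strand_balance(bq), 0)
})

test_that("shuffle permutes counts reproducibly", {
  set.seed(14)
  p <- random_profile(4)
  s1 <- profile_shuffle(p, seed = 99)
  s2 <- profile_shuffle(p, seed = 99)
  s3 <- profile_shuffle(p, seed = 100)
  expect_identical(s1$counts, s2$counts)
  expect_false(identical(s1$counts, s3$counts))
  expect_identical(sort(s1$counts), sort(p$counts))
  flat <- kmer_profile(rep(2, 64), 3)
  expect_identical(profile_shuffle(flat, seed = 1)$counts, flat$counts)
})

test_that("info reports totals, nullomers and count moments", {
  i <- profile_info(count_kmers("AAC", 2))
  expect_equal(i$total, 2)
  expect_equal(i$non_zero, 2)
  expect_equal(i$nullomers, 14)

  z <- profile_info(kmer_profile(numeric(64), 3))
  expect_equal(z$nullomers, 64)

  set.seed(15)
  p <- random_profile(4)
  i <- profile_info(p)
  expect_equal(i$non_zero + i$nullomers, 4^4)
  expect_equal(i$mean, mean(p$counts))
})

test_that("spectrum tallies frequency of frequencies", {
  sp <- kmer_spectrum(count_kmers("ACGTACGT", 4))
  expect_equal(sp$n_kmers[sp$count == 1], 3)
  expect_equal(sp$n_kmers[sp$count == 2], 1)

  set.seed(16)
  p <- random_profile(4, lambda = 2)
  sp <- kmer_spectrum(p)
  expect_equal(sum(sp$n_kmers), sum(p$counts > 0))
  expect_equal(sum(sp$count * sp$n_kmers), sum(p$counts))
  spz <- kmer_spectrum(p, include_zero = TRUE)
  expect_equal(sum(spz$n_kmers), 4^4)

  scaled <- kmer_profile(p$counts * 1.5, 4)
  expect_error(kmer_spectrum(scaled), "integral")
})
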