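# Pairwise transforms that make profiles of different library sizes
# comparable: global scaling to equal totals, and dynamic smoothing --
# a joint, local, bottom-up collapse of weakly covered regions of the
# quartary prefix tree, applied identically to both profiles.

#' Smoothing policy
#'
#' Governs [smooth_pair()]: a sibling group of four sub-blocks is collapsed
#' when `summary` of its four block totals is at or below `threshold` in
#' either profile. The default (min, 0) merges any group containing a
#' nullomer block, targeting the rare/absent words that drive library-size
#' sensitivity.
#'
#' @param summary one of `"min"`, `"max"`, `"mean"`, `"median"`, or a
#'   function reducing a numeric vector of four block totals to one number.
#' @param threshold non-negative number the summary is compared against.
#' @return an object of class `smoothing_policy`.
#' @export
smoothing_policy <- function(summary = "min", threshold = 0) {
  if (is.character(summary))
    summary <- match.arg(summary, c("min", "max", "mean", "median"))
  else if (!is.function(summary))
    stop("summary must be a name or a function", call. = FALSE)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  structure(list(summary = summary, threshold = threshold),
            class = "smoothing_policy")
}

# summary of each column of a 4 x G matrix, vectorised for the built-ins
.group_stat <- function(m4, summary) {
  if (is.function(summary)) return(apply(m4, 2, summary))
  lo <- pmin(m4[1, ], m4[2, ], m4[3, ], m4[4, ])
  hi <- pmax(m4[1, ], m4[2, ], m4[3, ], m4[4, ])
  switch(summary,
         min = lo,
         max = hi,
         mean = colMeans(m4),
         median = (colSums(m4) - lo - hi) / 2)  # median of 4 values
}

#' Scale a pair of profiles to equal totals
#'
#' Global library-size normalisation: the profile with the smaller total is
#' multiplied by larger_total / smaller_total (scaling up, never down, so
#' the deeper library's resolution is preserved); the other is returned
#' unchanged. Counts may become non-integral.
#'
#' @param a,b profiles with the same k and positive totals.
#' @return a list with elements `a` and `b`, totals equal to floating
#'   tolerance.
#' @export
scale_pair <- function(a, b) {
  .check_same_k(a, b)
  ta <- sum(a$counts); tb <- sum(b$counts)
  if (ta <= 0 || tb <= 0) stop("cannot scale a zero-total profile", call. = FALSE)
  if (ta < tb) a$counts <- a$counts * (tb / ta)
  else if (tb < ta) b$counts <- b$counts * (ta / tb)
  list(a = a, b = b)
}

#' Dynamic smoothing of a pair of profiles
#'
#' Locally collapses weakly covered words to a shorter effective word
#' length, jointly in both profiles so positions remain comparable.
#'
#' Working bottom-up over the quartary prefix tree: at level k every code
#' is its own block; at each level, every group of four sibling blocks that
#' are each already collapsed to a single carrier position is examined, and
#' if the policy's summary of the four block totals is at or below the
#' threshold in *either* profile, the group is merged in *both*: the
#' group total is stored at the lexicographically first code of the merged
#' prefix block and the remaining positions are zeroed. Only freshly merged
#' groups are candidates at the next level up, and the recursion stops at
#' word length 1 (the profile is never collapsed to a single bin). Totals
#' are conserved in each profile and the final block structure is identical
#' across the pair.
#'
#' @param a,b profiles with the same k.
#' @param policy a [smoothing_policy()].
#' @return a list with elements `a` and `b` (smoothed copies; inputs are
#'   not modified) and `blocks`, the 1-based start positions of the final
#'   block partition, shared by both profiles. A coarser partition's
#'   starts are a subset of a finer one's.
#' @export
smooth_pair <- function(a, b, policy = smoothing_policy()) {
  .check_same_k(a, b)
  if (!inherits(policy, "smoothing_policy")) stop("policy must be a smoothing_policy")
  k <- a$k
  ca <- a$counts; cb <- b$counts
  starts <- rep(TRUE, 4^k)
  if (k >= 2) {
    eligible <- rep(TRUE, 4^(k - 1))
    for (lev in k:2) {
      gsize <- 4^(k - lev + 1)       # codes per merged group at this level
      csize <- gsize / 4             # codes per child block
      cs_a <- colSums(matrix(ca, nrow = csize))
      cs_b <- colSums(matrix(cb, nrow = csize))
      stat_a <- .group_stat(matrix(cs_a, nrow = 4), policy$summary)
      stat_b <- .group_stat(matrix(cs_b, nrow = 4), policy$summary)
      merge <- eligible & (stat_a <= policy$threshold | stat_b <= policy$threshold)
      if (!any(merge)) break
      ga <- colSums(matrix(ca, nrow = gsize))
      gb <- colSums(matrix(cb, nrow = gsize))
      A <- matrix(ca, nrow = gsize); A[, merge] <- 0; A[1, merge] <- ga[merge]
      B <- matrix(cb, nrow = gsize); B[, merge] <- 0; B[1, merge] <- gb[merge]
      ca <- as.vector(A); cb <- as.vector(B)
      S <- matrix(starts, nrow = gsize); S[, merge] <- FALSE; S[1, merge] <- TRUE
      starts <- as.vector(S)
      if (lev == 2) break
      eligible <- colSums(matrix(merge, nrow = 4)) == 4
    }
  }
  list(a = kmer_profile(ca, k, a$label), b = kmer_profile(cb, k, b$label),
       blocks = which(starts))
}

#' Prepare a pair of profiles for distance calculation
#'
#' Applies, in this fixed order: [profile_balance()] to each profile
#' independently, then [smooth_pair()], then [scale_pair()], each step
#' optional. Smoothing precedes scaling so that it sees the raw integer
#' count structure, and scaling last equalises the areas on the final
#' block structure.
#'
#' @param a,b profiles with the same k.
#' @param do_balance,do_smooth,do_scale logical switches for the three
#'   steps.
#' @param policy a [smoothing_policy()] used when `do_smooth` is `TRUE`.
#' @return a list with elements `a` and `b`.
#' @export
prepare_pair <- function(a, b, do_balance = FALSE, do_smooth = FALSE,
                         do_scale = FALSE, policy = smoothing_policy()) {
  .check_same_k(a, b)
  if (do_balance) { a <- profile_balance(a); b <- profile_balance(b) }
  if (do_smooth) { s <- smooth_pair(a, b, policy); a <- s$a; b <- s$b }
  if (do_scale) { s <- scale_pair(a, b); a <- s$a; b <- s$b }
  list(a = a, b = b)
}
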