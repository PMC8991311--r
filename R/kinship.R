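#' Identity-by-descent coefficients for pairwise relationships
#'
#' Returns the Cotterman coefficients (k0, k1, k2): the probabilities that a
#' pair of non-inbred individuals shares 0, 1 or 2 alleles identical by
#' descent at an autosomal locus. These parameterise every kinship
#' likelihood ratio in the package.
#'
#' @param relationship one of `"unrelated"`, `"parent_child"`,
#'   `"full_sibling"`, `"half_sibling"`.
#' @return named numeric vector `c(k0, k1, k2)` summing to 1.
#' @examples
#' ibd_vector_for("full_sibling")
#' @export
ibd_vector_for <- function(relationship) {
  tab <- list(
    unrelated    = c(k0 = 1,    k1 = 0,   k2 = 0),
    parent_child = c(k0 = 0,    k1 = 1,   k2 = 0),
    full_sibling = c(k0 = 0.25, k1 = 0.5, k2 = 0.25),
    half_sibling = c(k0 = 0.5,  k1 = 0.5, k2 = 0))
  if (length(relationship) != 1L || !relationship %in% names(tab)) {
    stop("unknown relationship; valid labels: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  tab[[relationship]]
}

check_ibd <- function(k) {
  if (is.character(k)) k <- ibd_vector_for(k)
  k <- as.numeric(k)
  if (length(k) != 3L || any(k < 0 | k > 1) || abs(sum(k) - 1) > 1e-12) {
    stop("IBD vector must be three probabilities summing to 1",
         call. = FALSE)
  }
  names(k) <- c("k0", "k1", "k2")
  k
}

# Balding-Nichols next-draw probability of allele `a` after observing
# `cnt` copies of `a` among `n_obs` sampled alleles; theta = 0 gives p.
bn_prob <- function(p, cnt, n_obs, theta) {
  (theta * cnt + (1 - theta) * p) / (1 + (n_obs - 1) * theta)
}

# Conditional genotype probabilities given g1 = {a, b} under 0/1/2 IBD.
# Non-IBD alleles of g2 are fresh draws conditioned (sequentially, in the
# Balding-Nichols sense) on g1's two observed alleles; IBD copies are not
# new draws and add no conditioning counts. Vectorised over (c1, c2).
ibd_cond_probs <- function(a, b, c1, c2, pa, pb, p1, p2, theta) {
  # P0: both alleles of g2 are fresh draws
  q_c1 <- bn_prob(p1, (c1 == a) + (c1 == b), 2, theta)
  q_c2 <- bn_prob(p2, (c2 == a) + (c2 == b) + (c2 == c1), 3, theta)
  P0 <- ifelse(c1 == c2, 1, 2) * q_c1 * q_c2
  # P1: one allele IBD-copied from g1 (a or b with prob 1/2 each, or the
  # single allele if g1 is homozygous); the other is a fresh draw
  fresh <- function(v, pv) bn_prob(pv, (v == a) + (v == b), 2, theta)
  p_share <- function(v) {
    ifelse(c1 == v & c2 == v, fresh(c1, p1),
      ifelse(c1 == v, fresh(c2, p2),
        ifelse(c2 == v, fresh(c1, p1), 0)))
  }
  P1 <- if (a == b) p_share(a) else 0.5 * p_share(a) + 0.5 * p_share(b)
  # P2: both alleles IBD; g2 must equal g1 as a multiset
  P2 <- as.numeric(pair_equal(a, b, c1, c2))
  list(P0 = P0, P1 = P1, P2 = P2)
}

#' Single-locus kinship likelihood ratio
#'
#' Computes `P(g2 | g1, relationship) / P(g2 | g1, unrelated)` from the
#' IBD-state conditional genotype probabilities, with an optional
#' coancestry (theta) adjustment of conditional allele probabilities in the
#' Balding-Nichols form. With `theta = 0` the denominator is the plain
#' Hardy-Weinberg product form. A ratio of 0 is an exclusion: the pair
#' cannot stand in the hypothesised relationship at this locus barring
#' mutation.
#'
#' @param g1,g2 unordered allele pairs (length-2 numeric vectors of repeat
#'   counts); both alleles must be present in the locus frequency table.
#' @param k IBD vector from [ibd_vector_for()], or a relationship label.
#' @param locus either a locus name looked up in `freqs`, or a list with
#'   `alleles` and `freqs` components.
#' @param freqs a [frequency_set()] (needed when `locus` is a name).
#' @param theta coancestry coefficient in `[0, 1)`; default 0.
#' @return a single non-negative likelihood ratio.
#' @examples
#' loc <- list(name = "L", alleles = c(10, 11), freqs = c(0.5, 0.5))
#' single_locus_lr(c(10, 11), c(10, 11), "full_sibling", loc)  # 1.25
#' @export
single_locus_lr <- function(g1, g2, k, locus, freqs = NULL, theta = 0) {
  k <- check_ibd(k)
  if (theta < 0 || theta >= 1) {
    stop("`theta` must lie in [0, 1)", call. = FALSE)
  }
  sp <- if (is.character(locus)) locus_spec(freqs, locus) else locus
  g1 <- sort(as.numeric(g1)); g2 <- sort(as.numeric(g2))
  if (length(g1) != 2L || length(g2) != 2L || anyNA(g1) || anyNA(g2)) {
    stop("genotypes must be complete allele pairs", call. = FALSE)
  }
  p <- allele_freq(sp, c(g1, g2))
  cp <- ibd_cond_probs(g1[1], g1[2], g2[1], g2[2],
                       p[1], p[2], p[3], p[4], theta)
  unname((k["k0"] * cp$P0 + k["k1"] * cp$P1 + k["k2"] * cp$P2) / cp$P0)
}

# vectorised per-locus LR of one target genotype (a, b) against database
# genotype columns (c1, c2); NA database genotypes give NA
locus_lr_vec <- function(a, b, c1, c2, sp, k, theta) {
  out <- rep(NA_real_, length(c1))
  ok <- !is.na(c1) & !is.na(c2)
  if (!any(ok)) return(out)
  g <- sort(c(a, b))
  pa <- allele_freq(sp, g[1]); pb <- allele_freq(sp, g[2])
  p1 <- allele_freq(sp, c1[ok]); p2 <- allele_freq(sp, c2[ok])
  cp <- ibd_cond_probs(g[1], g[2], c1[ok], c2[ok], pa, pb, p1, p2, theta)
  out[ok] <- unname((k["k0"] * cp$P0 + k["k1"] * cp$P1 +
                       k["k2"] * cp$P2) / cp$P0)
  out
}

#' Multi-locus kinship likelihood ratio for a pair of profiles
#'
#' Multiplies single-locus ratios across the autosomal loci typed in both
#' profiles (computed as a sum of log10 values). Loci untyped in either
#' profile are skipped and counted. A zero single-locus ratio is counted as
#' an exclusion; with any exclusion the combined ratio is reported as 0 and
#' the log10 value as undefined (`NA`). Mutation is deliberately not
#' modelled inside the ratio: callers apply an exclusion tolerance instead,
#' which keeps the statistic transparent.
#'
#' @param p1,p2 profiles: one-row index data frames (see
#'   [assign_memberships()]) or lists with an `auto` element of per-locus
#'   allele pairs.
#' @param k IBD vector or relationship label.
#' @param freqs a [frequency_set()].
#' @param theta coancestry coefficient.
#' @return an object of class `kinship_result`: pair ids, hypothesis,
#'   per-locus ratios, `combined_log10_lr`, `combined_lr`, `n_exclusions`,
#'   `n_loci`.
#' @export
profile_lr <- function(p1, p2, k, freqs, theta = 0) {
  k <- check_ibd(k)
  g1 <- auto_genotypes(p1, freqs)
  g2 <- auto_genotypes(p2, freqs)
  loci <- freq_loci(freqs, "autosomal_str")
  per <- rep(NA_real_, length(loci))
  names(per) <- loci
  for (i in seq_along(loci)) {
    a <- g1[, i * 2L - 1L:0]
    b <- g2[, i * 2L - 1L:0]
    if (anyNA(a) || anyNA(b)) next
    per[i] <- single_locus_lr(a, b, k, loci[i], freqs, theta)
  }
  used <- !is.na(per)
  if (!any(used)) {
    stop("profiles share no typed autosomal loci", call. = FALSE)
  }
  n_excl <- sum(per[used] == 0)
  log10_lr <- if (n_excl > 0) NA_real_ else sum(log10(per[used]))
  pos <- used & per > 0
  structure(list(
    pair = c(profile_id(p1), profile_id(p2)),
    hypothesis = k, theta = theta,
    per_locus_lr = per[used],
    combined_lr = if (n_excl > 0) 0 else 10^log10_lr,
    combined_log10_lr = log10_lr,
    # exclusion-tolerant variant: product over non-excluded loci only,
    # always defined; callers use it where mutation-driven single-locus
    # exclusions should not zero the statistic
    log10_lr_tolerant = if (any(pos)) sum(log10(per[pos])) else 0,
    n_exclusions = n_excl,
    n_loci = sum(used)), class = "kinship_result")
}

#' @export
print.kinship_result <- function(x, ...) {
  cat(sprintf(
    "kinship LR %s vs %s: log10 LR = %s over %d loci (%d exclusion%s)\n",
    x$pair[1], x$pair[2],
    ifelse(is.na(x$combined_log10_lr), "undefined (excluded)",
           sprintf("%.3f", x$combined_log10_lr)),
    x$n_loci, x$n_exclusions, ifelse(x$n_exclusions == 1, "", "s")))
  invisible(x)
}

#' Rank a profile index by kinship likelihood ratio
#'
#' Computes the combined autosomal likelihood ratio of the target against
#' every record in the index under one relationship hypothesis and sorts
#' descending, ties broken by ascending record id. Records whose id equals
#' the target's are excluded as self-comparisons. Records with any
#' exclusion locus sort below all non-excluded records.
#'
#' @param target a one-row profile record.
#' @param index a profile index data frame.
#' @param k IBD vector or relationship label.
#' @param freqs a [frequency_set()].
#' @param theta coancestry coefficient.
#' @param top_n maximum rows returned (default all).
#' @return data frame with `record_id`, `combined_log10_lr` (`NA` when
#'   excluded), `n_exclusions`, `n_loci`, sorted by descending ratio.
#' @export
rank_database <- function(target, index, k, freqs, theta = 0,
                          top_n = Inf) {
  k <- check_ibd(k)
  if (!nrow(index)) {
    return(data.frame(record_id = character(0),
                      combined_log10_lr = numeric(0),
                      n_exclusions = integer(0), n_loci = integer(0)))
  }
  keep <- index$record_id != profile_id(target)
  index <- index[keep, , drop = FALSE]
  loci <- freq_loci(freqs, "autosomal_str")
  tg <- auto_genotypes(target, freqs)
  n <- nrow(index)
  logsum <- numeric(n); n_excl <- integer(n); n_loci <- integer(n)
  for (i in seq_along(loci)) {
    a <- tg[, i * 2L - 1L]; b <- tg[, i * 2L]
    if (is.na(a) || is.na(b)) next
    cols <- paste0(loci[i], c("_1", "_2"))
    lr <- locus_lr_vec(a, b, index[[cols[1]]], index[[cols[2]]],
                       locus_spec(freqs, loci[i]), k, theta)
    ok <- !is.na(lr)
    n_loci <- n_loci + ok
    excl <- ok & lr == 0
    n_excl <- n_excl + excl
    pos <- ok & lr > 0
    logsum[pos] <- logsum[pos] + log10(lr[pos])
  }
  key <- ifelse(n_excl > 0, -Inf, logsum)
  ord <- order(-key, index$record_id)
  out <- data.frame(
    record_id = index$record_id[ord],
    combined_log10_lr = ifelse(n_excl[ord] > 0, NA_real_, logsum[ord]),
    n_exclusions = n_excl[ord], n_loci = n_loci[ord],
    stringsAsFactors = FALSE)
  utils::head(out, top_n)
}
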