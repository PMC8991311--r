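#' Matching policy
#'
#' Bundles the thresholds that govern direct matching, partial-match
#' follow-up and search-key grouping. The two likelihood-ratio thresholds
#' realise the two-threshold rule used in partial-match programmes: a
#' candidate pair must pass the primary threshold under one first-order
#' relationship hypothesis (full sibling or parent-child) and a lower
#' confirmatory threshold under the complementary hypothesis. Defaults were
#' chosen from pilot simulations at 20 autosomal loci and are not a claim
#' about any jurisdiction's policy.
#'
#' @param min_shared_loci minimum mutually typed autosomal loci for a
#'   comparison to count (default 15).
#' @param allele_share_threshold number of shared autosomal alleles that
#'   triggers partial-match kinship evaluation (default 18, the 99th
#'   percentile of unrelated-pair sharing at 20 eight-allele loci in
#'   pilot simulation, below the 1st percentile for true siblings).
#' @param lr_threshold_sib,lr_threshold_pc primary combined-LR thresholds
#'   (plain ratio scale) under the full-sibling and parent-child
#'   hypotheses (default 100: pilot simulation puts ~95% of true sibling
#'   pairs above it and no unrelated pair in 600 near it).
#' @param lr_confirm confirmatory combined-LR threshold under the
#'   complementary hypothesis, applied to the exclusion-tolerant ratio
#'   (default 10).
#' @param y_max_mismatch_loci Y-haplotype loci allowed to differ by a
#'   single repeat step before two records stop sharing the Y key
#'   (default 1, tolerating one germline mutation).
#' @param mt_require_exact require exact mitochondrial label equality for
#'   the mt key (default TRUE; labels are opaque, so this is the only
#'   comparison implemented).
#' @return a `match_policy` list.
#' @export
match_policy <- function(min_shared_loci = 15,
                         allele_share_threshold = 18,
                         lr_threshold_sib = 100,
                         lr_threshold_pc = 100,
                         lr_confirm = 10,
                         y_max_mismatch_loci = 1,
                         mt_require_exact = TRUE) {
  pol <- list(
    min_shared_loci = check_count(min_shared_loci, "min_shared_loci",
                                  min = 1L),
    allele_share_threshold = check_count(allele_share_threshold,
                                         "allele_share_threshold", min = 0L),
    lr_threshold_sib = check_pos(lr_threshold_sib, "lr_threshold_sib"),
    lr_threshold_pc = check_pos(lr_threshold_pc, "lr_threshold_pc"),
    lr_confirm = check_pos(lr_confirm, "lr_confirm"),
    y_max_mismatch_loci = check_count(y_max_mismatch_loci,
                                      "y_max_mismatch_loci", min = 0L),
    mt_require_exact = isTRUE(mt_require_exact))
  class(pol) <- "match_policy"
  pol
}

# per-row comparison of one target's autosomal profile to an index:
# returns n compared loci, n equal loci, n shared alleles (vectorised)
auto_compare <- function(target, index, freqs) {
  loci <- freq_loci(freqs, "autosomal_str")
  tg <- auto_genotypes(target, freqs)
  n <- nrow(index)
  n_cmp <- integer(n); n_eq <- integer(n); n_shared <- integer(n)
  for (i in seq_along(loci)) {
    a1 <- tg[, i * 2L - 1L]; a2 <- tg[, i * 2L]
    if (is.na(a1) || is.na(a2)) next
    cols <- paste0(loci[i], c("_1", "_2"))
    c1 <- index[[cols[1]]]; c2 <- index[[cols[2]]]
    ok <- !is.na(c1) & !is.na(c2)
    n_cmp <- n_cmp + ok
    eq <- ok & pair_equal(a1, a2, c1, c2)
    n_eq <- n_eq + eq
    sh <- pair_shared(a1, a2, c1, c2)
    n_shared <- n_shared + ifelse(ok, sh, 0L)
  }
  data.frame(n_compared = n_cmp, n_equal = n_eq, n_shared = n_shared)
}

#' Direct (full-profile) search
#'
#' Returns the known-side records whose autosomal profile equals the
#' query's at every mutually typed locus, with at least
#' `min_shared_loci` loci compared. Identical twins carry identical
#' profiles, so a twin of the true source matches directly; resolving
#' which twin deposited the sample is outside what STR profiles can do.
#'
#' @param profile a one-row profile record.
#' @param indexes an `edim_indexes` object (offender, arrestee and
#'   unidentified-remains indexes are searched).
#' @param policy a [match_policy()].
#' @return data frame of matching records: `record_id`, `role`,
#'   `n_compared`.
#' @export
direct_search <- function(profile, indexes, policy = match_policy()) {
  known <- rbind(indexes$offender, indexes$arrestee, indexes$uhr)
  direct_search_index(profile, known, indexes$freqs, policy)
}

# direct search against an arbitrary index data frame
direct_search_index <- function(profile, index, freqs,
                                policy = match_policy()) {
  if (!nrow(index)) {
    return(data.frame(record_id = character(0), role = character(0),
                      n_compared = integer(0)))
  }
  cmp <- auto_compare(profile, index, freqs)
  hit <- cmp$n_compared >= policy$min_shared_loci &
    cmp$n_equal == cmp$n_compared &
    index$record_id != profile_id(profile)
  out <- data.frame(record_id = index$record_id[hit],
                    role = index$role[hit],
                    n_compared = cmp$n_compared[hit],
                    stringsAsFactors = FALSE)
  out[order(out$record_id), , drop = FALSE]
}

#' Partial-match scan with two-threshold kinship follow-up
#'
#' Scans every forensic-against-known pair, keeps pairs that share at
#' least `allele_share_threshold` autosomal alleles without being direct
#' matches, evaluates each under the full-sibling and parent-child
#' hypotheses, and emits candidates that pass the two-threshold rule (see
#' [match_policy()]).
#'
#' @param forensic_index,offender_index profile index data frames.
#' @param freqs a [frequency_set()].
#' @param policy a [match_policy()].
#' @param theta coancestry coefficient.
#' @return data frame of candidate leads: pair ids, shared-allele count,
#'   log10 LRs under both hypotheses and the passing hypothesis label.
#' @export
partial_match_scan <- function(forensic_index, offender_index, freqs,
                               policy = match_policy(), theta = 0) {
  out <- list()
  for (i in seq_len(nrow(forensic_index))) {
    f <- forensic_index[i, , drop = FALSE]
    cmp <- auto_compare(f, offender_index, freqs)
    cand <- which(cmp$n_shared >= policy$allele_share_threshold &
                    cmp$n_compared >= policy$min_shared_loci &
                    !(cmp$n_equal == cmp$n_compared) &
                    offender_index$record_id != f$record_id)
    for (j in cand) {
      o <- offender_index[j, , drop = FALSE]
      sib <- profile_lr(f, o, "full_sibling", freqs, theta)
      pc <- profile_lr(f, o, "parent_child", freqs, theta)
      # two-threshold rule: primary threshold under one first-order
      # hypothesis, confirmatory threshold under the complementary one.
      # The confirmatory check uses the exclusion-tolerant ratio: a
      # single 0-IBD or mutated locus excludes strictly under
      # parent_child even for true siblings, and the confirmatory step
      # measures overall similarity, not strict consistency.
      pass_sib <- sib$combined_lr >= policy$lr_threshold_sib &&
        10^pc$log10_lr_tolerant >= policy$lr_confirm
      pass_pc <- pc$combined_lr >= policy$lr_threshold_pc &&
        10^sib$log10_lr_tolerant >= policy$lr_confirm
      if (pass_sib || pass_pc) {
        out[[length(out) + 1L]] <- data.frame(
          forensic_id = f$record_id, known_id = o$record_id,
          n_shared = cmp$n_shared[j],
          log10_lr_sib = sib$combined_log10_lr,
          log10_lr_pc = pc$combined_log10_lr,
          hypothesis = if (pass_sib) "full_sibling" else "parent_child",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(forensic_id = character(0), known_id = character(0),
                      n_shared = integer(0), log10_lr_sib = numeric(0),
                      log10_lr_pc = numeric(0), hypothesis = character(0)))
  }
  do.call(rbind, out)
}

# Y-haplotype comparison: number of differing loci among mutually typed
# loci, and whether every difference is a single repeat step (vectorised
# over index rows)
y_compare <- function(target, index, y_loci) {
  n <- nrow(index)
  n_cmp <- integer(n); n_diff <- integer(n); single <- rep(TRUE, n)
  for (loc in y_loci) {
    a <- as.numeric(target[[loc]][1])
    if (is.na(a)) next
    v <- index[[loc]]
    ok <- !is.na(v)
    n_cmp <- n_cmp + ok
    d <- ok & v != a
    n_diff <- n_diff + d
    single <- single & (!d | abs(v - a) == 1)
  }
  data.frame(n_compared = n_cmp, n_diff = n_diff, single_step = single)
}

#' Familial search of a known index
#'
#' Deliberate ranked likelihood-ratio search for close relatives of a
#' forensic profile: the index is ranked under the full-sibling and
#' parent-child hypotheses via [rank_database()], the two rankings are
#' merged by the larger ratio per record, and each candidate is annotated
#' with Y-haplotype concordance where both records carry Y data. A
#' candidate whose Y haplotype differs at more loci than the policy's
#' mutation allowance is flagged `"Y-excluded"`: a coincidental autosomal
#' similarity rather than a paternal relative.
#'
#' @param target_case a one-row forensic record.
#' @param offender_index known-side index data frame.
#' @param freqs a [frequency_set()].
#' @param policy a [match_policy()].
#' @param theta coancestry coefficient.
#' @param top_n maximum candidates returned.
#' @return data frame ranked by descending merged log10 LR with per-
#'   hypothesis ratios, best hypothesis, and a `y_flag` column
#'   (`"concordant"`, `"Y-excluded"`, or `"no-Y"`).
#' @export
familial_search <- function(target_case, offender_index, freqs,
                            policy = match_policy(), theta = 0,
                            top_n = 20) {
  if (!nrow(offender_index)) {
    return(data.frame(record_id = character(0), log10_lr = numeric(0),
                      log10_lr_sib = numeric(0), log10_lr_pc = numeric(0),
                      hypothesis = character(0), y_flag = character(0)))
  }
  sib <- rank_database(target_case, offender_index, "full_sibling", freqs,
                       theta)
  pc <- rank_database(target_case, offender_index, "parent_child", freqs,
                      theta)
  m <- merge(sib[, c("record_id", "combined_log10_lr")],
             pc[, c("record_id", "combined_log10_lr")],
             by = "record_id", suffixes = c("_sib", "_pc"))
  key <- pmax(ifelse(is.na(m$combined_log10_lr_sib), -Inf,
                     m$combined_log10_lr_sib),
              ifelse(is.na(m$combined_log10_lr_pc), -Inf,
                     m$combined_log10_lr_pc))
  m$log10_lr <- ifelse(is.finite(key), key, NA_real_)
  m$hypothesis <- ifelse(
    !is.finite(key), "excluded",
    ifelse(ifelse(is.na(m$combined_log10_lr_sib), -Inf,
                  m$combined_log10_lr_sib) >= key,
           "full_sibling", "parent_child"))
  y_loci <- freq_loci(freqs, "y_str")
  m$y_flag <- "no-Y"
  if (length(y_loci) && !is.na(target_case[[y_loci[1]]][1])) {
    idx <- offender_index[match(m$record_id, offender_index$record_id), ,
                          drop = FALSE]
    yc <- y_compare(target_case, idx, y_loci)
    has_y <- yc$n_compared > 0
    m$y_flag[has_y] <- ifelse(
      yc$n_diff[has_y] <= policy$y_max_mismatch_loci, "concordant",
      "Y-excluded")
  }
  ord <- order(-key, m$record_id)
  out <- m[ord, c("record_id", "log10_lr", "combined_log10_lr_sib",
                  "combined_log10_lr_pc", "hypothesis", "y_flag")]
  names(out)[3:4] <- c("log10_lr_sib", "log10_lr_pc")
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Group forensic cases by a lineage search key
#'
#' The novel step of expanded indirect matching: a lineage-shared profile
#' component (Y-STR haplotype, mitochondrial type, or male X profile) is
#' used as a search key over the forensic index. Records sharing the key
#' are grouped (Y haplotypes may differ at up to `y_max_mismatch_loci`
#' loci, each by a single repeat step, linking records through germline
#' mutations; groups are the connected components of that relation).
#' Pairs of grouped records that are autosomal direct matches are treated
#' as same-source (or identical twins) and the duplicate record is dropped
#' from the group. Each surviving group's pairwise full-sibling kinship is
#' computed for downstream evaluation.
#'
#' @param forensic_index forensic index data frame.
#' @param key_kind `"y_str"`, `"mt"`, or `"x_maternal"`.
#' @param freqs a [frequency_set()].
#' @param policy a [match_policy()].
#' @param theta coancestry coefficient.
#' @return list of key groups; each has `key_kind`, `key_value`,
#'   `members` (record ids) and `pairwise` (data frame of record pairs
#'   with log10 sibling LRs).
#' @export
key_match_groups <- function(forensic_index, key_kind, freqs,
                             policy = match_policy(), theta = 0) {
  if (!key_kind %in% c("y_str", "mt", "x_maternal")) {
    stop("unknown key_kind; valid kinds: y_str, mt, x_maternal",
         call. = FALSE)
  }
  idx <- forensic_index
  n <- nrow(idx)
  if (n < 2L) return(list())
  comp <- switch(key_kind,
    y_str = {
      y_loci <- freq_loci(freqs, "y_str")
      if (!length(y_loci)) stop("no Y loci in frequency set", call. = FALSE)
      has <- rowSums(!is.na(as.matrix(idx[, y_loci, drop = FALSE]))) > 0
      link <- matrix(FALSE, n, n)
      for (i in which(has)) {
        yc <- y_compare(idx[i, , drop = FALSE], idx, y_loci)
        link[i, ] <- has & yc$n_compared > 0 &
          yc$n_diff <= policy$y_max_mismatch_loci & yc$single_step
      }
      link
    },
    mt = {
      lab <- idx$mt
      outer(lab, lab, function(a, b) !is.na(a) & !is.na(b) & a == b)
    },
    x_maternal = {
      x_loci <- freq_loci(freqs, "x_str")
      if (!length(x_loci)) stop("no X loci in frequency set", call. = FALSE)
      male <- idx$sex == "M"
      link <- matrix(FALSE, n, n)
      for (i in which(male)) {
        eq <- rep(TRUE, n); cmp <- rep(0L, n)
        for (loc in x_loci) {
          a <- idx[[paste0(loc, "_1")]][i]
          if (is.na(a)) next
          v <- idx[[paste0(loc, "_1")]]
          ok <- !is.na(v)
          cmp <- cmp + ok
          eq <- eq & (!ok | v == a)
        }
        link[i, ] <- male & eq & cmp > 0
      }
      link
    })
  comp <- comp | t(comp)
  diag(comp) <- FALSE
  edges <- which(comp & upper.tri(comp), arr.ind = TRUE)
  edge_list <- lapply(seq_len(nrow(edges)), function(r) edges[r, ])
  comp_id <- uf_components(n, edge_list)
  groups <- list()
  for (cid in unique(comp_id)) {
    members <- which(comp_id == cid)
    if (length(members) < 2L) next
    members <- members[order(idx$record_id[members])]
    # drop same-source duplicates (autosomal direct matches)
    keep <- members[1]
    for (m in members[-1]) {
      dup <- FALSE
      for (kk in keep) {
        cmp2 <- auto_compare(idx[m, , drop = FALSE],
                             idx[kk, , drop = FALSE], freqs)
        if (cmp2$n_compared >= policy$min_shared_loci &&
            cmp2$n_equal == cmp2$n_compared) {
          dup <- TRUE
          break
        }
      }
      if (!dup) keep <- c(keep, m)
    }
    if (length(keep) < 2L) next
    pairs <- utils::combn(keep, 2)
    pw <- data.frame(
      record_a = idx$record_id[pairs[1, ]],
      record_b = idx$record_id[pairs[2, ]],
      log10_lr_sib = vapply(seq_len(ncol(pairs)), function(j) {
        profile_lr(idx[pairs[1, j], , drop = FALSE],
                   idx[pairs[2, j], , drop = FALSE],
                   "full_sibling", freqs, theta)$combined_log10_lr
      }, numeric(1)),
      stringsAsFactors = FALSE)
    key_value <- switch(key_kind,
      y_str = paste(canon_allele(as.numeric(
        idx[keep[1], freq_loci(freqs, "y_str")])), collapse = "-"),
      mt = idx$mt[keep[1]],
      x_maternal = paste(canon_allele(as.numeric(
        idx[keep[1], paste0(freq_loci(freqs, "x_str"), "_1")])),
        collapse = "-"))
    groups[[length(groups) + 1L]] <- list(
      key_kind = key_kind, key_value = key_value,
      members = idx$record_id[keep], pairwise = pw)
  }
  # deterministic order by first member id
  if (length(groups) > 1L) {
    groups <- groups[order(vapply(groups, function(g) g$members[1],
                                  character(1)))]
  }
  groups
}

#' Male X-profile compatibility
#'
#' Tests whether two males carry identical hemizygous X profiles at all
#' mutually typed X loci. Brothers draw each X allele from their mother's
#' two copies, so identity is a corroborating signal of maternal
#' relatedness, not a requirement: maternal brothers differ wherever
#' their mother is heterozygous and they drew different copies. A
#' mismatch therefore lowers support but never excludes on its own.
#'
#' @param male1,male2 one-row profile records with `sex == "M"`.
#' @param freqs a [frequency_set()].
#' @return `TRUE` if all mutually typed X loci carry equal alleles.
#' @export
x_maternal_compat <- function(male1, male2, freqs) {
  if (!identical(male1$sex[1], "M") || !identical(male2$sex[1], "M")) {
    stop("x_maternal_compat() requires two male profiles", call. = FALSE)
  }
  x_loci <- freq_loci(freqs, "x_str")
  if (!length(x_loci)) stop("no X loci in frequency set", call. = FALSE)
  ok <- TRUE; compared <- 0L
  for (loc in x_loci) {
    a <- male1[[paste0(loc, "_1")]][1]
    b <- male2[[paste0(loc, "_1")]][1]
    if (is.na(a) || is.na(b)) next
    compared <- compared + 1L
    ok <- ok && a == b
  }
  if (!compared) stop("no mutually typed X loci", call. = FALSE)
  ok
}
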