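#' Expanded-indirect-matching workflow configuration
#'
#' Parameters of the tiered workflow run by [run_edim()]: first a direct
#' search of each forensic case against the known indexes, then lineage
#' search-key grouping of forensic cases with pairwise kinship evaluation,
#' and finally a genealogy referral for key-matched cases that no close-kin
#' evaluation resolves.
#'
#' @param policy a [match_policy()].
#' @param close_kin_log10_lr combined log10 likelihood-ratio threshold for
#'   issuing a close-kin lead (default 3 over at least
#'   `policy$min_shared_loci` loci; a tunable, not a published value).
#' @param key_order ordered subset of `c("y_str", "mt", "x_maternal")`;
#'   keys are tried in order and a case classified under an earlier key is
#'   not revisited.
#' @param igg_enabled when TRUE, key-matched cases below the close-kin
#'   threshold (or without a solved anchor) are flagged for investigative
#'   genetic genealogy referral rather than left unresolved. The referral
#'   is a terminal flag: consumer-database searching itself is out of
#'   scope.
#' @param uhr_as_known when TRUE (default) unidentified-human-remains
#'   records are searched on the known side and may anchor leads, in
#'   addition to their own cases being searchable.
#' @param theta coancestry coefficient passed to kinship evaluations.
#' @return an `edim_config` list.
#' @export
edim_config <- function(policy = match_policy(),
                        close_kin_log10_lr = 3,
                        key_order = c("y_str", "mt"),
                        igg_enabled = TRUE,
                        uhr_as_known = TRUE,
                        theta = 0) {
  if (!length(key_order) ||
      !all(key_order %in% c("y_str", "mt", "x_maternal"))) {
    stop("`key_order` must be a non-empty subset of y_str, mt, x_maternal",
         call. = FALSE)
  }
  if (!is.finite(close_kin_log10_lr)) {
    stop("`close_kin_log10_lr` must be finite", call. = FALSE)
  }
  structure(list(policy = policy,
                 close_kin_log10_lr = as.numeric(close_kin_log10_lr),
                 key_order = key_order,
                 igg_enabled = isTRUE(igg_enabled),
                 uhr_as_known = isTRUE(uhr_as_known),
                 theta = as.numeric(theta)),
            class = "edim_config")
}

#' Run the tiered expanded-indirect-matching workflow
#'
#' For every forensic case, in order: (1) a direct autosomal search against
#' the known indexes (offender, arrestee, and unidentified remains when
#' `uhr_as_known`); a full match closes the case as `direct_hit`. (2) For
#' the cases that remain unsolved, forensic cases are grouped by each
#' lineage search key in `key_order` and every within-group pair is
#' evaluated with a kinship likelihood ratio (the larger of the
#' full-sibling and parent-child hypotheses). An unsolved case whose
#' group-mate's case was directly solved, with pair log10 LR at or above
#' `close_kin_log10_lr`, receives a `close_kin_lead` anchored on the solved
#' case's known individual. (3) An unsolved key-matched case with no such
#' anchor becomes an `igg_referral` when enabled; everything else is
#' `unresolved`. Exactly one report is issued per forensic case,
#' deterministically ordered by record id.
#'
#' @param indexes an `edim_indexes` object.
#' @param cfg an [edim_config()].
#' @return data frame of lead reports with columns `case_id`, `record_id`,
#'   `outcome` (`direct_hit`, `close_kin_lead`, `igg_referral`,
#'   `unresolved`), `matched_record` (known record hit, or the anchor's
#'   known record for a close-kin lead), `anchor_case`, `key_kind`,
#'   `log10_lr`, `notes`.
#' @export
run_edim <- function(indexes, cfg = edim_config()) {
  if (!inherits(indexes, "edim_indexes")) {
    stop("`indexes` must be an edim_indexes object", call. = FALSE)
  }
  if (is.null(indexes$freqs)) stop("missing frequency set", call. = FALSE)
  freqs <- indexes$freqs
  policy <- cfg$policy
  forensic <- indexes$forensic
  forensic <- forensic[order(forensic$record_id), , drop = FALSE]
  n <- nrow(forensic)
  rep_df <- data.frame(
    case_id = forensic$case_id, record_id = forensic$record_id,
    outcome = rep("unresolved", n),
    matched_record = rep(NA_character_, n),
    anchor_case = rep(NA_character_, n),
    key_kind = rep(NA_character_, n),
    log10_lr = rep(NA_real_, n), notes = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (!n) return(rep_df)
  known <- rbind(indexes$offender, indexes$arrestee,
                 if (cfg$uhr_as_known) indexes$uhr)
  # tier 1: direct search
  for (i in seq_len(n)) {
    hits <- direct_search_index(forensic[i, , drop = FALSE], known, freqs,
                                policy)
    if (nrow(hits)) {
      rep_df$outcome[i] <- "direct_hit"
      rep_df$matched_record[i] <- hits$record_id[1]
      if (nrow(hits) > 1L) {
        rep_df$notes[i] <- sprintf("%d additional direct matches",
                                   nrow(hits) - 1L)
      }
    }
  }
  solved <- rep_df$outcome == "direct_hit"
  # tier 2: search-key grouping over all forensic cases, keys in order
  for (key in cfg$key_order) {
    open <- rep_df$outcome == "unresolved"
    if (!any(open)) break
    groups <- key_match_groups(forensic, key, freqs, policy, cfg$theta)
    for (grp in groups) {
      midx <- match(grp$members, rep_df$record_id)
      for (gi in seq_along(grp$members)) {
        i <- midx[gi]
        if (rep_df$outcome[i] != "unresolved") next
        # pairwise LRs of this member against its group mates
        pw <- grp$pairwise
        mine <- pw$record_a == grp$members[gi] |
          pw$record_b == grp$members[gi]
        pw <- pw[mine, , drop = FALSE]
        mate <- ifelse(pw$record_a == grp$members[gi], pw$record_b,
                       pw$record_a)
        mate_i <- match(mate, rep_df$record_id)
        lr <- best_pair_lr(forensic, grp$members[gi], mate, freqs,
                           cfg$theta)
        anchored <- solved[mate_i] & !is.na(lr) &
          lr >= cfg$close_kin_log10_lr
        if (any(anchored)) {
          best <- which(anchored)[order(-lr[anchored])][1]
          rep_df$outcome[i] <- "close_kin_lead"
          rep_df$matched_record[i] <- rep_df$matched_record[mate_i[best]]
          rep_df$anchor_case[i] <- mate[best]
          rep_df$key_kind[i] <- key
          rep_df$log10_lr[i] <- lr[best]
          rep_df$notes[i] <- sprintf(
            "candidate lead: close kin of %s (solved case %s)",
            rep_df$matched_record[mate_i[best]], mate[best])
        } else if (cfg$igg_enabled) {
          rep_df$outcome[i] <- "igg_referral"
          rep_df$key_kind[i] <- key
          rep_df$log10_lr[i] <- suppressWarnings(max(lr, na.rm = TRUE))
          if (!is.finite(rep_df$log10_lr[i])) rep_df$log10_lr[i] <- NA_real_
          rep_df$notes[i] <-
            "key-matched below close-kin criterion; refer for genealogy"
        }
      }
    }
  }
  rep_df
}

# max of sibling and parent-child log10 LR for one record against mates
best_pair_lr <- function(forensic, rec, mates, freqs, theta) {
  i <- match(rec, forensic$record_id)
  vapply(mates, function(m) {
    j <- match(m, forensic$record_id)
    sib <- profile_lr(forensic[i, , drop = FALSE],
                      forensic[j, , drop = FALSE], "full_sibling", freqs,
                      theta)$combined_log10_lr
    pc <- profile_lr(forensic[i, , drop = FALSE],
                     forensic[j, , drop = FALSE], "parent_child", freqs,
                     theta)$combined_log10_lr
    v <- suppressWarnings(max(sib, pc, na.rm = TRUE))
    if (is.finite(v)) v else NA_real_
  }, numeric(1))
}

#' Summarise a workflow run
#'
#' Counts and percentages per outcome, plus the uplift: the share of
#' close-kin leads among cases that were not directly hit — the gain that
#' indirect matching adds on top of direct database searching.
#'
#' @param reports lead-report data frame from [run_edim()].
#' @return list with `counts` (data frame outcome/n/pct) and `uplift_pct`.
#' @export
summarize_run <- function(reports) {
  lv <- c("direct_hit", "close_kin_lead", "igg_referral", "unresolved")
  n <- nrow(reports)
  cnt <- table(factor(reports$outcome, levels = lv))
  counts <- data.frame(outcome = lv, n = as.integer(cnt),
                       pct = if (n) as.numeric(100 * cnt / n) else
                         rep(0, 4))
  not_direct <- n - as.integer(cnt["direct_hit"])
  uplift <- if (not_direct > 0) {
    100 * as.integer(cnt["close_kin_lead"]) / not_direct
  } else 0
  list(counts = counts, uplift_pct = uplift, n_cases = n)
}
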