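#' Draw unrelated profiles under Hardy-Weinberg
#'
#' Generates `n` mutually unrelated individuals straight from the
#' frequency set (autosomal genotypes under Hardy-Weinberg, Y haplotypes
#' for males, one or two X alleles by sex, unique mitochondrial labels)
#' and returns them as a profile index. Uses the current RNG state, so
#' wrap in `set.seed()` for reproducibility.
#'
#' @param freqs a [frequency_set()].
#' @param n number of profiles.
#' @param role index role for the records (default `"offender"`).
#' @param prefix record-id prefix (default derived from role).
#' @param sex `"M"`, `"F"`, or `NULL` to draw 50/50.
#' @return a profile index data frame.
#' @export
hw_profiles <- function(freqs, n, role = "offender", prefix = NULL,
                        sex = NULL) {
  n <- check_count(n, "n")
  if (is.null(prefix)) prefix <- toupper(substr(role, 1, 1))
  sexes <- if (is.null(sex)) sample(c("M", "F"), n, replace = TRUE) else
    rep(sex, n)
  a_loci <- freq_loci(freqs, "autosomal_str")
  y_loci <- freq_loci(freqs, "y_str")
  x_loci <- freq_loci(freqs, "x_str")
  auto <- hw_draw(freqs, a_loci, n, 2L)
  y <- hw_draw(freqs, y_loci, n, 1L)
  if (length(y_loci)) y[sexes == "F", ] <- NA_real_
  x <- hw_draw(freqs, x_loci, n, 2L)
  if (length(x_loci)) x[sexes == "M", seq_along(x_loci) * 2L] <- NA_real_
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  df <- data.frame(record_id = ids, role = role,
                   case_id = if (role %in% c("forensic", "uhr")) {
                     sprintf("%s-case-%05d", role, seq_len(n))
                   } else NA_character_,
                   source_id = ids, sex = sexes, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(auto))
  if (length(y_loci)) df <- cbind(df, as.data.frame(y))
  if (length(x_loci)) df <- cbind(df, as.data.frame(x))
  df$mt <- sprintf("MT-%s%05d", prefix, seq_len(n))
  df
}

#' Simulate a sibling set with Mendelian transmission
#'
#' One founding couple drawn under Hardy-Weinberg and `n_children`
#' offspring under Mendelian transmission with stepwise mutation; sons
#' share their father's Y haplotype up to mutation and all children share
#' their mother's mitochondrial label. Uses the current RNG state.
#'
#' @param freqs a [frequency_set()].
#' @param n_children number of children (default 2).
#' @param sexes child sexes (recycled; default all male).
#' @param mut_auto,mut_y per-locus single-step mutation probabilities.
#' @param role,prefix index role and record-id prefix for the children.
#' @param family family tag used in ids and the mitochondrial label.
#' @return list with `children` (profile index data frame) and `parents`
#'   (list of the two parental allele matrices).
#' @export
simulate_sibling_set <- function(freqs, n_children = 2, sexes = "M",
                                 mut_auto = 0.002, mut_y = 0.002,
                                 role = "forensic", prefix = "S",
                                 family = "FAM") {
  n_children <- check_count(n_children, "n_children")
  a_loci <- freq_loci(freqs, "autosomal_str")
  y_loci <- freq_loci(freqs, "y_str")
  x_loci <- freq_loci(freqs, "x_str")
  p_auto <- hw_draw(freqs, a_loci, 2L, 2L)
  p_y <- hw_draw(freqs, y_loci, 2L, 1L)
  p_x <- hw_draw(freqs, x_loci, 2L, 2L)
  rownames(p_auto) <- rownames(p_y) <- rownames(p_x) <-
    c(paste0(family, "-FA"), paste0(family, "-MO"))
  if (length(x_loci)) p_x[1L, seq_along(x_loci) * 2L] <- NA_real_
  sexes <- rep(sexes, length.out = n_children)
  fa <- rep(paste0(family, "-FA"), n_children)
  mo <- rep(paste0(family, "-MO"), n_children)
  c_auto <- child_auto(p_auto, fa, mo, a_loci, freqs, mut_auto)
  c_y <- child_y(p_y, fa, sexes, y_loci, freqs, mut_y)
  c_x <- child_x(p_x, fa, mo, sexes, x_loci, freqs, mut_auto)
  ids <- sprintf("%s-%s%02d", family, prefix, seq_len(n_children))
  df <- data.frame(record_id = ids, role = role,
                   case_id = if (role %in% c("forensic", "uhr")) {
                     sprintf("case-%s-%02d", family, seq_len(n_children))
                   } else NA_character_,
                   source_id = ids, sex = sexes, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(c_auto))
  if (length(y_loci)) df <- cbind(df, as.data.frame(c_y))
  if (length(x_loci)) df <- cbind(df, as.data.frame(c_x))
  df$mt <- paste0("MT-", family)
  list(children = df, parents = list(auto = p_auto, y = p_y, x = p_x))
}

#' Calibrated workflow experiment
#'
#' Builds a forensic caseload in which a configurable fraction of unsolved
#' cases was committed by a man whose full brother committed another,
#' directly solvable, case: the brother carries a known offender profile,
#' so his own forensic case resolves as a direct hit and can anchor a
#' close-kin lead for the unsolved case through the shared Y-STR key. The
#' default sibling prevalence, 134,000 sibling pairs per 700,000 database
#' entries (0.1914...), is the twin-based sibship extrapolation of
#' [twin_extrapolation()], so the expected close-kin uplift equals the
#' analytic sibling-match percentage times the kinship detection rate.
#'
#' @param n_cases number of unsolved target cases.
#' @param sib_prob probability a target case has an anchored sibling
#'   (default `134000 / 700000`).
#' @param freqs a [frequency_set()]; default 20 autosomal + 17 Y loci
#'   with 8 alleles each.
#' @param cfg an [edim_config()].
#' @param mut_auto,mut_y mutation probabilities for the sibling draws.
#' @param seed integer seed.
#' @return list with `uplift_pct` (measured close-kin uplift among
#'   non-directly-hit cases), `summary` (from [summarize_run()]),
#'   `reports`, and `sib_truth` (logical ground truth per target case).
#' @export
simulate_edim_calibration <- function(n_cases = 120,
                                      sib_prob = 134000 / 700000,
                                      freqs = NULL,
                                      cfg = edim_config(key_order = "y_str"),
                                      mut_auto = 0.002, mut_y = 0.002,
                                      seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases")
  check_prob(sib_prob, "sib_prob")
  if (is.null(freqs)) {
    freqs <- generate_frequency_set(20, 17, 0, alleles_per_locus = 8,
                                    seed = 1901L)
  }
  with_seed(seed, {
    has_sib <- stats::runif(n_cases) < sib_prob
    forensic <- list(); offender <- list()
    for (i in seq_len(n_cases)) {
      fam <- sprintf("F%04d", i)
      if (has_sib[i]) {
        ss <- simulate_sibling_set(freqs, 2, "M", mut_auto, mut_y,
                                   family = fam)
        kids <- ss$children
        # first son: unsolved target case; second son: solved anchor
        kids$record_id <- c(sprintf("F-%s-T", fam), sprintf("F-%s-A", fam))
        kids$case_id <- c(sprintf("case-%s-T", fam),
                          sprintf("case-%s-A", fam))
        forensic[[length(forensic) + 1L]] <- kids
        anchor <- kids[2, , drop = FALSE]
        anchor$record_id <- sprintf("K-%s-A", fam)
        anchor$role <- "offender"
        anchor$case_id <- NA_character_
        offender[[length(offender) + 1L]] <- anchor
      } else {
        lone <- simulate_sibling_set(freqs, 1, "M", mut_auto, mut_y,
                                     family = fam)$children
        lone$record_id <- sprintf("F-%s-T", fam)
        lone$case_id <- sprintf("case-%s-T", fam)
        forensic[[length(forensic) + 1L]] <- lone
      }
    }
    forensic <- do.call(rbind, forensic)
    offender <- if (length(offender)) do.call(rbind, offender) else
      empty_index(freqs)
    idx <- new_indexes(offender, empty_index(freqs), forensic,
                       empty_index(freqs), freqs)
    reports <- run_edim(idx, cfg)
    s <- summarize_run(reports)
    target <- grepl("-T$", reports$record_id)
    list(uplift_pct = s$uplift_pct, summary = s, reports = reports,
         sib_truth = has_sib,
         target_outcomes = setNames(reports$outcome[target],
                                    reports$record_id[target]))
  })
}
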