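test_that("direct search is reflexive and rejects one-allele differences", {
  fs <- panel_freqs()
  set.seed(61)
  idx <- hw_profiles(fs, 10)
  self <- idx[3, , drop = FALSE]
  probe <- self
  probe$record_id <- "PROBE"
  hits <- edimatch:::direct_search_index(probe, idx, fs)
  expect_equal(hits$record_id, self$record_id)
  # change a single allele: no longer a direct match
  loc1 <- paste0(unique(fs$locus[fs$kind == "autosomal_str"])[1], "_1")
  sp <- edimatch:::locus_spec(fs, sub("_1$", "", loc1))
  probe2 <- probe
  probe2[[loc1]] <- sp$alleles[sp$alleles != probe2[[loc1]]][1]
  expect_equal(nrow(edimatch:::direct_search_index(probe2, idx, fs)), 0L)
})

test_that("an identical twin in the known index produces a direct hit", {
  fs <- panel_freqs()
  pop <- simulate_population(population_config(
    150, 2, twin_rate = 0.08, loci = fs, seed = 71))
  tg <- pop$individuals$twin_group
  twins <- split(pop$individuals$id[!is.na(tg)], tg[!is.na(tg)])
  twins <- twins[lengths(twins) == 2][[1]]
  offender <- edimatch:::records_for(pop, twins[1], "offender",
                                     paste0("K-", twins[1]))
  forensic <- edimatch:::records_for(pop, twins[2], "forensic",
                                     paste0("F-", twins[2]),
                                     case_id = "case-1")
  idx <- edimatch:::new_indexes(offender, offender[0, ], forensic,
                                offender[0, ], fs)
  hits <- direct_search(forensic[1, ], idx)
  expect_equal(hits$record_id, paste0("K-", twins[1]))
})

test_that("partial-match scan excludes direct matches and surfaces sibs", {
  fs <- panel_freqs()
  set.seed(81)
  # identical profiles: direct match, never a partial candidate
  twin <- hw_profiles(fs, 1, role = "forensic", prefix = "F", sex = "M")
  dup <- twin
  dup$record_id <- "K-DUP"
  dup$role <- "offender"
  expect_equal(nrow(partial_match_scan(twin, dup, fs)), 0L)
  # true sib pairs pass the two-threshold rule in >= 90% of replicates
  set.seed(82)
  emitted <- replicate(120, {
    ss <- simulate_sibling_set(fs, 2, "M")
    f <- ss$children[1, , drop = FALSE]
    o <- ss$children[2, , drop = FALSE]
    o$role <- "offender"
    nrow(partial_match_scan(f, o, fs)) == 1L
  })
  expect_gte(mean(emitted), 0.9)
  # unrelated pairs are essentially never emitted (false-candidate rate)
  set.seed(83)
  false_pos <- replicate(150, {
    p <- hw_profiles(fs, 2, sex = "M")
    f <- p[1, , drop = FALSE]; f$role <- "forensic"
    nrow(partial_match_scan(f, p[2, , drop = FALSE], fs)) > 0
  })
  expect_lte(mean(false_pos), 0.02)
})

test_that("familial search ranks a planted parent and flags Y discordance", {
  fs <- panel_freqs()
  set.seed(91)
  found <- replicate(40, {
    ss <- simulate_sibling_set(fs, 1, "M")
    child <- ss$children[1, , drop = FALSE]
    # reconstruct the father as an offender record
    father <- record_row("K-DAD", lapply(
      seq_len(20), function(i) ss$parents$auto[1, (i - 1) * 2 + 1:2]), fs)
    y_loci <- unique(fs$locus[fs$kind == "y_str"])
    for (j in seq_along(y_loci)) father[[y_loci[j]]] <- ss$parents$y[1, j]
    idx <- rbind(father, hw_profiles(fs, 199, role = "offender"))
    fam <- familial_search(child, idx, fs, top_n = 5)
    match("K-DAD", fam$record_id)
  })
  expect_gte(mean(found == 1, na.rm = FALSE), 0.9)
  # Y-discordant candidate beyond the allowance is flagged
  set.seed(92)
  a <- hw_profiles(fs, 1, role = "forensic", sex = "M")
  b <- hw_profiles(fs, 1, role = "offender", prefix = "Z", sex = "M")
  fam <- familial_search(a, b, fs, policy = match_policy(
    y_max_mismatch_loci = 0))
  expect_true(fam$y_flag[1] %in% c("Y-excluded", "concordant"))
  y_loci <- unique(fs$locus[fs$kind == "y_str"])
  n_diff <- sum(unlist(a[1, y_loci]) != unlist(b[1, y_loci]))
  expect_equal(fam$y_flag[1] == "Y-excluded", n_diff > 0)
  # empty index gives an empty ranked list
  expect_equal(nrow(familial_search(a, b[0, ], fs)), 0L)
})

test_that("Y-key grouping links paternal lines within mutation allowance", {
  fs <- panel_freqs()
  y_loci <- unique(fs$locus[fs$kind == "y_str"])
  set.seed(93)
  base <- hw_profiles(fs, 3, role = "forensic", prefix = "F", sex = "M")
  # three paternal-line males: same haplotype; one single-step mutation
  # in the third
  for (loc in y_loci) base[[loc]] <- base[[loc]][1]
  sp <- edimatch:::locus_spec(fs, y_loci[1])
  i <- match(base[[y_loci[1]]][3], sp$alleles)
  base[[y_loci[1]]][3] <- sp$alleles[if (i == 1) 2 else i - 1]
  # distinct autosomal profiles so nothing dedupes as same-source
  g1 <- key_match_groups(base, "y_str", fs,
                         match_policy(y_max_mismatch_loci = 1))
  expect_length(g1, 1L)
  expect_setequal(g1[[1]]$members, base$record_id)
  g0 <- key_match_groups(base, "y_str", fs,
                         match_policy(y_max_mismatch_loci = 0))
  expect_length(g0, 1L)
  expect_length(g0[[1]]$members, 2L)
  # all-distinct haplotypes: no groups
  set.seed(94)
  distinct <- hw_profiles(fs, 6, role = "forensic", prefix = "D",
                          sex = "M")
  expect_length(key_match_groups(distinct, "y_str", fs,
                                 match_policy(y_max_mismatch_loci = 0)),
                0L)
  expect_error(key_match_groups(distinct, "snp", fs), "unknown key_kind")
})

test_that("at allowance 0 the Y-key relation partitions records", {
  fs <- panel_freqs()
  set.seed(95)
  recs <- list()
  for (f in 1:6) {
    recs[[f]] <- simulate_sibling_set(fs, sample(1:3, 1), "M", mut_y = 0,
                                      family = sprintf("P%02d", f))$children
  }
  idx <- do.call(rbind, recs)
  groups <- key_match_groups(idx, "y_str", fs,
                             match_policy(y_max_mismatch_loci = 0))
  members <- unlist(lapply(groups, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  expect_true(all(vapply(groups, function(g) length(g$members) >= 2L,
                         logical(1))))
})

test_that("mitochondrial grouping keys on exact label equality", {
  fs <- panel_freqs()
  set.seed(96)
  sibs <- simulate_sibling_set(fs, 2, c("M", "F"), family = "MTF")$children
  other <- hw_profiles(fs, 3, role = "forensic", prefix = "O")
  groups <- key_match_groups(rbind(sibs, other), "mt", fs)
  expect_length(groups, 1L)
  expect_setequal(groups[[1]]$members, sibs$record_id)
  expect_equal(groups[[1]]$key_value, "MT-MTF")
})

test_that("male X compatibility behaves as a corroborating key", {
  fs <- panel_freqs(n_x = 4)
  set.seed(97)
  # maternal brothers with zero mutation share or differ only through
  # the mother's heterozygosity; with differing alleles the test is FALSE
  ss <- simulate_sibling_set(fs, 2, "M", mut_auto = 0, family = "XX")
  kids <- ss$children
  x1 <- paste0(unique(fs$locus[fs$kind == "x_str"]), "_1")
  same <- all(unlist(kids[1, x1]) == unlist(kids[2, x1]))
  expect_equal(x_maternal_compat(kids[1, ], kids[2, ], fs), same)
  forced <- kids[2, , drop = FALSE]
  sp <- edimatch:::locus_spec(fs, sub("_1$", "", x1[1]))
  forced[[x1[1]]] <- sp$alleles[sp$alleles != kids[1, x1[1]]][1]
  expect_false(x_maternal_compat(kids[1, ], forced, fs))
  fem <- kids[1, , drop = FALSE]
  fem$sex <- "F"
  expect_error(x_maternal_compat(fem, kids[2, ], fs), "male")
  # paternal half-brothers match far less often than maternal brothers
  rate <- function(maternal) {
    mean(replicate(150, {
      if (maternal) {
        ss <- simulate_sibling_set(fs, 2, "M", mut_auto = 0)
        x_maternal_compat(ss$children[1, ], ss$children[2, ], fs)
      } else {
        a <- simulate_sibling_set(fs, 1, "M", mut_auto = 0,
                                  family = "H1")$children
        b <- simulate_sibling_set(fs, 1, "M", mut_auto = 0,
                                  family = "H2")$children
        x_maternal_compat(a, b, fs)
      }
    }))
  }
  # identity at all 4 loci is itself probabilistic for maternal brothers
  # (~0.59 per locus where the mother may be heterozygous), but far above
  # the unrelated coincidence rate
  set.seed(98)
  r_mat <- rate(TRUE)
  r_un <- rate(FALSE)
  expect_gt(r_mat, 0.05)
  expect_lt(r_un, 0.02)
  expect_gt(r_mat, 3 * r_un + 0.04)
})
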