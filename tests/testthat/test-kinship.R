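test_that("IBD vectors carry the Mendelian relationship coefficients", {
  expect_equal(ibd_vector_for("unrelated"), c(k0 = 1, k1 = 0, k2 = 0))
  # parent-child: one allele is always transmitted, so always 1 IBD
  expect_equal(ibd_vector_for("parent_child"), c(k0 = 0, k1 = 1, k2 = 0))
  # full siblings: enumeration of the four parental transmission
  # combinations gives (1/4, 1/2, 1/4)
  expect_equal(ibd_vector_for("full_sibling"),
               c(k0 = 0.25, k1 = 0.5, k2 = 0.25))
  expect_equal(ibd_vector_for("half_sibling"),
               c(k0 = 0.5, k1 = 0.5, k2 = 0))
  expect_error(ibd_vector_for("cousin"), "valid labels")
})

test_that("single-locus ratios reproduce the hand-derived cases", {
  loc <- biallelic_locus()
  expect_equal(single_locus_lr(c(10, 11), c(10, 11), "full_sibling", loc),
               1.25)
  expect_equal(single_locus_lr(c(10, 11), c(10, 10), "unrelated", loc), 1)
  expect_equal(single_locus_lr(c(10, 10), c(11, 11), "parent_child", loc),
               0)
  expect_error(single_locus_lr(c(10, 12), c(10, 11), "full_sibling", loc),
               "not in the frequency table")
  expect_error(
    single_locus_lr(c(10, 11), c(10, 11), "full_sibling", loc, theta = 1),
    "theta")
})

test_that("theta = 0 path agrees with the textbook-formula oracle", {
  set.seed(101)
  for (rel in c("unrelated", "parent_child", "full_sibling",
                "half_sibling")) {
    k <- ibd_vector_for(rel)
    for (i in 1:250) {
      nall <- sample(3:6, 1)
      w <- rgamma(nall, 1.5)
      sp <- list(name = "R", alleles = 10 + seq_len(nall) - 1,
                 freqs = w / sum(w))
      g1 <- sample(sp$alleles, 2, replace = TRUE)
      g2 <- sample(sp$alleles, 2, replace = TRUE)
      expect_equal(single_locus_lr(g1, g2, k, sp),
                   textbook_lr(g1, g2, k, sp), tolerance = 1e-12)
    }
  }
})

test_that("conditional genotype distributions are proper and E[LR]=1", {
  # exhaustive enumeration over all genotypes of a 4-allele locus
  sp <- enum_locus()
  gts <- all_genotypes(sp)
  for (theta in c(0, 0.03)) {
    for (rel in c("parent_child", "full_sibling", "half_sibling")) {
      k <- ibd_vector_for(rel)
      for (r in seq_len(nrow(gts))) {
        g1 <- gts[r, ]
        lr <- apply(gts, 1, function(g2) {
          single_locus_lr(g1, g2, k, sp, theta = theta)
        })
        # P(g2 | g1, k) = LR * P0(g2 | g1); both must sum to 1 over g2
        p0v <- vapply(seq_len(nrow(gts)), function(j) {
          edimatch:::ibd_cond_probs(
            min(g1), max(g1), min(gts[j, ]), max(gts[j, ]),
            sp$freqs[match(min(g1), sp$alleles)],
            sp$freqs[match(max(g1), sp$alleles)],
            sp$freqs[match(min(gts[j, ]), sp$alleles)],
            sp$freqs[match(max(gts[j, ]), sp$alleles)], theta)$P0
        }, numeric(1))
        expect_equal(sum(p0v), 1, tolerance = 1e-12)
        expect_equal(sum(lr * p0v), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("symmetric hypotheses give symmetric ratios", {
  set.seed(77)
  sp <- enum_locus(c(0.15, 0.25, 0.6))
  gts <- all_genotypes(sp)
  for (rel in c("unrelated", "full_sibling")) {
    for (i in seq_len(nrow(gts))) {
      for (j in seq_len(nrow(gts))) {
        expect_equal(
          single_locus_lr(gts[i, ], gts[j, ], rel, sp),
          single_locus_lr(gts[j, ], gts[i, ], rel, sp),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("profile ratios multiply across loci and track exclusions", {
  fs <- two_locus_freqs()
  a <- record_row("A", list(c(10, 11), c(10, 11)), fs)
  b <- record_row("B", list(c(10, 11), c(10, 11)), fs)
  r <- profile_lr(a, b, "full_sibling", fs)
  expect_equal(r$combined_lr, 1.5625)
  expect_equal(r$combined_log10_lr, log10(1.25) * 2)
  expect_equal(r$n_exclusions, 0L)
  expect_equal(profile_lr(a, b, "unrelated", fs)$combined_lr, 1)
  # an opposite-homozygote locus excludes under parent_child
  c <- record_row("C", list(c(10, 10), c(10, 11)), fs)
  d <- record_row("D", list(c(11, 11), c(10, 11)), fs)
  r2 <- profile_lr(c, d, "parent_child", fs)
  expect_equal(r2$combined_lr, 0)
  expect_true(is.na(r2$combined_log10_lr))
  expect_equal(r2$n_exclusions, 1L)
  # tolerant variant keeps the non-excluded locus
  expect_equal(r2$log10_lr_tolerant,
               log10(single_locus_lr(c(10, 11), c(10, 11), "parent_child",
                                     edimatch:::locus_spec(fs, "L2"))))
  # untyped loci are skipped; no shared loci is an error
  e <- record_row("E", list(c(NA, NA), c(10, 11)), fs)
  expect_equal(profile_lr(a, e, "full_sibling", fs)$n_loci, 1L)
  f <- record_row("F", list(c(NA, NA), c(NA, NA)), fs)
  expect_error(profile_lr(a, f, "full_sibling", fs), "no typed")
})

test_that("simulated full sibs have positive combined log ratios", {
  fs <- panel_freqs()
  set.seed(404)
  hits <- replicate(300, {
    ss <- simulate_sibling_set(fs, 2, "M", mut_auto = 0.002)
    profile_lr(ss$children[1, ], ss$children[2, , drop = FALSE],
               "full_sibling", fs)$combined_log10_lr > 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("database ranking matches hand enumeration and its contract", {
  fs <- two_locus_freqs()
  # target {10,11} at both loci; candidates hand-ranked under sibship:
  # LR 1.25 per matching het locus, 0.75 for {10,10}, mixed orders
  target <- record_row("T", list(c(10, 11), c(10, 11)), fs)
  idx <- rbind(
    record_row("R3", list(c(10, 10), c(10, 10)), fs),
    record_row("R1", list(c(10, 11), c(10, 11)), fs),
    record_row("R2", list(c(10, 11), c(10, 10)), fs))
  rk <- rank_database(target, idx, "full_sibling", fs)
  expect_equal(rk$record_id, c("R1", "R2", "R3"))
  lr_het <- single_locus_lr(c(10, 11), c(10, 11), "full_sibling",
                            edimatch:::locus_spec(fs, "L1"))
  lr_hom <- single_locus_lr(c(10, 11), c(10, 10), "full_sibling",
                            edimatch:::locus_spec(fs, "L1"))
  expect_equal(rk$combined_log10_lr,
               c(2 * log10(lr_het), log10(lr_het) + log10(lr_hom),
                 2 * log10(lr_hom)))
  # empty index, self-exclusion, ties broken by ascending record id
  expect_equal(nrow(rank_database(target, idx[0, ], "full_sibling", fs)),
               0L)
  with_self <- rbind(idx, record_row("T", list(c(10, 11), c(10, 11)), fs))
  expect_false("T" %in% rank_database(target, with_self, "full_sibling",
                                      fs)$record_id)
  dup <- rbind(record_row("B2", list(c(10, 11), c(10, 11)), fs),
               record_row("B1", list(c(10, 11), c(10, 11)), fs))
  expect_equal(rank_database(target, dup, "full_sibling", fs)$record_id,
               c("B1", "B2"))
})

test_that("vectorised ranking agrees with the scalar per-pair computation", {
  fs <- panel_freqs()
  set.seed(55)
  idx <- hw_profiles(fs, 25)
  target <- hw_profiles(fs, 1, prefix = "T")
  rk <- rank_database(target, idx, "full_sibling", fs, theta = 0.02)
  per <- vapply(rk$record_id, function(id) {
    profile_lr(target, idx[idx$record_id == id, , drop = FALSE],
               "full_sibling", fs, theta = 0.02)$combined_log10_lr
  }, numeric(1))
  expect_equal(unname(per), rk$combined_log10_lr, tolerance = 1e-10)
})
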