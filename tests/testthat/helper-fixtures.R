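# shared fixtures, built in code

# two-allele locus with equal frequencies
biallelic_locus <- function(p = 0.5) {
  list(name = "BI", kind = "autosomal_str", alleles = c(10, 11),
       freqs = c(p, 1 - p))
}

# small multi-allele locus for exhaustive enumeration
enum_locus <- function(freqs = c(0.1, 0.2, 0.3, 0.4)) {
  list(name = "EN", kind = "autosomal_str",
       alleles = 10 + seq_along(freqs) - 1, freqs = freqs)
}

# standard 20 autosomal + 17 Y (+ optional X) panel used across tests
panel_freqs <- local({
  cache <- new.env()
  function(n_x = 0) {
    key <- paste0("x", n_x)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_frequency_set(20, 17, n_x,
                                             alleles_per_locus = 8,
                                             seed = 1901L)
    }
    cache[[key]]
  }
})

# all unordered genotypes of a locus spec as a 2-column matrix
all_genotypes <- function(sp) {
  g <- expand.grid(a = sp$alleles, b = sp$alleles)
  g <- g[g$a <= g$b, ]
  as.matrix(g)
}

# Hardy-Weinberg probability of an unordered genotype
hw_prob <- function(g, sp) {
  p <- sp$freqs[match(g, sp$alleles)]
  if (g[1] == g[2]) p[1]^2 else 2 * p[1] * p[2]
}

# independent textbook-formula kinship LR oracle (theta = 0):
# pattern-cased parent-child and identity indexes
textbook_lr <- function(g1, g2, k, sp) {
  p <- function(a) sp$freqs[match(a, sp$alleles)]
  g1 <- sort(g1); g2 <- sort(g2)
  hom1 <- g1[1] == g1[2]; hom2 <- g2[1] == g2[2]
  shared <- intersect(g1, g2)
  if (hom1 && hom2) {
    if (g1[1] == g2[1]) { x1 <- 1 / p(g1[1]); x2 <- 1 / p(g1[1])^2 }
    else { x1 <- 0; x2 <- 0 }
  } else if (hom1 && !hom2) {
    if (g1[1] %in% g2) { x1 <- 1 / (2 * p(g1[1])); x2 <- 0 }
    else { x1 <- 0; x2 <- 0 }
  } else if (!hom1 && hom2) {
    if (g2[1] %in% g1) { x1 <- 1 / (2 * p(g2[1])); x2 <- 0 }
    else { x1 <- 0; x2 <- 0 }
  } else {
    if (setequal(g1, g2)) {
      x1 <- (p(g1[1]) + p(g1[2])) / (4 * p(g1[1]) * p(g1[2]))
      x2 <- 1 / (2 * p(g1[1]) * p(g1[2]))
    } else if (length(shared) == 1L) {
      x1 <- 1 / (4 * p(shared)); x2 <- 0
    } else { x1 <- 0; x2 <- 0 }
  }
  unname(k[1] + k[2] * x1 + k[3] * x2)
}

# one-row index record from explicit genotypes (autosomal only)
record_row <- function(id, genotypes, freqs, role = "offender",
                       case_id = NA_character_, sex = "M") {
  loci <- unique(freqs$locus[freqs$kind == "autosomal_str"])
  df <- data.frame(record_id = id, role = role, case_id = case_id,
                   source_id = id, sex = sex, stringsAsFactors = FALSE)
  for (i in seq_along(loci)) {
    g <- sort(genotypes[[i]])
    df[[paste0(loci[i], "_1")]] <- g[1]
    df[[paste0(loci[i], "_2")]] <- g[2]
  }
  for (loc in unique(freqs$locus[freqs$kind == "y_str"])) {
    df[[loc]] <- NA_real_
  }
  for (loc in unique(freqs$locus[freqs$kind == "x_str"])) {
    df[[paste0(loc, "_1")]] <- NA_real_
    df[[paste0(loc, "_2")]] <- NA_real_
  }
  df$mt <- NA_character_
  df
}

# tiny frequency set with named autosomal loci for hand-built records
two_locus_freqs <- function() {
  frequency_set(data.frame(
    locus = rep(c("L1", "L2"), each = 2),
    kind = "autosomal_str",
    allele = c(10, 11, 10, 11),
    frequency = rep(0.5, 4)))
}
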