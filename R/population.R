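#' Population simulation configuration
#'
#' Collects the parameters of the multi-generation population simulator.
#' Founders are drawn under Hardy-Weinberg from the frequency set; children
#' receive one autosomal allele from each parent, sons copy their father's
#' Y-STR haplotype, all children copy their mother's mitochondrial type, and
#' males carry a single maternally inherited X allele per locus. Each birth
#' becomes an identical (monozygotic) twin pair with probability
#' `twin_rate`; twins are profile clones. STR mutation is symmetric
#' single-step (one repeat up or down, reflecting at the ends of the allele
#' ladder); mitochondrial mutation replaces the haplotype label with a fresh
#' one.
#'
#' @param n_founder_couples number of founding couples (generation 1).
#' @param n_generations total number of generations including founders.
#' @param mean_children mean of the Poisson offspring-count distribution per
#'   couple (default 2.2).
#' @param twin_rate probability that a birth is an identical-twin pair;
#'   default 1/250, the approximate human incidence of monozygotic twinning.
#' @param mut_auto,mut_y per-locus, per-meiosis single-step mutation
#'   probability for autosomal/X and Y STRs (defaults 0.002, typical of
#'   forensic STR loci).
#' @param mut_mt per-meiosis probability that the mitochondrial label is
#'   replaced by a fresh one (default 0.001).
#' @param loci a [frequency_set()].
#' @param seed integer seed; the same seed and configuration reproduce the
#'   population exactly.
#' @return a `population_config` list.
#' @export
population_config <- function(n_founder_couples, n_generations,
                              mean_children = 2.2, twin_rate = 1 / 250,
                              mut_auto = 0.002, mut_y = 0.002,
                              mut_mt = 0.001, loci, seed = 1L) {
  cfg <- list(
    n_founder_couples = check_count(n_founder_couples, "n_founder_couples"),
    n_generations = check_count(n_generations, "n_generations"),
    mean_children = check_pos(mean_children, "mean_children"),
    twin_rate = check_prob(twin_rate, "twin_rate"),
    mut_auto = check_prob(mut_auto, "mut_auto"),
    mut_y = check_prob(mut_y, "mut_y"),
    mut_mt = check_prob(mut_mt, "mut_mt"),
    loci = if (inherits(loci, "edim_freqs")) loci else frequency_set(loci),
    seed = check_count(seed, "seed", min = -.Machine$integer.max))
  class(cfg) <- "population_config"
  cfg
}

# single-step mutation on an allele ladder: +/-1 position, reflecting at ends
step_mutate <- function(values, ladder, hit) {
  idx <- match(values, ladder)
  n <- length(ladder)
  up <- stats::runif(length(values)) < 0.5
  new_idx <- idx + ifelse(up, 1L, -1L)
  new_idx[new_idx < 1L] <- 2L
  new_idx[new_idx > n] <- n - 1L
  values[hit] <- ladder[new_idx[hit]]
  values
}

#' Simulate a multi-generation population
#'
#' Generates founders under Hardy-Weinberg and breeds `n_generations - 1`
#' further generations under Mendelian transmission with stepwise mutation
#' and identical twinning (see [population_config()]). Couples are formed by
#' random male-female pairing within a generation, with a best-effort
#' reshuffle to avoid full-sibling matings. Each founder receives a unique
#' mitochondrial label.
#'
#' @param config a [population_config()].
#' @return an `edim_population`: a list with `individuals` (id, sex,
#'   father_id, mother_id, twin_group, generation), allele matrices `auto`
#'   (two columns per autosomal locus), `y`, `x` (two columns per X locus;
#'   males carry one), `mt` (named character vector), and the frequency set.
#' @examples
#' fs <- generate_frequency_set(3, 2, 1, alleles_per_locus = 5, seed = 1)
#' pop <- simulate_population(population_config(10, 3, loci = fs, seed = 2))
#' nrow(pop$individuals)
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "population_config")) {
    stop("`config` must be a population_config()", call. = FALSE)
  }
  freqs <- config$loci
  a_loci <- freq_loci(freqs, "autosomal_str")
  y_loci <- freq_loci(freqs, "y_str")
  x_loci <- freq_loci(freqs, "x_str")
  with_seed(config$seed, {
    n0 <- 2L * config$n_founder_couples
    sex <- rep(c("M", "F"), config$n_founder_couples)
    ids <- sprintf("I%06d", seq_len(n0))
    auto <- hw_draw(freqs, a_loci, n0, 2L)
    y <- hw_draw(freqs, y_loci, n0, 1L)
    if (length(y_loci)) y[sex == "F", ] <- NA_real_
    x <- hw_draw(freqs, x_loci, n0, 2L)
    if (length(x_loci)) x[sex == "M", seq_along(x_loci) * 2L] <- NA_real_
    mt <- sprintf("MT%06d", seq_len(n0))
    ind <- data.frame(id = ids, sex = sex, father_id = NA_character_,
                      mother_id = NA_character_, twin_group = NA_character_,
                      generation = 1L, stringsAsFactors = FALSE)
    rownames(auto) <- rownames(y) <- rownames(x) <- ids
    names(mt) <- ids
    counter <- n0
    mt_counter <- n0
    gen_ids <- ids
    for (g in seq_len(config$n_generations - 1L) + 1L) {
      gsex <- ind$sex[match(gen_ids, ind$id)]
      males <- gen_ids[gsex == "M"]
      females <- gen_ids[gsex == "F"]
      nc <- min(length(males), length(females))
      if (nc == 0L) {
        warning(sprintf(
          "lineage extinct at generation %d; returning truncated population",
          g), call. = FALSE)
        break
      }
      fa <- sample(males)[seq_len(nc)]
      mo <- sample(females)[seq_len(nc)]
      # best-effort full-sib mating avoidance
      sibs <- function(f, m) {
        pf <- ind$father_id[match(f, ind$id)]
        pm <- ind$father_id[match(m, ind$id)]
        !is.na(pf) & !is.na(pm) & pf == pm
      }
      for (try in 1:10) {
        bad <- which(sibs(fa, mo))
        if (!length(bad)) break
        for (b in bad) {
          j <- sample.int(nc, 1L)
          tmp <- mo[b]; mo[b] <- mo[j]; mo[j] <- tmp
        }
      }
      n_births <- stats::rpois(nc, config$mean_children)
      if (sum(n_births) == 0L) {
        warning(sprintf(
          "lineage extinct at generation %d; returning truncated population",
          g), call. = FALSE)
        break
      }
      b_fa <- rep(fa, n_births)
      b_mo <- rep(mo, n_births)
      nb <- length(b_fa)
      twin <- stats::runif(nb) < config$twin_rate
      csex <- sample(c("M", "F"), nb, replace = TRUE)
      c_auto <- child_auto(auto, b_fa, b_mo, a_loci, freqs, config$mut_auto)
      c_y <- child_y(y, b_fa, csex, y_loci, freqs, config$mut_y)
      c_x <- child_x(x, b_fa, b_mo, csex, x_loci, freqs, config$mut_auto)
      c_mt <- mt[b_mo]
      mut_hit <- stats::runif(nb) < config$mut_mt
      if (any(mut_hit)) {
        c_mt[mut_hit] <- sprintf("MT%06d", mt_counter + seq_len(sum(mut_hit)))
        mt_counter <- mt_counter + sum(mut_hit)
      }
      c_ids <- sprintf("I%06d", counter + seq_len(nb))
      counter <- counter + nb
      tg <- rep(NA_character_, nb)
      if (any(twin)) tg[twin] <- paste0("TW-", c_ids[twin])
      # clone twin co-siblings
      if (any(twin)) {
        w <- which(twin)
        t_ids <- sprintf("I%06d", counter + seq_along(w))
        counter <- counter + length(w)
        c_ids <- c(c_ids, t_ids)
        b_fa <- c(b_fa, b_fa[w]); b_mo <- c(b_mo, b_mo[w])
        csex <- c(csex, csex[w]); tg <- c(tg, tg[w])
        c_auto <- rbind(c_auto, c_auto[w, , drop = FALSE])
        c_y <- rbind(c_y, c_y[w, , drop = FALSE])
        c_x <- rbind(c_x, c_x[w, , drop = FALSE])
        c_mt <- c(c_mt, c_mt[w])
      }
      rownames(c_auto) <- rownames(c_y) <- rownames(c_x) <- c_ids
      names(c_mt) <- c_ids
      ind <- rbind(ind, data.frame(
        id = c_ids, sex = csex, father_id = b_fa, mother_id = b_mo,
        twin_group = tg, generation = g, stringsAsFactors = FALSE))
      auto <- rbind(auto, c_auto)
      y <- rbind(y, c_y)
      x <- rbind(x, c_x)
      mt <- c(mt, c_mt)
      gen_ids <- c_ids
    }
    structure(list(individuals = ind, auto = auto, y = y, x = x, mt = mt,
                   freqs = freqs, config = config),
              class = "edim_population")
  })
}

# Hardy-Weinberg draw of `copies` alleles per locus for n individuals
hw_draw <- function(freqs, loci, n, copies) {
  m <- matrix(NA_real_, n, length(loci) * copies)
  cn <- character(0)
  for (i in seq_along(loci)) {
    sp <- locus_spec(freqs, loci[i])
    for (j in seq_len(copies)) {
      col <- (i - 1L) * copies + j
      m[, col] <- sample(sp$alleles, n, replace = TRUE, prob = sp$freqs)
    }
    cn <- c(cn, if (copies == 2L) paste0(loci[i], c("_1", "_2"))
            else loci[i])
  }
  colnames(m) <- cn
  m
}

child_auto <- function(auto, fa, mo, loci, freqs, mut) {
  n <- length(fa)
  m <- matrix(NA_real_, n, length(loci) * 2L)
  colnames(m) <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  fi <- match(fa, rownames(auto)); mi <- match(mo, rownames(auto))
  for (i in seq_along(loci)) {
    sp <- locus_spec(freqs, loci[i])
    c1 <- (i - 1L) * 2L + 1L
    pf <- ifelse(stats::runif(n) < 0.5, auto[fi, c1], auto[fi, c1 + 1L])
    pm <- ifelse(stats::runif(n) < 0.5, auto[mi, c1], auto[mi, c1 + 1L])
    pf <- step_mutate(pf, sp$alleles, stats::runif(n) < mut)
    pm <- step_mutate(pm, sp$alleles, stats::runif(n) < mut)
    m[, c1] <- pf
    m[, c1 + 1L] <- pm
  }
  m
}

child_y <- function(y, fa, csex, loci, freqs, mut) {
  n <- length(fa)
  m <- matrix(NA_real_, n, length(loci))
  if (!length(loci)) return(m)
  colnames(m) <- loci
  fi <- match(fa, rownames(y))
  for (i in seq_along(loci)) {
    sp <- locus_spec(freqs, loci[i])
    v <- step_mutate(y[fi, i], sp$alleles, stats::runif(n) < mut)
    m[, i] <- ifelse(csex == "M", v, NA_real_)
  }
  m
}

child_x <- function(x, fa, mo, csex, loci, freqs, mut) {
  n <- length(fa)
  m <- matrix(NA_real_, n, length(loci) * 2L)
  if (!length(loci)) return(m)
  colnames(m) <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  fi <- match(fa, rownames(x)); mi <- match(mo, rownames(x))
  for (i in seq_along(loci)) {
    sp <- locus_spec(freqs, loci[i])
    c1 <- (i - 1L) * 2L + 1L
    # maternal allele: one of the mother's two X copies, per locus
    pm <- ifelse(stats::runif(n) < 0.5, x[mi, c1], x[mi, c1 + 1L])
    pm <- step_mutate(pm, sp$alleles, stats::runif(n) < mut)
    # paternal X goes to daughters only
    pf <- step_mutate(x[fi, c1], sp$alleles, stats::runif(n) < mut)
    m[, c1] <- pm
    m[, c1 + 1L] <- ifelse(csex == "F", pf, NA_real_)
  }
  m
}

#' @export
print.edim_population <- function(x, ...) {
  cat(sprintf(
    "edim population: %d individuals, %d generations, %d/%d/%d A/Y/X loci\n",
    nrow(x$individuals), max(x$individuals$generation),
    length(freq_loci(x$freqs, "autosomal_str")),
    length(freq_loci(x$freqs, "y_str")),
    length(freq_loci(x$freqs, "x_str"))))
  invisible(x)
}

#' Write a pedigree as PED-like text
#'
#' One line per individual: `family_id individual_id father_id mother_id
#' sex`, space separated, `0` for a missing parent, sex coded 1 = male,
#' 2 = female. All individuals are written under one family id.
#'
#' @param pop an `edim_population`.
#' @param path output file.
#' @param family_id family identifier (default `"FAM1"`).
#' @return `path`, invisibly.
#' @export
write_ped <- function(pop, path, family_id = "FAM1") {
  ind <- pop$individuals
  lines <- sprintf("%s %s %s %s %d", family_id, ind$id,
                   ifelse(is.na(ind$father_id), "0", ind$father_id),
                   ifelse(is.na(ind$mother_id), "0", ind$mother_id),
                   ifelse(ind$sex == "M", 1L, 2L))
  writeLines(lines, path)
  invisible(path)
}

# Mendelian-consistency walk used by tests: TRUE when every child allele
# matches a parental allele within `steps` ladder steps at every locus
mendel_consistent <- function(pop, steps = 0L) {
  ind <- pop$individuals
  kids <- ind[!is.na(ind$father_id), ]
  if (!nrow(kids)) return(TRUE)
  a_loci <- freq_loci(pop$freqs, "autosomal_str")
  ki <- match(kids$id, rownames(pop$auto))
  fi <- match(kids$father_id, rownames(pop$auto))
  mi <- match(kids$mother_id, rownames(pop$auto))
  ok <- TRUE
  near <- function(a, b1, b2) {
    (abs(a - b1) <= steps) | (abs(a - b2) <= steps)
  }
  for (i in seq_along(a_loci)) {
    c1 <- (i - 1L) * 2L + 1L
    pat <- near(pop$auto[ki, c1], pop$auto[fi, c1], pop$auto[fi, c1 + 1L])
    mat <- near(pop$auto[ki, c1 + 1L], pop$auto[mi, c1],
                pop$auto[mi, c1 + 1L])
    ok <- ok && all(pat & mat)
  }
  ok
}
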