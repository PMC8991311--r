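#' Profile records and indexes
#'
#' A profile index is a data frame with one row per record: metadata
#' columns `record_id`, `role` (`offender`, `arrestee`, `forensic`,
#' `uhr`), `case_id` (forensic and unidentified-remains records),
#' `source_id` (the true source individual, retained for evaluation
#' against simulated ground truth), `sex`, followed by genotype columns:
#' `<locus>_1`/`<locus>_2` for each autosomal and X locus, `<locus>` for
#' each Y locus, and `mt`. A set of indexes (class `edim_indexes`) bundles
#' the four role indexes with their frequency set.
#'
#' @name profile-indexes
NULL

meta_cols <- c("record_id", "role", "case_id", "source_id", "sex")

genotype_cols <- function(freqs) {
  a <- freq_loci(freqs, "autosomal_str")
  y <- freq_loci(freqs, "y_str")
  x <- freq_loci(freqs, "x_str")
  c(as.vector(rbind(paste0(a, "_1"), paste0(a, "_2"))), y,
    if (length(x)) as.vector(rbind(paste0(x, "_1"), paste0(x, "_2"))),
    "mt")
}

# build an empty index with the right columns
empty_index <- function(freqs) {
  cols <- c(meta_cols, genotype_cols(freqs))
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (cn in setdiff(genotype_cols(freqs), "mt")) df[[cn]] <- numeric(0)
  df
}

# records for the given individuals of a population
records_for <- function(pop, ids, role, record_id, case_id = NA_character_) {
  ind <- pop$individuals
  i <- match(ids, ind$id)
  df <- data.frame(record_id = record_id, role = role, case_id = case_id,
                   source_id = ids, sex = ind$sex[i],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(pop$auto[i, , drop = FALSE]))
  if (ncol(pop$y)) df <- cbind(df, as.data.frame(pop$y[i, , drop = FALSE]))
  if (ncol(pop$x)) df <- cbind(df, as.data.frame(pop$x[i, , drop = FALSE]))
  df$mt <- unname(pop$mt[ids])
  rownames(df) <- NULL
  df
}

new_indexes <- function(offender, arrestee, forensic, uhr, freqs) {
  ids <- c(offender$record_id, arrestee$record_id, forensic$record_id,
           uhr$record_id)
  if (anyDuplicated(ids)) {
    stop("record ids must be unique across all indexes", call. = FALSE)
  }
  structure(list(offender = offender, arrestee = arrestee,
                 forensic = forensic, uhr = uhr, freqs = freqs),
            class = "edim_indexes")
}

#' @export
print.edim_indexes <- function(x, ...) {
  cat(sprintf(
    "profile indexes: %d offender, %d arrestee, %d forensic, %d UHR\n",
    nrow(x$offender), nrow(x$arrestee), nrow(x$forensic), nrow(x$uhr)))
  invisible(x)
}

# record id of a one-row record (or list profile)
profile_id <- function(p) {
  if (is.data.frame(p)) return(p$record_id[1])
  if (!is.null(p$record_id)) return(p$record_id)
  "profile"
}

# 1 x 2A matrix of autosomal genotypes in frequency-set locus order
auto_genotypes <- function(p, freqs) {
  loci <- freq_loci(freqs, "autosomal_str")
  cols <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  if (is.data.frame(p)) {
    miss <- setdiff(cols, names(p))
    if (length(miss)) {
      stop("profile lacks genotype column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    return(matrix(as.numeric(p[1, cols]), 1,
                  dimnames = list(NULL, cols)))
  }
  m <- matrix(NA_real_, 1, length(cols), dimnames = list(NULL, cols))
  for (loc in intersect(names(p$auto), loci)) {
    g <- sort(as.numeric(p$auto[[loc]]))
    m[1, paste0(loc, c("_1", "_2"))] <- g
  }
  m
}

#' Membership sampling configuration
#'
#' Controls how simulated individuals enter the offender, forensic and
#' unidentified-human-remains indexes. Each individual enters each role
#' independently with the stated probability; first-degree relatives
#' (parents, children, siblings) of individuals already included in a role
#' are then re-drawn with their inclusion odds multiplied by
#' `familial_enrichment`, reflecting the clustering of database membership
#' within families. Forensic entries carry a case id and record their true
#' source individual so that downstream lead classification can be scored
#' against the simulation's ground truth.
#'
#' @param offender_fraction,forensic_fraction,uhr_fraction per-individual
#'   inclusion probabilities.
#' @param familial_enrichment odds multiplier >= 1 for first-degree
#'   relatives of included individuals (1 = independent inclusion).
#' @param seed integer seed.
#' @return a `membership_config` list.
#' @export
membership_config <- function(offender_fraction = 0.05,
                              forensic_fraction = 0.02,
                              uhr_fraction = 0.002,
                              familial_enrichment = 1,
                              seed = 1L) {
  cfg <- list(offender_fraction = check_prob(offender_fraction,
                                             "offender_fraction"),
              forensic_fraction = check_prob(forensic_fraction,
                                             "forensic_fraction"),
              uhr_fraction = check_prob(uhr_fraction, "uhr_fraction"),
              familial_enrichment = check_pos(familial_enrichment,
                                              "familial_enrichment"),
              seed = check_count(seed, "seed", min = -.Machine$integer.max))
  if (cfg$familial_enrichment < 1) {
    stop("`familial_enrichment` must be >= 1", call. = FALSE)
  }
  class(cfg) <- "membership_config"
  cfg
}

# first-degree relatives (parents, children, full/half siblings) of `ids`
first_degree <- function(ind, ids) {
  i <- match(ids, ind$id)
  parents <- c(ind$father_id[i], ind$mother_id[i])
  children <- ind$id[(!is.na(ind$father_id) & ind$father_id %in% ids) |
                       (!is.na(ind$mother_id) & ind$mother_id %in% ids)]
  key_f <- ind$father_id[i]; key_m <- ind$mother_id[i]
  sib <- ind$id[(!is.na(ind$father_id) & ind$father_id %in% key_f[!is.na(key_f)]) |
                  (!is.na(ind$mother_id) & ind$mother_id %in% key_m[!is.na(key_m)])]
  setdiff(unique(c(parents[!is.na(parents)], children, sib)), ids)
}

#' Assign database memberships to a simulated population
#'
#' Samples offender, forensic and unidentified-remains membership per
#' [membership_config()]. Deterministic for a fixed seed. The arrestee
#' index is created empty; it shares the offender index's role in every
#' search and can be populated by callers that need the distinction.
#'
#' @param pop an `edim_population`.
#' @param mcfg a [membership_config()].
#' @return an `edim_indexes` object.
#' @export
assign_memberships <- function(pop, mcfg) {
  if (!inherits(mcfg, "membership_config")) {
    stop("`mcfg` must be a membership_config()", call. = FALSE)
  }
  ind <- pop$individuals
  if (!nrow(ind)) stop("population is empty", call. = FALSE)
  with_seed(mcfg$seed, {
    draw_role <- function(p) {
      inc <- stats::runif(nrow(ind)) < p
      if (mcfg$familial_enrichment > 1 && any(inc) && p > 0 && p < 1) {
        rel <- first_degree(ind, ind$id[inc])
        rel <- setdiff(rel, ind$id[inc])
        if (length(rel)) {
          odds <- p / (1 - p) * mcfg$familial_enrichment
          p2 <- min(odds / (1 + odds), 1)
          j <- match(rel, ind$id)
          inc[j] <- stats::runif(length(j)) < p2
        }
      }
      ind$id[inc]
    }
    off_ids <- draw_role(mcfg$offender_fraction)
    for_ids <- draw_role(mcfg$forensic_fraction)
    uhr_ids <- draw_role(mcfg$uhr_fraction)
    offender <- if (length(off_ids)) {
      records_for(pop, off_ids, "offender", paste0("K-", off_ids))
    } else empty_index(pop$freqs)
    forensic <- if (length(for_ids)) {
      records_for(pop, for_ids, "forensic", paste0("F-", for_ids),
                  case_id = sprintf("case-%04d", seq_along(for_ids)))
    } else empty_index(pop$freqs)
    uhr <- if (length(uhr_ids)) {
      records_for(pop, uhr_ids, "uhr", paste0("U-", uhr_ids),
                  case_id = sprintf("uhr-%04d", seq_along(uhr_ids)))
    } else empty_index(pop$freqs)
    new_indexes(offender, empty_index(pop$freqs), forensic, uhr, pop$freqs)
  })
}

#' Two-brother worked fixture
#'
#' Builds the canonical two-full-brothers scenario used throughout the
#' package's documentation and tests: brothers with identical Y-STR
#' haplotypes have each left a forensic profile in a separate sexual
#' assault case; exactly one of them ("Bob") also has a known offender
#' profile from an earlier conviction, so his case resolves directly while
#' his brother's ("Doug") can only be reached indirectly through the shared
#' Y haplotype and a sibling kinship evaluation.
#'
#' @param seed integer seed (profiles are reproducible for a fixed seed).
#' @return list with elements `pop` (an `edim_population` of two parents
#'   and two sons) and `indexes` (offender entry for Bob; forensic entries
#'   for both brothers' cases).
#' @export
make_bob_doug_fixture <- function(seed = 2024L) {
  fs <- generate_frequency_set(20, 17, 4, alleles_per_locus = 8,
                               seed = 1901L)
  cfg <- population_config(1, 2, mean_children = 2, twin_rate = 0,
                           mut_auto = 0, mut_y = 0, mut_mt = 0,
                           loci = fs, seed = seed)
  # redraw until the founder couple has two sons
  pop <- NULL
  for (s in seed + 0:200) {
    cfg$seed <- check_count(s, "seed")
    cand <- suppressWarnings(simulate_population(cfg))
    kids <- cand$individuals[cand$individuals$generation == 2L, ]
    if (sum(kids$sex == "M") >= 2L) {
      keep <- c(cand$individuals$id[cand$individuals$generation == 1L],
                kids$id[kids$sex == "M"][1:2])
      cand$individuals <- cand$individuals[cand$individuals$id %in% keep, ]
      cand$auto <- cand$auto[keep, , drop = FALSE]
      cand$y <- cand$y[keep, , drop = FALSE]
      cand$x <- cand$x[keep, , drop = FALSE]
      cand$mt <- cand$mt[keep]
      pop <- cand
      break
    }
  }
  sons <- pop$individuals$id[pop$individuals$generation == 2L]
  bob <- sons[1]; doug <- sons[2]
  offender <- records_for(pop, bob, "offender", "K-BOB")
  forensic <- rbind(
    records_for(pop, bob, "forensic", "F-BOB", case_id = "case-bob"),
    records_for(pop, doug, "forensic", "F-DOUG", case_id = "case-doug"))
  idx <- new_indexes(offender, empty_index(fs), forensic,
                     empty_index(fs), fs)
  list(pop = pop, indexes = idx, bob = bob, doug = doug)
}

# ---- file I/O ------------------------------------------------------------

fmt_cell <- function(x) {
  if (is.numeric(x)) ifelse(is.na(x), ".", canon_allele(x))
  else ifelse(is.na(x), ".", as.character(x))
}

#' Write and read a genotype TSV
#'
#' One row per record; metadata columns then genotype columns (a column
#' pair per autosomal and X locus, one column per Y locus, one `mt`
#' column). Missing values are written as `.`. Reading validates every
#' genotype column against the frequency set and reports the offending
#' record, locus and line on failure.
#'
#' @param index a profile index data frame.
#' @param path file path.
#' @param freqs a [frequency_set()].
#' @return `read_genotypes_tsv()` returns an index data frame;
#'   `write_genotypes_tsv()` returns `path` invisibly.
#' @export
write_genotypes_tsv <- function(index, path, freqs) {
  cols <- c(meta_cols, genotype_cols(freqs))
  out <- index[, cols, drop = FALSE]
  for (cn in cols) out[[cn]] <- fmt_cell(out[[cn]])
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path, freqs) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  expect <- c(meta_cols, genotype_cols(freqs))
  extra <- setdiff(names(raw), expect)
  if (length(extra)) {
    stop("genotype file has column(s) for unknown loci: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(expect, names(raw))
  if (length(miss)) {
    stop("genotype file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw[raw == "."] <- NA
  if (!nrow(raw)) return(empty_index(freqs))
  num_cols <- setdiff(genotype_cols(freqs), "mt")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(!is.na(raw[[cn]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed allele '%s' in column %s at line %d",
                   raw[[cn]][bad[1]], cn, bad[1] + 1L), call. = FALSE)
    }
    raw[[cn]] <- v
  }
  # validate alleles against the locus ladders
  for (loc in freq_loci(freqs)) {
    sp <- locus_spec(freqs, loc)
    cns <- intersect(c(loc, paste0(loc, c("_1", "_2"))), names(raw))
    for (cn in cns) {
      vals <- raw[[cn]]
      bad <- which(!is.na(vals) & !(vals %in% sp$alleles))
      if (length(bad)) {
        stop(sprintf(
          "record %s: allele %s is not in the frequency table for locus %s",
          raw$record_id[bad[1]], canon_allele(vals[bad[1]]), loc),
          call. = FALSE)
      }
    }
  }
  raw
}

#' Save and load a full index set
#'
#' Writes the frequency CSV plus one genotype TSV per role into a
#' directory; loading the directory reproduces an equal structure
#' (round-trip stable).
#'
#' @param indexes an `edim_indexes` object.
#' @param dir directory path (created if needed).
#' @return `load_indexes()` returns an `edim_indexes`; `save_indexes()`
#'   returns `dir` invisibly.
#' @export
save_indexes <- function(indexes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frequency_csv(indexes$freqs, file.path(dir, "frequencies.csv"))
  for (role in c("offender", "arrestee", "forensic", "uhr")) {
    write_genotypes_tsv(indexes[[role]], file.path(dir, paste0(role, ".tsv")),
                        indexes$freqs)
  }
  invisible(dir)
}

#' @rdname save_indexes
#' @export
load_indexes <- function(dir) {
  freqs <- read_frequency_csv(file.path(dir, "frequencies.csv"))
  idx <- lapply(c("offender", "arrestee", "forensic", "uhr"), function(role) {
    read_genotypes_tsv(file.path(dir, paste0(role, ".tsv")), freqs)
  })
  new_indexes(idx[[1]], idx[[2]], idx[[3]], idx[[4]], freqs)
}

#' Write and read lead reports
#'
#' Lead reports (see [run_edim()]) are written as JSON lines
#' (`format = "jsonl"`, one object per report, round-trip stable) or CSV.
#' Field order is fixed, so output is deterministic for identical input.
#'
#' @param reports lead-report data frame from [run_edim()].
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `read_lead_reports()` returns the report data frame;
#'   `write_lead_reports()` returns `path` invisibly.
#' @export
write_lead_reports <- function(reports, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  cols <- lead_report_cols
  reports <- reports[, cols, drop = FALSE]
  if (format == "csv") {
    utils::write.csv(reports, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(reports)) {
      for (i in seq_len(nrow(reports))) {
        writeLines(jsonlite::toJSON(as.list(reports[i, ]),
                                    auto_unbox = TRUE, digits = NA,
                                    na = "null"), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_lead_reports
#' @export
read_lead_reports <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    out[out == ""] <- NA
  } else {
    lines <- readLines(path)
    if (!length(lines)) {
      out <- as.data.frame(setNames(
        rep(list(character(0)), length(lead_report_cols)),
        lead_report_cols), stringsAsFactors = FALSE)
    } else {
      rows <- lapply(lines, function(l) {
        x <- jsonlite::fromJSON(l)
        x[vapply(x, is.null, logical(1))] <- NA
        as.data.frame(x, stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
    }
  }
  if (nrow(out) && "log10_lr" %in% names(out)) {
    out$log10_lr <- as.numeric(out$log10_lr)
  }
  out
}

lead_report_cols <- c("case_id", "record_id", "outcome", "matched_record",
                      "anchor_case", "key_kind", "log10_lr", "notes")
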