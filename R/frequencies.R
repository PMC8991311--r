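#' Allele-frequency sets
#'
#' A frequency set is the package's locus catalogue: one row per allele with
#' columns `locus`, `kind` (`autosomal_str`, `y_str` or `x_str`), `allele`
#' (canonical repeat-count label, see [canon_allele()]) and `frequency`.
#' Every kinship likelihood ratio and every Hardy-Weinberg draw is taken
#' against such a table. Mitochondrial types are opaque haplotype labels and
#' carry no frequency table.
#'
#' @param df data frame with columns `locus`, `kind`, `allele`, `frequency`.
#' @return validated frequency set (class `edim_freqs`).
#' @export
frequency_set <- function(df) {
  need <- c("locus", "kind", "allele", "frequency")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("frequency set is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[need]
  df$locus <- as.character(df$locus)
  df$kind <- as.character(df$kind)
  df$allele <- canon_allele(as.numeric(df$allele))
  df$frequency <- as.numeric(df$frequency)
  bad_kind <- setdiff(unique(df$kind), c("autosomal_str", "y_str", "x_str"))
  if (length(bad_kind)) {
    stop("unknown locus kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$frequency <= 0 | df$frequency > 1)) {
    stop("all frequencies must lie in (0, 1]", call. = FALSE)
  }
  for (loc in unique(df$locus)) {
    rows <- df[df$locus == loc, ]
    if (abs(sum(rows$frequency) - 1) > 1e-9) {
      stop(sprintf("frequencies at locus %s sum to %.12f, not 1",
                   loc, sum(rows$frequency)), call. = FALSE)
    }
    if (length(unique(rows$kind)) != 1L) {
      stop(sprintf("locus %s has inconsistent kind", loc), call. = FALSE)
    }
    if (rows$kind[1] == "autosomal_str" && nrow(rows) < 2L) {
      stop(sprintf("autosomal locus %s needs at least 2 alleles", loc),
           call. = FALSE)
    }
    if (anyDuplicated(rows$allele)) {
      stop(sprintf("duplicate allele at locus %s", loc), call. = FALSE)
    }
  }
  class(df) <- c("edim_freqs", "data.frame")
  df
}

#' Generate a synthetic allele-frequency set
#'
#' Builds `n_auto` autosomal, `n_y` Y-chromosome and `n_x` X-chromosome STR
#' loci, each with `alleles_per_locus` consecutive integer repeat alleles and
#' Dirichlet-distributed frequencies. Deterministic for a fixed seed.
#'
#' @param n_auto,n_y,n_x numbers of loci per marker system (each may be 0,
#'   but at least one locus overall is required).
#' @param alleles_per_locus alleles per locus (>= 2).
#' @param seed integer seed.
#' @return a [frequency_set()].
#' @examples
#' fs <- generate_frequency_set(4, 2, 1, alleles_per_locus = 6, seed = 1)
#' table(fs$kind) / 6
#' @export
generate_frequency_set <- function(n_auto, n_y = 0, n_x = 0,
                                   alleles_per_locus = 8, seed = 1L) {
  n_auto <- check_count(n_auto, "n_auto", min = 0L)
  n_y <- check_count(n_y, "n_y", min = 0L)
  n_x <- check_count(n_x, "n_x", min = 0L)
  if (n_auto + n_y + n_x < 1L) {
    stop("`n_auto` + `n_y` + `n_x` must be at least 1", call. = FALSE)
  }
  alleles_per_locus <- check_count(alleles_per_locus, "alleles_per_locus",
                                   min = 2L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  names <- c(sprintf("AUTO%02d", seq_len(n_auto)),
             sprintf("YSTR%02d", seq_len(n_y)),
             sprintf("XSTR%02d", seq_len(n_x)))
  kinds <- rep(c("autosomal_str", "y_str", "x_str"), c(n_auto, n_y, n_x))
  with_seed(seed, {
    rows <- lapply(seq_along(names), function(i) {
      base <- sample(6:20, 1)
      alleles <- base + seq_len(alleles_per_locus) - 1L
      w <- stats::rgamma(alleles_per_locus, shape = 2)
      data.frame(locus = names[i], kind = kinds[i],
                 allele = alleles, frequency = w / sum(w))
    })
    frequency_set(do.call(rbind, rows))
  })
}

# locus names of a given kind, in table order
freq_loci <- function(freqs, kind = NULL) {
  if (is.null(kind)) return(unique(freqs$locus))
  unique(freqs$locus[freqs$kind == kind])
}

# alleles (numeric) and frequencies for one locus
locus_spec <- function(freqs, locus) {
  rows <- freqs[freqs$locus == locus, ]
  if (!nrow(rows)) stop(sprintf("unknown locus: %s", locus), call. = FALSE)
  list(name = locus, kind = rows$kind[1],
       alleles = as.numeric(rows$allele), freqs = rows$frequency)
}

# frequency of numeric allele(s) at a locus; error if absent from the ladder
allele_freq <- function(spec, allele) {
  idx <- match(allele, spec$alleles)
  if (anyNA(idx[!is.na(allele)])) {
    bad <- allele[!is.na(allele) & is.na(idx)][1]
    stop(sprintf("allele %s is not in the frequency table for locus %s",
                 canon_allele(bad), spec$name), call. = FALSE)
  }
  spec$freqs[idx]
}

#' Read and write allele-frequency CSV files
#'
#' The on-disk dialect is one row per allele with columns
#' `locus,kind,allele,frequency`.
#'
#' @param path file path.
#' @param freqs a [frequency_set()].
#' @return `read_frequency_csv()` returns a frequency set;
#'   `write_frequency_csv()` returns `path` invisibly.
#' @export
read_frequency_csv <- function(path) {
  frequency_set(utils::read.csv(path, stringsAsFactors = FALSE,
                                colClasses = c(allele = "character")))
}

#' @rdname read_frequency_csv
#' @export
write_frequency_csv <- function(freqs, path) {
  utils::write.csv(as.data.frame(freqs), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
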