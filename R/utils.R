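#' Round half away from zero
#'
#' Rounding used for displayed business-case figures, where ties go up
#' (2.5 -> 3) rather than to even as in [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                 name, min, deparse(x)), call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1] (got %s)",
                 name, deparse(x)), call. = FALSE)
  }
  as.numeric(x)
}

check_pos <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number (got %s)",
                 name, deparse(x)), call. = FALSE)
  }
  as.numeric(x)
}

#' Canonical allele label
#'
#' Allele labels are decimal repeat counts rendered as text with trailing
#' zeros stripped, so `9.30` and `9.3` compare equal and `10.0` prints as
#' `10`. Comparison throughout the package is on the numeric repeat count;
#' this canonical text form is used in all files.
#'
#' @param x numeric repeat counts.
#' @return character vector of canonical labels.
#' @export
canon_allele <- function(x) {
  out <- sub("0+$", "", sub("\\.$", "", formatC(x, format = "f", digits = 4)))
  out <- sub("\\.$", "", out)
  out[is.na(x)] <- NA_character_
  out
}

# multiset equality of two unordered allele pairs (vectorised on c1/c2)
pair_equal <- function(a1, a2, c1, c2) {
  (a1 == c1 & a2 == c2) | (a1 == c2 & a2 == c1)
}

# multiset intersection size of pair {a1,a2} with pairs {c1,c2} (vectorised)
pair_shared <- function(a1, a2, c1, c2) {
  ifelse(a1 == c1, 1 + (a2 == c2),
    ifelse(a1 == c2, 1 + (a2 == c1),
      (a2 == c1) + (a2 == c2)))
}

# minimal union-find for key-group connected components
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in edges) {
      ri <- find(e[1]); rj <- find(e[2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}
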