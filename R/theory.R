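## Closed-form binomial error model of majority-vote start correction, and
## the projection formulas for consistency and correction rates.

check_Ne <- function(N, e) {
  if (length(N) != 1L || N < 1 || N != round(N)) stop("N must be a positive integer")
  if (length(e) != 1L || e < 0 || e > 1) stop("e must be a probability")
}

#' Probability of exactly i erroneous starts among N orthologs
#'
#' Under the reference model -- each ortholog's start is called wrongly with
#' independent probability `e` -- the number of errors in a set of `N`
#' orthologs is binomial.
#'
#' @param i number of errors (0..N), vectorized
#' @param N number of orthologs in the set
#' @param e per-gene start-call error probability
#' @return probability (vector)
#' @export
p_errors <- function(i, N, e) {
  check_Ne(N, e)
  if (any(i < 0 | i > N | i != round(i))) stop("i must be in 0..N")
  dbinom(i, N, e)
}

#' Probability of at least one erroneous start in the set
#'
#' `1 - (1-e)^N`: how often an ortholog set is expected to look inconsistent
#' purely through prediction error.
#'
#' @inheritParams p_errors
#' @export
p_at_least_one <- function(N, e) {
  check_Ne(N, e)
  1 - (1 - e)^N
}

#' Probability that a majority of the orthologs are erroneous
#'
#' Sum of the binomial mass over the strict majority, i > N/2.  This is the
#' regime in which a majority vote cannot rescue the set.
#'
#' @inheritParams p_errors
#' @export
p_majority_error <- function(N, e) {
  check_Ne(N, e)
  i <- seq_len(N)
  sum(dbinom(i[i > N / 2], N, e))
}

#' Expected number of erroneous starts per ortholog set
#'
#' Over all error counts this is the binomial mean `N e`; restricted to
#' strict-majority error counts it is the expected number of errors the vote
#' cannot correct.
#'
#' @inheritParams p_errors
#' @param restrict_to_majority sum `i p_i` only over `i > N/2`
#' @export
expected_errors <- function(N, e, restrict_to_majority = FALSE) {
  check_Ne(N, e)
  i <- 0:N
  if (restrict_to_majority) i <- i[i > N / 2]
  sum(i * dbinom(i, N, e))
}

#' Expected fraction of erroneous genes corrected by the vote
#'
#' Errors in minority position are corrected; errors in strict-majority
#' position are not:
#' `1 - E[errors | majority restricted] / E[errors]`.
#'
#' @inheritParams p_errors
#' @export
corrected_gene_fraction <- function(N, e) {
  if (e == 0) return(1)
  1 - expected_errors(N, e, TRUE) / expected_errors(N, e, FALSE)
}

#' Projected number of ortholog sets made consistent
#'
#' `n_I = Y * I * M`, where `Y` is the ortholog-set yield (sets obtained per
#' maximum possible), `I` the measured consistency increase as a fraction of
#' actual sets, and `M` the maximum possible number of sets (the minimum
#' per-genome gene count).
#'
#' @param Y yield, fraction in `[0, 1]`
#' @param I consistency increase, fraction in `[0, 1]`
#' @param M maximum possible number of ortholog sets
#' @export
projected_consistent <- function(Y, I, M) {
  stopifnot(Y >= 0, Y <= 1, I >= 0, I <= 1, M >= 0)
  Y * I * M
}

#' Per-genome correction rate
#'
#' `R = C / (M N)`: total start-site changes divided by genomes times the
#' maximum possible number of ortholog sets.
#'
#' @param C total number of start-site changes across the genome set
#' @param M maximum possible number of ortholog sets
#' @param N number of genomes
#' @export
correction_rate <- function(C, M, N) {
  stopifnot(C >= 0, M > 0, N >= 1)
  C / (M * N)
}

#' Model table for a given (N, e)
#'
#' Convenience summary of the closed-form error model.
#'
#' @inheritParams p_errors
#' @return one-row data.frame
#' @export
theory_table <- function(N, e) {
  data.frame(
    N = N, e = e,
    p_at_least_one = p_at_least_one(N, e),
    p_majority_error = p_majority_error(N, e),
    expected_errors = expected_errors(N, e),
    expected_errors_majority = expected_errors(N, e, TRUE),
    corrected_gene_fraction = corrected_gene_fraction(N, e)
  )
}
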