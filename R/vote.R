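## Step E: the majority-vote decision rule.
##
## A start column "wins" when strictly more than N/2 of the originally
## chosen starts sit in it and every remaining member has a caller-proposed
## alternative start in the same column (a member whose row is gapped at
## that column has no anchor there and so can never qualify).  Because the
## majority is strict, at most one column can ever qualify; the documented
## tie-break (most votes, then most upstream i.e. lowest column) is kept for
## generality.

vote_engine <- function(chosen, alts, n = length(chosen)) {
  stopifnot(length(alts) == length(chosen))
  if (length(unique(chosen)) == 1L) {
    return(list(status = "already_consistent", consensus_col = chosen[1L],
                changed = rep(FALSE, n)))
  }
  cand <- sort(unique(chosen))
  votes <- vapply(cand, function(cc) sum(chosen == cc), 0L)
  qual <- logical(length(cand))
  for (k in seq_along(cand)) {
    if (votes[k] * 2L <= n) next
    minority <- which(chosen != cand[k])
    qual[k] <- all(vapply(minority, function(m) cand[k] %in% alts[[m]], TRUE))
  }
  if (!any(qual)) {
    return(list(status = "inconsistent", consensus_col = NA_integer_,
                changed = rep(FALSE, n)))
  }
  qc <- cand[qual]; qv <- votes[qual]
  win <- qc[order(-qv, qc)][1L]
  list(status = "revised", consensus_col = win, changed = chosen != win)
}

#' Majority-vote decision for one ortholog set
#'
#' Applies the genome-majority-vote rule to the start columns of an aligned
#' ortholog set: if all chosen starts already share a column the set is
#' `already_consistent`; otherwise, if a column holds a strict majority of
#' the chosen starts and every remaining member has an alternative start in
#' that column, the minority members are reassigned there (`revised`);
#' otherwise the original calls are kept and the set is flagged
#' `inconsistent` (no start prediction is made for it, but nothing is
#' deleted).
#'
#' @param columns per-member start columns as produced by
#'   [anchor_columns()], or any list of `list(chosen_col=, alt_cols=)`
#' @return a `gmv_decision`: list with `status` one of
#'   `already_consistent`, `revised`, `inconsistent`; `consensus_col`; and
#'   per-member logical `changed`
#' @export
gmv_vote <- function(columns) {
  chosen <- vapply(columns, `[[`, 0L, "chosen_col")
  alts <- lapply(columns, `[[`, "alt_cols")
  res <- vote_engine(chosen, alts)
  res$members <- names(columns)
  class(res) <- "gmv_decision"
  res
}

#' Majority-vote in preserve mode
#'
#' Variant used to refine a curated (primary) gene map with the help of a
#' second, alternative-start-bearing call source: if the primary starts
#' already coincide, or no column holds a strict majority of them, nothing
#' is done; otherwise minority members are replaced by the alternative
#' source's start in the majority column -- and only if every minority
#' member has one there.
#'
#' @param primary_cols integer vector of primary (curated) start columns,
#'   one per member
#' @param alt_cols list (per member) of integer columns available from the
#'   alternative call source (its chosen start and its alternatives)
#' @return a `gmv_decision` (status `inconsistent` covers both the
#'   no-majority and the missing-alternative case; primaries are untouched)
#' @export
gmv_vote_preserve <- function(primary_cols, alt_cols) {
  res <- vote_engine(primary_cols, alt_cols)
  res$members <- names(primary_cols)
  class(res) <- "gmv_decision"
  res
}

#' Is any fully consistent start available?
#'
#' True when some alignment column carries a chosen or alternative start for
#' every member -- the theoretical ceiling on consistency regardless of the
#' majority rule.
#'
#' @inheritParams gmv_vote
#' @return logical flag
#' @export
has_consistent_start <- function(columns) {
  pools <- lapply(columns, function(m) unique(c(m$chosen_col, m$alt_cols)))
  length(Reduce(intersect, pools)) > 0L
}

#' @export
print.gmv_decision <- function(x, ...) {
  cat("<gmv_decision> ", x$status,
      if (!is.na(x$consensus_col)) paste0(" @ column ", x$consensus_col),
      "; ", sum(x$changed), " member(s) changed\n", sep = "")
  invisible(x)
}
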