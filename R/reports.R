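## Evaluation statistics over vote decisions: consistency counts, validation
## against a gold standard, codon-change tallies, diversity summaries, and
## the yield / consistency-increase quantities used for projections.

voted_sets <- function(decisions) {
  decisions$sets[decisions$sets$status %in%
                   c("already_consistent", "revised", "inconsistent"), ,
                 drop = FALSE]
}

#' Consistency statistics for a set of vote decisions
#'
#' Counts mirror the standard consistency table: totals, initially
#' consistent / inconsistent sets, sets made consistent by the vote,
#' consistency after the vote, and the theoretical ceiling (sets with at
#' least one column where every member carries some start).  Percentages of
#' the total use the total set count as denominator, except
#' `pct_made_consistent`, which is relative to the initially inconsistent
#' count.
#'
#' @param decisions `gmv_decisions` from [decide_sets()]
#' @return one-row data.frame
#' @export
consistency_report <- function(decisions) {
  st <- voted_sets(decisions)
  total <- nrow(st)
  cons0 <- sum(st$status == "already_consistent")
  made <- sum(st$status == "revised")
  incons0 <- total - cons0
  after <- cons0 + made
  anyc <- sum(st$any_consistent, na.rm = TRUE)
  pct <- function(x, d) if (d > 0) 100 * x / d else NA_real_
  data.frame(
    total_sets = total,
    initially_inconsistent = incons0,
    initially_consistent = cons0,
    made_consistent = made,
    consistent_after = after,
    any_consistent_possible = anyc,
    pct_initially_inconsistent = pct(incons0, total),
    pct_initially_consistent = pct(cons0, total),
    pct_made_consistent = pct(made, incons0),
    pct_consistent_after = pct(after, total),
    pct_any_consistent = pct(anyc, total)
  )
}

#' Validation statistics against experimentally verified starts
#'
#' Reference scope scores the reference genome's own genes in gold-covered
#' sets: `GP` counts validated genes whose original start was wrong, `TP`
#' corrections onto the validated start, `FP` previously correct starts
#' moved away from it; `E = FP/(TP+FP)` and `S = TP/GP`.  Cross-genome
#' scope scores changes in the non-reference members of gold-covered sets
#' by whether the consensus column coincides with the validated start's
#' column in the reference row.
#'
#' @param decisions `gmv_decisions` (the run must have been given the gold
#'   standard so validated columns were recorded)
#' @param gold gold-standard data.frame from [read_gold_standard()]
#' @param pseudo_count when `TRUE` and no false positive was observed,
#'   report `E = (FP+1)/(TP+FP+1)` instead of an undefined/zero rate
#' @return one-row data.frame with GP, TP, FP, E, S, the change totals and
#'   the cross-genome agree/disagree counts and error rate
#' @export
validation_report <- function(decisions, gold, pseudo_count = FALSE) {
  sets <- voted_sets(decisions)
  mem <- decisions$members
  ref <- decisions$reference
  covered <- sets$set_id[!is.na(sets$gold_start)]
  rm_ <- mem[mem$genome_id == ref & mem$set_id %in% covered, , drop = FALSE]
  gold_start <- sets$gold_start[match(rm_$set_id, sets$set_id)]
  GP <- sum(rm_$old_start != gold_start)
  TP <- sum(rm_$changed & rm_$old_start != gold_start &
              rm_$new_start == gold_start)
  FP <- sum(rm_$changed & rm_$old_start == gold_start &
              rm_$new_start != gold_start)
  E <- if (TP + FP > 0) {
    if (pseudo_count && FP == 0) (FP + 1) / (TP + FP + 1) else FP / (TP + FP)
  } else if (pseudo_count) (FP + 1) / (TP + FP + 1) else NA_real_
  S <- if (GP > 0) TP / GP else NA_real_

  # cross-genome: changed non-reference members of covered sets, scored by
  # consensus column vs the validated start's column in the reference row
  cm <- mem[mem$changed & mem$genome_id != ref & mem$set_id %in% covered, ,
            drop = FALSE]
  gcol <- sets$gold_col[match(cm$set_id, sets$set_id)]
  agree <- sum(!is.na(gcol) & cm$consensus_col == gcol)
  disagree <- sum(!is.na(gcol) & cm$consensus_col != gcol)
  cross_E <- if (agree + disagree > 0) disagree / (agree + disagree) else NA_real_

  uncovered <- sum(!gold$key %in%
                     gene_key(mem[mem$genome_id == ref, , drop = FALSE]))
  data.frame(
    GP = GP, TP = TP, FP = FP, E = E, S = S,
    changes_reference = sum(mem$changed & mem$genome_id == ref),
    changes_total = sum(mem$changed),
    changes_nonreference = sum(mem$changed & mem$genome_id != ref),
    cross_agree = agree, cross_disagree = disagree,
    cross_error_rate = cross_E,
    gold_uncovered = uncovered
  )
}

#' Start-codon change statistics
#'
#' Tallies (codon before, codon after) over all members changed by the
#' vote; codons are the ones re-read from the genome sequence.  Canonical
#' codons get the 3x3 matrix of the usual table; anything else is counted
#' under "other".
#'
#' @param decisions `gmv_decisions`
#' @return list with `matrix` (4x4 including "other"), `total`, `same`,
#'   `different`
#' @export
codon_change_report <- function(decisions) {
  ch <- decisions$members[decisions$members$changed, , drop = FALSE]
  lv <- c(CANONICAL_STARTS, "other")
  old <- factor(ifelse(ch$old_codon %in% CANONICAL_STARTS, ch$old_codon, "other"),
                levels = lv)
  new <- factor(ifelse(ch$new_codon %in% CANONICAL_STARTS, ch$new_codon, "other"),
                levels = lv)
  m <- table(before = old, after = new)
  list(matrix = m, total = sum(m), same = sum(diag(m)),
       different = sum(m) - sum(diag(m)))
}

#' Sequence-diversity summary of ortholog sets
#'
#' Per-set minimum and mean normalized identity over all member pairs, and
#' the run-level median of the per-set minima (the usual single-number
#' diversity summary for a genome set).
#'
#' @param sets `gmv_sets`
#' @return list with `per_set` data.frame and `median_min_identity`
#' @export
diversity_report <- function(sets) {
  s <- sets$summary
  stopifnot(all(s$min_identity <= s$mean_identity + 1e-9, na.rm = TRUE))
  list(per_set = s,
       median_min_identity = median(s$min_identity, na.rm = TRUE))
}

#' Ortholog-set yield and consistency increase
#'
#' `M` is the maximum possible number of ortholog sets (the smallest
#' per-genome gene count), `O` the number actually obtained, `Y = O/M` the
#' yield, and `I` the consistency increase -- sets made consistent by the
#' vote as a fraction of `O`.
#'
#' @param gene_counts named integer vector: genes per genome
#' @param consistency one-row data.frame from [consistency_report()]
#' @return one-row data.frame with M, O, Y, I
#' @export
yield_and_increase <- function(gene_counts, consistency) {
  M <- min(gene_counts)
  O <- consistency$total_sets
  data.frame(M = M, O = O, Y = O / M,
             I = if (O > 0) consistency$made_consistent / O else NA_real_)
}
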