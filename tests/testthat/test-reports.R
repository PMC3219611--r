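test_that("consistency report counts and denominators are correct", {
  statuses <- c(rep("already_consistent", 6L), rep("revised", 3L),
                "inconsistent")
  sets <- do.call(rbind, lapply(seq_along(statuses), function(i)
    mk_set_row(sprintf("s%02d", i), statuses[i],
               any_consistent = i <= 9L)))
  dec <- fake_decisions(sets, mk_member_row("s01", "ref",
                                            "already_consistent", 1L, 1L))
  cr <- consistency_report(dec)
  expect_equal(cr$total_sets, 10L)
  expect_equal(cr$initially_inconsistent, 4L)
  expect_equal(cr$initially_consistent, 6L)
  expect_equal(cr$made_consistent, 3L)
  expect_equal(cr$consistent_after, 9L)
  expect_equal(cr$any_consistent_possible, 9L)
  expect_equal(cr$initially_consistent + cr$initially_inconsistent,
               cr$total_sets)
  expect_equal(cr$consistent_after,
               cr$initially_consistent + cr$made_consistent)
  expect_equal(cr$pct_made_consistent, 75)

  # all sets already consistent
  sets2 <- do.call(rbind, lapply(1:4, function(i)
    mk_set_row(sprintf("t%d", i), "already_consistent")))
  cr2 <- consistency_report(fake_decisions(sets2, sets2[0, ]))
  expect_equal(cr2$made_consistent, 0L)
  expect_equal(cr2$consistent_after, cr2$total_sets)
})

test_that("published consistency arithmetic reproduces from the printed counts", {
  statuses <- c(rep("already_consistent", 1910L), rep("revised", 278L),
                rep("inconsistent", 2446L - 1910L - 278L))
  sets <- data.frame(set_id = sprintf("s%04d", seq_along(statuses)),
                     status = statuses, consensus_col = NA_integer_,
                     n_changed = 0L, any_consistent = NA,
                     gold_start = NA_integer_, gold_col = NA_integer_,
                     min_identity = NA_real_, mean_identity = NA_real_,
                     stringsAsFactors = FALSE)
  cr <- consistency_report(fake_decisions(sets, sets[0, ]))
  expect_equal(round(cr$pct_made_consistent, 1), 51.9)
  expect_equal(round(cr$pct_initially_inconsistent, 1), 21.9)
  yi <- yield_and_increase(c(a = 4282L, b = 4290L, c = 5000L, d = 4400L,
                             e = 4350L), cr)
  expect_equal(yi$M, 4282L)
  expect_equal(round(100 * yi$Y, 1), 57.1)
  expect_equal(round(100 * yi$I, 1), 11.4)
  # projection from these rates
  expect_equal(round(projected_consistent(yi$Y, yi$I, yi$M)), 278)
})

test_that("curated-map consistency increase reproduces the printed fraction", {
  statuses <- c(rep("revised", 746L), rep("inconsistent", 925L - 746L),
                rep("already_consistent", 2289L - 925L))
  sets <- data.frame(set_id = sprintf("s%04d", seq_along(statuses)),
                     status = statuses, consensus_col = NA_integer_,
                     n_changed = 0L, any_consistent = NA,
                     gold_start = NA_integer_, gold_col = NA_integer_,
                     min_identity = NA_real_, mean_identity = NA_real_,
                     stringsAsFactors = FALSE)
  cr <- consistency_report(fake_decisions(sets, sets[0, ]))
  yi <- yield_and_increase(c(x = 4282L, y = 4300L), cr)
  expect_equal(round(yi$I, 3), 0.326)
})

test_that("validation statistics reproduce the printed error and sensitivity", {
  dec <- validation_fixture()
  gold <- data.frame(contig = "chr", strand = "+", stop = 1L,
                     validated_start = 100L, key = "nokey",
                     stringsAsFactors = FALSE)
  vr <- validation_report(dec, gold)
  expect_equal(vr$GP, 13L)
  expect_equal(vr$TP, 11L)
  expect_equal(vr$FP, 2L)
  expect_equal(round(vr$E, 3), 0.154)
  expect_equal(round(vr$S, 3), 0.846)
  expect_equal(vr$cross_agree, 82L)
  expect_equal(vr$cross_disagree, 6L)
  expect_equal(round(vr$cross_error_rate, 2), 0.07)
})

test_that("undefined error rates honor the pseudo-count option", {
  sets <- mk_set_row("s1", "inconsistent", gold_start = 100L)
  members <- mk_member_row("s1", "ref", "inconsistent", 90L, 90L)
  dec <- fake_decisions(sets, members)
  gold <- data.frame(contig = "chr", strand = "+", stop = 1L,
                     validated_start = 100L, key = "k", stringsAsFactors = FALSE)
  vr <- validation_report(dec, gold)
  expect_true(is.na(vr$E))                           # TP = FP = 0
  vr2 <- validation_report(dec, gold, pseudo_count = TRUE)
  expect_equal(vr2$E, 1)                             # (0+1)/(0+0+1)
  # the published pseudo-count arithmetic: TP=1, FP=0 -> E = 0.5
  sets3 <- rbind(sets, mk_set_row("s2", "revised", consensus_col = 7L,
                                  gold_start = 100L, gold_col = 7L))
  members3 <- rbind(members,
                    mk_member_row("s2", "ref", "revised", 90L, 100L,
                                  consensus_col = 7L))
  vr3 <- validation_report(fake_decisions(sets3, members3), gold,
                           pseudo_count = TRUE)
  expect_equal(vr3$E, 0.5)
})

test_that("codon-change tallies count re-read codons with matrix identities", {
  dec <- fake_decisions(
    mk_set_row("s1", "revised", consensus_col = 3L),
    rbind(mk_member_row("s1", "g1", "revised", 10L, 22L,
                        old_codon = "ATG", new_codon = "GTG"),
          mk_member_row("s1", "g2", "revised", 10L, 10L),
          mk_member_row("s1", "g3", "revised", 14L, 26L,
                        old_codon = "TTG", new_codon = "TTG")))
  ccr <- codon_change_report(dec)
  expect_equal(ccr$total, 2L)
  expect_equal(unname(ccr$matrix["ATG", "GTG"]), 1L)
  expect_equal(unname(ccr$matrix["TTG", "TTG"]), 1L)
  expect_equal(ccr$same, 1L)
  expect_equal(ccr$different, 1L)
  expect_equal(ccr$same + ccr$different, ccr$total)
  # no revisions: empty matrix
  ccr0 <- codon_change_report(fake_decisions(
    mk_set_row("s1", "already_consistent"),
    mk_member_row("s1", "g1", "already_consistent", 10L, 10L)))
  expect_equal(ccr0$total, 0L)
})

test_that("diversity summaries use per-set minima and their median", {
  sets <- structure(list(
    sets = data.frame(), reference = "r",
    summary = data.frame(set_id = c("a", "b", "c"),
                         min_identity = c(70, 85.2, 90),
                         mean_identity = c(80, 90, 95))),
    class = "gmv_sets")
  dr <- diversity_report(sets)
  expect_equal(dr$median_min_identity, 85.2)
  expect_true(all(dr$per_set$min_identity <= dr$per_set$mean_identity))
  # identical genes: all identities 100
  sets$summary$min_identity <- sets$summary$mean_identity <- 100
  expect_equal(diversity_report(sets)$median_min_identity, 100)
})
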