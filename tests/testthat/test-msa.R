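test_that("alignable-sequence extraction handles windows, strands and edges", {
  fx <- toy_two_gene_fixture()
  tsv <- write_toy_calls(fx, tempfile(fileext = ".tsv"))
  calls <- read_gene_calls(tsv, fx$genome)

  # gene 100 nt from the contig start: window truncates at base 1
  exA <- extract_alignable(calls[1L, ], fx$genome, upstream = 250L)
  expect_true(exA$truncated)
  expect_equal(exA$win_start, 1L)
  expect_equal(exA$chosen_local, fx$a$cand[1L])  # earliest = chosen here
  expect_equal(nchar(exA$seq), fx$a$stop + 2L)

  # with the full window available, length = upstream + coding length
  exA30 <- extract_alignable(calls[1L, ], fx$genome, upstream = 30L)
  expect_false(exA30$truncated)
  coding_len <- fx$a$stop + 2L - fx$a$cand[1L] + 1L
  expect_equal(nchar(exA30$seq), 30L + coding_len)
  expect_equal(exA30$chosen_local, 31L)

  # minus strand: sequence is the reverse complement, chosen-start local
  # position = upstream window + offset of chosen beyond earliest alternative
  exB <- extract_alignable(calls[2L, ], fx$genome, upstream = 40L)
  ctg <- as.character(fx$genome$contigs[["chr"]])
  expect_equal(exB$seq, rc(substring(ctg, exB$win_start, exB$win_end)))
  expect_equal(exB$chosen_local, 41L)            # chosen == earliest
  expect_equal(unname(exB$alt_local[as.character(fx$b$cand[2L])]),
               41L + (fx$b$cand[1L] - fx$b$cand[2L]))
  # anchor positions recover the planted candidates through the local map
  expect_equal(sort(as.integer(names(exB$alt_local))), sort(fx$b$cand))
})

test_that("identical sequences align gap-free with coinciding anchor columns", {
  s <- rand_dna(80L)
  seqs <- setNames(rep(s, 3L), c("g1", "g2", "g3"))
  al <- align_ortholog_set(seqs, "s1")
  expect_false(any(grepl("-", al$rows, fixed = TRUE)))
  ext <- lapply(seqs, function(x) list(chosen_local = 21L,
                                       alt_local = c(`5` = 12L, `14` = 21L)))
  cols <- anchor_columns(al, ext)
  expect_true(length(unique(vapply(cols, `[[`, 0L, "chosen_col"))) == 1L)
})

test_that("a single 3 nt insertion produces one 3-column gap block in the others", {
  set.seed(33)
  base <- rand_dna(60L)
  withins <- paste0(substring(base, 1L, 30L), "TTT", substring(base, 31L))
  seqs <- c(g1 = base, g2 = withins, g3 = base)
  al <- align_ortholog_set(seqs, "s2")
  expect_equal(gsub("-", "", al$rows[["g1"]], fixed = TRUE), base)
  expect_equal(gsub("-", "", al$rows[["g2"]], fixed = TRUE), withins)
  gap_cols <- gregexpr("-+", al$rows[["g1"]])[[1L]]
  expect_equal(length(gap_cols), 1L)
  expect_equal(attr(gap_cols, "match.length"), 3L)
  expect_false(grepl("-", al$rows[["g2"]], fixed = TRUE))
})

test_that("starts homologous across an upstream indel share a column", {
  set.seed(8)
  up <- rand_dna(30L)
  cds <- paste0("ATG", rand_orf_codons(10L), "TAA")
  seq_full <- paste0(up, cds)
  seq_del <- paste0(substring(up, 1L, 10L), substring(up, 14L), cds) # 3nt gone
  seqs <- c(a = seq_full, b = seq_del, c = seq_full)
  al <- align_ortholog_set(seqs, "s3")
  ext <- list(a = list(chosen_local = 31L, alt_local = c(`1` = 31L)),
              b = list(chosen_local = 28L, alt_local = c(`1` = 28L)),
              c = list(chosen_local = 31L, alt_local = c(`1` = 31L)))
  cols <- anchor_columns(al, ext)
  cc <- vapply(cols, `[[`, 0L, "chosen_col")
  expect_equal(length(unique(cc)), 1L)
})

test_that("de-gapping and coordinate maps are exact inverses", {
  set.seed(12)
  for (trial in 1:10) {
    base <- rand_dna(70L)
    mut <- function(s) {
      v <- strsplit(s, "")[[1L]]
      i <- sample(length(v), 6L)
      v[i] <- sample(c("A", "C", "G", "T"), 6L, TRUE)
      if (runif(1) < 0.5) { # random short indel
        at <- sample(20:50, 1L)
        v <- append(v, sample(c("A","C","G","T"), 3L, TRUE), after = at)
      }
      paste(v, collapse = "")
    }
    seqs <- setNames(c(base, mut(base), mut(base)), c("x", "y", "z"))
    al <- align_ortholog_set(seqs, "p")
    for (id in names(seqs)) {
      expect_equal(gsub("-", "", al$rows[[id]], fixed = TRUE),
                   unname(seqs[[id]]))
      map <- al$maps[[id]]
      expect_equal(length(map), nchar(seqs[[id]]))
      expect_true(all(diff(map) > 0L))           # strictly increasing
      chars <- strsplit(al$rows[[id]], "")[[1L]]
      expect_true(all(chars[map] != "-"))        # anchors land on residues
    }
  }
})

test_that("the built-in aligner is deterministic", {
  set.seed(3)
  seqs <- setNames(c(rand_dna(50L), rand_dna(52L), rand_dna(50L)),
                   c("g1", "g2", "g3"))
  a1 <- align_ortholog_set(seqs, "d")
  a2 <- align_ortholog_set(seqs, "d")
  expect_identical(a1$rows, a2$rows)
})

test_that("precomputed-alignment adapter reproduces direct parsing", {
  rows <- c(g1 = "AC-GTACGT", g2 = "ACCGTACGT", g3 = "AC-GTAC-T")
  seqs <- vapply(rows, function(r) gsub("-", "", r, fixed = TRUE), "")
  af <- tempfile(fileext = ".afa")
  writeLines(paste0(">", names(rows), "\n", rows), af)
  a_file <- align_ortholog_set(seqs, "ad", backend = "precomputed", aligned = af)
  a_mem <- align_ortholog_set(seqs, "ad", backend = "precomputed", aligned = rows)
  expect_identical(a_file$rows, a_mem$rows)
  expect_identical(a_file$maps, a_mem$maps)
  # leading/internal gaps shift columns by the gap count
  ext <- list(g1 = list(chosen_local = 3L, alt_local = c(`9` = 3L)),
              g2 = list(chosen_local = 4L, alt_local = c(`9` = 4L)),
              g3 = list(chosen_local = 3L, alt_local = c(`9` = 3L)))
  cols <- anchor_columns(a_mem, ext)
  expect_equal(cols$g1$chosen_col, 4L)  # one gap before local position 3
  expect_equal(cols$g2$chosen_col, 4L)
  # a de-gap mismatch is rejected
  expect_error(align_ortholog_set(c(seqs[1:2], g3 = "AAAA"),
                                  backend = "precomputed", aligned = rows),
               "de-gap")
})

test_that("anchors outside the extracted window are reported by gene", {
  rows <- c(g1 = "ACGT", g2 = "ACGT")
  al <- align_ortholog_set(vapply(rows, identity, ""), "e",
                           backend = "precomputed", aligned = rows)
  ext <- list(g1 = list(chosen_local = 9L, alt_local = c(`1` = 9L)),
              g2 = list(chosen_local = 1L, alt_local = c(`1` = 1L)))
  expect_error(anchor_columns(al, ext), "g1")
})
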