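# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no data files.

rc <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), ""),
         function(s) paste(rev(s), collapse = ""), "", USE.NAMES = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Non-stop codons for padding coding regions.
nonstop_codons <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

rand_orf_codons <- function(n) paste(sample(nonstop_codons, n, TRUE), collapse = "")

# Plant a gene into a contig (character string) at a given 1-based offset.
# `transcript` runs from the earliest candidate start through the stop codon,
# in transcript orientation; cand_local are 1-based candidate positions within
# it.  Returns the new contig plus genomic anchors.
plant_gene <- function(contig, at, transcript, cand_local, strand) {
  G <- nchar(transcript)
  insert <- if (strand == "+") transcript else rc(transcript)
  stopifnot(at + G - 1L <= nchar(contig))
  contig <- paste0(substring(contig, 1L, at - 1L), insert,
                   substring(contig, at + G))
  to_genomic <- function(l) if (strand == "+") at + l - 1L else at + G - l
  list(contig = contig,
       cand = vapply(cand_local, to_genomic, 0L),
       stop = to_genomic(G - 2L),
       span = c(at, at + G - 1L))
}

# A small two-gene fixture: one plus- and one minus-strand gene with two
# candidate starts each, on a 600 nt contig.  All anchors are derivable by
# the plant_gene arithmetic and verified in the tests.
toy_two_gene_fixture <- function(seed = 101L) {
  set.seed(seed)
  contig <- rand_dna(600L)
  tx_a <- paste0("ATG", "AAA", "GTG", rand_orf_codons(20L), "TAA")
  pa <- plant_gene(contig, at = 101L, tx_a, cand_local = c(1L, 7L), strand = "+")
  tx_b <- paste0("GTG", "CCC", "CCC", "TTG", rand_orf_codons(15L), "TGA")
  pb <- plant_gene(pa$contig, at = 350L, tx_b, cand_local = c(1L, 10L),
                   strand = "-")
  genome <- gmv_genome("toy", c(chr = pb$contig))
  list(genome = genome, tx_a = tx_a, tx_b = tx_b, a = pa, b = pb)
}

toy_calls_df <- function(fx) {
  data.frame(
    genome_id = "toy", gene_id = c("geneA", "geneB"), contig = "chr",
    strand = c("+", "-"),
    start = c(fx$a$cand[1L], fx$b$cand[1L]),
    stop = c(fx$a$stop, fx$b$stop),
    score = c(55.1, 48.2),
    alternatives = c(
      sprintf("%d:ATG:55.1;%d:GTG:40.0", fx$a$cand[1L], fx$a$cand[2L]),
      sprintf("%d:GTG:48.2;%d:TTG:31.5", fx$b$cand[1L], fx$b$cand[2L])
    ),
    stringsAsFactors = FALSE
  )
}

write_toy_calls <- function(fx, path) {
  df <- toy_calls_df(fx)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# ---------------------------------------------------------------------------
# Independent vote oracle: enumerate every column and apply the decision rule
# literally; returns the same shape as gmv_vote().
brute_vote <- function(chosen, alts, n_cols = max(c(unlist(alts), chosen))) {
  n <- length(chosen)
  if (length(unique(chosen)) == 1L)
    return(list(status = "already_consistent", consensus_col = chosen[1L],
                changed = rep(FALSE, n)))
  winners <- integer(0)
  votes <- integer(0)
  for (cc in seq_len(n_cols)) {
    v <- sum(chosen == cc)
    if (v * 2L <= n) next
    rest <- which(chosen != cc)
    if (all(vapply(rest, function(m) cc %in% alts[[m]], TRUE))) {
      winners <- c(winners, cc)
      votes <- c(votes, v)
    }
  }
  if (length(winners) == 0L)
    return(list(status = "inconsistent", consensus_col = NA_integer_,
                changed = rep(FALSE, n)))
  win <- winners[order(-votes, winners)][1L]
  list(status = "revised", consensus_col = win, changed = chosen != win)
}

brute_any_consistent <- function(columns, n_cols = NULL) {
  pools <- lapply(columns, function(m) unique(c(m$chosen_col, m$alt_cols)))
  if (is.null(n_cols)) n_cols <- max(unlist(pools))
  any(vapply(seq_len(n_cols), function(cc)
    all(vapply(pools, function(p) cc %in% p, TRUE)), TRUE))
}

# Random per-member start columns for property tests: a shared "true" column
# plus noise, so all three decision outcomes occur.
random_columns <- function(n, n_cols = 60L, p_true = 0.6) {
  true_col <- sample.int(n_cols, 1L)
  lapply(seq_len(n), function(i) {
    chosen <- if (runif(1) < p_true) true_col else sample.int(n_cols, 1L)
    extra <- sample.int(n_cols, sample(0:3, 1L))
    pool <- unique(c(chosen, if (runif(1) < 0.7) true_col, extra))
    list(chosen_col = chosen, alt_cols = pool)
  })
}

# ---------------------------------------------------------------------------
# Independent pan-RBH oracle: exhaustive search over all one-gene-per-genome
# tuples, requiring every ordered genome pair to be a unique mutual best hit.
brute_pan_rbh <- function(scores, genes_by_genome) {
  gids <- sort(names(genes_by_genome))
  all_genes <- unlist(genes_by_genome, use.names = FALSE)
  smat <- matrix(NA_real_, length(all_genes), length(all_genes),
                 dimnames = list(all_genes, all_genes))
  for (r in seq_len(nrow(scores))) {
    smat[scores$gene_id_a[r], scores$gene_id_b[r]] <- scores$norm_identity[r]
    smat[scores$gene_id_b[r], scores$gene_id_a[r]] <- scores$norm_identity[r]
  }
  unique_best <- function(gene, target_genome) {
    v <- smat[gene, genes_by_genome[[target_genome]]]
    if (all(is.na(v))) return(NA_character_)
    mx <- max(v, na.rm = TRUE)
    hits <- names(v)[!is.na(v) & abs(v - mx) < 1e-12]
    if (length(hits) == 1L) hits else NA_character_
  }
  tuples <- expand.grid(genes_by_genome[gids], stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  names(tuples) <- gids
  keep <- logical(nrow(tuples))
  for (t in seq_len(nrow(tuples))) {
    ok <- TRUE
    for (a in gids) {
      for (b in gids) {
        if (a == b) next
        h <- unique_best(tuples[[a]][t], b)
        if (is.na(h) || h != tuples[[b]][t]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    keep[t] <- ok
  }
  found <- tuples[keep, , drop = FALSE]
  # canonical representation: sorted "genome=gene" strings per tuple
  apply(found, 1L, function(r)
    paste(paste0(gids, "=", r[gids]), collapse = ";"), simplify = TRUE)
}

canonical_sets <- function(sets_obj) {
  tab <- sets_obj$sets
  gids <- sort(unique(tab$genome_id))
  vapply(split(tab, tab$set_id), function(st) {
    st <- st[order(st$genome_id), ]
    paste(paste0(st$genome_id, "=", st$gene_id), collapse = ";")
  }, "", USE.NAMES = FALSE)
}

# Random symmetric score tables with deliberate tie opportunities (scores on
# a coarse grid), for ortholog-assembly oracle tests.
random_score_table <- function(n_genomes, genes_per_genome, seed) {
  set.seed(seed)
  gids <- sprintf("G%d", seq_len(n_genomes))
  genes <- setNames(lapply(gids, function(g)
    sprintf("%s_g%d", g, seq_len(genes_per_genome))), gids)
  rows <- list()
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (i >= j) next
    for (a in genes[[i]]) for (b in genes[[j]]) {
      if (runif(1) < 0.25) next            # some pairs have no hit at all
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id_a = a, gene_id_b = b, genome_a = gids[i], genome_b = gids[j],
        pct_identity = NA_real_, aln_len = NA_integer_,
        len_a = NA_integer_, len_b = NA_integer_,
        norm_identity = sample(seq(30, 95, by = 5), 1L),
        stringsAsFactors = FALSE)
    }
  }
  list(scores = do.call(rbind, rows), genes = genes)
}

# Minimal decisions object for report tests (no sequences involved).
fake_decisions <- function(sets, members, reference = "ref") {
  structure(list(sets = sets, members = members, reference = reference,
                 mode = "standard"),
            class = "gmv_decisions")
}

# Row constructors for decision tables used in report tests.
mk_set_row <- function(set_id, status, consensus_col = NA_integer_,
                       any_consistent = TRUE, gold_start = NA_integer_,
                       gold_col = NA_integer_) {
  data.frame(set_id = set_id, status = status, consensus_col = consensus_col,
             n_changed = 0L, any_consistent = any_consistent,
             gold_start = gold_start, gold_col = gold_col,
             min_identity = NA_real_, mean_identity = NA_real_,
             stringsAsFactors = FALSE)
}

mk_member_row <- function(set_id, genome_id, status, old_start, new_start,
                          consensus_col = NA_integer_, old_codon = "ATG",
                          new_codon = "ATG") {
  data.frame(set_id = set_id, genome_id = genome_id,
             gene_id = paste0(genome_id, "_", set_id), contig = "chr",
             strand = "+", status = status, consensus_col = consensus_col,
             old_start = old_start, new_start = new_start,
             old_codon = old_codon, new_codon = new_codon,
             changed = old_start != new_start, stringsAsFactors = FALSE)
}

# Decisions carrying the published validation counts: GP=13 (11 TP),
# 2 FP, and 82 agreeing / 6 disagreeing cross-genome changes.
validation_fixture <- function() {
  sets <- list(); members <- list()
  add <- function(s, m) { sets[[length(sets) + 1L]] <<- s
                          members[[length(members) + 1L]] <<- m }
  for (i in 1:13) {
    id <- sprintf("gp%02d", i)
    changed <- i <= 11          # 11 corrected onto the validated start (TP)
    add(mk_set_row(id, if (changed) "revised" else "inconsistent",
                   consensus_col = 7L, gold_start = 100L, gold_col = 7L),
        mk_member_row(id, "ref", if (changed) "revised" else "inconsistent",
                      90L, if (changed) 100L else 90L, consensus_col = 7L))
  }
  for (i in 1:2) {
    id <- sprintf("fp%02d", i)
    add(mk_set_row(id, "revised", consensus_col = 9L,
                   gold_start = 100L, gold_col = 7L),
        mk_member_row(id, "ref", "revised", 100L, 110L, consensus_col = 9L))
  }
  # 41 sets whose consensus matches the validated column (2 changed
  # non-reference members each) and 3 that do not
  for (i in 1:44) {
    id <- sprintf("cx%02d", i)
    cc <- if (i <= 41) 7L else 9L
    add(mk_set_row(id, "revised", consensus_col = cc,
                   gold_start = 100L, gold_col = 7L),
        rbind(mk_member_row(id, "ref", "revised", 100L, 100L,
                            consensus_col = cc),
              mk_member_row(id, "gB", "revised", 90L, 95L, consensus_col = cc),
              mk_member_row(id, "gC", "revised", 90L, 95L, consensus_col = cc)))
  }
  fake_decisions(do.call(rbind, sets), do.call(rbind, members))
}
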