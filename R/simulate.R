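## Synthetic genome-set generator.
##
## Emulates the generative assumptions behind the binomial error model: F
## ortholog families shared by N genomes derived from a common ancestor by
## independent per-site substitutions, each gene carrying a ladder of
## in-frame candidate start codons (ATG/GTG/TTG) that share one ORF, and
## predicted starts flipped to a wrong candidate independently with
## probability e.  Substitutions are suppressed at candidate start codons
## and at the stop codon, and substitutions that would create an in-frame
## stop within an ORF are reverted, so the truth stays well defined across
## genomes.  No indels are simulated; indel handling is exercised by the
## alignment fixtures instead.

NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, STOP_CODONS)
})

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Simulate a genome set with known start-site truth
#'
#' @param n_genomes number of genomes N (default 5)
#' @param n_families number of ortholog families F
#' @param divergence per-site substitution probability from the common
#'   ancestor (default 0.025, i.e. ~95% pairwise nucleotide identity)
#' @param e per-gene probability that the predicted start is wrong
#'   (default 0.05); must be < 0.5 for majority correction to make sense,
#'   values >= 0.5 draw a warning
#' @param alt_range integer range for the number of candidate starts per
#'   family (default 2..4; at least 2 whenever `e > 0`)
#' @param seed mandatory RNG seed; the same seed reproduces the simulation
#'   byte for byte
#' @return a `gmv_sim`: list with `genomes` (named list of `gmv_genome`),
#'   `calls` (named list of `gmv_calls`), `truth` (data.frame: family,
#'   genome_id, gene_id, contig, strand, true_start, predicted_start,
#'   error) and `config`
#' @export
simulate_gmv <- function(n_genomes = 5L, n_families = 200L,
                         divergence = 0.025, e = 0.05,
                         alt_range = c(2L, 4L), seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(n_genomes >= 2L, n_families >= 1L,
            divergence >= 0, divergence < 1, e >= 0, e <= 1,
            length(alt_range) == 2L, alt_range[1L] <= alt_range[2L])
  if (e >= 0.5)
    warning("e >= 0.5: majority correction is invalid in this regime")
  if (e > 0 && alt_range[1L] < 2L)
    stop("alt_range must allow at least 2 candidate starts when e > 0")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  genome_ids <- sprintf("genome%02d", seq_len(n_genomes))
  contig <- "chr"

  ## --- ancestor layout -----------------------------------------------------
  fam <- vector("list", n_families)
  chunks <- vector("list", 2L * n_families + 1L)
  chunks[[1L]] <- strsplit(paste(sample(c("A", "C", "G", "T"), 300L, TRUE),
                                 collapse = ""), "")[[1L]]
  cursor <- 300L
  for (f in seq_len(n_families)) {
    krng <- seq.int(alt_range[1L], alt_range[2L])
    k <- krng[sample.int(length(krng), 1L)]
    cand_codons <- sample(CANONICAL_STARTS, k, TRUE, prob = c(0.80, 0.12, 0.08))
    spacers <- if (k > 1L) sample(1:3, k - 1L, TRUE) else integer(0)
    core_len <- sample(60:120, 1L)
    core <- sample(NONSTOP_CODONS, core_len, TRUE)
    stop_codon <- sample(STOP_CODONS, 1L)
    codons <- character(0)
    cand_codon_idx <- integer(k)
    for (j in seq_len(k)) {
      cand_codon_idx[j] <- length(codons) + 1L
      codons <- c(codons, cand_codons[j])
      if (j < k) codons <- c(codons, sample(NONSTOP_CODONS, spacers[j], TRUE))
    }
    codons <- c(codons, core, stop_codon)
    gene <- strsplit(paste(codons, collapse = ""), "")[[1L]]
    G <- length(gene)
    strand <- sample(c("+", "-"), 1L)
    spacer_len <- sample(40:80, 1L)
    spacer <- sample(c("A", "C", "G", "T"), spacer_len, TRUE)
    offset <- cursor + spacer_len        # gene occupies offset+1 .. offset+G
    chunks[[2L * f]] <- spacer
    chunks[[2L * f + 1L]] <- if (strand == "+") gene else
      rev(unname(comp_base[gene]))
    cursor <- offset + G
    cand_local <- 3L * (cand_codon_idx - 1L) + 1L
    true_j <- sample(k, 1L)
    fam[[f]] <- list(k = k, G = G, strand = strand, offset = offset,
                     cand_local = cand_local, stop_local = G - 2L,
                     true_j = true_j)
  }
  tail_pad <- sample(c("A", "C", "G", "T"), 300L, TRUE)
  ancestor <- c(unlist(chunks, use.names = FALSE), tail_pad)
  L <- length(ancestor)

  to_genomic <- function(fm, local) {
    if (fm$strand == "+") fm$offset + local else fm$offset + fm$G - local + 1L
  }

  ## protection mask: candidate start codons and stop codons never mutate
  protected <- logical(L)
  for (f in seq_len(n_families)) {
    fm <- fam[[f]]
    for (l in c(fm$cand_local, fm$stop_local)) {
      g <- sort(c(to_genomic(fm, l), to_genomic(fm, l + 2L)))
      protected[g[1L]:g[2L]] <- TRUE
    }
  }

  ## --- per-genome mutation and calls ---------------------------------------
  genomes <- calls <- setNames(vector("list", n_genomes), genome_ids)
  truth_rows <- vector("list", n_genomes)
  others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (gi in seq_len(n_genomes)) {
    gseq <- ancestor
    mut <- which(runif(L) < divergence & !protected)
    if (length(mut)) {
      pick <- ceiling(runif(length(mut)) * 3)
      gseq[mut] <- mapply(function(b, p) others[[b]][p], ancestor[mut], pick,
                          USE.NAMES = FALSE)
    }
    # revert any substitution that created an in-frame stop within an ORF
    for (f in seq_len(n_families)) {
      fm <- fam[[f]]
      idx <- if (fm$strand == "+")
        seq.int(fm$offset + 1L, fm$offset + fm$G)
      else seq.int(fm$offset + fm$G, fm$offset + 1L)
      chars <- gseq[idx]
      if (fm$strand == "-") chars <- unname(comp_base[chars])
      cod <- matrix(chars, nrow = 3L)
      bad <- which(apply(cod, 2L, paste, collapse = "") %in% STOP_CODONS)
      bad <- bad[bad != ncol(cod)]          # the terminal stop codon is real
      for (b in bad) {
        pos <- idx[(3L * (b - 1L) + 1L):(3L * b)]
        gseq[pos] <- ancestor[pos]
      }
    }
    genome <- gmv_genome(genome_ids[gi],
                         setNames(paste(gseq, collapse = ""), contig))

    err <- runif(n_families) < e
    pred_j <- true_j <- vapply(fam, `[[`, 0L, "true_j")
    for (f in which(err)) {
      wrong <- setdiff(seq_len(fam[[f]]$k), true_j[f])
      pred_j[f] <- wrong[sample.int(length(wrong), 1L)]
    }
    gene_id <- sprintf("%s_f%05d", genome_ids[gi], seq_len(n_families))
    strand <- vapply(fam, `[[`, "", "strand")
    start <- stop_ <- integer(n_families)
    alts <- vector("list", n_families)
    true_start <- integer(n_families)
    for (f in seq_len(n_families)) {
      fm <- fam[[f]]
      cand_g <- vapply(fm$cand_local, function(l) to_genomic(fm, l), 0L)
      scores <- round(90 - 7 * seq_len(fm$k) + runif(fm$k), 2L)
      start[f] <- cand_g[pred_j[f]]
      stop_[f] <- to_genomic(fm, fm$stop_local)
      true_start[f] <- cand_g[fm$true_j]
      alts[[f]] <- data.frame(pos = cand_g, codon = NA_character_,
                              score = scores)
    }
    calls_g <- build_gene_calls(
      genome_id = rep(genome_ids[gi], n_families), gene_id = gene_id,
      contig = rep(contig, n_families), strand = strand,
      start = start, stop = stop_,
      score = vapply(seq_len(n_families),
                     function(f) alts[[f]]$score[pred_j[f]], 0),
      alternatives = alts, genome = genome)
    genomes[[gi]] <- genome
    calls[[gi]] <- calls_g
    truth_rows[[gi]] <- data.frame(
      family = seq_len(n_families), genome_id = genome_ids[gi],
      gene_id = gene_id, contig = contig, strand = strand,
      true_start = true_start, predicted_start = start,
      error = err, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  structure(list(genomes = genomes, calls = calls, truth = truth,
                 config = list(n_genomes = n_genomes, n_families = n_families,
                               divergence = divergence, e = e,
                               alt_range = alt_range, seed = seed)),
            class = "gmv_sim")
}

#' @export
print.gmv_sim <- function(x, ...) {
  cfg <- x$config
  cat("<gmv_sim> ", cfg$n_genomes, " genomes x ", cfg$n_families,
      " families; divergence ", cfg$divergence, ", start error rate ",
      cfg$e, ", seed ", cfg$seed, "\n", sep = "")
  cat("  planted errors: ", sum(x$truth$error), " / ", nrow(x$truth),
      " genes\n", sep = "")
  invisible(x)
}

#' Write a simulation to disk in the pipeline's input dialects
#'
#' @param sim `gmv_sim`
#' @param dir output directory (created if needed)
#' @return named list of file paths
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- calls <- character(length(sim$genomes))
  for (i in seq_along(sim$genomes)) {
    gid <- names(sim$genomes)[i]
    fasta[i] <- file.path(dir, paste0(gid, ".fasta"))
    Biostrings::writeXStringSet(sim$genomes[[i]]$contigs, fasta[i])
    calls[i] <- file.path(dir, paste0(gid, "_calls.tsv"))
    write_gene_calls(sim$calls[[i]], calls[i])
  }
  truth <- file.path(dir, "truth.tsv")
  write.table(sim$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, calls = calls, truth = truth)
}

#' Compare a pipeline run against the planted truth
#'
#' Scores every planted prediction error by whether the pipeline's final
#' start equals the true start, and every originally correct gene by
#' whether it was left intact, then sets the observed rates against the
#' closed-form model: the fraction of families with at least one error vs
#' `1-(1-e)^N` and the corrected-error fraction vs
#' `1 - E[majority errors]/E[errors]`.
#'
#' @param sim `gmv_sim`
#' @param run `gmv_run` obtained by running the pipeline on the simulated
#'   genomes and calls
#' @return one-row data.frame of observed and predicted quantities
#' @export
recovery_summary <- function(sim, run) {
  truth <- sim$truth
  mem <- run$decisions$members
  final <- truth$predicted_start
  m <- match(truth$gene_id, mem$gene_id)
  hit <- !is.na(m)
  final[hit] <- mem$new_start[m[hit]]
  corrected <- truth$error & final == truth$true_start
  broken <- !truth$error & final != truth$true_start
  fam_err <- tapply(truth$error, truth$family, any)
  cfg <- sim$config
  data.frame(
    n_genomes = cfg$n_genomes, n_families = cfg$n_families, e = cfg$e,
    genes_in_sets = sum(hit),
    planted_errors = sum(truth$error),
    frac_families_ge1_error = mean(fam_err),
    frac_errors_corrected = if (any(truth$error)) mean(corrected[truth$error]) else NA_real_,
    frac_correct_broken = mean(broken[!truth$error]),
    theory_ge1_error = p_at_least_one(cfg$n_genomes, cfg$e),
    theory_corrected = corrected_gene_fraction(cfg$n_genomes, cfg$e)
  )
}

#' Simulate, run the pipeline, and summarize recovery in one call
#'
#' @inheritParams simulate_gmv
#' @param ... passed to [run_gmv()]
#' @return list with `sim`, `run` and `summary` (from [recovery_summary()])
#' @export
end_to_end_recovery <- function(n_genomes = 5L, n_families = 200L,
                                divergence = 0.025, e = 0.05,
                                alt_range = c(2L, 4L), seed, ...) {
  sim <- simulate_gmv(n_genomes = n_genomes, n_families = n_families,
                      divergence = divergence, e = e,
                      alt_range = alt_range, seed = seed)
  run <- run_gmv(sim$genomes, sim$calls, ...)
  list(sim = sim, run = run, summary = recovery_summary(sim, run))
}
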