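## End-to-end orchestration: calls -> pair scores -> ortholog sets ->
## alignments -> vote decisions -> revised maps + reports.  Every stage can
## also be run separately from its predecessor's on-disk artifact; the
## pipeline proper contains no randomness.

## Batched alignment of many ortholog sets.  All pairwise alignments across
## all sets go through a small number of vectorized calls; sets whose
## pairwise alignments are gap-free (the common case for closely related
## genomes) skip the star merge entirely.
align_sets_batch <- function(seq_sets, chunk = 20000L) {
  ns <- length(seq_sets)
  if (ns == 0L) return(list())
  sizes <- lengths(seq_sets)
  np <- sizes * (sizes - 1L) / 2L
  set_of_pair <- rep.int(seq_len(ns), np)
  pa <- pb <- character(sum(np))
  pos <- 0L
  for (s in seq_len(ns)) {
    cmb <- utils::combn(sizes[s], 2L)
    idx <- pos + seq_len(ncol(cmb))
    pa[idx] <- seq_sets[[s]][cmb[1L, ]]
    pb[idx] <- seq_sets[[s]][cmb[2L, ]]
    pos <- pos + ncol(cmb)
  }
  gapfree <- logical(length(pa))
  for (lo in seq(1L, length(pa), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(pa))
    aln <- align_nt_pairs(pa[lo:hi], pb[lo:hi])
    gapfree[lo:hi] <- lengths(Biostrings::insertion(aln)) == 0L &
      lengths(Biostrings::deletion(aln)) == 0L
  }
  trivial <- vapply(split(gapfree, set_of_pair), all, TRUE)[as.character(seq_len(ns))]
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    out[[s]] <- if (trivial[s] && length(unique(nchar(seq_sets[[s]]))) == 1L)
      new_alignment(names(seq_sets)[s], seq_sets[[s]])
    else
      align_ortholog_set(seq_sets[[s]], set_id = names(seq_sets)[s])
  }
  names(out) <- names(seq_sets)
  out
}

#' Vote on every ortholog set and assemble the decisions table
#'
#' Runs Steps D and E for each ortholog set: extracts upstream-extended
#' member sequences, aligns them, maps start anchors to columns, applies the
#' majority vote, and converts the consensus column back to genomic anchors
#' and codons (codons are re-read from the genome sequence, never copied
#' from the calls file).
#'
#' @param sets `gmv_sets` from [ortholog_sets()]
#' @param calls_by_genome named list of `gmv_calls`
#' @param genomes named list of `gmv_genome`
#' @param upstream upstream window in bp (default 250)
#' @param gold optional gold standard from [read_gold_standard()]; adds
#'   validated-start columns for sets whose reference member is covered
#' @param mode `"standard"` or `"preserve"`
#' @param primary_by_genome for `mode = "preserve"`: named list of curated
#'   primary `gmv_calls`, matched to the alternative-source calls by
#'   (contig, strand, stop)
#' @return a `gmv_decisions` object: list with `members` (one row per set
#'   member) and `sets` (one row per set) data.frames
#' @export
decide_sets <- function(sets, calls_by_genome, genomes, upstream = 250L,
                        gold = NULL, mode = c("standard", "preserve"),
                        primary_by_genome = NULL) {
  mode <- match.arg(mode)
  if (mode == "preserve" && is.null(primary_by_genome))
    stop("preserve mode needs primary_by_genome")
  all_calls <- do.call(rbind, lapply(unname(calls_by_genome),
                                     function(x) as.data.frame(x)))
  set_tab <- sets$sets
  set_ids <- unique(set_tab$set_id)
  reference <- sets$reference
  genomes <- lapply(genomes, cache_genome)
  member_idx <- match(set_tab$gene_id, all_calls$gene_id)
  if (anyNA(member_idx)) stop("ortholog set references unknown gene_id")
  krows_by_set <- split(member_idx, set_tab$set_id)[set_ids]

  primary_lookup <- NULL
  if (mode == "preserve") {
    pl <- do.call(rbind, lapply(unname(primary_by_genome), function(x)
      data.frame(genome_id = x$genome_id, key = gene_key(x),
                 start = x$start, stringsAsFactors = FALSE)))
    primary_lookup <- setNames(pl$start, paste(pl$genome_id, pl$key))
  }

  # per set: member call rows and extracted sequences
  rows_by_set <- split(set_tab, set_tab$set_id)[set_ids]
  extracts <- vector("list", length(set_ids))
  seq_sets <- vector("list", length(set_ids))
  skip <- logical(length(set_ids))
  for (s in seq_along(set_ids)) {
    st <- rows_by_set[[s]]
    krows <- krows_by_set[[s]]
    ex <- vector("list", nrow(st))
    for (m in seq_len(nrow(st))) {
      k <- krows[m]
      cl <- list(contig = all_calls$contig[k], strand = all_calls$strand[k],
                 start = all_calls$start[k], stop = all_calls$stop[k],
                 alternatives = all_calls$alternatives[k])
      ex[[m]] <- extract_alignable(cl, genomes[[st$genome_id[m]]], upstream)
    }
    names(ex) <- st$genome_id
    extracts[[s]] <- ex
    seq_sets[[s]] <- vapply(ex, `[[`, "", "seq")
    if (mode == "preserve") {
      keys <- paste(st$genome_id,
                    gene_key(all_calls[krows, , drop = FALSE]))
      if (any(!keys %in% names(primary_lookup))) skip[s] <- TRUE
    }
  }
  names(seq_sets) <- set_ids
  alignments <- align_sets_batch(seq_sets[!skip])

  member_rows <- vector("list", length(set_ids))
  set_rows <- vector("list", length(set_ids))
  for (s in seq_along(set_ids)) {
    st <- rows_by_set[[s]]
    krows <- krows_by_set[[s]]
    if (skip[s]) {
      set_rows[[s]] <- data.frame(set_id = set_ids[s], status = "no_primary",
                                  consensus_col = NA_integer_, n_changed = 0L,
                                  any_consistent = NA, gold_start = NA_integer_,
                                  gold_col = NA_integer_,
                                  stringsAsFactors = FALSE)
      next
    }
    alnm <- alignments[[set_ids[s]]]
    cols <- anchor_columns(alnm, extracts[[s]])

    if (mode == "standard") {
      dec <- gmv_vote(cols)
      old_start <- all_calls$start[krows]
      pools <- cols
    } else {
      keys <- paste(st$genome_id, gene_key(all_calls[krows, , drop = FALSE]))
      old_start <- unname(primary_lookup[keys])
      prim_cols <- integer(nrow(st))
      ok <- TRUE
      for (m in seq_len(nrow(st))) {
        ext <- extracts[[s]][[m]]
        loc <- if (ext$strand == "+") old_start[m] - ext$win_start + 1L
               else ext$win_end - old_start[m] + 1L
        map <- alnm$maps[[m]]
        if (loc < 1L || loc > length(map)) { ok <- FALSE; break }
        prim_cols[m] <- map[loc]
      }
      if (!ok) {
        dec <- list(status = "inconsistent", consensus_col = NA_integer_,
                    changed = rep(FALSE, nrow(st)))
      } else {
        dec <- gmv_vote_preserve(setNames(prim_cols, st$genome_id),
                                 lapply(cols, function(m)
                                   unique(c(m$chosen_col, m$alt_cols))))
      }
      pools <- cols
    }

    new_start <- old_start
    new_codon <- old_codon <- character(nrow(st))
    for (m in seq_len(nrow(st))) {
      k <- krows[m]
      ctg <- contig_string(genomes[[st$genome_id[m]]], all_calls$contig[k])
      old_codon[m] <- codon_at(ctg, old_start[m], all_calls$strand[k])
      if (dec$changed[m]) {
        ac <- pools[[m]]$alt_cols
        hit <- names(ac)[ac == dec$consensus_col]
        stopifnot(length(hit) >= 1L)
        new_start[m] <- as.integer(hit[1L])
        new_codon[m] <- codon_at(ctg, new_start[m], all_calls$strand[k])
      } else new_codon[m] <- old_codon[m]
    }

    gold_start <- gold_col <- NA_integer_
    if (!is.null(gold) && reference %in% st$genome_id) {
      m <- which(st$genome_id == reference)
      k <- krows[m]
      gkey <- gene_key(all_calls[k, , drop = FALSE])
      gm <- match(gkey, gold$key)
      if (!is.na(gm)) {
        gold_start <- gold$validated_start[gm]
        ext <- extracts[[s]][[m]]
        loc <- if (ext$strand == "+") gold_start - ext$win_start + 1L
               else ext$win_end - gold_start + 1L
        map <- alnm$maps[[m]]
        if (loc >= 1L && loc <= length(map)) gold_col <- map[loc]
      }
    }

    member_rows[[s]] <- data.frame(
      set_id = set_ids[s], genome_id = st$genome_id, gene_id = st$gene_id,
      contig = all_calls$contig[krows], strand = all_calls$strand[krows],
      status = dec$status, consensus_col = dec$consensus_col,
      old_start = old_start, new_start = new_start,
      old_codon = old_codon, new_codon = new_codon,
      changed = dec$changed, stringsAsFactors = FALSE, row.names = NULL)
    set_rows[[s]] <- data.frame(
      set_id = set_ids[s], status = dec$status,
      consensus_col = dec$consensus_col, n_changed = sum(dec$changed),
      any_consistent = has_consistent_start(cols),
      gold_start = gold_start, gold_col = gold_col,
      stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, member_rows)
  if (is.null(members))
    members <- data.frame(set_id = character(0), genome_id = character(0),
                          gene_id = character(0), contig = character(0),
                          strand = character(0), status = character(0),
                          consensus_col = integer(0), old_start = integer(0),
                          new_start = integer(0), old_codon = character(0),
                          new_codon = character(0), changed = logical(0),
                          stringsAsFactors = FALSE)
  setdf <- do.call(rbind, set_rows)
  sm <- match(setdf$set_id, sets$summary$set_id)
  setdf$min_identity <- sets$summary$min_identity[sm]
  setdf$mean_identity <- sets$summary$mean_identity[sm]
  structure(list(members = members, sets = setdf, reference = reference,
                 mode = mode),
            class = "gmv_decisions")
}

#' @export
print.gmv_decisions <- function(x, ...) {
  tb <- table(x$sets$status)
  cat("<gmv_decisions> ", nrow(x$sets), " ortholog set(s): ",
      paste(names(tb), as.integer(tb), sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write / read the member-level decisions TSV
#' @param decisions `gmv_decisions`
#' @param path output path
#' @export
write_decisions <- function(decisions, path) {
  write.table(decisions$members, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_decisions
#' @export
write_set_decisions <- function(decisions, path) {
  write.table(decisions$sets, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read the ortholog-set TSV
#' @param sets `gmv_sets`
#' @param path output path
#' @export
write_ortholog_sets <- function(sets, path) {
  df <- sets$sets
  m <- match(df$set_id, sets$summary$set_id)
  df$min_identity <- sets$summary$min_identity[m]
  df$reference <- sets$reference
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_sets
#' @export
read_ortholog_sets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  summ <- unique(df[c("set_id", "min_identity")])
  summ$mean_identity <- NA_real_
  structure(list(sets = df[c("set_id", "genome_id", "gene_id")],
                 summary = summ, reference = df$reference[1L]),
            class = "gmv_sets")
}

#' Run the full genome-majority-vote pipeline
#'
#' Orchestrates all stages: pairwise protein identities, pan-reciprocal
#' best-hit ortholog sets, per-set multiple alignment, the majority vote,
#' revised GFF3 maps and the standard reports.  The pipeline is
#' deterministic; per-stage artifacts are written when `outdir` is given so
#' any stage can be re-run separately from its predecessor's output.
#'
#' @param genomes named list of `gmv_genome` objects, or character vector of
#'   FASTA paths
#' @param calls named list of `gmv_calls`, or character vector of calls-TSV
#'   paths (parallel to `genomes`)
#' @param reference reference genome id
#' @param floor minimum normalized identity for ortholog candidate pairs
#'   (percent)
#' @param upstream upstream window in bp
#' @param gold optional gold-standard data.frame or TSV path
#' @param mode `"standard"` or `"preserve"`
#' @param primary for `mode = "preserve"`: named list of curated `gmv_calls`
#'   or TSV paths
#' @param outdir optional output directory for stage artifacts
#' @param scores optional precomputed pair-score table (skips the alignment
#'   backend)
#' @param ... passed to [pair_scores()]
#' @return a `gmv_run`: list with `scores`, `sets`, `decisions`, `reports`
#'   and the run parameters
#' @export
run_gmv <- function(genomes, calls, reference = NULL, floor = 30,
                    upstream = 250L, gold = NULL,
                    mode = c("standard", "preserve"), primary = NULL,
                    outdir = NULL, scores = NULL, ...) {
  mode <- match.arg(mode)
  if (is.character(genomes))
    genomes <- lapply(genomes, read_genome_fasta)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  if (length(genomes) < 2L) stop("need at least two genomes")
  if (is.character(calls))
    calls <- lapply(seq_along(calls), function(i)
      read_gene_calls(calls[i], genomes[[i]]))
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    names(calls) <- vapply(calls, function(x) x$genome_id[1L], "")
  stopifnot(setequal(names(genomes), names(calls)))
  if (is.character(gold)) gold <- read_gold_standard(gold)
  if (mode == "preserve" && is.character(primary))
    primary <- lapply(seq_along(primary), function(i)
      read_gene_calls(primary[i], genomes[[i]]))
  if (!is.null(primary) && (is.null(names(primary)) || any(!nzchar(names(primary)))))
    names(primary) <- vapply(primary, function(x) x$genome_id[1L], "")

  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scores))
    scores <- pair_scores(calls, floor = floor, ...)
  if (!is.null(outdir)) write_pair_scores(scores, file.path(outdir, "pair_scores.tsv"))

  sets <- ortholog_sets(scores, calls, reference = reference)
  if (nrow(sets$sets) == 0L)
    warning("ortholog inference yielded no sets; decisions will be empty")
  if (!is.null(outdir)) write_ortholog_sets(sets, file.path(outdir, "ortholog_sets.tsv"))

  decisions <- decide_sets(sets, calls, genomes, upstream = upstream,
                           gold = gold, mode = mode,
                           primary_by_genome = primary)
  if (!is.null(outdir)) {
    write_decisions(decisions, file.path(outdir, "decisions.tsv"))
    write_set_decisions(decisions, file.path(outdir, "set_decisions.tsv"))
    for (gid in names(calls))
      write_revised_gff3(calls[[gid]],
                         decisions$members[decisions$members$changed, , drop = FALSE],
                         file.path(outdir, paste0("revised_", gid, ".gff3")))
  }

  reports <- list(
    consistency = consistency_report(decisions),
    codon_changes = codon_change_report(decisions),
    diversity = diversity_report(sets)
  )
  if (!is.null(gold))
    reports$validation <- validation_report(decisions, gold)
  if (!is.null(outdir)) {
    write.table(reports$consistency, file.path(outdir, "consistency_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(scores = scores, sets = sets, decisions = decisions,
                 reports = reports, reference = sets$reference, mode = mode,
                 params = list(floor = floor, upstream = upstream)),
            class = "gmv_run")
}

#' @export
print.gmv_run <- function(x, ...) {
  cat("Genome majority vote run (", x$mode, " mode)\n", sep = "")
  cat("  genomes: ", length(unique(x$sets$sets$genome_id)),
      "; reference: ", x$reference, "\n", sep = "")
  print(x$decisions)
  invisible(x)
}

#' @export
summary.gmv_run <- function(object, ...) {
  cr <- object$reports$consistency
  cat("Ortholog sets:                 ", cr$total_sets, "\n")
  cat("  initially consistent:        ", cr$initially_consistent,
      sprintf(" (%.1f%%)", cr$pct_initially_consistent), "\n", sep = "")
  cat("  initially inconsistent:      ", cr$initially_inconsistent,
      sprintf(" (%.1f%%)", cr$pct_initially_inconsistent), "\n", sep = "")
  cat("  made consistent by the vote: ", cr$made_consistent,
      sprintf(" (%.1f%% of inconsistent)", cr$pct_made_consistent), "\n", sep = "")
  cat("  consistent after the vote:   ", cr$consistent_after,
      sprintf(" (%.1f%%)", cr$pct_consistent_after), "\n", sep = "")
  cat("  >=1 consistent start exists: ", cr$any_consistent_possible,
      sprintf(" (%.1f%%)", cr$pct_any_consistent), "\n", sep = "")
  cat("Start-site changes:            ", sum(object$decisions$members$changed),
      "\n")
  invisible(cr)
}
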