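#' Length-normalized percent identity
#'
#' The ranking score for orthology: percent identity of a pairwise alignment
#' multiplied by the number of aligned residue pairs and divided by the
#' length of the longer of the two sequences.  A perfect match over only part
#' of the longer sequence is thereby down-weighted.
#'
#' @param pct_identity percent identity over aligned (non-gap) positions
#' @param aln_len number of aligned residue pairs
#' @param len_a,len_b ungapped sequence lengths
#' @return normalized identity, in percent
#' @export
#' @examples
#' normalized_identity(90, 80, 100, 100)  # 72
#' normalized_identity(100, 50, 50, 200)  # 25
normalized_identity <- function(pct_identity, aln_len, len_a, len_b) {
  if (any(len_a <= 0 | len_b <= 0)) stop("sequence lengths must be positive")
  stopifnot(all(pct_identity >= 0 & pct_identity <= 100),
            all(aln_len <= len_a + len_b))
  pct_identity * aln_len / pmax(len_a, len_b)
}

## Align a set of (pattern, subject) protein pairs in one vectorized call and
## return per-pair identity components.  pct_identity counts matches over
## aligned residue pairs (gap columns excluded), so normalized identity can
## never exceed it.
align_protein_pairs <- function(pa, pb) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(pa), Biostrings::AAStringSet(pb),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  nm <- Biostrings::nmatch(aln)
  pairs <- nm + Biostrings::nmismatch(aln)
  data.frame(pct_identity = ifelse(pairs > 0, 100 * nm / pairs, 0),
             aln_len = pairs)
}

## Deterministic amino-acid k-mer seed prefilter: candidate cross-genome gene
## pairs sharing at least `min_seeds` exact k-mers.  Orthologs at realistic
## identity share many; unrelated proteins essentially none.
seed_candidates <- function(pa, pb, k = 6L, min_seeds = 2L) {
  kmerize <- function(p) {
    len <- nchar(p)
    nk <- pmax(len - k + 1L, 0L)
    idx <- rep.int(seq_along(p), nk)
    off <- unlist(lapply(nk, seq_len), use.names = FALSE)
    data.frame(gene = idx, kmer = substring(p[idx], off, off + k - 1L))
  }
  ka <- kmerize(pa); kb <- kmerize(pb)
  m <- merge(ka, kb, by = "kmer")
  if (nrow(m) == 0L) return(cbind(a = integer(0), b = integer(0)))
  tab <- table(paste(m$gene.x, m$gene.y))
  keep <- names(tab)[tab >= min_seeds]
  if (length(keep) == 0L) return(cbind(a = integer(0), b = integer(0)))
  parts <- do.call(rbind, strsplit(keep, " ", fixed = TRUE))
  cbind(a = as.integer(parts[, 1L]), b = as.integer(parts[, 2L]))
}

#' Pairwise protein identities for all cross-genome gene pairs
#'
#' The built-in backend performs deterministic global protein alignment
#' (BLOSUM62, affine gaps 10/0.5).  For large inputs an exact k-mer seed
#' prefilter restricts which pairs are aligned; pairs sharing no seeds are
#' treated as no-hits, which is how a seeded search behaves.  Alternatively a
#' precomputed pairwise-identity table (e.g. from an external search tool)
#' may be supplied.
#'
#' @param calls_by_genome named list of `gmv_calls`, one per genome
#' @param floor minimum normalized identity (percent) to retain a pair
#' @param backend `"builtin"` or `"precomputed"`
#' @param precomputed data.frame from [read_pair_scores()] when
#'   `backend = "precomputed"`
#' @param prefilter `"auto"` (seed prefilter once a genome pair exceeds
#'   `prefilter_limit` candidate pairs), `"none"` (exhaustive), or `"seed"`
#' @param prefilter_limit exhaustive-alignment cutoff for `"auto"`
#' @param seed_k,min_seeds seed length (aa) and minimum shared seeds
#' @return data.frame: gene_id_a, gene_id_b, genome_a, genome_b,
#'   pct_identity, aln_len, len_a, len_b, norm_identity (symmetric pairs are
#'   stored once, with genome_a < genome_b)
#' @export
pair_scores <- function(calls_by_genome, floor = 30,
                        backend = c("builtin", "precomputed"),
                        precomputed = NULL,
                        prefilter = c("auto", "none", "seed"),
                        prefilter_limit = 20000L,
                        seed_k = 6L, min_seeds = 2L) {
  backend <- match.arg(backend)
  prefilter <- match.arg(prefilter)
  gids <- sort(names(calls_by_genome))
  if (length(gids) < 2L) stop("need at least two genomes")
  if (backend == "precomputed") {
    return(precomputed_pair_scores(calls_by_genome, precomputed, floor))
  }
  out <- vector("list", 0L)
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (i >= j) next
    ca <- calls_by_genome[[gids[i]]]; cb <- calls_by_genome[[gids[j]]]
    pa <- ca$protein; pb <- cb$protein
    use_seed <- switch(prefilter,
                       none = FALSE, seed = TRUE,
                       auto = length(pa) * length(pb) > prefilter_limit)
    if (use_seed) {
      cand <- seed_candidates(pa, pb, k = seed_k, min_seeds = min_seeds)
    } else {
      cand <- cbind(a = rep(seq_along(pa), times = length(pb)),
                    b = rep(seq_along(pb), each = length(pa)))
    }
    if (nrow(cand) == 0L) next
    sc <- align_protein_pairs(pa[cand[, "a"]], pb[cand[, "b"]])
    la <- nchar(pa[cand[, "a"]]); lb <- nchar(pb[cand[, "b"]])
    ni <- normalized_identity(sc$pct_identity, sc$aln_len, la, lb)
    keep <- ni >= floor
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id_a = ca$gene_id[cand[keep, "a"]],
      gene_id_b = cb$gene_id[cand[keep, "b"]],
      genome_a = gids[i], genome_b = gids[j],
      pct_identity = sc$pct_identity[keep], aln_len = sc$aln_len[keep],
      len_a = la[keep], len_b = lb[keep], norm_identity = ni[keep],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene_id_a = character(0), gene_id_b = character(0),
                      genome_a = character(0), genome_b = character(0),
                      pct_identity = numeric(0), aln_len = integer(0),
                      len_a = integer(0), len_b = integer(0),
                      norm_identity = numeric(0)))
  do.call(rbind, out)
}

precomputed_pair_scores <- function(calls_by_genome, precomputed, floor) {
  if (is.null(precomputed)) stop("backend 'precomputed' needs a score table")
  gene2gen <- unlist(lapply(calls_by_genome,
                            function(x) setNames(x$genome_id, x$gene_id)))
  names(gene2gen) <- unlist(lapply(calls_by_genome, `[[`, "gene_id"))
  df <- precomputed
  known <- df$gene_id_a %in% names(gene2gen) & df$gene_id_b %in% names(gene2gen)
  if (!all(known)) {
    warning(sum(!known), " precomputed pair(s) reference unknown genes; ",
            "treated as no-hits")
    df <- df[known, , drop = FALSE]
  }
  ga <- unname(gene2gen[df$gene_id_a]); gb <- unname(gene2gen[df$gene_id_b])
  cross <- ga != gb
  df <- df[cross, , drop = FALSE]; ga <- ga[cross]; gb <- gb[cross]
  flip <- ga > gb
  tmp <- df$gene_id_a[flip]; df$gene_id_a[flip] <- df$gene_id_b[flip]
  df$gene_id_b[flip] <- tmp
  tmpl <- df$len_a[flip]; df$len_a[flip] <- df$len_b[flip]; df$len_b[flip] <- tmpl
  tmpg <- ga[flip]; ga[flip] <- gb[flip]; gb[flip] <- tmpg
  df$genome_a <- ga; df$genome_b <- gb
  if (is.null(df$norm_identity))
    df$norm_identity <- normalized_identity(df$pct_identity, df$aln_len,
                                            df$len_a, df$len_b)
  df <- df[df$norm_identity >= floor, , drop = FALSE]
  df <- df[!duplicated(paste(df$gene_id_a, df$gene_id_b)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assemble pan-reciprocal best-hit ortholog sets
#'
#' An ortholog set contains exactly one gene per genome such that every pair
#' of members is a mutual unique best hit between their two genomes, ranked
#' by normalized identity.  Exact best-hit ties void both candidacies for
#' that genome pair (no orthology is fabricated from ambiguity).  Assembly
#' seeds from the reference genome's genes and verifies pan-RBH closure over
#' all member pairs; families missing a genome yield no set.
#'
#' @param scores data.frame from [pair_scores()]
#' @param calls_by_genome named list of `gmv_calls`
#' @param reference reference genome id (default: first sorted id)
#' @return a `gmv_sets` object: list with `sets` (data.frame set_id,
#'   genome_id, gene_id, one row per member), `summary` (set_id,
#'   min_identity, mean_identity) and `reference`
#' @export
ortholog_sets <- function(scores, calls_by_genome, reference = NULL) {
  gids <- sort(names(calls_by_genome))
  if (is.null(reference)) reference <- gids[1L]
  stopifnot(reference %in% gids)

  # symmetric long form: one row per (query gene, target genome) hit
  long <- rbind(
    data.frame(q = scores$gene_id_a, t = scores$gene_id_b,
               qg = scores$genome_a, tg = scores$genome_b,
               s = scores$norm_identity, stringsAsFactors = FALSE),
    data.frame(q = scores$gene_id_b, t = scores$gene_id_a,
               qg = scores$genome_b, tg = scores$genome_a,
               s = scores$norm_identity, stringsAsFactors = FALSE)
  )
  # unique best hit per (query gene, target genome); ties void the slot
  key <- paste(long$q, long$tg, sep = "\r")
  ord <- order(key, -long$s)
  long <- long[ord, ]; key <- key[ord]
  first <- !duplicated(key)
  best <- long[first, , drop = FALSE]
  # exact ties (second-best score equal to best) void the slot
  idx2 <- which(!first)
  first2 <- !duplicated(key[idx2])
  second_s <- setNames(long$s[idx2[first2]], key[idx2[first2]])
  ss <- second_s[key[first]]
  tied <- !is.na(ss) & abs(ss - best$s) < 1e-12
  best$t[tied] <- NA_character_
  bh_key <- paste(best$q, best$tg, sep = "\r")
  lookup <- function(genes, tgt)
    best$t[match(paste(genes, tgt, sep = "\r"), bh_key)]

  ref_genes <- calls_by_genome[[reference]]$gene_id
  others <- setdiff(gids, reference)
  # seed candidate members from the reference genome's best hits
  M <- matrix(NA_character_, length(ref_genes), length(gids),
              dimnames = list(NULL, gids))
  M[, reference] <- ref_genes
  for (og in others) M[, og] <- lookup(ref_genes, og)
  ok <- rowSums(is.na(M)) == 0L
  # pan-RBH closure: every ordered pair of members must be a unique best hit
  for (a in gids) for (b in gids) {
    if (a == b) next
    h <- lookup(M[, a], b)
    ok <- ok & !is.na(h) & h == M[, b]
  }
  M <- M[ok, , drop = FALSE]
  n_ok <- nrow(M)
  set_ids <- sprintf("set%05d", seq_len(n_ok))
  sets <- if (n_ok) data.frame(
    set_id = rep(set_ids, each = length(gids)),
    genome_id = rep(gids, times = n_ok),
    gene_id = as.vector(t(M)),
    stringsAsFactors = FALSE
  ) else data.frame(set_id = character(0), genome_id = character(0),
                    gene_id = character(0), stringsAsFactors = FALSE)

  summ <- set_identity_summary(M, scores, gids)
  structure(list(sets = sets, summary = summ, reference = reference),
            class = "gmv_sets")
}

## Per-set min and mean normalized identity over all member pairs.
## M is the n_sets x n_genomes member matrix (columns ordered by gids).
set_identity_summary <- function(M, scores, gids) {
  n <- nrow(M)
  if (is.null(n) || n == 0L)
    return(data.frame(set_id = character(0), min_identity = numeric(0),
                      mean_identity = numeric(0)))
  skey <- paste(scores$gene_id_a, scores$gene_id_b, sep = "\r")
  skey_r <- paste(scores$gene_id_b, scores$gene_id_a, sep = "\r")
  cmb <- utils::combn(length(gids), 2L)
  vals <- matrix(NA_real_, n, ncol(cmb))
  for (p in seq_len(ncol(cmb))) {
    k1 <- paste(M[, cmb[1L, p]], M[, cmb[2L, p]], sep = "\r")
    v <- scores$norm_identity[match(k1, skey)]
    miss <- is.na(v)
    if (any(miss))
      v[miss] <- scores$norm_identity[match(k1[miss], skey_r)]
    vals[, p] <- v
  }
  data.frame(set_id = sprintf("set%05d", seq_len(n)),
             min_identity = apply(vals, 1L, min, na.rm = TRUE),
             mean_identity = rowMeans(vals, na.rm = TRUE),
             stringsAsFactors = FALSE)
}

#' @export
print.gmv_sets <- function(x, ...) {
  ns <- length(unique(x$sets$set_id))
  cat("<gmv_sets> ", ns, " pan-reciprocal best-hit ortholog set(s) over ",
      length(unique(x$sets$genome_id)), " genome(s); reference: ",
      x$reference, "\n", sep = "")
  if (ns) cat("  median per-set min identity: ",
              round(median(x$summary$min_identity), 1), "%\n", sep = "")
  invisible(x)
}
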