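## Step D: upstream-extended sequences, multiple alignment, column maps.
##
## The built-in aligner is a deterministic center-star progressive aligner
## over Biostrings global pairwise alignments (match 2, mismatch -3, gap
## open 5, gap extend 2).  The center is the sequence with the highest mean
## pairwise identity (ties broken by genome id); remaining rows are merged
## under the usual once-a-gap-always-a-gap rule.

NT_MAT_PARAMS <- list(match = 2, mismatch = -3, gapOpening = 5, gapExtension = 2)

nt_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(
    match = NT_MAT_PARAMS$match, mismatch = NT_MAT_PARAMS$mismatch,
    baseOnly = FALSE)
}

align_nt_pairs <- function(pa, pb) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(pa), Biostrings::DNAStringSet(pb),
    type = "global", substitutionMatrix = nt_submat(),
    gapOpening = NT_MAT_PARAMS$gapOpening,
    gapExtension = NT_MAT_PARAMS$gapExtension)
}

#' Extract the alignable sequence for one gene
#'
#' Returns the gene's nucleotide sequence in transcript orientation spanning
#' from `upstream` bases before the earliest (most 5') alternative start --
#' truncated at the contig edge if necessary -- through the last base of the
#' stop codon, together with the mapping from genomic anchors to local
#' (1-based, transcript orientation) positions.
#'
#' @param call one-row slice of a `gmv_calls` data.frame
#' @param genome matching `gmv_genome`
#' @param upstream upstream window length in bp (default 250)
#' @return list with `seq`, `chosen_local`, `alt_local` (named by position),
#'   `win_start`, `win_end`, `truncated`, `strand`, `contig`
#' @export
extract_alignable <- function(call, genome, upstream = 250L) {
  if (is.data.frame(call)) stopifnot(nrow(call) == 1L)
  ctg <- contig_string(genome, call$contig)
  clen <- nchar(ctg)
  alt <- call$alternatives[[1L]]
  d <- transcript_dist(alt$pos, call$stop, call$strand)
  earliest <- alt$pos[which.max(d)]
  if (call$strand == "+") {
    win_start <- max(1L, earliest - as.integer(upstream))
    win_end <- call$stop + 2L
    truncated <- earliest - as.integer(upstream) < 1L
    seq <- substring(ctg, win_start, win_end)
    to_local <- function(p) p - win_start + 1L
  } else {
    win_start <- call$stop - 2L
    win_end <- min(clen, earliest + as.integer(upstream))
    truncated <- earliest + as.integer(upstream) > clen
    seq <- revcomp(substring(ctg, win_start, win_end))
    to_local <- function(p) win_end - p + 1L
  }
  list(seq = seq,
       chosen_local = to_local(call$start),
       alt_local = setNames(to_local(alt$pos), alt$pos),
       win_start = win_start, win_end = win_end, truncated = truncated,
       strand = call$strand, contig = call$contig)
}

## Decompose one pairwise alignment into the center-relative profile used
## for the star merge:
##   a_char[i]  character of the row aligned to center residue i ('-' if gap)
##   ins[i+1]   row residues inserted after center residue i (index 1 =
##              before the first center residue)
profile_from_aligned <- function(c_aln, r_aln) {
  cc <- strsplit(c_aln, "")[[1L]]
  rr <- strsplit(r_aln, "")[[1L]]
  stopifnot(length(cc) == length(rr))
  Lc <- sum(cc != "-")
  a_char <- rep("-", Lc)
  ins <- rep("", Lc + 1L)
  cp <- 0L
  for (i in seq_along(cc)) {
    if (cc[i] != "-") {
      cp <- cp + 1L
      a_char[cp] <- rr[i]
    } else {
      ins[cp + 1L] <- paste0(ins[cp + 1L], rr[i])
    }
  }
  list(a_char = a_char, ins = ins)
}

#' Multiple alignment of one ortholog set's sequences
#'
#' @param seqs named character vector (names are genome ids) of the
#'   upstream-extended sequences, length >= 2
#' @param set_id identifier carried into the result
#' @param backend `"builtin"` (center-star) or `"precomputed"` (adapter for
#'   an externally produced alignment)
#' @param aligned for `backend = "precomputed"`: named character vector of
#'   aligned rows (equal lengths, gaps as `-`), or a path to an aligned
#'   FASTA file
#' @return a `gmv_alignment`: list with `set_id`, `rows` (named aligned
#'   strings) and `maps` (per row, integer vector mapping ungapped position
#'   to alignment column)
#' @export
align_ortholog_set <- function(seqs, set_id = NA_character_,
                               backend = c("builtin", "precomputed"),
                               aligned = NULL) {
  backend <- match.arg(backend)
  if (backend == "precomputed") {
    if (is.character(aligned) && length(aligned) == 1L && file.exists(aligned))
      aligned <- setNames(toupper(as.character(Biostrings::readBStringSet(aligned))),
                          sub("\\s.*$", "", names(Biostrings::readBStringSet(aligned))))
    return(new_alignment(set_id, aligned, check_against = seqs))
  }
  if (length(seqs) < 2L) stop("need at least two sequences to align")
  if (any(!nzchar(seqs))) stop("empty sequence in ortholog set")
  ids <- names(seqs)
  cmb <- utils::combn(length(seqs), 2L)
  aln <- align_nt_pairs(seqs[cmb[1L, ]], seqs[cmb[2L, ]])
  nm <- Biostrings::nmatch(aln)
  pid <- 100 * nm / (nm + Biostrings::nmismatch(aln))
  # mean pairwise identity per row; center = max, ties by genome id
  msum <- numeric(length(seqs))
  for (p in seq_len(ncol(cmb))) {
    msum[cmb[1L, p]] <- msum[cmb[1L, p]] + pid[p]
    msum[cmb[2L, p]] <- msum[cmb[2L, p]] + pid[p]
  }
  center <- order(-msum, ids)[1L]

  nindel_tot <- sum(lengths(Biostrings::insertion(aln))) +
    sum(lengths(Biostrings::deletion(aln)))
  if (nindel_tot == 0L && length(unique(nchar(seqs))) == 1L)
    return(new_alignment(set_id, seqs))  # gap-free: rows are the inputs

  # star merge around the center using the center-vs-row pairwise alignments
  Lc <- nchar(seqs[center])
  others <- setdiff(seq_along(seqs), center)
  profiles <- vector("list", length(seqs))
  profiles[[center]] <- list(a_char = strsplit(seqs[center], "")[[1L]],
                             ins = rep("", Lc + 1L))
  for (r in others) {
    p <- which((cmb[1L, ] == center & cmb[2L, ] == r) |
                 (cmb[1L, ] == r & cmb[2L, ] == center))[1L]
    a <- aln[p]
    pa_str <- as.character(Biostrings::alignedPattern(a))
    sa_str <- as.character(Biostrings::alignedSubject(a))
    profiles[[r]] <- if (cmb[1L, p] == center)
      profile_from_aligned(pa_str, sa_str)
    else
      profile_from_aligned(sa_str, pa_str)
  }
  W <- Reduce(pmax, lapply(profiles, function(p) nchar(p$ins)))
  rows <- vapply(profiles, function(p) {
    pad <- paste0(p$ins, strrep("-", W - nchar(p$ins)))
    paste0(pad[1L], paste0(p$a_char, pad[-1L], collapse = ""))
  }, "")
  new_alignment(set_id, setNames(rows, ids))
}

new_alignment <- function(set_id, rows, check_against = NULL) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by genome id")
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows must have equal length")
  maps <- lapply(strsplit(rows, ""), function(ch) which(ch != "-"))
  if (!is.null(check_against)) {
    degap <- vapply(rows, function(r) gsub("-", "", r, fixed = TRUE), "")
    if (!identical(unname(degap[names(check_against)]),
                   unname(toupper(check_against))))
      stop("aligned rows do not de-gap to the input sequences")
  }
  structure(list(set_id = set_id, rows = rows, maps = maps),
            class = "gmv_alignment")
}

#' @export
print.gmv_alignment <- function(x, ...) {
  cat("<gmv_alignment> set ", x$set_id, ": ", length(x$rows), " rows x ",
      nchar(x$rows[[1L]]), " columns\n", sep = "")
  invisible(x)
}

#' Write an alignment as aligned FASTA (debug output)
#' @param alignment `gmv_alignment`
#' @param path output path
#' @export
write_alignment_fasta <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(alignment$rows), path)
  invisible(path)
}

#' Map start anchors to alignment columns
#'
#' Every chosen and alternative start anchor of every member is assigned the
#' alignment column of its own (never gapped) row position.
#'
#' @param alignment `gmv_alignment`
#' @param extracts named list (by genome id) of [extract_alignable()] results
#' @return list per member: `chosen_col` (integer) and `alt_cols` (integer
#'   vector named by genomic anchor position)
#' @export
anchor_columns <- function(alignment, extracts) {
  ids <- names(alignment$rows)
  stopifnot(all(ids %in% names(extracts)))
  out <- lapply(ids, function(id) {
    ext <- extracts[[id]]
    map <- alignment$maps[[id]]
    npos <- length(map)
    if (ext$chosen_local < 1L || ext$chosen_local > npos ||
        any(ext$alt_local < 1L | ext$alt_local > npos))
      stop("anchor outside extracted window for genome ", id)
    list(chosen_col = map[ext$chosen_local],
         alt_cols = setNames(map[ext$alt_local], names(ext$alt_local)))
  })
  setNames(out, ids)
}
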