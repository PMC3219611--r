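#' Read a genome from a FASTA file
#'
#' Loads all contigs, uppercases them, and checks the alphabet.  Sequences
#' containing N are accepted; any other character is an error.
#'
#' @param path path to a nucleotide FASTA file
#' @param genome_id identifier for the genome; defaults to the file name
#'   without extension
#' @return a `gmv_genome`: list with `genome_id` and `contigs` (a named
#'   [Biostrings::DNAStringSet])
#' @export
read_genome_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate contig id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for contig ", ids[which(nchar(seqs) == 0L)[1L]],
         " in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in contig ", ids[which(bad)[1L]], " of ", path)
  gmv_genome(if (is.null(genome_id)) sub("\\.(fa|fna|fasta)$", "", basename(path))
             else genome_id,
             setNames(seqs, ids))
}

#' Construct a genome object from in-memory sequences
#'
#' @param genome_id genome identifier
#' @param contigs named character vector or DNAStringSet of contig sequences
#' @return a `gmv_genome`
#' @export
gmv_genome <- function(genome_id, contigs) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  stopifnot(is(contigs, "DNAStringSet"), !is.null(names(contigs)),
            all(Biostrings::width(contigs) > 0L))
  structure(list(genome_id = genome_id, contigs = contigs),
            class = "gmv_genome")
}

#' @export
print.gmv_genome <- function(x, ...) {
  cat("<gmv_genome> ", x$genome_id, ": ", length(x$contigs), " contig(s), ",
      sum(Biostrings::width(x$contigs)), " bp\n", sep = "")
  invisible(x)
}

contig_string <- function(genome, contig) {
  if (!contig %in% names(genome$contigs))
    stop("unknown contig '", contig, "' in genome ", genome$genome_id)
  if (is.character(genome$contigs)) genome$contigs[[contig]]
  else as.character(genome$contigs[[contig]])
}

## character-cached view of a genome, for inner loops
cache_genome <- function(genome) {
  list(genome_id = genome$genome_id,
       contigs = setNames(as.character(genome$contigs), names(genome$contigs)))
}

## ---------------------------------------------------------------------------
## Gene calls with alternative starts
##
## TSV dialect: genome_id, gene_id, contig, strand, start, stop, score,
## alternatives -- where alternatives is ';'-separated "pos:codon:score" and
## start/stop are transcript-orientation first-codon-base anchors.

parse_alternatives <- function(s) {
  if (is.na(s) || !nzchar(s)) return(data.frame(pos = integer(0),
                                                codon = character(0),
                                                score = numeric(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(pos = as.integer(vapply(parts, `[`, "", 1L)),
             codon = toupper(vapply(parts, `[`, "", 2L)),
             score = as.numeric(vapply(parts, `[`, "", 3L)))
}

format_alternatives <- function(alt) {
  paste(sprintf("%d:%s:%g", alt$pos, alt$codon, alt$score), collapse = ";")
}

#' Read gene calls with alternative start sites
#'
#' Parses the gene-calls TSV, resolves strand-aware anchors against the
#' genome, translates each gene's protein, and enforces the gene-record
#' invariants: the chosen start must be listed among the alternatives, every
#' alternative must be in frame with and upstream of the (fixed) stop, no
#' alternative may have an in-frame stop codon between itself and the
#' annotated stop, and the coding length must be at least 6 nt.
#'
#' @param path path to the calls TSV
#' @param genome matching `gmv_genome` (used to derive codons and proteins)
#' @return a `gmv_calls` data.frame: one row per gene with columns
#'   `genome_id, gene_id, contig, strand, start, stop, score, start_codon,
#'   canonical, protein` and a list-column `alternatives` of data.frames
#'   `(pos, codon, score)` whose codons are re-read from the genome sequence
#' @export
read_gene_calls <- function(path, genome) {
  if (!file.exists(path)) stop("gene-calls TSV not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "gene_id", "contig", "strand", "start", "stop",
            "score", "alternatives")
  if (!all(need %in% names(df)))
    stop("gene-calls TSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  alts <- lapply(df$alternatives, parse_alternatives)
  build_gene_calls(df$genome_id, df$gene_id, df$contig, df$strand,
                   as.integer(df$start), as.integer(df$stop),
                   as.numeric(df$score), alts, genome)
}

#' Assemble and validate gene calls from vectors
#'
#' Low-level constructor shared by [read_gene_calls()] and the synthetic-data
#' generator.  Performs full invariant validation against the genome.
#'
#' @param genome_id,gene_id,contig,strand,start,stop,score per-gene vectors
#' @param alternatives list of data.frames `(pos, codon, score)`; codons may
#'   be `NA` and are always re-read from the sequence
#' @param genome `gmv_genome`
#' @return `gmv_calls` data.frame (see [read_gene_calls()])
#' @export
build_gene_calls <- function(genome_id, gene_id, contig, strand, start, stop,
                             score, alternatives, genome) {
  n <- length(gene_id)
  stopifnot(length(strand) == n, length(start) == n, length(stop) == n,
            length(alternatives) == n)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  seqs <- setNames(as.character(genome$contigs), names(genome$contigs))
  if (!all(contig %in% names(seqs)))
    stop("gene on unknown contig: ",
         gene_id[which(!contig %in% names(seqs))[1L]])
  ctg <- seqs[contig]
  clen <- nchar(ctg)
  span <- gene_span(start, stop, strand)
  if (any(span[, "left"] < 1L | span[, "right"] > clen))
    stop("gene coordinates outside contig: ",
         gene_id[which(span[, "left"] < 1L | span[, "right"] > clen)[1L]])

  d <- transcript_dist(start, stop, strand)
  bad <- d < 3L | d %% 3L != 0L
  if (any(bad))
    stop("chosen start not in frame with stop (or coding length < 6 nt) for: ",
         paste(head(gene_id[bad], 5L), collapse = ", "))

  # validate alternatives: in frame, upstream of stop, chosen start present
  for (k in seq_len(n)) {
    a <- alternatives[[k]]
    if (nrow(a) == 0L || !start[k] %in% a$pos)
      stop("chosen start absent from alternatives list for gene ", gene_id[k])
    da <- transcript_dist(a$pos, stop[k], strand[k])
    if (any(da < 3L | da %% 3L != 0L))
      stop("alternative start not in frame with stop for gene ", gene_id[k])
    sp <- gene_span(a$pos, stop[k], strand[k])
    if (any(sp[, "left"] < 1L | sp[, "right"] > clen[k]))
      stop("alternative start outside contig for gene ", gene_id[k])
  }

  # no in-frame internal stop between any alternative and the stop anchor;
  # checked in one vectorized translation pass over all alternatives
  idx <- rep.int(seq_len(n), vapply(alternatives, nrow, 0L))
  apos <- unlist(lapply(alternatives, `[[`, "pos"), use.names = FALSE)
  if (length(apos)) {
    cds_all <- coding_seq(ctg[idx], apos, stop[idx], strand[idx])
    body <- substr(cds_all, 1L, nchar(cds_all) - 3L)  # exclude the stop codon
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAStringSet(body),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "solve", no.init.codon = TRUE)))
    internal <- grepl("*", substring(aa, 2L), fixed = TRUE)
    if (any(internal))
      stop("in-frame stop codon between an alternative start and the stop ",
           "for gene ", gene_id[idx[which(internal)[1L]]])
  }

  start_codon <- codon_at(ctg, start, strand)
  canonical <- start_codon %in% CANONICAL_STARTS
  if (!all(canonical))
    warning("non-canonical start codon(s) accepted for: ",
            paste(head(gene_id[!canonical], 5L), collapse = ", "))
  stop_cod <- codon_at(ctg, stop, strand)
  if (!all(stop_cod %in% STOP_CODONS))
    warning("codon at stop anchor is not a stop codon for: ",
            paste(head(gene_id[!stop_cod %in% STOP_CODONS], 5L), collapse = ", "))

  protein <- translate_cds(coding_seq(ctg, start, stop, strand))
  alternatives <- lapply(seq_len(n), function(k) {
    a <- alternatives[[k]]
    a$codon <- codon_at(ctg[k], a$pos, strand[k])
    a[order(transcript_dist(a$pos, stop[k], strand[k]), decreasing = TRUE), ,
      drop = FALSE]
  })

  out <- data.frame(genome_id = genome_id, gene_id = gene_id, contig = contig,
                    strand = strand, start = as.integer(start),
                    stop = as.integer(stop), score = score,
                    start_codon = start_codon, canonical = canonical,
                    protein = protein, stringsAsFactors = FALSE)
  out$alternatives <- alternatives
  class(out) <- c("gmv_calls", "data.frame")
  out
}

#' Write gene calls to the TSV dialect read by [read_gene_calls()]
#' @param calls `gmv_calls` data.frame
#' @param path output path
#' @export
write_gene_calls <- function(calls, path) {
  df <- calls[c("genome_id", "gene_id", "contig", "strand", "start", "stop",
                "score")]
  df$alternatives <- vapply(calls$alternatives, format_alternatives, "")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Key identifying a gene across call sources
#'
#' Stops are treated as fixed, so a gene is identified by its contig, strand
#' and stop anchor when matching caller output, curated maps and validated
#' starts.
#' @param calls data.frame with contig, strand, stop columns
#' @return character vector of keys
#' @export
gene_key <- function(calls) {
  paste(calls$contig, calls$strand, calls$stop, sep = "|")
}

#' Read a gold standard of validated start sites
#'
#' @param path TSV with columns contig, strand, stop, validated_start
#' @param genome_id genome the validated starts belong to
#' @return data.frame with a `key` column compatible with [gene_key()]
#' @export
read_gold_standard <- function(path, genome_id = NA_character_) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "strand", "stop", "validated_start")
  if (!all(need %in% names(df)))
    stop("gold-standard TSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$key <- gene_key(df)
  if (anyDuplicated(df$key))
    stop("duplicate gene key in gold standard: ", df$key[duplicated(df$key)][1L])
  df$genome_id <- genome_id
  df
}

## ---------------------------------------------------------------------------
## Pairwise-identity TSV

#' Read precomputed pairwise protein identities
#'
#' @param path TSV with columns gene_id_a, gene_id_b, pct_identity, aln_len,
#'   len_a, len_b
#' @return data.frame with an added `norm_identity` column
#' @export
read_pair_scores <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id_a", "gene_id_b", "pct_identity", "aln_len", "len_a", "len_b")
  if (!all(need %in% names(df)))
    stop("pairwise-identity TSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$norm_identity <- normalized_identity(df$pct_identity, df$aln_len,
                                          df$len_a, df$len_b)
  df
}

#' Write pairwise protein identities
#' @param scores data.frame as returned by [pair_scores()]
#' @param path output path
#' @export
write_pair_scores <- function(scores, path) {
  write.table(scores[c("gene_id_a", "gene_id_b", "pct_identity", "aln_len",
                       "len_a", "len_b", "norm_identity")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## GFF3 output of revised maps

#' Write a revised gene map as GFF3
#'
#' One `gene` feature per input gene.  Genes revised by the vote get their
#' start-side boundary moved; stop-side boundaries are never changed.
#' Attributes record the decision status, ortholog set id, and the old and
#' new start anchors.
#'
#' @param calls `gmv_calls` for one genome
#' @param decisions member-level decisions data.frame from [run_gmv()] /
#'   [decide_sets()]; may be `NULL` for an unrevised map
#' @param path output path
#' @return the path, invisibly
#' @export
write_revised_gff3 <- function(calls, decisions, path) {
  new_start <- calls$start
  status <- rep("unassigned", nrow(calls))
  set_id <- rep(NA_character_, nrow(calls))
  old_start <- calls$start
  if (!is.null(decisions) && nrow(decisions)) {
    d <- decisions[decisions$genome_id == calls$genome_id[1L], , drop = FALSE]
    if (any(!d$gene_id %in% calls$gene_id))
      stop("decision references unknown gene_id")
    i <- match(d$gene_id, calls$gene_id)
    new_start[i] <- d$new_start
    status[i] <- d$status
    set_id[i] <- d$set_id
  }
  span <- gene_span(new_start, calls$stop, calls$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = calls$contig,
    ranges = IRanges::IRanges(span[, "left"], span[, "right"]),
    strand = calls$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "gmvote", type = "gene", ID = calls$gene_id,
    old_start = old_start, new_start = new_start,
    gmv_status = status, ortholog_set = set_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read back a GFF3 written by [write_revised_gff3()]
#'
#' @param path GFF3 path
#' @return data.frame with gene_id, contig, strand, start (anchor), stop-side
#'   boundary untouched, plus the gmvote attributes
#' @export
read_revised_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  strand <- as.character(BiocGenerics::strand(gr))
  left <- BiocGenerics::start(gr)
  right <- BiocGenerics::end(gr)
  # attributes that were NA throughout are omitted from the file
  col_or <- function(nm, default) {
    mc <- S4Vectors::mcols(gr)
    if (nm %in% names(mc)) mc[[nm]] else rep(default, length(gr))
  }
  data.frame(
    gene_id = gr$ID,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = ifelse(strand == "+", left, right),
    stop = ifelse(strand == "+", right - 2L, left + 2L),
    old_start = as.integer(col_or("old_start", NA_integer_)),
    new_start = as.integer(col_or("new_start", NA_integer_)),
    gmv_status = as.character(col_or("gmv_status", NA_character_)),
    ortholog_set = as.character(col_or("ortholog_set", NA_character_)),
    stringsAsFactors = FALSE
  )
}
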