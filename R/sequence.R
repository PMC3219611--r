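## Coordinate conventions
##
## All user-facing coordinates are 1-based genomic positions (GFF3 style).
## A start anchor is the position of the FIRST base of the initiation codon
## in transcript orientation: on "+" the leftmost base of the codon, on "-"
## the rightmost base in genome coordinates.  Stop anchors follow the same
## rule for the stop codon.  Consequences used throughout:
##   "+" gene span: [start, stop + 2];   transcript start->stop dist = stop - start
##   "-" gene span: [stop - 2, start];   transcript start->stop dist = start - stop

STOP_CODONS <- c("TAA", "TAG", "TGA")
CANONICAL_STARTS <- c("ATG", "GTG", "TTG")

revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), "", USE.NAMES = FALSE)
}

#' Transcript-orientation distance from a start-side anchor to the stop anchor
#'
#' Positive when the anchor lies upstream (5') of the stop anchor.  In-frame
#' anchors have distances divisible by 3.
#' @param pos,stop anchor positions (1-based genomic)
#' @param strand "+" or "-"
#' @return integer distance in nucleotides
#' @keywords internal
transcript_dist <- function(pos, stop, strand) {
  n <- max(length(pos), length(stop), length(strand))
  pos <- rep_len(pos, n); stop <- rep_len(stop, n)
  strand <- rep_len(strand, n)
  ifelse(strand == "+", stop - pos, pos - stop)
}

#' Codon at an anchor, read in transcript orientation
#'
#' @param seq contig sequence as a single character string
#' @param pos anchor position(s) (first base of the codon, transcript
#'   orientation)
#' @param strand "+" or "-" (scalar or vector)
#' @return uppercase 3-mer(s)
#' @export
codon_at <- function(seq, pos, strand) {
  n <- max(length(seq), length(pos), length(strand))
  seq <- rep_len(seq, n); pos <- rep_len(pos, n); strand <- rep_len(strand, n)
  out <- substring(seq, pos, pos + 2L)
  minus <- strand == "-"
  if (any(minus)) out[minus] <- revcomp(substring(seq, pos - 2L, pos)[minus])
  out
}

#' Coding sequence from an anchor through the stop codon
#'
#' @inheritParams codon_at
#' @param stop stop anchor(s)
#' @return character vector of nucleotide sequences in transcript orientation
#'   (includes the stop codon)
#' @export
coding_seq <- function(seq, pos, stop, strand) {
  n <- max(length(seq), length(pos), length(stop), length(strand))
  seq <- rep_len(seq, n); pos <- rep_len(pos, n)
  stop <- rep_len(stop, n); strand <- rep_len(strand, n)
  out <- substring(seq, pos, stop + 2L)
  minus <- strand == "-"
  if (any(minus)) out[minus] <- revcomp(substring(seq, stop - 2L, pos)[minus])
  out
}

#' Translate bacterial coding sequences
#'
#' Uses the bacterial genetic code (transl_table 11); the initiation codon is
#' reported as M regardless of whether it is ATG, GTG or TTG, and the trailing
#' stop (if present) is dropped.  Ambiguity codes translate to X.
#'
#' @param cds character vector of coding sequences in transcript orientation
#' @return character vector of amino-acid sequences
#' @export
translate_cds <- function(cds) {
  if (length(cds) == 0L) return(character(0))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
  substr(aa, 1L, 1L) <- "M"
  sub("\\*$", "", aa)
}

#' Genomic span of a gene given its start and stop anchors
#'
#' @inheritParams transcript_dist
#' @return two-column matrix (left, right) of 1-based inclusive genomic bounds
#' @keywords internal
gene_span <- function(pos, stop, strand) {
  n <- max(length(pos), length(stop), length(strand))
  pos <- rep_len(pos, n); stop <- rep_len(stop, n)
  strand <- rep_len(strand, n)
  left <- ifelse(strand == "+", pos, stop - 2L)
  right <- ifelse(strand == "+", stop + 2L, pos)
  cbind(left = as.integer(left), right = as.integer(right))
}
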