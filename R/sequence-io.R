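#' Read a genome FASTA into a named, upper-case DNAStringSet
#'
#' Thin wrapper over [Biostrings::readDNAStringSet] that normalises case,
#' strips description text from contig names and enforces unique contig
#' names so sequences are addressable by name.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet` named by contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  # keep only the first word of each header, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig name(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Read a transcript annotation table
#'
#' Expects a tab-separated file with header columns `gene_id`,
#' `transcript_id`, `chromosome`, `strand`, `tss` (1-based position of the
#' first transcribed base), the shape of a BioMart transcript export.
#'
#' @param path path to the TSV.
#' @return a `data.frame` of validated transcript records.
#' @export
readTranscripts <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE)
  need <- c("gene_id", "transcript_id", "chromosome", "strand", "tss")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("annotation is missing required column(s): ",
         paste(missing, collapse = ", "),
         " (required: ", paste(need, collapse = ", "), ")")
  df <- df[, need]
  validateTranscripts(df)
}

#' Validate an in-memory transcript annotation
#'
#' Applied by [readTranscripts()] and accepted anywhere an annotation is
#' taken: strands must be "+"/"-" (the typographic minus is accepted and
#' normalised), `tss` must be a positive integer, and
#' (gene_id, transcript_id) pairs must be unique.
#'
#' @param df a data.frame with the annotation columns.
#' @return the normalised data.frame (tss integer, strand in c("+","-")).
#' @export
validateTranscripts <- function(df) {
  need <- c("gene_id", "transcript_id", "chromosome", "strand", "tss")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("annotation is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$strand <- gsub("−", "-", as.character(df$strand))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop("unknown strand symbol in annotation row(s) ",
         paste(head(bad, 5), collapse = ", "),
         " (must be '+' or '-')")
  tss <- suppressWarnings(as.numeric(df$tss))
  badTss <- which(is.na(tss) | tss != floor(tss) | tss < 1)
  if (length(badTss))
    stop("non-integer or non-positive tss in annotation row(s) ",
         paste(head(badTss, 5), collapse = ", "))
  df$tss <- as.integer(tss)
  key <- paste(df$gene_id, df$transcript_id)
  if (anyDuplicated(key))
    stop("duplicate (gene_id, transcript_id) pair(s): ",
         paste(head(unique(key[duplicated(key)]), 5), collapse = "; "))
  rownames(df) <- NULL
  df
}

#' Reverse-complement a nucleotide string
#'
#' Alphabet-checked reverse complement over {A,C,G,T,N}; N maps to N and
#' the operation is an involution.
#'
#' @param seq a single character string (may be empty).
#' @return the reverse complement as a character string.
#' @examples
#' revComp("GGGT")  # "ACCC"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  if (grepl("[^ACGTNacgtn]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Extract sense-oriented TRR windows around each TSS
#'
#' For a plus-strand transcript the TRR is
#' `contig[tss - upstream .. tss + downstream - 1]` (1-based inclusive);
#' for a minus-strand transcript it is the reverse complement of
#' `contig[tss - downstream + 1 .. tss + upstream]`. Either way the
#' returned string reads 5'->3' on the coding strand with the TSS base at
#' 0-based index `upstream`. Transcripts whose window overhangs the contig
#' (or whose contig is absent) are excluded, not truncated, and reported
#' in `trrExcluded()`.
#'
#' @param genome a named `DNAStringSet` from [readGenome()].
#' @param transcripts annotation data.frame (see [readTranscripts()]).
#' @param upstream,downstream window extents in nt.
#' @param quiet suppress the exclusion-count message.
#' @return a [TRRSet].
#' @export
extractTRR <- function(genome, transcripts, upstream = 2000L,
                       downstream = 1000L, quiet = FALSE) {
  transcripts <- validateTranscripts(transcripts)
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  stopifnot(upstream > 0L, downstream > 0L)
  ctgLen <- setNames(Biostrings::width(genome), names(genome))

  tss <- transcripts$tss
  plus <- transcripts$strand == "+"
  startPos <- ifelse(plus, tss - upstream, tss - downstream + 1L)
  endPos   <- ifelse(plus, tss + downstream - 1L, tss + upstream)

  known <- transcripts$chromosome %in% names(genome)
  inBounds <- known & startPos >= 1L &
    endPos <= ctgLen[transcripts$chromosome]
  inBounds[is.na(inBounds)] <- FALSE

  excluded <- S4Vectors::DataFrame(
    transcript_id = transcripts$transcript_id[!inBounds],
    reason = ifelse(known[!inBounds],
                    "TRR window exceeds contig bounds",
                    "contig not in genome")
  )
  keep <- which(inBounds)
  if (!quiet && nrow(excluded) > 0L)
    message(nrow(excluded), " transcript(s) excluded (TRR outside contig)")

  if (length(keep)) {
    seqs <- Biostrings::DNAStringSet(mapply(function(chr, s, e) {
      genome[[chr]][s:e]
    }, transcripts$chromosome[keep], startPos[keep], endPos[keep],
    SIMPLIFY = FALSE, USE.NAMES = FALSE))
    minus <- which(!plus[keep])
    if (length(minus))
      seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  } else {
    seqs <- Biostrings::DNAStringSet()
  }
  names(seqs) <- transcripts$transcript_id[keep]

  methods::new("TRRSet",
      sequences = seqs,
      info = S4Vectors::DataFrame(transcripts[keep, , drop = FALSE]),
      excluded = excluded,
      upstream = upstream, downstream = downstream)
}

#' Map TRR-local motif coordinates to genomic coordinates
#'
#' Local coordinates are 0-based half-open on the coding-strand axis; the
#' returned genomic interval is 1-based inclusive on the contig's forward
#' strand, with the BED-style strand of the motif's G-rich strand
#' (coding motif on a "+" gene, or template motif on a "-" gene, is "+").
#'
#' @param motifs DataFrame/data.frame of motifs (as in [pqsMotifs()]).
#' @param trrset the `TRRSet` the motifs were called on.
#' @return data.frame with `chrom`, `gstart`, `gend` (1-based inclusive),
#'   `bed_strand` plus the input columns.
#' @export
motifGenomicCoords <- function(motifs, trrset) {
  motifs <- as.data.frame(motifs)
  info <- as.data.frame(trrInfo(trrset))
  idx <- match(motifs$transcript_id, info$transcript_id)
  if (anyNA(idx)) stop("motif transcript_id absent from TRRSet")
  up <- trrset@upstream
  tss <- info$tss[idx]
  geneStrand <- info$strand[idx]
  plus <- geneStrand == "+"
  # local [s, e) -> genomic
  gstart <- ifelse(plus, tss - up + motifs$start,
                   tss + up - (motifs$end - 1L))
  gend   <- ifelse(plus, tss - up + motifs$end - 1L,
                   tss + up - motifs$start)
  gRich <- ifelse(motifs$strand == "coding", geneStrand,
                  ifelse(geneStrand == "+", "-", "+"))
  cbind(motifs,
        data.frame(chrom = info$chromosome[idx],
                   gstart = as.integer(gstart), gend = as.integer(gend),
                   bed_strand = gRich))
}

#' Write motif calls as BED6
#'
#' Coordinates are converted from TRR-local to genomic, sorted by contig
#' and start, and written 0-based half-open with name = transcript id and
#' score = motif length. The strand column carries the strand of the
#' G-rich (motif) strand in genomic terms.
#'
#' @param motifs motif table (see [pqsMotifs()]).
#' @param trrset the `TRRSet` the motifs belong to.
#' @param path output file.
#' @return invisibly, the GRanges written.
#' @export
writeMotifsBed <- function(motifs, trrset, path) {
  motifs <- as.data.frame(motifs)
  if (nrow(motifs) == 0L) {
    file.create(path)
    return(invisible(GenomicRanges::GRanges()))
  }
  g <- motifGenomicCoords(motifs, trrset)
  if (any(g$gstart < 1L)) stop("negative genomic coordinates in motif set")
  g <- g[order(g$chrom, g$gstart), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$gstart, end = g$gend),
    strand = g$bed_strand
  )
  S4Vectors::mcols(gr)$name <- g$transcript_id
  S4Vectors::mcols(gr)$score <- g$end - g$start
  rtracklayer::export(gr, path, format = "BED")
  invisible(gr)
}
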