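#' Find putative quadruplex sequences (PQS) in a nucleotide string
#'
#' Matches the canonical promoter-G4 grammar G>=3 (N1-7 G>=3)>=3: at least
#' `minTracts` maximal runs of `minRun`+ consecutive guanines, consecutive
#' runs separated by loops of `loopMin`..`loopMax` nucleotides (loops may
#' contain any base including N; G-runs themselves may not contain N).
#' Matching is greedy leftmost with maximal tract extension: a match
#' starts at the leftmost usable G-run, extends through as many qualifying
#' tracts as loop lengths allow before closing, and scanning resumes after
#' its end, so matches are non-overlapping and `n`, the motif count per
#' window, is well defined. G-runs are consumed whole; long runs are never
#' split to manufacture extra tracts.
#'
#' @param seq a single string over {A,C,G,T,N} (case-insensitive).
#' @param minRun minimum G-run (tract) length, default 3.
#' @param loopMin,loopMax loop length bounds, defaults 1 and 7.
#' @param minTracts minimum number of tracts, default 4 (the grammar's
#'   first tract plus at least three loop+tract repeats).
#' @return a data.frame with 0-based half-open `start`, `end` and the
#'   matched `sequence`, ordered left to right; zero rows when no match.
#' @examples
#' findPQS("GGGAGGGAGGGAGGG")
#' @export
findPQS <- function(seq, minRun = 3L, loopMin = 1L, loopMax = 7L,
                    minTracts = 4L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  minRun <- as.integer(minRun); minTracts <- as.integer(minTracts)
  loopMin <- as.integer(loopMin); loopMax <- as.integer(loopMax)
  if (minRun < 1L || loopMin < 1L || minTracts < 2L)
    stop("minRun and loopMin must be positive and minTracts >= 2")
  if (loopMin > loopMax) stop("loopMin must not exceed loopMax")
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  empty <- data.frame(start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  if (nchar(seq) < minTracts * minRun + (minTracts - 1L) * loopMin)
    return(empty)

  # maximal G-runs of qualifying length, as 0-based half-open intervals
  m <- gregexpr(sprintf("G{%d,}", minRun), seq)[[1]]
  if (m[1] == -1L) return(empty)
  runStart <- as.integer(m) - 1L
  runEnd <- runStart + attr(m, "match.length")

  out <- list()
  i <- 1L
  nRun <- length(runStart)
  while (i <= nRun) {
    # greedily chain tracts while the inter-run gap is a legal loop
    j <- i
    while (j < nRun) {
      gap <- runStart[j + 1L] - runEnd[j]
      if (gap >= loopMin && gap <= loopMax) j <- j + 1L else break
    }
    if (j - i + 1L >= minTracts) {
      s <- runStart[i]; e <- runEnd[j]
      out[[length(out) + 1L]] <- c(s, e)
      i <- j + 1L          # resume after the match: runs are disjoint
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(empty)
  se <- do.call(rbind, out)
  data.frame(start = se[, 1], end = se[, 2],
             sequence = substring(seq, se[, 1] + 1L, se[, 2]),
             stringsAsFactors = FALSE)
}

#' Scan a TRRSet for PQS on both strands
#'
#' Coding-strand motifs come from scanning each sense sequence directly;
#' template-strand motifs from scanning its reverse complement, with
#' coordinates mapped back to the coding-strand axis (an interval
#' `[s, e)` on the reverse complement maps to `[L - e, L - s)`). Coverage
#' masks mark, per strand, every position under at least one motif.
#'
#' @param trrset a [TRRSet].
#' @param minRun,loopMin,loopMax,minTracts grammar parameters passed to
#'   [findPQS()].
#' @return a [PQSScan].
#' @export
scanTRR <- function(trrset, minRun = 3L, loopMin = 1L, loopMax = 7L,
                    minTracts = 4L) {
  stopifnot(methods::is(trrset, "TRRSet"))
  info <- as.data.frame(trrInfo(trrset))
  n <- length(trrset@sequences)
  L <- trrset@upstream + trrset@downstream
  codingMask <- matrix(FALSE, nrow = n, ncol = L,
                       dimnames = list(info$transcript_id, NULL))
  templateMask <- codingMask
  rows <- vector("list", n)
  seqChar <- as.character(trrset@sequences)
  for (i in seq_len(n)) {
    s <- seqChar[i]
    cd <- findPQS(s, minRun, loopMin, loopMax, minTracts)
    tm <- findPQS(revComp(s), minRun, loopMin, loopMax, minTracts)
    if (nrow(tm)) {
      # mirror template coordinates onto the coding-strand axis
      newStart <- L - tm$end
      tm$end <- L - tm$start
      tm$start <- newStart
      tm <- tm[order(tm$start), , drop = FALSE]
    }
    both <- rbind(
      if (nrow(cd)) cbind(cd, strand = "coding") else NULL,
      if (nrow(tm)) cbind(tm, strand = "template") else NULL
    )
    if (!is.null(both) && nrow(both)) {
      both$transcript_id <- info$transcript_id[i]
      both$gene_id <- info$gene_id[i]
      rows[[i]] <- both
      for (r in seq_len(nrow(both))) {
        idx <- (both$start[r] + 1L):both$end[r]
        if (both$strand[r] == "coding") codingMask[i, idx] <- TRUE
        else templateMask[i, idx] <- TRUE
      }
    }
  }
  motifs <- do.call(rbind, rows)
  if (is.null(motifs))
    motifs <- data.frame(transcript_id = character(), gene_id = character(),
                         strand = character(), start = integer(),
                         end = integer(), sequence = character(),
                         stringsAsFactors = FALSE)
  motifs <- motifs[, c("transcript_id", "gene_id", "strand",
                       "start", "end", "sequence")]
  rownames(motifs) <- NULL
  methods::new("PQSScan",
      motifs = S4Vectors::DataFrame(motifs),
      codingMask = codingMask, templateMask = templateMask,
      trrLength = as.integer(L))
}

# which transcripts (mask rows) have >=1 covered position in the region
# on the requested strand(s)
.maskHasMotif <- function(scan, region, strand) {
  idx <- switch(region,
    whole = seq_len(scan@trrLength),
    .REGIONS[[region]]
  )
  if (is.null(idx)) stop("unknown region: ", region)
  cd <- rowSums(scan@codingMask[, idx, drop = FALSE]) > 0L
  tm <- rowSums(scan@templateMask[, idx, drop = FALSE]) > 0L
  switch(strand, coding = cd, template = tm, either = cd | tm,
         stop("unknown strand: ", strand))
}

#' Percentage of genes with at least one PQS in a region
#'
#' One transcript per gene must already be selected (pass `pick`, e.g. one
#' iteration from [pickTranscripts()]); region membership means the motif
#' covers at least one nucleotide of the region on the requested
#' strand(s), with "either" the union of strands.
#'
#' @param scan a [PQSScan].
#' @param geneOf named character vector mapping transcript id -> gene id
#'   (defaults to the scan's own motif/transcript table).
#' @param pick character vector of transcript ids, one per gene; default
#'   uses every transcript row in the scan.
#' @param region one of "whole", "distal", "proximal", "downstream".
#' @param strand one of "coding", "template", "either".
#' @return percentage in 0..100.
#' @export
countGenesWithPQS <- function(scan, geneOf, pick = NULL,
                              region = c("whole", "distal", "proximal",
                                         "downstream"),
                              strand = c("either", "coding", "template")) {
  region <- match.arg(region); strand <- match.arg(strand)
  stopifnot(methods::is(scan, "PQSScan"))
  tids <- rownames(scan@codingMask)
  if (missing(geneOf)) stop("geneOf mapping (transcript -> gene) is required")
  if (is.null(pick)) pick <- tids
  pick <- intersect(pick, tids)
  genes <- unique(geneOf[pick])
  if (length(genes) == 0L) stop("empty gene set")
  has <- .maskHasMotif(scan, region, strand)[match(pick, tids)]
  hit <- unique(geneOf[pick][has])
  100 * length(hit) / length(genes)
}
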