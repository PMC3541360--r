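#' G4 abundance score F for one coverage mask
#'
#' F is the percentage of TRR nucleotides covered by at least one PQS on a
#' strand: 100 * popcount(mask) / T. With non-overlapping motif calls this
#' equals 100 * sum(ge_i - gs_i) / T over the motifs. F = 0 when the TRR
#' has no motif on that strand.
#'
#' @param mask logical vector of length `T` (one strand of one TRR).
#' @param T TRR length, default 3000.
#' @return percentage in 0..100.
#' @export
fScore <- function(mask, T = 3000L) {
  if (length(mask) != T) stop("mask length must equal T")
  100 * sum(mask) / T
}

#' Genome-wide positional PQS probability profile W_k
#'
#' W_k is the fraction of TRRs whose position k (relative to TSS) is
#' covered by a PQS, computed per strand over all supplied transcripts:
#' W_k = (1/m) * sum_j alpha_{j,k}. By default the full (redundant)
#' transcript set of the scan is used and the profile is reused unchanged
#' across transcript-pick iterations.
#'
#' @param scan a [PQSScan].
#' @param transcripts optional character vector restricting the rows used.
#' @return list with `W_coding`, `W_template` (length-3000 numeric in
#'   0..1) and `m`, the number of transcripts used.
#' @export
positionalProfile <- function(scan, transcripts = NULL) {
  stopifnot(methods::is(scan, "PQSScan"))
  cd <- scan@codingMask; tm <- scan@templateMask
  if (!is.null(transcripts)) {
    keep <- rownames(cd) %in% transcripts
    cd <- cd[keep, , drop = FALSE]; tm <- tm[keep, , drop = FALSE]
  }
  m <- nrow(cd)
  if (m == 0L) stop("no transcripts to profile")
  list(W_coding = colMeans(cd), W_template = colMeans(tm), m = m)
}

#' G4 location-significance score Q for one coverage mask
#'
#' Q = sum_k alpha_k * W_k: the genome-wide positional probabilities
#' summed over this TRR's own covered positions, so motifs sitting where
#' the genome concentrates its PQS (the W_k peak just upstream of the
#' TSS) contribute more than motifs of equal length elsewhere.
#'
#' @param mask logical vector (one strand of one TRR).
#' @param W numeric vector of the same length (that strand's profile).
#' @return dimensionless nonnegative score; 0 for an empty mask.
#' @export
qScore <- function(mask, W) {
  if (length(mask) != length(W)) stop("mask and W lengths differ")
  sum(W[mask])
}

#' Cumulative-frequency percentile of per-transcript scores
#'
#' Transcripts with score 0 are excluded from the reference distribution
#' and receive NA; every nonzero score s maps to
#' 100 * #{nonzero s' <= s} / #{nonzero} (inclusive rank, so the maximum
#' is always 100 and ties share a percentile).
#'
#' @param scores numeric vector of per-transcript F or Q scores.
#' @return numeric vector of percentiles in (0, 100], NA where score = 0.
#' @examples
#' cumulativeFrequency(c(1, 2, 3, 4))  # 25 50 75 100
#' @export
cumulativeFrequency <- function(scores) {
  stopifnot(is.numeric(scores))
  nz <- scores[scores != 0]
  if (length(nz) == 0L) stop("all scores are zero; CF undefined")
  out <- rep(NA_real_, length(scores))
  idx <- which(scores != 0)
  srt <- sort(nz)
  # inclusive rank via binary search on the sorted reference
  out[idx] <- 100 * findInterval(scores[idx], srt) / length(srt)
  out
}

#' Classify G4 importance from CF and CQ percentiles
#'
#' Both percentiles above 50 -> "important"; both below 50 ->
#' "less-important"; anything else (mixed, exactly 50, or undefined
#' because the underlying score was zero) -> "intermediate".
#'
#' @param CF,CQ numeric vectors of CF_o and CQ_o percentiles (NA allowed).
#' @return character vector in {"important","less-important","intermediate"}.
#' @export
classifyImportance <- function(CF, CQ) {
  stopifnot(length(CF) == length(CQ))
  out <- rep("intermediate", length(CF))
  hi <- !is.na(CF) & !is.na(CQ) & CF > 50 & CQ > 50
  lo <- !is.na(CF) & !is.na(CQ) & CF < 50 & CQ < 50
  out[hi] <- "important"
  out[lo] <- "less-important"
  out
}

#' Product-moment correlation between score vectors
#'
#' The standard Pearson coefficient, used to relate CF and CQ percentiles
#' per strand. Errors on constant input, where r is undefined.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return r in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("fewer than 2 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Per-transcript score table (F, Q, CF, CQ, importance)
#'
#' Computes, for every transcript in the scan: strand-wise F and Q, their
#' overall sums (F_o = F_cd + F_ncd, Q_o = Q_cd + Q_ncd exactly),
#' cumulative-frequency percentiles over the supplied reference set, and
#' the importance class from CF_o/CQ_o.
#'
#' @param scan a [PQSScan].
#' @param profile a positional profile from [positionalProfile()];
#'   computed from the full scan when NULL.
#' @param reference optional character vector of transcript ids defining
#'   the CF/CQ reference distribution (e.g. one non-redundant pick);
#'   defaults to all transcripts in the scan. Percentiles are reported for
#'   every transcript, ranked against the reference.
#' @return data.frame with one row per transcript: ids, F_cd/F_ncd/F_o,
#'   Q_cd/Q_ncd/Q_o, CF_* / CQ_* percentiles, `class` and logical
#'   `important`.
#' @export
scoreTranscripts <- function(scan, profile = NULL, reference = NULL) {
  stopifnot(methods::is(scan, "PQSScan"))
  if (is.null(profile)) profile <- positionalProfile(scan)
  cd <- scan@codingMask; tm <- scan@templateMask
  L <- scan@trrLength
  tid <- rownames(cd)
  motifs <- as.data.frame(pqsMotifs(scan))
  gid <- motifs$gene_id[match(tid, motifs$transcript_id)]

  F_cd <- 100 * rowSums(cd) / L
  F_ncd <- 100 * rowSums(tm) / L
  Q_cd <- as.numeric(cd %*% profile$W_coding)
  Q_ncd <- as.numeric(tm %*% profile$W_template)

  df <- data.frame(
    transcript_id = tid,
    gene_id = gid,
    F_cd = F_cd, F_ncd = F_ncd, F_o = F_cd + F_ncd,
    Q_cd = Q_cd, Q_ncd = Q_ncd, Q_o = Q_cd + Q_ncd,
    stringsAsFactors = FALSE
  )
  ref <- if (is.null(reference)) tid else intersect(reference, tid)
  refIdx <- match(ref, tid)
  for (col in c("F_cd", "F_ncd", "F_o", "Q_cd", "Q_ncd", "Q_o")) {
    cfcol <- sub("^F", "CF", sub("^Q", "CQ", col))
    vals <- df[[col]]
    refVals <- vals[refIdx]
    nz <- sort(refVals[refVals != 0])
    df[[cfcol]] <- if (length(nz) == 0L) NA_real_ else {
      out <- rep(NA_real_, length(vals))
      idx <- which(vals != 0)
      out[idx] <- 100 * findInterval(vals[idx], nz) / length(nz)
      out
    }
  }
  df$class <- classifyImportance(df$CF_o, df$CQ_o)
  df$important <- df$class == "important"
  rownames(df) <- NULL
  df
}

#' Randomly pick one transcript per gene, over several iterations
#'
#' Accounts for transcript redundancy: each iteration draws, uniformly at
#' random and independently, one transcript for every gene. Deterministic
#' under a fixed seed; downstream statistics are then reported as
#' mean +/- SD across iterations.
#'
#' @param transcripts annotation data.frame with `gene_id` and
#'   `transcript_id` (a `TRRSet` info table also works).
#' @param nIter number of iterations, default 10.
#' @param seed integer seed.
#' @return list of length `nIter`; each element a character vector of
#'   transcript ids named by gene id.
#' @export
pickTranscripts <- function(transcripts, nIter = 10L, seed = 1L) {
  transcripts <- as.data.frame(transcripts)
  stopifnot(all(c("gene_id", "transcript_id") %in% colnames(transcripts)),
            nIter >= 1L)
  byGene <- split(transcripts$transcript_id, transcripts$gene_id)
  if (any(lengths(byGene) == 0L)) stop("gene with zero transcripts")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  lapply(seq_len(nIter), function(i) {
    picked <- vapply(byGene, function(tx) {
      if (length(tx) == 1L) tx else sample(tx, 1L)
    }, character(1))
    picked
  })
}

#' Length-normalised region breakdown of motif counts
#'
#' Motifs are assigned to the distal (-2000..-501), proximal (-500..-1) or
#' downstream (TSS..+999) region by their start position (a motif spanning
#' a boundary counts once, in its start's region). Counts are divided by
#' region length and the three rates rescaled to percentages summing
#' to 100, so a uniform motif density yields 33.33% everywhere.
#'
#' @param motifs motif table (rows of [pqsMotifs()]), possibly pre-filtered
#'   to one importance class.
#' @param upstream upstream TRR extent (region boundaries scale off it).
#' @return named numeric of length 3 (distal, proximal, downstream),
#'   percentages summing to 100.
#' @export
regionBreakdown <- function(motifs, upstream = 2000L) {
  motifs <- as.data.frame(motifs)
  if (nrow(motifs) == 0L) stop("no motifs in this class")
  offs <- motifs$start - upstream          # 0-based offset of motif start
  reg <- cut(offs, breaks = c(-Inf, -500.5, -0.5, Inf),
             labels = c("distal", "proximal", "downstream"))
  counts <- table(reg)
  rates <- as.numeric(counts) / as.numeric(.REGION_LEN[names(counts)])
  pct <- 100 * rates / sum(rates)
  setNames(pct, names(counts))
}

#' Tissue-level PQS enrichment
#'
#' The percentage of genes active in a tissue whose TRR carries at least
#' one PQS in the requested region, reported as mean +/- SD over the
#' transcript-pick iterations, with a one-way ANOVA p-value testing for
#' differences between iterations (computed on the per-gene 0/1 indicator
#' grouped by iteration).
#'
#' @param scan a [PQSScan].
#' @param geneOf named character vector transcript id -> gene id.
#' @param tissueGenes character vector of gene ids active in the tissue.
#' @param picks list of per-iteration transcript picks from
#'   [pickTranscripts()].
#' @param region,strand as in [countGenesWithPQS()].
#' @return list with `mean`, `sd`, `perIteration`, `anova_p`, `n_genes`.
#' @export
tissueEnrichment <- function(scan, geneOf, tissueGenes, picks,
                             region = "whole", strand = "either") {
  tids <- rownames(scan@codingMask)
  genes <- intersect(unique(tissueGenes), unique(geneOf[tids]))
  if (length(genes) == 0L) stop("tissue gene set does not intersect the annotation")
  has <- .maskHasMotif(scan, region, strand)
  perIter <- vapply(picks, function(p) {
    p <- p[genes]
    p <- p[!is.na(p) & p %in% tids]
    if (length(p) == 0L) return(NA_real_)
    100 * mean(has[match(p, tids)])
  }, numeric(1))
  indicator <- lapply(seq_along(picks), function(i) {
    p <- picks[[i]][genes]; p <- p[!is.na(p) & p %in% tids]
    data.frame(iter = i, hit = as.numeric(has[match(p, tids)]))
  })
  ind <- do.call(rbind, indicator)
  pval <- if (length(picks) >= 2L && stats::sd(ind$hit) > 0) {
    summary(stats::aov(hit ~ factor(iter), data = ind))[[1]][["Pr(>F)"]][1]
  } else NA_real_
  list(mean = mean(perIter, na.rm = TRUE),
       sd = stats::sd(perIter),
       perIteration = perIter,
       anova_p = pval,
       n_genes = length(genes))
}
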