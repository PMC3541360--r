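#' Read gene sets from a GMT file
#'
#' GMT lines are `name<TAB>description<TAB>member1<TAB>member2...`;
#' duplicate members within a line are collapsed. Malformed lines (fewer
#' than two fields) raise an error naming the line number. Parsing is
#' delegated to [fgsea::gmtPathways] after validation.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (gene ids), with a parallel
#'   `description` attribute.
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 2 tab-separated fields")
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  attr(sets, "description") <- setNames(
    vapply(fields, `[`, character(1), 2L),
    vapply(fields, `[`, character(1), 1L)
  )[names(sets)]
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors; an optional `description`
#'   attribute (named by set) fills the second column.
#' @param path output path.
#' @export
writeGeneSets <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-pathway percentage of G4-important genes, per iteration
#'
#' For one iteration's score table (one transcript per gene), the fraction
#' of analyzable member genes classified G4-important:
#' 100 * #{members with CF_o > 50 and CQ_o > 50} /
#' #{members with not both F_o and Q_o zero}. Genes with both scores zero
#' are excluded from the denominator.
#'
#' @param members character vector of member gene ids (duplicates ignored).
#' @param scores a score table from [scoreTranscripts()] restricted to one
#'   transcript per gene.
#' @return percentage in 0..100.
#' @export
pathwayPctImportant <- function(members, scores) {
  members <- unique(members)
  rows <- scores[scores$gene_id %in% members, , drop = FALSE]
  analyzable <- rows[!(rows$F_o == 0 & rows$Q_o == 0), , drop = FALSE]
  if (nrow(analyzable) == 0L)
    stop("no analyzable genes (all members have both scores zero)")
  imp <- !is.na(analyzable$CF_o) & !is.na(analyzable$CQ_o) &
    analyzable$CF_o > 50 & analyzable$CQ_o > 50
  100 * mean(imp)
}

#' Wilcoxon rank-sum comparison of pathway scores against the genome
#'
#' Two-sided rank-sum test of member-gene scores against the genome-wide
#' background of the same iteration (all transcripts without redundancy
#' from that iteration's pick). `P_max`, the worst p-value over
#' iterations, is the reported summary; p <= 0.05 is a reporting
#' threshold, not a filter.
#'
#' @param memberScores numeric vector (e.g. member CQ_o values).
#' @param genomeScores numeric vector for the background.
#' @return two-sided p-value.
#' @export
compareToGenome <- function(memberScores, genomeScores) {
  memberScores <- memberScores[!is.na(memberScores)]
  genomeScores <- genomeScores[!is.na(genomeScores)]
  if (length(memberScores) < 2L || length(genomeScores) < 2L)
    stop("both samples must have at least 2 values")
  suppressWarnings(
    stats::wilcox.test(memberScores, genomeScores,
                       alternative = "two.sided")$p.value
  )
}

#' One-way ANOVA across transcript-pick iterations
#'
#' Tests whether a pathway's per-gene scores differ between iterations;
#' p >= 0.05 indicates the random transcript picks did not materially
#' change the pathway's score distribution. Identical groups give F = 0
#' and p = 1.
#'
#' @param scoresByIteration list of numeric vectors, one per iteration.
#' @return ANOVA p-value.
#' @export
iterationConsistency <- function(scoresByIteration) {
  if (length(scoresByIteration) < 2L) stop("need at least 2 iterations")
  if (any(vapply(scoresByIteration, length, integer(1)) < 2L))
    stop("every iteration group needs at least 2 values")
  df <- data.frame(
    value = unlist(scoresByIteration, use.names = FALSE),
    iter = factor(rep(seq_along(scoresByIteration),
                      lengths(scoresByIteration)))
  )
  if (stats::sd(df$value) == 0) return(1)
  tab <- summary(stats::aov(value ~ iter, data = df))[[1]]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(p)) 1 else p
}

#' Pathway-level G4-importance summary
#'
#' Runs the full pathway procedure over a list of gene sets: per
#' iteration, scores are restricted to that iteration's one-transcript-
#' per-gene pick; pathways with more than `minSize` member genes present
#' in the annotation are summarised by the mean +/- SD percentage of
#' G4-important genes, the percentage of members with any PQS, worst-case
#' (maximal) Wilcoxon p-values of member CF_o and CQ_o against the
#' genome-wide background, and ANOVA consistency across iterations. A
#' pathway is flagged G4-important when its mean percentage exceeds 50.
#'
#' @param geneSets named list from [readGeneSets()].
#' @param scoresPerIteration list of score tables, one per iteration, each
#'   restricted to one transcript per gene (see [scoreTranscripts()] and
#'   [pickTranscripts()]).
#' @param minSize strict lower bound on member-gene count, default 50.
#' @return data.frame with one row per retained pathway.
#' @export
pathwaySummary <- function(geneSets, scoresPerIteration, minSize = 50L) {
  stopifnot(length(scoresPerIteration) >= 1L)
  allGenes <- unique(scoresPerIteration[[1]]$gene_id)
  rows <- lapply(names(geneSets), function(id) {
    members <- intersect(unique(geneSets[[id]]), allGenes)
    if (length(members) <= minSize) return(NULL)
    pct <- numeric(0); pCF <- numeric(0); pCQ <- numeric(0)
    cfGroups <- list(); cqGroups <- list()
    withG4 <- numeric(0)
    for (i in seq_along(scoresPerIteration)) {
      sc <- scoresPerIteration[[i]]
      rowsI <- sc[sc$gene_id %in% members, , drop = FALSE]
      pct[i] <- tryCatch(pathwayPctImportant(members, sc),
                         error = function(e) NA_real_)
      withG4[i] <- 100 * mean(rowsI$F_o > 0 | rowsI$Q_o > 0)
      bg <- sc
      pCF[i] <- compareToGenome(rowsI$CF_o, bg$CF_o)
      pCQ[i] <- compareToGenome(rowsI$CQ_o, bg$CQ_o)
      cfGroups[[i]] <- rowsI$CF_o[!is.na(rowsI$CF_o)]
      cqGroups[[i]] <- rowsI$CQ_o[!is.na(rowsI$CQ_o)]
    }
    nIter <- length(scoresPerIteration)
    aCF <- if (nIter >= 2L) iterationConsistency(cfGroups) else NA_real_
    aCQ <- if (nIter >= 2L) iterationConsistency(cqGroups) else NA_real_
    desc <- attr(geneSets, "description")
    data.frame(
      pathway_id = id,
      description = if (!is.null(desc) && id %in% names(desc)) desc[[id]] else id,
      n_genes = length(members),
      pct_high = mean(pct, na.rm = TRUE),
      pct_high_sd = if (nIter >= 2L) stats::sd(pct) else NA_real_,
      pct_with_g4 = mean(withG4),
      pct_with_g4_sd = if (nIter >= 2L) stats::sd(withG4) else NA_real_,
      p_CF = max(pCF), p_CQ = max(pCQ),
      anova_p_CF = aCF, anova_p_CQ = aCQ,
      anova_p = min(aCF, aCQ),
      important = mean(pct, na.rm = TRUE) > 50,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no pathway exceeds the minimum size threshold (", minSize, ")")
  rownames(out) <- NULL
  out[order(-out$pct_high), , drop = FALSE]
}
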