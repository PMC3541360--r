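test_that("fScore is the covered percentage of the TRR", {
  m <- rep(FALSE, 3000); m[1:30] <- TRUE
  expect_equal(fScore(m), 1.0)
  expect_equal(fScore(rep(FALSE, 3000)), 0.0)
  m2 <- rep(FALSE, 3000); m2[c(10:35, 100:124)] <- TRUE  # 26 + 25 nt
  expect_equal(fScore(m2), 1.7)
  expect_error(fScore(rep(FALSE, 10)), "length")
})

test_that("positionalProfile averages coverage indicators over transcripts", {
  sim <- simulateGenome(nGenes = 15, seed = 12)
  trr <- extractTRR(sim$genome, sim$transcripts, quiet = TRUE)
  scan <- scanTRR(trr)
  prof <- positionalProfile(scan)
  cd <- coverageMask(scan, "coding")
  expect_identical(prof$m, nrow(cd))
  expect_true(all(prof$W_coding >= 0 & prof$W_coding <= 1))
  # direct-summation oracle: sum_k W_k = mean per-transcript popcount
  expect_equal(sum(prof$W_coding), mean(rowSums(cd)))
  expect_equal(sum(prof$W_template),
               mean(rowSums(coverageMask(scan, "template"))))
  # two transcripts, a position covered in exactly one has W = 0.5
  sub <- positionalProfile(scan, rownames(cd)[1:2])
  onceCovered <- which(colSums(cd[1:2, , drop = FALSE]) == 1)
  if (length(onceCovered))
    expect_true(all(sub$W_coding[onceCovered] == 0.5))
})

test_that("qScore is the W-weighted coverage sum", {
  W <- rep(0.01, 3000)
  m <- rep(FALSE, 3000); m[201:250] <- TRUE
  expect_equal(qScore(m, W), 0.5)
  expect_equal(qScore(rep(FALSE, 3000), W), 0)
  # single-transcript corpus: W = own mask, Q = popcount
  expect_equal(qScore(m, as.numeric(m)), 50)
  expect_error(qScore(m, W[1:10]), "length")
})

test_that("cumulativeFrequency excludes zeros and uses inclusive ranks", {
  expect_equal(cumulativeFrequency(c(1, 2, 3, 4)), c(25, 50, 75, 100))
  expect_equal(cumulativeFrequency(c(0, 0, 5)), c(NA, NA, 100))
  expect_equal(cumulativeFrequency(c(2, 2, 4)),
               c(200 / 3, 200 / 3, 100))
  expect_error(cumulativeFrequency(c(0, 0)), "all scores are zero")
  # order-preserving and permutation-consistent
  set.seed(5)
  x <- c(rexp(50), rep(0, 10))
  p <- sample(length(x))
  expect_equal(cumulativeFrequency(x)[p], cumulativeFrequency(x[p]))
  nz <- which(x != 0)
  cf <- cumulativeFrequency(x)
  ord <- nz[order(x[nz])]
  expect_true(all(diff(cf[ord]) >= 0))
  expect_equal(max(cf, na.rm = TRUE), 100)
})

test_that("importance classification follows the dual-percentile rule", {
  # the cardiac troponin I promoter percentiles classify as important
  expect_identical(classifyImportance(92.6, 95.2), "important")
  # KIT's mixed percentiles are neither class
  expect_identical(classifyImportance(43.5, 73.4), "intermediate")
  expect_identical(classifyImportance(10, 10), "less-important")
  expect_identical(classifyImportance(50, 50), "intermediate")
  expect_identical(classifyImportance(NA, 80), "intermediate")
})

test_that("pearsonR matches the closed-form oracle", {
  expect_equal(pearsonR(1:10, 1:10), 1.0)
  expect_equal(pearsonR(1:10, -(1:10)), -1.0)
  expect_equal(pearsonR(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-6)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "constant")
  set.seed(9)
  for (i in 1:25) {
    x <- rnorm(50); y <- 0.3 * x + rnorm(50)
    expect_equal(pearsonR(x, y), pearsonOracle(x, y), tolerance = 1e-12)
  }
})

test_that("score table satisfies the additive strand identities exactly", {
  sim <- simulateGenome(nGenes = 40, seed = 19)
  trr <- extractTRR(sim$genome, sim$transcripts, quiet = TRUE)
  scan <- scanTRR(trr)
  prof <- positionalProfile(scan)
  sc <- scoreTranscripts(scan, prof)
  expect_identical(sc$F_o, sc$F_cd + sc$F_ncd)
  expect_identical(sc$Q_o, sc$Q_cd + sc$Q_ncd)
  # F = 0 iff the strand mask is empty
  cd <- coverageMask(scan, "coding")
  expect_identical(sc$F_cd == 0, unname(rowSums(cd)[sc$transcript_id] == 0))
  # direct-summation oracles for F and Q on a sample of transcripts
  for (i in sample(nrow(sc), 10)) {
    tid <- sc$transcript_id[i]
    expect_equal(sc$F_cd[i], 100 * sum(cd[tid, ]) / 3000)
    expect_equal(sc$Q_cd[i], sum(prof$W_coding[cd[tid, ]]))
  }
  # CF/CQ monotone nondecreasing in F/Q among nonzero scores
  nz <- which(sc$F_o > 0)
  ordF <- nz[order(sc$F_o[nz])]
  expect_true(all(diff(sc$CF_o[ordF]) >= 0))
})

test_that("planted F is exact when coverage is known by construction", {
  sim <- simulateGenome(nGenes = 25, maxTranscripts = 1, gc = 0.1,
                        countModel = "fixed", fixedCount = 1,
                        fracImportant = 1, codingProb = 1, seed = 77)
  trr <- extractTRR(sim$genome, sim$transcripts, quiet = TRUE)
  scan <- scanTRR(trr)
  sc <- scoreTranscripts(scan)
  truth <- sim$truthMotifs
  lens <- setNames(truth$end - truth$start, truth$transcript_id)
  spurious <- !(as.data.frame(pqsMotifs(scan))$start %in% truth$start)
  if (!any(spurious))
    expect_equal(sc$F_cd, unname(100 * lens[sc$transcript_id] / 3000))
})

test_that("pickTranscripts is deterministic, per-gene, and uniform", {
  tx <- data.frame(gene_id = rep(c("G1", "G2", "G3"), c(1, 2, 4)),
                   transcript_id = paste0("T", 1:7))
  p1 <- pickTranscripts(tx, nIter = 5, seed = 42)
  p2 <- pickTranscripts(tx, nIter = 5, seed = 42)
  expect_identical(p1, p2)
  expect_identical(length(p1), 5L)
  # single-transcript gene always picks its only transcript
  expect_true(all(vapply(p1, function(p) p[["G1"]] == "T1", logical(1))))
  # uniformity over many iterations: each of G3's four transcripts ~ n/4
  pm <- pickTranscripts(tx, nIter = 4000, seed = 7)
  tabs <- table(vapply(pm, function(p) p[["G3"]], character(1)))
  expect_identical(sort(names(tabs)), paste0("T", 4:7))
  sdMulti <- sqrt(4000 * 0.25 * 0.75)
  expect_true(all(abs(tabs - 1000) < 3 * sdMulti))
  expect_error(pickTranscripts(data.frame(gene_id = character(),
                                          transcript_id = character()),
                               nIter = 1),
               NA)  # empty annotation is fine (no genes)
})

test_that("regionBreakdown normalises counts by region length", {
  mkMotifs <- function(offsets)
    data.frame(start = offsets + 2000L, end = offsets + 2015L)
  # counts 10 / 20 / 30 over lengths 1500 / 500 / 1000
  offs <- c(seq(-1900, -600, length.out = 10),
            seq(-480, -40, length.out = 20),
            seq(10, 900, length.out = 30))
  out <- regionBreakdown(mkMotifs(round(offs)))
  expect_equal(unname(out), c(8.695652, 52.173913, 39.130435),
               tolerance = 1e-6)
  expect_equal(sum(out), 100)
  # counts proportional to lengths -> equal shares
  offs2 <- c(seq(-2000, -501, length.out = 15),
             seq(-500, -1, length.out = 5),
             seq(0, 980, length.out = 10))
  expect_equal(unname(regionBreakdown(mkMotifs(round(offs2)))),
               rep(100 / 3, 3))
  # all motifs proximal
  out3 <- regionBreakdown(mkMotifs(c(-400L, -300L)))
  expect_equal(unname(out3[c("distal", "proximal", "downstream")]),
               c(0, 100, 0))
  expect_error(regionBreakdown(mkMotifs(integer(0))), "no motifs")
})

test_that("tissue enrichment recovers the planting probability over seeds", {
  means <- numeric(20)
  p <- 0.7
  for (s in 1:20) {
    sim <- simulateGenome(nGenes = 40, maxTranscripts = 2,
                          fracImportant = p, gc = 0.15,
                          countModel = "fixed", fixedCount = 1,
                          seed = 900 + s)
    trr <- extractTRR(sim$genome, sim$transcripts, quiet = TRUE)
    scan <- scanTRR(trr)
    info <- as.data.frame(trrInfo(trr))
    geneOf <- setNames(info$gene_id, info$transcript_id)
    picks <- pickTranscripts(info, nIter = 3, seed = s)
    e <- tissueEnrichment(scan, geneOf, unique(info$gene_id), picks)
    means[s] <- e$mean
  }
  sdBinom <- 100 * sqrt(p * (1 - p) / 40)
  expect_lt(abs(mean(means) - 100 * p), 3 * sdBinom)
})

test_that("W_k peaks just upstream of the TSS under Gaussian planting", {
  sim <- simulateGenome(nGenes = 150, maxTranscripts = 1,
                        fracImportant = 1, lambdaImportant = 3,
                        gaussWeight = 1, mu = -50, sigma = 150,
                        codingProb = 1, gc = 0.2, seed = 23)
  trr <- extractTRR(sim$genome, sim$transcripts, quiet = TRUE)
  scan <- scanTRR(trr)
  prof <- positionalProfile(scan)
  argmaxOffset <- indexToOffset(which.max(prof$W_coding))
  expect_gte(argmaxOffset, -200)
  expect_lte(argmaxOffset, 0)
})

test_that("planted importance classes are recovered at large effect size", {
  accs <- numeric(20)
  for (s in 1:20) {
    sim <- simulateGenome(nGenes = 60, maxTranscripts = 1,
                          fracImportant = 0.3, lambdaImportant = 6,
                          lambdaBackground = 1, seed = 6000 + s)
    trr <- extractTRR(sim$genome, sim$transcripts, quiet = TRUE)
    scan <- scanTRR(trr)
    sc <- scoreTranscripts(scan)
    cls <- merge(sc, sim$geneClasses, by = "gene_id")
    planted <- cls$class.y == "important"
    accs[s] <- mean(cls$important[planted])
  }
  expect_gte(mean(accs), 0.9)
})
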