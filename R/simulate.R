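# Synthetic-data generators with recorded ground truth. Defaults describe
# the study conditions the rest of the package is validated under: a
# Gaussian positional law centred 50 nt upstream of the TSS (sd 150 nt)
# for G4-important genes, tract lengths 3-5 and loops 1-7 matching the
# scanner grammar, and planted loops/flanks free of G (and C) so truth
# intervals are exact by construction.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# one random PQS respecting the grammar: 4 G-tracts of 3-5, loops 1-7
# drawn from {A,C,T} so the planted interval cannot merge with its
# surroundings on either strand
.samplePQS <- function(tractRange = 3:5, loopRange = 1:7) {
  tracts <- sample(tractRange, 4L, replace = TRUE)
  loops <- sample(loopRange, 3L, replace = TRUE)
  parts <- character(7L)
  parts[c(1, 3, 5, 7)] <- vapply(tracts, function(n)
    strrep("G", n), character(1))
  parts[c(2, 4, 6)] <- vapply(loops, function(n)
    paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  paste(parts, collapse = "")
}

.randomBases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Simulate a planted-motif genome with annotation and truth records
#'
#' Builds one contig carrying `nGenes` gene loci. Each gene gets 1 to
#' `maxTranscripts` transcripts whose TSSs are staggered by
#' `txSpacing` nt, a strand, and an importance class: "important" genes
#' receive `lambdaImportant` planted PQS per TRR (Poisson), placed by a
#' mixture of a Gaussian at `mu` +/- `sigma` (weight `gaussWeight`) and a
#' uniform law; "background" genes receive `lambdaBackground` uniformly
#' placed PQS. Motifs are drawn from the scanner grammar (tracts 3-5,
#' loops 1-7, G/C-free loops) and planted with 8-nt A/T flanks -- wider
#' than the longest legal loop, so no G-run can merge with or chain into
#' a planted motif and the scanner recovers exactly the truth interval; a
#' motif that cannot be placed without overlap after bounded retries
#' raises an error.
#'
#' @param nGenes number of genes, default 200.
#' @param maxTranscripts maximum transcripts per gene (uniform 1..max).
#' @param fracImportant fraction of genes planted as G4-important.
#' @param lambdaImportant,lambdaBackground expected planted motifs per
#'   TRR for each class.
#' @param mu,sigma Gaussian positional law (TSS-relative offset of the
#'   motif start), defaults -50 and 150.
#' @param gaussWeight mixture weight of the Gaussian for important genes
#'   (background genes are always uniform).
#' @param codingProb probability a planted motif sits on the coding
#'   strand.
#' @param gc background GC fraction, default 0.42 (G fraction gc/2).
#' @param countModel "poisson" or "fixed"; "fixed" plants exactly
#'   `fixedCount` motifs per important-gene TRR.
#' @param fixedCount motif count under `countModel = "fixed"`.
#' @param txSpacing TSS stagger between transcripts of a gene, nt.
#' @param seed integer seed; fixes every draw.
#' @return list with `genome` (DNAStringSet), `transcripts` (annotation
#'   data.frame), `truthMotifs` (per-transcript TRR-local truth
#'   intervals), `geneClasses` (gene_id, class), and `config`.
#' @export
simulateGenome <- function(nGenes = 200L, maxTranscripts = 3L,
                           fracImportant = 0.3,
                           lambdaImportant = 6, lambdaBackground = 1,
                           mu = -50, sigma = 150, gaussWeight = 0.9,
                           codingProb = 0.7, gc = 0.42,
                           countModel = c("poisson", "fixed"),
                           fixedCount = 1L, txSpacing = 40L, seed = 1L) {
  countModel <- match.arg(countModel)
  stopifnot(nGenes >= 1L, fracImportant >= 0, fracImportant <= 1,
            mu >= -.TRR_UP, mu < .TRR_DOWN, gc > 0, gc < 1)
  .withSeed(seed, {
    nImp <- round(nGenes * fracImportant)
    classes <- c(rep("important", nImp),
                 rep("background", nGenes - nImp))
    classes <- sample(classes)

    regions <- vector("list", nGenes)
    geneRows <- vector("list", nGenes)
    truthRows <- vector("list", nGenes)
    gap <- 100L

    for (g in seq_len(nGenes)) {
      geneId <- sprintf("G%04d", g)
      nTx <- sample.int(maxTranscripts, 1L)
      txOff <- (seq_len(nTx) - 1L) * txSpacing
      strand <- sample(c("+", "-"), 1L)
      regLen <- .TRR_UP + max(txOff) + .TRR_DOWN
      reg <- .randomBases(regLen, gc)

      lambda <- if (classes[g] == "important") lambdaImportant
                else lambdaBackground
      nMotif <- if (countModel == "fixed") {
        if (classes[g] == "important") as.integer(fixedCount) else 0L
      } else stats::rpois(1L, lambda)

      used <- matrix(numeric(0), ncol = 2)  # 0-based [s, e) incl. flanks
      planted <- list()
      for (k in seq_len(nMotif)) {
        motif <- .samplePQS()
        len <- nchar(motif)
        placed <- FALSE
        for (try in 1:200) {
          useGauss <- classes[g] == "important" &&
            stats::runif(1) < gaussWeight
          off <- if (useGauss) round(stats::rnorm(1, mu, sigma))
                 else sample.int(.TRR_LEN - len, 1L) - 1L - .TRR_UP
          off <- max(-.TRR_UP, min(off, .TRR_DOWN - len - 1L))
          s <- off + .TRR_UP              # 0-based within first TRR axis
          e <- s + len
          fs <- s - 8L; fe <- e + 8L      # flanked interval (> loopMax)
          if (fs < 0L || fe > regLen) next
          if (nrow(used) &&
              any(pmax(used[, 1], fs) < pmin(used[, 2], fe))) next
          coding <- stats::runif(1) < codingProb
          ins <- if (coding) motif else revComp(motif)
          reg[(s + 1L):e] <- strsplit(ins, "")[[1]]
          # A/T flanks stop tract extension or chaining across the edge
          flanks <- c((fs + 1L):s, (e + 1L):fe)
          reg[flanks] <- sample(c("A", "T"), length(flanks), replace = TRUE)
          used <- rbind(used, c(fs, fe))
          planted[[length(planted) + 1L]] <-
            data.frame(gene_id = geneId,
                       strand = if (coding) "coding" else "template",
                       geneStart = s, geneEnd = e, sequence = motif,
                       stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place motif ", k, " in gene ", geneId,
               " without overlap (planting intensity too high)")
      }
      regions[[g]] <- list(seq = reg, strand = strand, nTx = nTx,
                           txOff = txOff, geneId = geneId, regLen = regLen)
      geneRows[[g]] <- planted
    }

    # assemble the contig and the annotation
    contigParts <- character(nGenes)
    annot <- vector("list", nGenes)
    truth <- vector("list", nGenes)
    pos <- 1L
    for (g in seq_len(nGenes)) {
      r <- regions[[g]]
      senseStr <- paste(r$seq, collapse = "")
      contigParts[g] <- if (r$strand == "+") senseStr else revComp(senseStr)
      # transcript TSSs in genomic coordinates
      iTSS <- .TRR_UP + r$txOff          # 0-based local index of TSS base
      tssG <- if (r$strand == "+") pos + iTSS
              else pos + (r$regLen - 1L) - iTSS
      annot[[g]] <- data.frame(
        gene_id = r$geneId,
        transcript_id = sprintf("%s.T%d", r$geneId, seq_len(r$nTx)),
        chromosome = "chr1", strand = r$strand, tss = as.integer(tssG),
        stringsAsFactors = FALSE)
      planted <- geneRows[[g]]
      if (length(planted)) {
        pm <- do.call(rbind, planted)
        perTx <- lapply(seq_len(r$nTx), function(j) {
          s <- pm$geneStart - r$txOff[j]; e <- pm$geneEnd - r$txOff[j]
          keep <- s >= 0L & e <= .TRR_LEN
          if (!any(keep)) return(NULL)
          data.frame(transcript_id = sprintf("%s.T%d", r$geneId, j),
                     gene_id = r$geneId, strand = pm$strand[keep],
                     start = s[keep], end = e[keep],
                     sequence = pm$sequence[keep],
                     stringsAsFactors = FALSE)
        })
        truth[[g]] <- do.call(rbind, perTx)
      }
      pos <- pos + r$regLen + gap
    }
    spacer <- paste(.randomBases(gap, gc), collapse = "")
    contig <- paste(contigParts, collapse = spacer)

    truthMotifs <- do.call(rbind, truth)
    if (is.null(truthMotifs))
      truthMotifs <- data.frame(transcript_id = character(),
                                gene_id = character(), strand = character(),
                                start = integer(), end = integer(),
                                sequence = character())
    rownames(truthMotifs) <- NULL
    list(
      genome = Biostrings::DNAStringSet(setNames(contig, "chr1")),
      transcripts = do.call(rbind, annot),
      truthMotifs = truthMotifs,
      geneClasses = data.frame(
        gene_id = sprintf("G%04d", seq_len(nGenes)),
        class = classes, stringsAsFactors = FALSE),
      config = list(nGenes = nGenes, fracImportant = fracImportant,
                    lambdaImportant = lambdaImportant,
                    lambdaBackground = lambdaBackground,
                    mu = mu, sigma = sigma, gaussWeight = gaussWeight,
                    codingProb = codingProb, gc = gc, seed = seed)
    )
  })
}

#' Simulate gene sets with controlled importance enrichment
#'
#' Each pathway samples `size` member genes; a member is drawn from the
#' planted-important class with probability `enrichment` and from the
#' background class otherwise, so `enrichment` is the expected fraction
#' of important members.
#'
#' @param geneClasses data.frame from [simulateGenome()] (`gene_id`,
#'   `class`).
#' @param nPathways number of gene sets.
#' @param size members per set (must not exceed the available genes).
#' @param enrichment probability in [0,1] that a member is important.
#' @param seed integer seed.
#' @return named list of gene-id vectors with `truth` attribute (the
#'   realised fraction of important members per set) and a `description`
#'   attribute.
#' @export
simulateGeneSets <- function(geneClasses, nPathways = 5L, size = 60L,
                             enrichment = 0.7, seed = 1L) {
  imp <- geneClasses$gene_id[geneClasses$class == "important"]
  bg <- geneClasses$gene_id[geneClasses$class != "important"]
  if (size > nrow(geneClasses)) stop("pathway size exceeds gene count")
  if ((enrichment > 0 && length(imp) == 0L) ||
      (enrichment < 1 && length(bg) == 0L))
    stop("infeasible enrichment for the available gene classes")
  .withSeed(seed, {
    sets <- list(); truth <- numeric(nPathways)
    for (p in seq_len(nPathways)) {
      fromImp <- stats::rbinom(size, 1L, enrichment) == 1L
      nImp <- min(sum(fromImp), length(imp))
      members <- c(sample(imp, nImp),
                   sample(bg, min(size - nImp, length(bg))))
      sets[[sprintf("path%02d", p)]] <- members
      truth[p] <- nImp / length(members)
    }
    attr(sets, "truth") <- setNames(truth, names(sets))
    attr(sets, "description") <- setNames(
      sprintf("synthetic pathway %d (enrichment %.2f)",
              seq_len(nPathways), enrichment), names(sets))
    sets
  })
}

#' Simulate a two-state CD melting curve
#'
#' Forward model of [fitMeltingTwoState()] with linear baselines and
#' Gaussian noise proportional to the clean signal range.
#'
#' @param tm melting temperature, degrees C (default 71.4).
#' @param dH unfolding enthalpy, kJ mol-1 (default 170).
#' @param temperature sampling grid, degrees C.
#' @param baselines numeric (bf0, bf1, bu0, bu1): folded/unfolded
#'   intercepts (signal) and slopes (signal per K).
#' @param noise relative Gaussian noise (sd as a fraction of the clean
#'   range), default 0.
#' @param seed integer seed.
#' @return data.frame (temperature_C, signal) with a `truth` attribute.
#' @export
simulateMeltingCurve <- function(tm = 71.4, dH = 170,
                                 temperature = seq(20, 95, by = 2.5),
                                 baselines = c(bf0 = 1.44, bf1 = -0.0015,
                                               bu0 = 0.247, bu1 = -5e-4),
                                 noise = 0, seed = 1L) {
  TK <- temperature + 273.15
  clean <- .meltModel(TK, tm + 273.15, dH * 1000,
                      baselines[[1]], baselines[[2]],
                      baselines[[3]], baselines[[4]])
  y <- if (noise > 0) .withSeed(seed,
        clean + stats::rnorm(length(clean), 0, noise * diff(range(clean))))
       else clean
  out <- data.frame(temperature_C = temperature, signal = y)
  attr(out, "truth") <- list(tm = tm, dH = dH, baselines = baselines,
                             dS = 1000 * dH / (tm + 273.15))
  out
}

#' Simulate an exponential unfolding trace
#'
#' Forward model of [fitDoubleExponential()]; set `A2 = 0` for a pure
#' single exponential. Noise is Gaussian with sd `noise * (A1 + A2)`.
#'
#' @param A1,k1,A2,k2,C model parameters (rates s-1).
#' @param time sampling grid, s; the default covers both phases of the
#'   default rates.
#' @param noise relative noise, default 0.
#' @param seed integer seed.
#' @return data.frame (time_s, signal) with a `truth` attribute.
#' @export
simulateKineticTrace <- function(A1 = 0.5, k1 = 1e-2, A2 = 0.5, k2 = 3e-4,
                                 C = 0,
                                 time = sort(unique(c(seq(0, 1000, by = 10),
                                                      seq(1000, 15000, by = 250)))),
                                 noise = 0, seed = 1L) {
  clean <- A1 * exp(-k1 * time) + A2 * exp(-k2 * time) + C
  amp <- abs(A1) + abs(A2)
  y <- if (noise > 0) .withSeed(seed,
        clean + stats::rnorm(length(clean), 0, noise * amp))
       else clean
  out <- data.frame(time_s = time, signal = y)
  attr(out, "truth") <- list(A1 = A1, k1 = k1, A2 = A2, k2 = k2, C = C)
  out
}

#' Simulate temperature-dependent rate constants
#'
#' Arrhenius forward model k(T) = A exp(-Ea / RT) with optional lognormal
#' noise on the rates.
#'
#' @param Ea activation energy, kJ mol-1 (default 22.1).
#' @param lnA log pre-exponential factor (ln of s-1).
#' @param temperature temperatures, degrees C.
#' @param noise lognormal sd on log k, default 0.
#' @param seed integer seed.
#' @return data.frame (temperature_C, k) with a `truth` attribute.
#' @export
simulateRates <- function(Ea = 22.1, lnA = 1.5,
                          temperature = c(25, 35, 45, 55),
                          noise = 0, seed = 1L) {
  TK <- temperature + 273.15
  k <- exp(lnA - Ea * 1000 / (.R_GAS * TK))
  if (noise > 0) k <- .withSeed(seed,
      k * exp(stats::rnorm(length(k), 0, noise)))
  out <- data.frame(temperature_C = temperature, k = k)
  attr(out, "truth") <- list(Ea = Ea, lnA = lnA)
  out
}

#' Simulate a thiazole-orange-like emission spectrum
#'
#' Gaussian emission band scaled by the retained (non-displaced)
#' fluorescence fraction, for FID validation.
#'
#' @param scale fraction of the standard's intensity retained (1 = no
#'   ligand).
#' @param wavelength grid in nm.
#' @param peak,width band centre and sd in nm.
#' @param noise relative Gaussian noise on intensities.
#' @param seed integer seed.
#' @return data.frame (wavelength_nm, intensity).
#' @export
simulateEmissionSpectrum <- function(scale = 1, wavelength = seq(510, 750, 2),
                                     peak = 535, width = 28,
                                     noise = 0, seed = 1L) {
  clean <- scale * exp(-(wavelength - peak)^2 / (2 * width^2))
  y <- if (noise > 0) .withSeed(seed,
        clean + stats::rnorm(length(clean), 0, noise * max(scale, 1e-9)))
       else clean
  data.frame(wavelength_nm = wavelength, intensity = y)
}

#' Simulate a sigmoidal dose-response / FID displacement curve
#'
#' Four-parameter-logistic forward model of [fitMidpoint()], sampled on a
#' ligand titration grid with absolute Gaussian noise.
#'
#' @param midpoint DC50/EC50 in uM (default 0.31).
#' @param hill Hill slope (default 1.5).
#' @param top,bottom plateaus (default 100 and 0, percent displacement).
#' @param concentration titration grid, uM (default 0.0125..20 covering
#'   the transition).
#' @param noise absolute Gaussian sd on the response (default 0; "2%
#'   noise" on a 0-100 scale is `noise = 2`).
#' @param seed integer seed.
#' @return data.frame (conc_uM, response) with a `truth` attribute.
#' @export
simulateDoseResponse <- function(midpoint = 0.31, hill = 1.5,
                                 top = 100, bottom = 0,
                                 concentration = c(0.0125, 0.025, 0.05, 0.125,
                                                   0.25, 0.5, 1, 2, 5, 10, 20),
                                 noise = 0, seed = 1L) {
  if (top == bottom) stop("degenerate curve: top equals bottom")
  clean <- .fourPL(concentration, bottom, top, log10(midpoint), hill)
  y <- if (noise > 0) .withSeed(seed,
        clean + stats::rnorm(length(clean), 0, noise))
       else clean
  out <- data.frame(conc_uM = concentration, response = y)
  attr(out, "truth") <- list(midpoint = midpoint, hill = hill,
                             top = top, bottom = bottom)
  out
}

#' Write a simulated genome to FASTA and its annotation to TSV
#'
#' @param sim result of [simulateGenome()].
#' @param fastaPath,annotPath output paths.
#' @return invisibly, the two paths.
#' @export
writeSimulatedGenome <- function(sim, fastaPath, annotPath) {
  Biostrings::writeXStringSet(sim$genome, fastaPath)
  utils::write.table(sim$transcripts, annotPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fastaPath, annot = annotPath))
}
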