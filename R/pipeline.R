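# Pipeline orchestration: scan -> score -> enrich/pathway with
# reproducibility metadata, plus batched biophysical fits. All outputs
# are plain TSV/JSON written atomically (temp file + rename) together
# with a provenance block (input checksums, parameters, seed) so a run
# can be replayed from its provenance alone.

.writeAtomic <- function(write, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  write(tmp)
  file.rename(tmp, path)
  path
}

.writeTsv <- function(df, path) {
  .writeAtomic(function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE), path)
}

#' Run the promoter G4 landscape pipeline
#'
#' Reads a genome and annotation, extracts TRRs, scans both strands for
#' PQS, computes the positional profile and per-transcript score table
#' (full redundant transcript set), repeats scoring over `iterations`
#' random one-transcript-per-gene picks, and optionally aggregates to
#' tissue and pathway level. Every table is written under `outDir`
#' together with `provenance.json`.
#'
#' @param fasta,annot input genome FASTA and transcript TSV paths.
#' @param outDir output directory (created if missing).
#' @param tissueGmt,pathwayGmt optional GMT paths for tissue activity
#'   lists and pathway gene sets.
#' @param upstream,downstream TRR extents (defaults 2000/1000).
#' @param loopMin,loopMax scanner loop bounds (defaults 1/7).
#' @param iterations transcript-pick iterations (default 10).
#' @param minSize pathway size threshold (default 50).
#' @param seed integer seed governing the picks.
#' @param region region used for the tissue enrichment table.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results (`trrset`,
#'   `scan`, `profile`, `scores`, `picks`, `scoresPerIteration`,
#'   `prevalence`, `regionBreakdown`, `tissue`, `pathways`, `provenance`).
#' @export
runLandscape <- function(fasta, annot, outDir,
                         tissueGmt = NULL, pathwayGmt = NULL,
                         upstream = 2000L, downstream = 1000L,
                         loopMin = 1L, loopMax = 7L,
                         iterations = 10L, minSize = 50L, seed = 17L,
                         region = "whole", quiet = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- "read_genome"
  res <- tryCatch({
    genome <- readGenome(fasta)
    stage <- "read_transcripts"
    transcripts <- readTranscripts(annot)
    stage <- "extract_trr"
    trrset <- extractTRR(genome, transcripts, upstream, downstream,
                         quiet = quiet)
    stage <- "scan_trr"
    scan <- scanTRR(trrset, loopMin = loopMin, loopMax = loopMax)
    stage <- "score"
    profile <- positionalProfile(scan)
    scores <- scoreTranscripts(scan, profile)
    info <- as.data.frame(trrInfo(trrset))
    geneOf <- setNames(info$gene_id, info$transcript_id)
    picks <- pickTranscripts(info, nIter = iterations, seed = seed)
    scoresPerIteration <- lapply(picks, function(p) {
      sub <- scoreTranscripts(scan, profile, reference = unname(p))
      sub[sub$transcript_id %in% p, , drop = FALSE]
    })
    prevalence <- data.frame(
      region = "whole",
      strand = c("either", "coding", "template"),
      pct_genes = vapply(c("either", "coding", "template"), function(s)
        mean(vapply(picks, function(p)
          countGenesWithPQS(scan, geneOf, unname(p), "whole", s),
          numeric(1))), numeric(1))
    )
    stage <- "region_breakdown"
    motifs <- as.data.frame(pqsMotifs(scan))
    cls <- setNames(scores$class, scores$transcript_id)
    rb <- lapply(c("important", "less-important"), function(cl) {
      sub <- motifs[cls[motifs$transcript_id] == cl, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      data.frame(class = cl, t(regionBreakdown(sub, upstream)))
    })
    rb <- do.call(rbind, rb)
    stage <- "tissue_enrichment"
    tissue <- NULL
    if (!is.null(tissueGmt)) {
      sets <- readGeneSets(tissueGmt)
      tissue <- do.call(rbind, lapply(names(sets), function(nm) {
        e <- tissueEnrichment(scan, geneOf, sets[[nm]], picks,
                              region = region)
        data.frame(tissue = nm, n_genes = e$n_genes, mean = e$mean,
                   sd = e$sd, anova_p = e$anova_p)
      }))
    }
    stage <- "pathway"
    pathways <- NULL
    if (!is.null(pathwayGmt)) {
      sets <- readGeneSets(pathwayGmt)
      pathways <- pathwaySummary(sets, scoresPerIteration, minSize)
    }
    list(trrset = trrset, scan = scan, profile = profile, scores = scores,
         picks = picks, scoresPerIteration = scoresPerIteration,
         prevalence = prevalence, regionBreakdown = rb, tissue = tissue,
         pathways = pathways)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  inputs <- c(fasta = fasta, annot = annot,
              tissueGmt = tissueGmt, pathwayGmt = pathwayGmt)
  prov <- list(
    package = "promG4",
    version = as.character(utils::packageVersion("promG4")),
    inputs = as.list(inputs),
    checksums = as.list(tools::md5sum(unlist(inputs))),
    parameters = list(upstream = upstream, downstream = downstream,
                      loopMin = loopMin, loopMax = loopMax,
                      iterations = iterations, minSize = minSize,
                      seed = seed, region = region),
    warnings = list(excluded_transcripts = nrow(trrExcluded(res$trrset)))
  )
  .writeTsv(res$scores, file.path(outDir, "scores.tsv"))
  .writeTsv(res$prevalence, file.path(outDir, "prevalence.tsv"))
  if (!is.null(res$regionBreakdown))
    .writeTsv(res$regionBreakdown, file.path(outDir, "region_breakdown.tsv"))
  .writeTsv(data.frame(offset = indexToOffset(seq_len(res$scan@trrLength),
                                              upstream),
                       W_coding = res$profile$W_coding,
                       W_template = res$profile$W_template),
            file.path(outDir, "positional_profile.tsv"))
  if (!is.null(res$tissue))
    .writeTsv(res$tissue, file.path(outDir, "tissue_enrichment.tsv"))
  if (!is.null(res$pathways))
    .writeTsv(res$pathways, file.path(outDir, "pathway_summary.tsv"))
  writeMotifsBed(pqsMotifs(res$scan), res$trrset,
                 file.path(outDir, "motifs.bed"))
  .writeAtomic(function(tmp)
    jsonlite::write_json(prov, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null"),
    file.path(outDir, "provenance.json"))
  res$provenance <- prov
  invisible(res)
}

#' Run the biophysical fitting commands in batch
#'
#' Fits whichever inputs are supplied and writes one JSON report per
#' analysis under `outDir`: a two-state melting fit (with dG at 310 K), a
#' set of kinetic traces at several temperatures followed by Arrhenius
#' and Eyring analysis of the slow (unfolding) rate, an FID spectra
#' bundle with DC50, and a dose-response EC50 fit.
#'
#' @param outDir output directory.
#' @param meltingCsv CSV with columns temperature_C, signal.
#' @param kineticsCsvs named character vector of CSVs (columns time_s,
#'   signal), names = temperature in degrees C.
#' @param trapConcentration C-rich trap concentration, mol L-1, for
#'   pseudo-first-order normalisation (default 2e-6).
#' @param fidSpectraCsvs named character vector of CSVs (columns
#'   wavelength_nm, intensity), names = ligand concentration in uM.
#' @param fidStandardCsv CSV for the no-ligand standard spectrum.
#' @param doseCsv CSV with columns conc_uM, response.
#' @return invisibly, a list of the fit objects.
#' @export
runFits <- function(outDir, meltingCsv = NULL, kineticsCsvs = NULL,
                    trapConcentration = 2e-6, fidSpectraCsvs = NULL,
                    fidStandardCsv = NULL, doseCsv = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  if (!is.null(meltingCsv)) {
    d <- utils::read.csv(meltingCsv)
    fit <- fitMeltingTwoState(d$temperature_C, d$signal, celsius = TRUE)
    out$melting <- fit
    .writeAtomic(function(tmp) jsonlite::write_json(list(
      model = "two-state van't Hoff, linear baselines",
      tm_C = fit@tm, dH_kJ = fit@dH, dS_J = fit@dS,
      dG310_kJ = meltingDG(fit, 310),
      se = as.list(fit@se), baselines = as.list(fit@baselines)),
      tmp, auto_unbox = TRUE, digits = NA),
      file.path(outDir, "melting_fit.json"))
  }
  if (!is.null(kineticsCsvs)) {
    tempsC <- as.numeric(names(kineticsCsvs))
    if (anyNA(tempsC))
      stop("kineticsCsvs must be named by temperature (degrees C)")
    fits <- lapply(kineticsCsvs, function(p) {
      d <- utils::read.csv(p)
      fitDoubleExponential(d$time_s, d$signal)
    })
    # slow component = unfolding; fast = trap hybridisation
    kSlow <- vapply(fits, function(f)
      if (f@model == "double") f@k2 else f@k1, numeric(1))
    arr <- if (length(kSlow) >= 3L)
      fitArrhenius(tempsC, kSlow, celsius = TRUE) else NULL
    eyr <- if (length(kSlow) >= 3L)
      eyringParams(tempsC, kSlow, celsius = TRUE) else NULL
    out$kinetics <- list(fits = fits, arrhenius = arr, eyring = eyr)
    .writeAtomic(function(tmp) jsonlite::write_json(list(
      traces = lapply(seq_along(fits), function(i) {
        f <- fits[[i]]
        list(temperature_C = tempsC[i], model = f@model,
             A1 = f@A1, k1 = f@k1, A2 = f@A2, k2 = f@k2, C = f@C0,
             k2nd_slow_Msinv = pseudoFirstOrder(
               if (f@model == "double") f@k2 else f@k1, trapConcentration))
      }),
      arrhenius = if (!is.null(arr)) list(Ea_kJ = arr@Ea, lnA = arr@lnA,
                                          se_Ea = arr@se[["Ea"]]),
      eyring = if (!is.null(eyr)) list(dH_act_kJ = eyr@dH_act,
                                       dS_act_J = eyr@dS_act)),
      tmp, auto_unbox = TRUE, digits = NA),
      file.path(outDir, "kinetics_fit.json"))
  }
  if (!is.null(fidSpectraCsvs) && !is.null(fidStandardCsv)) {
    spectra <- lapply(fidSpectraCsvs, utils::read.csv)
    names(spectra) <- names(fidSpectraCsvs)
    fid <- fidAnalysis(spectra, utils::read.csv(fidStandardCsv))
    out$fid <- fid
    .writeAtomic(function(tmp) jsonlite::write_json(list(
      table = fid$table,
      dc50_uM = if (!is.null(fid$fit)) fid$fit@midpoint,
      hill = if (!is.null(fid$fit)) fid$fit@hill,
      method = if (!is.null(fid$fit)) fid$fit@method),
      tmp, auto_unbox = TRUE, digits = NA, dataframe = "rows"),
      file.path(outDir, "fid_analysis.json"))
  }
  if (!is.null(doseCsv)) {
    d <- utils::read.csv(doseCsv)
    fit <- fitMidpoint(d$conc_uM, d$response, kind = "EC50")
    out$dose <- fit
    .writeAtomic(function(tmp) jsonlite::write_json(list(
      ec50_uM = fit@midpoint, hill = fit@hill, top = fit@top,
      bottom = fit@bottom, method = fit@method),
      tmp, auto_unbox = TRUE, digits = NA),
      file.path(outDir, "dose_fit.json"))
  }
  invisible(out)
}
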