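#' TRRSet: a set of sense-oriented transcription-regulatory regions
#'
#' Holds one fixed-width window per retained transcript, always read 5'->3'
#' on the coding (sense) strand with the TSS base at array index
#' `upstream` (0-based). Transcripts whose window would overhang a contig
#' are excluded, never truncated, so every sequence has identical length
#' and abundance scores share a common denominator.
#'
#' @slot sequences a [Biostrings::DNAStringSet], one entry per retained
#'   transcript, named by transcript id.
#' @slot info a [S4Vectors::DataFrame] with columns `transcript_id`,
#'   `gene_id`, `chromosome`, `strand`, `tss`, parallel to `sequences`.
#' @slot excluded a [S4Vectors::DataFrame] with columns `transcript_id`
#'   and `reason` for transcripts whose TRR fell outside the contig.
#' @slot upstream,downstream integer extents of the window in nt.
#' @exportClass TRRSet
setClass("TRRSet",
  slots = c(
    sequences = "DNAStringSet",
    info = "DataFrame",
    excluded = "DataFrame",
    upstream = "integer",
    downstream = "integer"
  )
)

setValidity("TRRSet", function(object) {
  msg <- character()
  len <- object@upstream + object@downstream
  if (length(object@sequences) != nrow(object@info))
    msg <- c(msg, "sequences and info must be parallel")
  if (length(object@sequences) &&
      !all(Biostrings::width(object@sequences) == len))
    msg <- c(msg, sprintf("all TRR sequences must have width %d", len))
  need <- c("transcript_id", "gene_id", "chromosome", "strand", "tss")
  if (!all(need %in% colnames(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PQSScan: motif calls and per-position coverage for a TRRSet
#'
#' Motif coordinates are TRR-local, 0-based half-open, always on the
#' coding-strand axis; template-strand motifs are reported with their
#' G-rich sequence (read on the template strand) and mirrored coordinates.
#' Coverage masks record, per strand, whether each of the 3000 positions
#' lies under at least one motif (union of spans, a nucleotide in two
#' motifs counts once).
#'
#' @slot motifs a [S4Vectors::DataFrame] with columns `transcript_id`,
#'   `gene_id`, `strand` ("coding"/"template"), `start`, `end` (0-based
#'   half-open on the coding axis), `sequence`.
#' @slot codingMask,templateMask logical matrices, one row per transcript
#'   (rownames = transcript ids), `trrLength` columns.
#' @slot trrLength integer TRR width.
#' @exportClass PQSScan
setClass("PQSScan",
  slots = c(
    motifs = "DataFrame",
    codingMask = "matrix",
    templateMask = "matrix",
    trrLength = "integer"
  )
)

setValidity("PQSScan", function(object) {
  msg <- character()
  if (!identical(dim(object@codingMask), dim(object@templateMask)))
    msg <- c(msg, "coding and template masks must have identical shape")
  if (ncol(object@codingMask) != object@trrLength)
    msg <- c(msg, "mask width must equal trrLength")
  if (!is.logical(object@codingMask) || !is.logical(object@templateMask))
    msg <- c(msg, "masks must be logical matrices")
  if (length(msg)) msg else TRUE
})

# ---- curve-fit result classes -------------------------------------------

#' Two-state melting fit result
#'
#' @slot tm melting temperature, degrees C.
#' @slot dH unfolding enthalpy, kJ mol-1.
#' @slot dS unfolding entropy, J mol-1 K-1 (derived as 1000*dH/Tm(K), i.e.
#'   dG(Tm) = 0 by construction).
#' @slot baselines numeric vector (folded intercept/slope, unfolded
#'   intercept/slope) in signal units and signal units per K.
#' @slot se named numeric vector of parameter standard errors.
#' @slot data the fitted (temperature K, signal) table.
#' @slot converged logical.
#' @exportClass MeltingFit
setClass("MeltingFit",
  slots = c(tm = "numeric", dH = "numeric", dS = "numeric",
            baselines = "numeric", se = "numeric", data = "data.frame",
            converged = "logical")
)

#' Exponential-decay kinetic fit result
#'
#' @slot model "double" or "single" (selected by corrected AIC, with a
#'   single-exponential fallback when the two rates are indistinguishable).
#' @slot A1,A2 amplitudes (signal units); A2 = 0 for a single-exponential.
#' @slot k1,k2 observed rate constants, s-1, with k1 >= k2.
#' @slot C0 signal offset (value at infinite time).
#' @slot se named numeric vector of standard errors.
#' @slot aicc named numeric vector of corrected-AIC values per candidate.
#' @exportClass KineticFit
setClass("KineticFit",
  slots = c(model = "character", A1 = "numeric", k1 = "numeric",
            A2 = "numeric", k2 = "numeric", C0 = "numeric",
            se = "numeric", aicc = "numeric")
)

#' Arrhenius fit result
#'
#' @slot Ea activation energy, kJ mol-1 (Ea = -slope * R from ln k vs 1/T).
#' @slot lnA log pre-exponential factor (ln of s-1).
#' @slot se standard errors (Ea in kJ mol-1, lnA dimensionless).
#' @slot meanT mean experimental temperature, K.
#' @exportClass ArrheniusFit
setClass("ArrheniusFit",
  slots = c(Ea = "numeric", lnA = "numeric", se = "numeric",
            meanT = "numeric")
)

#' Eyring fit / conversion result
#'
#' @slot dH_act activation enthalpy, kJ mol-1.
#' @slot dS_act activation entropy, J mol-1 K-1 (NA when derived from Ea
#'   alone).
#' @slot se standard errors where available.
#' @slot Tref reference temperature, K, used for the Ea -> dH_act shortcut.
#' @exportClass EyringFit
setClass("EyringFit",
  slots = c(dH_act = "numeric", dS_act = "numeric", se = "numeric",
            Tref = "numeric")
)

#' Four-parameter-logistic midpoint fit (DC50 / EC50)
#'
#' @slot midpoint concentration at half-maximal response, in the input
#'   concentration unit (conventionally uM).
#' @slot hill Hill slope.
#' @slot top,bottom response plateaus.
#' @slot kind "DC50" or "EC50".
#' @slot se named standard errors.
#' @slot method "4PL" or "interpolation" (fallback when the plateaus are
#'   not bracketed by the data).
#' @exportClass SigmoidFit
setClass("SigmoidFit",
  slots = c(midpoint = "numeric", hill = "numeric", top = "numeric",
            bottom = "numeric", kind = "character", se = "numeric",
            method = "character")
)
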