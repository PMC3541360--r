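#' @name promG4-accessors
#' @title Accessors for TRRSet and PQSScan objects
#' @description Slot access for the core containers goes through these
#'   accessors; the slots themselves are implementation detail.
#' @param x a `TRRSet` or `PQSScan`.
#' @param strand for `coverageMask`, which strand mask to return.
#' @return `trrSequences`: a `DNAStringSet`; `trrInfo`, `trrExcluded`,
#'   `pqsMotifs`: a `DataFrame`; `coverageMask`: a logical matrix with one
#'   row per transcript.
NULL

#' @rdname promG4-accessors
#' @export
setGeneric("trrSequences", function(x) standardGeneric("trrSequences"))

#' @rdname promG4-accessors
#' @export
setGeneric("trrInfo", function(x) standardGeneric("trrInfo"))

#' @rdname promG4-accessors
#' @export
setGeneric("trrExcluded", function(x) standardGeneric("trrExcluded"))

#' @rdname promG4-accessors
#' @export
setGeneric("pqsMotifs", function(x) standardGeneric("pqsMotifs"))

#' @rdname promG4-accessors
#' @export
setGeneric("coverageMask",
  function(x, strand = c("coding", "template")) standardGeneric("coverageMask"))

#' @rdname promG4-accessors
setMethod("trrSequences", "TRRSet", function(x) x@sequences)

#' @rdname promG4-accessors
setMethod("trrInfo", "TRRSet", function(x) x@info)

#' @rdname promG4-accessors
setMethod("trrExcluded", "TRRSet", function(x) x@excluded)

#' @rdname promG4-accessors
setMethod("pqsMotifs", "PQSScan", function(x) x@motifs)

#' @rdname promG4-accessors
setMethod("coverageMask", "PQSScan", function(x, strand = c("coding", "template")) {
  strand <- match.arg(strand)
  if (strand == "coding") x@codingMask else x@templateMask
})

setMethod("show", "TRRSet", function(object) {
  cat(sprintf("TRRSet with %d TRR(s) of width %d (%d upstream / %d downstream)\n",
              length(object@sequences), object@upstream + object@downstream,
              object@upstream, object@downstream))
  cat(sprintf("  genes: %d, excluded transcripts: %d\n",
              length(unique(object@info$gene_id)), nrow(object@excluded)))
})

setMethod("length", "TRRSet", function(x) length(x@sequences))

setMethod("show", "PQSScan", function(object) {
  tab <- table(factor(object@motifs$strand, levels = c("coding", "template")))
  cat(sprintf("PQSScan: %d motif(s) over %d TRR(s) (coding %d, template %d)\n",
              nrow(object@motifs), nrow(object@codingMask),
              tab[["coding"]], tab[["template"]]))
})

setMethod("show", "MeltingFit", function(object) {
  cat(sprintf("Two-state melting fit: Tm = %.2f C, dH = %.1f kJ/mol, dS = %.1f J/mol/K\n",
              object@tm, object@dH, object@dS))
  cat(sprintf("  dG(310 K) = %.2f kJ/mol%s\n", meltingDG(object, 310),
              if (object@converged) "" else "  [not converged]"))
})

setMethod("show", "KineticFit", function(object) {
  if (object@model == "double")
    cat(sprintf("Double-exponential fit: A1 = %.3g (k1 = %.3g /s), A2 = %.3g (k2 = %.3g /s), C = %.3g\n",
                object@A1, object@k1, object@A2, object@k2, object@C0))
  else
    cat(sprintf("Single-exponential fit: A = %.3g (k = %.3g /s), C = %.3g\n",
                object@A1, object@k1, object@C0))
})

setMethod("show", "ArrheniusFit", function(object) {
  cat(sprintf("Arrhenius fit: Ea = %.2f kJ/mol (se %.2g), ln A = %.3f\n",
              object@Ea, object@se[["Ea"]], object@lnA))
})

setMethod("show", "EyringFit", function(object) {
  cat(sprintf("Eyring analysis: dH_act = %.2f kJ/mol, dS_act = %s J/mol/K\n",
              object@dH_act,
              if (is.na(object@dS_act)) "NA" else sprintf("%.1f", object@dS_act)))
})

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf("%s fit (%s): midpoint = %.4g, hill = %.3g, range %.3g..%.3g\n",
              object@kind, object@method, object@midpoint, object@hill,
              object@bottom, object@top))
})
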