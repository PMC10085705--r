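#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Accessors for the core classes; prefer these to direct slot access.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))
#' @rdname accessors
#' @export
setGeneric("motifBlocks", function(x) standardGeneric("motifBlocks"))
#' @rdname accessors
#' @export
setGeneric("motifStems", function(x) standardGeneric("motifStems"))
#' @rdname accessors
#' @export
setGeneric("linkerRange", function(x) standardGeneric("linkerRange"))
#' @rdname accessors
#' @export
setGeneric("typeName", function(x) standardGeneric("typeName"))
#' @rdname accessors
#' @export
setGeneric("blockOrder", function(x) standardGeneric("blockOrder"))
#' @rdname accessors
#' @export
setGeneric("stemExtents", function(x) standardGeneric("stemExtents"))
#' @rdname accessors
#' @export
setGeneric("alignmentIds", function(x) standardGeneric("alignmentIds"))
#' @rdname accessors
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))
#' @rdname accessors
#' @export
setGeneric("consensusPairs", function(x) standardGeneric("consensusPairs"))
#' @rdname accessors
#' @export
setGeneric("kObs", function(x) standardGeneric("kObs"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

setMethod("motifName", "MotifDescriptor", function(x) x@name)
setMethod("motifBlocks", "MotifDescriptor", function(x) x@blocks)
setMethod("motifStems", "MotifDescriptor", function(x) x@stems)
setMethod("linkerRange", "MotifDescriptor", function(x) x@linkerRange)
setMethod("typeName", "PermutationLayout", function(x) x@typeName)
setMethod("blockOrder", "PermutationLayout", function(x) x@order)
setMethod("stemExtents", "PermutationLayout", function(x) x@stemExtents)
setMethod("typeName", "CompiledPattern", function(x) x@layout@typeName)
setMethod("alignmentIds", "StructuredAlignment", function(x) x@ids)
setMethod("alignmentRows", "StructuredAlignment", function(x) {
  structure(x@rows, names = x@ids)
})
setMethod("consensusPairs", "StructuredAlignment", function(x) x@pairs)
setMethod("kObs", "DecayFit", function(x) x@k)
setMethod("rSquared", "DecayFit", function(x) x@r2)
setMethod("isConverged", "DecayFit", function(x) x@converged)

#' @export
setMethod("show", "MotifDescriptor", function(object) {
  cat(sprintf("MotifDescriptor '%s': %d blocks, %d stems, linker %d:%d\n",
              object@name, length(object@blocks), length(object@stems),
              object@linkerRange[1], object@linkerRange[2]))
  for (b in object@blocks) {
    parts <- vapply(b@elements, function(e) switch(e@kind,
      literal = e@literal,
      stem_half = sprintf("[%s%s]", e@stemId,
                          if (e@side == "first") "" else "'"),
      spacer = sprintf("n{%d,%d}", e@lengthRange[1], e@lengthRange[2]),
      cleavage_site = "^"), "")
    cat(sprintf("  block %s: %s\n", b@label, paste(parts, collapse = " ")))
  }
  for (s in object@stems)
    cat(sprintf("  stem %s: %d-%d bp%s%s%s\n", s@stemId,
                s@lengthRange[1], s@lengthRange[2],
                if (s@wobble) ", wobble" else "",
                if (s@mismatchBudget > 0L)
                  sprintf(", mismatch<=%d", s@mismatchBudget) else "",
                if (s@required) "" else ", optional"))
})

#' @export
setMethod("show", "PermutationLayout", function(object) {
  cat(sprintf("PermutationLayout type %s (%d elements, %d stems)\n",
              object@typeName, nrow(object@elements),
              nrow(object@stemExtents)))
})

#' @export
setMethod("show", "CompiledPattern", function(object) {
  cat(sprintf("CompiledPattern %s/%s: %d units, match length %d-%d nt\n",
              object@motif, typeName(object), nrow(object@plan),
              object@minLen, object@maxLen))
})

#' @export
setMethod("show", "StructuredAlignment", function(object) {
  cat(sprintf("StructuredAlignment: %d sequences x %d columns, %d pairs",
              length(object@ids),
              if (length(object@rows)) nchar(object@rows[1]) else 0L,
              nrow(object@pairs)))
  if (nrow(object@pairs))
    cat(sprintf(" (%d tiers)", length(unique(object@pairs$tier))))
  cat("\n")
})

#' @export
setMethod("show", "DecayFit", function(object) {
  if (object@converged)
    cat(sprintf(
      "DecayFit: k_obs = %.4g min^-1 (se %.2g), y0 = %.3f, plateau = %.3f, R2 = %.3f, n = %d\n",
      object@k, object@seK, object@y0, object@plateau, object@r2,
      object@nPoints))
  else
    cat(sprintf("DecayFit: not converged (%s), n = %d\n",
                object@message, object@nPoints))
})
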