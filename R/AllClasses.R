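#' @import methods
NULL

# RNA alphabet helpers used by validity methods; heavier matching machinery
# lives in utils.R.
.IUPAC_RNA <- c(A = "A", C = "C", G = "G", U = "U",
                R = "AG", Y = "CU", S = "CG", W = "AU", K = "GU", M = "AC",
                B = "CGU", D = "AGU", H = "ACU", V = "ACG", N = "ACGU")

.validIupac <- function(x) {
  chars <- strsplit(toupper(chartr("T", "U", x)), "")[[1]]
  all(chars %in% names(.IUPAC_RNA))
}

#' MotifElement: one element of a motif block
#'
#' An element is either a (possibly degenerate) sequence literal, one half of
#' a stem, a variable-length spacer, or the cleavage-site marker. Elements are
#' ordered 5' to 3' within their block and that order is immutable under
#' block permutation.
#'
#' @slot kind one of \code{"literal"}, \code{"stem_half"}, \code{"spacer"},
#'   \code{"cleavage_site"}.
#' @slot literal IUPAC RNA string (only for literals).
#' @slot stemId stem identifier (only for stem halves).
#' @slot side \code{"first"} or \code{"second"} half (declaration order;
#'   linear order in a permuted layout may differ).
#' @slot lengthRange integer min/max length in nucleotides (spacers).
#' @exportClass MotifElement
setClass("MotifElement",
  representation(kind = "character", literal = "character",
                 stemId = "character", side = "character",
                 lengthRange = "integer"),
  prototype(kind = NA_character_, literal = NA_character_,
            stemId = NA_character_, side = NA_character_,
            lengthRange = c(NA_integer_, NA_integer_)))

setValidity("MotifElement", function(object) {
  msg <- character()
  if (!object@kind %in% c("literal", "stem_half", "spacer", "cleavage_site"))
    msg <- c(msg, sprintf("unknown element kind '%s'", object@kind))
  if (object@kind == "literal") {
    if (is.na(object@literal) || nchar(object@literal) == 0L)
      msg <- c(msg, "literal element needs a non-empty sequence")
    else if (!.validIupac(object@literal))
      msg <- c(msg, sprintf("literal '%s' contains non-IUPAC characters",
                            object@literal))
  }
  if (object@kind == "stem_half") {
    if (is.na(object@stemId))
      msg <- c(msg, "stem_half element needs a stem id")
    if (!object@side %in% c("first", "second"))
      msg <- c(msg, "stem_half side must be 'first' or 'second'")
    if (!is.na(object@literal))
      msg <- c(msg, "stem_half elements carry no sequence")
  }
  if (object@kind == "spacer") {
    lr <- object@lengthRange
    if (any(is.na(lr)) || lr[1] < 0L || lr[1] > lr[2])
      msg <- c(msg, "spacer needs 0 <= min <= max length")
  }
  if (length(msg)) msg else TRUE
})

#' StemSpec: pairing requirements for one stem
#'
#' @slot stemId identifier referenced by two stem_half elements.
#' @slot lengthRange integer min/max helix length in base pairs.
#' @slot wobble logical; are G-U pairs permitted.
#' @slot mismatchBudget integer; non-pairing positions tolerated.
#' @slot required logical; required stems define the core topology, optional
#'   stems model tertiary contacts such as the hammerhead stem I-II
#'   interaction.
#' @exportClass StemSpec
setClass("StemSpec",
  representation(stemId = "character", lengthRange = "integer",
                 wobble = "logical", mismatchBudget = "integer",
                 required = "logical"),
  prototype(wobble = FALSE, mismatchBudget = 0L, required = TRUE))

setValidity("StemSpec", function(object) {
  msg <- character()
  lr <- object@lengthRange
  if (any(is.na(lr)) || lr[1] < 1L || lr[1] > lr[2])
    msg <- c(msg, sprintf("stem %s: need 1 <= min <= max length",
                          object@stemId))
  if (object@mismatchBudget < 0L)
    msg <- c(msg, "mismatch budget must be >= 0")
  if (!any(is.na(lr)) && object@mismatchBudget >= lr[1])
    msg <- c(msg, sprintf("stem %s: mismatch budget must be < min length",
                          object@stemId))
  if (length(msg)) msg else TRUE
})

#' MotifBlock: an indivisible, ordered run of motif elements
#'
#' @slot label single-character block label (e.g. C, G, S).
#' @slot elements list of \linkS4class{MotifElement}, 5' to 3'.
#' @exportClass MotifBlock
setClass("MotifBlock",
  representation(label = "character", elements = "list"))

setValidity("MotifBlock", function(object) {
  msg <- character()
  if (length(object@label) != 1L || nchar(object@label) != 1L)
    msg <- c(msg, "block label must be a single character")
  if (length(object@elements) == 0L)
    msg <- c(msg, sprintf("block %s has no elements", object@label))
  if (!all(vapply(object@elements, is, TRUE, class2 = "MotifElement")))
    msg <- c(msg, "block elements must be MotifElement objects")
  if (length(msg)) msg else TRUE
})

#' MotifDescriptor: a permutable block-structured RNA motif
#'
#' The central descriptor object: blocks of conserved literals and stem
#' half-sites whose internal order is fixed, joined in any block order by
#' variable-length linkers. A descriptor is valid for every permutation of
#' its blocks (it carries no ordering-specific fields).
#'
#' @slot name motif name.
#' @slot blocks list of \linkS4class{MotifBlock}.
#' @slot stems list of \linkS4class{StemSpec}.
#' @slot linkerRange integer min/max nucleotides between consecutive blocks.
#' @slot notes free-text annotation.
#' @exportClass MotifDescriptor
setClass("MotifDescriptor",
  representation(name = "character", blocks = "list", stems = "list",
                 linkerRange = "integer", notes = "character"),
  prototype(notes = character()))

setValidity("MotifDescriptor", function(object) {
  msg <- character()
  labs <- vapply(object@blocks, function(b) b@label, "")
  if (anyDuplicated(labs))
    msg <- c(msg, "duplicate block labels")
  ids <- vapply(object@stems, function(s) s@stemId, "")
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicate stem ids")
  # collect stem halves across blocks
  halves <- list()
  ncleave <- 0L
  for (b in object@blocks) for (e in b@elements) {
    if (e@kind == "stem_half") {
      if (!e@stemId %in% ids)
        msg <- c(msg, sprintf("stem_half references undeclared stem '%s'",
                              e@stemId))
      halves[[length(halves) + 1L]] <- c(e@stemId, e@side)
    }
    if (e@kind == "cleavage_site") ncleave <- ncleave + 1L
  }
  if (ncleave > 1L)
    msg <- c(msg, "at most one cleavage site per descriptor")
  hid <- vapply(halves, `[`, "", 1L)
  for (s in object@stems) {
    n <- sum(hid == s@stemId)
    sides <- vapply(halves[hid == s@stemId], `[`, "", 2L)
    if (s@required && n != 2L)
      msg <- c(msg, sprintf("required stem %s has %d halves (need 2)",
                            s@stemId, n))
    if (!s@required && !n %in% c(0L, 2L))
      msg <- c(msg, sprintf("optional stem %s has %d halves (need 0 or 2)",
                            s@stemId, n))
    if (n == 2L && !setequal(sides, c("first", "second")))
      msg <- c(msg, sprintf("stem %s needs one first and one second half",
                            s@stemId))
  }
  lr <- object@linkerRange
  if (any(is.na(lr)) || lr[1] < 0L || lr[1] > lr[2])
    msg <- c(msg, "linker range needs 0 <= min <= max")
  if (length(msg)) msg else TRUE
})

#' PermutationLayout: one block ordering, linearized
#'
#' The 5'-to-3' concatenation of the descriptor's blocks in one order, with a
#' linker slot between consecutive blocks. Its type name is the concatenated
#' block labels (e.g. "SGC").
#'
#' @slot typeName the order string, e.g. \code{"SGC"}.
#' @slot order character vector of block labels.
#' @slot elements data.frame with one row per linearized element: columns
#'   \code{block}, \code{kind}, \code{literal}, \code{stemId}, \code{side},
#'   \code{minLen}, \code{maxLen}.
#' @slot stemExtents data.frame: \code{stemId}, \code{from}, \code{to}
#'   (element row indices of the linearly first and second half),
#'   \code{required}.
#' @exportClass PermutationLayout
setClass("PermutationLayout",
  representation(typeName = "character", order = "character",
                 elements = "data.frame", stemExtents = "data.frame"))

setValidity("PermutationLayout", function(object) {
  msg <- character()
  if (object@typeName != paste(object@order, collapse = ""))
    msg <- c(msg, "typeName must be the concatenated block order")
  ext <- object@stemExtents
  if (nrow(ext) && any(ext$from >= ext$to))
    msg <- c(msg, "stem extents must satisfy from < to")
  if (nrow(ext) && (any(ext$from < 1L) || any(ext$to > nrow(object@elements))))
    msg <- c(msg, "stem extents outside element table")
  if (length(msg)) msg else TRUE
})

#' CompiledPattern: a (descriptor, layout) pair ready for scanning
#'
#' @slot motif descriptor name.
#' @slot layout the \linkS4class{PermutationLayout} compiled.
#' @slot plan data.frame of matchable units in linear order with length
#'   bounds (columns as in the layout's element table).
#' @slot stems named list of \linkS4class{StemSpec} for pairing policy.
#' @slot minLen,maxLen total match length bounds.
#' @exportClass CompiledPattern
setClass("CompiledPattern",
  representation(motif = "character", layout = "PermutationLayout",
                 plan = "data.frame", stems = "list",
                 minLen = "integer", maxLen = "integer"))

setValidity("CompiledPattern", function(object) {
  msg <- character()
  if (object@minLen != sum(object@plan$minLen))
    msg <- c(msg, "minLen must equal the sum of element minima")
  for (s in object@stems)
    if (!is(s, "StemSpec")) msg <- c(msg, "stems must be StemSpec objects")
  if (length(msg)) msg else TRUE
})

#' StructuredAlignment: aligned sequences with a consensus pair table
#'
#' @slot ids sequence identifiers.
#' @slot rows aligned rows (equal width, gap character '-').
#' @slot pairs data.frame of consensus base pairs: 1-based column indices
#'   \code{i} < \code{j}, \code{tier} (nesting level; pseudoknots occupy
#'   distinct tiers), and optional \code{stem} label (NA when unknown).
#' @slot ss consensus structure string (WUSS) the pair table was derived
#'   from, kept for lossless Stockholm round-trips (NA when constructed
#'   from a pair table directly).
#' @slot ref optional reference row (NA when absent).
#' @exportClass StructuredAlignment
setClass("StructuredAlignment",
  representation(ids = "character", rows = "character", pairs = "data.frame",
                 ss = "character", ref = "character"),
  prototype(ss = NA_character_, ref = NA_character_))

setValidity("StructuredAlignment", function(object) {
  msg <- character()
  if (length(object@ids) != length(object@rows))
    msg <- c(msg, "ids and rows differ in length")
  if (!is.na(object@ss) && length(object@rows) &&
      nchar(object@ss) != nchar(object@rows[1]))
    msg <- c(msg, "SS_cons width differs from alignment width")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicate sequence ids")
  w <- unique(nchar(object@rows))
  if (length(w) > 1L)
    msg <- c(msg, "alignment rows differ in width")
  p <- object@pairs
  if (nrow(p)) {
    if (any(p$i >= p$j)) msg <- c(msg, "pair columns must satisfy i < j")
    cols <- c(p$i, p$j)
    if (anyDuplicated(cols))
      msg <- c(msg, "a column may appear in at most one pair")
    if (length(w) == 1L && any(cols > w))
      msg <- c(msg, "pair column outside alignment")
    # tiers must be internally non-crossing
    for (tr in unique(p$tier)) {
      q <- p[p$tier == tr, , drop = FALSE]
      if (nrow(q) > 1L) {
        for (a in seq_len(nrow(q) - 1L)) for (b in (a + 1L):nrow(q)) {
          x <- sort(c(q$i[a], q$j[a])); y <- sort(c(q$i[b], q$j[b]))
          if ((x[1] < y[1] && y[1] < x[2] && x[2] < y[2]) ||
              (y[1] < x[1] && x[1] < y[2] && y[2] < x[2])) {
            msg <- c(msg, sprintf("crossing pairs within tier %s", tr))
            break
          }
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' DecayFit: one-phase exponential decay fit of a cleavage time course
#'
#' Model: f(t) = (y0 - plateau) * exp(-k t) + plateau, fitted to the
#' fraction of full-length transcript L/(L+S) versus time.
#'
#' @slot k observed cleavage rate constant (per minute).
#' @slot y0 initial fraction full-length.
#' @slot plateau asymptotic fraction.
#' @slot r2 coefficient of determination.
#' @slot seK standard error of k (NA when unavailable).
#' @slot converged did the optimizer converge to a non-degenerate fit.
#' @slot nPoints number of time points used.
#' @slot message diagnostics for non-converged fits.
#' @exportClass DecayFit
setClass("DecayFit",
  representation(k = "numeric", y0 = "numeric", plateau = "numeric",
                 r2 = "numeric", seK = "numeric", converged = "logical",
                 nPoints = "integer", message = "character"),
  prototype(seK = NA_real_, message = ""))

setValidity("DecayFit", function(object) {
  msg <- character()
  if (object@converged) {
    if (!is.na(object@k) && object@k <= 0)
      msg <- c(msg, "converged fit requires k > 0")
    if (!is.na(object@r2) && object@r2 > 1 + 1e-9)
      msg <- c(msg, "R2 cannot exceed 1")
  }
  if (length(msg)) msg else TRUE
})
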