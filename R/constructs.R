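#' @include simulate.R
NULL

# Return a copy of a descriptor with all variable lengths pinned, so that
# sampled instances have a deterministic architecture.
.pinDescriptor <- function(descriptor, stemLengths, linker) {
  stems <- lapply(descriptor@stems, function(s) {
    if (s@stemId %in% names(stemLengths)) {
      len <- as.integer(stemLengths[[s@stemId]])
      initialize(s, lengthRange = c(len, len))
    } else s
  })
  initialize(descriptor, stems = stems,
             linkerRange = rep(as.integer(linker), 2L))
}

#' Synthetic analogues of the validated permuted-ribozyme constructs
#'
#' Generates in-silico transcripts with the geometry of the experimentally
#' characterized constructs: a type-SGC construct of 79 nt whose predicted
#' scissile bond lies after position 15 (5'/3' cleavage fragments of 15 and
#' 64 nt), and a type-CSG construct of 77 nt cleaving after position 48
#' (fragments of 48 and 29 nt). The motif instance itself is sampled from
#' the built-in hammerhead descriptor with stem I pinned at 5 bp, stems
#' II/III at 4 bp and 3-nt linkers; flanking nucleotides are random. These
#' are synthetic stand-ins -- the geometry matches the published constructs,
#' the primary sequence does not.
#'
#' @param name \code{"SGC-1"} or \code{"CSG-1"} (synthetic analogues).
#' @param seed RNG seed for the sampled instance and flanks.
#' @return list with \code{sequence}, \code{type}, \code{site} (0-based
#'   inter-nucleotide cleavage coordinate), \code{len5}, \code{len3} and
#'   the instance \code{span} within the construct.
#' @examples
#' x <- syntheticConstruct("SGC-1", seed = 1)
#' c(x$len5, x$len3)  # 15 64
#' @export
syntheticConstruct <- function(name = c("SGC-1", "CSG-1"), seed = 1L) {
  name <- match.arg(name)
  d <- .pinDescriptor(builtinDescriptor("hammerhead"),
                      c(I = 5L, II = 4L, III = 4L), linker = 3L)
  geom <- switch(name,
    "SGC-1" = list(order = c("S", "G", "C"), total = 79L, site = 15L),
    "CSG-1" = list(order = c("C", "S", "G"), total = 77L, site = 48L))
  layout <- permutationLayout(d, geom$order)
  .withSeed(seed, {
    inst <- sampleInstance(d, layout, policy = "none", wobbleProb = 0)
    instLen <- nchar(inst$sequence)
    flank5 <- geom$site - inst$truth$cleavage
    flank3 <- geom$total - flank5 - instLen
    stopifnot(flank5 >= 0L, flank3 >= 0L)
    sequence <- paste0(
      paste(.sampleBg(flank5), collapse = ""),
      inst$sequence,
      paste(.sampleBg(flank3), collapse = ""))
    el <- inst$truth$elements
    el$start <- el$start + flank5
    el$end <- el$end + flank5
    list(sequence = sequence, type = typeName(layout), site = geom$site,
         len5 = geom$site, len3 = geom$total - geom$site,
         span = c(flank5, flank5 + instLen), elements = el)
  })
}
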