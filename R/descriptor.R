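#' @include AllClasses.R utils.R
NULL

# ---- element constructors (internal) ---------------------------------------

.literalElement <- function(seq) {
  new("MotifElement", kind = "literal", literal = .normalizeRna(seq))
}
.stemElement <- function(stemId, side) {
  new("MotifElement", kind = "stem_half", stemId = stemId, side = side)
}
.spacerElement <- function(min, max) {
  new("MotifElement", kind = "spacer",
      lengthRange = c(as.integer(min), as.integer(max)))
}
.cleaveElement <- function() new("MotifElement", kind = "cleavage_site")

# ---- descriptor grammar ----------------------------------------------------

#' Parse a motif descriptor from text
#'
#' The descriptor grammar is line-oriented. Directives:
#' \preformatted{
#'   motif <name>
#'   stem <id> len=<min>:<max> [wobble] [mismatch=<k>] [optional]
#'   linker <min>:<max>
#'   block <label>
#'     seq <IUPAC>
#'     stem5 <id>   # linearly-declared first half
#'     stem3 <id>   # second half
#'     spacer <min>:<max>
#'     cleave
#' }
#' Comments start with \code{#}; blank lines are ignored; element lines apply
#' to the most recent \code{block}. T is normalized to U.
#'
#' @param text descriptor file content (single string or character vector of
#'   lines).
#' @return a validated \linkS4class{MotifDescriptor}.
#' @seealso [readDescriptor()], [descriptorText()], [builtinDescriptor()]
#' @examples
#' d <- builtinDescriptor("hammerhead")
#' identical(parseDescriptor(descriptorText(d)), d)
#' @export
parseDescriptor <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  name <- NA_character_
  stems <- list()
  blocks <- list()
  linker <- NA_integer_
  notes <- character()
  curBlock <- NULL

  flushBlock <- function() {
    if (!is.null(curBlock)) {
      if (length(curBlock$elements) == 0L)
        .stopf("line %d: block %s has no elements",
               curBlock$line, curBlock$label)
      blocks[[length(blocks) + 1L]] <<-
        new("MotifBlock", label = curBlock$label,
            elements = curBlock$elements)
    }
    curBlock <<- NULL
  }
  parseRange <- function(tok, lineno, what) {
    m <- regmatches(tok, regexec("^([0-9]+):([0-9]+)$", tok))[[1]]
    if (length(m) != 3L)
      .stopf("line %d: malformed %s range '%s' (expected min:max)",
             lineno, what, tok)
    c(as.integer(m[2]), as.integer(m[3]))
  }

  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    kw <- tok[1]
    if (kw == "motif") {
      if (length(tok) < 2L) .stopf("line %d: motif needs a name", i)
      name <- tok[2]
    } else if (kw == "stem") {
      if (length(tok) < 3L) .stopf("line %d: stem needs id and len=", i)
      id <- tok[2]
      lenTok <- grep("^len=", tok, value = TRUE)
      if (!length(lenTok)) .stopf("line %d: stem %s lacks len=min:max", i, id)
      lr <- parseRange(sub("^len=", "", lenTok[1]), i, "stem length")
      mmTok <- grep("^mismatch=", tok, value = TRUE)
      mm <- if (length(mmTok)) as.integer(sub("^mismatch=", "", mmTok[1]))
            else 0L
      stems[[length(stems) + 1L]] <- new("StemSpec",
        stemId = id, lengthRange = lr,
        wobble = "wobble" %in% tok, mismatchBudget = mm,
        required = !("optional" %in% tok))
    } else if (kw == "linker") {
      if (length(tok) < 2L) .stopf("line %d: linker needs min:max", i)
      linker <- parseRange(tok[2], i, "linker")
    } else if (kw == "block") {
      if (length(tok) < 2L) .stopf("line %d: block needs a label", i)
      flushBlock()
      curBlock <- list(label = tok[2], elements = list(), line = i)
    } else if (kw %in% c("seq", "stem5", "stem3", "spacer", "cleave")) {
      if (is.null(curBlock))
        .stopf("line %d: element '%s' outside any block", i, kw)
      el <- switch(kw,
        seq = {
          if (length(tok) < 2L) .stopf("line %d: seq needs a sequence", i)
          if (!.validIupac(tok[2]))
            .stopf("line %d: '%s' is not an IUPAC nucleotide string",
                   i, tok[2])
          .literalElement(tok[2])
        },
        stem5 = {
          if (length(tok) < 2L) .stopf("line %d: stem5 needs a stem id", i)
          .stemElement(tok[2], "first")
        },
        stem3 = {
          if (length(tok) < 2L) .stopf("line %d: stem3 needs a stem id", i)
          .stemElement(tok[2], "second")
        },
        spacer = {
          if (length(tok) < 2L) .stopf("line %d: spacer needs min:max", i)
          r <- parseRange(tok[2], i, "spacer")
          .spacerElement(r[1], r[2])
        },
        cleave = .cleaveElement())
      curBlock$elements[[length(curBlock$elements) + 1L]] <- el
    } else {
      .stopf("line %d: unknown directive '%s'", i, kw)
    }
  }
  flushBlock()
  if (is.na(name)) .stopf("descriptor lacks a 'motif <name>' directive")
  if (any(is.na(linker))) linker <- c(0L, 50L)
  d <- new("MotifDescriptor", name = name, blocks = blocks, stems = stems,
           linkerRange = linker, notes = notes)
  validObject(d)
  d
}

#' Read a motif descriptor file
#'
#' @param path path to a descriptor file (see [parseDescriptor()] for the
#'   grammar).
#' @return a \linkS4class{MotifDescriptor}.
#' @export
readDescriptor <- function(path) {
  parseDescriptor(readLines(path, warn = FALSE))
}

#' Serialize a descriptor back to its file grammar
#'
#' \code{parseDescriptor(descriptorText(d))} is the identity.
#'
#' @param descriptor a \linkS4class{MotifDescriptor}.
#' @return a single string in the descriptor grammar.
#' @export
descriptorText <- function(descriptor) {
  stopifnot(is(descriptor, "MotifDescriptor"))
  out <- c(sprintf("motif %s", descriptor@name))
  for (s in descriptor@stems)
    out <- c(out, sprintf("stem %s len=%d:%d%s%s%s", s@stemId,
      s@lengthRange[1], s@lengthRange[2],
      if (s@wobble) " wobble" else "",
      if (s@mismatchBudget > 0L) sprintf(" mismatch=%d", s@mismatchBudget)
      else "",
      if (s@required) "" else " optional"))
  out <- c(out, sprintf("linker %d:%d", descriptor@linkerRange[1],
                        descriptor@linkerRange[2]))
  for (b in descriptor@blocks) {
    out <- c(out, sprintf("block %s", b@label))
    for (e in b@elements)
      out <- c(out, switch(e@kind,
        literal = sprintf("  seq %s", e@literal),
        stem_half = sprintf("  %s %s",
                            if (e@side == "first") "stem5" else "stem3",
                            e@stemId),
        spacer = sprintf("  spacer %d:%d", e@lengthRange[1],
                         e@lengthRange[2]),
        cleavage_site = "  cleave"))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @rdname descriptorText
#' @param path output file path.
#' @export
writeDescriptor <- function(descriptor, path) {
  writeLines(sub("\n$", "", descriptorText(descriptor)), path)
  invisible(path)
}

#' Built-in motif descriptors
#'
#' \describe{
#'   \item{hammerhead}{The hammerhead ribozyme catalytic core as three
#'     permutable blocks: Block C (one side of stem I, the conserved CUGANGA
#'     box, one side of stem II), Block G (the other side of stem II, the
#'     conserved GAAA, one side of stem III) and Block S (the other side of
#'     stem III, the cleavage triplet NUH with the scissile bond 3' of the H,
#'     the remaining side of stem I). Stems I-III are required; a fourth,
#'     optional stem records the loop-loop interaction between stems I and
#'     II, whose half-sites lie outside the core blocks and which is
#'     therefore excluded from block-level topology.}
#'   \item{twister}{A schematic three-block decomposition of a twister-like
#'     motif with stems P1/P2/P4 and an optional pseudoknot helix whose
#'     halves sit in two different blocks; the sequence literals are
#'     approximate placeholders, included to exercise generic multi-block
#'     support rather than to encode the published twister consensus.}
#' }
#'
#' @param name \code{"hammerhead"} or \code{"twister"}.
#' @return a \linkS4class{MotifDescriptor}.
#' @examples
#' builtinDescriptor("hammerhead")
#' @export
builtinDescriptor <- function(name = c("hammerhead", "twister")) {
  name <- match.arg(name)
  parseDescriptor(.BUILTIN_DESCRIPTORS[[name]])
}

.BUILTIN_DESCRIPTORS <- list(
  hammerhead = "motif hammerhead
# Hammerhead ribozyme catalytic core as three permutable blocks.
stem I len=3:8 wobble
stem II len=3:8 wobble
stem III len=2:6 wobble
stem P len=2:6 wobble optional
linker 0:8
block C
  stem5 I
  seq CUGANGA
  stem5 II
block G
  stem3 II
  seq GAAA
  stem5 III
block S
  stem3 III
  seq NUH
  cleave
  stem3 I
",
  twister = "motif twister
# Schematic twister-like decomposition; literals are placeholders.
stem P1 len=3:7 wobble
stem P2 len=3:7 wobble
stem P4 len=2:5 wobble
stem T1 len=2:4 wobble optional
linker 0:6
block A
  stem5 P1
  seq NUA
  cleave
  stem5 T1
  stem5 P2
block B
  stem3 P2
  spacer 2:5
  stem5 P4
block C
  stem3 P4
  stem3 T1
  seq AN
  stem3 P1
")

# ---- permutation enumeration ----------------------------------------------

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# Length bounds of a single element row.
.elementBounds <- function(e, stems, linkerRange) {
  switch(e@kind,
    literal = rep(nchar(e@literal), 2L),
    stem_half = stems[[e@stemId]]@lengthRange,
    spacer = e@lengthRange,
    cleavage_site = c(0L, 0L))
}

#' Build the linearized layout for one block order
#'
#' Concatenates the descriptor's blocks in the given order, inserting a
#' variable-length linker slot between consecutive blocks, and records the
#' linear extent of every stem whose two halves are both placed.
#'
#' @param descriptor a \linkS4class{MotifDescriptor}.
#' @param order character vector of block labels (all labels, each once).
#' @return a \linkS4class{PermutationLayout}.
#' @export
permutationLayout <- function(descriptor, order) {
  labs <- vapply(descriptor@blocks, function(b) b@label, "")
  if (!setequal(order, labs) || length(order) != length(labs))
    .stopf("order must be a permutation of block labels %s",
           paste(labs, collapse = ""))
  stems <- descriptor@stems
  names(stems) <- vapply(stems, function(s) s@stemId, "")
  rows <- list()
  addRow <- function(block, kind, literal, stemId, side, lo, hi) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, kind = kind, literal = literal, stemId = stemId,
      side = side, minLen = as.integer(lo), maxLen = as.integer(hi),
      stringsAsFactors = FALSE)
  }
  for (bi in seq_along(order)) {
    if (bi > 1L)
      addRow(NA_character_, "linker", NA_character_, NA_character_,
             NA_character_, descriptor@linkerRange[1],
             descriptor@linkerRange[2])
    b <- descriptor@blocks[[match(order[bi], labs)]]
    for (e in b@elements) {
      lohi <- .elementBounds(e, stems, descriptor@linkerRange)
      addRow(b@label, e@kind,
             if (e@kind == "literal") e@literal else NA_character_,
             if (e@kind == "stem_half") e@stemId else NA_character_,
             if (e@kind == "stem_half") e@side else NA_character_,
             lohi[1], lohi[2])
    }
  }
  el <- do.call(rbind, rows)
  ext <- list()
  for (s in stems) {
    idx <- which(el$kind == "stem_half" & el$stemId == s@stemId)
    if (length(idx) == 2L)
      ext[[length(ext) + 1L]] <- data.frame(
        stemId = s@stemId, from = min(idx), to = max(idx),
        required = s@required, stringsAsFactors = FALSE)
  }
  ext <- if (length(ext)) do.call(rbind, ext) else
    data.frame(stemId = character(), from = integer(), to = integer(),
               required = logical())
  new("PermutationLayout", typeName = paste(order, collapse = ""),
      order = order, elements = el, stemExtents = ext)
}

#' Enumerate all block permutations of a descriptor
#'
#' An n-block descriptor has n! orderings. The three-block hammerhead core
#' gives the six permutation types CGS, CSG, GCS, GSC, SCG and SGC; the
#' previously known circular permutations type I/II/III correspond to
#' CGS/GSC/SCG.
#'
#' @param descriptor a \linkS4class{MotifDescriptor}.
#' @return list of \linkS4class{PermutationLayout}, in lexicographic order of
#'   type name.
#' @examples
#' vapply(enumeratePermutations(builtinDescriptor("hammerhead")),
#'        typeName, "")
#' @export
enumeratePermutations <- function(descriptor) {
  stopifnot(is(descriptor, "MotifDescriptor"))
  labs <- sort(vapply(descriptor@blocks, function(b) b@label, ""))
  perms <- .permutations(labs)
  nm <- vapply(perms, paste, "", collapse = "")
  perms <- perms[order(nm)]
  lapply(perms, function(p) permutationLayout(descriptor, p))
}

# ---- topology --------------------------------------------------------------

#' Count crossing stem pairs of a layout
#'
#' Two stems cross when their linear extents interleave
#' (\eqn{i < i' < j < j'}): drawn on a line, their connecting arcs must
#' intersect, i.e. the pair forms a pseudoknot. A layout with zero crossing
#' pairs is a helical junction. For the hammerhead blocks, the circular
#' orders CGS/GSC/SCG are junctions while the non-circular orders
#' SGC/CSG/GCS are pseudoknotted.
#'
#' The count is helix-level (crossing stem pairs, not crossing base pairs),
#' so it does not depend on stem lengths. Optional stems (tertiary
#' interactions) are excluded unless \code{includeOptional}.
#'
#' @param layout a \linkS4class{PermutationLayout}.
#' @param includeOptional also count placed optional stems.
#' @return list with \code{crossingPairs} (integer) and \code{class}
#'   (\code{"junction"} or \code{"pseudoknotted"}).
#' @examples
#' d <- builtinDescriptor("hammerhead")
#' countPseudoknots(permutationLayout(d, c("S", "C", "G")))
#' countPseudoknots(permutationLayout(d, c("S", "G", "C")))
#' @export
countPseudoknots <- function(layout, includeOptional = FALSE) {
  stopifnot(is(layout, "PermutationLayout"))
  ext <- layout@stemExtents
  if (!includeOptional) ext <- ext[ext$required, , drop = FALSE]
  n <- nrow(ext)
  crossing <- 0L
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      i <- ext$from[a]; j <- ext$to[a]
      ii <- ext$from[b]; jj <- ext$to[b]
      if ((i < ii && ii < j && j < jj) || (ii < i && i < jj && jj < j))
        crossing <- crossing + 1L
    }
  }
  list(crossingPairs = crossing,
       class = if (crossing == 0L) "junction" else "pseudoknotted")
}

#' Topology table over all permutations
#'
#' @param descriptor a \linkS4class{MotifDescriptor}.
#' @param includeOptional also count placed optional stems.
#' @return data.frame with columns \code{order}, \code{crossingPairs},
#'   \code{class}, one row per permutation.
#' @export
topologyTable <- function(descriptor, includeOptional = FALSE) {
  layouts <- enumeratePermutations(descriptor)
  do.call(rbind, lapply(layouts, function(l) {
    tp <- countPseudoknots(l, includeOptional = includeOptional)
    data.frame(order = typeName(l), crossingPairs = tp$crossingPairs,
               class = tp$class, stringsAsFactors = FALSE)
  }))
}
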