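#' @include descriptor.R
NULL

#' Scan options
#'
#' @param bothStrands scan the reverse complement as well (used by
#'   [scanFasta()]).
#' @param forceWobble permit G-U pairs in every stem, regardless of the
#'   per-stem descriptor flag.
#' @param mismatchBudget if non-NULL, overrides every stem's mismatch budget.
#' @param allowAmbiguous if TRUE, ambiguous sequence characters (N etc.)
#'   satisfy literal checks; by default they fail both literal and pairing
#'   checks.
#' @return a named list of options for [scanSequence()] / [scanFasta()].
#' @export
scanConfig <- function(bothStrands = TRUE, forceWobble = FALSE,
                       mismatchBudget = NULL, allowAmbiguous = FALSE) {
  list(bothStrands = bothStrands, forceWobble = forceWobble,
       mismatchBudget = mismatchBudget, allowAmbiguous = allowAmbiguous)
}

#' Compile a descriptor/layout pair into a search pattern
#'
#' The compiled pattern's match language is exactly the set of sequences
#' satisfying every literal, length and pairing constraint of that block
#' permutation.
#'
#' @param descriptor a \linkS4class{MotifDescriptor}.
#' @param layout a \linkS4class{PermutationLayout} of that descriptor (see
#'   [permutationLayout()] / [enumeratePermutations()]).
#' @return a \linkS4class{CompiledPattern}.
#' @examples
#' d <- builtinDescriptor("hammerhead")
#' compilePattern(d, permutationLayout(d, c("S", "G", "C")))
#' @export
compilePattern <- function(descriptor, layout) {
  stopifnot(is(descriptor, "MotifDescriptor"),
            is(layout, "PermutationLayout"))
  plan <- layout@elements
  if (any(is.na(plan$maxLen) | is.infinite(plan$maxLen)))
    .stopf("cannot compile: element with unbounded maximum length")
  stems <- descriptor@stems
  names(stems) <- vapply(stems, function(s) s@stemId, "")
  # only stems with both halves in the plan constrain matching; a stem half
  # contributes its length twice (once per half)
  placed <- unique(plan$stemId[plan$kind == "stem_half"])
  placed <- placed[!is.na(placed)]
  new("CompiledPattern", motif = descriptor@name, layout = layout,
      plan = plan, stems = stems[placed],
      minLen = sum(plan$minLen), maxLen = sum(plan$maxLen))
}

# Effective pairing policy for one stem under a scan config.
.stemPolicy <- function(stem, config) {
  list(wobble = stem@wobble || isTRUE(config$forceWobble),
       budget = if (!is.null(config$mismatchBudget))
         as.integer(config$mismatchBudget) else stem@mismatchBudget)
}

#' Scan one sequence with a compiled pattern
#'
#' Exhaustive backtracking over element lengths and positions: every
#' distinct placement satisfying the pattern is returned, deduplicated by
#' (span, element spans) and sorted by start, end, then type name. Element
#' lengths are explored shortest-first. The given strand of the given
#' sequence is scanned; strand handling lives in [scanFasta()].
#'
#' @param sequence a nucleotide string (DNA or RNA alphabet; T is treated
#'   as U; case-insensitive).
#' @param pattern a \linkS4class{CompiledPattern}.
#' @param config options from [scanConfig()].
#' @param seqId sequence identifier recorded in the output.
#' @return a match data.frame with columns \code{seqId}, \code{start},
#'   \code{end} (0-based half-open), \code{type}, \code{strand},
#'   \code{cleavage} (0-based inter-nucleotide coordinate or NA) and a
#'   list-column \code{elements} of per-element span tables.
#' @export
scanSequence <- function(sequence, pattern, config = scanConfig(),
                         seqId = "seq") {
  stopifnot(is(pattern, "CompiledPattern"))
  ch <- .seqChars(sequence)
  L <- length(ch)
  plan <- pattern@plan
  nEl <- nrow(plan)
  out <- list()
  if (L < pattern@minLen) return(.emptyMatches())

  # per-element precomputation
  litSets <- vector("list", nEl)
  for (k in seq_len(nEl))
    if (plan$kind[k] == "literal")
      litSets[[k]] <- strsplit(plan$literal[k], "")[[1]]
  policies <- lapply(pattern@stems, .stemPolicy, config = config)
  ambiguousOk <- isTRUE(config$allowAmbiguous)
  ambiguousSet <- setdiff(names(.IUPAC_RNA), c("A", "C", "G", "U"))
  # minimum length of the remaining plan suffix, for pruning
  sufMin <- rev(cumsum(rev(plan$minLen)))

  spans <- matrix(0L, nrow = nEl, ncol = 2L)  # 1-based inclusive, 0 len ok
  stemLen <- list()   # stemId -> fixed length
  stemSeq <- list()   # stemId -> first-half chars (linear order)
  cleavePos <- NA_integer_

  litMatch <- function(k, p, len) {
    codes <- litSets[[k]]
    for (q in seq_len(len)) {
      b <- ch[p + q - 1L]
      if (!(b %in% strsplit(.IUPAC_RNA[[codes[q]]], "")[[1]] ||
            (ambiguousOk && b %in% ambiguousSet)))
        return(FALSE)
    }
    TRUE
  }

  emit <- function(s, e) {
    elTab <- data.frame(
      index = seq_len(nEl), block = plan$block, kind = plan$kind,
      stemId = plan$stemId,
      start = spans[, 1L] - 1L, end = spans[, 2L],
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <<- list(
      start = s - 1L, end = e, cleavage = cleavePos, elements = elTab)
  }

  rec <- function(k, p) {
    if (k > nEl) { emit(sStart, p - 1L); return(invisible()) }
    if (p - 1L + sufMin[k] > L) return(invisible())
    kind <- plan$kind[k]
    if (kind == "literal") {
      len <- plan$minLen[k]
      if (p + len - 1L <= L && litMatch(k, p, len)) {
        spans[k, ] <<- c(p, p + len - 1L)
        rec(k + 1L, p + len)
      }
    } else if (kind == "cleavage_site") {
      spans[k, ] <<- c(p, p - 1L)
      old <- cleavePos
      cleavePos <<- p - 1L   # 0-based inter-nucleotide coordinate
      rec(k + 1L, p)
      cleavePos <<- old
    } else if (kind %in% c("spacer", "linker")) {
      for (len in plan$minLen[k]:plan$maxLen[k]) {
        if (p + len - 1L > L) break
        spans[k, ] <<- c(p, p + len - 1L)
        rec(k + 1L, p + len)
      }
    } else if (kind == "stem_half") {
      id <- plan$stemId[k]
      pol <- policies[[id]]
      if (!is.null(stemLen[[id]])) {
        len <- stemLen[[id]]
        if (p + len - 1L <= L) {
          second <- ch[p:(p + len - 1L)]
          if (.stemMismatches(stemSeq[[id]], second,
                              wobble = pol$wobble) <= pol$budget) {
            spans[k, ] <<- c(p, p + len - 1L)
            rec(k + 1L, p + len)
          }
        }
      } else {
        rng <- pattern@stems[[id]]@lengthRange
        for (len in rng[1]:rng[2]) {
          if (p + len - 1L > L) break
          stemLen[[id]] <<- len
          stemSeq[[id]] <<- ch[p:(p + len - 1L)]
          spans[k, ] <<- c(p, p + len - 1L)
          rec(k + 1L, p + len)
          stemLen[[id]] <<- NULL
          stemSeq[[id]] <<- NULL
        }
      }
    }
    invisible()
  }

  sStart <- 1L
  lastStart <- L - pattern@minLen + 1L
  for (s in seq_len(max(lastStart, 0L))) {
    sStart <- s
    rec(1L, s)
  }
  .assembleMatches(out, seqId, typeName(pattern@layout), strand = "+")
}

.emptyMatches <- function() {
  data.frame(seqId = character(), start = integer(), end = integer(),
             type = character(), strand = character(),
             cleavage = integer(), elements = I(list()),
             stringsAsFactors = FALSE)
}

.assembleMatches <- function(raw, seqId, type, strand) {
  if (!length(raw)) return(.emptyMatches())
  df <- data.frame(
    seqId = seqId,
    start = vapply(raw, function(m) m$start, 0L),
    end = vapply(raw, function(m) m$end, 0L),
    type = type, strand = strand,
    cleavage = vapply(raw, function(m) as.integer(m$cleavage), 0L),
    stringsAsFactors = FALSE)
  df$elements <- I(lapply(raw, function(m) m$elements))
  key <- vapply(raw, function(m)
    paste(m$start, m$end, paste(m$elements$start, m$elements$end,
                                collapse = ","), sep = "|"), "")
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(df$start, df$end, df$type), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Map a plus-strand match on revcomp(seq) of length L back to the forward
# strand.
.mapMinus <- function(df, L) {
  if (!nrow(df)) return(df)
  newStart <- L - df$end
  newEnd <- L - df$start
  df$elements <- I(lapply(seq_len(nrow(df)), function(i) {
    e <- df$elements[[i]]
    s2 <- L - e$end; e2 <- L - e$start
    e$start <- s2; e$end <- e2
    e[order(e$start), , drop = FALSE]
  }))
  df$cleavage <- ifelse(is.na(df$cleavage), NA_integer_, L - df$cleavage)
  df$start <- newStart
  df$end <- newEnd
  df$strand <- "-"
  df
}

#' Scan sequences in a FASTA file (or in memory) with every permutation
#'
#' Each record is scanned on the plus strand and, by default, on the reverse
#' complement; minus-strand matches are reported in forward-strand
#' coordinates.
#'
#' @param fasta path to a (optionally gzipped) FASTA file, or a named
#'   character vector of sequences.
#' @param descriptor a \linkS4class{MotifDescriptor}.
#' @param orders character vector of permutation type names to scan
#'   (default: all).
#' @param config options from [scanConfig()].
#' @return combined match data.frame (see [scanSequence()]), sorted within
#'   each record.
#' @export
scanFasta <- function(fasta, descriptor, orders = NULL,
                      config = scanConfig()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && !grepl("^>", fasta)
              && file.exists(fasta)) {
    x <- Biostrings::readBStringSet(fasta)
    stats::setNames(as.character(x), sub("[ \t].*$", "", names(x)))
  } else {
    fasta
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    .stopf("all sequences must be named")
  if (anyDuplicated(names(seqs))) {
    dup <- names(seqs)[duplicated(names(seqs))][1]
    .stopf("duplicate record id '%s'", dup)
  }
  layouts <- enumeratePermutations(descriptor)
  if (!is.null(orders)) {
    keep <- vapply(layouts, typeName, "") %in% orders
    if (!any(keep)) .stopf("no layout matches orders %s",
                           paste(orders, collapse = ","))
    layouts <- layouts[keep]
  }
  patterns <- lapply(layouts, function(l) compilePattern(descriptor, l))
  res <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    for (pat in patterns) {
      res[[length(res) + 1L]] <- scanSequence(s, pat, config, seqId = id)
      if (isTRUE(config$bothStrands)) {
        m <- scanSequence(.revcompStr(s), pat, config, seqId = id)
        res[[length(res) + 1L]] <- .mapMinus(m, nchar(s))
      }
    }
  }
  res <- res[vapply(res, nrow, 0L) > 0L]
  if (!length(res)) return(.emptyMatches())
  df <- do.call(rbind, res)
  df <- df[order(match(df$seqId, names(seqs)), df$start, df$end, df$type),
           , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Predict cleavage site and fragment lengths for a match
#'
#' By structural analogy, a matched self-cleaving motif cleaves at the
#' descriptor's annotated site; the 5' fragment length equals the
#' inter-nucleotide coordinate and the two fragment lengths always sum to
#' the construct length.
#'
#' @param match one match row (from [scanSequence()]/[scanFasta()]).
#' @param construct the full construct sequence the match was found in.
#' @return list with \code{site} (0-based inter-nucleotide coordinate on the
#'   forward strand), \code{len5}, \code{len3} and \code{degenerate} (TRUE
#'   when one fragment is empty).
#' @examples
#' \dontrun{
#' m <- scanFasta(c(rz = seq), builtinDescriptor("hammerhead"))
#' predictCleavage(m[1, ], seq)
#' }
#' @export
predictCleavage <- function(match, construct) {
  if (is.data.frame(match)) {
    if (nrow(match) != 1L) .stopf("predictCleavage expects a single match")
    cl <- match$cleavage
    strand <- match$strand
  } else .stopf("match must be a one-row match data.frame")
  if (is.na(cl)) .stopf("no cleavage site annotated")
  L <- nchar(construct)
  if (cl < 0L || cl > L) .stopf("cleavage coordinate outside construct")
  # on the minus strand the 5' fragment of the transcript corresponds to the
  # downstream part of the forward strand
  len5 <- if (strand == "+") cl else L - cl
  len3 <- L - len5
  list(site = cl, len5 = len5, len3 = len3,
       degenerate = len5 == 0L || len3 == 0L)
}

#' Write matches as BED-like TSV
#'
#' Columns: seq_id, start, end, type_name, score ("."), strand, JSON-encoded
#' element spans, cleavage coordinate (or ".").
#'
#' @param matches match data.frame.
#' @param path output path.
#' @export
writeMatches <- function(matches, path) {
  js <- vapply(seq_len(nrow(matches)), function(i)
    as.character(jsonlite::toJSON(matches$elements[[i]], dataframe = "rows",
                                  na = "null")), "")
  tab <- data.frame(
    seq_id = matches$seqId, start = matches$start, end = matches$end,
    type_name = matches$type, score = ".", strand = matches$strand,
    elements = if (nrow(matches)) js else character(),
    cleavage = ifelse(is.na(matches$cleavage), ".",
                      as.character(matches$cleavage)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Independently re-verify a match against pattern constraints
#'
#' A soundness checker deliberately separate from the scanner: it takes a
#' reported placement and tests every literal, length and pairing constraint
#' directly on the substrings.
#'
#' @param match one match row.
#' @param sequence the forward-strand sequence scanned.
#' @param pattern the \linkS4class{CompiledPattern} used.
#' @param config options from [scanConfig()].
#' @return TRUE when every constraint holds.
#' @export
verifyMatch <- function(match, sequence, pattern, config = scanConfig()) {
  el <- match$elements[[1]]
  seqF <- .normalizeRna(sequence)
  s <- if (match$strand == "+") seqF else .revcompStr(seqF)
  L <- nchar(s)
  # element spans on the scanned strand, in plan order
  toScanned <- function(start, end) {
    if (match$strand == "+") c(start, end) else c(L - end, L - start)
  }
  plan <- pattern@plan
  ext <- function(start, end)
    if (end > start) substr(s, start + 1L, end) else ""
  halves <- list()
  prevEnd <- NULL
  for (i in order(el$index)) {
    k <- el$index[i]
    se <- toScanned(el$start[i], el$end[i])
    w <- se[2] - se[1]
    if (!is.null(prevEnd) && se[1] != prevEnd) return(FALSE)  # must tile
    prevEnd <- se[2]
    if (w < plan$minLen[k] || w > plan$maxLen[k]) return(FALSE)
    sub <- ext(se[1], se[2])
    if (plan$kind[k] == "literal") {
      pat <- strsplit(plan$literal[k], "")[[1]]
      got <- strsplit(sub, "")[[1]]
      if (length(got) != length(pat)) return(FALSE)
      ok <- mapply(function(b, c) .matchesIupac(b, c,
        isTRUE(config$allowAmbiguous)), got, pat)
      if (!all(ok)) return(FALSE)
    } else if (plan$kind[k] == "stem_half") {
      id <- plan$stemId[k]
      halves[[id]] <- c(halves[[id]], list(strsplit(sub, "")[[1]]))
    }
  }
  for (id in names(halves)) {
    h <- halves[[id]]
    if (length(h) != 2L) return(FALSE)
    if (length(h[[1]]) != length(h[[2]])) return(FALSE)
    pol <- .stemPolicy(pattern@stems[[id]], config)
    if (.stemMismatches(h[[1]], h[[2]], wobble = pol$wobble) > pol$budget)
      return(FALSE)
  }
  TRUE
}
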