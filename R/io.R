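#' @include covariation.R
NULL

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings with the error context this package's
#' tools expect. Sequences are returned as a named character vector; record
#' descriptions after the first whitespace are dropped from the names.
#'
#' @param path FASTA file (gzip accepted on read).
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) .stopf("cannot read FASTA '%s'", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) .stopf("malformed FASTA '%s': %s",
                                           path, conditionMessage(e)))
  out <- stats::setNames(as.character(x), sub("[ \t].*$", "", names(x)))
  if (anyDuplicated(names(out)))
    .stopf("duplicate record id '%s' in '%s'",
           names(out)[duplicated(names(out))][1], path)
  out
}

#' @rdname readFasta
#' @param sequences named character vector.
#' @param width line-wrap width.
#' @export
writeFasta <- function(sequences, path, width = 70L) {
  if (is.null(names(sequences))) .stopf("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

# ---- WUSS ------------------------------------------------------------------

.WUSS_OPEN <- c("<", "(", "[", "{")
.WUSS_CLOSE <- c(">", ")", "]", "}")

#' Parse a WUSS consensus structure string
#'
#' Supports the bracket families \code{<>}, \code{()}, \code{[]}, \code{{}}
#' and pseudoknot letter tiers (\code{Aa}, \code{Bb}, ...). Each family is
#' parsed with its own stack and assigned its own tier, so pseudoknots
#' occupy distinct tiers and every tier is internally nested. Unknown
#' characters (and unmatched openers/closers) are treated as unpaired, with
#' a warning for characters outside the WUSS vocabulary.
#'
#' @param ss structure string.
#' @return data.frame with columns \code{i}, \code{j} (1-based columns,
#'   i < j), \code{tier} and \code{stem} (NA).
#' @examples
#' parseWuss("<<..>>AaBb")
#' @export
parseWuss <- function(ss) {
  ch <- strsplit(ss, "")[[1]]
  unpaired <- c(".", ",", ":", "_", "-", "~")
  stacks <- list()
  pairs <- list()
  tierKey <- character()
  warned <- FALSE
  for (p in seq_along(ch)) {
    c0 <- ch[p]
    if (c0 %in% unpaired) next
    if (c0 %in% .WUSS_OPEN) {
      key <- c0
      stacks[[key]] <- c(stacks[[key]], p)
    } else if (c0 %in% .WUSS_CLOSE) {
      key <- .WUSS_OPEN[match(c0, .WUSS_CLOSE)]
      st <- stacks[[key]]
      if (length(st)) {
        pairs[[length(pairs) + 1L]] <- c(st[length(st)], p, match0 = NA)
        names(pairs)[length(pairs)] <- key
        stacks[[key]] <- st[-length(st)]
      }
    } else if (grepl("^[A-Z]$", c0)) {
      stacks[[c0]] <- c(stacks[[c0]], p)
    } else if (grepl("^[a-z]$", c0)) {
      key <- toupper(c0)
      st <- stacks[[key]]
      if (length(st)) {
        pairs[[length(pairs) + 1L]] <- c(st[length(st)], p, match0 = NA)
        names(pairs)[length(pairs)] <- key
        stacks[[key]] <- st[-length(st)]
      }
    } else if (!warned) {
      warning(sprintf("unknown WUSS character '%s' treated as unpaired",
                      c0))
      warned <- TRUE
    }
  }
  if (!length(pairs)) return(.emptyPairs())
  fam <- names(pairs)
  famLevels <- unique(fam)
  df <- data.frame(
    i = vapply(pairs, `[`, 0, 1L),
    j = vapply(pairs, `[`, 0, 2L),
    tier = match(fam, famLevels),
    stem = NA_character_, stringsAsFactors = FALSE)
  df <- df[order(df$tier, df$i), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Render a pair table as a WUSS string
#'
#' Tier 1 uses angle brackets; additional tiers use pseudoknot letters.
#'
#' @param pairs pair table (columns \code{i}, \code{j}, \code{tier}).
#' @param width total string width.
#' @export
pairsToWuss <- function(pairs, width) {
  out <- rep(".", width)
  tiers <- sort(unique(pairs$tier))
  for (tn in seq_along(tiers)) {
    sub <- pairs[pairs$tier == tiers[tn], , drop = FALSE]
    if (tn == 1L) {
      out[sub$i] <- "<"; out[sub$j] <- ">"
    } else {
      L <- LETTERS[tn - 1L]
      out[sub$i] <- L; out[sub$j] <- tolower(L)
    }
  }
  paste(out, collapse = "")
}

# ---- Stockholm -------------------------------------------------------------

#' Read a Stockholm 1.0 alignment
#'
#' Parses sequence rows and the \code{#=GC SS_cons} consensus structure
#' (interleaved blocks are concatenated). The SS_cons string is converted
#' to a pair table with [parseWuss()] and preserved verbatim for lossless
#' round-trips.
#'
#' @param path Stockholm file.
#' @return a \linkS4class{StructuredAlignment}.
#' @export
readStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    .stopf("'%s' line 1: missing '# STOCKHOLM 1.0' header", path)
  seqs <- list(); order <- character(); ss <- ""
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || ln == "//") next
    if (grepl("^#=GC[ \t]+SS_cons[ \t]", ln)) {
      ss <- paste0(ss, sub("^#=GC[ \t]+SS_cons[ \t]+", "", ln))
    } else if (grepl("^#", ln)) {
      next
    } else {
      tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(tok) != 2L)
        .stopf("'%s' line %d: malformed sequence line", path, i)
      if (is.null(seqs[[tok[1]]])) order <- c(order, tok[1])
      seqs[[tok[1]]] <- paste0(seqs[[tok[1]]] %||% "", tok[2])
    }
  }
  if (!length(seqs)) .stopf("'%s': no sequence rows", path)
  rows <- unlist(seqs[order], use.names = FALSE)
  if (length(unique(nchar(rows))) != 1L)
    .stopf("'%s': alignment rows differ in width", path)
  structuredAlignment(order, rows, ss = if (nzchar(ss)) ss else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a StructuredAlignment as Stockholm 1.0
#'
#' @param aln a \linkS4class{StructuredAlignment}.
#' @param path output file.
#' @export
writeStockholm <- function(aln, path) {
  stopifnot(is(aln, "StructuredAlignment"))
  width <- max(nchar(aln@ids), nchar("#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0", "")
  lines <- c(lines, sprintf("%-*s %s", width, aln@ids, aln@rows))
  ss <- if (!is.na(aln@ss)) aln@ss
        else if (nrow(aln@pairs)) pairsToWuss(aln@pairs, nchar(aln@rows[1]))
        else NULL
  if (!is.null(ss))
    lines <- c(lines, sprintf("%-*s %s", width, "#=GC SS_cons", ss))
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

# ---- TSV -------------------------------------------------------------------

#' Read / write TSV with named-column checking
#'
#' @param path file path.
#' @param required column names that must be present; a missing column is a
#'   named error, never silent truncation.
#' @return data.frame.
#' @export
readTsv <- function(path, required = character()) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      quote = ""),
    error = function(e) .stopf("cannot read TSV '%s': %s", path,
                               conditionMessage(e)))
  miss <- setdiff(required, names(tab))
  if (length(miss))
    .stopf("'%s': missing column(s): %s", path, paste(miss, collapse = ", "))
  tab
}

#' @rdname readTsv
#' @param tab data.frame to write.
#' @export
writeTsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
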