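# Shared nucleotide helpers. Everything internal works on uppercase RNA
# character vectors; T is folded into U at the boundaries.

.normalizeRna <- function(x) toupper(chartr("Tt", "Uu", x))

.seqChars <- function(x) strsplit(.normalizeRna(x), "")[[1]]

.COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

# Reverse complement of a plain character string (RNA alphabet out).
.revcompStr <- function(x) {
  ch <- rev(.seqChars(x))
  out <- .COMPLEMENT[ch]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

# Does concrete base `b` satisfy degenerate IUPAC code `code`?
# Vectorized over b. Non-ACGU observed bases (N etc.) never match unless
# allowAmbiguous.
.matchesIupac <- function(b, code, allowAmbiguous = FALSE) {
  set <- .IUPAC_RNA[[code]]
  ok <- !is.na(match(b, strsplit(set, "")[[1]]))
  if (allowAmbiguous) {
    amb <- b %in% setdiff(names(.IUPAC_RNA), c("A", "C", "G", "U"))
    ok <- ok | amb
  }
  ok
}

# Base-pair test for one position: Watson-Crick, optionally G-U wobble.
.isPaired <- function(a, b, wobble = FALSE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "C" & b == "G") | (a == "G" & b == "C")
  if (wobble)
    wc <- wc | (a == "G" & b == "U") | (a == "U" & b == "G")
  wc
}

# Antiparallel helix check between two equal-length half strings (character
# vectors, 5'->3' each, first half linearly upstream). Returns the number of
# non-pairing positions.
.stemMismatches <- function(first, second, wobble = FALSE) {
  sum(!.isPaired(first, rev(second), wobble = wobble))
}

# Uniform integer draw from lo..hi, robust to lo == hi (sample() would
# otherwise sample from 1:lo).
.sampleInt <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
}

# Uniform draw of concrete bases satisfying a degenerate code.
.sampleIupac <- function(code, n = 1L) {
  set <- strsplit(.IUPAC_RNA[[code]], "")[[1]]
  set[sample.int(length(set), n, replace = TRUE)]
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
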