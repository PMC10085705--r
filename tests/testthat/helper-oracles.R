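# Independent oracles used to cross-check the package implementation.
# Written deliberately as plain enumerations, separate from the package's
# compiled-pattern scanner and helix-extent bookkeeping.

# All placements of a (descriptor, block order) in a sequence, found by
# direct recursion over the linearized element list with every allowed
# element length tried. Returns a character vector of placement keys
# "start|end|s1,e1;s2,e2;..." with 0-based half-open spans in plan order.
oracleScan <- function(sequence, descriptor, order) {
  ch <- strsplit(toupper(chartr("Tt", "Uu", sequence)), "")[[1]]
  L <- length(ch)
  stems <- motifStems(descriptor)
  names(stems) <- vapply(stems, function(s) s@stemId, "")
  labs <- vapply(motifBlocks(descriptor), function(b) b@label, "")
  lr <- linkerRange(descriptor)

  # linear element list: (kind, payload) with linker slots between blocks
  els <- list()
  for (bi in seq_along(order)) {
    if (bi > 1L) els[[length(els) + 1L]] <- list(kind = "linker", lo = lr[1],
                                                 hi = lr[2])
    b <- motifBlocks(descriptor)[[match(order[bi], labs)]]
    for (e in b@elements)
      els[[length(els) + 1L]] <- switch(e@kind,
        literal = list(kind = "literal", pat = strsplit(e@literal, "")[[1]]),
        stem_half = list(kind = "stem", id = e@stemId,
                         lo = stems[[e@stemId]]@lengthRange[1],
                         hi = stems[[e@stemId]]@lengthRange[2],
                         wob = stems[[e@stemId]]@wobble,
                         mm = stems[[e@stemId]]@mismatchBudget),
        spacer = list(kind = "linker", lo = e@lengthRange[1],
                      hi = e@lengthRange[2]),
        cleavage_site = list(kind = "cleave"))
  }
  iup <- c(A = "A", C = "C", G = "G", U = "U", R = "AG", Y = "CU", S = "CG",
           W = "AU", K = "GU", M = "AC", B = "CGU", D = "AGU", H = "ACU",
           V = "ACG", N = "ACGU")
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  pairOk <- function(a, b, wob) {
    ok <- identical(comp[[a]], b)
    if (!ok && wob) ok <- (a == "G" && b == "U") || (a == "U" && b == "G")
    ok
  }
  hits <- character()
  n <- length(els)
  place <- function(k, pos, seen, spans) {
    if (k > n) {
      start <- spans[[1]][1]
      hits[[length(hits) + 1L]] <<- paste0(start, "|", pos - 1L, "|",
        paste(vapply(spans, function(s) paste0(s[1], ",", s[2]), ""),
              collapse = ";"))
      return(invisible())
    }
    e <- els[[k]]
    if (e$kind == "cleave") {
      place(k + 1L, pos, seen, c(spans, list(c(pos - 1L, pos - 1L))))
    } else if (e$kind == "literal") {
      len <- length(e$pat)
      if (pos + len - 1L <= L) {
        ok <- TRUE
        for (q in seq_len(len))
          if (!grepl(ch[pos + q - 1L], iup[[e$pat[q]]], fixed = TRUE)) {
            ok <- FALSE; break
          }
        if (ok) place(k + 1L, pos + len, seen,
                      c(spans, list(c(pos - 1L, pos + len - 1L))))
      }
    } else if (e$kind == "linker") {
      for (len in e$lo:e$hi) {
        if (pos + len - 1L > L) break
        place(k + 1L, pos + len, seen,
              c(spans, list(c(pos - 1L, pos + len - 1L))))
      }
    } else {  # stem half
      prev <- seen[[e$id]]
      if (!is.null(prev)) {
        len <- length(prev)
        if (pos + len - 1L <= L) {
          second <- ch[pos:(pos + len - 1L)]
          bad <- sum(!vapply(seq_len(len), function(q)
            pairOk(prev[q], second[len + 1L - q], e$wob), TRUE))
          if (bad <= e$mm)
            place(k + 1L, pos + len, seen,
                  c(spans, list(c(pos - 1L, pos + len - 1L))))
        }
      } else {
        for (len in e$lo:e$hi) {
          if (pos + len - 1L > L) break
          seen2 <- seen
          seen2[[e$id]] <- ch[pos:(pos + len - 1L)]
          place(k + 1L, pos + len, seen2,
                c(spans, list(c(pos - 1L, pos + len - 1L))))
        }
      }
    }
    invisible()
  }
  for (s in seq_len(L)) place(1L, s, list(), list())
  unique(hits)
}

# Placement keys from the package scanner's match table, same format.
matchKeys <- function(matches) {
  if (!nrow(matches)) return(character())
  vapply(seq_len(nrow(matches)), function(i) {
    el <- matches$elements[[i]]
    el <- el[order(el$index), , drop = FALSE]
    paste0(matches$start[i], "|", matches$end[i], "|",
           paste(paste0(el$start, ",", el$end), collapse = ";"))
  }, "")
}

# Crossing-pair count via the "one endpoint strictly inside" formulation,
# distinct from the package's interleaving test.
oracleCrossings <- function(layout, includeOptional = FALSE) {
  ext <- stemExtents(layout)
  if (!includeOptional) ext <- ext[ext$required, , drop = FALSE]
  n <- nrow(ext)
  if (n < 2L) return(0L)
  cnt <- 0L
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    insideA <- function(x) x > ext$from[a] && x < ext$to[a]
    if (xor(insideA(ext$from[b]), insideA(ext$to[b]))) cnt <- cnt + 1L
  }
  cnt
}

# Random block descriptor: each of `nBlocks` blocks carries one literal;
# `nStems` stems have their two halves dropped into random distinct
# positions. Used for property tests of enumeration/topology.
randomDescriptor <- function(nBlocks = 3L, nStems = 2L, seed = 1L) {
  set.seed(seed)
  labs <- LETTERS[seq_len(nBlocks)]
  bases <- c("A", "C", "G", "U")
  blocks <- lapply(labs, function(l) list(
    paste(sample(bases, sample(2:4, 1), replace = TRUE), collapse = "")))
  lines <- c("motif random")
  for (si in seq_len(nStems))
    lines <- c(lines, sprintf("stem s%d len=%d:%d", si, 2L + (si %% 2L),
                              3L + (si %% 2L)))
  lines <- c(lines, "linker 0:3")
  # stem halves distributed over blocks (before or after the literal)
  halfAt <- lapply(seq_len(nStems), function(si)
    sort(sample(nBlocks, 2L, replace = TRUE)))
  for (bi in seq_len(nBlocks)) {
    lines <- c(lines, sprintf("block %s", labs[bi]))
    for (si in seq_len(nStems))
      if (halfAt[[si]][1] == bi)
        lines <- c(lines, sprintf("  stem5 s%d", si))
    lines <- c(lines, sprintf("  seq %s", blocks[[bi]][[1]]))
    for (si in seq_len(nStems))
      if (halfAt[[si]][2] == bi)
        lines <- c(lines, sprintf("  stem3 s%d", si))
  }
  parseDescriptor(lines)
}

# Narrow-range hammerhead variant used where oracle comparisons must stay
# cheap: same blocks and literals, tighter stem/linker ranges.
narrowHammerhead <- function() {
  parseDescriptor("motif hh_narrow
stem I len=4:5 wobble
stem II len=3:4 wobble
stem III len=3:4 wobble
linker 0:4
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
")
}

# Fixed-length-stem hammerhead: with min == max there is no shorter
# alternative placement that could absorb a broken outer pair, so
# pair-breaking edits beyond the mismatch budget are guaranteed fatal.
rigidHammerhead <- function() {
  parseDescriptor("motif hh_rigid
stem I len=5:5 wobble
stem II len=4:4 wobble
stem III len=4:4 wobble
linker 2:3
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
")
}

# Apply the M1-style mutation: the highly conserved G in the first part of
# the CUGANGA box (its third nucleotide) is substituted.
applyM1 <- function(instance) {
  el <- instance$truth$elements
  lit <- el[el$kind == "literal", , drop = FALSE]
  box <- lit[vapply(seq_len(nrow(lit)), function(i) {
    substr(instance$sequence, lit$start[i] + 1L, lit$end[i])
  }, "") |> grepl(pattern = "^CUGA.GA$") |> which(), , drop = FALSE]
  stopifnot(nrow(box) == 1L)
  pos <- box$start[1] + 3L  # 1-based position of the G
  s <- instance$sequence
  substr(s, pos, pos) <- "A"
  instance$sequence <- s
  instance
}
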