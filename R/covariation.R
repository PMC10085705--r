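#' @include AllClasses.R utils.R
NULL

# ---- alignment encoding ----------------------------------------------------

# Integer-encode alignment rows: A/C/G/U -> 1..4, everything else (gaps,
# ambiguity codes) -> NA. Rows become the matrix rows, columns alignment
# columns.
.encodeAlignment <- function(aln) {
  rows <- .normalizeRna(aln@rows)
  m <- do.call(rbind, strsplit(rows, ""))
  code <- match(m, c("A", "C", "G", "U"))
  matrix(code, nrow = nrow(m), ncol = ncol(m))
}

# Mutual information (bits) between two integer-coded columns, over rows
# ungapped in both. Returns NA when fewer than 2 usable rows.
.mutualInfo <- function(xi, xj) {
  ok <- !is.na(xi) & !is.na(xj)
  n <- sum(ok)
  if (n < 2L) return(NA_real_)
  xi <- xi[ok]; xj <- xj[ok]
  joint <- tabulate((xj - 1L) * 4L + xi, nbins = 16L) / n
  pi <- tabulate(xi, nbins = 4L) / n
  pj <- tabulate(xj, nbins = 4L) / n
  expd <- as.vector(outer(pi, pj))
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / expd[nz]))
}

# MI over all unordered pairs of `columns`; returns a symmetric matrix with
# NA diagonal, dimnames = column indices.
.miMatrix <- function(code, columns) {
  L <- length(columns)
  M <- matrix(NA_real_, L, L, dimnames = list(columns, columns))
  if (L < 2L) return(M)
  for (a in seq_len(L - 1L)) {
    xa <- code[, columns[a]]
    for (b in (a + 1L):L) {
      M[a, b] <- M[b, a] <- .mutualInfo(xa, code[, columns[b]])
    }
  }
  M
}

# Average-product correction over the supplied MI matrix: APC(i,j) =
# mean_i * mean_j / overall mean, with column means over all partners.
.apcMatrix <- function(M) {
  cm <- rowMeans(M, na.rm = TRUE)
  overall <- mean(M[upper.tri(M)], na.rm = TRUE)
  if (!is.finite(overall) || overall <= 0) return(M * 0)
  outer(cm, cm) / overall
}

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# ---- constructor -----------------------------------------------------------

#' Construct a StructuredAlignment
#'
#' @param ids sequence identifiers.
#' @param rows aligned rows (equal width; gap character '-').
#' @param pairs consensus pair table (data.frame with columns \code{i},
#'   \code{j}, optional \code{tier} and \code{stem}); alternatively derive it
#'   from \code{ss}.
#' @param ss WUSS consensus structure string (see [parseWuss()]).
#' @param ref optional reference row.
#' @return a \linkS4class{StructuredAlignment}.
#' @export
structuredAlignment <- function(ids, rows, pairs = NULL, ss = NULL,
                                ref = NA_character_) {
  if (is.null(pairs)) {
    pairs <- if (is.null(ss)) .emptyPairs() else parseWuss(ss)
  } else {
    pairs <- as.data.frame(pairs)
    if (is.null(pairs$tier)) pairs$tier <- 1L
    if (is.null(pairs$stem)) pairs$stem <- NA_character_
  }
  a <- new("StructuredAlignment", ids = as.character(ids),
           rows = toupper(as.character(rows)), pairs = pairs,
           ss = if (is.null(ss)) NA_character_ else ss, ref = ref)
  validObject(a)
  a
}

.emptyPairs <- function() {
  data.frame(i = integer(), j = integer(), tier = integer(),
             stem = character(), stringsAsFactors = FALSE)
}

# ---- per-pair statistics ---------------------------------------------------

#' Covariation statistics for column pairs
#'
#' For each requested pair of alignment columns, counts realized pair types
#' over rows ungapped at both columns, counts compensatory sequence pairs
#' (row pairs that differ at both columns while both rows form canonical
#' Watson-Crick pairs), and computes mutual information (bits), the
#' average-product-corrected MI, and a permutation-null p-value obtained by
#' shuffling the columns independently.
#'
#' The APC column means are taken over all column pairs of the alignment (as
#' in standard covariation analysis), so the background trend subtracted
#' from a pair does not consist of the pair's own signal.
#'
#' @param aln a \linkS4class{StructuredAlignment}.
#' @param pairs data.frame with columns \code{i}, \code{j} (default: the
#'   alignment's consensus pairs).
#' @param nPerm number of independent within-column shuffles for the
#'   permutation null.
#' @param seed RNG seed for the permutation null (required when
#'   \code{nPerm > 0}).
#' @return data.frame with one row per pair: columns \code{i}, \code{j},
#'   \code{tier}, \code{stem}, \code{nUngapped}, \code{canonical},
#'   \code{wobble}, \code{nonCanonical}, \code{gapped},
#'   \code{compensatory}, \code{mi}, \code{miApc}, \code{pPerm}.
#' @examples
#' a <- structuredAlignment(paste0("s", 1:4),
#'   c("AAU", "GAC", "CAG", "UAA"), pairs = data.frame(i = 1, j = 3))
#' pairStatistics(a, nPerm = 0)
#' @export
pairStatistics <- function(aln, pairs = consensusPairs(aln), nPerm = 1000L,
                           seed = NULL) {
  stopifnot(is(aln, "StructuredAlignment"))
  pairs <- as.data.frame(pairs)
  if (!nrow(pairs)) return(cbind(pairs, .emptyPairStats()))
  if (nPerm > 0L && is.null(seed))
    .stopf("a seed is required for the permutation null")
  code <- .encodeAlignment(aln)
  width <- ncol(code)
  nRows <- nrow(code)
  M <- .miMatrix(code, seq_len(width))
  APC <- .apcMatrix(M)

  cons <- consensusPairs(aln)
  res <- vector("list", nrow(pairs))
  permStats <- function(xi, xj) {
    ok <- !is.na(xi) & !is.na(xj)
    obs <- .mutualInfo(xi, xj)
    n <- sum(ok)
    if (n < 2L || nPerm == 0L) return(NA_real_)
    hits <- 0L
    for (r in seq_len(nPerm)) {
      pi <- xi; pj <- xj
      pi[ok] <- sample(xi[ok])
      pj[ok] <- sample(xj[ok])
      if (.mutualInfo(pi, pj) >= obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + nPerm)
  }

  computed <- .withSeed(seed, {
    lapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs$i[r]; j <- pairs$j[r]
      xi <- code[, i]; xj <- code[, j]
      ok <- !is.na(xi) & !is.na(xj)
      if (!any(ok))
        return(data.frame(nUngapped = 0L, canonical = 0L, wobble = 0L,
                          nonCanonical = 0L, gapped = nRows,
                          compensatory = NA_integer_, mi = NA_real_,
                          miApc = NA_real_, pPerm = NA_real_,
                          flagged = TRUE))
      a <- c("A", "C", "G", "U")[xi[ok]]
      b <- c("A", "C", "G", "U")[xj[ok]]
      canon <- .isPaired(a, b, wobble = FALSE)
      wob <- !canon & .isPaired(a, b, wobble = TRUE)
      # compensatory: row pairs differing at both columns, both canonical
      comp <- 0L
      if (sum(ok) >= 2L) {
        di <- outer(xi[ok], xi[ok], "!=")
        dj <- outer(xj[ok], xj[ok], "!=")
        cc <- outer(canon, canon, "&")
        comp <- sum(di & dj & cc & upper.tri(di))
      }
      data.frame(
        nUngapped = sum(ok), canonical = sum(canon), wobble = sum(wob),
        nonCanonical = sum(!canon & !wob), gapped = sum(!ok),
        compensatory = comp, mi = M[i, j], miApc = M[i, j] - APC[i, j],
        pPerm = permStats(xi, xj), flagged = FALSE)
    })
  })
  stats <- do.call(rbind, computed)
  tier <- if (!is.null(pairs$tier)) pairs$tier else {
    idx <- match(paste(pairs$i, pairs$j), paste(cons$i, cons$j))
    if (nrow(cons)) cons$tier[idx] else NA_integer_
  }
  stem <- if (!is.null(pairs$stem)) pairs$stem else {
    idx <- match(paste(pairs$i, pairs$j), paste(cons$i, cons$j))
    if (nrow(cons)) cons$stem[idx] else NA_character_
  }
  out <- cbind(data.frame(i = pairs$i, j = pairs$j, tier = tier,
                          stem = stem, stringsAsFactors = FALSE), stats)
  rownames(out) <- NULL
  out
}

.emptyPairStats <- function() {
  data.frame(nUngapped = integer(), canonical = integer(),
             wobble = integer(), nonCanonical = integer(),
             gapped = integer(), compensatory = integer(), mi = numeric(),
             miApc = numeric(), pPerm = numeric(), flagged = logical())
}

# ---- plausibility filters --------------------------------------------------

#' Flag sequences whose stems realize too few C-G pairs
#'
#' Candidate matches whose predicted helices contain extremely few C-G/G-C
#' pairs are implausible as conserved RNA structure. A sequence is flagged
#' when, across the consensus pairs considered, its fraction of realized
#' C-G/G-C pairs (among positions ungapped in that sequence) falls below
#' \code{threshold}. Raising the threshold never unflags a sequence.
#'
#' @param aln a \linkS4class{StructuredAlignment}.
#' @param threshold minimum tolerated C-G fraction (default 0.15).
#' @param stems restrict to pairs with these stem labels (default: all
#'   consensus pairs).
#' @return named logical vector, one flag per sequence; sequences with no
#'   evaluable pair are NA.
#' @export
cgScarcityFilter <- function(aln, threshold = 0.15, stems = NULL) {
  stopifnot(is(aln, "StructuredAlignment"))
  p <- consensusPairs(aln)
  if (!is.null(stems)) p <- p[p$stem %in% stems, , drop = FALSE]
  code <- .encodeAlignment(aln)
  out <- rep(NA, nrow(code))
  names(out) <- aln@ids
  if (!nrow(p)) return(out)
  for (r in seq_len(nrow(code))) {
    a <- code[r, p$i]; b <- code[r, p$j]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    cg <- (a[ok] == 2L & b[ok] == 3L) | (a[ok] == 3L & b[ok] == 2L)
    out[r] <- mean(cg) < threshold
  }
  out
}

#' Flag long insertions that cannot fold into a hairpin
#'
#' Predicted structures that rely on a very long inserted segment are only
#' plausible when the insertion can fold away as a hairpin. Insertions
#' longer than \code{maxLen} are flagged unless an exhaustive search finds a
#' self-complementary hairpin (stem of at least \code{minStem} base pairs,
#' loop of at least \code{minLoop} nucleotides).
#'
#' @param insertion the inserted nucleotide sequence.
#' @param maxLen insertions at most this long are never flagged (default 12).
#' @param minStem minimum hairpin stem length in base pairs.
#' @param minLoop minimum hairpin loop length in nucleotides.
#' @param wobble count G-U as pairing in the hairpin stem.
#' @return list with \code{flagged}, \code{length} and \code{hasHairpin}.
#' @export
insertionHairpinFilter <- function(insertion, maxLen = 12L, minStem = 3L,
                                   minLoop = 3L, wobble = TRUE) {
  ch <- .seqChars(insertion)
  n <- length(ch)
  found <- FALSE
  if (n >= 2L * minStem + minLoop) {
    for (k in minStem:((n - minLoop) %/% 2L)) {
      for (a in seq_len(n - 2L * k - minLoop + 1L)) {
        maxLoop <- n - a + 1L - 2L * k
        for (l in minLoop:maxLoop) {
          arm1 <- ch[a:(a + k - 1L)]
          arm2 <- ch[(a + k + l):(a + 2L * k + l - 1L)]
          if (.stemMismatches(arm1, arm2, wobble = wobble) == 0L) {
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (found) break
    }
  }
  list(flagged = n > maxLen && !found, length = n, hasHairpin = found)
}

# ---- candidate evaluation --------------------------------------------------

#' Covariation-screen configuration
#'
#' @param K minimum number of supported consensus pairs for a "promising"
#'   verdict (default 3).
#' @param alpha permutation-null significance level.
#' @param nPerm shuffles per pair for the permutation null.
#' @param seed RNG seed (mandatory for any stochastic run).
#' @param cgThreshold C-G scarcity threshold (see [cgScarcityFilter()]).
#' @param insertionMax longest unflagged insertion (see
#'   [insertionHairpinFilter()]).
#' @return named list of thresholds, echoed into every report.
#' @export
covariationConfig <- function(K = 3L, alpha = 0.05, nPerm = 1000L,
                              seed = NULL, cgThreshold = 0.15,
                              insertionMax = 12L) {
  list(K = as.integer(K), alpha = alpha, nPerm = as.integer(nPerm),
       seed = seed, cgThreshold = cgThreshold,
       insertionMax = as.integer(insertionMax))
}

#' Evaluate a candidate alignment for covariation support
#'
#' Computes per-pair covariation statistics and per-sequence plausibility
#' flags, then issues a verdict: \code{"promising"} when at least \code{K}
#' consensus pairs each show at least one compensatory sequence pair and a
#' permutation p-value below \code{alpha}, and no required stem is entirely
#' invariant; \code{"insufficient data"} for alignments of fewer than two
#' sequences (a single example cannot exhibit covariation);
#' \code{"not promising"} otherwise.
#'
#' @param aln a \linkS4class{StructuredAlignment}.
#' @param config thresholds from [covariationConfig()]; \code{seed} is
#'   mandatory.
#' @return list with \code{verdict}, \code{pairStats}, \code{seqFlags}
#'   (C-G scarcity), \code{supportedPairs} and the echoed \code{config}.
#' @export
evaluateCandidate <- function(aln, config = covariationConfig()) {
  stopifnot(is(aln, "StructuredAlignment"))
  if (length(aln@ids) < 2L)
    return(list(verdict = "insufficient data", pairStats = NULL,
                seqFlags = NULL, supportedPairs = 0L, config = config))
  if (is.null(config$seed))
    .stopf("covariationConfig(seed=) is mandatory for evaluateCandidate")
  ps <- pairStatistics(aln, nPerm = config$nPerm, seed = config$seed)
  flags <- cgScarcityFilter(aln, threshold = config$cgThreshold)
  supported <- !is.na(ps$compensatory) & ps$compensatory >= 1L &
    !is.na(ps$pPerm) & ps$pPerm < config$alpha
  # a stem is invariant when every one of its pairs shows no variation at
  # either column
  code <- .encodeAlignment(aln)
  variable <- function(colIdx) {
    v <- code[, colIdx]
    length(unique(v[!is.na(v)])) > 1L
  }
  stemInvariant <- FALSE
  stemsPresent <- unique(ps$stem[!is.na(ps$stem)])
  for (st in stemsPresent) {
    rows <- which(ps$stem == st)
    if (!any(vapply(rows, function(r) variable(ps$i[r]) || variable(ps$j[r]),
                    TRUE)))
      stemInvariant <- TRUE
  }
  verdict <- if (sum(supported) >= config$K && !stemInvariant)
    "promising" else "not promising"
  list(verdict = verdict, pairStats = ps, seqFlags = flags,
       supportedPairs = sum(supported), invariantStem = stemInvariant,
       config = config)
}
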