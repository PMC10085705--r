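#' @include descriptor.R covariation.R kinetics.R
NULL

.BASES <- c("A", "C", "G", "U")
.WC_PAIRS <- list(c("A", "U"), c("U", "A"), c("C", "G"), c("G", "C"))

.sampleBg <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  sample(.BASES, n, replace = TRUE, prob = p)
}

# partner of `b` across an antiparallel helix; emits a G-U wobble with
# probability wobbleProb where geometrically possible
.pairPartner <- function(b, wobble, wobbleProb) {
  p <- .COMPLEMENT[[b]]
  if (wobble && b %in% c("G", "U") && stats::runif(1) < wobbleProb)
    p <- if (b == "G") "U" else "G"
  p
}

#' Sample one concrete motif instance with ground truth
#'
#' Emits a sequence satisfying the descriptor under the given block order:
#' degenerate literal positions are drawn uniformly over their IUPAC sets,
#' stems as complementary antiparallel pairs (G-U wobble emitted with
#' probability \code{wobbleProb} where the stem permits it), spacers and
#' linkers with lengths uniform over their ranges. Mutation policies:
#' \code{"compensatory"} rewrites stem pairs jointly (pair-preserving) at
#' the given per-position rate; \code{"breaking"} mutates one partner of
#' \code{count} randomly chosen stem positions so the pair no longer forms.
#'
#' @param descriptor a \linkS4class{MotifDescriptor}.
#' @param layout a \linkS4class{PermutationLayout}.
#' @param seed RNG seed.
#' @param policy \code{"none"}, \code{"compensatory"} or \code{"breaking"}.
#' @param rate per-position compensatory substitution probability.
#' @param count number of pair-breaking edits.
#' @param wobbleProb per-position probability of emitting a wobble pair.
#' @return list with \code{sequence} and \code{truth}; the truth carries the
#'   permutation \code{type}, per-element spans (0-based half-open, within
#'   the instance), the \code{cleavage} coordinate and a \code{mutations}
#'   log distinguishing pair-preserving from pair-breaking edits.
#' @export
sampleInstance <- function(descriptor, layout, seed = NULL,
                           policy = c("none", "compensatory", "breaking"),
                           rate = 0.1, count = 1L, wobbleProb = 0.1) {
  policy <- match.arg(policy)
  stopifnot(is(descriptor, "MotifDescriptor"),
            is(layout, "PermutationLayout"))
  stems <- descriptor@stems
  names(stems) <- vapply(stems, function(s) s@stemId, "")
  plan <- layout@elements
  .withSeed(seed, {
    nEl <- nrow(plan)
    parts <- vector("list", nEl)
    stemLen <- list(); stemFirst <- list()
    firstIdx <- list(); secondIdx <- list()
    for (k in seq_len(nEl)) {
      parts[[k]] <- switch(plan$kind[k],
        literal = vapply(strsplit(plan$literal[k], "")[[1]],
                         .sampleIupac, "", n = 1L),
        stem_half = {
          id <- plan$stemId[k]
          if (is.null(stemLen[[id]])) {
            rng <- stems[[id]]@lengthRange
            len <- .sampleInt(rng[1], rng[2])
            stemLen[[id]] <- len
            stemFirst[[id]] <- sample(.BASES, len, replace = TRUE)
            firstIdx[[id]] <- k
            stemFirst[[id]]
          } else {
            secondIdx[[id]] <- k
            vapply(rev(stemFirst[[id]]), .pairPartner, "",
                   wobble = stems[[id]]@wobble, wobbleProb = wobbleProb)
          }
        },
        spacer = ,
        linker = {
          len <- .sampleInt(plan$minLen[k], plan$maxLen[k])
          if (len) .sampleBg(len) else character()
        },
        cleavage_site = character())
    }

    # mutation policies act on stems via the parts of both halves
    mutations <- list()
    placed <- names(secondIdx)
    mutatePair <- function(id, q, breaking) {
      # q indexes the first half 5'->3'; its partner sits at len+1-q of the
      # second half
      len <- stemLen[[id]]
      i1 <- firstIdx[[id]]; i2 <- secondIdx[[id]]
      old1 <- parts[[i1]][q]; old2 <- parts[[i2]][len + 1L - q]
      if (breaking) {
        wob <- stems[[id]]@wobble
        badFor <- function(a) .BASES[!.isPaired(rep(a, 4), .BASES,
                                                wobble = wob)]
        parts[[i2]][len + 1L - q] <<- sample(badFor(old1), 1L)
      } else {
        np <- .WC_PAIRS[[sample.int(4L, 1L)]]
        parts[[i1]][q] <<- np[1]
        parts[[i2]][len + 1L - q] <<- np[2]
      }
      mutations[[length(mutations) + 1L]] <<- data.frame(
        stemId = id, position = q,
        kind = if (breaking) "breaking" else "compensatory",
        from = paste0(old1, "/", old2),
        to = paste0(parts[[i1]][q], "/", parts[[i2]][len + 1L - q]),
        stringsAsFactors = FALSE)
    }
    if (policy == "compensatory") {
      for (id in placed) for (q in seq_len(stemLen[[id]]))
        if (stats::runif(1) < rate) mutatePair(id, q, breaking = FALSE)
    } else if (policy == "breaking" && length(placed)) {
      all <- do.call(rbind, lapply(placed, function(id)
        data.frame(id = id, q = seq_len(stemLen[[id]]))))
      pick <- all[sample.int(nrow(all), min(count, nrow(all))), ,
                  drop = FALSE]
      for (r in seq_len(nrow(pick)))
        mutatePair(pick$id[r], pick$q[r], breaking = TRUE)
    }

    lens <- vapply(parts, length, 0L)
    ends <- cumsum(lens)
    starts <- ends - lens
    cleaveK <- which(plan$kind == "cleavage_site")
    truth <- list(
      type = typeName(layout),
      elements = data.frame(index = seq_len(nEl), block = plan$block,
                            kind = plan$kind, stemId = plan$stemId,
                            start = starts, end = ends,
                            stringsAsFactors = FALSE),
      cleavage = if (length(cleaveK)) starts[cleaveK[1]] else NA_integer_,
      mutations = if (length(mutations)) do.call(rbind, mutations)
                  else data.frame())
    list(sequence = paste(unlist(parts), collapse = ""), truth = truth)
  })
}

#' Plant motif instances in random background sequences
#'
#' Each instance is inserted into its own i.i.d. background sequence of the
#' stated GC content, at a random offset and on a random strand; decoy
#' records are pure background. All coordinates in the truth table are on
#' the forward strand (0-based half-open), matching scanner output.
#'
#' @param instances list of results from [sampleInstance()].
#' @param nDecoys number of background-only records.
#' @param gc background GC fraction, in (0, 1).
#' @param seed RNG seed.
#' @param hostLength length of each emitted record (default: longest
#'   instance plus 60 nt).
#' @return list with \code{sequences} (named character vector) and
#'   \code{truth} (data.frame: seqId, start, end, strand, type, cleavage,
#'   plus a list-column of mapped element spans).
#' @export
plantInBackground <- function(instances, nDecoys = 0L, gc = 0.5,
                              seed = NULL, hostLength = NULL) {
  stopifnot(gc > 0, gc < 1)
  lens <- vapply(instances, function(x) nchar(x$sequence), 0L)
  if (is.null(hostLength))
    hostLength <- (if (length(lens)) max(lens) else 100L) + 60L
  if (length(lens) && any(lens > hostLength))
    .stopf("instance longer than host sequence (%d > %d)", max(lens),
           hostLength)
  .withSeed(seed, {
    seqs <- character(); truthRows <- list(); elemList <- list()
    for (i in seq_along(instances)) {
      inst <- instances[[i]]
      len <- nchar(inst$sequence)
      host <- .sampleBg(hostLength, gc)
      s0 <- sample.int(hostLength - len + 1L, 1L) - 1L  # 0-based offset
      strand <- sample(c("+", "-"), 1L)
      insSeq <- if (strand == "+") inst$sequence
                else .revcompStr(inst$sequence)
      host[(s0 + 1L):(s0 + len)] <- strsplit(insSeq, "")[[1]]
      id <- sprintf("plant_%03d", i)
      seqs[[id]] <- paste(host, collapse = "")
      el <- inst$truth$elements
      if (strand == "+") {
        el$start <- s0 + el$start; el$end <- s0 + el$end
        cleave <- if (is.na(inst$truth$cleavage)) NA_integer_
                  else s0 + inst$truth$cleavage
      } else {
        newStart <- s0 + len - el$end
        newEnd <- s0 + len - el$start
        el$start <- newStart; el$end <- newEnd
        el <- el[order(el$start), , drop = FALSE]
        cleave <- if (is.na(inst$truth$cleavage)) NA_integer_
                  else s0 + len - inst$truth$cleavage
      }
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        seqId = id, start = s0, end = s0 + len, strand = strand,
        type = inst$truth$type, cleavage = cleave,
        stringsAsFactors = FALSE)
      elemList[[length(elemList) + 1L]] <- el
    }
    for (j in seq_len(nDecoys))
      seqs[[sprintf("decoy_%03d", j)]] <-
        paste(.sampleBg(hostLength, gc), collapse = "")
    truth <- if (length(truthRows)) do.call(rbind, truthRows) else
      data.frame(seqId = character(), start = integer(), end = integer(),
                 strand = character(), type = character(),
                 cleavage = integer(), stringsAsFactors = FALSE)
    truth$elements <- I(elemList)
    list(sequences = seqs, truth = truth)
  })
}

#' Simulate a gapless structured alignment with compensatory variation
#'
#' One architecture (all element lengths) is drawn once, then \code{n}
#' sequences are emitted on it: degenerate literal, spacer and linker
#' positions vary independently between sequences, while stem positions
#' start from a shared reference pair and are jointly rewritten to a random
#' Watson-Crick pair at the given per-position rate -- the compensatory
#' signal a covariation screen must detect. The consensus pair table (with
#' stem labels and pseudoknot-aware tiers) is attached.
#'
#' @param descriptor a \linkS4class{MotifDescriptor}.
#' @param layout a \linkS4class{PermutationLayout}.
#' @param n number of sequences (>= 2).
#' @param rate per-position compensatory substitution probability.
#' @param seed RNG seed.
#' @return a \linkS4class{StructuredAlignment}.
#' @export
simulateAlignment <- function(descriptor, layout, n = 50L, rate = 0.3,
                              seed = NULL) {
  stopifnot(n >= 2L)
  stems <- descriptor@stems
  names(stems) <- vapply(stems, function(s) s@stemId, "")
  plan <- layout@elements
  .withSeed(seed, {
    nEl <- nrow(plan)
    # fixed architecture
    elLen <- integer(nEl)
    stemLen <- list()
    for (k in seq_len(nEl)) {
      elLen[k] <- switch(plan$kind[k],
        literal = nchar(plan$literal[k]),
        stem_half = {
          id <- plan$stemId[k]
          if (is.null(stemLen[[id]])) {
            rng <- stems[[id]]@lengthRange
            stemLen[[id]] <- .sampleInt(rng[1], rng[2])
          }
          stemLen[[id]]
        },
        cleavage_site = 0L,
        .sampleInt(plan$minLen[k], plan$maxLen[k]))
    }
    ends <- cumsum(elLen); starts <- ends - elLen
    refStem <- lapply(stemLen, function(len)
      sample(.BASES, len, replace = TRUE))

    firstIdx <- list(); secondIdx <- list()
    for (k in which(plan$kind == "stem_half")) {
      id <- plan$stemId[k]
      if (is.null(firstIdx[[id]])) firstIdx[[id]] <- k
      else secondIdx[[id]] <- k
    }

    rows <- character(n)
    for (s in seq_len(n)) {
      parts <- vector("list", nEl)
      stemSeq <- lapply(refStem, function(x) x)
      for (id in names(stemSeq)) {
        for (q in seq_along(stemSeq[[id]]))
          if (stats::runif(1) < rate)
            stemSeq[[id]][q] <- .WC_PAIRS[[sample.int(4L, 1L)]][1]
      }
      for (k in seq_len(nEl)) {
        parts[[k]] <- switch(plan$kind[k],
          literal = vapply(strsplit(plan$literal[k], "")[[1]],
                           .sampleIupac, "", n = 1L),
          stem_half = {
            id <- plan$stemId[k]
            if (k == firstIdx[[id]]) stemSeq[[id]]
            else rev(.COMPLEMENT[stemSeq[[id]]])
          },
          cleavage_site = character(),
          if (elLen[k]) .sampleBg(elLen[k]) else character())
      }
      rows[s] <- paste(unlist(parts), collapse = "")
    }

    # consensus pairs with tier assignment (crossing stems get new tiers)
    pairRows <- list()
    extents <- list()
    for (id in names(secondIdx)) {
      a <- starts[firstIdx[[id]]]; b <- starts[secondIdx[[id]]]
      extents[[id]] <- c(a + 1L, b + stemLen[[id]])
    }
    crosses <- function(x, y)
      (x[1] < y[1] && y[1] < x[2] && x[2] < y[2]) ||
      (y[1] < x[1] && x[1] < y[2] && y[2] < x[2])
    tiers <- list()
    tierOf <- list()
    for (id in names(extents)) {
      placedTier <- NA_integer_
      for (tn in seq_along(tiers)) {
        if (!any(vapply(tiers[[tn]], function(o)
          crosses(extents[[id]], extents[[o]]), TRUE))) {
          placedTier <- tn; break
        }
      }
      if (is.na(placedTier)) {
        tiers[[length(tiers) + 1L]] <- character()
        placedTier <- length(tiers)
      }
      tiers[[placedTier]] <- c(tiers[[placedTier]], id)
      tierOf[[id]] <- placedTier
    }
    for (id in names(secondIdx)) {
      len <- stemLen[[id]]
      a <- starts[firstIdx[[id]]]; b <- starts[secondIdx[[id]]]
      for (q in seq_len(len))
        pairRows[[length(pairRows) + 1L]] <- data.frame(
          i = a + q, j = b + len - q + 1L, tier = tierOf[[id]],
          stem = id, stringsAsFactors = FALSE)
    }
    pairs <- if (length(pairRows)) do.call(rbind, pairRows) else
      .emptyPairs()
    structuredAlignment(sprintf("sim_%03d", seq_len(n)), rows,
                        pairs = pairs)
  })
}

#' Simulate a noisy one-phase decay time course
#'
#' f(t) = (y0 - plateau) exp(-k t) + plateau plus Gaussian noise of
#' standard deviation \code{sigma}, clipped to [0, 1] (the clipped count is
#' attached as an attribute).
#'
#' @param k rate constant (per minute), > 0.
#' @param t time grid (minutes); default: 30 points spanning 3/k.
#' @param y0 initial fraction.
#' @param plateau asymptotic fraction.
#' @param sigma Gaussian noise SD (>= 0).
#' @param seed RNG seed.
#' @inheritParams timeSeries
#' @return a time series (see [timeSeries()]).
#' @examples
#' ts <- simulateDecay(0.13, sigma = 0)
#' @export
simulateDecay <- function(k, t = seq(0, 3 / k, length.out = 30L), y0 = 1,
                          plateau = 0, sigma = 0, seed = NULL,
                          construct = NA_character_,
                          replicate = NA_character_) {
  stopifnot(k > 0, sigma >= 0)
  .withSeed(seed, {
    f <- (y0 - plateau) * exp(-k * t) + plateau
    if (sigma > 0) f <- f + stats::rnorm(length(t), 0, sigma)
    clipped <- sum(f < 0 | f > 1)
    out <- timeSeries(t, pmin(pmax(f, 0), 1), construct, replicate)
    attr(out, "clipped") <- clipped
    out
  })
}
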