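test_that("compiled pattern length bounds follow element arithmetic", {
  d <- builtinDescriptor("hammerhead")
  for (l in enumeratePermutations(d)) {
    pat <- compilePattern(d, l)
    litSum <- sum(nchar(stats::na.omit(pat@plan$literal)))
    stemMinSum <- sum(vapply(pat@stems, function(s)
      if (s@required) s@lengthRange[1] else 0L, 0L)) * 2L
    expect_gte(pat@minLen, litSum + stemMinSum)
    expect_equal(pat@minLen, sum(pat@plan$minLen))
    expect_gte(pat@maxLen, pat@minLen)
  }
  # unbounded element rejected
  lay <- permutationLayout(d, c("S", "G", "C"))
  lay@elements$maxLen[1] <- NA_integer_
  expect_error(compilePattern(d, lay), "unbounded")
})

test_that("unmutated planted instances are recovered exactly, for every order", {
  d <- narrowHammerhead()
  for (l in enumeratePermutations(d)) {
    pat <- compilePattern(d, l)
    for (seed in 1:5) {
      inst <- sampleInstance(d, l, seed = seed, wobbleProb = 0.1)
      m <- scanSequence(inst$sequence, pat)
      truthKey <- paste0(0, "|", nchar(inst$sequence), "|",
                         paste(paste0(inst$truth$elements$start, ",",
                                      inst$truth$elements$end),
                               collapse = ";"))
      expect_true(truthKey %in% matchKeys(m),
                  info = paste("order", typeName(l), "seed", seed))
      expect_true(all(m$cleavage >= 0 & m$cleavage <= nchar(inst$sequence)))
    }
  }
})

test_that("the M1-style conserved-G substitution abolishes matching", {
  d <- narrowHammerhead()
  for (l in enumeratePermutations(d)) {
    pat <- compilePattern(d, l)
    inst <- applyM1(sampleInstance(d, l, seed = 42, wobbleProb = 0))
    expect_equal(nrow(scanSequence(inst$sequence, pat)), 0L,
                 info = typeName(l))
  }
})

test_that("empty and too-short sequences yield no matches", {
  d <- narrowHammerhead()
  pat <- compilePattern(d, permutationLayout(d, c("S", "G", "C")))
  expect_equal(nrow(scanSequence("", pat)), 0L)
  expect_equal(nrow(scanSequence("ACGU", pat)), 0L)
})

test_that("matches are deduplicated and sorted by start, end, type", {
  d <- narrowHammerhead()
  inst <- sampleInstance(d, permutationLayout(d, c("S", "G", "C")),
                         seed = 5, wobbleProb = 0)
  m <- scanFasta(c(x = inst$sequence), d, config = scanConfig())
  keys <- paste(m$seqId, m$strand, matchKeys(m))
  expect_equal(anyDuplicated(keys), 0L)
  perSeq <- split(seq_len(nrow(m)), m$seqId)
  for (idx in perSeq) {
    o <- order(m$start[idx], m$end[idx], m$type[idx])
    expect_equal(o, seq_along(idx))
  }
})

test_that("scan agrees with the brute-force enumeration oracle", {
  d <- narrowHammerhead()
  orders <- list(c("S", "G", "C"), c("C", "S", "G"), c("S", "C", "G"))
  for (k in seq_along(orders)) {
    l <- permutationLayout(d, orders[[k]])
    pat <- compilePattern(d, l)
    planted <- plantInBackground(
      list(sampleInstance(d, l, seed = k, wobbleProb = 0.1)),
      nDecoys = 1L, gc = 0.5, seed = 900 + k, hostLength = 120L)
    for (s in planted$sequences) {
      expect_setequal(matchKeys(scanSequence(s, pat)),
                      oracleScan(s, d, orders[[k]]))
    }
  }
})

test_that("minus-strand matches map correctly to forward coordinates", {
  d <- narrowHammerhead()
  l <- permutationLayout(d, c("C", "S", "G"))
  # force a minus-strand plant by searching seeds
  for (seed in 1:20) {
    pl <- plantInBackground(list(sampleInstance(d, l, seed = seed,
                                                wobbleProb = 0)),
                            gc = 0.5, seed = seed, hostLength = 110L)
    if (pl$truth$strand[1] == "-") break
  }
  expect_equal(pl$truth$strand[1], "-")
  m <- scanFasta(pl$sequences, d, orders = "CSG", config = scanConfig())
  hit <- m[m$strand == "-" & m$start == pl$truth$start[1] &
           m$end == pl$truth$end[1], , drop = FALSE]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$cleavage, pl$truth$cleavage[1])
  el <- hit$elements[[1]]
  expect_equal(el$start, pl$truth$elements[[1]]$start)
  expect_equal(el$end, pl$truth$elements[[1]]$end)
})

test_that("strand symmetry: scanning the reverse complement mirrors coordinates", {
  d <- narrowHammerhead()
  l <- permutationLayout(d, c("S", "G", "C"))
  inst <- sampleInstance(d, l, seed = 3, wobbleProb = 0)
  pl <- plantInBackground(list(inst), gc = 0.45, seed = 31,
                          hostLength = 100L)
  s <- pl$sequences[[1]]
  rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(chartr("T", "U",
    toupper(s)), "")[[1]]), collapse = ""))
  m1 <- scanFasta(stats::setNames(s, "f"), d, orders = "SGC")
  m2 <- scanFasta(stats::setNames(rc, "r"), d, orders = "SGC")
  expect_equal(nrow(m1), nrow(m2))
  L <- nchar(s)
  flip <- function(df) data.frame(start = L - df$end, end = L - df$start,
                                  strand = ifelse(df$strand == "+", "-",
                                                  "+"))
  expect_setequal(paste(m1$start, m1$end, m1$strand),
                  do.call(paste, flip(m2)))
})

test_that("compensatory edits keep matches; breaking edits beyond budget kill them", {
  d <- rigidHammerhead()
  l <- permutationLayout(d, c("S", "G", "C"))
  pat <- compilePattern(d, l)
  foundComp <- 0L; foundBreak <- 0L; n <- 50L
  for (seed in seq_len(n)) {
    comp <- sampleInstance(d, l, seed = seed, policy = "compensatory",
                           rate = 0.4, wobbleProb = 0)
    if (nrow(comp$truth$mutations))
      expect_true(all(comp$truth$mutations$kind == "compensatory"))
    if (nrow(scanSequence(comp$sequence, pat)) > 0L)
      foundComp <- foundComp + 1L
    brk <- sampleInstance(d, l, seed = seed, policy = "breaking",
                          count = 2L, wobbleProb = 0)
    expect_true(all(brk$truth$mutations$kind == "breaking"))
    if (nrow(scanSequence(brk$sequence, pat)) > 0L)
      foundBreak <- foundBreak + 1L
  }
  expect_equal(foundComp, n)
  expect_equal(foundBreak, 0L)
})

test_that("every reported match re-verifies against the raw constraints", {
  d <- narrowHammerhead()
  l <- permutationLayout(d, c("G", "C", "S"))
  pat <- compilePattern(d, l)
  pl <- plantInBackground(
    lapply(1:3, function(s) sampleInstance(d, l, seed = s,
                                           wobbleProb = 0.1)),
    nDecoys = 3L, gc = 0.5, seed = 77, hostLength = 120L)
  m <- scanFasta(pl$sequences, d, orders = "GCS")
  for (i in seq_len(nrow(m)))
    expect_true(verifyMatch(m[i, ], pl$sequences[[m$seqId[i]]], pat))
})

test_that("duplicate FASTA record ids are rejected", {
  d <- narrowHammerhead()
  expect_error(scanFasta(c(a = "ACGU", a = "ACGU"), d), "duplicate")
})

test_that("fragment lengths from predictCleavage sum to the construct length", {
  d <- narrowHammerhead()
  l <- permutationLayout(d, c("S", "G", "C"))
  for (seed in 1:5) {
    pl <- plantInBackground(list(sampleInstance(d, l, seed = seed,
                                                wobbleProb = 0)),
                            gc = 0.5, seed = seed, hostLength = 90L)
    m <- scanFasta(pl$sequences, d, orders = "SGC")
    hit <- m[m$start == pl$truth$start[1] & m$end == pl$truth$end[1] &
             m$strand == pl$truth$strand[1], , drop = FALSE][1, ]
    s <- pl$sequences[[1]]
    pc <- predictCleavage(hit, s)
    expect_equal(pc$len5 + pc$len3, nchar(s))
    expect_false(pc$degenerate)
  }
  # degenerate flag at the boundary
  fake <- scanSequence(sampleInstance(d, l, seed = 1,
                                      wobbleProb = 0)$sequence,
                       compilePattern(d, l))[1, , drop = FALSE]
  fake$cleavage <- 0L
  expect_true(predictCleavage(fake, "ACGU")$degenerate)
  fake$cleavage <- NA_integer_
  expect_error(predictCleavage(fake, "ACGU"), "no cleavage site")
})
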