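test_that("mutual information matches closed forms", {
  # uniform 4-state bijection across {AU, GC, CG, UA}: MI = 2 bits
  a <- structuredAlignment(paste0("s", 1:4),
                           c("A-U", "G-C", "C-G", "U-A") |> gsub(
                             pattern = "-", replacement = "A"),
                           pairs = data.frame(i = 1L, j = 3L))
  ps <- pairStatistics(a, nPerm = 0)
  expect_equal(ps$mi, 2)
  expect_equal(ps$canonical, 4L)

  # invariant columns: MI = 0, no compensatory pairs
  b <- structuredAlignment(paste0("s", 1:5), rep("GAC", 5),
                           pairs = data.frame(i = 1L, j = 3L))
  pb <- pairStatistics(b, nPerm = 0)
  expect_equal(pb$mi, 0)
  expect_equal(pb$compensatory, 0L)

  # independent columns with identical composition: MI near 0
  set.seed(9)
  rows <- replicate(40, paste(sample(c("A", "C", "G", "U"), 2,
                                     replace = TRUE), collapse = "A"))
  cS <- structuredAlignment(paste0("s", 1:40), rows,
                            pairs = data.frame(i = 1L, j = 3L))
  expect_lt(pairStatistics(cS, nPerm = 0)$mi, 0.5)
})

test_that("MI is invariant under row permutation and bounded by miApc", {
  d <- builtinDescriptor("hammerhead")
  l <- permutationLayout(d, c("S", "G", "C"))
  aln <- simulateAlignment(d, l, n = 25, rate = 0.3, seed = 4)
  ps <- pairStatistics(aln, nPerm = 0)
  expect_true(all(ps$mi >= 0))
  expect_true(all(ps$miApc <= ps$mi + 1e-12))
  perm <- sample(length(alignmentIds(aln)))
  aln2 <- structuredAlignment(alignmentIds(aln)[perm],
                              alignmentRows(aln)[perm],
                              pairs = consensusPairs(aln))
  ps2 <- pairStatistics(aln2, nPerm = 0)
  expect_equal(ps2$mi, ps$mi)
})

test_that("permutation p-values are seed-reproducible and calibrated", {
  d <- builtinDescriptor("hammerhead")
  l <- permutationLayout(d, c("S", "G", "C"))
  aln <- simulateAlignment(d, l, n = 30, rate = 0.4, seed = 8)
  p1 <- pairStatistics(aln, nPerm = 200, seed = 123)
  p2 <- pairStatistics(aln, nPerm = 200, seed = 123)
  expect_identical(p1$pPerm, p2$pPerm)
  expect_error(pairStatistics(aln, nPerm = 100), "seed")
  # strongly covarying pairs get small p; an invariant pair gets p = 1
  expect_lt(min(p1$pPerm), 0.05)
  b <- structuredAlignment(paste0("s", 1:5), rep("GAC", 5),
                           pairs = data.frame(i = 1L, j = 3L))
  expect_equal(pairStatistics(b, nPerm = 50, seed = 1)$pPerm, 1)
})

test_that("compensatory counts equal the brute-force double loop", {
  d <- builtinDescriptor("hammerhead")
  l <- permutationLayout(d, c("C", "S", "G"))
  aln <- simulateAlignment(d, l, n = 15, rate = 0.5, seed = 21)
  ps <- pairStatistics(aln, nPerm = 0)
  rows <- unname(alignmentRows(aln))
  wc <- c(A = "U", U = "A", C = "G", G = "C")
  for (r in seq_len(nrow(ps))) {
    i <- ps$i[r]; j <- ps$j[r]
    cnt <- 0L
    for (a in seq_along(rows)[-length(rows)]) for (b in (a + 1L):length(rows)) {
      ai <- substr(rows[a], i, i); aj <- substr(rows[a], j, j)
      bi <- substr(rows[b], i, i); bj <- substr(rows[b], j, j)
      if (ai != bi && aj != bj &&
          identical(wc[[ai]], aj) && identical(wc[[bi]], bj))
        cnt <- cnt + 1L
    }
    expect_equal(ps$compensatory[r], cnt)
  }
})

test_that("consensus pairs outrank unpaired column pairs by corrected MI", {
  d <- builtinDescriptor("hammerhead")
  l <- permutationLayout(d, c("S", "G", "C"))
  wins <- 0L; nRuns <- 20L
  for (seed in seq_len(nRuns)) {
    aln <- simulateAlignment(d, l, n = 50, rate = 0.3, seed = seed)
    ps <- pairStatistics(aln, nPerm = 0)
    code <- permotif:::.encodeAlignment(aln)
    paired <- c(ps$i, ps$j)
    unp <- setdiff(which(apply(code, 2, function(v)
      length(unique(v[!is.na(v)])) > 1L)), paired)
    set.seed(seed)
    k <- min(nrow(ps), floor(length(unp) / 2))
    pick <- matrix(sample(unp, 2L * k), ncol = 2)
    rnd <- data.frame(i = pmin(pick[, 1], pick[, 2]),
                      j = pmax(pick[, 1], pick[, 2]))
    pr <- pairStatistics(aln, pairs = rnd, nPerm = 0)
    if (min(ps$miApc) > max(pr$miApc)) wins <- wins + 1L
  }
  expect_gte(wins / nRuns, 0.95)
})

test_that("C-G scarcity filter flags pairless sequences and is monotone", {
  # three consensus pairs; row 1 realizes zero C-G, row 2 all C-G
  rows <- c("AAAUUU", "CCCGGG", "CGAUCG")
  aln <- structuredAlignment(paste0("s", 1:3), rows,
                             pairs = data.frame(i = 1:3, j = 6:4))
  fl <- cgScarcityFilter(aln, threshold = 0.15)
  expect_true(fl[["s1"]])
  expect_false(fl[["s2"]])
  expect_false(any(cgScarcityFilter(aln, threshold = 0)))
  # monotone: raising the threshold never unflags
  for (th in c(0, 0.1, 0.4, 0.7, 1)) {
    lo <- cgScarcityFilter(aln, threshold = th)
    hi <- cgScarcityFilter(aln, threshold = min(th + 0.3, 1))
    expect_true(all(hi[lo]))
  }
})

test_that("insertion filter spares short or hairpin-capable insertions", {
  polyA <- strrep("A", 30)
  expect_true(insertionHairpinFilter(polyA)$flagged)
  # 20-nt insertion with complementary 4-bp arms and a 4-nt loop
  hp <- paste0("AAAA", "GCGC", "UUUU", "GCGC", "AAAA")
  r <- insertionHairpinFilter(hp)
  expect_true(r$hasHairpin)
  expect_false(r$flagged)
  expect_false(insertionHairpinFilter("ACGUA")$flagged)  # below L
  expect_equal(insertionHairpinFilter("ACGUA")$length, 5L)
})

test_that("candidate evaluation verdicts follow the screen's rules", {
  d <- builtinDescriptor("hammerhead")
  l <- permutationLayout(d, c("S", "G", "C"))
  cfg <- covariationConfig(nPerm = 200, seed = 99)
  # rich compensatory signal: promising
  aln <- simulateAlignment(d, l, n = 50, rate = 0.4, seed = 15)
  ev <- evaluateCandidate(aln, cfg)
  expect_equal(ev$verdict, "promising")
  expect_gte(ev$supportedPairs, cfg$K)
  # a single sequence cannot show covariation
  one <- structuredAlignment("only", alignmentRows(aln)[1],
                             pairs = consensusPairs(aln))
  expect_equal(evaluateCandidate(one, cfg)$verdict, "insufficient data")
  # an invariant alignment is never promising
  flat <- structuredAlignment(paste0("s", 1:6),
                              rep(alignmentRows(aln)[1], 6),
                              pairs = consensusPairs(aln))
  expect_equal(evaluateCandidate(flat, cfg)$verdict, "not promising")
  # two similar sequences: evaluable (the two-sequence candidate situation)
  two <- simulateAlignment(d, l, n = 2, rate = 0.4, seed = 33)
  evTwo <- evaluateCandidate(two, cfg)
  expect_true(evTwo$verdict %in% c("promising", "not promising"))
  expect_false(is.null(evTwo$pairStats))
})
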