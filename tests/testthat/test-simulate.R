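test_that("generators are pure functions of parameters and seed", {
  d <- narrowHammerhead()
  l <- permutationLayout(d, c("S", "G", "C"))
  i1 <- sampleInstance(d, l, seed = 11)
  i2 <- sampleInstance(d, l, seed = 11)
  expect_identical(i1, i2)
  p1 <- plantInBackground(list(i1), nDecoys = 2L, gc = 0.6, seed = 4)
  p2 <- plantInBackground(list(i1), nDecoys = 2L, gc = 0.6, seed = 4)
  expect_identical(p1, p2)
  a1 <- simulateAlignment(d, l, n = 5, rate = 0.3, seed = 2)
  expect_identical(alignmentRows(a1),
                   alignmentRows(simulateAlignment(d, l, n = 5, rate = 0.3,
                                                   seed = 2)))
  s1 <- simulateDecay(0.1, sigma = 0.05, seed = 9)
  expect_identical(s1, simulateDecay(0.1, sigma = 0.05, seed = 9))
})

test_that("planted FASTA files are byte-identical across runs", {
  d <- narrowHammerhead()
  l <- permutationLayout(d, c("C", "G", "S"))
  mk <- function(path) {
    pl <- plantInBackground(lapply(1:3, function(s)
      sampleInstance(d, l, seed = s)), nDecoys = 2L, gc = 0.5, seed = 55)
    writeFasta(pl$sequences, path)
    readBin(path, "raw", file.info(path)$size)
  }
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  expect_identical(mk(f1), mk(f2))
})

test_that("instance truth spans tile the instance and locate the cleavage site", {
  d <- builtinDescriptor("hammerhead")
  for (l in enumeratePermutations(d)) {
    inst <- sampleInstance(d, l, seed = 7)
    el <- inst$truth$elements
    expect_equal(el$start[1], 0L)
    expect_equal(el$end[nrow(el)], nchar(inst$sequence))
    expect_true(all(el$start[-1] == el$end[-nrow(el)]))
    expect_true(inst$truth$cleavage >= 0 &&
                inst$truth$cleavage <= nchar(inst$sequence))
  }
})

test_that("unmutated instances match their own compiled pattern", {
  d <- narrowHammerhead()
  for (l in enumeratePermutations(d)) {
    pat <- compilePattern(d, l)
    for (seed in 1:3) {
      inst <- sampleInstance(d, l, seed = 40 + seed, wobbleProb = 0.1)
      expect_gt(nrow(scanSequence(inst$sequence, pat)), 0L)
    }
  }
})

test_that("background GC content tracks the requested fraction", {
  d <- narrowHammerhead()
  pl <- plantInBackground(list(), nDecoys = 30L, gc = 0.7, seed = 12,
                          hostLength = 300L)
  gc <- mean(strsplit(paste(pl$sequences, collapse = ""), "")[[1]] %in%
             c("G", "C"))
  expect_equal(gc, 0.7, tolerance = 0.03)
  expect_error(plantInBackground(list(), nDecoys = 1L, gc = 1.2, seed = 1))
})

test_that("instances longer than the host are rejected", {
  d <- narrowHammerhead()
  inst <- sampleInstance(d, permutationLayout(d, c("S", "G", "C")),
                         seed = 1)
  expect_error(plantInBackground(list(inst), hostLength = 10L, seed = 1),
               "longer than host")
})

test_that("simulated alignments carry a stem-consistent pair table", {
  d <- builtinDescriptor("hammerhead")
  l <- permutationLayout(d, c("S", "G", "C"))
  aln <- simulateAlignment(d, l, n = 10, rate = 0, seed = 6)
  p <- consensusPairs(aln)
  expect_setequal(unique(p$stem), c("I", "II", "III"))
  # with rate 0 every sequence realizes the reference: columns at pairs are
  # perfectly complementary
  rows <- alignmentRows(aln)
  wc <- c(A = "U", U = "A", C = "G", G = "C")
  for (r in seq_len(nrow(p))) {
    i <- p$i[r]; j <- p$j[r]
    ok <- vapply(rows, function(x)
      identical(wc[[substr(x, i, i)]], substr(x, j, j)), TRUE)
    expect_true(all(ok))
  }
  # pseudoknotted order needs >= 2 tiers; tiers are internally nested
  expect_gte(length(unique(p$tier)), 2L)
  expect_silent(validObject(aln))
})

test_that("noise-free decay simulation reproduces the model curve", {
  t <- seq(0, 60, 3)
  ts <- simulateDecay(0.13, t = t, sigma = 0)
  expect_equal(ts$f, exp(-0.13 * t))
  expect_equal(kObs(fitDecay(ts)), 0.13, tolerance = 1e-7)
  ts2 <- simulateDecay(0.05, y0 = 0.9, plateau = 0.2, t = t, sigma = 0)
  expect_equal(ts2$f, 0.7 * exp(-0.05 * t) + 0.2)
})
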