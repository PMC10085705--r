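test_that("hammerhead descriptor parses into three blocks and four stems", {
  d <- builtinDescriptor("hammerhead")
  expect_s4_class(d, "MotifDescriptor")
  labs <- vapply(motifBlocks(d), function(b) b@label, "")
  expect_setequal(labs, c("C", "G", "S"))
  req <- vapply(motifStems(d), function(s) s@required, TRUE)
  expect_equal(sum(req), 3L)
  expect_equal(sum(!req), 1L)
  # conserved box literals present
  lits <- unlist(lapply(motifBlocks(d), function(b)
    vapply(Filter(function(e) e@kind == "literal", b@elements),
           function(e) e@literal, "")))
  expect_true("CUGANGA" %in% lits)
  expect_true("GAAA" %in% lits)
})

test_that("serialization round-trips both built-in descriptors", {
  for (nm in c("hammerhead", "twister")) {
    d <- builtinDescriptor(nm)
    expect_identical(parseDescriptor(descriptorText(d)), d)
    p <- withr::local_tempfile(fileext = ".txt")
    writeDescriptor(d, p)
    expect_identical(readDescriptor(p), d)
  }
})

test_that("malformed descriptors fail with informative errors", {
  # stem referenced by only one half
  expect_error(parseDescriptor(
    "motif x\nstem I len=2:4\nlinker 0:3\nblock A\n  stem5 I\n  seq ACGU"),
    "stem I has 1 halves")
  # undeclared stem
  expect_error(parseDescriptor(
    "motif x\nlinker 0:3\nblock A\n  stem5 Z\n  seq AC\n  stem3 Z"),
    "undeclared")
  # duplicate block label
  expect_error(parseDescriptor(
    "motif x\nlinker 0:3\nblock A\n  seq AC\nblock A\n  seq GU"),
    "duplicate block labels")
  # syntax errors carry line numbers
  expect_error(parseDescriptor("motif x\nfrobnicate"), "line 2")
  expect_error(parseDescriptor(
    "motif x\nblock A\n  seq QQ"), "IUPAC")
  # element outside a block
  expect_error(parseDescriptor("motif x\nseq ACGU"), "outside any block")
})

test_that("permutation enumeration yields n! distinct lexicographic orders", {
  d <- builtinDescriptor("hammerhead")
  layouts <- enumeratePermutations(d)
  expect_equal(vapply(layouts, typeName, ""),
               c("CGS", "CSG", "GCS", "GSC", "SCG", "SGC"))

  d1 <- parseDescriptor("motif one\nlinker 0:2\nblock A\n  seq ACGU")
  expect_length(enumeratePermutations(d1), 1L)

  d4 <- randomDescriptor(nBlocks = 4L, nStems = 2L, seed = 11)
  l4 <- enumeratePermutations(d4)
  expect_length(l4, 24L)
  expect_equal(anyDuplicated(vapply(l4, typeName, "")), 0L)
})

test_that("intra-block element order is identical across layouts", {
  d <- builtinDescriptor("hammerhead")
  ref <- NULL
  for (l in enumeratePermutations(d)) {
    el <- l@elements
    perBlock <- lapply(split(el[el$kind != "linker", ],
                             el$block[el$kind != "linker"]),
                       function(x) paste(x$kind, x$literal, x$stemId,
                                         x$side, collapse = "|"))
    if (is.null(ref)) ref <- perBlock else expect_identical(perBlock, ref)
  }
})

test_that("circular hammerhead orders are junctions, non-circular are pseudoknotted", {
  d <- builtinDescriptor("hammerhead")
  tt <- topologyTable(d)
  expect_equal(tt$crossingPairs[match(c("CGS", "GSC", "SCG"), tt$order)],
               rep(0L, 3))
  expect_equal(tt$class[match(c("CGS", "GSC", "SCG"), tt$order)],
               rep("junction", 3))
  expect_true(all(tt$crossingPairs[match(c("SGC", "CSG", "GCS"),
                                         tt$order)] >= 2L))
  expect_equal(tt$crossingPairs[match(c("SGC", "CSG", "GCS"), tt$order)],
               rep(3L, 3))
})

test_that("cyclic rotations share a crossing count and topology matches the oracle", {
  rotations <- function(x) lapply(seq_along(x) - 1L,
                                  function(r) c(x, x)[(r + 1):(r + length(x))])
  for (seed in 1:6) {
    nB <- sample(3:5, 1)
    d <- randomDescriptor(nBlocks = nB, nStems = sample(2:4, 1),
                          seed = 100 + seed)
    layouts <- enumeratePermutations(d)
    for (l in layouts)
      expect_equal(countPseudoknots(l)$crossingPairs, oracleCrossings(l),
                   info = paste("order", typeName(l), "seed", seed))
    # rotation classes
    base <- blockOrder(layouts[[1]])
    counts <- vapply(rotations(base), function(ord)
      countPseudoknots(permutationLayout(d, ord))$crossingPairs, 0L)
    expect_true(all(counts == counts[1]))
  }
})

test_that("optional stems join the topology count only on request", {
  d <- builtinDescriptor("twister")
  layouts <- enumeratePermutations(d)
  for (l in layouts) {
    without <- countPseudoknots(l)$crossingPairs
    with <- countPseudoknots(l, includeOptional = TRUE)$crossingPairs
    expect_gte(with, without)
    expect_equal(countPseudoknots(l, TRUE)$crossingPairs,
                 oracleCrossings(l, TRUE))
  }
  # the hammerhead interaction stem has no placed halves: no effect
  dh <- builtinDescriptor("hammerhead")
  for (l in enumeratePermutations(dh))
    expect_equal(countPseudoknots(l, TRUE), countPseudoknots(l))
})
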