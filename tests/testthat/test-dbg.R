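test_that("canonical k-mer counting merges twin occurrences", {
  # two occurrences of canonical AAA (AAAA has AAA twice)
  expect_equal(countKmers("AAAA", 3), c(AAA = 2))
  # AGCTTA: AGC and GCT are a twin pair and share one canonical form
  expect_equal(countKmers("AGCTTA", 3), c(AAG = 1, AGC = 2, TAA = 1))
  # a read shorter than k contributes nothing
  expect_length(countKmers("AG", 3), 0)
  # windows containing N are excluded
  expect_equal(countKmers("AANCC", 3), structure(numeric(0), names = character(0)))
  expect_equal(sum(countKmers("ACGTGTCA", 5)), 4)  # all windows valid
  # even k breaks twin pairing and is refused
  expect_error(countKmers("ACGT", 4), "odd")
})

test_that("counting is strand symmetric", {
  set.seed(5)
  for (i in 1:10) {
    s <- randomSeq(sample(20:60, 1))
    a <- countKmers(s, 11)
    b <- countKmers(c(s, revComp(s)), 11)
    expect_identical(names(a), names(b))
    expect_equal(unname(b), unname(2 * a))
  }
})

test_that("a non-branching chain condenses to a single node pair", {
  set.seed(3)
  T <- randomSeq(60)
  g <- buildGraph(T, k = 15, covCutoff = 0)
  expect_equal(numNodes(g), 1L)
  expect_equal(unname(as.character(nodeSeqs(g)))[1], min(T, revComp(T)))
  expect_equal(nodeKmerCount(g), 46L)
  expect_equal(nodeCoverage(g), 46)  # one read, each k-mer seen once
  expect_equal(nrow(graphEdges(g)), 0L)
})

test_that("an exon-skipping pair builds a 4-node bubble spelling both isoforms", {
  toy <- bubbleToy()
  g <- toy$graph
  expect_equal(numNodes(g), 4L)
  p1 <- findPathSpelling(g, toy$T1)
  p2 <- findPathSpelling(g, toy$T2)
  expect_false(is.null(p1))
  expect_false(is.null(p2))
  expect_equal(length(p1), 3L)  # prefix, mid, suffix
  expect_equal(length(p2), 3L)
  # the two isoform paths share their ends and differ in the middle
  expect_equal(p1@ids[-2], p2@ids[-2])
  expect_false(p1@ids[2] == p2@ids[2])
  # the shared branch end has two outgoing continuations
  expect_equal(nrow(outSteps(g, p1@ids[1], p1@orient[1])), 2L)
})

test_that("the coverage cutoff removes the weak branch and re-condenses", {
  toy <- bubbleToy()
  reads <- c(rep(toy$T1, 5), toy$T2)
  g <- buildGraph(reads, k = 11, covCutoff = 3, tipLen = 11)
  # the T2-specific middle (average coverage 1) is gone; what remains
  # re-condenses to a single node spelling T1
  expect_equal(numNodes(g), 1L)
  expect_equal(unname(as.character(nodeSeqs(g)))[1],
               min(toy$T1, revComp(toy$T1)))
  expect_true(all(avgNodeCoverage(g) >= 3))
})

test_that("short dead-end tips are removed when a sibling exists", {
  set.seed(3)
  T <- randomSeq(60)
  tipRead <- paste0(substr(T, 1, 30), "ACGCCTAG")  # 8-base artifact branch
  g0 <- buildGraph(c(T, tipRead), k = 15, covCutoff = 0, tipLen = 15)
  # tip spells (k-1) + 8 = 22 >= tipLen = 15: kept
  expect_gt(numNodes(g0), 1L)
  g1 <- buildGraph(c(T, tipRead), k = 15, covCutoff = 0, tipLen = 30)
  # 22 < 30: removed, graph re-condenses to the plain chain
  expect_equal(numNodes(g1), 1L)
  expect_equal(unname(as.character(nodeSeqs(g1)))[1], min(T, revComp(T)))
  # a linear single-node graph is never a tip (no branch point)
  g2 <- buildGraph(T, k = 15, covCutoff = 0, tipLen = 1000)
  expect_equal(numNodes(g2), 1L)
})

test_that("spellPath follows (k-1)-overlaps and rejects non-adjacent steps", {
  toy <- bubbleToy()
  g <- toy$graph
  p1 <- findPathSpelling(g, toy$T1)
  sp <- spellPath(g, p1)
  expect_true(sp == toy$T1 || sp == revComp(toy$T1))
  lens <- nchar(as.character(nodeSeqs(g))[p1@ids])
  expect_equal(nchar(sp), sum(lens) - (length(p1) - 1L) * (graphK(g) - 1L))
  # single "-" step spells the reverse complement of the stored node
  expect_equal(spellPath(g, graphPath(1L, "-")),
               revComp(as.character(nodeSeqs(g))[1]))
  # the two middle nodes of the bubble are not adjacent
  mids <- sort(unique(c(findPathSpelling(g, toy$T1)@ids[2],
                        findPathSpelling(g, toy$T2)@ids[2])))
  expect_error(spellPath(g, graphPath(mids, c("+", "+"))), "not adjacent")
  expect_error(spellPath(g, graphPath(99L, "+")), "unknown node")
})

test_that("twinPath is an involution and spells the reverse complement", {
  toy <- bubbleToy()
  g <- toy$graph
  for (p in list(findPathSpelling(g, toy$T1), graphPath(1L, "-"))) {
    tp <- twinPath(p)
    expect_equal(spellPath(g, tp), revComp(spellPath(g, p)))
    expect_equal(twinPath(tp)@ids, p@ids)
    expect_equal(twinPath(tp)@orient, p@orient)
  }
})

test_that("outSteps is deterministic and twin-symmetric", {
  toy <- bubbleToy()
  g <- toy$graph
  p1 <- findPathSpelling(g, toy$T1)
  s <- outSteps(g, p1@ids[1], p1@orient[1])
  expect_equal(nrow(s), 2L)
  expect_equal(s$id, sort(s$id))
  e <- graphEdges(g)
  # every edge has its twin mirror
  key <- paste(e$from, e$fromOrient, e$to, e$toOrient)
  flip <- function(o) ifelse(o == "+", "-", "+")
  twin <- paste(e$to, flip(e$toOrient), e$from, flip(e$fromOrient))
  expect_true(all(twin %in% key))
  expect_error(outSteps(g, 99L, "+"), "unknown")
})

test_that("fold-back (hairpin) junctions are not condensed across", {
  # AGCTTA folds back onto its own twin at both ends (palindromic AGCT/TTAA
  # overlaps); the chain stops at the fold-back, leaving hairpin edges
  g <- buildGraph("AGCTTA", k = 3, covCutoff = 0, tipLen = 3)
  expect_equal(unname(as.character(nodeSeqs(g))), "GCTTA")
  expect_equal(nodeCoverage(g), 4)
  e <- graphEdges(g)
  expect_true(all(e$from == 1L & e$to == 1L))
  expect_true(all(e$fromOrient != e$toOrient))
})

test_that("GFA round-trips bit-exactly", {
  toy <- bubbleToy()
  g <- toy$graph
  tmp <- tempfile(fileext = ".gfa")
  on.exit(unlink(tmp))
  writeGFA(g, tmp)
  g2 <- readGFA(tmp)
  expect_equal(graphK(g2), graphK(g))
  expect_identical(as.character(nodeSeqs(g2)), as.character(nodeSeqs(g)))
  expect_equal(nodeCoverage(g2), nodeCoverage(g))
  expect_identical(graphEdges(g2), graphEdges(g))
  ln <- readLines(tmp)
  expect_match(ln[1], "^H\tVN:Z:1\\.0\tkk:i:11$")
  expect_equal(sum(startsWith(ln, "S")), 4L)
})

test_that("every surviving canonical k-mer lives in exactly one node", {
  set.seed(9)
  for (i in 1:5) {
    tx <- replicate(2, randomSeq(sample(50:90, 1)))
    g <- buildGraph(tx, k = 11, covCutoff = 0, tipLen = 11)
    counted <- names(countKmers(tx, 11))
    inNodes <- unlist(lapply(unname(as.character(nodeSeqs(g))), function(s) {
      n <- nchar(s) - 10L
      km <- substring(s, 1:n, 11:nchar(s))
      rc <- revComp(km)
      pmin(km, rc)
    }))
    expect_identical(sort(inNodes), sort(counted))
  }
})
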