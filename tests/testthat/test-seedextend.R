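# Most tests run on the frozen exon-skipping bubble (see helper-fixtures.R):
# prefix -> {mid1 | mid2} -> suffix at k = 11, transcripts T1/T2.

ntParams <- function(...) searchParams(ei = 1e-3, ef = 1e-10, ...)

test_that("selectSeeds seeds each transcript with its matching nodes", {
  toy <- bubbleToy()
  g <- toy$graph
  sc <- ntScheme()
  db <- transcriptDb(c(tx1 = toy$T1, tx2 = toy$T2), "nt")
  seeds <- selectSeeds(g, db, sc, ntParams())
  expect_setequal(names(seeds), c("tx1", "tx2"))
  p1 <- findPathSpelling(g, toy$T1)
  p2 <- findPathSpelling(g, toy$T2)
  # tx1 is seeded by its three path nodes but not by tx2's middle
  expect_setequal(seeds$tx1$node, p1@ids)
  expect_false(p2@ids[2] %in% seeds$tx1$node)
  # seeds are sorted by e-value: the long middle node beats the short ends
  expect_true(all(diff(seeds$tx1$log10_evalue) >= 0))
  # truncation to the single best node
  s1 <- selectSeeds(g, db, sc, ntParams(nSeeds = 1L))
  expect_equal(nrow(s1$tx1), 1L)
  expect_equal(s1$tx1$node, seeds$tx1$node[1])
  # every node hit lands in the pool when one is supplied
  pool <- newCandidatePool()
  selectSeeds(g, db, sc, ntParams(), pool = pool)
  expect_setequal(poolTranscripts(pool), c("tx1", "tx2"))
})

test_that("a single matching node seeds its transcript", {
  set.seed(31)
  T <- randomSeq(80)
  g <- buildGraph(T, k = 15, covCutoff = 0)
  db <- transcriptDb(c(t = T), "nt")
  seeds <- selectSeeds(g, db, ntScheme(), ntParams())
  expect_equal(seeds$t$node, 1L)
})

test_that("extendForward follows the e-value gradient through the bubble", {
  toy <- bubbleToy()
  g <- toy$graph
  sc <- ntScheme()
  db <- transcriptDb(c(tx1 = toy$T1, tx2 = toy$T2), "nt")
  p1 <- findPathSpelling(g, toy$T1)
  start <- graphPath(p1@ids[1], p1@orient[1])
  res <- extendForward(g, start, "tx1", db, sc, ntParams())
  expect_equal(spellPath(g, res$path), spellPath(g, p1))
  expect_false(res$truncated)
  # the same start extended for tx2 picks the other middle
  res2 <- extendForward(g, start, "tx2", db, sc, ntParams())
  expect_equal(spellPath(g, res2$path),
               spellPath(g, findPathSpelling(g, toy$T2)))
  # a dead end returns unchanged
  tail1 <- graphPath(p1@ids[3], p1@orient[3])
  res3 <- extendForward(g, tail1, "tx1", db, sc, ntParams())
  expect_equal(res3$path@ids, tail1@ids)
  # maxSteps truncates and flags
  res4 <- extendForward(g, start, "tx1", db, sc, ntParams(maxSteps = 1L))
  expect_true(res4$truncated)
  expect_equal(length(res4$path), 2L)
})

test_that("accepted extensions strictly improve the e-value", {
  toy <- bubbleToy()
  g <- toy$graph
  sc <- ntScheme()
  db <- transcriptDb(c(tx1 = toy$T1), "nt")
  p1 <- findPathSpelling(g, toy$T1)
  start <- graphPath(p1@ids[1], p1@orient[1])
  seedHit <- searchDb(spellPath(g, start), db, sc)
  res <- extendForward(g, start, "tx1", db, sc, ntParams())
  expect_lt(res$log10_evalue, seedHit$log10_evalue[1])
})

test_that("extendSeed merges the twin extension with the forward one", {
  toy <- bubbleToy()
  g <- toy$graph
  sc <- ntScheme()
  db <- transcriptDb(c(tx1 = toy$T1), "nt")
  p1 <- findPathSpelling(g, toy$T1)
  # seeding from the middle node must still recover the whole isoform
  res <- extendSeed(g, p1@ids[2], p1@orient[2], "tx1", db, sc, ntParams())
  sp <- spellPath(g, res$path)
  expect_true(sp == toy$T1 || sp == revComp(toy$T1))
  expect_equal(res$hit$subject, "tx1")
  # spell(merged) ends with the forward extension's spelling
  fwd <- extendForward(g, graphPath(p1@ids[2], p1@orient[2]), "tx1", db, sc,
                       ntParams())
  expect_true(endsWith(sp, spellPath(g, fwd$path)))
  # an isolated node merges to itself
  set.seed(37)
  T <- randomSeq(60)
  g1 <- buildGraph(T, k = 15, covCutoff = 0)
  res1 <- extendSeed(g1, 1L, "+", "t", transcriptDb(c(t = T), "nt"),
                     sc, ntParams())
  expect_equal(length(res1$path), 1L)
})

test_that("lookahead commits a multi-node step past a very short node", {
  # hand-built chain u -> s -> v at k = 11: s contributes only 2 bases that
  # MISMATCH the database transcript, so the one-node step cannot improve;
  # only u.s.v does (v's 30 matching bases dominate the 2 mismatches)
  set.seed(41)
  A <- randomSeq(30)
  B <- randomSeq(30)
  u <- A
  s <- paste0(substr(A, 21, 30), "GG")
  v <- paste0(substr(s, 3, 12), B)
  g <- chainGraph(c(u, s, v), k = 11)
  db <- transcriptDb(c(t = paste0(A, "CC", B)), "nt")
  sc <- ntScheme()
  par <- searchParams(ei = 1, ef = 1e-4, lookahead = 2L)
  res <- extendForward(g, graphPath(1L, "+"), "t", db, sc, par)
  expect_equal(res$path@ids, c(1L, 2L, 3L))
  expect_equal(spellPath(g, res$path), paste0(A, "GG", B))
  # lookahead disabled: the path stays blocked at u
  res0 <- extendForward(g, graphPath(1L, "+"), "t", db, sc,
                        searchParams(ei = 1, ef = 1e-4, lookahead = 0L))
  expect_equal(res0$path@ids, 1L)
  # no descendant improves: unchanged, but explored hits reach the pool
  db2 <- transcriptDb(c(t = A, w = B), "nt")
  pool <- newCandidatePool()
  la <- shortNodeLookahead(g, graphPath(1L, "+"), "t", db2, sc, par,
                           pool = pool)
  expect_false(la$improved)
  expect_equal(la$path@ids, 1L)
  expect_true("w" %in% poolTranscripts(pool))  # explored u.s.v hit w
})

test_that("runSearch recovers both isoforms and fills the pool monotonically", {
  toy <- bubbleToy()
  g <- toy$graph
  sc <- ntScheme()
  db <- transcriptDb(c(tx1 = toy$T1, tx2 = toy$T2), "nt")
  par <- ntParams()
  pool <- runSearch(g, db, sc, par)
  expect_setequal(poolTranscripts(pool), c("tx1", "tx2"))
  for (tid in c(tx1 = "tx1", tx2 = "tx2")) {
    b <- poolBest(pool, tid)
    target <- if (tid == "tx1") toy$T1 else toy$T2
    sp <- spellPath(g, b$path)
    expect_true(sp == target || sp == revComp(target))
  }
  # pool e-values are at least as good as the best seed's
  seeds <- selectSeeds(g, db, sc, par)
  for (tid in names(seeds)) {
    expect_lte(poolBest(pool, tid)$hit$log10_evalue,
               seeds[[tid]]$log10_evalue[1])
  }
  # empty graph gives an empty pool
  empty <- suppressWarnings(buildGraph("AC", k = 11))
  expect_length(poolTranscripts(runSearch(empty, db, sc, par)), 0L)
})

test_that("runSearch is deterministic", {
  toy <- bubbleToy()
  g <- toy$graph
  sc <- ntScheme()
  db <- transcriptDb(c(tx1 = toy$T1, tx2 = toy$T2), "nt")
  par <- ntParams()
  snapshot <- function(pool) {
    lapply(poolTranscripts(pool), function(tid) {
      b <- poolBest(pool, tid)
      list(path = pathString(b$path), l10 = b$hit$log10_evalue)
    })
  }
  expect_identical(snapshot(runSearch(g, db, sc, par)),
                   snapshot(runSearch(g, db, sc, par)))
})
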