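# Shared fixtures and independent oracles, built in code.

randomSeq <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Pure-R affine-gap local alignment score: the independent dynamic-programming
# reference for the compiled engine. q, s are residue vectors; a gap of
# length L costs gapOpen + L * gapExtend.
rswScore <- function(q, s, submat, gapOpen, gapExtend) {
  m <- length(q)
  n <- length(s)
  if (m == 0L || n == 0L) return(0)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  Fm <- matrix(NEG, m + 1, n + 1)
  go <- gapOpen + gapExtend
  ge <- gapExtend
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - ge)
      Fm[i, j] <- max(H[i - 1, j] - go, Fm[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[q[i - 1], s[j - 1]],
                     E[i, j], Fm[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# reference nt score over both query strands
rswScoreNt <- function(qs, ss, scheme) {
  q <- strsplit(qs, "", fixed = TRUE)[[1]]
  r <- strsplit(revComp(qs), "", fixed = TRUE)[[1]]
  s <- strsplit(ss, "", fixed = TRUE)[[1]]
  max(rswScore(q, s, scheme@submat, scheme@gapOpen, scheme@gapExtend),
      rswScore(r, s, scheme@submat, scheme@gapOpen, scheme@gapExtend))
}

# reference translated score: best over the six frames, each scored by the
# pure-R DP on the Biostrings translation
rswScoreTx <- function(qs, pep, scheme) {
  best <- 0
  L <- nchar(qs)
  p <- strsplit(pep, "", fixed = TRUE)[[1]]
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) qs else revComp(qs)
    for (off in 0:2) {
      len3 <- ((L - off) %/% 3L) * 3L
      if (len3 < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, off + 1L, off + len3)),
        if.fuzzy.codon = "X"))
      a <- strsplit(aa, "", fixed = TRUE)[[1]]
      best <- max(best, rswScore(a, p, scheme@submat,
                                 scheme@gapOpen, scheme@gapExtend))
    }
  }
  best
}

# Frozen 4-node bubble at k = 11: prefix -> {mid1 | mid2} -> suffix, the
# graph shape an exon-skipping event produces.
bubbleToy <- function() {
  set.seed(1)
  P <- randomSeq(30)
  M1 <- randomSeq(20)
  M2 <- randomSeq(20)
  S <- randomSeq(30)
  T1 <- paste0(P, M1, S)
  T2 <- paste0(P, M2, S)
  g <- buildGraph(c(T1, T2), k = 11, covCutoff = 0, tipLen = 11)
  list(graph = g, T1 = T1, T2 = T2, P = P, M1 = M1, M2 = M2, S = S)
}

# locate the path spelling a given sequence (forward or reverse complement)
# among all simple paths; NULL if absent
findPathSpelling <- function(graph, target) {
  for (p in enumerateSimplePaths(graph)) {
    s <- spellPath(graph, p)
    if (s == target || s == revComp(target)) return(p)
  }
  NULL
}

# all simple oriented paths (no node id repeated, either orientation)
enumerateSimplePaths <- function(graph) {
  res <- list()
  dfs <- function(ids, ors) {
    res[[length(res) + 1L]] <<- graphPath(ids, ors)
    tail <- length(ids)
    nx <- outSteps(graph, ids[tail], ors[tail])
    for (r in seq_len(nrow(nx))) {
      if (nx$id[r] %in% ids) next
      dfs(c(ids, nx$id[r]), c(ors, nx$orient[r]))
    }
  }
  for (id in seq_len(numNodes(graph))) {
    for (o in c("+", "-")) dfs(id, o)
  }
  res
}

# acyclicity of the oriented node graph (hairpins count as cycles)
isOrientedDag <- function(graph) {
  e <- graphEdges(graph)
  if (!nrow(e)) return(TRUE)
  if (any(e$from == e$to)) return(FALSE)
  verts <- paste0(rep(seq_len(numNodes(graph)), each = 2), c("+", "-"))
  from <- paste0(e$from, e$fromOrient)
  to <- paste0(e$to, e$toOrient)
  indeg <- as.list(table(factor(to, levels = verts)))
  adj <- split(to, factor(from, levels = verts))
  queue <- verts[unlist(indeg) == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(verts)
}

# small acyclic instance (isoform-like transcripts sharing ends) plus a
# mutated nt database; deterministic under `seed`
randomDagInstance <- function(seed) {
  for (sub in 0:49) {
    set.seed(seed * 1000L + sub)
    P <- randomSeq(sample(25:35, 1))
    S <- randomSeq(sample(25:35, 1))
    mids <- replicate(sample(2:3, 1), randomSeq(sample(12:20, 1)))
    tx <- vapply(mids, function(m) paste0(P, m, S), "")
    g <- buildGraph(tx, k = 11, covCutoff = 0, tipLen = 11)
    if (numNodes(g) >= 3 && numNodes(g) <= 12 && isOrientedDag(g)) {
      dbseqs <- vapply(seq_along(tx), function(i)
        mutateOrtholog(tx[i], 0.92, "nt", seed = seed * 1000L + sub + i), "")
      names(dbseqs) <- paste0("t", seq_along(tx))
      return(list(graph = g, db = transcriptDb(dbseqs, "nt"), tx = tx))
    }
  }
  NULL
}

# build a DeBruijnGraph by hand from node sequences whose consecutive pairs
# overlap by k-1 (a simple chain i+ -> (i+1)+ with twin closure)
chainGraph <- function(seqs, k, extraEdges = NULL) {
  n <- length(seqs)
  flip <- function(o) ifelse(o == "+", "-", "+")
  e <- data.frame(from = integer(), fromOrient = character(),
                  to = integer(), toOrient = character(),
                  stringsAsFactors = FALSE)
  addEdge <- function(e, a, ao, b, bo) {
    rbind(e,
          data.frame(from = a, fromOrient = ao, to = b, toOrient = bo,
                     stringsAsFactors = FALSE),
          data.frame(from = b, fromOrient = flip(bo),
                     to = a, toOrient = flip(ao), stringsAsFactors = FALSE))
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) e <- addEdge(e, i, "+", i + 1L, "+")
  }
  if (!is.null(extraEdges)) {
    for (r in seq_len(nrow(extraEdges))) {
      e <- addEdge(e, extraEdges$from[r], extraEdges$fromOrient[r],
                   extraEdges$to[r], extraEdges$toOrient[r])
    }
  }
  e <- unique(e)
  methods::new("DeBruijnGraph", k = as.integer(k), covCutoff = 0,
               tipLen = as.integer(2L * k), nodeSeq = seqs,
               nodeCov = as.numeric(nchar(seqs) - k + 1L), edges = e)
}

# one-row hit data.frame for constructing report-module inputs
fakeHit <- function(subject, q_start, q_end, s_start, s_end,
                    raw = 10L, bit = 20, frame = 0L) {
  data.frame(subject = subject, raw = raw, bit = bit,
             log10_evalue = log10Evalue(bit, 10, 100),
             evalue = evalueFromBit(bit, 10, 100),
             q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, frame = frame,
             stringsAsFactors = FALSE)
}
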