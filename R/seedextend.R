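# Improvement tolerance: an e-value counts as better only if smaller by a
# relative 1e-12, i.e. log10 difference below -1e-12/ln(10).
.TOL_L10 <- 1e-12 / log(10)

.newCtx <- function(db, scheme, pool, cache) {
  list(db = db, scheme = scheme, pool = pool, cache = cache,
       stats = new.env(parent = emptyenv()))
}

.bump <- function(ctx, what, by = 1L) {
  cur <- if (exists(what, envir = ctx$stats, inherits = FALSE))
    get(what, envir = ctx$stats) else 0L
  assign(what, cur + by, envir = ctx$stats)
}

# record hits of one alignment invocation into the pool: per subject keep the
# strictly smaller e-value (first invocation wins ties, keeping runs
# deterministic)
.updatePool <- function(pool, path, hits) {
  for (i in seq_len(nrow(hits))) {
    tid <- hits$subject[i]
    cur <- if (exists(tid, envir = pool@env, inherits = FALSE))
      get(tid, envir = pool@env, inherits = FALSE) else NULL
    if (is.null(cur) || hits$log10_evalue[i] < cur$hit$log10_evalue) {
      assign(tid, list(path = path, hit = hits[i, , drop = FALSE]),
             envir = pool@env)
    }
  }
}

# search the spelled sequence of a path against the database, with a cache
# keyed by spelled sequence; every invocation (cached or not) updates the
# pool for all subjects hit
.searchPath <- function(graph, path, ctx) {
  seq <- spellPath(graph, path)
  hits <- if (exists(seq, envir = ctx$cache, inherits = FALSE)) {
    get(seq, envir = ctx$cache, inherits = FALSE)
  } else {
    .bump(ctx, "alignments")
    h <- searchDb(seq, ctx$db, ctx$scheme, Inf)
    assign(seq, h, envir = ctx$cache)
    h
  }
  .bump(ctx, "invocations")
  .updatePool(ctx$pool, path, hits)
  hits
}

.hitFor <- function(hits, transcriptId) {
  i <- which(hits$subject == transcriptId)
  if (!length(i)) NULL else hits[i[1], , drop = FALSE]
}

.appendStep <- function(path, id, orient) {
  graphPath(c(path@ids, id), c(path@orient, orient))
}

# deterministic candidate choice: best e-value, then bit score descending,
# then shorter spelled length, then lexicographically smallest oriented ids
.bestCandIdx <- function(l10, bit, len, key) {
  order(l10, -bit, len, key)[1]
}

.pathKey <- function(path) {
  paste(sprintf("%09d%s", path@ids, path@orient), collapse = "")
}

.resolveShortLen <- function(params, graph) {
  if (is.na(params@shortLen)) graphK(graph) else params@shortLen
}

#' Choose seed nodes per database transcript
#'
#' Applies the alignment engine from every node of the graph (as a
#' single-node path in "+" orientation; the opposite strand is handled by
#' strand-aware alignment) to the transcript database, keeps per transcript
#' the \code{nSeeds} nodes with the best e-value at most \code{ei} (ties:
#' bit score descending, then node id), and records every node hit into the
#' candidate pool.
#'
#' @param graph a [DeBruijnGraph-class].
#' @param db a [TranscriptDB-class].
#' @param scheme a [ScoringScheme-class].
#' @param params a [SearchParams-class].
#' @param pool a [CandidatePool-class] to update (created if NULL).
#' @param cache environment caching hit tables by spelled sequence
#'   (created if NULL).
#' @return named list (by transcript id) of data.frames with columns node,
#'   orient, raw, bit, log10_evalue, evalue, best seed first.
#' @export
selectSeeds <- function(graph, db, scheme, params, pool = NULL, cache = NULL) {
  if (is.null(pool)) pool <- newCandidatePool()
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ctx <- .newCtx(db, scheme, pool, cache)
  eiL10 <- log10(params@ei)
  acc <- vector("list", numNodes(graph))
  for (id in seq_len(numNodes(graph))) {
    hits <- .searchPath(graph, graphPath(id, "+"), ctx)
    if (!nrow(hits)) next
    hits <- hits[hits$log10_evalue <= eiL10, , drop = FALSE]
    if (!nrow(hits)) next
    hits$node <- id
    acc[[id]] <- hits
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc)) return(list())
  all <- do.call(rbind, acc)
  out <- lapply(split(all, all$subject), function(h) {
    h <- h[order(h$log10_evalue, -h$bit, h$node), , drop = FALSE]
    h <- utils::head(h, params@nSeeds)
    rownames(h) <- NULL
    data.frame(node = h$node, orient = "+",
               raw = h$raw, bit = h$bit,
               log10_evalue = h$log10_evalue, evalue = h$evalue,
               stringsAsFactors = FALSE)
  })
  out[sort(names(out))]
}

# lookahead past very short nodes: from the blocked path, step first through a
# candidate contributing fewer than shortLen new bases, then explore up to
# `lookahead` added nodes in total; commit the whole multi-node step only if
# some terminal e-value improves on the pre-step best
.lookahead <- function(graph, path, transcriptId, ctx, params, shortLen,
                       curL10) {
  D <- params@lookahead
  if (D < 2L) return(NULL)
  k <- graphK(graph)
  tail <- length(path@ids)
  succ <- outSteps(graph, path@ids[tail], path@orient[tail])
  if (!nrow(succ)) return(NULL)
  contrib <- nchar(graph@nodeSeq[succ$id]) - (k - 1L)
  shortIdx <- which(contrib < shortLen)
  if (!length(shortIdx)) return(NULL)

  best <- NULL
  consider <- function(p, depth) {
    hits <- .searchPath(graph, p, ctx)
    h <- .hitFor(hits, transcriptId)
    if (depth >= 2L) {
      cand <- list(
        path = p,
        l10 = if (is.null(h)) Inf else h$log10_evalue,
        bit = if (is.null(h)) -Inf else h$bit,
        len = nchar(spellPath(graph, p)),
        key = .pathKey(p)
      )
      if (is.null(best) ||
          cand$l10 < best$l10 - .TOL_L10 ||
          (abs(cand$l10 - best$l10) <= .TOL_L10 &&
             (cand$bit > best$bit ||
                (cand$bit == best$bit &&
                   (cand$len < best$len ||
                      (cand$len == best$len && cand$key < best$key)))))) {
        best <<- cand
      }
    }
    if (depth < D) {
      nx <- outSteps(graph, p@ids[length(p@ids)], p@orient[length(p@ids)])
      for (r in seq_len(nrow(nx))) {
        consider(.appendStep(p, nx$id[r], nx$orient[r]), depth + 1L)
      }
    }
  }
  for (r in shortIdx) {
    consider(.appendStep(path, succ$id[r], succ$orient[r]), 1L)
  }
  if (!is.null(best) && best$l10 < curL10 - .TOL_L10) best else NULL
}

#' Lookahead extension past very short nodes
#'
#' When the best one-node extension fails to improve the e-value and some
#' candidate next node contributes fewer than \code{shortLen} new bases,
#' explores extensions up to \code{lookahead} nodes deep past the short node
#' and commits the multi-node step only if a terminal e-value improves on
#' the pre-step best. With \code{lookahead < 2} this is always a no-change.
#' All explored paths' hits are recorded in the pool.
#'
#' @inheritParams selectSeeds
#' @param path the blocked [GraphPath-class].
#' @param transcriptId the transcript whose e-value drives the extension.
#' @return list(path, improved, log10_evalue); \code{path} is unchanged when
#'   no committed step exists.
#' @export
shortNodeLookahead <- function(graph, path, transcriptId, db, scheme, params,
                               pool = NULL, cache = NULL) {
  if (is.null(pool)) pool <- newCandidatePool()
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ctx <- .newCtx(db, scheme, pool, cache)
  shortLen <- .resolveShortLen(params, graph)
  hits <- .searchPath(graph, path, ctx)
  h <- .hitFor(hits, transcriptId)
  curL10 <- if (is.null(h)) Inf else h$log10_evalue
  res <- .lookahead(graph, path, transcriptId, ctx, params, shortLen, curL10)
  if (is.null(res)) {
    list(path = path, improved = FALSE, log10_evalue = curL10)
  } else {
    list(path = res$path, improved = TRUE, log10_evalue = res$l10)
  }
}

.extendForward <- function(graph, path, transcriptId, ctx, params) {
  shortLen <- .resolveShortLen(params, graph)
  k <- graphK(graph)
  hits <- .searchPath(graph, path, ctx)
  h <- .hitFor(hits, transcriptId)
  curL10 <- if (is.null(h)) Inf else h$log10_evalue
  curBit <- if (is.null(h)) -Inf else h$bit
  steps <- 0L
  truncated <- FALSE

  repeat {
    if (steps >= params@maxSteps) {
      truncated <- TRUE
      break
    }
    tail <- length(path@ids)
    succ <- outSteps(graph, path@ids[tail], path@orient[tail])
    if (!nrow(succ)) break  # no more outgoing edges

    nc <- nrow(succ)
    cands <- vector("list", nc)
    l10 <- numeric(nc); bit <- numeric(nc)
    len <- numeric(nc); key <- character(nc)
    for (r in seq_len(nc)) {
      p2 <- .appendStep(path, succ$id[r], succ$orient[r])
      h2 <- .hitFor(.searchPath(graph, p2, ctx), transcriptId)
      cands[[r]] <- p2
      l10[r] <- if (is.null(h2)) Inf else h2$log10_evalue
      bit[r] <- if (is.null(h2)) -Inf else h2$bit
      len[r] <- nchar(graph@nodeSeq[succ$id[r]]) - (k - 1L)
      key[r] <- .pathKey(p2)
    }
    bi <- .bestCandIdx(l10, bit, len, key)
    if (l10[bi] < curL10 - .TOL_L10) {
      path <- cands[[bi]]
      curL10 <- l10[bi]
      curBit <- bit[bi]
      steps <- steps + 1L
      next
    }
    la <- .lookahead(graph, path, transcriptId, ctx, params, shortLen, curL10)
    if (!is.null(la)) {
      added <- length(la$path@ids) - length(path@ids)
      path <- la$path
      curL10 <- la$l10
      curBit <- la$bit
      steps <- steps + added
      next
    }
    break  # e-value no longer improves
  }
  if (truncated) .bump(ctx, "truncated")
  list(path = path, log10_evalue = curL10, bit = curBit,
       steps = steps, truncated = truncated)
}

#' Greedy single-direction extension of a path
#'
#' At each iteration all one-node extensions along outgoing edges are
#' spelled and searched against the database (each invocation updates the
#' pool for every transcript hit); the extension with the best e-value to
#' \code{transcriptId} is accepted iff strictly better than the current
#' best. The loop stops when there are no outgoing edges, when the e-value
#' no longer improves (subject to the short-node lookahead), or at
#' \code{maxSteps}.
#'
#' @inheritParams shortNodeLookahead
#' @return list(path, log10_evalue, bit, steps, truncated).
#' @export
extendForward <- function(graph, path, transcriptId, db, scheme, params,
                          pool = NULL, cache = NULL) {
  if (is.null(pool)) pool <- newCandidatePool()
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ctx <- .newCtx(db, scheme, pool, cache)
  .extendForward(graph, path, transcriptId, ctx, params)
}

.extendSeed <- function(graph, seedId, seedOrient, transcriptId, ctx, params) {
  p0 <- graphPath(seedId, seedOrient)
  fwd <- .extendForward(graph, p0, transcriptId, ctx, params)
  twn <- .extendForward(graph, twinPath(p0), transcriptId, ctx, params)
  tp <- twinPath(twn$path)  # ends with the seed step by construction
  nt <- length(tp@ids)
  if (tp@ids[nt] != seedId || tp@orient[nt] != seedOrient)
    stop("internal consistency error: twin extension does not end at the seed")
  if (nt > 1L) {
    merged <- graphPath(
      c(tp@ids[-nt], fwd$path@ids),
      c(tp@orient[-nt], fwd$path@orient)
    )
  } else {
    merged <- fwd$path
  }
  hits <- .searchPath(graph, merged, ctx)
  h <- .hitFor(hits, transcriptId)
  list(path = merged, hit = h)
}

#' Extend a seed node in both directions and merge
#'
#' Extends forward from the seed and from its twin, merges the twin of the
#' backward extension (its terminal seed step removed) with the forward
#' extension, searches the merged path against the database, records it in
#' the pool, and returns it.
#'
#' @inheritParams shortNodeLookahead
#' @param seedId,seedOrient the oriented seed node.
#' @return list(path = merged [GraphPath-class], hit = best hit to
#'   \code{transcriptId} or NULL).
#' @export
extendSeed <- function(graph, seedId, seedOrient = "+", transcriptId, db,
                       scheme, params, pool = NULL, cache = NULL) {
  if (is.null(pool)) pool <- newCandidatePool()
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  ctx <- .newCtx(db, scheme, pool, cache)
  .extendSeed(graph, seedId, seedOrient, transcriptId, ctx, params)
}

#' Run the full seed-and-extend search
#'
#' Selects seeds per database transcript, extends every (transcript, seed)
#' pair in deterministic order (transcript id ascending, seed rank
#' ascending), memoizing duplicate (seed, transcript) work, and returns the
#' candidate pool: for each transcript, the best (path, hit) over every
#' alignment invocation performed during the search.
#'
#' @inheritParams selectSeeds
#' @param verbose emit per-stage counters to stderr.
#' @return A [CandidatePool-class].
#' @export
runSearch <- function(graph, db, scheme, params = searchParams(),
                      verbose = FALSE) {
  pool <- newCandidatePool()
  if (numNodes(graph) == 0L) return(pool)
  cache <- new.env(parent = emptyenv())
  ctx <- .newCtx(db, scheme, pool, cache)
  seeds <- selectSeeds(graph, db, scheme, params, pool, cache)
  if (verbose)
    message(sprintf("seeds: %d transcript(s) seeded from %d node(s)",
                    length(seeds), numNodes(graph)))
  memo <- new.env(parent = emptyenv())
  next_ext <- 0L
  for (tid in names(seeds)) {  # already sorted
    sa <- seeds[[tid]]
    for (r in seq_len(nrow(sa))) {
      key <- paste0(sa$node[r], sa$orient[r], "|", tid)
      if (exists(key, envir = memo, inherits = FALSE)) next
      assign(key, TRUE, envir = memo)
      .extendSeed(graph, sa$node[r], sa$orient[r], tid, ctx, params)
      next_ext <- next_ext + 1L
    }
  }
  if (verbose) {
    al <- if (exists("alignments", envir = ctx$stats)) get("alignments", envir = ctx$stats) else 0L
    inv <- if (exists("invocations", envir = ctx$stats)) get("invocations", envir = ctx$stats) else 0L
    message(sprintf("extensions: %d; database searches: %d (%d distinct)",
                    next_ext, inv, al))
  }
  pool
}
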