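#' Count canonical k-mers in a set of reads
#'
#' Every k-mer occurrence (either strand) is counted once under its
#' canonical form, the lexicographic minimum of the k-mer and its reverse
#' complement. Windows containing N (or any non-ACGT character) are skipped.
#' k must be odd so that no k-mer is its own reverse complement, which would
#' break twin pairing.
#'
#' @param reads character vector of read sequences, or a data.frame with a
#'   \code{seq} column.
#' @param k odd k-mer size >= 3.
#' @return named numeric vector of counts, names sorted.
#' @examples
#' countKmers("AAAA", 3)  # canonical AAA counted twice
#' @export
countKmers <- function(reads, k) {
  reads <- .readSeqs(reads)
  k <- .checkK(k)
  res <- cpp_count_kmers(reads, k)
  stats::setNames(res$count, res$kmer)
}

.readSeqs <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot("seq" %in% names(reads))
    reads <- reads$seq
  }
  as.character(reads)
}

.checkK <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 3L)
    stop("k must be a single integer >= 3")
  if (k %% 2L == 0L)
    stop("k must be odd: even k admits self-complementary k-mers, ",
         "which break twin pairing")
  k
}

.emptyEdges <- function() {
  data.frame(
    from = integer(), fromOrient = character(),
    to = integer(), toOrient = character(),
    stringsAsFactors = FALSE
  )
}

.sortEdges <- function(e) {
  if (!nrow(e)) return(e)
  o <- order(e$from, match(e$fromOrient, c("+", "-")),
             e$to, match(e$toOrient, c("+", "-")))
  e <- e[o, , drop = FALSE]
  rownames(e) <- NULL
  e
}

.newGraph <- function(k, covCutoff, tipLen, nodeSeq, nodeCov, edges) {
  new("DeBruijnGraph",
    k = as.integer(k), covCutoff = as.numeric(covCutoff),
    tipLen = as.integer(tipLen),
    nodeSeq = as.character(nodeSeq), nodeCov = as.numeric(nodeCov),
    edges = .sortEdges(edges)
  )
}

# spelled sequence of one oriented node
.spellNode <- function(graph, id, orient) {
  s <- graph@nodeSeq[id]
  if (orient == "+") s else .rc(s)
}

#' Build a condensed de Bruijn graph from reads
#'
#' Counts canonical k-mers, collapses maximal non-branching chains into
#' nodes, removes short tips, applies the k-mer coverage cutoff \code{c} to
#' average node coverage, and re-condenses to a fixpoint. Node ids are
#' assigned deterministically (nodes sorted by stored sequence).
#'
#' @param reads character vector of read sequences or a data.frame with a
#'   \code{seq} column (e.g. from [readFastq], after [trimReads]).
#' @param k odd k-mer size (25 and 31 are typical short-read choices).
#' @param covCutoff minimum average k-mer coverage of a retained node
#'   (Velvet-style \code{cov_cutoff}; 0 disables).
#' @param tipLen maximum spelled length of a removable tip; default 2k.
#' @return A [DeBruijnGraph-class].
#' @export
buildGraph <- function(reads, k, covCutoff = 0, tipLen = 2L * as.integer(k)) {
  reads <- .readSeqs(reads)
  k <- .checkK(k)
  tipLen <- as.integer(tipLen)
  if (tipLen < k) stop("tipLen must be >= k")
  res <- cpp_condense(reads, k)
  if (length(res$seq) == 0L) {
    warning("no k-mer survives; returning an empty graph")
    return(.newGraph(k, covCutoff, tipLen, character(), numeric(), .emptyEdges()))
  }
  em <- res$edges
  edges <- data.frame(
    from = as.integer(em[, 1L]),
    fromOrient = c("+", "-")[em[, 2L] + 1L],
    to = as.integer(em[, 3L]),
    toOrient = c("+", "-")[em[, 4L] + 1L],
    stringsAsFactors = FALSE
  )
  g <- .newGraph(k, covCutoff, tipLen, res$seq, res$cov, edges)
  g <- removeTips(g, tipLen)
  g <- .recondense(g)
  g <- .applyCovCutoff(g, covCutoff)
  g <- .recondense(g)
  .renumberGraph(g)
}

# ---- accessors -------------------------------------------------------------

#' @rdname DeBruijnGraph-class
#' @param graph a [DeBruijnGraph-class].
#' @export
graphK <- function(graph) graph@k

#' @rdname DeBruijnGraph-class
#' @export
numNodes <- function(graph) length(graph@nodeSeq)

#' @rdname DeBruijnGraph-class
#' @return \code{nodeSeqs}: a [Biostrings::DNAStringSet] of node sequences
#'   (canonical orientation), named by node id.
#' @export
nodeSeqs <- function(graph) {
  s <- Biostrings::DNAStringSet(graph@nodeSeq)
  names(s) <- as.character(seq_along(graph@nodeSeq))
  s
}

#' @rdname DeBruijnGraph-class
#' @export
nodeCoverage <- function(graph) graph@nodeCov

#' @rdname DeBruijnGraph-class
#' @export
nodeKmerCount <- function(graph) nchar(graph@nodeSeq) - graph@k + 1L

#' @rdname DeBruijnGraph-class
#' @export
avgNodeCoverage <- function(graph) {
  kc <- nodeKmerCount(graph)
  ifelse(kc > 0, graph@nodeCov / kc, 0)
}

#' @rdname DeBruijnGraph-class
#' @export
graphEdges <- function(graph) graph@edges

# ---- oriented queries ------------------------------------------------------

#' Outgoing steps of an oriented node
#'
#' Successors of \code{(id, orient)}, in deterministic order (ascending id,
#' "+" before "-").
#'
#' @param graph a [DeBruijnGraph-class].
#' @param id node id.
#' @param orient "+" or "-".
#' @return data.frame with columns id, orient.
#' @export
outSteps <- function(graph, id, orient = "+") {
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > numNodes(graph))
    stop("unknown node id: ", id)
  e <- graph@edges
  sel <- e$from == id & e$fromOrient == orient
  out <- data.frame(id = e$to[sel], orient = e$toOrient[sel],
                    stringsAsFactors = FALSE)
  out[order(out$id, match(out$orient, c("+", "-"))), , drop = FALSE]
}

.indeg <- function(graph, id, orient) {
  e <- graph@edges
  sum(e$to == id & e$toOrient == orient)
}

.outdeg <- function(graph, id, orient) {
  e <- graph@edges
  sum(e$from == id & e$fromOrient == orient)
}

.hasEdge <- function(graph, a, ao, b, bo) {
  e <- graph@edges
  any(e$from == a & e$fromOrient == ao & e$to == b & e$toOrient == bo)
}

#' Spell the nucleotide sequence of a path
#'
#' Concatenates the oriented node sequences with the (k-1)-overlap removed
#' at each junction; a "-" step spells the reverse complement of the stored
#' node sequence. Errors if consecutive steps are not joined by an edge.
#'
#' @param graph a [DeBruijnGraph-class].
#' @param path a [GraphPath-class].
#' @return nucleotide string.
#' @export
spellPath <- function(graph, path) {
  k <- graph@k
  n <- length(path@ids)
  if (any(path@ids < 1L | path@ids > numNodes(graph)))
    stop("path references unknown node id")
  parts <- character(n)
  parts[1] <- .spellNode(graph, path@ids[1], path@orient[1])
  if (n > 1L) {
    for (i in 2:n) {
      if (!.hasEdge(graph, path@ids[i - 1L], path@orient[i - 1L],
                    path@ids[i], path@orient[i]))
        stop("steps ", i - 1L, " and ", i, " of the path are not adjacent")
      parts[i] <- substring(.spellNode(graph, path@ids[i], path@orient[i]), k)
    }
  }
  paste0(parts, collapse = "")
}

#' Twin (reverse-complement) of a path
#'
#' Steps reversed with orientations flipped, so that
#' \code{spellPath(graph, twinPath(p)) == revComp(spellPath(graph, p))}.
#'
#' @param path a [GraphPath-class].
#' @return A [GraphPath-class].
#' @export
twinPath <- function(path) {
  graphPath(rev(path@ids), rev(.flipOrient(path@orient)))
}

# ---- simplification --------------------------------------------------------

.dropNodes <- function(graph, dropIds) {
  if (!length(dropIds)) return(graph)
  keep <- setdiff(seq_len(numNodes(graph)), dropIds)
  remap <- integer(numNodes(graph))
  remap[keep] <- seq_along(keep)
  e <- graph@edges
  sel <- !(e$from %in% dropIds | e$to %in% dropIds)
  e <- e[sel, , drop = FALSE]
  e$from <- remap[e$from]
  e$to <- remap[e$to]
  .newGraph(graph@k, graph@covCutoff, graph@tipLen,
            graph@nodeSeq[keep], graph@nodeCov[keep], e)
}

#' Remove short dead-end tips
#'
#' Iteratively removes nodes that are dead ends in the oriented sense
#' (in-degree 0 or out-degree 0), have spelled length below \code{tipLen},
#' and have a sibling alternative at their branch point (the neighbour they
#' attach to has another edge in the same direction). Removal is one node at
#' a time (shortest first, then lowest id) until a fixpoint; twin symmetry
#' is preserved structurally.
#'
#' @param graph a [DeBruijnGraph-class].
#' @param tipLen maximum spelled length of a removable tip (default: the
#'   value stored in the graph).
#' @return A [DeBruijnGraph-class] without qualifying tips.
#' @export
removeTips <- function(graph, tipLen = graph@tipLen) {
  repeat {
    n <- numNodes(graph)
    if (n == 0L) return(graph)
    lens <- nchar(graph@nodeSeq)
    cand <- integer()
    candLen <- integer()
    for (id in seq_len(n)) {
      if (lens[id] >= tipLen) next
      outP <- .outdeg(graph, id, "+")
      inP <- .indeg(graph, id, "+")
      if (outP == 0L && inP == 0L) next  # isolated, not a tip
      qualifies <- FALSE
      if (outP == 0L) {  # dead end forward: look at predecessors of (id,+)
        e <- graph@edges
        pr <- e[e$to == id & e$toOrient == "+", , drop = FALSE]
        for (r in seq_len(nrow(pr))) {
          if (.outdeg(graph, pr$from[r], pr$fromOrient[r]) >= 2L) {
            qualifies <- TRUE
            break
          }
        }
      } else if (inP == 0L) {  # dead end backward: successors of (id,+)
        sc <- outSteps(graph, id, "+")
        for (r in seq_len(nrow(sc))) {
          if (.indeg(graph, sc$id[r], sc$orient[r]) >= 2L) {
            qualifies <- TRUE
            break
          }
        }
      }
      if (qualifies) {
        cand <- c(cand, id)
        candLen <- c(candLen, lens[id])
      }
    }
    if (!length(cand)) return(graph)
    pick <- cand[order(candLen, cand)][1]
    graph <- .dropNodes(graph, pick)
  }
}

.applyCovCutoff <- function(graph, covCutoff) {
  g <- .newGraph(graph@k, covCutoff, graph@tipLen,
                 graph@nodeSeq, graph@nodeCov, graph@edges)
  if (covCutoff <= 0 || numNodes(g) == 0L) return(g)
  low <- which(avgNodeCoverage(g) < covCutoff)
  .dropNodes(g, low)
}

# Merge every (a,o1) -> (b,o2) with outdeg(a,o1)==1, indeg(b,o2)==1 and
# a != b (hairpins are never condensed across), to a fixpoint.
.recondense <- function(graph) {
  k <- graph@k
  repeat {
    e <- graph@edges
    merged <- FALSE
    for (r in seq_len(nrow(e))) {
      a <- e$from[r]; ao <- e$fromOrient[r]
      b <- e$to[r]; bo <- e$toOrient[r]
      if (a == b) next
      if (.outdeg(graph, a, ao) != 1L) next
      if (.indeg(graph, b, bo) != 1L) next
      graph <- .mergePair(graph, a, ao, b, bo)
      merged <- TRUE
      break
    }
    if (!merged) return(graph)
  }
}

.mergePair <- function(graph, a, ao, b, bo) {
  k <- graph@k
  sa <- .spellNode(graph, a, ao)
  sb <- .spellNode(graph, b, bo)
  newSeq <- paste0(sa, substring(sb, k))
  rcNew <- .rc(newSeq)
  if (newSeq <= rcNew) {
    ns <- newSeq
    f <- "+"  # merged node's "+" spells sa..sb
  } else {
    ns <- rcNew
    f <- "-"
  }
  e <- graph@edges
  drop <- (e$from == a & e$fromOrient == ao & e$to == b & e$toOrient == bo) |
    (e$from == b & e$fromOrient == .flipOrient(bo) &
       e$to == a & e$toOrient == .flipOrient(ao))
  e <- e[!drop, , drop = FALSE]

  mapEnd <- function(id, o) {
    no <- o
    hitA <- id == a
    hitB <- id == b
    no[hitA] <- ifelse(o[hitA] == ao, f, .flipOrient(f))
    no[hitB] <- ifelse(o[hitB] == bo, f, .flipOrient(f))
    id[hitA | hitB] <- 0L  # placeholder for the merged node
    list(id = id, o = no)
  }
  mf <- mapEnd(e$from, e$fromOrient)
  mt <- mapEnd(e$to, e$toOrient)
  e$from <- mf$id; e$fromOrient <- mf$o
  e$to <- mt$id; e$toOrient <- mt$o

  keep <- setdiff(seq_len(numNodes(graph)), c(a, b))
  remap <- integer(numNodes(graph) + 1L)
  remap[keep] <- seq_along(keep)
  newId <- length(keep) + 1L
  e$from <- ifelse(e$from == 0L, newId, remap[e$from])
  e$to <- ifelse(e$to == 0L, newId, remap[e$to])
  e <- unique(e)
  .newGraph(graph@k, graph@covCutoff, graph@tipLen,
            c(graph@nodeSeq[keep], ns),
            c(graph@nodeCov[keep], graph@nodeCov[a] + graph@nodeCov[b]),
            e)
}

# deterministic ids: nodes sorted by stored sequence
.renumberGraph <- function(graph) {
  n <- numNodes(graph)
  if (n == 0L) return(graph)
  ord <- order(graph@nodeSeq)
  remap <- integer(n)
  remap[ord] <- seq_len(n)
  e <- graph@edges
  e$from <- remap[e$from]
  e$to <- remap[e$to]
  .newGraph(graph@k, graph@covCutoff, graph@tipLen,
            graph@nodeSeq[ord], graph@nodeCov[ord], e)
}

# ---- GFA 1.0 ---------------------------------------------------------------

#' Write a graph as GFA 1.0
#'
#' One S line per twin pair (canonical orientation) with a \code{KC:i:} k-mer
#' count tag; one L line per twin edge pair with a \code{<k-1>M} overlap
#' CIGAR; the header carries \code{VN:Z:1.0} and a \code{kk:i:} tag with k.
#'
#' @param graph a [DeBruijnGraph-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGFA <- function(graph, path) {
  k <- graph@k
  out <- sprintf("H\tVN:Z:1.0\tkk:i:%d", k)
  n <- numNodes(graph)
  if (n) {
    out <- c(out, sprintf("S\t%d\t%s\tKC:i:%d",
                          seq_len(n), graph@nodeSeq,
                          as.integer(graph@nodeCov)))
  }
  e <- graph@edges
  if (nrow(e)) {
    keys <- .edgeKeys(e)
    twin <- paste(e$to, .flipOrient(e$toOrient),
                  e$from, .flipOrient(e$fromOrient))
    half <- e[keys <= twin, , drop = FALSE]
    out <- c(out, sprintf("L\t%d\t%s\t%d\t%s\t%dM",
                          half$from, half$fromOrient,
                          half$to, half$toOrient, k - 1L))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a GFA 1.0 graph written by [writeGFA]
#'
#' Segment names must be positive integers; the twin-symmetric closure of
#' the L lines is reconstructed. Round-trips are bit-exact on sequences,
#' counts and edges.
#'
#' @param path GFA file.
#' @return A [DeBruijnGraph-class].
#' @export
readGFA <- function(path) {
  ln <- readLines(path)
  typ <- substr(ln, 1L, 1L)
  hdr <- strsplit(ln[typ == "H"][1], "\t", fixed = TRUE)[[1]]
  ktag <- grep("^kk:i:", hdr, value = TRUE)
  if (!length(ktag)) stop("GFA header lacks the kk:i: k-mer tag")
  k <- as.integer(sub("^kk:i:", "", ktag[1]))

  sl <- strsplit(ln[typ == "S"], "\t", fixed = TRUE)
  ids <- vapply(sl, function(x) x[2], character(1))
  if (anyNA(suppressWarnings(as.integer(ids))))
    stop("segment names must be positive integers")
  ids <- as.integer(ids)
  seqs <- toupper(vapply(sl, function(x) x[3], character(1)))
  covs <- vapply(sl, function(x) {
    tag <- grep("^KC:i:", x, value = TRUE)
    if (length(tag)) as.numeric(sub("^KC:i:", "", tag[1])) else NA_real_
  }, numeric(1))
  ord <- order(ids)
  ids <- ids[ord]; seqs <- seqs[ord]; covs <- covs[ord]
  if (!identical(ids, seq_along(ids)))
    stop("segment names must be 1..N")

  el <- strsplit(ln[typ == "L"], "\t", fixed = TRUE)
  if (length(el)) {
    e <- data.frame(
      from = as.integer(vapply(el, `[`, character(1), 2)),
      fromOrient = vapply(el, `[`, character(1), 3),
      to = as.integer(vapply(el, `[`, character(1), 4)),
      toOrient = vapply(el, `[`, character(1), 5),
      stringsAsFactors = FALSE
    )
    twin <- data.frame(
      from = e$to, fromOrient = .flipOrient(e$toOrient),
      to = e$from, toOrient = .flipOrient(e$fromOrient),
      stringsAsFactors = FALSE
    )
    e <- unique(rbind(e, twin))
  } else {
    e <- .emptyEdges()
  }
  .newGraph(k, 0, 2L * k, seqs, covs, e)
}
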