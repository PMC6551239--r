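#' Condensed de Bruijn graph with twin-node semantics
#'
#' Nodes are maximal non-branching chains of k-mers, each stored once per
#' twin pair in canonical orientation (lexicographic minimum of the spelled
#' sequence and its reverse complement). An oriented node \code{(id, "+")}
#' spells the stored sequence, \code{(id, "-")} its reverse complement.
#' Edges are oriented and closed under twin symmetry: for every edge
#' \code{(a,o1) -> (b,o2)} the edge \code{(b,flip(o2)) -> (a,flip(o1))} is
#' present, and the (k-1)-suffix of the tail's spelled sequence equals the
#' (k-1)-prefix of the head's.
#'
#' @slot k k-mer size (odd integer).
#' @slot covCutoff k-mer coverage cutoff applied during construction.
#' @slot tipLen maximum spelled length of a removable tip.
#' @slot nodeSeq character vector of node sequences; node id i is position i.
#' @slot nodeCov numeric vector, summed k-mer counts per node.
#' @slot edges data.frame with columns from, fromOrient, to, toOrient.
#'
#' @seealso [buildGraph], [spellPath], [outSteps], [writeGFA]
#' @export
setClass("DeBruijnGraph",
  slots = c(
    k = "integer",
    covCutoff = "numeric",
    tipLen = "integer",
    nodeSeq = "character",
    nodeCov = "numeric",
    edges = "data.frame"
  )
)

.flipOrient <- function(o) ifelse(o == "+", "-", "+")

.edgeKeys <- function(edges) {
  paste(edges$from, edges$fromOrient, edges$to, edges$toOrient)
}

setValidity("DeBruijnGraph", function(object) {
  msgs <- character()
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 3L || k %% 2L == 0L)
    msgs <- c(msgs, "k must be a single odd integer >= 3")
  if (length(object@nodeSeq) != length(object@nodeCov))
    msgs <- c(msgs, "nodeSeq and nodeCov lengths differ")
  if (length(object@nodeSeq) && any(nchar(object@nodeSeq) < k))
    msgs <- c(msgs, "node sequences must have length >= k")
  e <- object@edges
  need <- c("from", "fromOrient", "to", "toOrient")
  if (!all(need %in% names(e))) {
    msgs <- c(msgs, "edges must have columns from, fromOrient, to, toOrient")
  } else if (nrow(e)) {
    n <- length(object@nodeSeq)
    if (any(e$from < 1L | e$from > n | e$to < 1L | e$to > n))
      msgs <- c(msgs, "edge endpoints outside node range")
    keys <- .edgeKeys(e)
    twin <- paste(e$to, .flipOrient(e$toOrient), e$from, .flipOrient(e$fromOrient))
    if (!all(twin %in% keys))
      msgs <- c(msgs, "edge set not closed under twin symmetry")
    tails <- object@nodeSeq[e$from]
    fm <- e$fromOrient == "-"
    if (any(fm)) tails[fm] <- cpp_revcomp(tails[fm])
    heads <- object@nodeSeq[e$to]
    tm <- e$toOrient == "-"
    if (any(tm)) heads[tm] <- cpp_revcomp(heads[tm])
    suf <- substr(tails, nchar(tails) - k + 2L, nchar(tails))
    pre <- substr(heads, 1L, k - 1L)
    if (!all(suf == pre))
      msgs <- c(msgs, "edge without (k-1) suffix/prefix overlap")
  }
  if (length(msgs)) msgs else TRUE
})

#' Oriented path through a de Bruijn graph
#'
#' An ordered list of oriented node references. Consecutive steps must be
#' joined by an edge of the graph the path is used with; this is checked by
#' [spellPath], not stored here.
#'
#' @slot ids integer node identifiers.
#' @slot orient character vector of "+"/"-", same length as ids.
#' @export
setClass("GraphPath", slots = c(ids = "integer", orient = "character"))

setValidity("GraphPath", function(object) {
  if (length(object@ids) == 0L) return("path must be non-empty")
  if (length(object@ids) != length(object@orient))
    return("ids and orient lengths differ")
  if (!all(object@orient %in% c("+", "-")))
    return("orient entries must be '+' or '-'")
  TRUE
})

#' Construct a GraphPath
#'
#' @param ids integer node ids.
#' @param orient orientations, "+" or "-" (recycled if length 1).
#' @return A [GraphPath-class] object.
#' @examples
#' graphPath(c(1L, 3L), c("+", "-"))
#' @export
graphPath <- function(ids, orient = "+") {
  ids <- as.integer(ids)
  orient <- rep_len(as.character(orient), length(ids))
  new("GraphPath", ids = ids, orient = orient)
}

#' @describeIn graphPath number of steps in the path.
#' @param x a GraphPath.
#' @export
setMethod("length", "GraphPath", function(x) length(x@ids))

#' Format a path as a signed node list
#'
#' @param path a [GraphPath-class].
#' @return A string such as \code{"3+,7-,12+"}.
#' @export
pathString <- function(path) {
  paste0(path@ids, path@orient, collapse = ",")
}

setMethod("show", "GraphPath", function(object) {
  cat("GraphPath:", pathString(object), "\n")
})

setMethod("show", "DeBruijnGraph", function(object) {
  cat(sprintf(
    "DeBruijnGraph: k=%d, %d node pair(s), %d oriented edge(s), c=%g, tipLen=%d\n",
    object@k, length(object@nodeSeq), nrow(object@edges),
    object@covCutoff, object@tipLen
  ))
})

#' Scoring scheme for the local-alignment engine
#'
#' Bundles the substitution scores, affine gap penalties and Karlin-Altschul
#' parameters (lambda, K) used to convert raw Smith-Waterman scores into bit
#' scores and e-values. Use [ntScheme] (nucleotide/nucleotide) or [txScheme]
#' (six-frame translated vs protein) to construct one.
#'
#' @slot mode "nt" or "tx".
#' @slot alphabet residue alphabet used for integer encoding.
#' @slot submat integer substitution matrix over the alphabet.
#' @slot gapOpen,gapExtend non-negative gap penalties; a gap of length L
#'   costs gapOpen + L * gapExtend.
#' @slot lambda,K Karlin-Altschul parameters.
#' @export
setClass("ScoringScheme",
  slots = c(
    mode = "character",
    alphabet = "character",
    submat = "matrix",
    gapOpen = "numeric",
    gapExtend = "numeric",
    lambda = "numeric",
    K = "numeric"
  )
)

setValidity("ScoringScheme", function(object) {
  msgs <- character()
  if (!object@mode %in% c("nt", "tx")) msgs <- c(msgs, "mode must be 'nt' or 'tx'")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    msgs <- c(msgs, "gap penalties must be non-negative")
  if (object@lambda <= 0) msgs <- c(msgs, "lambda must be positive")
  if (object@K <= 0) msgs <- c(msgs, "K must be positive")
  if (nrow(object@submat) != length(object@alphabet) ||
      ncol(object@submat) != length(object@alphabet))
    msgs <- c(msgs, "submat dimensions must match alphabet")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf(
    "ScoringScheme(%s): gapOpen=%g gapExtend=%g lambda=%.4g K=%.4g\n",
    object@mode, object@gapOpen, object@gapExtend, object@lambda, object@K
  ))
})

#' Transcript database for homology search
#'
#' Holds the related organism's transcripts (nucleotide, for same-organism
#' searches) or proteins (for cross-organism translated searches) with
#' pre-computed integer encodings for the alignment kernel.
#'
#' @slot ids unique record identifiers.
#' @slot seq residue strings.
#' @slot mode "nt" or "tx" (tx means protein subjects).
#' @slot enc list of integer encodings, parallel to seq.
#' @slot totalLen total residue count (the database length n in e-values).
#' @export
setClass("TranscriptDB",
  slots = c(
    ids = "character",
    seq = "character",
    mode = "character",
    enc = "list",
    totalLen = "numeric"
  )
)

setValidity("TranscriptDB", function(object) {
  msgs <- character()
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "duplicate record ids")
  if (any(nchar(object@seq) == 0L)) msgs <- c(msgs, "empty sequence in database")
  if (!object@mode %in% c("nt", "tx")) msgs <- c(msgs, "mode must be 'nt' or 'tx'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TranscriptDB", function(object) {
  cat(sprintf(
    "TranscriptDB(%s): %d record(s), %g residue(s)\n",
    object@mode, length(object@ids), object@totalLen
  ))
})

#' Parameters of the seed-and-extend search
#'
#' @slot ei initial e-value cutoff for seed hits (lenient).
#' @slot ef final e-value cutoff for reported transcripts (stringent, < ei).
#' @slot nSeeds seed nodes retained per database transcript.
#' @slot shortLen a candidate node contributing fewer than this many new
#'   bases counts as "very short" for the lookahead rule; NA means use k.
#' @slot lookahead maximum nodes committed in one multi-node step past a
#'   short node (0 or 1 disables the lookahead).
#' @slot maxSteps safety bound on accepted extension steps per direction.
#' @export
setClass("SearchParams",
  slots = c(
    ei = "numeric",
    ef = "numeric",
    nSeeds = "integer",
    shortLen = "integer",
    lookahead = "integer",
    maxSteps = "integer"
  )
)

setValidity("SearchParams", function(object) {
  msgs <- character()
  if (object@ei <= 0 || object@ef <= 0) msgs <- c(msgs, "cutoffs must be positive")
  if (object@ef >= object@ei) msgs <- c(msgs, "ef must be smaller than ei")
  if (object@nSeeds < 1L) msgs <- c(msgs, "nSeeds must be >= 1")
  if (object@maxSteps < 1L) msgs <- c(msgs, "maxSteps must be >= 1")
  if (object@lookahead < 0L) msgs <- c(msgs, "lookahead must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct search parameters
#'
#' Defaults follow the translated-search regime used throughout the method:
#' a lenient initial cutoff \code{ei} admits short seed nodes that later
#' grow into significant paths, and the stringent final cutoff \code{ef}
#' gates reporting. Eight seed nodes per transcript are kept.
#'
#' @param ei initial e-value cutoff (default 1e-6).
#' @param ef final e-value cutoff (default 1e-20).
#' @param nSeeds seeds per transcript (default 8).
#' @param shortLen short-node threshold in new bases; NA = use the graph's k.
#' @param lookahead depth of the multi-node step past short nodes (default 2).
#' @param maxSteps bound on accepted steps per extension direction.
#' @return A [SearchParams-class] object.
#' @export
searchParams <- function(ei = 1e-6, ef = 1e-20, nSeeds = 8L, shortLen = NA_integer_,
                         lookahead = 2L, maxSteps = 10000L) {
  new("SearchParams",
    ei = ei, ef = ef, nSeeds = as.integer(nSeeds),
    shortLen = as.integer(shortLen), lookahead = as.integer(lookahead),
    maxSteps = as.integer(maxSteps)
  )
}

setMethod("show", "SearchParams", function(object) {
  cat(sprintf(
    "SearchParams: ei=%g ef=%g nSeeds=%d shortLen=%s lookahead=%d maxSteps=%d\n",
    object@ei, object@ef, object@nSeeds,
    ifelse(is.na(object@shortLen), "k", as.character(object@shortLen)),
    object@lookahead, object@maxSteps
  ))
})

#' Per-transcript running best (path, hit) pool
#'
#' Environment-backed so that every alignment invocation performed during a
#' search can update it in place. For each database transcript it stores the
#' minimum-e-value hit seen so far together with the path that produced it.
#'
#' @slot env environment mapping transcript id to list(path, hit).
#' @seealso [newCandidatePool], [poolTranscripts], [poolBest]
#' @export
setClass("CandidatePool", slots = c(env = "environment"))

#' Create an empty candidate pool
#' @return A [CandidatePool-class].
#' @export
newCandidatePool <- function() {
  new("CandidatePool", env = new.env(parent = emptyenv()))
}

#' Transcripts with at least one recorded hit
#' @param pool a [CandidatePool-class].
#' @return Sorted character vector of transcript ids.
#' @export
poolTranscripts <- function(pool) sort(ls(pool@env))

#' Best recorded (path, hit) for one transcript
#' @param pool a [CandidatePool-class].
#' @param transcriptId transcript identifier.
#' @return list(path = GraphPath, hit = one-row data.frame), or NULL.
#' @export
poolBest <- function(pool, transcriptId) {
  if (!exists(transcriptId, envir = pool@env, inherits = FALSE)) return(NULL)
  get(transcriptId, envir = pool@env, inherits = FALSE)
}

setMethod("show", "CandidatePool", function(object) {
  cat(sprintf("CandidatePool: %d transcript(s) with hits\n", length(ls(object@env))))
})
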