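# spelled interval of each path step: node i occupies [o_i, o_i + len_i) with
# o_{i+1} = o_i + len_i - (k-1)
.stepIntervals <- function(graph, path) {
  k <- graphK(graph)
  lens <- nchar(graph@nodeSeq[path@ids])
  starts <- c(0, cumsum(lens - (k - 1)))[seq_along(lens)]
  data.frame(start = starts, end = starts + lens)
}

#' Trim a path to the aligned nodes
#'
#' Only the nodes of a path that take part in the best alignment are
#' reported: steps whose spelled interval is disjoint from the aligned query
#' interval \code{[q_start, q_end)} are dropped from both ends (interior
#' steps are always kept), and the hit's query coordinates are shifted onto
#' the trimmed spelling.
#'
#' @param graph a [DeBruijnGraph-class].
#' @param path a [GraphPath-class] whose spelled sequence carries the hit.
#' @param hit one-row hit data.frame (as from [searchDb]).
#' @return list(path = trimmed [GraphPath-class], hit = hit with shifted
#'   query coordinates).
#' @export
trimToAlignment <- function(graph, path, hit) {
  iv <- .stepIntervals(graph, path)
  qs <- hit$q_start
  qe <- hit$q_end
  keep <- which(iv$start < qe & iv$end > qs)
  if (!length(keep))
    stop("alignment interval does not intersect any path node ",
         "(inconsistent hit)")
  first <- min(keep)
  last <- max(keep)
  newPath <- graphPath(path@ids[first:last], path@orient[first:last])
  off <- iv$start[first]
  hit$q_start <- qs - off
  hit$q_end <- qe - off
  list(path = newPath, hit = hit)
}

.emptyRecords <- function() {
  data.frame(
    transcript_id = character(), node_path = character(),
    path_len_nt = integer(), raw = integer(), bit_score = numeric(),
    log10_evalue = numeric(), evalue = numeric(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), frame = integer(),
    subject_len = integer(), subject_coverage = numeric(),
    seq = character(), stringsAsFactors = FALSE
  )
}

.recordRow <- function(graph, db, tid, path, hit) {
  tr <- trimToAlignment(graph, path, hit)
  seq <- spellPath(graph, tr$path)
  slen <- nchar(db@seq[match(tid, db@ids)])
  data.frame(
    transcript_id = tid,
    node_path = pathString(tr$path),
    path_len_nt = nchar(seq),
    raw = tr$hit$raw,
    bit_score = tr$hit$bit,
    log10_evalue = tr$hit$log10_evalue,
    evalue = tr$hit$evalue,
    q_start = as.integer(tr$hit$q_start),
    q_end = as.integer(tr$hit$q_end),
    s_start = as.integer(tr$hit$s_start),
    s_end = as.integer(tr$hit$s_end),
    frame = as.integer(tr$hit$frame),
    subject_len = slen,
    subject_coverage = (tr$hit$s_end - tr$hit$s_start) / slen,
    seq = seq,
    stringsAsFactors = FALSE
  )
}

#' Extract the final similar transcripts from a candidate pool
#'
#' Transcripts whose best e-value passes the final cutoff \code{ef} are
#' reported with their best path trimmed to the aligned nodes. Different
#' transcripts may report the same or very similar paths; no deduplication
#' is performed. Subject coverage is the aligned subject span divided by the
#' subject length (amino acids for translated searches, matching the coding
#' region).
#'
#' @param pool a [CandidatePool-class] from [runSearch].
#' @param db the [TranscriptDB-class] that was searched.
#' @param ef final e-value cutoff (reported hits have evalue <= ef).
#' @param graph the [DeBruijnGraph-class] the pool's paths refer to.
#' @return data.frame with one row per recovered transcript: transcript_id,
#'   node_path, path_len_nt, raw, bit_score, log10_evalue, evalue, q_start,
#'   q_end, s_start, s_end, frame, subject_len, subject_coverage, seq
#'   (coordinates 0-based half-open; [writeResultsTsv] converts to 1-based
#'   inclusive at the file boundary).
#' @export
finalizeTranscripts <- function(pool, db, ef, graph) {
  efL10 <- log10(ef)
  rows <- list()
  for (tid in poolTranscripts(pool)) {
    b <- poolBest(pool, tid)
    if (b$hit$log10_evalue > efL10) next
    rows[[length(rows) + 1L]] <- .recordRow(graph, db, tid, b$path, b$hit)
  }
  if (!length(rows)) return(.emptyRecords())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count transcripts recovered close to full length
#'
#' @param records data.frame from [finalizeTranscripts] or
#'   [nodesOnlyBaseline].
#' @param threshold minimum subject coverage, in (0, 1]; 0.8 is the usual
#'   "80 percent full length" criterion, 1.0 the strict variant.
#' @return integer count of records with subject_coverage >= threshold.
#' @export
fullLengthCount <- function(records, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  sum(records$subject_coverage >= threshold - 1e-12)
}

#' Nodes-only baseline: best single-node hit per transcript
#'
#' What a contig-level search recovers without any path extension: per
#' database transcript, the best hit among single-node paths passing
#' \code{ef}. Record shape matches [finalizeTranscripts].
#'
#' @param graph a [DeBruijnGraph-class].
#' @param db a [TranscriptDB-class].
#' @param scheme a [ScoringScheme-class].
#' @param ef final e-value cutoff.
#' @return data.frame as in [finalizeTranscripts].
#' @export
nodesOnlyBaseline <- function(graph, db, scheme, ef) {
  pool <- newCandidatePool()
  cache <- new.env(parent = emptyenv())
  ctx <- .newCtx(db, scheme, pool, cache)
  for (id in seq_len(numNodes(graph))) {
    .searchPath(graph, graphPath(id, "+"), ctx)
  }
  finalizeTranscripts(pool, db, ef, graph)
}

#' Write recovered transcripts as TSV
#'
#' Coordinates are converted to 1-based inclusive (BLAST convention) at this
#' boundary; internal records stay 0-based half-open.
#'
#' @param records data.frame from [finalizeTranscripts].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeResultsTsv <- function(records, path) {
  out <- records[, c("transcript_id", "node_path", "path_len_nt",
                     "bit_score", "evalue", "q_start", "q_end",
                     "s_start", "s_end", "frame", "subject_coverage")]
  out$q_start <- out$q_start + 1L
  out$s_start <- out$s_start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write recovered transcripts as FASTA
#'
#' Headers are \code{<transcript_id>|<signed node list>|e=<evalue>} for
#' traceability from each sequence back to the graph.
#'
#' @param records data.frame from [finalizeTranscripts].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRecoveredFasta <- function(records, path) {
  ids <- sprintf("%s|%s|e=%.3g", records$transcript_id, records$node_path,
                 records$evalue)
  writeFasta(stats::setNames(records$seq, ids), path)
  invisible(path)
}
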