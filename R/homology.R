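.NT_ALPHABET <- c("A", "C", "G", "T", "N")

.LOG2 <- log(2)
.LOG10_2 <- log10(2)

# integer-encode a residue string against an alphabet (0-based codes);
# unknown characters map to `unknown` (e.g. "N" or "X")
.encodeSeq <- function(seq, alphabet, unknown) {
  if (nchar(seq) == 0L) return(integer())
  v <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], alphabet)
  v[is.na(v)] <- match(unknown, alphabet)
  as.integer(v - 1L)
}

#' Solve the Karlin-Altschul identity for lambda
#'
#' Finds the unique positive lambda with
#' \eqn{\sum_{i,j} p_i p_j e^{\lambda s_{ij}} = 1}, the scale parameter of
#' local-alignment score statistics for an ungapped scoring system. Requires
#' a negative expected pair score and at least one positive score.
#'
#' @param submat substitution matrix (scores).
#' @param freqs background residue frequencies, recycled over rows and
#'   columns of \code{submat}; default uniform.
#' @return lambda, to relative tolerance 1e-9.
#' @examples
#' m <- matrix(-1, 4, 4); diag(m) <- 1
#' solveLambda(m)  # log(3)
#' @export
solveLambda <- function(submat, freqs = NULL) {
  n <- nrow(submat)
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  freqs <- freqs / sum(freqs)
  p <- outer(freqs, freqs)
  es <- sum(p * submat)
  if (es >= 0)
    stop("expected pair score must be negative (got ", signif(es, 4), ")")
  if (max(submat) <= 0)
    stop("scoring system has no positive score")
  f <- function(lam) sum(p * exp(lam * submat)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
}

#' Nucleotide scoring scheme
#'
#' blastn-like defaults: match +2, mismatch -3, gap open 5, gap extend 2.
#' N scores as a mismatch against everything. lambda is solved from the
#' ungapped Karlin-Altschul identity over a uniform ACGT background and
#' reused for gapped scores (a documented approximation); K defaults to the
#' published blastn value for this score pair.
#'
#' @param match,mismatch substitution scores.
#' @param gapOpen,gapExtend affine gap penalties (gap of length L costs
#'   gapOpen + L * gapExtend).
#' @param K Karlin-Altschul K.
#' @param lambda override the solved lambda (rarely needed).
#' @return A [ScoringScheme-class] in "nt" mode.
#' @export
ntScheme <- function(match = 2L, mismatch = -3L, gapOpen = 5L, gapExtend = 2L,
                     K = 0.41, lambda = NULL) {
  a <- .NT_ALPHABET
  m <- matrix(as.integer(mismatch), length(a), length(a),
              dimnames = list(a, a))
  diag(m) <- as.integer(match)
  m["N", ] <- as.integer(mismatch)
  m[, "N"] <- as.integer(mismatch)
  if (is.null(lambda)) {
    core <- m[1:4, 1:4]
    lambda <- solveLambda(core)
  }
  new("ScoringScheme",
    mode = "nt", alphabet = a, submat = m,
    gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend),
    lambda = lambda, K = K
  )
}

#' Translated-search scoring scheme
#'
#' BLOSUM62 with gap open 11 / extend 1 and the published gapped
#' Karlin-Altschul constants lambda = 0.267, K = 0.041 (blastx-like).
#' Queries are translated in all six frames; stop codons are rendered as
#' \code{*} and scored by the matrix's stop column.
#'
#' @param gapOpen,gapExtend affine gap penalties.
#' @param lambda,K Karlin-Altschul parameters.
#' @return A [ScoringScheme-class] in "tx" mode.
#' @export
txScheme <- function(gapOpen = 11L, gapExtend = 1L, lambda = 0.267, K = 0.041) {
  m <- .blosum62()
  storage.mode(m) <- "integer"
  new("ScoringScheme",
    mode = "tx", alphabet = colnames(m), submat = m,
    gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend),
    lambda = lambda, K = K
  )
}

#' Bit score of a raw alignment score
#'
#' \eqn{bit = (\lambda \cdot raw - \ln K) / \ln 2}.
#'
#' @param raw raw Smith-Waterman score.
#' @param scheme a [ScoringScheme-class].
#' @return bit score.
#' @export
bitScore <- function(raw, scheme) {
  (scheme@lambda * raw - log(scheme@K)) / .LOG2
}

#' E-value of a bit score
#'
#' \eqn{E = m n 2^{-bit}} with raw (uncorrected) search-space lengths; in
#' translated mode the effective query length m is the nucleotide length
#' divided by 3 (floored). Computed in log space internally so that very
#' strong hits do not underflow comparisons; the returned e-value may round
#' to 0 for extreme scores.
#'
#' @param bit bit score.
#' @param m query length (residues of the query as searched).
#' @param n database length (total residues).
#' @return e-value.
#' @seealso [log10Evalue]
#' @export
evalueFromBit <- function(bit, m, n) {
  10^log10Evalue(bit, m, n)
}

#' @rdname evalueFromBit
#' @return \code{log10Evalue}: base-10 logarithm of the e-value (the scale
#'   on which all internal comparisons are made).
#' @export
log10Evalue <- function(bit, m, n) {
  log10(m) + log10(n) - bit * .LOG10_2
}

.emptyAlignment <- function() {
  list(raw = 0L, q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L, frame = 0L)
}

#' Best local nucleotide alignment over both query strands
#'
#' Optimal Smith-Waterman score with affine gaps over \{query,
#' reverse-complement(query)\} x subject. Query coordinates are reported on
#' the forward strand (0-based, half-open). A tie between strands prefers
#' the forward strand.
#'
#' @param query,subject nucleotide strings.
#' @param scheme an "nt" [ScoringScheme-class].
#' @return list(raw, q_start, q_end, s_start, s_end, frame = 0).
#' @export
alignLocalNt <- function(query, subject, scheme) {
  stopifnot(scheme@mode == "nt")
  if (nchar(query) == 0L || nchar(subject) == 0L) return(.emptyAlignment())
  qe <- .encodeSeq(query, scheme@alphabet, "N")
  se <- .encodeSeq(subject, scheme@alphabet, "N")
  re <- .encodeSeq(revComp(query), scheme@alphabet, "N")
  .bestNtAlignment(qe, re, se, nchar(query), scheme)
}

# choose the better strand by a score-only pass, then locate that strand's
# alignment; query coordinates on the forward strand
.bestNtAlignment <- function(qe, re, se, L, scheme) {
  sm <- scheme@submat
  go <- scheme@gapOpen
  ge <- scheme@gapExtend
  sf <- cpp_sw_score(qe, se, sm, go, ge)[1]
  sr <- cpp_sw_score(re, se, sm, go, ge)[1]
  if (sr > sf) {
    rev <- cpp_sw(re, se, sm, go, ge)
    list(raw = rev[1],
         q_start = L - rev[3], q_end = L - rev[2],
         s_start = rev[4], s_end = rev[5], frame = 0L)
  } else if (sf > 0L) {
    fwd <- cpp_sw(qe, se, sm, go, ge)
    list(raw = fwd[1],
         q_start = fwd[2], q_end = fwd[3],
         s_start = fwd[4], s_end = fwd[5], frame = 0L)
  } else {
    .emptyAlignment()
  }
}

# six-frame translations of a nucleotide query, with the information needed
# to map amino-acid query coordinates back to forward-strand nucleotides
.sixFrames <- function(query) {
  L <- nchar(query)
  frames <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) query else revComp(query)
    for (off in 0:2) {
      len3 <- ((L - off) %/% 3L) * 3L
      if (len3 < 3L) next
      dna <- Biostrings::DNAString(substr(s, off + 1L, off + len3))
      aa <- as.character(Biostrings::translate(dna, if.fuzzy.codon = "X"))
      frames[[length(frames) + 1L]] <- list(
        aa = aa, off = off, strand = strand,
        frame = strand * (off + 1L)
      )
    }
  }
  frames
}

# map an amino-acid interval of one frame back to forward-strand nucleotides
.frameToNt <- function(fr, aaStart, aaEnd, L) {
  a <- fr$off + 3L * aaStart
  b <- fr$off + 3L * aaEnd
  if (fr$strand == 1L) c(a, b) else c(L - b, L - a)
}

#' Best translated alignment over six reading frames
#'
#' The nucleotide query is translated in all six frames (standard genetic
#' code, stops as \code{*}) and aligned locally against a protein subject;
#' the best frame's alignment is returned with query coordinates converted
#' back to forward-strand nucleotide positions. Frame ties prefer
#' +1, +2, +3, -1, -2, -3.
#'
#' @param query nucleotide string.
#' @param subject amino-acid string.
#' @param scheme a "tx" [ScoringScheme-class].
#' @return list(raw, q_start, q_end in nucleotides, s_start, s_end in amino
#'   acids, frame in \{+1,+2,+3,-1,-2,-3\}).
#' @export
alignTranslated <- function(query, subject, scheme) {
  stopifnot(scheme@mode == "tx")
  if (nchar(query) < 3L || nchar(subject) == 0L) return(.emptyAlignment())
  frames <- .sixFrames(query)
  se <- .encodeSeq(subject, scheme@alphabet, "X")
  L <- nchar(query)
  best <- NULL
  for (fr in frames) {
    qe <- .encodeSeq(fr$aa, scheme@alphabet, "X")
    r <- cpp_sw(qe, se, scheme@submat, scheme@gapOpen, scheme@gapExtend)
    if (r[1] > 0L && (is.null(best) || r[1] > best$r[1])) {
      best <- list(r = r, fr = fr)
    }
  }
  if (is.null(best)) return(.emptyAlignment())
  nt <- .frameToNt(best$fr, best$r[2], best$r[3], L)
  list(raw = best$r[1],
       q_start = nt[1], q_end = nt[2],
       s_start = best$r[4], s_end = best$r[5],
       frame = best$fr$frame)
}

#' Build a transcript database
#'
#' @param seqs named character vector or XStringSet: nucleotide transcripts
#'   ("nt" mode, same-organism searches) or protein sequences ("tx" mode,
#'   cross-organism translated searches).
#' @param mode "nt" or "tx".
#' @return A [TranscriptDB-class] with pre-encoded sequences.
#' @export
transcriptDb <- function(seqs, mode = c("nt", "tx")) {
  mode <- match.arg(mode)
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("database sequences must be named")
  seqs <- toupper(seqs)
  if (mode == "nt") {
    alphabet <- .NT_ALPHABET
    unknown <- "N"
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stop("non-nucleotide character in nt database record ",
           names(seqs)[which(bad)[1]])
  } else {
    alphabet <- colnames(.blosum62())
    unknown <- "X"
  }
  enc <- lapply(seqs, .encodeSeq, alphabet = alphabet, unknown = unknown)
  new("TranscriptDB",
    ids = names(seqs), seq = unname(seqs), mode = mode,
    enc = unname(enc), totalLen = sum(nchar(seqs))
  )
}

#' Database lengths
#' @param db a [TranscriptDB-class].
#' @return named integer vector of record lengths (residues).
#' @export
dbLengths <- function(db) stats::setNames(nchar(db@seq), db@ids)

#' @rdname dbLengths
#' @return \code{dbSeqs}: named character vector of the records.
#' @export
dbSeqs <- function(db) stats::setNames(db@seq, db@ids)

.emptyHits <- function() {
  data.frame(
    subject = character(), raw = integer(), bit = numeric(),
    log10_evalue = numeric(), evalue = numeric(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), frame = integer(),
    stringsAsFactors = FALSE
  )
}

#' Search a query sequence against a transcript database
#'
#' Per-subject best local alignment (nucleotide or six-frame translated,
#' depending on the database mode), with bit scores and e-values computed
#' from the scheme's Karlin-Altschul parameters. Hits are returned in
#' deterministic order: ascending e-value, then descending bit score, then
#' subject id.
#'
#' @param query nucleotide string.
#' @param db a [TranscriptDB-class].
#' @param scheme a [ScoringScheme-class] matching the database mode.
#' @param eCut report only hits with e-value <= eCut (default Inf).
#' @return data.frame with columns subject, raw, bit, log10_evalue, evalue,
#'   q_start, q_end, s_start, s_end, frame (coordinates 0-based half-open;
#'   query coordinates on the forward strand, subject coordinates in the
#'   subject's residues).
#' @export
searchDb <- function(query, db, scheme, eCut = Inf) {
  if (scheme@mode != db@mode)
    stop("scheme mode (", scheme@mode, ") != database mode (", db@mode, ")")
  L <- nchar(query)
  if (L == 0L || length(db@ids) == 0L) return(.emptyHits())
  m <- if (scheme@mode == "nt") L else max(1L, L %/% 3L)
  n <- db@totalLen
  go <- scheme@gapOpen
  ge <- scheme@gapExtend
  sm <- scheme@submat

  rows <- vector("list", length(db@ids))
  if (scheme@mode == "nt") {
    qe <- .encodeSeq(query, scheme@alphabet, "N")
    re <- .encodeSeq(revComp(query), scheme@alphabet, "N")
    for (i in seq_along(db@ids)) {
      se <- db@enc[[i]]
      if (!length(se)) next
      al <- .bestNtAlignment(qe, re, se, L, scheme)
      if (al$raw > 0L) rows[[i]] <- al
    }
  } else {
    if (L < 3L) return(.emptyHits())
    frames <- .sixFrames(query)
    fenc <- lapply(frames, function(fr) .encodeSeq(fr$aa, scheme@alphabet, "X"))
    for (i in seq_along(db@ids)) {
      se <- db@enc[[i]]
      if (!length(se)) next
      # score-only pass per frame, then locate the winning frame's alignment
      bj <- 0L
      bs <- 0L
      for (j in seq_along(frames)) {
        sco <- cpp_sw_score(fenc[[j]], se, sm, go, ge)[1]
        if (sco > bs) { bs <- sco; bj <- j }
      }
      if (bj == 0L) next
      r <- cpp_sw(fenc[[bj]], se, sm, go, ge)
      fr <- frames[[bj]]
      nt <- .frameToNt(fr, r[2], r[3], L)
      rows[[i]] <- list(raw = r[1], q_start = nt[1], q_end = nt[2],
                        s_start = r[4], s_end = r[5], frame = fr$frame)
    }
  }

  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) return(.emptyHits())
  idx <- which(keep)
  raw <- vapply(rows[idx], `[[`, numeric(1), "raw")
  bit <- bitScore(raw, scheme)
  l10 <- log10Evalue(bit, m, n)
  hits <- data.frame(
    subject = db@ids[idx],
    raw = as.integer(raw),
    bit = bit,
    log10_evalue = l10,
    evalue = 10^l10,
    q_start = vapply(rows[idx], `[[`, numeric(1), "q_start"),
    q_end = vapply(rows[idx], `[[`, numeric(1), "q_end"),
    s_start = vapply(rows[idx], `[[`, numeric(1), "s_start"),
    s_end = vapply(rows[idx], `[[`, numeric(1), "s_end"),
    frame = vapply(rows[idx], `[[`, numeric(1), "frame"),
    stringsAsFactors = FALSE
  )
  if (is.finite(eCut)) hits <- hits[hits$log10_evalue <= log10(eCut), , drop = FALSE]
  hits <- hits[order(hits$log10_evalue, -hits$bit, hits$subject), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Import external aligner hits (tabular outfmt-6-like)
#'
#' Columns: qseqid sseqid bitscore evalue qstart qend sstart send frame,
#' with 1-based inclusive coordinates, converted on ingest to the package's
#' 0-based half-open convention. This allows a tabular-output wrapper around
#' an external aligner to stand in for the internal engine.
#'
#' @param path TSV file.
#' @return data.frame with one row per hit (columns as in [searchDb], plus
#'   \code{query}).
#' @export
readTabularHits <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 9L)
    stop("expected 9 columns: qseqid sseqid bitscore evalue qstart qend sstart send frame")
  names(x)[1:9] <- c("query", "subject", "bit", "evalue",
                     "q_start", "q_end", "s_start", "s_end", "frame")
  data.frame(
    query = x$query, subject = x$subject,
    raw = NA_integer_, bit = x$bit,
    log10_evalue = log10(x$evalue), evalue = x$evalue,
    q_start = x$q_start - 1L, q_end = x$q_end,
    s_start = x$s_start - 1L, s_end = x$s_end,
    frame = x$frame, stringsAsFactors = FALSE
  )
}
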