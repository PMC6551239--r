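.STOP_CODONS <- c("TAA", "TAG", "TGA")

.senseCodons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(sort(all), .STOP_CODONS)
}

#' Configuration of the synthetic-data generator
#'
#' The generator emulates the input regime the method targets: multi-exon
#' gene models with exon-skipping isoforms, a diverged ortholog database,
#' and short single-end reads (71 bp by default) with per-base qualities.
#' Transcripts are clean ORFs (ATG start, sense codons, one terminal stop;
#' exon lengths are multiples of 3) so that protein-mode orthologs are
#' well defined.
#'
#' @param seed integer RNG seed driving all three generators.
#' @param nGenes number of genes.
#' @param exonsPerGene inclusive range of exon counts per gene.
#' @param exonLen inclusive range of exon lengths (nt; rounded to codons).
#' @param isoformCount inclusive range of isoforms per gene; isoform 1 keeps
#'   all exons, further isoforms each skip one distinct internal exon.
#' @param transcriptLen inclusive target range for isoform-1 length (nt).
#' @param readLen read length (default 71).
#' @param covMeanLog,covSdLog log-normal per-transcript coverage parameters
#'   (meanlog/sdlog); sdlog 0 gives fixed coverage exp(meanlog).
#' @param baseErrorRate per-base substitution error rate of the reads.
#' @param lowQualTailFrac fraction of reads given a low-quality (Q2) tail of
#'   1-10 bases (bases unchanged), to exercise quality trimming.
#' @param orthologIdentity target residue identity of the ortholog database.
#' @param orthologMode "protein" (translated ortholog, for tx searches) or
#'   "nt".
#' @return list of class "SimConfig".
#' @export
simConfig <- function(seed = 1L, nGenes = 20L,
                      exonsPerGene = c(4L, 7L), exonLen = c(120L, 399L),
                      isoformCount = c(1L, 2L), transcriptLen = c(500L, 2000L),
                      readLen = 71L, covMeanLog = log(30), covSdLog = 0.4,
                      baseErrorRate = 0.001, lowQualTailFrac = 0.05,
                      orthologIdentity = 0.85,
                      orthologMode = c("protein", "nt")) {
  orthologMode <- match.arg(orthologMode)
  stopifnot(
    nGenes >= 1L, readLen >= 1L,
    length(exonsPerGene) == 2L, exonsPerGene[1] <= exonsPerGene[2],
    length(exonLen) == 2L, exonLen[1] <= exonLen[2], exonLen[1] >= 9L,
    length(isoformCount) == 2L, isoformCount[1] <= isoformCount[2],
    isoformCount[1] >= 1L,
    length(transcriptLen) == 2L, transcriptLen[1] <= transcriptLen[2],
    baseErrorRate >= 0, baseErrorRate < 1,
    lowQualTailFrac >= 0, lowQualTailFrac <= 1,
    orthologIdentity > 0, orthologIdentity <= 1
  )
  structure(
    list(
      seed = as.integer(seed), nGenes = as.integer(nGenes),
      exonsPerGene = as.integer(exonsPerGene), exonLen = as.integer(exonLen),
      isoformCount = as.integer(isoformCount),
      transcriptLen = as.integer(transcriptLen),
      readLen = as.integer(readLen),
      covMeanLog = covMeanLog, covSdLog = covSdLog,
      baseErrorRate = baseErrorRate, lowQualTailFrac = lowQualTailFrac,
      orthologIdentity = orthologIdentity, orthologMode = orthologMode
    ),
    class = "SimConfig"
  )
}

.sampleRange <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

#' Simulate a planted transcriptome
#'
#' Genes are built as ordered exon lists; isoform 1 concatenates all exons,
#' each further isoform skips one distinct internal exon (the structure that
#' creates bubbles in the de Bruijn graph). Deterministic under the
#' config seed.
#'
#' @param config a [simConfig] object.
#' @return list with \code{transcripts} (named character; ids
#'   \code{g<g>.i<j>}), \code{geneModels} (data.frame: gene, isoform, exon,
#'   start, end; transcript coordinates, 0-based half-open) and
#'   \code{exonSeqs} (per-gene list of exon sequences).
#' @export
simulateTranscriptome <- function(config) {
  set.seed(config$seed)
  sense <- .senseCodons()
  transcripts <- character()
  exonSeqs <- list()
  gm <- list()
  for (g in seq_len(config$nGenes)) {
    niso <- .sampleRange(config$isoformCount)
    nEx <- .sampleRange(config$exonsPerGene)
    if (niso > 1L) nEx <- max(nEx, 3L, niso + 1L)
    minE <- 3L * ((config$exonLen[1] + 2L) %/% 3L)
    maxE <- 3L * (config$exonLen[2] %/% 3L)
    exLens <- NULL
    for (try in 1:500) {
      cand <- 3L * sample((minE %/% 3L):(maxE %/% 3L), nEx, replace = TRUE)
      tot <- sum(cand)
      if (tot >= config$transcriptLen[1] && tot <= config$transcriptLen[2]) {
        exLens <- cand
        break
      }
    }
    if (is.null(exLens)) exLens <- cand  # accept the last draw

    exs <- character(nEx)
    for (i in seq_len(nEx)) {
      codons <- sample(sense, exLens[i] %/% 3L, replace = TRUE)
      if (i == 1L) codons[1] <- "ATG"
      if (i == nEx) codons[length(codons)] <- "TAA"
      exs[i] <- paste0(codons, collapse = "")
    }
    exonSeqs[[sprintf("g%03d", g)]] <- exs

    skip <- if (niso > 1L) sample(2:(nEx - 1L), niso - 1L) else integer()
    for (j in seq_len(niso)) {
      keep <- if (j == 1L) seq_len(nEx) else setdiff(seq_len(nEx), skip[j - 1L])
      tid <- sprintf("g%03d.i%d", g, j)
      transcripts[tid] <- paste0(exs[keep], collapse = "")
      ends <- cumsum(exLens[keep])
      gm[[length(gm) + 1L]] <- data.frame(
        gene = sprintf("g%03d", g), isoform = j, exon = keep,
        start = ends - exLens[keep], end = ends,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    transcripts = transcripts,
    geneModels = do.call(rbind, gm),
    exonSeqs = exonSeqs
  )
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Derive a diverged ortholog of a transcript
#'
#' Stands in for the related organism's database entry. In "nt" mode, point
#' substitutions are applied at rate 1 - identity. In "protein" mode the
#' transcript's ORF is translated (terminal stop dropped) and amino acids
#' are substituted at rate 1 - identity. Deterministic under \code{seed}.
#'
#' @param transcript nucleotide string (a clean ORF for protein mode).
#' @param identity target fraction of identical residues, in (0, 1].
#' @param mode "protein" or "nt".
#' @param seed optional RNG seed.
#' @return the ortholog sequence (amino acids in protein mode).
#' @export
mutateOrtholog <- function(transcript, identity = 0.85,
                           mode = c("protein", "nt"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(identity > 0, identity <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "nt") {
    v <- strsplit(transcript, "", fixed = TRUE)[[1]]
    flip <- which(runif(length(v)) < 1 - identity)
    for (i in flip) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    paste0(v, collapse = "")
  } else {
    if (nchar(transcript) %% 3L != 0L)
      stop("protein mode requires an ORF (length a multiple of 3)")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(transcript),
                                             if.fuzzy.codon = "X"))
    aa <- sub("\\*$", "", aa)
    v <- strsplit(aa, "", fixed = TRUE)[[1]]
    flip <- which(runif(length(v)) < 1 - identity)
    for (i in flip) v[i] <- sample(setdiff(.AA20, v[i]), 1L)
    paste0(v, collapse = "")
  }
}

#' Simulate short reads from transcripts
#'
#' Per transcript, a log-normal coverage is drawn and
#' \code{round(cov * len / readLen)} reads are emitted: one deterministic
#' tiling pass first (stride readLen/3, mimicking even fragmentation and
#' guaranteeing every k-mer is observed once coverage permits), the rest at
#' uniform random starts. Each read takes a random strand; substitution
#' errors at \code{baseErrorRate}; qualities Q38, with an optional fraction
#' of reads carrying a Q2 tail.
#'
#' @param transcripts named character vector.
#' @param config a [simConfig] object (readLen must not exceed the shortest
#'   transcript).
#' @return data.frame with columns id, seq, qual (Phred+33). Ids record the
#'   provenance as \code{r<serial>/<transcript>/<0-based start><strand>}.
#' @export
simulateReads <- function(transcripts, config) {
  stopifnot(config$readLen <= min(nchar(transcripts)))
  set.seed(config$seed + 1L)
  rl <- config$readLen
  out <- vector("list", length(transcripts))
  counter <- 0L
  for (t in seq_along(transcripts)) {
    tseq <- transcripts[[t]]
    tid <- names(transcripts)[t]
    L <- nchar(tseq)
    cov <- if (config$covSdLog > 0)
      rlnorm(1, config$covMeanLog, config$covSdLog) else exp(config$covMeanLog)
    n <- max(1L, round(cov * L / rl))
    stride <- max(1L, rl %/% 3L)
    tile <- unique(c(seq(0L, L - rl, by = stride), L - rl))
    pos <- if (n >= length(tile)) {
      c(tile, sample(0:(L - rl), n - length(tile), replace = TRUE))
    } else {
      tile[seq_len(n)]
    }
    seqs <- substring(tseq, pos + 1L, pos + rl)
    minus <- runif(n) < 0.5
    if (any(minus)) seqs[minus] <- revComp(seqs[minus])
    if (config$baseErrorRate > 0) {
      nerr <- stats::rbinom(n, rl, config$baseErrorRate)
      for (i in which(nerr > 0L)) {
        v <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        at <- sample.int(rl, nerr[i])
        for (p in at) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
        seqs[i] <- paste0(v, collapse = "")
      }
    }
    qual <- rep(strrep(rawToChar(as.raw(38L + 33L)), rl), n)
    if (config$lowQualTailFrac > 0) {
      tails <- which(runif(n) < config$lowQualTailFrac)
      for (i in tails) {
        tl <- sample.int(10L, 1L)
        qual[i] <- paste0(substr(qual[i], 1L, rl - tl),
                          strrep(rawToChar(as.raw(2L + 33L)), tl))
      }
    }
    # read ids carry the provenance: r<serial>/<transcript>/<0-based start><strand>
    out[[t]] <- data.frame(
      id = sprintf("r%07d/%s/%d%s", counter + seq_len(n), tid, pos,
                   ifelse(minus, "-", "+")),
      seq = seqs, qual = qual, stringsAsFactors = FALSE
    )
    counter <- counter + n
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a full dataset (transcriptome, ortholog database, reads)
#'
#' Runs [simulateTranscriptome], [simulateReads] and [mutateOrtholog] (one
#' ortholog per transcript, ids \code{ort_<transcript>}) under the config
#' seed, optionally writing \code{transcripts.fasta},
#' \code{ortholog_db.fasta}, \code{reads.fastq}, \code{gene_models.tsv} and
#' \code{truth.tsv} to a directory.
#'
#' @param config a [simConfig] object.
#' @param dir optional output directory (created if missing).
#' @return list(transcripts, geneModels, exonSeqs, reads, orthologDb, truth,
#'   config).
#' @export
simulateDataset <- function(config, dir = NULL) {
  tx <- simulateTranscriptome(config)
  reads <- simulateReads(tx$transcripts, config)
  orth <- character(length(tx$transcripts))
  names(orth) <- paste0("ort_", names(tx$transcripts))
  for (i in seq_along(tx$transcripts)) {
    orth[i] <- mutateOrtholog(tx$transcripts[[i]], config$orthologIdentity,
                              config$orthologMode,
                              seed = config$seed + 7919L + i)
  }
  truth <- data.frame(
    transcript = names(tx$transcripts),
    ortholog = names(orth),
    stringsAsFactors = FALSE
  )
  res <- list(
    transcripts = tx$transcripts, geneModels = tx$geneModels,
    exonSeqs = tx$exonSeqs, reads = reads, orthologDb = orth,
    truth = truth, config = config
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeFasta(tx$transcripts, file.path(dir, "transcripts.fasta"))
    writeFasta(orth, file.path(dir, "ortholog_db.fasta"))
    writeFastq(reads, file.path(dir, "reads.fastq"))
    utils::write.table(tx$geneModels, file.path(dir, "gene_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
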