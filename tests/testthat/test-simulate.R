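test_that("the transcriptome generator is deterministic and exon-structured", {
  cfg <- simConfig(seed = 5, nGenes = 4, isoformCount = c(2, 2))
  a <- simulateTranscriptome(cfg)
  b <- simulateTranscriptome(cfg)
  expect_identical(a, b)

  # isoform 1 is the concatenation of all exons
  for (gn in names(a$exonSeqs)) {
    i1 <- a$transcripts[paste0(gn, ".i1")]
    expect_equal(unname(i1), paste0(a$exonSeqs[[gn]], collapse = ""))
  }
  # a skipping isoform differs from isoform 1 by exactly one internal exon
  gm <- a$geneModels
  for (gn in names(a$exonSeqs)) {
    kept <- gm$exon[gm$gene == gn & gm$isoform == 2]
    all1 <- gm$exon[gm$gene == gn & gm$isoform == 1]
    skipped <- setdiff(all1, kept)
    expect_length(skipped, 1L)
    expect_true(skipped > 1 && skipped < max(all1))  # internal
    expect_equal(unname(a$transcripts[paste0(gn, ".i2")]),
                 paste0(a$exonSeqs[[gn]][kept], collapse = ""))
  }
  # gene-model intervals tile each isoform
  for (i in seq_len(nrow(gm))) {
    tid <- paste0(gm$gene[i], ".i", gm$isoform[i])
    ex <- unname(substr(a$transcripts[tid], gm$start[i] + 1L, gm$end[i]))
    expect_equal(ex, a$exonSeqs[[gm$gene[i]]][gm$exon[i]])
  }
})

test_that("transcripts are clean ORFs", {
  cfg <- simConfig(seed = 8, nGenes = 5, isoformCount = c(1, 2))
  tx <- simulateTranscriptome(cfg)$transcripts
  for (t in tx) {
    expect_equal(nchar(t) %% 3L, 0L)
    expect_equal(substr(t, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(t)))
    expect_equal(substring(aa, nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))  # no internal stop
  }
})

test_that("ortholog mutation hits its divergence target", {
  set.seed(1)
  tx <- paste0("ATG", paste0(sample(setdiff(
    as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                    c("A","C","G","T"), paste0)),
    c("TAA","TAG","TGA")), 999, TRUE), collapse = ""), "TAA")
  # identity 1: unchanged (nt), exact translation (protein)
  expect_equal(mutateOrtholog(tx, 1, "nt", seed = 2), tx)
  aa <- mutateOrtholog(tx, 1, "protein", seed = 2)
  expect_equal(nchar(aa), nchar(tx) / 3L - 1L)
  # same seed, same mutant
  expect_identical(mutateOrtholog(tx, 0.9, "nt", seed = 3),
                   mutateOrtholog(tx, 0.9, "nt", seed = 3))
  # nt divergence within 3 sigma of Binomial(L, 0.1)
  mut <- mutateOrtholog(tx, 0.9, "nt", seed = 4)
  L <- nchar(tx)
  d <- sum(strsplit(tx, "")[[1]] != strsplit(mut, "")[[1]])
  expect_lt(abs(d - 0.1 * L), 3 * sqrt(L * 0.1 * 0.9))
  # protein divergence likewise
  p0 <- mutateOrtholog(tx, 1, "protein", seed = 5)
  p1 <- mutateOrtholog(tx, 0.85, "protein", seed = 5)
  dp <- sum(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  n <- nchar(p0)
  expect_lt(abs(dp - 0.15 * n), 3 * sqrt(n * 0.15 * 0.85))
})

test_that("read counts, content and error rate follow the configuration", {
  cfg <- simConfig(seed = 11, nGenes = 1, isoformCount = c(1, 1),
                   covSdLog = 0, covMeanLog = log(20),
                   baseErrorRate = 0, lowQualTailFrac = 0)
  tx <- simulateTranscriptome(cfg)$transcripts
  reads <- simulateReads(tx, cfg)
  L <- nchar(tx[[1]])
  expect_equal(nrow(reads), round(20 * L / 71))
  expect_true(all(nchar(reads$seq) == 71L))
  # error-free reads are exact substrings of the transcript or its twin
  hay <- c(tx[[1]], revComp(tx[[1]]))
  expect_true(all(vapply(reads$seq, function(s)
    any(grepl(s, hay, fixed = TRUE)), logical(1))))
  # same seed reproduces the reads
  expect_identical(simulateReads(tx, cfg), reads)

  # observed mismatch rate (against the true source interval, recovered from
  # the provenance in the read id) within 3 sigma of the target
  cfg2 <- simConfig(seed = 11, nGenes = 1, isoformCount = c(1, 1),
                    covSdLog = 0, covMeanLog = log(20),
                    baseErrorRate = 0.02, lowQualTailFrac = 0)
  reads2 <- simulateReads(tx, cfg2)
  m <- regmatches(reads2$id,
                  regexec("^r[0-9]+/(.+)/([0-9]+)([+-])$", reads2$id))
  nb <- sum(vapply(seq_len(nrow(reads2)), function(i) {
    pos <- as.integer(m[[i]][3])
    ref <- substr(tx[[m[[i]][2]]], pos + 1L, pos + 71L)
    if (m[[i]][4] == "-") ref <- revComp(ref)
    sum(strsplit(reads2$seq[i], "")[[1]] != strsplit(ref, "")[[1]])
  }, numeric(1)))
  tot <- 71 * nrow(reads2)
  expect_lt(abs(nb / tot - 0.02), 3 * sqrt(0.02 * 0.98 / tot))
})

test_that("low-quality tails exercise the trimming rule", {
  cfg <- simConfig(seed = 13, nGenes = 1, isoformCount = c(1, 1),
                   covSdLog = 0, baseErrorRate = 0, lowQualTailFrac = 0.5)
  tx <- simulateTranscriptome(cfg)$transcripts
  reads <- simulateReads(tx, cfg)
  tr <- trimReads(reads, 15L)
  shortened <- nchar(tr$seq) < 71L
  expect_gt(mean(shortened), 0.2)
  expect_lt(mean(shortened), 0.8)
  expect_true(all(nchar(tr$seq[shortened]) >= 61L))  # tails are at most 10
})

test_that("error-free coverage >= 15x leaves no k-mer unseen", {
  cfg <- simConfig(seed = 17, nGenes = 2, isoformCount = c(1, 1),
                   covSdLog = 0, covMeanLog = log(15),
                   baseErrorRate = 0, lowQualTailFrac = 0)
  tx <- simulateTranscriptome(cfg)$transcripts
  reads <- simulateReads(tx, cfg)
  have <- names(countKmers(reads$seq, 25))
  want <- names(countKmers(unname(tx), 25))
  expect_true(all(want %in% have))
})

test_that("simulateDataset writes the five text outputs consistently", {
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  cfg <- simConfig(seed = 19, nGenes = 2, isoformCount = c(1, 2))
  sim <- simulateDataset(cfg, dir)
  expect_setequal(list.files(dir),
                  c("transcripts.fasta", "ortholog_db.fasta", "reads.fastq",
                    "gene_models.tsv", "truth.tsv"))
  expect_identical(readFasta(file.path(dir, "transcripts.fasta")),
                   sim$transcripts)
  expect_identical(readFasta(file.path(dir, "ortholog_db.fasta")),
                   sim$orthologDb)
  fq <- readFastq(file.path(dir, "reads.fastq"))
  expect_equal(nrow(fq), nrow(sim$reads))
  expect_equal(sim$truth$ortholog, paste0("ort_", sim$truth$transcript))
  # protein mode: ortholog length matches the transcript's ORF
  expect_equal(nchar(sim$orthologDb[["ort_g001.i1"]]),
               nchar(sim$transcripts[["g001.i1"]]) / 3L - 1L)
})
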