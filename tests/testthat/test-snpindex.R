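test_that("FASTQ filtering is strict in the low-quality fraction", {
  quals <- list(
    rep(40L, 100),                      # clean read: kept
    c(rep(20L, 10), rep(40L, 90)),      # exactly 10% below Q30: kept
    c(rep(29L, 11), rep(40L, 89))       # 11% below Q30: discarded
  )
  res <- fastq_quality_filter(quals, q_threshold = 30, max_fraction = 0.10)
  expect_identical(res$keep, c(TRUE, TRUE, FALSE))
  expect_identical(res$n_kept, 2L)
  # identical decisions from an actual FASTQ file
  fq <- write_fastq(tempfile(fileext = ".fastq"), quals)
  res_file <- fastq_quality_filter(fq, q_threshold = 30, max_fraction = 0.10)
  expect_identical(res_file$keep, res$keep)
  expect_identical(length(res_file$kept), 2L)
})

test_that("the filter decision is permutation invariant", {
  set.seed(19)
  for (i in 1:50) {
    q <- sample(15:41, 80, replace = TRUE)
    a <- fastq_quality_filter(list(q))$keep
    b <- fastq_quality_filter(list(sample(q)))$keep
    expect_identical(a, b)
  }
})

test_that("suspected Phred+64 input is rejected, not rescaled", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "hhhhhhhh"), fq)
  expect_error(fastq_quality_filter(fq), "Phred\\+64")
})

test_that("malformed FASTQ fails with a clear message", {
  fq <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), fq)  # quality shorter than read
  expect_error(fastq_quality_filter(fq), "malformed FASTQ")
})

test_that("reference substitution writes exactly the tabled positions", {
  ref <- Biostrings::DNAStringSet(c(chrA = "ACGT"))
  tab <- data.frame(chrom = "chrA", pos = 2L, ref_base = "C", alt_base = "T")
  out <- substitute_reference(ref, tab)
  expect_identical(as.character(out[["chrA"]]), "ATGT")
  expect_identical(attr(out, "n_substituted"), 1L)
  # empty table is the identity
  id <- substitute_reference(ref, tab[0, ])
  expect_identical(as.character(id), as.character(ref))
})

test_that("substitution count equals the Hamming distance to the input", {
  set.seed(23)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  ref <- Biostrings::DNAStringSet(c(chr1 = seq1))
  pos <- sort(sample.int(300, 40))
  cur <- strsplit(seq1, "")[[1]][pos]
  alt <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  tab <- data.frame(chrom = "chr1", pos = pos, ref_base = cur, alt_base = alt)
  out <- substitute_reference(ref, tab)
  hamming <- sum(strsplit(as.character(out[[1]]), "")[[1]] !=
                   strsplit(seq1, "")[[1]])
  expect_identical(hamming, attr(out, "n_substituted"))
  expect_identical(hamming, 40L)
  expect_identical(Biostrings::width(out), Biostrings::width(ref))
  # lenient re-application is idempotent: substitutes already in place
  expect_warning(twice <- substitute_reference(out, tab, mode = "lenient"),
                 "skipped")
  expect_identical(as.character(twice), as.character(out))
  expect_identical(attr(twice, "n_substituted"), 0L)
  # strict mode reports the mismatch instead
  expect_error(substitute_reference(out, tab, mode = "strict"),
               "reference-base mismatch")
})

test_that("substitution validates coordinates and bases", {
  ref <- Biostrings::DNAStringSet(c(chrA = "ACGT"))
  expect_error(substitute_reference(
    ref, data.frame(chrom = "chrA", pos = 9L, ref_base = "A", alt_base = "T")),
    "out of range")
  expect_error(substitute_reference(
    ref, data.frame(chrom = "chrB", pos = 1L, ref_base = "A", alt_base = "T")),
    "not found")
  expect_error(substitute_reference(
    ref, data.frame(chrom = "chrA", pos = 1L, ref_base = "A", alt_base = "N")),
    "outside")
})

test_that("FASTA round trip preserves substituted sequences at 60 columns", {
  ref <- Biostrings::DNAStringSet(
    c(chr1 = paste(rep("ACGTACGTAC", 13), collapse = "")))
  fa <- tempfile(fileext = ".fa")
  write_reference_fasta(ref, fa)
  lines <- readLines(fa)
  expect_true(all(nchar(lines[-1]) <= 60))
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back[[1]]), as.character(ref[[1]]))
})

test_that("SNP-index is the alt fraction with depth-0 left undefined", {
  counts <- data.frame(chrom = "c", pos = 1:4,
                       ref_count = c(0L, 10L, 3L, 0L),
                       alt_count = c(20L, 10L, 7L, 0L))
  idx <- compute_snp_index(counts)
  expect_equal(idx$snp_index, c(1, 0.5, 0.7, NA))
  expect_identical(idx$depth, c(20L, 20L, 10L, 0L))
  expect_error(compute_snp_index(data.frame(ref_count = -1, alt_count = 2)),
               "non-negative")
})

test_that("homozygous extraction applies both strict thresholds", {
  rows <- compute_snp_index(data.frame(
    chrom = "c", pos = 1:5,
    ref_count = c(0L, 0L, 2L, 1L, 0L),
    alt_count = c(6L, 5L, 18L, 19L, 0L)))
  # depth 6/index 1 kept; depth 5 discarded; index 0.90 discarded;
  # index 0.95/depth 20 kept; depth 0 (undefined) discarded
  out <- extract_homozygous(rows, min_depth = 5, min_index = 0.9)
  expect_identical(out$pos, c(1L, 4L))
})

test_that("extraction equals a brute-force scan on simulated sites", {
  sim <- make_allele_counts(n_sites = 10000, seed = 41)
  idx <- compute_snp_index(sim$counts)
  got <- extract_homozygous(idx)
  brute <- idx[vapply(seq_len(nrow(idx)), function(i) {
    d <- idx$depth[i]
    d > 5 && d > 0 && idx$alt_count[i] / d > 0.9
  }, logical(1)), ]
  expect_identical(got$pos, brute$pos[order(brute$chrom, brute$pos)])
})

test_that("allele counts round-trip through the TSV reader", {
  sim <- make_allele_counts(n_sites = 50, seed = 2)
  tsv <- tempfile(fileext = ".tsv")
  write.table(sim$counts, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_allele_counts(tsv)
  expect_identical(back$pos, sim$counts$pos)
  expect_identical(back$alt_count, sim$counts$alt_count)
})

test_that("VCF allelic depths load when vcfR is available", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD\t1/1:2,18",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:AD\t0/1:9,11",
    "chr1\t300\t.\tG\tA,C\t.\tPASS\t.\tGT:AD\t1/2:1,5,6"), vcf)
  expect_warning(tab <- read_allele_counts(vcf), "multiallelic")
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$alt_count, c(18L, 11L))
})
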