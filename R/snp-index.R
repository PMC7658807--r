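#' Quality-filter FASTQ reads by fraction of low-quality bases
#'
#' Discards a read if and only if strictly more than `max_fraction` of its
#' bases have a Phred quality below `q_threshold` (defaults: more than 10%
#' of bases under Q30). A read at exactly the threshold fraction is kept.
#' The decision depends only on the multiset of quality scores of the read.
#'
#' @param reads a FASTQ file path, a
#'   [Biostrings::QualityScaledDNAStringSet], or a list of integer Phred
#'   quality vectors (one per read).
#' @param q_threshold minimum acceptable Phred score (a base with quality
#'   `< q_threshold` counts as low quality).
#' @param max_fraction maximum tolerated fraction of low-quality bases;
#'   strictly exceeding it discards the read.
#' @return A list with `keep` (logical per read), `kept` and `discarded`
#'   (the partitioned reads, same type as the input), and `n_kept`,
#'   `n_discarded`. Qualities are interpreted as Phred+33; input that looks
#'   like Phred+64 is rejected with an error rather than silently rescaled.
#' @export
fastq_quality_filter <- function(reads, q_threshold = 30, max_fraction = 0.10) {
  if (!is_number(q_threshold) || !is_number(max_fraction) ||
      max_fraction < 0 || max_fraction > 1) {
    abort("'q_threshold' must be a number and 'max_fraction' in [0, 1]")
  }
  if (is.character(reads) && length(reads) == 1L) {
    if (!file.exists(reads)) abort("FASTQ file not found: %s", reads)
    reads <- tryCatch(
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(reads)),
      error = function(e) abort("malformed FASTQ '%s': %s", reads,
                                conditionMessage(e)))
  }
  if (methods::is(reads, "QualityScaledDNAStringSet")) {
    ascii <- tryCatch({
      qchar <- as.character(Biostrings::quality(reads))
      a <- lapply(qchar, utf8ToInt)
      bad <- lengths(a) != Biostrings::width(reads) |
        vapply(a, function(x) anyNA(x) || any(x < 33), logical(1))
      if (any(bad)) {
        stop(sprintf("quality string of read %d does not match its sequence",
                     which(bad)[1L]))
      }
      a
    }, error = function(e) abort("malformed FASTQ qualities: %s",
                                 conditionMessage(e)))
    maxa <- max(unlist(ascii, use.names = FALSE), -Inf)
    if (is.finite(maxa) && maxa > 75) {
      abort(paste("quality characters up to ASCII %d found: this looks like",
                  "Phred+64 encoding; re-encode to Phred+33"), maxa)
    }
    quals <- lapply(ascii, function(a) a - 33L)
  } else if (is.list(reads)) {
    if (!all(vapply(reads, is.numeric, logical(1)))) {
      abort("'reads' as a list must contain integer quality vectors")
    }
    quals <- reads
  } else {
    abort("'reads' must be a FASTQ path, QualityScaledDNAStringSet, or list of quality vectors")
  }
  if (any(lengths(quals) == 0L)) {
    abort("read %d has no quality values", which(lengths(quals) == 0L)[1L])
  }
  frac_low <- vapply(quals, function(q) mean(q < q_threshold), numeric(1))
  keep <- frac_low <= max_fraction   # discard iff strictly more than the cap
  list(keep = keep,
       kept = reads[keep], discarded = reads[!keep],
       n_kept = sum(keep), n_discarded = sum(!keep))
}

#' Build a wild-type-substituted reference sequence
#'
#' Writes the tabled single-nucleotide substitutions of a wild-type line
#' into a public reference genome, so that when mutant reads are mapped
#' back, only mutant-specific variants stand out as high-SNP-index sites.
#' Lengths are preserved; only the tabled positions change.
#'
#' @param reference a [Biostrings::DNAStringSet] (or FASTA file path).
#' @param table data frame with columns `chrom`, `pos` (1-based),
#'   `ref_base`, `alt_base`; `(chrom, pos)` pairs must be unique and bases
#'   in `A`, `C`, `G`, `T`.
#' @param mode `"strict"` errors when the sequence base at a tabled
#'   position does not match `ref_base`; `"lenient"` warns, skips the row,
#'   and keeps going (so re-applying a table to an already-substituted
#'   reference is the identity).
#' @return The modified `DNAStringSet`, with attributes `n_substituted`
#'   and `n_skipped`.
#' @export
substitute_reference <- function(reference, table, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (is.character(reference) && length(reference) == 1L) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (!methods::is(reference, "DNAStringSet")) {
    abort("'reference' must be a DNAStringSet or FASTA path")
  }
  req <- c("chrom", "pos", "ref_base", "alt_base")
  if (!all(req %in% names(table))) {
    abort("substitution table needs columns: %s", paste(req, collapse = ", "))
  }
  if (nrow(table) == 0L) {
    attr(reference, "n_substituted") <- 0L
    attr(reference, "n_skipped") <- 0L
    return(reference)
  }
  if (anyDuplicated(table[c("chrom", "pos")])) {
    abort("duplicated (chrom, pos) rows in substitution table")
  }
  bases_ok <- table$ref_base %in% c("A", "C", "G", "T") &
    table$alt_base %in% c("A", "C", "G", "T")
  if (!all(bases_ok)) {
    abort("row %d has bases outside {A,C,G,T}", which(!bases_ok)[1L])
  }
  # truncate sequence names at first whitespace, the usual FASTA convention
  seq_names <- sub("\\s.*$", "", names(reference))
  n_sub <- 0L; n_skip <- 0L
  out <- reference
  for (ch in unique(table$chrom)) {
    si <- match(ch, seq_names)
    if (is.na(si)) abort("chromosome '%s' not found in reference", ch)
    rows <- table[table$chrom == ch, ]
    if (any(rows$pos < 1 | rows$pos > Biostrings::width(reference)[si])) {
      abort("position out of range for '%s' (length %d)",
            ch, Biostrings::width(reference)[si])
    }
    current <- as.character(Biostrings::extractAt(
      reference[[si]], IRanges::IRanges(rows$pos, width = 1L)))
    match_ref <- current == rows$ref_base
    if (!all(match_ref) && mode == "strict") {
      bad <- which(!match_ref)[1L]
      abort("reference-base mismatch at %s:%d (expected %s, found %s)",
            ch, rows$pos[bad], rows$ref_base[bad], current[bad])
    }
    if (!all(match_ref)) {
      warnf("%d of %d tabled positions on '%s' do not carry the expected reference base; skipped",
            sum(!match_ref), nrow(rows), ch)
      n_skip <- n_skip + sum(!match_ref)
    }
    apply_rows <- rows[match_ref, , drop = FALSE]
    if (nrow(apply_rows) > 0L) {
      out[[si]] <- Biostrings::replaceLetterAt(
        out[[si]], apply_rows$pos, paste(apply_rows$alt_base, collapse = ""))
      n_sub <- n_sub + nrow(apply_rows)
    }
  }
  attr(out, "n_substituted") <- n_sub
  attr(out, "n_skipped") <- n_skip
  out
}

#' Write a reference as wrapped FASTA
#'
#' @param sequences a `DNAStringSet`.
#' @param path output file path.
#' @param width line-wrapping width (default 60 columns).
#' @export
write_reference_fasta <- function(sequences, path, width = 60L) {
  Biostrings::writeXStringSet(sequences, filepath = path, width = width)
  invisible(path)
}

#' Compute the SNP-index of allele-count rows
#'
#' The SNP-index of a site is the fraction of reads carrying the
#' non-reference allele, `alt_count / (ref_count + alt_count)`. Sites with
#' zero depth have an undefined index (`NA`), never a silent 0.
#'
#' @param counts data frame with columns `ref_count` and `alt_count`
#'   (non-negative integers), typically also `chrom` and `pos`.
#' @return The input with `depth` and `snp_index` columns added.
#' @export
compute_snp_index <- function(counts) {
  if (!all(c("ref_count", "alt_count") %in% names(counts))) {
    abort("'counts' needs columns ref_count and alt_count")
  }
  if (any(counts$ref_count < 0 | counts$alt_count < 0, na.rm = TRUE) ||
      any(!is.finite(counts$ref_count) | !is.finite(counts$alt_count))) {
    abort("read counts must be finite and non-negative")
  }
  counts$depth <- counts$ref_count + counts$alt_count
  counts$snp_index <- ifelse(counts$depth > 0,
                             counts$alt_count / counts$depth, NA_real_)
  counts
}

#' Extract candidate homozygous SNPs
#'
#' Keeps sites with sequencing depth strictly greater than `min_depth` and
#' SNP-index strictly greater than `min_index` (defaults: depth > 5 and
#' index > 0.9), the filter that isolates homozygous mutant variants from
#' mapping noise. Sites with undefined index (zero depth) never pass.
#'
#' @param rows output of [compute_snp_index()].
#' @param min_depth depth must strictly exceed this (default 5).
#' @param min_index SNP-index must strictly exceed this (default 0.9).
#' @return The passing subset, sorted by `chrom` then `pos` when those
#'   columns are present.
#' @export
extract_homozygous <- function(rows, min_depth = 5, min_index = 0.9) {
  if (!all(c("depth", "snp_index") %in% names(rows))) {
    abort("'rows' must carry depth and snp_index; run compute_snp_index() first")
  }
  keep <- !is.na(rows$snp_index) &
    rows$depth > min_depth & rows$snp_index > min_index
  out <- rows[keep, , drop = FALSE]
  if (all(c("chrom", "pos") %in% names(out))) {
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read per-site allele counts from TSV or VCF
#'
#' TSV input needs columns `chrom`, `pos`, `ref_count`, `alt_count`. VCF
#' input (requires the `vcfR` package) takes the per-sample allelic depths
#' (`AD` field) of the first sample; multiallelic records are skipped with
#' a warning, keeping upstream alignment and variant calling out of scope.
#'
#' @param path file path ending in `.vcf`/`.vcf.gz` or a tab-separated
#'   table.
#' @return Data frame with `chrom`, `pos`, `ref_count`, `alt_count`.
#' @export
read_allele_counts <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("reading VCF requires the 'vcfR' package; supply a TSV instead")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcfR::getALT(v))
    if (any(multi)) {
      warnf("%d multiallelic records skipped", sum(multi))
    }
    ad <- vcfR::extract.gt(v, element = "AD")[, 1L]
    parts <- strsplit(ad, ",", fixed = TRUE)
    ref_n <- suppressWarnings(vapply(parts, function(p) as.integer(p[1L]), integer(1)))
    alt_n <- suppressWarnings(vapply(parts, function(p) as.integer(p[2L]), integer(1)))
    out <- data.frame(chrom = vcfR::getCHROM(v),
                      pos = as.integer(vcfR::getPOS(v)),
                      ref_count = ref_n, alt_count = alt_n)[!multi, , drop = FALSE]
    out <- out[complete.cases(out), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref_count", "alt_count")
  if (!all(req %in% names(tab))) {
    abort("TSV must have columns: %s", paste(req, collapse = ", "))
  }
  tab[req]
}
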