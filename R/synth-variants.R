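#' Simulate per-site allele-count tables with known genotypes
#'
#' Generates the input of SNP-index mapping: per-site reference and
#' alternative read counts for a mix of truly homozygous, heterozygous and
#' absent variants under a sequencing-error model. Site depth is drawn from
#' a negative binomial (over-dispersed relative to Poisson, as real
#' coverage is); given depth `n`, the alternative-read count is binomial
#' with success probability `1 - error_rate` (homozygous), `0.5`
#' (heterozygous) or `error_rate` (absent).
#'
#' @param n_sites number of sites.
#' @param genotype_mix numeric of length 3, fractions of
#'   `(homozygous, heterozygous, absent)` sites; must sum to 1.
#' @param depth_mean mean sequencing depth.
#' @param depth_dispersion negative-binomial size parameter; smaller means
#'   more over-dispersion.
#' @param error_rate per-base error fraction in `[0, 0.5)`.
#' @param depth_min floor applied to sampled depths (default 0; depth-0
#'   sites have undefined SNP-index downstream).
#' @param seed integer seed (pure function of arguments).
#' @return A list with `counts` (data frame `chrom`, `pos`, `ref_count`,
#'   `alt_count`) and `truth` (data frame `chrom`, `pos`, `genotype` in
#'   `{"hom", "het", "absent"}`).
#' @export
make_allele_counts <- function(n_sites = 1000,
                               genotype_mix = c(0.25, 0.25, 0.5),
                               depth_mean = 30,
                               depth_dispersion = 5,
                               error_rate = 0.01,
                               depth_min = 0,
                               seed = 1L) {
  if (!is_count(n_sites)) abort("'n_sites' must be a positive integer")
  if (length(genotype_mix) != 3L || any(genotype_mix < 0) ||
      abs(sum(genotype_mix) - 1) > 1e-8) {
    abort("'genotype_mix' must be three non-negative fractions summing to 1")
  }
  if (!is_number(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    abort("'error_rate' must lie in [0, 0.5)")
  }
  if (!is_number(depth_mean) || depth_mean <= 0) abort("'depth_mean' must be > 0")
  if (!is_number(depth_dispersion) || depth_dispersion <= 0) {
    abort("'depth_dispersion' must be > 0")
  }

  withr::local_preserve_seed()
  set.seed(as.integer(seed))

  genotype <- sample(c("hom", "het", "absent"), n_sites, replace = TRUE,
                     prob = genotype_mix)
  depth <- pmax(rnbinom(n_sites, size = depth_dispersion, mu = depth_mean),
                depth_min)
  p_alt <- c(hom = 1 - error_rate, het = 0.5, absent = error_rate)[genotype]
  alt <- rbinom(n_sites, size = depth, prob = p_alt)
  pos <- sort(sample.int(n_sites * 50L, n_sites))

  list(
    counts = data.frame(chrom = "chr1", pos = pos,
                        ref_count = as.integer(depth - alt),
                        alt_count = as.integer(alt)),
    truth = data.frame(chrom = "chr1", pos = pos, genotype = genotype)
  )
}
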