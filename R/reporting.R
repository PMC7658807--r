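#' Relative expression by the 2^-dCp method
#'
#' Relative qPCR expression of a target gene against a reference gene,
#' `2^-(Cp_target - Cp_reference)`: equal crossing points give 1, each
#' extra cycle of the target halves the value. Vectorized; the difference
#' is invariant under a common shift of both Cp values.
#'
#' @param cp_target crossing-point (Cp) cycles of the target gene.
#' @param cp_reference Cp cycles of the reference gene.
#' @return `2^-(cp_target - cp_reference)`.
#' @export
relative_expression_2dcp <- function(cp_target, cp_reference) {
  if (!is.numeric(cp_target) || !is.numeric(cp_reference) ||
      any(!is.finite(cp_target)) || any(!is.finite(cp_reference))) {
    abort("Cp values must be finite numbers")
  }
  2^(-(cp_target - cp_reference))
}

#' Relative expression of every gene in a Cp table
#'
#' Applies [relative_expression_2dcp()] per sample against a named
#' reference gene.
#'
#' @param cp_table data frame with columns `sample`, `gene`, `cp`.
#' @param reference_gene gene id used as the per-sample reference; must be
#'   present (once) in every sample.
#' @return The non-reference rows with a `relative_expression` column
#'   added.
#' @export
relative_expression_table <- function(cp_table, reference_gene) {
  req <- c("sample", "gene", "cp")
  if (!all(req %in% names(cp_table))) {
    abort("'cp_table' needs columns: %s", paste(req, collapse = ", "))
  }
  if (any(!is.finite(cp_table$cp)) || any(cp_table$cp <= 0)) {
    abort("Cp values must be finite and positive")
  }
  ref <- cp_table[cp_table$gene == reference_gene, ]
  if (anyDuplicated(ref$sample)) {
    abort("reference gene '%s' appears more than once in a sample", reference_gene)
  }
  missing <- setdiff(unique(cp_table$sample), ref$sample)
  if (length(missing) > 0L) {
    abort("reference gene '%s' missing for sample(s): %s", reference_gene,
          paste(missing, collapse = ", "))
  }
  out <- cp_table[cp_table$gene != reference_gene, , drop = FALSE]
  ref_cp <- setNames(ref$cp, ref$sample)
  out$relative_expression <- relative_expression_2dcp(out$cp, ref_cp[out$sample])
  rownames(out) <- NULL
  out
}

#' Group comparison by t test or ANOVA with Tukey HSD
#'
#' The statistics harness used to present per-replicate quantifications:
#' a two-tailed Student's t test for two groups, or one-/two-way ANOVA
#' followed by Tukey's honest significant difference for factorial designs.
#' The replicate unit is whatever one row of `data` represents (typically
#' one cell, trace, or biological replicate aggregated upstream); this
#' function never aggregates.
#'
#' @param data data frame of per-replicate measurements.
#' @param response name of the numeric response column.
#' @param factors character vector of one (t test / one-way) or two
#'   (two-way) grouping column names.
#' @param method `"t"`, `"anova1"`, or `"anova2"`.
#' @return A `group_stats` data frame: one row per test or per Tukey
#'   pairwise contrast, with columns `comparison`, `test`, `statistic`,
#'   `p_value`, `stars`. Attributes record the design and method. Stars:
#'   `***` < 0.001, `**` < 0.01, `*` < 0.05, `ns` otherwise.
#' @details A two-way layout must be balanced (equal cell counts);
#'   unbalanced two-way designs raise an error rather than silently using
#'   order-dependent sums of squares. One-way Tukey on unbalanced groups
#'   uses the standard Tukey-Kramer adjustment.
#' @export
compare_groups <- function(data, response, factors,
                           method = c("t", "anova1", "anova2")) {
  method <- match.arg(method)
  if (!response %in% names(data)) abort("response column '%s' not found", response)
  if (!all(factors %in% names(data))) {
    abort("grouping column(s) not found: %s",
          paste(setdiff(factors, names(data)), collapse = ", "))
  }
  y <- data[[response]]
  if (!is.numeric(y) || any(!is.finite(y))) {
    abort("response must be numeric and finite")
  }
  g1 <- factor(data[[factors[1L]]])
  counts <- table(g1)
  if (length(counts) < 2L || any(counts < 2L)) {
    abort("need at least 2 groups with at least 2 replicates each")
  }

  if (method == "t") {
    if (length(factors) != 1L || nlevels(g1) != 2L) {
      abort("the t test needs exactly one factor with exactly 2 levels (got %d)",
            nlevels(g1))
    }
    tt <- t.test(y ~ g1, var.equal = TRUE, alternative = "two.sided")
    res <- data.frame(
      comparison = paste(levels(g1), collapse = " vs "),
      test = "Student t (two-tailed)",
      statistic = unname(tt$statistic),
      p_value = tt$p.value)
  } else if (method == "anova1") {
    if (length(factors) != 1L) abort("one-way ANOVA needs exactly one factor")
    fit <- aov(y ~ g1)
    an <- summary(fit)[[1L]]
    tk <- TukeyHSD(fit)$g1
    res <- rbind(
      data.frame(comparison = factors[1L], test = "one-way ANOVA F",
                 statistic = an$`F value`[1L], p_value = an$`Pr(>F)`[1L]),
      data.frame(comparison = rownames(tk), test = "Tukey HSD",
                 statistic = tk[, "diff"], p_value = tk[, "p adj"]))
  } else {
    if (length(factors) != 2L) abort("two-way ANOVA needs exactly two factors")
    g2 <- factor(data[[factors[2L]]])
    cell_counts <- table(g1, g2)
    if (any(cell_counts == 0L) || length(unique(as.vector(cell_counts))) != 1L) {
      abort("two-way ANOVA requires a balanced design (equal counts per cell); got counts %s",
            paste(as.vector(cell_counts), collapse = ","))
    }
    fit <- aov(y ~ g1 * g2)
    an <- summary(fit)[[1L]]
    terms <- trimws(rownames(an))
    term_labels <- c(factors[1L], factors[2L],
                     paste(factors, collapse = ":"))[seq_len(sum(terms != "Residuals"))]
    keep <- terms != "Residuals"
    res <- data.frame(comparison = term_labels,
                      test = "two-way ANOVA F",
                      statistic = an$`F value`[keep],
                      p_value = an$`Pr(>F)`[keep])
    tk <- TukeyHSD(fit, which = "g1:g2")$`g1:g2`
    res <- rbind(res, data.frame(
      comparison = rownames(tk), test = "Tukey HSD",
      statistic = tk[, "diff"], p_value = tk[, "p adj"]))
  }
  res$stars <- as.character(p_stars(res$p_value))
  rownames(res) <- NULL
  attr(res, "method") <- method
  attr(res, "design") <- paste(factors, collapse = " x ")
  class(res) <- c("group_stats", "data.frame")
  res
}
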