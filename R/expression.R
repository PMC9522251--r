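# FACS-compartment expression profiling: per-compartment mean TPM,
# proportional expression, information content, and the seven-way
# enrichment classification.

COMPARTMENTS <- c("X1", "X2", "Xins")
ENRICHMENT_LEVELS <- c("X1", "X2", "Xins", "X1_X2", "X1_Xins", "X2_Xins", "ubiquitous")

#' Mean TPM per FACS compartment
#'
#' Averages per-sample TPM values within each FACS compartment (X1 = cycling
#' stem cells, X2 = G1 stem cells plus postmitotic progeny, Xins =
#' differentiated cells).
#'
#' @param tpm data.frame with a `gene_id` column and one numeric column per
#'   sample (see [read_expression()]).
#' @param sample_to_compartment Named character vector mapping every sample
#'   column to one of `"X1"`, `"X2"`, `"Xins"`.
#' @return data.frame with columns gene_id, tpm_x1, tpm_x2, tpm_xins.
#' @export
summarize_compartments <- function(tpm, sample_to_compartment) {
  stopifnot(is.data.frame(tpm), "gene_id" %in% names(tpm))
  samples <- setdiff(names(tpm), "gene_id")
  unmapped <- setdiff(samples, names(sample_to_compartment))
  if (length(unmapped)) stopf("sample without compartment label: %s", unmapped[1])
  comp <- sample_to_compartment[samples]
  if (any(!comp %in% COMPARTMENTS)) {
    stopf("unknown compartment '%s' (must be one of %s)",
          comp[!comp %in% COMPARTMENTS][1], paste(COMPARTMENTS, collapse = ", "))
  }
  missing_comp <- setdiff(COMPARTMENTS, comp)
  if (length(missing_comp)) stopf("compartment with zero samples: %s", missing_comp[1])
  m <- as.matrix(tpm[, samples, drop = FALSE])
  if (any(m < 0)) stopf("TPM values must be non-negative")
  mean_of <- function(k) rowMeans(m[, comp == k, drop = FALSE])
  data.frame(gene_id = tpm$gene_id,
             tpm_x1 = mean_of("X1"), tpm_x2 = mean_of("X2"), tpm_xins = mean_of("Xins"),
             stringsAsFactors = FALSE)
}

#' Proportional expression across compartments
#'
#' Divides each compartment's TPM by the gene's total TPM (Xk% in the field's
#' notation). Genes with zero total TPM are flagged unexpressed (p-values NA)
#' rather than silently assigned (1/3, 1/3, 1/3); they are excluded from
#' classification downstream.
#'
#' @param ce data.frame from [summarize_compartments()].
#' @return `ce` with added columns p1, p2, p3 (summing to 1 for expressed
#'   genes) and logical `expressed`.
#' @export
proportional_expression <- function(ce) {
  stopifnot(all(c("tpm_x1", "tpm_x2", "tpm_xins") %in% names(ce)))
  tot <- ce$tpm_x1 + ce$tpm_x2 + ce$tpm_xins
  expressed <- tot > 0
  ce$p1 <- ifelse(expressed, ce$tpm_x1 / tot, NA_real_)
  ce$p2 <- ifelse(expressed, ce$tpm_x2 / tot, NA_real_)
  ce$p3 <- ifelse(expressed, ce$tpm_xins / tot, NA_real_)
  ce$expressed <- expressed
  ce
}

#' Information content of a proportional-expression profile
#'
#' Scalar summary of how far a gene's compartment proportions diverge from
#' the even point (1/3, 1/3, 1/3):
#' `IC = 0.01*p1*log(p1) + 0.01*p2*log(p2) + 0.01*p3*log(p3)`, with any
#' proportion below 0.01 clamped to 0.01 before evaluation. IC is always
#' <= 0; values closer to 0 indicate stronger compartment specificity.
#' The 0.01 prefactor is a pure scale factor kept exactly as defined; only
#' the ordering of genes matters downstream.
#'
#' @param p1,p2,p3 Numeric vectors of proportions (recycled).
#' @param base Logarithm base; natural log by default.
#' @return Numeric vector of IC values (NA propagates).
#' @examples
#' information_content(1/3, 1/3, 1/3) # 0.01*log(1/3)
#' @export
information_content <- function(p1, p2, p3, base = exp(1)) {
  term <- function(p) {
    p <- pmax(p, 0.01)
    0.01 * p * log(p, base = base)
  }
  term(p1) + term(p2) + term(p3)
}

#' Seven-way FACS enrichment classification
#'
#' Assigns each profile to exactly one of X1, X2, Xins, X1_X2, X1_Xins,
#' X2_Xins or ubiquitous. Single-compartment rules (p > 0.5) are evaluated
#' first, then pairwise rules (p_i + p_j > 0.75 with neither single rule
#' firing), then ubiquitous. `strict = TRUE` uses strict `>` at both
#' thresholds (the operative definition); `strict = FALSE` uses `>=`
#' (the variant printed alongside the figure legends).
#'
#' @param p1,p2,p3 Proportion vectors (recycled to common length).
#' @param strict Logical; threshold comparison, see Details.
#' @return Factor with levels X1, X2, Xins, X1_X2, X1_Xins, X2_Xins,
#'   ubiquitous; NA for profiles containing NA (unexpressed genes).
#' @export
classify_enrichment <- function(p1, p2, p3, strict = TRUE) {
  n <- max(length(p1), length(p2), length(p3))
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n); p3 <- rep_len(p3, n)
  ok <- !(is.na(p1) | is.na(p2) | is.na(p3))
  if (any(abs(p1[ok] + p2[ok] + p3[ok] - 1) > 1e-6)) {
    stopf("proportions must sum to 1")
  }
  gt <- if (strict) `>` else `>=`
  out <- rep(NA_character_, n)
  s1 <- ok & gt(p1, 0.5); s2 <- ok & gt(p2, 0.5); s3 <- ok & gt(p3, 0.5)
  out[s1] <- "X1"
  out[!s1 & s2] <- "X2"
  out[!s1 & !s2 & s3] <- "Xins"
  single <- s1 | s2 | s3
  rest <- ok & !single
  p12 <- rest & gt(p1 + p2, 0.75)
  p13 <- rest & gt(p1 + p3, 0.75)
  p23 <- rest & gt(p2 + p3, 0.75)
  out[p12] <- "X1_X2"
  out[!p12 & p13] <- "X1_Xins"
  out[!p12 & !p13 & p23] <- "X2_Xins"
  out[rest & !(p12 | p13 | p23)] <- "ubiquitous"
  factor(out, levels = ENRICHMENT_LEVELS)
}

#' Full expression-profile table
#'
#' Convenience wrapper: compartment means, proportional expression, IC and
#' enrichment category in one pass.
#'
#' @inheritParams summarize_compartments
#' @inheritParams classify_enrichment
#' @return data.frame with columns gene_id, tpm_x1, tpm_x2, tpm_xins,
#'   p1, p2, p3, expressed, ic, category.
#' @export
expression_profiles <- function(tpm, sample_to_compartment, strict = TRUE) {
  ce <- summarize_compartments(tpm, sample_to_compartment)
  ce <- proportional_expression(ce)
  ce$ic <- information_content(ce$p1, ce$p2, ce$p3)
  ce$category <- classify_enrichment(ce$p1, ce$p2, ce$p3, strict = strict)
  ce
}

#' Group comparison tests used across the analyses
#'
#' Thin dispatcher over the standard tests: Kruskal-Wallis across >= 2
#' groups, two-sided Wilcoxon rank-sum for exactly 2 groups (normal
#' approximation with tie correction for n > 20), and the chi-square test
#' with Yates continuity correction on a 2x2 count table.
#'
#' @param samples For `"kruskal"`/`"wilcoxon"`: a list of numeric vectors.
#'   For `"chi2_yates"`: a 2x2 numeric matrix of counts.
#' @param test One of `"kruskal"`, `"wilcoxon"`, `"chi2_yates"`.
#' @return List with elements `statistic` and `p_value`.
#' @export
compare_groups <- function(samples, test = c("kruskal", "wilcoxon", "chi2_yates")) {
  test <- match.arg(test)
  if (test == "chi2_yates") {
    m <- as.matrix(samples)
    if (!all(dim(m) == c(2, 2))) stopf("chi2_yates needs a 2x2 count table")
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected < 1)) warnf("chi-square approximation unreliable: expected cell count < 1")
    res <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    return(list(statistic = unname(res$statistic), p_value = res$p.value))
  }
  stopifnot(is.list(samples))
  if (any(lengths(samples) == 0)) stopf("empty group")
  if (test == "kruskal") {
    if (length(samples) < 2) stopf("kruskal needs >= 2 groups")
    res <- stats::kruskal.test(samples)
    return(list(statistic = unname(res$statistic), p_value = res$p.value))
  }
  if (length(samples) != 2) stopf("wilcoxon needs exactly 2 groups")
  x <- samples[[1]]; y <- samples[[2]]
  use_exact <- max(length(x), length(y)) <= 20 && !anyDuplicated(c(x, y))
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
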