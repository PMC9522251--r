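# Validation of predicted regulatory links against RNAi
# differential-expression sets: closed-form expected link counts under an
# independence null, observed counts, observed/expected ratios, and
# permutation p-values.

#' Expected number of validated regulatory links
#'
#' Under the independence null the expected number of differentially
#' expressed TFs that are linked to an enhancer carrying the knockdown TF's
#' footprint is `P(A) * P(B) * P(C) * nge` with `P(A) = ndge/nge`,
#' `P(B) = ncis/nge`, `P(C) = ncisTF/ncis`. The product simplifies to
#' `ndge * ncisTF / nge`; the full product is evaluated and the algebraic
#' identity asserted.
#'
#' @param nge Total number of TFs in the genome (the gene universe).
#' @param ndge Number of differentially expressed TFs.
#' @param ncis Number of TFs linked to an enhancer.
#' @param ncisTF Number of enhancer-linked TFs whose enhancer contains a
#'   footprint of the knockdown TF.
#' @return Expected link count (real).
#' @examples
#' expected_links(100, 10, 50, 20) # 0.1 * 0.5 * 0.4 * 100 = 2
#' @export
expected_links <- function(nge, ndge, ncis, ncisTF) {
  if (nge <= 0) stopf("nge must be positive")
  if (ndge < 0 || ndge > nge) stopf("need 0 <= ndge <= nge")
  if (ncisTF < 0 || ncisTF > ncis || ncis > nge) stopf("need 0 <= ncisTF <= ncis <= nge")
  if (ncis == 0) {
    if (ncisTF > 0) stopf("ncis = 0 with ncisTF > 0 violates ncisTF <= ncis")
    return(0)
  }
  expected <- (ndge / nge) * (ncis / nge) * (ncisTF / ncis) * nge
  stopifnot(isTRUE(all.equal(expected, ndge * ncisTF / nge)))
  expected
}

#' Observed number of validated regulatory links
#'
#' Number of distinct TF target genes that are differentially expressed in
#' the knockdown experiment and carry at least one link of the given
#' footprint class from the knockdown TF. Counting is per target gene: a
#' target supported by several footprints counts once.
#'
#' @param experiment List with `knockdown_tf` (gene_id) and `detf_set`
#'   (character vector of differentially expressed TF gene_ids).
#' @param links Link table from [build_links()], restricted to TF targets.
#' @param footprint_class `"bound"` or `"unbound"`.
#' @return Integer count.
#' @export
observed_links <- function(experiment, links, footprint_class = c("bound", "unbound")) {
  footprint_class <- match.arg(footprint_class)
  targets <- class_targets(links, experiment$knockdown_tf, footprint_class)
  sum(targets %in% experiment$detf_set)
}

class_targets <- function(links, kd, footprint_class) {
  want <- footprint_class == "bound"
  unique(links$target_gene_id[links$tf_gene_id == kd & links$bound == want])
}

#' Observed/expected link enrichment for one knockdown
#'
#' Derives all counts from the inputs and reports, separately for bound and
#' unbound footprint classes, the observed link count, the closed-form
#' expectation, and their ratio. A ratio with expected = 0 is reported as NA
#' (undefined), never as 0 or Inf.
#'
#' @inheritParams observed_links
#' @param tf_universe Character vector of all TF gene_ids (the universe over
#'   which every count is defined).
#' @return One-row data.frame: knockdown_tf, nge, ndge, ncis, then per class
#'   ncisTF_*, observed_*, expected_*, ratio_*.
#' @export
oe_ratio <- function(experiment, links, tf_universe) {
  kd <- experiment$knockdown_tf
  if (!kd %in% tf_universe) stopf("knockdown TF %s not in the TF universe", kd)
  links <- links[links$target_gene_id %in% tf_universe, , drop = FALSE]
  nge <- length(unique(tf_universe))
  detf <- intersect(unique(experiment$detf_set), tf_universe)
  ndge <- length(detf)
  ncis <- length(unique(links$target_gene_id))
  one_class <- function(cl) {
    tg <- class_targets(links, kd, cl)
    ncisTF <- length(tg)
    observed <- sum(tg %in% detf)
    expected <- expected_links(nge, ndge, ncis, ncisTF)
    ratio <- if (expected > 0) observed / expected else NA_real_
    list(ncisTF = ncisTF, observed = observed, expected = expected, ratio = ratio)
  }
  b <- one_class("bound"); u <- one_class("unbound")
  data.frame(knockdown_tf = kd, nge = nge, ndge = ndge, ncis = ncis,
             ncisTF_bound = b$ncisTF, observed_bound = b$observed,
             expected_bound = b$expected, ratio_bound = b$ratio,
             ncisTF_unbound = u$ncisTF, observed_unbound = u$observed,
             expected_unbound = u$expected, ratio_unbound = u$ratio,
             stringsAsFactors = FALSE)
}

#' Permutation p-value for the observed link count
#'
#' Default null: the differential-expression label set is resampled --
#' `ndge` TFs are drawn uniformly without replacement from the universe and
#' the observed count recomputed; `p = (1 + #(observed* >= observed)) /
#' (n_perm + 1)`. With `full_null = TRUE` the footprint-bearing target set is
#' additionally resampled uniformly (the fuller null in which enhancers and
#' footprints are also randomly assigned to genes).
#'
#' @inheritParams oe_ratio
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param full_null Also resample the footprint-target sets (default FALSE).
#' @return List with per-class p-values (`p_bound`, `p_unbound`), observed
#'   counts, and the permutation null mean/sd per class (used for the
#'   Monte-Carlo cross-check against the closed-form expectation).
#' @export
permutation_p <- function(experiment, links, tf_universe, n_perm = 1000,
                          seed = 1, full_null = FALSE) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  kd <- experiment$knockdown_tf
  links <- links[links$target_gene_id %in% tf_universe, , drop = FALSE]
  universe <- unique(tf_universe)
  nge <- length(universe)
  detf <- intersect(unique(experiment$detf_set), universe)
  ndge <- length(detf)
  if (ndge > nge) stopf("ndge exceeds the universe size")
  sets <- list(bound = match(class_targets(links, kd, "bound"), universe),
               unbound = match(class_targets(links, kd, "unbound"), universe))
  obs <- vapply(c("bound", "unbound"), function(cl) {
    sum(universe[sets[[cl]]] %in% detf)
  }, 0)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      de_idx <- sample.int(nge, ndge)
      member <- logical(nge); member[de_idx] <- TRUE
      vapply(c("bound", "unbound"), function(cl) {
        idx <- sets[[cl]]
        if (full_null && length(idx)) idx <- sample.int(nge, length(idx))
        sum(member[idx])
      }, 0)
    }, c(bound = 0, unbound = 0))
  })
  pval <- function(cl) {
    (1 + sum(null_counts[cl, ] >= obs[[cl]])) / (n_perm + 1)
  }
  list(p_bound = pval("bound"), p_unbound = pval("unbound"),
       observed_bound = obs[["bound"]], observed_unbound = obs[["unbound"]],
       null_mean_bound = mean(null_counts["bound", ]),
       null_sd_bound = stats::sd(null_counts["bound", ]),
       null_mean_unbound = mean(null_counts["unbound", ]),
       null_sd_unbound = stats::sd(null_counts["unbound", ]),
       n_perm = n_perm)
}

#' Validate a cohort of knockdown experiments
#'
#' Runs [oe_ratio()] (and optionally [permutation_p()]) for every knockdown
#' in a DE table and summarizes the cohort.
#'
#' @param de_table data.frame with columns knockdown_tf, gene_id (see
#'   [read_de_lists()]).
#' @inheritParams permutation_p
#' @param n_perm Permutations per knockdown; 0 skips permutation testing.
#' @return List with `per_tf` (one row per knockdown, observed/expected/
#'   ratio/p per class) and `summary` from [cohort_summary()].
#' @export
validate_grn <- function(de_table, links, tf_universe, n_perm = 1000, seed = 1) {
  kds <- sort(unique(de_table$knockdown_tf))
  if (length(kds) == 0) stopf("no knockdown experiments in the DE table")
  rows <- lapply(seq_along(kds), function(i) {
    kd <- kds[i]
    exper <- list(knockdown_tf = kd,
                  detf_set = de_table$gene_id[de_table$knockdown_tf == kd])
    row <- oe_ratio(exper, links, tf_universe)
    if (n_perm > 0) {
      pp <- permutation_p(exper, links, tf_universe, n_perm = n_perm,
                          seed = seed + i)
      row$p_bound <- pp$p_bound
      row$p_unbound <- pp$p_unbound
    }
    row
  })
  per_tf <- do.call(rbind, rows)
  rownames(per_tf) <- NULL
  list(per_tf = per_tf, summary = cohort_summary(per_tf))
}

#' Cohort summary of link-enrichment results
#'
#' Arithmetic mean of the defined observed/expected ratios per footprint
#' class; undefined ratios (expected = 0) are excluded from the mean and the
#' number of contributing knockdowns reported.
#'
#' @param per_tf data.frame of per-knockdown results (from [validate_grn()]
#'   or rbind-ed [oe_ratio()] rows).
#' @return data.frame with one row per class: class, mean_ratio, n_defined,
#'   n_total.
#' @export
cohort_summary <- function(per_tf) {
  one <- function(cl) {
    r <- per_tf[[paste0("ratio_", cl)]]
    ok <- !is.na(r)
    if (!any(ok)) stopf("all %s ratios undefined", cl)
    data.frame(class = cl, mean_ratio = mean(r[ok]), n_defined = sum(ok),
               n_total = length(r), stringsAsFactors = FALSE)
  }
  rbind(one("bound"), one("unbound"))
}
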