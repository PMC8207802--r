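# Per-individual and per-population genetic-load statistics and the
# domestic-vs-wild contrasts.

#' Per-individual genetic-load summary
#'
#' Counts derived deleterious (hSNP) and synonymous alleles per sample,
#' split by heterozygous/homozygous state.  Genotypes must already be
#' polarized to derived-allele dosages (0/1/2); `NA` genotypes are
#' excluded from numerators and denominators site-wise.
#'
#' @param derived_dosage integer matrix (sites x samples) of derived-allele
#'   dosages.
#' @param site_class character vector per site: which class each site
#'   belongs to; the summary counts classes `"deleterious"` and
#'   `"synonymous"` (see [site_load_classes()]).
#' @param samples data.frame with `sample_id` and `population` for the
#'   columns of `derived_dosage`.
#' @return data.frame (one row per sample) with fields `n_del_alleles`,
#'   `n_het_del`, `n_hom_del`, `n_syn_alleles`, `n_het_syn`, `n_hom_syn`,
#'   `n_del_sites`, `del_syn_ratio`, `het_del_fraction`.
#' @export
individual_load <- function(derived_dosage, site_class, samples) {
  stopifnot(nrow(derived_dosage) == length(site_class),
            ncol(derived_dosage) == nrow(samples))
  if (anyNA(samples$population))
    stop("samples missing from the population map")
  cnt <- function(cls, what) {
    g <- derived_dosage[site_class == cls, , drop = FALSE]
    switch(what,
           alleles = colSums(g, na.rm = TRUE),
           het = colSums(g == 1, na.rm = TRUE),
           hom = colSums(g == 2, na.rm = TRUE),
           sites = colSums(g >= 1, na.rm = TRUE))
  }
  out <- data.frame(
    sample_id = samples$sample_id, population = samples$population,
    n_del_alleles = cnt("deleterious", "alleles"),
    n_het_del = cnt("deleterious", "het"),
    n_hom_del = cnt("deleterious", "hom"),
    n_del_sites = cnt("deleterious", "sites"),
    n_syn_alleles = cnt("synonymous", "alleles"),
    n_het_syn = cnt("synonymous", "het"),
    n_hom_syn = cnt("synonymous", "hom"),
    row.names = NULL)
  out$del_syn_ratio <- ifelse(out$n_syn_alleles > 0,
                              out$n_del_alleles / out$n_syn_alleles, NA)
  denom <- out$n_het_del + out$n_hom_del
  out$het_del_fraction <- ifelse(denom > 0, out$n_het_del / denom, NA)
  out
}

#' Map annotation records to load classes
#'
#' @param annotations data.frame from [annotate_variants()] (or any frame
#'   with `effect` and `is_hsnp`).
#' @return character vector: `"deleterious"` for hSNPs, `"synonymous"`,
#'   `"other"` otherwise.
#' @export
site_load_classes <- function(annotations) {
  ifelse(annotations$is_hsnp, "deleterious",
         ifelse(annotations$effect == "synonymous", "synonymous", "other"))
}

#' Population-level load profile
#'
#' Per-population means of the individual load summaries plus the mean
#' derived allele frequency of deleterious and synonymous sites.
#' The population heterozygous-deleterious fraction is the mean of
#' per-individual fractions (primary) with the pooled-count fraction also
#' reported.
#'
#' @param summaries output of [individual_load()].
#' @param derived_dosage,site_class as for [individual_load()] (for the
#'   allele-frequency component; optional).
#' @param populations sample population labels aligned with
#'   `derived_dosage` columns.
#' @return data.frame, one row per population.
#' @export
population_load_profile <- function(summaries, derived_dosage = NULL,
                                    site_class = NULL, populations = NULL) {
  pops <- split(summaries, summaries$population)
  if (any(vapply(pops, nrow, 0L) < 1)) stop("each population needs >= 1 sample")
  out <- do.call(rbind, lapply(names(pops), function(p) {
    s <- pops[[p]]
    data.frame(
      population = p, n_samples = nrow(s),
      mean_del_alleles = mean(s$n_del_alleles),
      mean_del_sites = mean(s$n_del_sites),
      mean_syn_alleles = mean(s$n_syn_alleles),
      mean_del_syn_ratio = mean(s$del_syn_ratio, na.rm = TRUE),
      mean_het_del_fraction = mean(s$het_del_fraction, na.rm = TRUE),
      pooled_het_del_fraction =
        sum(s$n_het_del) / max(sum(s$n_het_del) + sum(s$n_hom_del), 1))
  }))
  if (!is.null(derived_dosage)) {
    stopifnot(!is.null(site_class), !is.null(populations))
    for (p in out$population) {
      g <- derived_dosage[, populations == p, drop = FALSE]
      freq <- function(cls) {
        gg <- g[site_class == cls, , drop = FALSE]
        if (nrow(gg) == 0) return(NA_real_)
        called <- 2 * rowSums(!is.na(gg))
        der <- rowSums(gg, na.rm = TRUE)
        keep <- called > 0
        if (!any(keep)) return(NA_real_)
        mean(der[keep] / called[keep])
      }
      out$mean_del_freq[out$population == p] <- freq("deleterious")
      out$mean_syn_freq[out$population == p] <- freq("synonymous")
    }
  }
  out
}

#' Two-group rank-sum comparison
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of per-individual
#' statistics between two groups: exact enumeration when the pooled sample
#' is small (n_A + n_B <= 12) and tie-free, otherwise the normal
#' approximation with tie and continuity corrections.  (The published
#' analysis labels this unpaired domestic-vs-wild comparison a "Wilcoxon
#' signed-rank test"; the unpaired rank-sum test is what the design
#' supports, and that is what is computed here.)
#'
#' @param values_a,values_b numeric vectors.
#' @param name statistic name carried through to the output.
#' @return one-row data.frame: `statistic`, `mean_a`, `mean_b`, `W`,
#'   `p_value`, `test_type`, `direction`.
#' @export
compare_groups <- function(values_a, values_b, name = "statistic") {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    warning("constant pooled data; p = 1")
    return(data.frame(statistic = name, mean_a = mean(values_a),
                      mean_b = mean(values_b),
                      W = length(values_a) * length(values_b) / 2,
                      p_value = 1, test_type = "degenerate",
                      direction = "none"))
  }
  ties <- any(duplicated(pooled))
  exact <- (length(pooled) <= 12) && !ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  data.frame(
    statistic = name,
    mean_a = mean(values_a), mean_b = mean(values_b),
    W = unname(wt$statistic), p_value = wt$p.value,
    test_type = if (exact) "exact" else "normal approximation",
    direction = if (mean(values_a) > mean(values_b)) "A > B"
                else if (mean(values_a) < mean(values_b)) "A < B" else "none")
}

#' Percentage excess of mean load in one population over another
#'
#' `100 * (mean_A - mean_B) / mean_B` of per-individual deleterious allele
#' counts.
#'
#' @param summaries_a,summaries_b [individual_load()] outputs (or any
#'   frames with `n_del_alleles`).
#' @param field which per-individual field to compare.
#' @return numeric percentage (NA if the reference mean is 0).
#' @export
load_excess <- function(summaries_a, summaries_b, field = "n_del_alleles") {
  ma <- mean(summaries_a[[field]])
  mb <- mean(summaries_b[[field]])
  if (mb == 0) return(NA_real_)
  100 * (ma - mb) / mb
}

#' Mean deleteriousness score by chromosome size class
#'
#' @param annotations data.frame with `delta` scores and a
#'   `chromosome_class` column (see [chromosome_class()]).
#' @return list with `means` (data.frame per class) and `comparisons`
#'   (pairwise [compare_groups()] rows for classes present).
#' @export
score_by_chromosome_class <- function(annotations) {
  scored <- annotations[!is.na(annotations$delta), , drop = FALSE]
  classes <- levels(annotations$chromosome_class)
  means <- data.frame(
    chromosome_class = classes,
    n = vapply(classes, function(cl)
      sum(scored$chromosome_class == cl), 0L),
    mean_delta = vapply(classes, function(cl) {
      v <- scored$delta[scored$chromosome_class == cl]
      if (length(v)) mean(v) else NA_real_
    }, 0))
  present <- means$chromosome_class[means$n > 0]
  comparisons <- NULL
  if (length(present) >= 2) {
    prs <- utils::combn(as.character(present), 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      a <- scored$delta[scored$chromosome_class == prs[1, i]]
      b <- scored$delta[scored$chromosome_class == prs[2, i]]
      cbind(class_a = prs[1, i], class_b = prs[2, i],
            compare_groups(a, b, name = "mean_delta"))
    }))
  }
  list(means = means, comparisons = comparisons)
}
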