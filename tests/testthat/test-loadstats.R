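# Load accounting, rank-sum comparisons and chromosome-class summaries.

toy_samples <- function(n, pop = "p") {
  data.frame(sample_id = sprintf("%s_%d", pop, seq_len(n)), population = pop)
}

test_that("individual load counts match the hand-worked toy", {
  # 3 hSNP sites genotyped het / hom-derived / hom-ancestral; 2 synonymous
  # sites both het
  dd <- matrix(c(1L, 2L, 0L, 1L, 1L), ncol = 1)
  cls <- c("deleterious", "deleterious", "deleterious",
           "synonymous", "synonymous")
  s <- individual_load(dd, cls, toy_samples(1))
  expect_equal(s$n_del_alleles, 3)
  expect_equal(s$n_het_del, 1)
  expect_equal(s$n_hom_del, 1)
  expect_equal(s$het_del_fraction, 0.5)
  expect_equal(s$n_syn_alleles, 2)
  # identity n_del = het + 2 hom
  expect_equal(s$n_del_alleles, s$n_het_del + 2 * s$n_hom_del)
})

test_that("all-ancestral genotypes give zero counts and undefined fraction", {
  dd <- matrix(0L, nrow = 4, ncol = 2)
  cls <- rep(c("deleterious", "synonymous"), 2)
  s <- individual_load(dd, cls, toy_samples(2))
  expect_true(all(s$n_del_alleles == 0))
  expect_true(all(is.na(s$het_del_fraction)))
})

test_that("duplicating hSNP sites doubles counts but not the het fraction", {
  set.seed(2)
  dd <- matrix(sample(0:2, 30, replace = TRUE), ncol = 3)
  cls <- rep("deleterious", 10)
  s1 <- individual_load(dd, cls, toy_samples(3))
  s2 <- individual_load(rbind(dd, dd), rep(cls, 2), toy_samples(3))
  expect_equal(s2$n_del_alleles, 2 * s1$n_del_alleles)
  expect_equal(s2$het_del_fraction, s1$het_del_fraction)
})

test_that("missing genotypes are excluded site-wise", {
  dd <- matrix(c(1L, NA, 2L, NA), ncol = 1)
  cls <- c("deleterious", "deleterious", "synonymous", "synonymous")
  s <- individual_load(dd, cls, toy_samples(1))
  expect_equal(s$n_del_alleles, 1)
  expect_equal(s$n_syn_alleles, 2)
})

test_that("allele counts are conserved between individuals and populations", {
  set.seed(5)
  dd <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                      prob = c(.5, .25, .2, .05)), ncol = 10)
  cls <- rep(c("deleterious", "synonymous"), 10)
  samples <- toy_samples(10)
  s <- individual_load(dd, cls, samples)
  del <- cls == "deleterious"
  expect_equal(sum(s$n_del_alleles), sum(dd[del, ], na.rm = TRUE))
})

test_that("population profile reproduces toy frequencies", {
  # one site, 2 diploids het and hom-derived -> derived frequency 0.75
  dd <- matrix(c(1L, 2L), ncol = 2)
  cls <- "deleterious"
  samples <- toy_samples(2)
  s <- individual_load(dd, cls, samples)
  prof <- population_load_profile(s, dd, cls, samples$population)
  expect_equal(prof$mean_del_freq, 0.75)
  # toy of 4 sites with derived counts {1,1,2,4} of 4 alleles -> mean 0.5
  dd2 <- matrix(c(1L, 0L, 0L, 1L, 1L, 1L, 2L, 2L), ncol = 2, byrow = TRUE)
  cls2 <- rep("synonymous", 4)
  s2 <- individual_load(dd2, cls2, samples)
  prof2 <- population_load_profile(s2, dd2, cls2, samples$population)
  expect_equal(prof2$mean_syn_freq, 0.5)
  expect_true(is.na(prof2$mean_del_freq))   # class with zero sites
  # all sites fixed derived -> mean frequency 1
  dd3 <- matrix(2L, 3, 2)
  s3 <- individual_load(dd3, rep("deleterious", 3), samples)
  prof3 <- population_load_profile(s3, dd3, rep("deleterious", 3),
                                   samples$population)
  expect_equal(prof3$mean_del_freq, 1)
})

test_that("rank-sum comparison matches enumeration and approximation", {
  # single tied pair -> degenerate p = 1
  expect_warning(r0 <- compare_groups(5, 5), "constant")
  expect_equal(r0$p_value, 1)
  # A = [1,2] vs B = [3,4]: exact two-sided p = 2/6
  r1 <- compare_groups(c(1, 2), c(3, 4))
  expect_equal(r1$test_type, "exact")
  expect_equal(r1$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r1$p_value, oracle_ranksum_p(c(1, 2), c(3, 4)))
  # exact branch equals full enumeration for all n_A + n_B <= 10
  set.seed(31)
  for (na in 1:5) for (nb in na:(10 - na)) {
    a <- round(rnorm(na), 6); b <- round(rnorm(nb, 0.5), 6)
    r <- compare_groups(a, b)
    expect_equal(r$test_type, "exact")
    expect_equal(r$p_value, oracle_ranksum_p(a, b), tolerance = 1e-10,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
  # exact vs normal approximation agree within 0.05 on n = 6 vs 6
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6, 0.8)
    p_exact <- oracle_ranksum_p(a, b)
    p_norm <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.05)
  }
  # ties force the approximation branch
  r2 <- compare_groups(c(1, 1, 2), c(2, 3, 4))
  expect_equal(r2$test_type, "normal approximation")
})

test_that("load excess follows its definition", {
  a <- data.frame(n_del_alleles = c(102.95))
  b <- data.frame(n_del_alleles = c(100))
  expect_equal(load_excess(a, b), 2.95)
  expect_equal(load_excess(b, b), 0)
  expect_equal(load_excess(data.frame(n_del_alleles = c(10, 12)),
                           data.frame(n_del_alleles = c(10, 10))), 10)
  expect_true(is.na(load_excess(a, data.frame(n_del_alleles = 0))))
})

test_that("chromosome classes map and summarise correctly", {
  cls <- chromosome_class(c(1, 5, 6, 10, 11, 38, 39, "chr2", "Z"))
  expect_equal(as.character(cls),
               c("macro", "macro", "intermediate", "intermediate", "micro",
                 "micro", "unassigned", "macro", "unassigned"))
  ann <- data.frame(delta = c(-1, -3, -2, -4),
                    chromosome_class = chromosome_class(c(1, 1, 11, 11)))
  res <- score_by_chromosome_class(ann)
  expect_equal(res$means$mean_delta[res$means$chromosome_class == "macro"], -2)
  expect_equal(res$means$mean_delta[res$means$chromosome_class == "micro"], -3)
  expect_true(is.na(
    res$means$mean_delta[res$means$chromosome_class == "intermediate"]))
  expect_equal(nrow(res$comparisons), 1)
})

test_that("stronger conservation yields more negative scores on a contig", {
  # contigs differing only in homolog conservation (micro-like = slowly
  # diverging homolog set): the micro-like contig's variants score lower
  # in nearly every replicate
  worse <- logical(25)
  for (i in 1:25) {
    cfg <- rescale(simulation_config(contig_length_bp = 2e4,
                                     coding_fraction = 0.5, seed = 500 + i),
                   2000)
    sim <- simulate_two_population(cfg)
    ns <- sim$sites$class %in% c("missense", "nonsense")
    if (sum(ns) < 4) { worse[i] <- NA; next }
    ann_macro <- annotate_variants(sim$sites$pos[ns], sim$sites$derived[ns],
                                   sim$layout, homolog_n = 5L,
                                   homolog_rate = 0.25, seed = i)
    ann_micro <- annotate_variants(sim$sites$pos[ns], sim$sites$derived[ns],
                                   sim$layout, homolog_n = 5L,
                                   homolog_rate = 0.02, seed = i)
    worse[i] <- mean(ann_micro$delta) < mean(ann_macro$delta)
  }
  expect_gte(mean(worse, na.rm = TRUE), 0.9)
})
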