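# Forward Wright-Fisher simulation of the wild/domestic pair plus outgroup.

#' Simulate a two-population dataset under the configured demography
#'
#' Runs a discrete-generation Wright-Fisher simulation (see
#' `src/wf.cpp`): burn-in of `burnin_factor * N_anc` generations in the
#' ancestral population, then the post-split epochs with per-generation
#' linear size interpolation, migration and selection.  Non-synonymous
#' mutations draw a fitness cost from the gamma DFE (clipped at s = 1
#' after rescaling); synonymous and noncoding mutations are neutral.
#' The outgroup is generated by placing Poisson(divergence x L)
#' substitutions on an independent branch and is emitted as homozygous
#' diploid genotypes.
#'
#' @param config a `dc_simconfig` (already rescaled if desired; see
#'   [rescale()]).
#' @param layout optional `dc_layout`; built from the config when absent.
#' @return object of class `dc_simdata`: list with `sites` (data.frame:
#'   pos (0-based), ref, derived, class, s, h, outgroup allele), the
#'   haplotype matrix `haplotypes` (sites x haplotypes, 0 ancestral /
#'   1 derived), `hap_population` labels, `samples` (sample ids and
#'   populations), `outgroup` allele codes (0 ancestral, 1 derived,
#'   2 other), `layout`, `config` and a `truth` log.
#' @export
simulate_two_population <- function(config, layout = NULL) {
  stopifnot(inherits(config, "dc_simconfig"))
  if (is.null(layout)) layout <- build_genome_layout(config)
  dem <- config$demography
  L <- config$contig_length_bp

  sizes1 <- sizes_per_generation(dem, 1)
  sizes2 <- sizes_per_generation(dem, 2)
  n_burn <- as.integer(round(config$burnin_factor * dem$N_anc))
  eff <- effect_lookup(layout)

  sweep <- list()
  if (!is.null(config$sweep)) {
    sw <- config$sweep
    n2_at <- if (length(sizes2)) sizes2[max(1L, length(sizes2) - sw$t_before_present)]
             else dem$N_anc
    sweep <- list(t_before_present = as.integer(sw$t_before_present),
                  pos = as.integer(sw$pos),
                  s = sw$s,
                  h = if (is.null(sw$h)) 0.5 else sw$h,
                  copies = max(1L, as.integer(round(sw$init_freq * 2 * n2_at))),
                  pop = if (is.null(sw$pop)) 2L else as.integer(sw$pop))
  }

  set.seed(derive_seed(config$seed, "wright-fisher"))
  dfe_scale <- if (config$dfe_shape > 0) config$dfe_mean_s / config$dfe_shape else 0
  res <- cpp_wf_simulate(
    L = L, eff = eff, n_burn = n_burn, N_anc = dem$N_anc,
    sizes1 = sizes1, sizes2 = sizes2,
    m12 = dem$m12, m21 = dem$m21,
    mu = config$mu, rec = config$rec_rate,
    dfe_shape = config$dfe_shape, dfe_scale = dfe_scale,
    h = config$dominance_h, s_max = 1.0,
    sweep = sweep,
    n1 = as.integer(config$sample_sizes[1]),
    n2 = if (length(sizes2)) as.integer(config$sample_sizes[2]) else 0L,
    gc_interval = 64L)

  refc <- reference_codes(layout)
  S <- length(res$pos)
  ref_base <- BASES[refc[res$pos + 1] + 1]
  ALT <- rbind(c(1L, 2L, 3L), c(0L, 2L, 3L), c(0L, 1L, 3L), c(0L, 1L, 2L))
  der_code <- ALT[cbind(refc[res$pos + 1] + 1L, res$alt + 1L)]
  der_base <- BASES[der_code + 1]
  cls <- c("noncoding", "synonymous", "missense", "nonsense")[res$class + 1]

  # outgroup: substitutions on an independent branch
  set.seed(derive_seed(config$seed, "outgroup"))
  n_sub <- rpois(1, config$outgroup_divergence * L)
  sub_pos <- sample.int(L, min(n_sub, L)) - 1L
  out_code <- integer(S)                     # 0 = ancestral (ref)
  hit <- match(res$pos, sub_pos)
  changed <- which(!is.na(hit))
  if (length(changed)) {
    for (k in changed) {
      nb <- sample(setdiff(0:3, refc[res$pos[k] + 1]), 1)
      out_code[k] <- if (nb == der_code[k]) 1L else 2L
    }
  }

  n1 <- as.integer(config$sample_sizes[1])
  n2 <- if (length(sizes2)) as.integer(config$sample_sizes[2]) else 0L
  samples <- data.frame(
    sample_id = c(sprintf("wild_%02d", seq_len(n1)),
                  if (n2) sprintf("dom_%02d", seq_len(n2)),
                  if (config$n_outgroup) sprintf("out_%02d",
                                                 seq_len(config$n_outgroup))),
    population = c(rep("wild", n1), rep("domestic", n2),
                   rep("outgroup", config$n_outgroup)))

  sites <- data.frame(pos = res$pos, ref = ref_base, derived = der_base,
                      class = cls, s = res$s, h = res$h,
                      outgroup_code = out_code)
  truth <- list(config = config, n_burn = n_burn,
                sweep_pos = if (!is.null(config$sweep)) res$sweep_pos else NA,
                seed_layout = derive_seed(config$seed, "layout"),
                seed_wf = derive_seed(config$seed, "wright-fisher"),
                seed_outgroup = derive_seed(config$seed, "outgroup"),
                n_segregating = S)
  structure(list(sites = sites, haplotypes = res$haplotypes,
                 hap_population = rep(c("wild", "domestic"),
                                      c(2 * n1, 2 * n2)),
                 samples = samples, layout = layout, config = config,
                 truth = truth),
            class = "dc_simdata")
}

#' @exportS3Method base::print
print.dc_simdata <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d segregating sites, %d haplotypes (%s)\n",
              nrow(x$sites), ncol(x$haplotypes),
              paste(sprintf("%s: %d", names(table(x$hap_population)),
                            table(x$hap_population)), collapse = ", ")))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s %d", names(table(x$sites$class)),
                            table(x$sites$class)), collapse = ", ")))
  invisible(x)
}

#' Derived-allele dosage matrix of a simulated dataset
#'
#' Collapses the haplotype matrix to per-diploid derived dosages (0/1/2)
#' for the focal populations; simulator output is fully called and
#' polarized by construction.
#'
#' @param sim a `dc_simdata`.
#' @return integer matrix, sites x diploid samples.
#' @export
sim_genotypes <- function(sim) {
  H <- sim$haplotypes
  nd <- ncol(H) / 2
  H[, 2 * seq_len(nd) - 1, drop = FALSE] + H[, 2 * seq_len(nd), drop = FALSE]
}

#' Population labels for the columns of [sim_genotypes()]
#'
#' @param sim a `dc_simdata`.
#' @return character vector of population labels per diploid sample.
#' @export
sim_populations <- function(sim) {
  sim$hap_population[2 * seq_len(ncol(sim$haplotypes) / 2)]
}
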