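# Simulation configuration: demography truth, DFE, genome composition and
# population-size rescaling.

#' Demographic truth for the forward simulator
#'
#' Piecewise-linear population-size epochs for two populations descending
#' from a common ancestor, with constant asymmetric migration after the
#' split.  Times are generations before present; epochs must tile
#' `[0, t_split]` for each population.
#'
#' @param N_anc ancestral diploid size before the split.
#' @param t_split generations before present at which the populations split.
#' @param epochs1,epochs2 data.frames with columns `t_start` (older bound),
#'   `t_end` (younger bound), `size_start`, `size_end`; sizes interpolate
#'   linearly within an epoch.  Population 1 is the wild population,
#'   population 2 the domestic one.
#' @param m12 per-generation probability that an individual of population 1
#'   is replaced by a migrant from population 2; `m21` vice versa.
#' @return object of class `dc_demography`.
#' @export
demography_truth <- function(N_anc, t_split, epochs1, epochs2,
                             m12 = 0, m21 = 0) {
  check_epochs <- function(ep, who) {
    ep <- ep[order(-ep$t_start), , drop = FALSE]
    if (ep$t_start[1] != t_split)
      stop(who, ": oldest epoch must start at t_split")
    if (ep$t_end[nrow(ep)] != 0)
      stop(who, ": youngest epoch must end at the present (0)")
    if (nrow(ep) > 1 && any(ep$t_end[-nrow(ep)] != ep$t_start[-1]))
      stop(who, ": epochs must tile [0, t_split] without gaps or overlap")
    if (any(ep$t_start <= ep$t_end))
      stop(who, ": epochs need t_start > t_end (times are before present)")
    if (any(c(ep$size_start, ep$size_end) < 2))
      stop(who, ": population sizes must be >= 2")
    ep
  }
  stopifnot(N_anc >= 2, t_split >= 0, m12 >= 0, m12 < 1, m21 >= 0, m21 < 1)
  if (t_split > 0) {
    epochs1 <- check_epochs(epochs1, "population 1")
    epochs2 <- check_epochs(epochs2, "population 2")
  }
  structure(list(N_anc = N_anc, t_split = t_split, epochs1 = epochs1,
                 epochs2 = epochs2, m12 = m12, m21 = m21),
            class = "dc_demography")
}

#' Built-in demography presets
#'
#' `"fig1d_model3"` encodes the two-population history inferred for
#' chicken domestication: a split 12,300 generations ago (1 generation =
#' 1 year); the wild population (G. g. spadiceus-like) expanding slightly
#' to 257,000 until 10,300 generations ago then contracting to 154,000;
#' the domestic population declining from 138,000 at the split to 52,000
#' (the domestication bottleneck) until 6,990 generations ago, then
#' recovering to 152,000.  The pre-split ancestral size and the migration
#' rates are not pinned down by the published point estimates and are
#' exposed as arguments; defaults are 200,000 diploids (between the
#' post-split starting sizes) and symmetric migration with
#' 2*N_anc*m = 1 (admixture between domestic flocks and sympatric
#' jungle fowl is pervasive but weak at this timescale).
#'
#' @param name preset name.
#' @param N_anc ancestral diploid size.
#' @param m12,m21 per-generation migration probabilities.
#' @return a `dc_demography` object (see [demography_truth()]).
#' @export
demography_preset <- function(name = "fig1d_model3", N_anc = 200000,
                              m12 = 2.5e-6, m21 = 2.5e-6) {
  name <- match.arg(name, "fig1d_model3")
  demography_truth(
    N_anc = N_anc, t_split = 12300,
    epochs1 = data.frame(
      t_start = c(12300, 10300), t_end = c(10300, 0),
      size_start = c(N_anc, 257000), size_end = c(257000, 154000)),
    epochs2 = data.frame(
      t_start = c(12300, 6990), t_end = c(6990, 0),
      size_start = c(138000, 52000), size_end = c(52000, 152000)),
    m12 = m12, m21 = m21)
}

#' Forward-simulation configuration
#'
#' Bundles the genome composition, mutation/recombination rates, the
#' distribution of fitness effects, the demographic truth and sampling
#' design for [simulate_two_population()].  Defaults describe a
#' chicken-like genome: 4.2% coding, mu = 1.91e-9 per site per generation,
#' r = 3e-8 per bp, a gamma DFE (shape 0.2, mean s = 0.01) on
#' non-synonymous changes with partial recessivity (h = 0.25), and an
#' outgroup diverged by 0.015 substitutions per site.  The DFE and
#' dominance values are stand-in defaults chosen from typical vertebrate
#' estimates, not measured quantities; treat them as documented knobs.
#'
#' @param contig_length_bp simulated contig length.
#' @param coding_fraction fraction of the contig covered by CDS.
#' @param mu mutation probability per site per generation.
#' @param rec_rate recombination probability per adjacent-base boundary
#'   per generation.
#' @param dfe_shape,dfe_mean_s gamma shape and mean of the selection
#'   coefficient (s >= 0, fitness cost) of non-synonymous mutations.
#' @param dominance_h dominance of deleterious alleles (0 = fully
#'   recessive).
#' @param demography a `dc_demography`; default [demography_preset()].
#' @param sample_sizes named integer vector `c(wild =, domestic =)` of
#'   diploids sampled at the end.
#' @param n_outgroup outgroup diploids emitted for polarization.
#' @param outgroup_divergence expected substitutions per site on the
#'   outgroup branch.
#' @param mask_fraction fraction of the contig annotated as repeat /
#'   low-complexity mask (placed outside CDS).
#' @param burnin_factor burn-in length in units of the (rescaled)
#'   ancestral population size.
#' @param rescale_Q population-size rescaling factor already applied to
#'   this configuration (see [rescale()]); 1 for natural units.
#' @param sweep optional beneficial-mutation injection:
#'   `list(t_before_present =, pos =, s =, h =, init_freq =, pop =)`
#'   with `s < 0` meaning a fitness advantage in the genic scheme
#'   1 / 1-hs / 1-s.
#' @param seed integer root seed; all stage streams derive from it.
#' @return object of class `dc_simconfig`.
#' @export
simulation_config <- function(contig_length_bp = 1e6,
                              coding_fraction = 0.042,
                              mu = 1.91e-9,
                              rec_rate = 3e-8,
                              dfe_shape = 0.2,
                              dfe_mean_s = 0.01,
                              dominance_h = 0.25,
                              demography = demography_preset(),
                              sample_sizes = c(wild = 10L, domestic = 10L),
                              n_outgroup = 4L,
                              outgroup_divergence = 0.015,
                              mask_fraction = 0.02,
                              burnin_factor = 10,
                              rescale_Q = 1,
                              sweep = NULL,
                              seed = 1L) {
  stopifnot(coding_fraction >= 0, coding_fraction < 1,
            mu >= 0, rec_rate >= 0, dfe_mean_s >= 0, dfe_shape > 0,
            dominance_h >= 0, dominance_h <= 1, rescale_Q >= 1,
            outgroup_divergence >= 0, mask_fraction >= 0, mask_fraction < 1,
            inherits(demography, "dc_demography"))
  cfg <- structure(list(
    contig_length_bp = as.integer(contig_length_bp),
    coding_fraction = coding_fraction, mu = mu, rec_rate = rec_rate,
    dfe_shape = dfe_shape, dfe_mean_s = dfe_mean_s,
    dominance_h = dominance_h, demography = demography,
    sample_sizes = sample_sizes, n_outgroup = as.integer(n_outgroup),
    outgroup_divergence = outgroup_divergence,
    mask_fraction = mask_fraction, burnin_factor = burnin_factor,
    rescale_Q = rescale_Q, sweep = sweep, seed = as.integer(seed)),
    class = "dc_simconfig")
  check_sample_sizes(cfg)
  cfg
}

check_sample_sizes <- function(cfg) {
  dem <- cfg$demography
  if (dem$t_split > 0) {
    finals <- c(dem$epochs1$size_end[nrow(dem$epochs1)],
                dem$epochs2$size_end[nrow(dem$epochs2)])
  } else {
    finals <- c(dem$N_anc, dem$N_anc)
  }
  if (any(cfg$sample_sizes > finals))
    stop("sample sizes exceed final population sizes")
  invisible(cfg)
}

#' Rescale a simulation configuration
#'
#' Shrinks population sizes and time spans by Q while scaling mutation,
#' recombination, selection and migration up by Q, preserving the
#' population-scaled compounds theta = 4*N*mu, N*s, N*m and t/N exactly.
#' Selection coefficients exceeding 1 after rescaling are clipped at
#' simulation time (an effectively lethal mutation stays lethal).
#'
#' @param config a `dc_simconfig` in natural units (or already rescaled).
#' @param Q rescaling factor, >= 1.
#' @return rescaled `dc_simconfig` with `rescale_Q` multiplied by Q.
#' @export
rescale <- function(config, Q) {
  stopifnot(inherits(config, "dc_simconfig"), Q >= 1)
  if (Q == 1) return(config)
  dem <- config$demography
  sc <- function(n) {
    out <- pmax(round(n / Q), 2)
    if (any(n / Q < 2))
      stop("rescaled population size below 2; choose a smaller Q")
    out
  }
  scale_ep <- function(ep) {
    data.frame(t_start = round(ep$t_start / Q), t_end = round(ep$t_end / Q),
               size_start = sc(ep$size_start), size_end = sc(ep$size_end))
  }
  m12 <- dem$m12 * Q; m21 <- dem$m21 * Q
  if (m12 >= 1 || m21 >= 1)
    stop("rescaled migration rate reaches 1; choose a smaller Q")
  dem2 <- demography_truth(
    N_anc = sc(dem$N_anc), t_split = round(dem$t_split / Q),
    epochs1 = if (dem$t_split > 0) scale_ep(dem$epochs1) else dem$epochs1,
    epochs2 = if (dem$t_split > 0) scale_ep(dem$epochs2) else dem$epochs2,
    m12 = m12, m21 = m21)
  cfg <- config
  cfg$demography <- dem2
  cfg$mu <- config$mu * Q
  cfg$rec_rate <- config$rec_rate * Q
  cfg$dfe_mean_s <- config$dfe_mean_s * Q
  if (!is.null(config$sweep)) {
    cfg$sweep <- config$sweep
    cfg$sweep$s <- config$sweep$s * Q
    cfg$sweep$t_before_present <- round(config$sweep$t_before_present / Q)
  }
  cfg$rescale_Q <- config$rescale_Q * Q
  check_sample_sizes(cfg)
  cfg
}

# per-generation integer size vector after the split (index 1 = first
# generation after the split, last = present)
sizes_per_generation <- function(dem, pop = 1) {
  Tt <- dem$t_split
  if (Tt == 0) return(integer(0))
  ep <- if (pop == 1) dem$epochs1 else dem$epochs2
  tb <- Tt - seq_len(Tt)               # time before present of each generation
  idx <- findInterval(-tb, -ep$t_start)  # epoch containing tb
  idx <- pmin(pmax(idx, 1L), nrow(ep))
  frac <- (ep$t_start[idx] - tb) / (ep$t_start[idx] - ep$t_end[idx])
  sz <- ep$size_start[idx] + frac * (ep$size_end[idx] - ep$size_start[idx])
  pmax(as.integer(round(sz)), 2L)
}

# derive a stage-specific seed from the root seed (documented, stable)
derive_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 2654435761) %% 2147480000
  as.integer((as.numeric(root) * 97 + h) %% 2147480000) + 1L
}
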