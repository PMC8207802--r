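# Windowed diversity/differentiation statistics and sweep calling:
# nucleotide diversity (pi), Hudson FST, locus-specific branch length
# (LSBL), pi-ratio, empirical-quantile sweep calls and the hSNP-in-sweep
# permutation contrast.

site_pi_values <- function(derived, called) {
  # per-site heterozygosity 2 a (n-a) / (n (n-1)) from derived count a of
  # n called alleles
  ok <- called >= 2
  out <- numeric(length(derived))
  out[ok] <- 2 * derived[ok] * (called[ok] - derived[ok]) /
    (called[ok] * (called[ok] - 1))
  out[!ok] <- NA
  out
}

window_starts <- function(contig_length, window, step) {
  if (window < step || step <= 0) stop("need window >= step > 0")
  if (contig_length < window) return(integer(0))
  seq(0L, contig_length - window, by = step)
}

#' Sliding-window nucleotide diversity
#'
#' Per site with derived count a of n called alleles, site pi =
#' 2a(n-a)/(n(n-1)); the window value is the sum of site pi divided by the
#' full window length in bp (matching the windowed-pi convention of
#' common VCF tools), over sliding windows.
#'
#' @param pos 0-based site positions.
#' @param derived,called derived and called allele counts per site.
#' @param contig_length contig length in bp.
#' @param window,step window and step sizes in bp (defaults 50 kb / 25 kb).
#' @param denominator `"window"` (full window length) or `"callable"`
#'   (number of sites with data is not tracked per bp here, so callable
#'   mode divides by the number of variant sites used; intended for
#'   relative comparisons only).
#' @return data.frame: `start`, `end`, `n_sites`, `pi`.
#' @export
windowed_pi <- function(pos, derived, called, contig_length,
                        window = 50000L, step = 25000L,
                        denominator = c("window", "callable")) {
  denominator <- match.arg(denominator)
  sp <- site_pi_values(derived, called)
  starts <- window_starts(contig_length, window, step)
  out <- data.frame(start = starts, end = pmin(starts + window, contig_length))
  out$n_sites <- 0L
  out$pi <- NA_real_
  for (k in seq_along(starts)) {
    inw <- pos >= out$start[k] & pos < out$end[k]
    v <- sp[inw]
    usable <- inw & !is.na(sp)
    out$n_sites[k] <- sum(usable)
    denom <- if (denominator == "window") window else max(sum(usable), 1)
    if (any(inw) && all(is.na(v))) out$pi[k] <- NA
    else out$pi[k] <- sum(v, na.rm = TRUE) / denom
  }
  out
}

#' Hudson FST components for one site
#'
#' Returns the numerator and denominator of Hudson's estimator; window
#' FST is the ratio of the summed numerators to summed denominators
#' ("ratio of averages"), clamped to \[0, 1\].
#'
#' @param derived_a,total_a derived and total allele counts in population A.
#' @param derived_b,total_b same for population B.
#' @return data.frame with `num` and `den` per site.
#' @export
site_fst <- function(derived_a, total_a, derived_b, total_b) {
  if (any(total_a < 2) || any(total_b < 2))
    stop("Hudson FST needs >= 2 called alleles per population")
  p1 <- derived_a / total_a
  p2 <- derived_b / total_b
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (total_a - 1) -
    p2 * (1 - p2) / (total_b - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(num = num, den = den)
}

#' Windowed Hudson FST
#'
#' @inheritParams windowed_pi
#' @param derived_a,called_a,derived_b,called_b per-site allele counts in
#'   the two populations.
#' @return data.frame `start`, `end`, `n_sites`, `fst` (NA where every
#'   site is monomorphic in both populations).
#' @export
windowed_fst <- function(pos, derived_a, called_a, derived_b, called_b,
                         contig_length, window = 50000L, step = 25000L) {
  ok <- called_a >= 2 & called_b >= 2
  comp <- site_fst(pmax(derived_a[ok], 0), called_a[ok],
                   pmax(derived_b[ok], 0), called_b[ok])
  posk <- pos[ok]
  starts <- window_starts(contig_length, window, step)
  out <- data.frame(start = starts, end = pmin(starts + window, contig_length))
  out$n_sites <- 0L
  out$fst <- NA_real_
  for (k in seq_along(starts)) {
    inw <- posk >= out$start[k] & posk < out$end[k]
    out$n_sites[k] <- sum(inw)
    den <- sum(comp$den[inw])
    if (is.finite(den) && den > 0)
      out$fst[k] <- min(max(sum(comp$num[inw]) / den, 0), 1)
  }
  out
}

#' Locus-specific branch length
#'
#' `LSBL(A; B, C) = (d_AB + d_AC - d_BC) / 2`, clamped below at 0; the
#' population-A-specific branch from three pairwise distances (here,
#' window FST values).
#'
#' @param fst_ab,fst_ac,fst_bc pairwise distances in \[0, 1\].
#' @return numeric vector.
#' @export
lsbl <- function(fst_ab, fst_ac, fst_bc) {
  rng <- range(c(fst_ab, fst_ac, fst_bc), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("LSBL inputs must be in [0, 1]")
  pmax((fst_ab + fst_ac - fst_bc) / 2, 0)
}

#' Windowed scan over two focal populations and an outgroup
#'
#' Computes per-window pi for each focal population, pairwise window FST
#' for all three pairs, LSBL for each focal population and the pi-ratio
#' (pi_wild / pi_domestic).
#'
#' @param pos 0-based site positions.
#' @param counts named list with per-population lists
#'   `list(derived =, called =)` for `wild`, `domestic`, `outgroup`.
#' @param contig_length,window,step see [windowed_pi()].
#' @return data.frame of window statistics.
#' @export
scan_windows <- function(pos, counts, contig_length, window = 50000L,
                         step = 25000L) {
  w_pi_w <- windowed_pi(pos, counts$wild$derived, counts$wild$called,
                        contig_length, window, step)
  w_pi_d <- windowed_pi(pos, counts$domestic$derived, counts$domestic$called,
                        contig_length, window, step)
  f_wd <- windowed_fst(pos, counts$wild$derived, counts$wild$called,
                       counts$domestic$derived, counts$domestic$called,
                       contig_length, window, step)
  f_wo <- windowed_fst(pos, counts$wild$derived, counts$wild$called,
                       counts$outgroup$derived, counts$outgroup$called,
                       contig_length, window, step)
  f_do <- windowed_fst(pos, counts$domestic$derived, counts$domestic$called,
                       counts$outgroup$derived, counts$outgroup$called,
                       contig_length, window, step)
  out <- data.frame(start = w_pi_w$start, end = w_pi_w$end,
                    n_sites = f_wd$n_sites,
                    pi_wild = w_pi_w$pi, pi_domestic = w_pi_d$pi,
                    fst_wd = f_wd$fst, fst_wo = f_wo$fst, fst_do = f_do$fst)
  out$lsbl_wild <- lsbl(ifelse(is.na(out$fst_wd), 0, out$fst_wd),
                        ifelse(is.na(out$fst_wo), 0, out$fst_wo),
                        ifelse(is.na(out$fst_do), 0, out$fst_do))
  out$lsbl_domestic <- lsbl(ifelse(is.na(out$fst_wd), 0, out$fst_wd),
                            ifelse(is.na(out$fst_do), 0, out$fst_do),
                            ifelse(is.na(out$fst_wo), 0, out$fst_wo))
  out$pi_ratio <- out$pi_wild / out$pi_domestic
  out
}

#' Call sweeps as top-quantile windows
#'
#' Selects windows whose statistic reaches the empirical quantile and
#' merges overlapping or adjacent selected windows.
#'
#' @param windows data.frame of window statistics (needs `start`, `end`).
#' @param statistic column name to threshold on.
#' @param quantile_cut empirical quantile (default 0.99).
#' @return list of class `dc_sweepset`: `regions` (merged data.frame),
#'   `threshold`, `statistic`, `quantile`.
#' @export
call_sweeps <- function(windows, statistic = "lsbl_domestic",
                        quantile_cut = 0.99) {
  v <- windows[[statistic]]
  if (all(is.na(v))) stop("statistic is missing in every window")
  if (sum(!is.na(v)) < 10) stop("need >= 10 non-missing windows")
  thr <- quantile(v, quantile_cut, na.rm = TRUE, names = FALSE)
  sel <- which(!is.na(v) & v >= thr)
  regions <- if (length(sel))
    merge_intervals(new_intervals(windows$start[sel], windows$end[sel]))
  else data.frame(start = integer(), end = integer())
  structure(list(regions = regions, threshold = thr, statistic = statistic,
                 quantile = quantile_cut),
            class = "dc_sweepset")
}

#' @exportS3Method base::print
print.dc_sweepset <- function(x, ...) {
  cat(sprintf("Sweep set: %d region(s), %s >= %.4g (quantile %.2f)\n",
              nrow(x$regions), x$statistic, x$threshold, x$quantile))
  invisible(x)
}

#' hSNP density and frequency inside versus outside sweeps
#'
#' Compares the density (per Mb) and the mean derived allele frequency of
#' hSNPs inside sweep regions with the rest of the contig.  The null is
#' built by relocating each sweep region uniformly at random along the
#' contig (lengths preserved) `n_perm` times; the two-sided empirical
#' p-value is `(k + 1) / (n_perm + 1)`.
#'
#' @param sweeps a `dc_sweepset`.
#' @param hsnp_pos 0-based positions of hSNP sites.
#' @param hsnp_freq derived allele frequencies per hSNP site (optional,
#'   for the frequency contrast).
#' @param contig_length contig length (bp).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list: densities, frequency means, permutation p-values, seed.
#' @export
sweep_load_contrast <- function(sweeps, hsnp_pos, hsnp_freq = NULL,
                                contig_length, n_perm = 1000L, seed = 1L) {
  reg <- sweeps$regions
  inside_bp <- total_length(reg)
  if (inside_bp == 0) stop("sweep set is empty; contrast undefined")
  outside_bp <- contig_length - inside_bp
  degenerate <- outside_bp <= 0
  inside <- positions_in_intervals(hsnp_pos, reg)

  dens <- function(n, bp) if (bp > 0) n / bp * 1e6 else NA_real_
  obs_density_in <- dens(sum(inside), inside_bp)
  obs_density_out <- dens(sum(!inside), outside_bp)
  obs_freq_in <- if (!is.null(hsnp_freq) && any(inside))
    mean(hsnp_freq[inside]) else NA_real_
  obs_freq_out <- if (!is.null(hsnp_freq) && any(!inside))
    mean(hsnp_freq[!inside]) else NA_real_

  p_density <- p_freq <- NA_real_
  if (!degenerate && length(hsnp_pos)) {
    set.seed(seed)
    lens <- reg$end - reg$start
    k_dens <- 0L; k_freq <- 0L; n_freq_valid <- 0L
    obs_d <- obs_density_in - ifelse(is.na(obs_density_out), 0, obs_density_out)
    obs_f <- obs_freq_in - obs_freq_out
    for (b in seq_len(n_perm)) {
      starts <- floor(runif(length(lens)) * (contig_length - lens))
      prm <- merge_intervals(new_intervals(as.integer(starts),
                                           as.integer(starts + lens)))
      pin <- positions_in_intervals(hsnp_pos, prm)
      pbp <- total_length(prm)
      d <- dens(sum(pin), pbp) - dens(sum(!pin), contig_length - pbp)
      if (abs(d) >= abs(obs_d)) k_dens <- k_dens + 1L
      if (!is.null(hsnp_freq) && any(pin) && any(!pin) && !is.na(obs_f)) {
        f <- mean(hsnp_freq[pin]) - mean(hsnp_freq[!pin])
        n_freq_valid <- n_freq_valid + 1L
        if (abs(f) >= abs(obs_f)) k_freq <- k_freq + 1L
      }
    }
    p_density <- (k_dens + 1) / (n_perm + 1)
    if (!is.null(hsnp_freq) && n_freq_valid > 0)
      p_freq <- (k_freq + 1) / (n_freq_valid + 1)
  } else if (degenerate) {
    p_density <- 1
    warning("sweep regions cover the whole contig; permutation degenerate")
  }
  list(density_inside_per_mb = obs_density_in,
       density_outside_per_mb = obs_density_out,
       mean_freq_inside = obs_freq_in, mean_freq_outside = obs_freq_out,
       p_density = p_density, p_freq = p_freq,
       n_perm = n_perm, seed = seed, degenerate = degenerate)
}
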