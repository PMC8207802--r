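# Shared fixture builders: all synthetic, generated in code.

# neutral single-population configuration (theta = 4*N*mu per site)
neutral_config <- function(seed, N = 200L, L = 50000L, theta = 0.002,
                           burnin_factor = 10, rec = 1e-6) {
  dem <- demography_truth(N_anc = N, t_split = 0, epochs1 = NULL,
                          epochs2 = NULL)
  simulation_config(contig_length_bp = L, coding_fraction = 0,
                    mu = theta / (4 * N), rec_rate = rec, dfe_mean_s = 0,
                    demography = dem,
                    sample_sizes = c(wild = 10L, domestic = 0L),
                    n_outgroup = 0L, outgroup_divergence = 0,
                    mask_fraction = 0, burnin_factor = burnin_factor,
                    seed = seed)
}

sample_pi <- function(sim) {
  H <- sim$haplotypes
  n <- ncol(H)
  a <- rowSums(H)
  sum(2 * a * (n - a) / (n * (n - 1))) / sim$config$contig_length_bp
}

# tiny deterministic layout with one plus- and one minus-strand gene
toy_layout <- function(seq = NULL) {
  if (is.null(seq)) {
    set.seed(42)
    seq <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  }
  structure(list(contig = "toy", contig_length = length(seq),
                 reference = seq,
                 cds = data.frame(start = c(30L, 150L), end = c(90L, 210L),
                                  strand = c("+", "-"),
                                  gene_id = c("gplus", "gminus")),
                 masks = data.frame(start = integer(), end = integer()),
                 seed = 42L),
            class = "dc_layout")
}

# brute-force effect oracle: translate the whole CDS before and after the
# substitution with Biostrings and compare proteins
oracle_effect <- function(pos, alt, layout) {
  cds <- layout$cds
  gi <- NA
  for (g in seq_len(nrow(cds)))
    if (pos >= cds$start[g] && pos < cds$end[g]) gi <- g
  if (is.na(gi)) return("noncoding")
  translate_gene <- function(reference) {
    seq <- paste(reference[(cds$start[gi] + 1):cds$end[gi]], collapse = "")
    dna <- Biostrings::DNAString(seq)
    if (cds$strand[gi] == "-") dna <- Biostrings::reverseComplement(dna)
    as.character(Biostrings::translate(dna, no.init.codon = TRUE))
  }
  p0 <- translate_gene(layout$reference)
  mutated <- layout$reference
  mutated[pos + 1] <- alt
  p1 <- translate_gene(mutated)
  if (p1 == p0) return("synonymous")
  diff <- which(strsplit(p1, "")[[1]] != strsplit(p0, "")[[1]])
  if (any(strsplit(p1, "")[[1]][diff] == "*")) "nonsense" else "missense"
}

# exact two-sided rank-sum p by full enumeration of label assignments
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  r <- rank(pooled)
  u_of <- function(sel) sum(r[sel]) - length(a) * (length(a) + 1) / 2
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_along(a))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
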