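# Synthetic genome layout: reference sequence, CDS annotation, masks, and
# the per-site codon-effect lookup used by both the simulator and the
# annotation oracle tests.

BASES <- c("A", "C", "G", "T")

# codon id = b1*16 + b2*4 + b3 with A=0, C=1, G=2, T=3 (transcript strand)
codon_aa_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  ids <- expand.grid(b3 = 0:3, b2 = 0:3, b1 = 0:3)   # varies b3 fastest
  codons <- paste0(BASES[ids$b1 + 1], BASES[ids$b2 + 1], BASES[ids$b3 + 1])
  aa <- unname(gc[codons])
  ord <- ids$b1 * 16 + ids$b2 * 4 + ids$b3
  out <- character(64)
  out[ord + 1] <- aa
  out
}

#' Build a synthetic genome layout
#'
#' Places equally sized, non-overlapping protein-coding genes (CDS length a
#' multiple of 3, random strand) so that the total CDS fraction matches
#' `coding_fraction` to within half a percentage point, draws a random
#' reference sequence, and adds repeat/low-complexity-style mask intervals
#' outside the CDS.  Deterministic given the configuration seed.
#'
#' @param config a `dc_simconfig`.
#' @param gene_length_target approximate CDS length per gene in bp.
#' @return object of class `dc_layout`: list with `contig`,
#'   `contig_length`, `reference` (character vector of bases), `cds`
#'   (data.frame: start, end, strand, gene_id; 0-based half-open), `masks`
#'   (data.frame start/end) and `seed`.
#' @export
build_genome_layout <- function(config, gene_length_target = 1200L) {
  L <- config$contig_length_bp
  if (L < 3000) stop("contig too short to lay out genes (need >= 3000 bp)")
  set.seed(derive_seed(config$seed, "layout"))
  reference <- sample(BASES, L, replace = TRUE)

  cds <- data.frame(start = integer(), end = integer(), strand = character(),
                    gene_id = character())
  target <- round(L * config$coding_fraction)
  if (config$coding_fraction > 0) {
    n_genes <- max(1L, round(target / gene_length_target))
    per_gene_codons <- floor(target / n_genes / 3)
    if (per_gene_codons < 2)
      stop("coding fraction too small to place a codon-multiple CDS")
    glen <- rep(per_gene_codons * 3L, n_genes)
    # distribute the remainder in whole codons to stay within 0.5 pp
    rem <- floor((target - sum(glen)) / 3)
    if (rem > 0) glen[seq_len(min(rem, n_genes))] <-
        glen[seq_len(min(rem, n_genes))] + 3L
    # equally spaced gene starts with uniform jitter inside each slot
    slot <- floor(L / n_genes)
    if (any(glen >= slot)) stop("contig too short for the requested genes")
    jitter <- floor(runif(n_genes) * (slot - glen))
    starts <- (seq_len(n_genes) - 1L) * slot + jitter
    cds <- data.frame(
      start = as.integer(starts), end = as.integer(starts + glen),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      gene_id = sprintf("gene%03d", seq_len(n_genes)))
  }

  masks <- data.frame(start = integer(), end = integer())
  if (config$mask_fraction > 0) {
    free <- complement_intervals(cds[c("start", "end")], L)
    free <- free[free$end - free$start >= 400, , drop = FALSE]
    want <- round(L * config$mask_fraction)
    picks <- free[sample(nrow(free)), , drop = FALSE]
    got <- 0L; ms <- integer(); me <- integer()
    for (k in seq_len(nrow(picks))) {
      if (got >= want) break
      w <- min(picks$end[k] - picks$start[k] - 200L, want - got, 2000L)
      if (w < 100) next
      s0 <- picks$start[k] + 100L
      ms <- c(ms, s0); me <- c(me, s0 + w)
      got <- got + w
    }
    if (length(ms)) masks <- merge_intervals(new_intervals(ms, me))
  }

  structure(list(contig = "sim_contig", contig_length = L,
                 reference = reference, cds = cds, masks = masks,
                 seed = config$seed),
            class = "dc_layout")
}

#' @exportS3Method base::print
print.dc_layout <- function(x, ...) {
  cat(sprintf("Genome layout '%s': %d bp, %d CDS (%.2f%% coding), %d masks\n",
              x$contig, x$contig_length, nrow(x$cds),
              100 * total_length(x$cds) / x$contig_length, nrow(x$masks)))
  invisible(x)
}

# Integer-coded reference (A=0..T=3)
reference_codes <- function(layout) {
  match(layout$reference, BASES) - 1L
}

# For every site and each of the three possible alternate bases (ordered by
# base, skipping the reference base), the coding-effect class:
# 0 noncoding, 1 synonymous, 2 missense, 3 nonsense.  Returned as a raw
# matrix 3 x L consumed by the simulator core.
effect_lookup <- function(layout) {
  L <- layout$contig_length
  aa_tab <- codon_aa_table()
  refc <- reference_codes(layout)
  eff <- matrix(raw(1), nrow = 3, ncol = L)
  if (nrow(layout$cds) == 0) return(eff)

  comp <- c(3L, 2L, 1L, 0L)                 # A<->T, C<->G on integer codes
  for (g in seq_len(nrow(layout$cds))) {
    s <- layout$cds$start[g]; e <- layout$cds$end[g]
    minus <- layout$cds$strand[g] == "-"
    pos <- s:(e - 1)
    gseq <- refc[pos + 1]
    tseq <- if (minus) rev(comp[gseq + 1]) else gseq       # transcript strand
    off <- seq_along(tseq) - 1L
    cidx <- off %/% 3L                       # codon index
    cpos <- off %% 3L                        # position within codon
    base1 <- tseq[cidx * 3L + 1L]
    base2 <- tseq[cidx * 3L + 2L]
    base3 <- tseq[cidx * 3L + 3L]
    cid <- base1 * 16L + base2 * 4L + base3
    ref_aa <- aa_tab[cid + 1L]
    mult <- 4L^(2L - cpos)
    tref <- tseq                             # transcript-strand ref base
    # genome position of each transcript offset
    gpos <- if (minus) rev(pos) else pos
    ALT <- rbind(c(1L, 2L, 3L), c(0L, 2L, 3L), c(0L, 1L, 3L), c(0L, 1L, 2L))
    for (slot in 1:3) {
      # slot-th alternate base in genome-strand order
      galt <- ALT[cbind(refc[gpos + 1] + 1L, slot)]
      talt <- if (minus) comp[galt + 1] else galt
      cid_alt <- cid + (talt - tref) * mult
      alt_aa <- aa_tab[cid_alt + 1L]
      cls <- ifelse(alt_aa == ref_aa, 1L,
                    ifelse(alt_aa == "*", 3L, 2L))
      eff[slot, gpos + 1] <- as.raw(cls)
    }
  }
  eff
}
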