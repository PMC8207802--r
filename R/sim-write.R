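# Serialisation of a simulated dataset to the standard formats.

#' Write a simulated dataset to disk
#'
#' Emits the reference FASTA, CDS annotation (GFF3), mask intervals (BED),
#' genotypes of the focal populations plus outgroup (VCF v4.2, phased GT,
#' INFO/AA carrying the true ancestral allele), a population map TSV and a
#' truth table TSV with the per-site simulated class and selection
#' coefficient.
#'
#' @param sim a `dc_simdata` from [simulate_two_population()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_outputs <- function(sim, out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  layout <- sim$layout
  paths <- c(
    fasta = file.path(out_dir, "reference.fa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    bed = file.path(out_dir, "masks.bed"),
    vcf = file.path(out_dir, "genotypes.vcf"),
    popmap = file.path(out_dir, "popmap.tsv"),
    truth = file.path(out_dir, "truth.tsv"))

  dna <- Biostrings::DNAStringSet(paste(layout$reference, collapse = ""))
  names(dna) <- layout$contig
  Biostrings::writeXStringSet(dna, paths["fasta"])

  if (nrow(layout$cds)) {
    gr <- GenomicRanges::GRanges(
      seqnames = layout$contig,
      ranges = IRanges::IRanges(start = layout$cds$start + 1L,
                                end = layout$cds$end),
      strand = layout$cds$strand)
    gr$type <- "CDS"
    gr$source <- "domcost"
    gr$phase <- 0L
    gr$ID <- layout$cds$gene_id
    rtracklayer::export(gr, paths["gff3"], format = "gff3")
  } else {
    writeLines("##gff-version 3", paths["gff3"])
  }

  write_bed(paths["bed"], layout$contig, layout$masks)

  # VCF: REF = ancestral base; ALT = derived base plus, where the outgroup
  # carries a third state, that base
  sites <- sim$sites
  S <- nrow(sites)
  n_focal_hap <- ncol(sim$haplotypes)
  n_out <- sim$config$n_outgroup
  alt <- vector("list", S)
  out_allele <- integer(S)                 # allele index of the outgroup base
  if (S > 0) for (r in seq_len(S)) {
    alt[[r]] <- sites$derived[r]
    out_allele[r] <- if (sites$outgroup_code[r] == 0) 0L
      else if (sites$outgroup_code[r] == 1) 1L
      else {
        third <- setdiff(BASES, c(sites$ref[r], sites$derived[r]))[1]
        alt[[r]] <- c(sites$derived[r], third)
        2L
      }
  }
  geno_alleles <- cbind(
    if (S > 0) sim$haplotypes else matrix(integer(), 0, n_focal_hap),
    matrix(rep(out_allele, 2 * n_out), nrow = S))
  info <- if (S > 0)
    sprintf("AA=%s;EFF=%s;SELS=%g", sites$ref, sites$class, sites$s)
  else character(0)
  write_vcf(paths["vcf"], layout$contig, layout$contig_length,
            pos = sites$pos, ref = sites$ref, alt = alt,
            geno_alleles = geno_alleles,
            sample_ids = sim$samples$sample_id, info = info)

  write.table(sim$samples, paths["popmap"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sites
  truth$config_seed <- rep(sim$config$seed, nrow(sites))
  truth$rescale_Q <- rep(sim$config$rescale_Q, nrow(sites))
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
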