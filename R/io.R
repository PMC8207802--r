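# Format readers and writers.  All conversions between the package's
# 0-based half-open coordinates and the 1-based conventions of VCF/GFF3
# happen here and in sim-write.R, nowhere else.

#' Read a population map
#'
#' @param path TSV with columns `sample_id` and `population`.
#' @return data.frame.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(pm)))
    stop("population map needs columns sample_id and population")
  pm
}

#' Read genotypes from a VCF
#'
#' Retains bi-allelic SNVs; multi-allelic SNV records are split into one
#' row per alternate allele (sharing the position).  Genotypes are coded
#' as alternate-allele dosage 0/1/2 (NA missing; for split records the
#' dosage counts that alternate only, and a third allele at the site
#' appears as dosage code 3 so polarization can flag it).  VCF positions
#' are converted to internal 0-based coordinates.
#'
#' @param path VCF file (plain text or gzipped).
#' @param popmap optional population map data.frame; sample columns are
#'   checked against it.
#' @return list: `variants` (data.frame contig, pos, ref, alt, aa), `geno`
#'   (integer matrix sites x samples), `samples` (data.frame).
#' @export
read_vcf <- function(path, popmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  if (!is.null(popmap)) {
    missing <- setdiff(samples, popmap$sample_id)
    if (length(missing))
      stop("samples absent from the population map: ",
           paste(missing, collapse = ", "))
  }
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0) {
    return(list(
      variants = data.frame(contig = character(), pos = integer(),
                            ref = character(), alt = character(),
                            aa = character()),
      geno = matrix(integer(), 0, length(samples),
                    dimnames = list(NULL, samples)),
      samples = data.frame(sample_id = samples,
                           population = if (is.null(popmap)) NA_character_
                           else popmap$population[match(samples,
                                                        popmap$sample_id)])))
  }
  aa <- rep(NA_character_, n_rec)
  info <- fix$INFO
  has_aa <- grepl("(^|;)AA=", info)
  aa[has_aa] <- sub(".*(?:^|;)AA=([^;]+).*", "\\1", info[has_aa])

  gt_raw <- v@gt[, -1, drop = FALSE]
  gt_field <- sub(":.*", "", gt_raw)               # GT is the first key
  a1 <- substr(gt_field, 1, 1)
  sep <- substr(gt_field, 2, 2)
  a2 <- substr(gt_field, 3, 3)
  bad <- !(sep %in% c("/", "|")) & gt_field != "."
  if (any(bad))
    stop("malformed GT at record(s): ",
         paste(head(which(rowSums(matrix(bad, n_rec)) > 0)), collapse = ", "))

  rows <- list(); genos <- list()
  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    snv <- nchar(fix$REF[r]) == 1 & nchar(alts) == 1 & alts != "*"
    if (!any(snv)) next
    for (ai in which(snv)) {
      g1 <- a1[r, ]; g2 <- a2[r, ]
      ok <- c("0", as.character(ai))
      d <- ifelse(g1 == "." | g2 == "", NA_integer_,
                  (g1 == ai) + (g2 == ai))
      # a called allele that is neither REF nor this ALT: flag with code 3
      third <- !is.na(d) & (!(g1 %in% ok) | !(g2 %in% ok))
      d[third] <- 3L
      rows[[length(rows) + 1]] <- data.frame(
        contig = fix$CHROM[r], pos = as.integer(fix$POS[r]) - 1L,
        ref = fix$REF[r], alt = alts[ai], aa = aa[r],
        stringsAsFactors = FALSE)
      genos[[length(genos) + 1]] <- d
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows)
              else data.frame(contig = character(), pos = integer(),
                              ref = character(), alt = character(),
                              aa = character())
  geno <- if (length(genos))
    matrix(unlist(genos), ncol = length(samples), byrow = TRUE,
           dimnames = list(NULL, samples))
  else matrix(integer(), 0, length(samples), dimnames = list(NULL, samples))
  list(variants = variants, geno = geno,
       samples = data.frame(
         sample_id = samples,
         population = if (is.null(popmap)) NA_character_
         else popmap$population[match(samples, popmap$sample_id)]))
}

#' Write a VCF v4.2
#'
#' @param path output file.
#' @param contig,contig_length contig name and length for the header.
#' @param pos 0-based positions (written 1-based).
#' @param ref,alt reference and alternate alleles; `alt` may be a list for
#'   multi-allelic records.
#' @param geno_alleles integer matrix pairs: 2 columns per sample
#'   (haplotype allele indexes), or NULL.
#' @param sample_ids sample names matching the genotype columns.
#' @param info character vector of INFO strings (optional).
#' @return the path, invisibly.
#' @export
write_vcf <- function(path, contig, contig_length, pos, ref, alt,
                      geno_alleles = NULL, sample_ids = NULL, info = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, as.integer(contig_length)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect class\">",
    "##INFO=<ID=DSCORE,Number=1,Type=Float,Description=\"Alignment delta score\">",
    "##INFO=<ID=HSNP,Number=0,Type=Flag,Description=\"High-impact SNP\">",
    "##INFO=<ID=SELS,Number=1,Type=Float,Description=\"True selection coefficient (simulated data)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"), con)
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(geno_alleles)) header <- c(header, "FORMAT", sample_ids)
  writeLines(paste(header, collapse = "\t"), con)
  if (length(pos) == 0) return(invisible(path))
  alt_str <- if (is.list(alt)) vapply(alt, paste, "", collapse = ",") else alt
  info_str <- if (is.null(info)) "." else info
  for (r in seq_along(pos)) {
    fields <- c(contig, pos[r] + 1L, ".", ref[r], alt_str[r], ".", "PASS",
                info_str[r])
    if (!is.null(geno_alleles)) {
      g <- geno_alleles[r, ]
      gt <- paste(g[c(TRUE, FALSE)], g[c(FALSE, TRUE)], sep = "|")
      gt[is.na(g[c(TRUE, FALSE)])] <- "./."
      fields <- c(fields, "GT", gt)
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read CDS annotation from GFF3
#'
#' @param path GFF3 file.
#' @return data.frame `start`, `end` (0-based half-open), `strand`,
#'   `gene_id`.
#' @export
read_cds_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             gene_id = as.character(gr$ID),
             stringsAsFactors = FALSE)
}

#' Read intervals from BED
#'
#' @param path BED file (0-based half-open on disk).
#' @return data.frame `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

write_bed <- function(path, contig, intervals) {
  if (nrow(intervals) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- data.frame(contig, intervals$start, intervals$end)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a joint SFS as a plain-text matrix
#'
#' @param sfs a `dc_jsfs`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# joint SFS n1=%d n2=%d masked=(0,0),(%d,%d) total_bp=%s",
                     sfs$n1, sfs$n2, sfs$n1, sfs$n2,
                     format(sfs$provenance$total_bp)), con)
  write.table(sfs$counts, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a joint SFS written by [write_sfs()]
#'
#' @param path file path.
#' @return a `dc_jsfs`.
#' @export
read_sfs <- function(path) {
  hdr <- readLines(path, n = 1)
  n1 <- as.integer(sub(".*n1=(\\d+).*", "\\1", hdr))
  n2 <- as.integer(sub(".*n2=(\\d+).*", "\\1", hdr))
  bp <- suppressWarnings(as.numeric(sub(".*total_bp=([^ ]+).*", "\\1", hdr)))
  m <- as.matrix(read.table(path, skip = 1))
  dimnames(m) <- NULL
  new_jsfs(m, n1, n2, provenance = list(total_bp = bp))
}
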