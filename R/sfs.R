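# Building the two-population joint SFS from polarized genotypes.

#' Construct a joint SFS object
#'
#' Low-level constructor; most users will call [joint_sfs()].
#'
#' @param counts (n1+1) x (n2+1) matrix of site counts indexed by derived
#'   allele count in each population (0-based).
#' @param n1,n2 haploid sample sizes.
#' @param provenance list describing the regions behind the spectrum
#'   (`n_regions`, `total_bp`); an `id` hash is added if absent.
#' @param sites optional per-site records (data.frame with `i`, `j`,
#'   `region`) enabling the region bootstrap.
#' @return object of class `dc_jsfs`.
#' @export
new_jsfs <- function(counts, n1, n2, provenance = list(), sites = NULL) {
  stopifnot(nrow(counts) == n1 + 1, ncol(counts) == n2 + 1)
  if (is.null(provenance$total_bp)) provenance$total_bp <- NA_real_
  if (is.null(provenance$id))
    provenance$id <- paste0("sfs-", paste(dim(counts), collapse = "x"), "-",
                            signif(sum(counts, na.rm = TRUE), 10))
  structure(list(counts = counts, n1 = n1, n2 = n2,
                 provenance = provenance, sites = sites),
            class = "dc_jsfs")
}

#' @exportS3Method base::print
print.dc_jsfs <- function(x, ...) {
  cat(sprintf("Joint SFS: %d x %d haploid samples, %g polymorphic sites\n",
              x$n1, x$n2, sum(x$counts[-c(1, length(x$counts))], na.rm = TRUE)))
  if (!is.null(x$provenance$n_regions))
    cat(sprintf("  regions: %d (%g bp)\n", x$provenance$n_regions,
                x$provenance$total_bp))
  invisible(x)
}

#' Putatively neutral regions from a genome layout
#'
#' Complements the coding annotation and any masks within the contig,
#' splits at the removed segments and drops fragments shorter than
#' `min_len`.
#'
#' @param layout a genome layout (see [build_genome_layout()]) or a list
#'   with `contig_length`, `cds`, `masks` interval data.frames.
#' @param extra_masks optional additional interval data.frame
#'   (`start`/`end`, 0-based half-open).
#' @param min_len minimum retained region length in bp.
#' @return data.frame of regions (`start`, `end`) with attributes
#'   `n_regions` and `total_bp`.
#' @export
build_neutral_mask <- function(layout, extra_masks = NULL, min_len = 1000L) {
  excl <- rbind(layout$cds[c("start", "end")], layout$masks[c("start", "end")])
  if (!is.null(extra_masks)) excl <- rbind(excl, extra_masks[c("start", "end")])
  regions <- complement_intervals(
    if (nrow(excl)) merge_intervals(new_intervals(excl$start, excl$end))
    else excl,
    layout$contig_length)
  regions <- regions[regions$end - regions$start >= min_len, , drop = FALSE]
  if (nrow(regions) == 0)
    stop("no neutral regions of length >= ", min_len,
         " bp; consider a smaller min_len")
  rownames(regions) <- NULL
  attr(regions, "n_regions") <- nrow(regions)
  attr(regions, "total_bp") <- total_length(regions)
  regions
}

#' Joint site frequency spectrum from polarized derived counts
#'
#' Tallies polymorphic sites by derived allele count in two populations.
#' Sites that are unpolarized, outside `regions`, or (in the default
#' strict mode) genotyped in fewer than the full set of alleles are
#' excluded; alternatively sites are projected down to (n1, n2) by the
#' hypergeometric expectation.
#'
#' @param derived1,derived2 integer vectors: derived allele count per site
#'   in population 1 and 2 (NA = unpolarized site).
#' @param called1,called2 called allele totals per site.
#' @param n1,n2 haploid sample sizes of the spectrum.
#' @param pos optional 0-based site positions (required with `regions`).
#' @param regions optional region set (from [build_neutral_mask()]);
#'   sites outside are dropped and region ids are recorded per site for
#'   the block bootstrap.
#' @param projection if `TRUE`, sites with more called alleles than
#'   (n1, n2) are projected down hypergeometrically; otherwise only sites
#'   with exactly (n1, n2) called alleles are used.
#' @return a `dc_jsfs` object.
#' @export
joint_sfs <- function(derived1, derived2, called1, called2, n1, n2,
                      pos = NULL, regions = NULL, projection = FALSE) {
  stopifnot(length(derived1) == length(derived2))
  keep <- !is.na(derived1) & !is.na(derived2)
  region_id <- rep(NA_integer_, length(derived1))
  if (!is.null(regions)) {
    if (is.null(pos)) stop("regions given but no site positions")
    region_id <- interval_index_of(pos, regions)
    keep <- keep & !is.na(region_id)
  }
  counts <- matrix(0, n1 + 1, n2 + 1)
  sites <- NULL
  if (any(keep)) {
    d1 <- derived1[keep]; d2 <- derived2[keep]
    c1 <- called1[keep]; c2 <- called2[keep]
    rg <- region_id[keep]
    if (!projection) {
      full <- c1 == n1 & c2 == n2
      d1 <- d1[full]; d2 <- d2[full]; rg <- rg[full]
      if (length(d1)) {
        poly <- !(d1 == 0 & d2 == 0) & !(d1 == n1 & d2 == n2)
        d1 <- d1[poly]; d2 <- d2[poly]; rg <- rg[poly]
        for (s in seq_along(d1))
          counts[d1[s] + 1, d2[s] + 1] <- counts[d1[s] + 1, d2[s] + 1] + 1
        sites <- data.frame(i = d1, j = d2, region = rg)
      }
    } else {
      ok <- c1 >= n1 & c2 >= n2
      d1 <- d1[ok]; d2 <- d2[ok]; c1 <- c1[ok]; c2 <- c2[ok]; rg <- rg[ok]
      proj <- function(d, cc, n) {
        # expected count distribution of a hypergeometric draw of n from cc
        vapply(0:n, function(i) stats::dhyper(i, d, cc - d, n), 0)
      }
      for (s in seq_along(d1)) {
        w <- outer(proj(d1[s], c1[s], n1), proj(d2[s], c2[s], n2))
        counts <- counts + w
      }
      sites <- if (length(d1))
        data.frame(i = pmin(d1, n1), j = pmin(d2, n2), region = rg) else NULL
      counts[1, 1] <- 0
      counts[n1 + 1, n2 + 1] <- 0
    }
  }
  prov <- list(
    n_regions = if (!is.null(regions)) attr(regions, "n_regions") else NA,
    total_bp = if (!is.null(regions)) attr(regions, "total_bp") else NA_real_)
  new_jsfs(counts, n1, n2, provenance = prov, sites = sites)
}
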