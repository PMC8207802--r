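# Variant annotation: codon-aware coding-effect classification, the
# alignment-based deleteriousness (delta) score, the hSNP threshold rule,
# and ancestral-allele polarization against the outgroup.

#' Classify the coding effect of single-nucleotide variants
#'
#' Translates the affected codon on the annotated strand with the standard
#' genetic code: silent changes are `synonymous`, amino-acid changes
#' `missense`, stop gains `nonsense`; variants outside every CDS are
#' `noncoding`.  Stop-loss changes are grouped with `missense`.
#'
#' @param pos integer vector of 0-based variant positions.
#' @param alt character vector of alternate bases (genome strand).
#' @param layout a `dc_layout` (see [build_genome_layout()]).
#' @return data.frame with `effect`, `gene_id`, `aa_ref`, `aa_alt`
#'   (amino acids NA outside CDS).
#' @export
classify_coding_effect <- function(pos, alt, layout) {
  stopifnot(length(pos) == length(alt))
  refc <- reference_codes(layout)
  altc <- match(toupper(alt), BASES) - 1L
  if (anyNA(altc)) stop("alternate alleles must be single bases A/C/G/T")
  if (any(pos < 0 | pos >= layout$contig_length))
    stop("variant position beyond the contig")
  if (any(altc == refc[pos + 1]))
    stop("alternate allele equals the reference base at some sites")

  out <- data.frame(effect = rep("noncoding", length(pos)),
                    gene_id = NA_character_,
                    aa_ref = NA_character_, aa_alt = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(layout$cds) == 0) return(out)
  cds <- layout$cds[order(layout$cds$start), , drop = FALSE]
  gi <- interval_index_of(pos, cds[c("start", "end")])
  hit <- which(!is.na(gi))
  if (!length(hit)) return(out)

  aa_tab <- codon_aa_table()
  comp <- c(3L, 2L, 1L, 0L)
  for (k in hit) {
    g <- gi[k]
    s <- cds$start[g]; e <- cds$end[g]
    minus <- cds$strand[g] == "-"
    off <- if (minus) (e - 1L - pos[k]) else (pos[k] - s)
    cpos <- off %% 3L
    c0 <- off - cpos                       # transcript offset of codon start
    # transcript offsets c0..c0+2 -> genome positions
    gpos <- if (minus) e - 1L - (c0 + 0:2) else s + c0 + 0:2
    tref <- refc[gpos + 1]
    if (minus) tref <- comp[tref + 1]
    cid <- tref[1] * 16L + tref[2] * 4L + tref[3]
    talt <- if (minus) comp[altc[k] + 1] else altc[k]
    cid_alt <- cid + (talt - tref[cpos + 1]) * 4L^(2L - cpos)
    aa_r <- aa_tab[cid + 1L]; aa_a <- aa_tab[cid_alt + 1L]
    out$effect[k] <- if (aa_a == aa_r) "synonymous"
                     else if (aa_a == "*") "nonsense" else "missense"
    out$gene_id[k] <- cds$gene_id[g]
    out$aa_ref[k] <- aa_r
    out$aa_alt[k] <- aa_a
  }
  out
}

#' Translate a CDS from the layout reference
#'
#' @param layout a `dc_layout`.
#' @param gene_id gene identifier in the layout.
#' @return `Biostrings::AAString` of the protein (stops included as `*`).
#' @export
gene_protein <- function(layout, gene_id) {
  g <- layout$cds[layout$cds$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1) stop("unknown gene_id: ", gene_id)
  seq <- paste(layout$reference[(g$start + 1):g$end], collapse = "")
  dna <- Biostrings::DNAString(seq)
  if (g$strand == "-") dna <- Biostrings::reverseComplement(dna)
  Biostrings::translate(dna, no.init.codon = TRUE)
}

#' Delta-score model configuration
#'
#' @param matrix_name substitution matrix name (default BLOSUM62).
#' @param gap_opening,gap_extension affine gap penalties (positive costs).
#' @param threshold deleteriousness threshold; scores at or below it flag
#'   a variant as high-impact (hSNP).
#' @return list of class `dc_deltamodel`.
#' @export
delta_score_model <- function(matrix_name = "BLOSUM62", gap_opening = 10,
                              gap_extension = 1, threshold = -2.5) {
  mat <- get_subst_matrix(matrix_name)
  structure(list(matrix_name = matrix_name, matrix = mat,
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 threshold = threshold),
            class = "dc_deltamodel")
}

get_subst_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix must be symmetric")
  m
}

semi_global_score <- function(query, subject, model) {
  # free end gaps on the homolog (subject): pattern is aligned globally,
  # the subject locally
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(subject),
    type = "global-local",
    substitutionMatrix = model$matrix,
    gapOpening = model$gap_opening,
    gapExtension = model$gap_extension,
    scoreOnly = TRUE)
}

#' Alignment delta score of an amino-acid substitution
#'
#' For each homolog, aligns the variant protein and the reference protein
#' (semi-global affine alignment, free end gaps on the homolog side) and
#' takes the score difference; the returned value is the mean over the
#' homolog set.  Conserved positions yield strongly negative deltas.
#'
#' @param ref_protein reference protein sequence (character or AAString).
#' @param substitution list or vector `(pos, aa_ref, aa_alt)`; `pos` is the
#'   1-based residue index.
#' @param homologs character vector of homolog protein sequences.
#' @param model a `dc_deltamodel`.
#' @return numeric delta score (0 when `aa_alt == aa_ref`).
#' @export
delta_score <- function(ref_protein, substitution, homologs,
                        model = delta_score_model()) {
  ref <- as.character(ref_protein)
  p <- as.integer(substitution[[1]])
  aa_ref <- as.character(substitution[[2]])
  aa_alt <- as.character(substitution[[3]])
  if (length(homologs) == 0) stop("homolog set must be non-empty")
  if (p < 1 || p > nchar(ref)) stop("substitution outside the protein")
  if (substr(ref, p, p) != aa_ref)
    stop("substitution inconsistent with the reference protein")
  ok_res <- c(strsplit("ACDEFGHIKLMNPQRSTVWY*", "")[[1]])
  if (!aa_alt %in% ok_res || !aa_ref %in% ok_res)
    stop("non-standard residue in substitution")
  if (aa_alt == aa_ref) return(0)
  var <- ref
  substr(var, p, p) <- aa_alt
  deltas <- vapply(homologs, function(h) {
    semi_global_score(var, h, model) - semi_global_score(ref, h, model)
  }, 0, USE.NAMES = FALSE)
  mean(deltas)
}

#' hSNP rule: is a score deleterious?
#'
#' @param score numeric delta scores.
#' @param threshold cutoff; scores at or below it are deleterious.
#' @return logical vector.
#' @export
classify_deleterious <- function(score, threshold = -2.5) {
  stopifnot(all(is.finite(score[!is.na(score)])))
  score <= threshold
}

#' Synthetic homolog set for delta scoring
#'
#' Generates diverged homologs by substituting residues of the reference
#' protein uniformly at random at a fixed per-residue rate.  This is a
#' synthetic stand-in for a database homolog search: it preserves the
#' score's alignment mechanics (conservation across the set) without any
#' external database.
#'
#' @param ref_protein protein sequence.
#' @param n number of homologs.
#' @param rate per-residue substitution probability.
#' @param seed integer seed.
#' @return character vector of homolog sequences.
#' @export
make_homologs <- function(ref_protein, n = 20L, rate = 0.05, seed = 1L) {
  ref <- strsplit(as.character(ref_protein), "")[[1]]
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    h <- ref
    flip <- which(runif(length(h)) < rate & h != "*")
    if (length(flip))
      h[flip] <- vapply(h[flip], function(a) sample(setdiff(aas, a), 1), "")
    paste(h, collapse = "")
  }, "")
}

#' Polarize variants against outgroup genotypes
#'
#' @param alt_dosage_outgroup integer matrix (sites x outgroup samples) of
#'   alternate-allele dosages 0/1/2, `NA` for missing, or code 3 where the
#'   outgroup carries a third allele.
#' @return character vector per site: `"ref"`, `"alt"` (the ancestral
#'   allele) or `NA` for unpolarized sites (outgroup polymorphic, missing,
#'   or carrying a third allele).
#' @export
polarize <- function(alt_dosage_outgroup) {
  apply(alt_dosage_outgroup, 1, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0 || any(g == 3)) return(NA_character_)
    if (all(g == 0)) return("ref")
    if (all(g == 2)) return("alt")
    NA_character_
  })
}

#' Chicken chromosome size classes
#'
#' @param chrom chromosome labels (numbers or `"chr"`-prefixed).
#' @param macro,intermediate,micro integer vectors defining the classes;
#'   chicken defaults: macro 1-5, intermediate 6-10, micro 11-38.
#' @return factor with levels macro/intermediate/micro/unassigned.
#' @export
chromosome_class <- function(chrom, macro = 1:5, intermediate = 6:10,
                             micro = 11:38) {
  num <- suppressWarnings(as.integer(sub("^chr", "", as.character(chrom))))
  cls <- ifelse(is.na(num), "unassigned",
         ifelse(num %in% macro, "macro",
         ifelse(num %in% intermediate, "intermediate",
         ifelse(num %in% micro, "micro", "unassigned"))))
  factor(cls, levels = c("macro", "intermediate", "micro", "unassigned"))
}

#' Annotate a variant table end to end
#'
#' Classifies coding effects, scores missense/nonsense variants with the
#' alignment delta score against per-gene synthetic homolog sets, applies
#' the hSNP threshold, and polarizes against the outgroup.
#'
#' @param pos,alt variant positions (0-based) and alternate bases.
#' @param layout a `dc_layout`.
#' @param outgroup optional outgroup dosage matrix for [polarize()].
#' @param model a `dc_deltamodel`.
#' @param homolog_n,homolog_rate synthetic homolog set parameters
#'   (see [make_homologs()]).
#' @param seed seed for homolog generation.
#' @return data.frame of `AnnotatedVariant` records: `pos`, `alt`,
#'   `effect`, `gene_id`, `aa_ref`, `aa_alt`, `delta`, `is_hsnp`,
#'   `ancestral` (`"ref"`/`"alt"`/NA).
#' @export
annotate_variants <- function(pos, alt, layout, outgroup = NULL,
                              model = delta_score_model(),
                              homolog_n = 20L, homolog_rate = 0.05,
                              seed = 1L) {
  eff <- classify_coding_effect(pos, alt, layout)
  out <- data.frame(pos = pos, alt = alt, effect = eff$effect,
                    gene_id = eff$gene_id, aa_ref = eff$aa_ref,
                    aa_alt = eff$aa_alt, delta = NA_real_,
                    is_hsnp = FALSE, stringsAsFactors = FALSE)
  scored <- which(out$effect %in% c("missense", "nonsense"))
  if (length(scored)) {
    prot_cache <- list()
    hom_cache <- list()
    for (k in scored) {
      gid <- out$gene_id[k]
      if (is.null(prot_cache[[gid]])) {
        prot_cache[[gid]] <- as.character(gene_protein(layout, gid))
        hom_cache[[gid]] <- make_homologs(prot_cache[[gid]], n = homolog_n,
                                          rate = homolog_rate,
                                          seed = derive_seed(seed, gid))
      }
      cds <- layout$cds[layout$cds$gene_id == gid, ]
      off <- if (cds$strand == "-") cds$end - 1L - out$pos[k]
             else out$pos[k] - cds$start
      res <- off %/% 3L + 1L
      out$delta[k] <- delta_score(prot_cache[[gid]],
                                  list(res, out$aa_ref[k], out$aa_alt[k]),
                                  hom_cache[[gid]], model)
    }
    out$is_hsnp[scored] <- classify_deleterious(out$delta[scored],
                                                model$threshold)
  }
  out$ancestral <- if (!is.null(outgroup)) polarize(outgroup)
                   else NA_character_
  out
}
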