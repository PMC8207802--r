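# End-to-end orchestration: simulate -> annotate -> load -> scan ->
# demography, with a run manifest of seeds and output checksums.

#' Assemble a pipeline configuration
#'
#' @param out_dir working directory for stage outputs.
#' @param seed root seed; every stage derives its own stream from it.
#' @param stages character vector of stages to run, in dependency order
#'   from `simulate`, `annotate`, `load`, `scan`, `demography`.
#' @param sim_config a `dc_simconfig` for the simulate stage.
#' @param window,step sweep-scan window geometry (bp).
#' @param sweep_statistic,sweep_quantile sweep-calling options.
#' @param models demographic models to fit.
#' @param fit_args extra arguments passed to [fit_demography()].
#' @param truth_annotation use the simulator's true classes and selection
#'   coefficients to define deleterious sites (fast) instead of the
#'   alignment delta score (full annotation).
#' @return list of class `dc_pipeconfig`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "annotate", "load",
                                       "scan", "demography"),
                            sim_config = NULL,
                            window = 50000L, step = 25000L,
                            sweep_statistic = "lsbl_domestic",
                            sweep_quantile = 0.99,
                            models = c("A", "B", "C", "D"),
                            fit_args = list(restarts = c(6L, 3L, 1L),
                                            maxit = c(100L, 200L, 400L),
                                            pts = 60L, steps = 30L),
                            truth_annotation = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(sim_config))
    sim_config <- rescale(simulation_config(seed = seed), 1000)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 sim_config = sim_config, window = window, step = step,
                 sweep_statistic = sweep_statistic,
                 sweep_quantile = sweep_quantile, models = models,
                 fit_args = fit_args, truth_annotation = truth_annotation),
            class = "dc_pipeconfig")
}

stage_outputs <- list(
  simulate = c("genotypes.vcf", "reference.fa", "genes.gff3", "masks.bed",
               "popmap.tsv", "truth.tsv"),
  annotate = "annotated.tsv",
  load = c("load_per_sample.tsv", "load_per_population.tsv",
           "load_comparisons.tsv"),
  scan = c("windows.tsv", "sweeps.bed", "sweep_contrast.tsv"),
  demography = c("sfs.txt", "fits.json"))

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order, failing fast with a
#' stage-attributed error when an upstream output is missing, and writes a
#' JSON manifest with per-stage seeds, wall-clock times and output
#' checksums.
#'
#' @param config a `dc_pipeconfig`.
#' @return the manifest list, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dc_pipeconfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(f) file.path(config$out_dir, f)
  need <- function(stage, files) {
    miss <- files[!file.exists(od(files))]
    if (length(miss))
      stop(sprintf("stage '%s' requires missing upstream output(s): %s",
                   stage, paste(miss, collapse = ", ")))
  }
  manifest <- list(tool = "domcost", version = "0.1.0",
                   seed = config$seed, stages = list())
  t_stage <- function(expr) {
    t0 <- Sys.time()
    force(expr)
    as.numeric(Sys.time() - t0, units = "secs")
  }

  for (stage in config$stages) {
    secs <- switch(stage,
      simulate = t_stage({
        sim <- simulate_two_population(config$sim_config)
        write_outputs(sim, config$out_dir)
      }),
      annotate = t_stage({
        need("annotate", stage_outputs$simulate)
        ann <- annotate_stage(config)
        write.table(ann, od("annotated.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }),
      load = t_stage({
        need("load", "annotated.tsv")
        load_stage(config)
      }),
      scan = t_stage({
        need("scan", "annotated.tsv")
        scan_stage(config)
      }),
      demography = t_stage({
        need("demography", stage_outputs$simulate)
        demography_stage(config)
      }),
      stop("unknown stage: ", stage))
    outs <- od(stage_outputs[[stage]])
    outs <- outs[file.exists(outs)]
    manifest$stages[[stage]] <- list(
      seed = derive_seed(config$seed, stage),
      seconds = round(secs, 2),
      outputs = as.list(setNames(unname(tools::md5sum(outs)),
                                 basename(outs))))
  }
  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# internal stage implementations -------------------------------------------

read_stage_inputs <- function(config) {
  od <- function(f) file.path(config$out_dir, f)
  popmap <- read_popmap(od("popmap.tsv"))
  vcf <- read_vcf(od("genotypes.vcf"), popmap)
  ref <- Biostrings::readDNAStringSet(od("reference.fa"))
  layout <- list(contig = names(ref)[1],
                 contig_length = Biostrings::width(ref)[1],
                 reference = strsplit(as.character(ref[[1]]), "")[[1]],
                 cds = read_cds_gff3(od("genes.gff3")),
                 masks = tryCatch(read_bed(od("masks.bed")),
                                  error = function(e)
                                    data.frame(start = integer(),
                                               end = integer())))
  class(layout) <- "dc_layout"
  list(vcf = vcf, layout = layout, popmap = popmap)
}

annotate_stage <- function(config) {
  inp <- read_stage_inputs(config)
  vcf <- inp$vcf
  focal <- vcf$samples$population != "outgroup"
  outg <- vcf$geno[, !focal, drop = FALSE]
  if (config$truth_annotation) {
    truth <- read.table(file.path(config$out_dir, "truth.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
    idx <- match(vcf$variants$pos, truth$pos)
    ann <- data.frame(pos = vcf$variants$pos, alt = vcf$variants$alt,
                      effect = truth$class[idx], gene_id = NA, aa_ref = NA,
                      aa_alt = NA, delta = NA_real_,
                      is_hsnp = truth$class[idx] %in%
                        c("missense", "nonsense") & truth$s[idx] > 0,
                      stringsAsFactors = FALSE)
    ann$ancestral <- polarize(outg)
  } else {
    ann <- annotate_variants(vcf$variants$pos, vcf$variants$alt, inp$layout,
                             outgroup = outg,
                             seed = derive_seed(config$seed, "annotate"))
  }
  ann
}

# derived-allele dosage given polarization; NA rows for unpolarized sites
derived_dosage_matrix <- function(geno, ancestral) {
  d <- geno
  d[d == 3L] <- NA_integer_
  flip <- which(ancestral == "alt")
  d[flip, ] <- 2L - d[flip, , drop = FALSE]
  d[is.na(ancestral) | !(ancestral %in% c("ref", "alt")), ] <- NA_integer_
  d
}

load_stage <- function(config) {
  od <- function(f) file.path(config$out_dir, f)
  inp <- read_stage_inputs(config)
  ann <- read.table(od("annotated.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  focal <- inp$vcf$samples$population != "outgroup"
  geno <- inp$vcf$geno[, focal, drop = FALSE]
  samples <- inp$vcf$samples[focal, ]
  dd <- derived_dosage_matrix(geno, ann$ancestral)
  keep <- !is.na(ann$ancestral)
  cls <- site_load_classes(ann)[keep]
  summ <- individual_load(dd[keep, , drop = FALSE], cls, samples)
  prof <- population_load_profile(summ, dd[keep, , drop = FALSE], cls,
                                  samples$population)
  wild <- summ[summ$population == "wild", ]
  dom <- summ[summ$population == "domestic", ]
  cmp <- rbind(
    compare_groups(dom$n_del_alleles, wild$n_del_alleles, "n_del_alleles"),
    compare_groups(dom$del_syn_ratio, wild$del_syn_ratio, "del_syn_ratio"),
    compare_groups(dom$het_del_fraction, wild$het_del_fraction,
                   "het_del_fraction"))
  cmp$excess_pct <- c(load_excess(dom, wild), NA, NA)
  write.table(summ, od("load_per_sample.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(prof, od("load_per_population.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cmp, od("load_comparisons.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(summaries = summ, profile = prof, comparisons = cmp))
}

scan_stage <- function(config) {
  od <- function(f) file.path(config$out_dir, f)
  inp <- read_stage_inputs(config)
  ann <- read.table(od("annotated.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  pops <- inp$vcf$samples$population
  counts <- lapply(c(wild = "wild", domestic = "domestic",
                     outgroup = "outgroup"), function(p) {
    g <- inp$vcf$geno[, pops == p, drop = FALSE]
    g[g == 3L] <- NA_integer_
    list(derived = rowSums(g, na.rm = TRUE), called = 2 * rowSums(!is.na(g)))
  })
  # scan runs on alternate-allele counts; FST/pi are polarization-free
  win <- scan_windows(inp$vcf$variants$pos, counts,
                      inp$layout$contig_length, config$window, config$step)
  sweeps <- call_sweeps(win, config$sweep_statistic, config$sweep_quantile)
  hsnp <- which(ann$is_hsnp & !is.na(ann$ancestral))
  dd <- derived_dosage_matrix(inp$vcf$geno[, pops == "domestic", drop = FALSE],
                              ann$ancestral)
  freq <- rowSums(dd, na.rm = TRUE)[hsnp] /
    pmax(2 * rowSums(!is.na(dd))[hsnp], 1)
  contrast <- sweep_load_contrast(
    sweeps, inp$vcf$variants$pos[hsnp], freq, inp$layout$contig_length,
    seed = derive_seed(config$seed, "scan"))
  write.table(win, od("windows.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bed(od("sweeps.bed"), inp$layout$contig, sweeps$regions)
  write.table(as.data.frame(contrast[c("density_inside_per_mb",
                                       "density_outside_per_mb",
                                       "mean_freq_inside",
                                       "mean_freq_outside", "p_density",
                                       "p_freq", "n_perm")]),
              od("sweep_contrast.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(windows = win, sweeps = sweeps, contrast = contrast))
}

demography_stage <- function(config) {
  od <- function(f) file.path(config$out_dir, f)
  inp <- read_stage_inputs(config)
  pops <- inp$vcf$samples$population
  outg <- inp$vcf$geno[, pops == "outgroup", drop = FALSE]
  anc <- polarize(outg)
  regions <- build_neutral_mask(inp$layout)
  gw <- inp$vcf$geno[, pops == "wild", drop = FALSE]
  gd <- inp$vcf$geno[, pops == "domestic", drop = FALSE]
  gw[gw == 3L] <- NA_integer_; gd[gd == 3L] <- NA_integer_
  ddw <- derived_dosage_matrix(gw, anc)
  ddd <- derived_dosage_matrix(gd, anc)
  sfs <- joint_sfs(rowSums(ddw, na.rm = TRUE), rowSums(ddd, na.rm = TRUE),
                   2 * rowSums(!is.na(ddw)), 2 * rowSums(!is.na(ddd)),
                   n1 = 2 * sum(pops == "wild"),
                   n2 = 2 * sum(pops == "domestic"),
                   pos = inp$vcf$variants$pos, regions = regions)
  # unpolarized sites: rowSums over all-NA rows give 0 with full "called"
  # counts of 0, dropped by the strict filter
  fits <- lapply(config$models, function(m) {
    do.call(fit_demography,
            c(list(sfs = sfs, model = m,
                   seed = derive_seed(config$seed, paste0("fit", m))),
              config$fit_args))
  })
  sel <- model_select(fits)
  write_sfs(sfs, od("sfs.txt"))
  jsonlite::write_json(
    list(selection = sel,
         fits = lapply(fits, function(f)
           list(model = f$model, loglik = f$loglik, aic = f$aic,
                theta_hat = f$theta_hat, par = as.list(f$par)))),
    od("fits.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sfs = sfs, fits = fits, selection = sel))
}
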