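## Orchestration: YAML run configuration and the headline analyses
## (sweep scan, pan-gene, SV divergence, SV-expression, simulation),
## each a pure function of (inputs, config, seed) at the file level.
## A thin command-line wrapper around these functions is installed at
## inst/scripts/silkpan-cli.R.

#' Read and validate a run configuration
#'
#' @param path YAML file; must carry `version: 1` and a `seed`.
#'   Thresholds default to the pipeline's standard values (5 kb / 500 bp
#'   windows, top 1%/5%/5% tails, FDR 1e-4 and fold change 2 for
#'   divergence, FDR 0.001 for expression, 5 kb regulatory flanks,
#'   2.5 kb error flank, 100 kb SV cap, 500 bp merge distance).
#' @return Config list of class `silkpan_config`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$version) || cfg$version != 1)
    stop("unsupported or missing config version (expected 1)")
  if (is.null(cfg$seed)) stop("config must set a seed")
  defaults <- list(window = 5000, step = 500,
                   q_fst = 0.99, q_xpclr = 0.95, q_tajd = 0.05,
                   fdr_divergence = 1e-4, fold_change = 2,
                   fdr_expression = 0.001, flank = 5000,
                   error_flank = 2500, max_sv_len = 1e5, merge_dist = 500)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = c("silkpan_config", "list"))
}

.configOf <- function(config) {
  if (is.character(config)) readRunConfig(config) else config
}

.provenance <- function(outdir, cfg, stage) {
  tmp <- tempfile()
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  rec <- list(stage = stage,
              package = "silkpan",
              version = as.character(utils::packageVersion("silkpan")),
              config_md5 = unname(tools::md5sum(tmp)),
              seed = cfg$seed)
  unlink(tmp)
  jsonlite::write_json(rec, file.path(outdir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

.stageDir <- function(cfg) {
  outdir <- cfg$output_dir
  if (is.null(outdir)) stop("config must set output_dir")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outdir
}

#' Simulate a full synthetic input set
#'
#' Writes a SNP VCF, an SV VCF, an occupancy TSV, a sample manifest and
#' a ground-truth JSON under `config$output_dir`. Deterministic for a
#' given (config, seed).
#'
#' @param config A config list or YAML path (see [readRunConfig()]);
#'   uses the `simulate:` section (chrom_lengths, pops, n_sites, F_st,
#'   sweeps, sv, occupancy).
#' @return Invisible list of written paths.
#' @export
runSimulate <- function(config) {
  cfg <- .configOf(config)
  outdir <- .stageDir(cfg)
  sim <- cfg$simulate
  if (is.null(sim)) stop("config lacks a simulate: section")
  chrom_lengths <- unlist(sim$chrom_lengths)
  pops <- unlist(sim$pops)
  sweeps <- if (!is.null(sim$sweeps))
    do.call(rbind, lapply(sim$sweeps, as.data.frame)) else NULL
  snp <- simulateSNPCohort(
    chrom_lengths = chrom_lengths, pops = pops,
    F_st = if (is.null(sim$F_st)) 0.1 else unlist(sim$F_st),
    n_sites = if (is.null(sim$n_sites)) 10000 else sim$n_sites,
    sweeps = sweeps, seed = cfg$seed)
  vcf_path <- file.path(outdir, "snp.vcf")
  writeSNPVcf(snp$genotypes, vcf_path)
  manifest <- file.path(outdir, "samples.tsv")
  write.table(data.frame(sample = colnames(snp$genotypes),
                         group = colData(snp$genotypes)$population),
              manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  svs <- cfg$simulate$sv
  sv_path <- NULL
  if (!is.null(svs)) {
    svsim <- simulateSVCohort(
      n_sites = if (is.null(svs$n_sites)) 5000 else svs$n_sites,
      n_shifted = if (is.null(svs$n_shifted)) 100 else svs$n_shifted,
      pops = unlist(svs$pops),
      chrom_lengths = chrom_lengths, seed = cfg$seed + 1)
    sv_path <- file.path(outdir, "sv.vcf")
    writeSVVcf(svsim$cohort, sv_path)
    jsonlite::write_json(svsim$truth, file.path(outdir, "sv.truth.json"),
                         auto_unbox = TRUE)
  }
  occ <- cfg$simulate$occupancy
  occ_path <- NULL
  if (!is.null(occ)) {
    osim <- simulateOccupancy(n_genomes = occ$n_genomes,
                              class_counts = unlist(occ$class_counts),
                              seed = cfg$seed + 2)
    occ_path <- file.path(outdir, "occupancy.tsv")
    writeOccupancyTsv(osim$occupancy, occ_path)
    write.table(data.frame(sample = colnames(osim$occupancy),
                           group = colData(osim$occupancy)$group),
                file.path(outdir, "genomes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth_path <- file.path(outdir, "snp.truth.json")
  jsonlite::write_json(list(sweeps = sweeps, seed = cfg$seed), truth_path,
                       auto_unbox = TRUE)
  .provenance(outdir, cfg, "simulate")
  invisible(list(snp_vcf = vcf_path, manifest = manifest, sv_vcf = sv_path,
                 occupancy = occ_path, truth = truth_path))
}

#' Run the sweep scan (tracks, regions, genes)
#'
#' Computes FST, Tajima's D (both populations) and XP-CLR tracks over
#' the sliding-window grid, intersects the percentile tails into
#' candidate sweep regions, and (when gene models are configured)
#' assigns overlapping genes.
#'
#' @param config Config list or YAML path; needs `sweep_scan:` with
#'   `vcf`, `manifest`, `ancestral`, `descendant`, optional `gff3`.
#' @return Invisible list with the tracks, regions and written paths.
#' @export
runSweepScan <- function(config) {
  cfg <- .configOf(config)
  outdir <- .stageDir(cfg)
  sc <- cfg$sweep_scan
  if (is.null(sc)) stop("config lacks a sweep_scan: section")
  pop <- readSampleManifest(sc$manifest)
  gm <- readSNPVcf(sc$vcf, pop)
  chrlen <- seqlengths(rowRanges(gm))
  if (any(is.na(chrlen)))
    chrlen <- vapply(split(end(rowRanges(gm)),
                           as.character(seqnames(rowRanges(gm)))), max, 1)
  windows <- scanWindows(chrlen, cfg$window, cfg$step)
  anc <- sc$ancestral; des <- sc$descendant
  fst <- scanFst(gm, windows, anc, des)
  d_des <- scanTajimaD(gm, windows, des)
  d_anc <- scanTajimaD(gm, windows, anc)
  counts <- .siteAlleleCounts(.popDosage(gm, anc))
  p_ref <- ifelse(counts$an >= 2, counts$ac / counts$an, NA_real_)
  cdes <- .siteAlleleCounts(.popDosage(gm, des))
  p_obj <- ifelse(cdes$an >= 2, cdes$ac / cdes$an, NA_real_)
  omega <- estimateOmega(p_ref, p_obj,
                         min_sites = min(1000, floor(nrow(gm) / 2)))
  params <- sweepModelParams(omega,
                             Ne = if (is.null(sc$Ne)) 10000 else sc$Ne,
                             recomb_rate = if (is.null(sc$recomb_rate))
                               1e-6 else sc$recomb_rate)
  xp <- scanXpclr(gm, windows, anc, des, params)
  regions <- callSweeps(fst, xp, d_des, d_anc,
                        sweepCallConfig(cfg$q_fst, cfg$q_xpclr, cfg$q_tajd))
  writeTrackTsv(fst, file.path(outdir, "fst.tsv"))
  writeTrackTsv(xp, file.path(outdir, "xpclr.tsv"))
  writeTrackTsv(d_des, file.path(outdir, "tajd_descendant.tsv"))
  writeTrackTsv(d_anc, file.path(outdir, "tajd_ancestral.tsv"))
  writeTrackBed(regions, file.path(outdir, "sweep_regions.bed"))
  genes <- NULL
  if (!is.null(sc$gff3)) {
    models <- readGeneModels(sc$gff3)
    ass <- regionsToGenes(regions, models$genes)
    genes <- ass$genes
    writeLines(genes, file.path(outdir, "sweep_genes.txt"))
  }
  .provenance(outdir, cfg, "sweep_scan")
  invisible(list(fst = fst, xpclr = xp, d_descendant = d_des,
                 d_ancestral = d_anc, regions = regions, genes = genes,
                 omega = omega))
}

#' Run the pan-gene analysis
#'
#' Classifies orthogroups, computes accumulation curves, fits the
#' exponential plateau model to the pan curve, and (when contrasts are
#' configured) runs the presence/absence frequency-differentiation scan.
#'
#' @param config Config list or YAML path; needs `pangene:` with
#'   `occupancy` (TSV) and `manifest`, optional `contrasts` (list of
#'   two-element group lists).
#' @return Invisible list with classification, curves, model and scan
#'   results.
#' @export
runPangene <- function(config) {
  cfg <- .configOf(config)
  outdir <- .stageDir(cfg)
  pg <- cfg$pangene
  if (is.null(pg)) stop("config lacks a pangene: section")
  grp <- readSampleManifest(pg$manifest)
  occ <- readOccupancyTsv(pg$occupancy, grp)
  cls <- classifyOrthogroups(occ)
  write.table(data.frame(orthogroup = rownames(presence(occ)),
                         class = as.character(cls$class)),
              file.path(outdir, "occupancy_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  curves <- accumulationCurves(occ, n_orders = if (is.null(pg$n_orders))
    100 else pg$n_orders, seed = cfg$seed)
  write.table(data.frame(x = curves$x, pan = curves$pan, core = curves$core),
              file.path(outdir, "accumulation_curves.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  model <- fitExponential(curves$x, curves$pan)
  plateau <- plateauSize(model)
  jsonlite::write_json(list(A = model$A, B = model$B, C = model$C,
                            rss = model$rss, plateau = plateau),
                       file.path(outdir, "pan_model.json"),
                       auto_unbox = TRUE, digits = NA)
  scans <- list()
  for (ct in pg$contrasts) {
    nm <- paste(ct[[1]], ct[[2]], sep = "_vs_")
    res <- geneFrequencyDifferentiation(occ, ct[[1]], ct[[2]],
                                        fdr = cfg$fdr_divergence,
                                        fc = cfg$fold_change)
    write.table(cbind(orthogroup = rownames(res), res),
                file.path(outdir, paste0("genefreq_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    scans[[nm]] <- res
  }
  .provenance(outdir, cfg, "pangene")
  invisible(list(classification = cls, curves = curves, model = model,
                 plateau = plateau, scans = scans))
}

#' Run the SV pipeline (filter, frequencies, divergence, annotation)
#'
#' @param config Config list or YAML path; needs `sv:` with `vcf` and
#'   `manifest`, optional `error_bed`, `gff3`, `contrasts`.
#' @return Invisible list with the cohort, filter tally, allele
#'   frequencies, divergence tables and annotation.
#' @export
runSVScan <- function(config) {
  cfg <- .configOf(config)
  outdir <- .stageDir(cfg)
  sv <- cfg$sv
  if (is.null(sv)) stop("config lacks a sv: section")
  grp <- readSampleManifest(sv$manifest)
  svc <- readSVVcf(sv$vcf, grp)
  err <- if (!is.null(sv$error_bed)) readBedRegions(sv$error_bed) else GRanges()
  flt <- filterSVs(svc, err, flank = cfg$error_flank,
                   max_len = cfg$max_sv_len)
  svc <- flt$kept
  af <- svAlleleFrequency(svc)
  write.table(data.frame(site_id = rownames(af), af, check.names = FALSE),
              file.path(outdir, "sv_allele_frequencies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  scans <- list()
  for (ct in sv$contrasts) {
    nm <- paste(ct[[1]], ct[[2]], sep = "_vs_")
    res <- svDivergenceScan(svc, ct[[1]], ct[[2]],
                            fdr = cfg$fdr_divergence, fc = cfg$fold_change)
    write.table(res, file.path(outdir, paste0("svdiverge_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    scans[[nm]] <- res
  }
  annot <- NULL
  if (!is.null(sv$gff3)) {
    models <- readGeneModels(sv$gff3)
    annot <- annotateSVContext(svc, models, flank = cfg$flank)
    write.table(cbind(site_id = mcols(rowRanges(svc))$site_id, annot),
                file.path(outdir, "sv_context.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .provenance(outdir, cfg, "sv")
  invisible(list(cohort = svc, tally = flt$tally, af = af, scans = scans,
                 annotation = annot))
}

#' Run the SV-expression association
#'
#' @param config Config list or YAML path; needs `sv_expression:` with
#'   `sv_vcf`, `manifest`, `gff3`, `expression` (TSV: gene rows, library
#'   columns named strain.tissue.replicate).
#' @return Invisible list with pairs and test results.
#' @export
runSVExpression <- function(config) {
  cfg <- .configOf(config)
  outdir <- .stageDir(cfg)
  se <- cfg$sv_expression
  if (is.null(se)) stop("config lacks a sv_expression: section")
  grp <- readSampleManifest(se$manifest)
  svc <- readSVVcf(se$sv_vcf, grp)
  models <- readGeneModels(se$gff3)
  mat <- as.matrix(read.table(se$expression, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE))
  parts <- strsplit(colnames(mat), ".", fixed = TRUE)
  expr <- StrainExpression(mat,
                           strain = vapply(parts, `[`, "", 1),
                           tissue = vapply(parts, `[`, "", 2),
                           replicate = as.integer(vapply(parts, `[`, "", 3)),
                           unit = "fpkm")
  strains <- intersect(colnames(svc), unique(colData(expr)$strain))
  pairs <- buildSVGenePairs(svc, models, strains, flank = cfg$flank)
  res <- pairDifferentialExpression(pairs, expr, fdr = cfg$fdr_expression)
  write.table(res$tests, file.path(outdir, "pair_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$pairs, file.path(outdir, "pair_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .provenance(outdir, cfg, "sv_expression")
  invisible(list(pairs = pairs, results = res))
}
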