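#' Pipeline configuration
#'
#' Bundles every stage's parameters. Input genotypes come either from a
#' [sim_config()] (simulated at run time) or from PED/MAP paths.
#'
#' @param sim a [sim_config()], or NULL when reading files.
#' @param ped_path,map_path PLINK text input (ignored when `sim` given).
#' @param gene_path,gene_format optional candidate-gene interval file for
#'   annotation (see [read_gene_intervals()]).
#' @param qc a [qc_params()] object. The default tests Hardy-Weinberg in
#'   population A only, which is what PLINK's `--hwe` does when the
#'   phenotype is case/control (the breed label): testing the pooled
#'   cohorts would preferentially remove the most divergent markers
#'   through the Wahlund effect.
#' @param region a [region_params()] object.
#' @param flank_bp annotation flank (default 3 Mb).
#' @param kinship_chromosomes `"autosomes"` (default) or `"all"`.
#' @param emmax_test `"wald_chisq"` or `"f"`.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param out_dir output directory, or NULL to keep results in memory only.
#' @param plot write Manhattan plots (only when `out_dir` is set).
#' @param seed seed for the simulation stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, ped_path = NULL, map_path = NULL,
                            gene_path = NULL, gene_format = "bed",
                            qc = qc_params(hwe_population =
                                             "population_A_only"),
                            region = region_params(), flank_bp = 3000000,
                            kinship_chromosomes = "autosomes",
                            emmax_test = "wald_chisq", alpha = 0.05,
                            out_dir = NULL, plot = TRUE, seed = 1) {
  if (is.null(sim) && (is.null(ped_path) || is.null(map_path)))
    stop("supply either a sim_config or ped_path + map_path")
  if (!is.null(ped_path) && is.null(sim)) {
    if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
    if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  }
  structure(list(sim = sim, ped_path = ped_path, map_path = map_path,
                 gene_path = gene_path, gene_format = gene_format,
                 qc = qc, region = region, flank_bp = flank_bp,
                 kinship_chromosomes = kinship_chromosomes,
                 emmax_test = emmax_test, alpha = alpha, out_dir = out_dir,
                 plot = plot, seed = seed), class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full differentiation-scan pipeline
#'
#' simulate/read -> QC -> Fst and Fisher tracks -> IBS kinship -> null-model
#' REML -> EMMAX scan -> per-method region calling -> cross-method VGR
#' intersection -> optional gene annotation and recovery scoring ->
#' Manhattan plots. Identical config and seed reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return list of class `vgr_run`: the run manifest (stage counts,
#'   inflation factors, file inventory) plus all in-memory results
#'   (`dataset`, `qc_report`, `tracks`, `kinship`, `vc`, `regions`,
#'   `vgrs`, `annotation`, `recovery`, `truth`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  emit <- function(name, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- pipeline_stage("simulate", {
      cfg <- config$sim
      cfg$seed <- config$seed
      simulate_dataset(cfg)
    })
    raw <- sim$dataset
    truth <- sim$truth
    emit("simulated.ped", function(p)
      write_ped_map(raw, p, file.path(out_dir, "simulated.map")))
    emit("truth_regions.bed", function(p)
      write_regions_bed(truth$regions, p,
                        names = paste0("planted_", seq_len(nrow(truth$regions)))))
    emit("truth_loci.tsv", function(p)
      utils::write.table(truth$loci, p, quote = FALSE, sep = "\t",
                         row.names = FALSE))
  } else {
    raw <- pipeline_stage("read",
      read_ped_map(config$ped_path, config$map_path))
  }

  qc <- pipeline_stage("qc", apply_qc(raw, config$qc))
  if (n_markers(qc$dataset) == 0)
    stop("pipeline stage 'qc' failed: no markers passed quality control",
         call. = FALSE)
  ds <- qc$dataset
  emit("qc_removed.tsv", function(p)
    utils::write.table(qc$report$removed, p, quote = FALSE, sep = "\t",
                       row.names = FALSE))

  fst <- pipeline_stage("fst_track", suppressWarnings(fst_track(ds)))
  fisher <- pipeline_stage("fisher_track", suppressWarnings(fisher_track(ds)))
  emit("fst_track.tsv", function(p) write_track(fst, p))
  emit("fisher_track.tsv", function(p) write_track(fisher, p))

  K <- pipeline_stage("kinship",
    ibs_kinship(ds, chromosomes = config$kinship_chromosomes))
  emit("kinship.tsv", function(p) write_kinship(K, p))

  vc <- pipeline_stage("reml", {
    y <- as.numeric(ds$samples$population == "B")
    emma_reml(y, K = K)
  })
  emmax <- pipeline_stage("emmax_scan",
    emmax_scan(ds, K, vc, test = config$emmax_test))
  emit("emmax_scan.tsv", function(p) {
    out <- as.data.frame(emmax)
    names(out)[names(out) == "value"] <- "p"
    utils::write.table(out, p, quote = FALSE, sep = "\t", row.names = FALSE)
  })

  lambda_fisher <- genomic_inflation(p = fisher$value[is.finite(fisher$value)])
  lambda_emmax <- genomic_inflation(p = emmax$value[is.finite(emmax$value)])

  regions_plink <- pipeline_stage("call_regions_plink",
    call_regions(fst, config$region))
  regions_emmax <- pipeline_stage("call_regions_emmax",
    call_regions(emmax, config$region))
  emit("regions_plink.tsv", function(p) write_region_table(regions_plink, p))
  emit("regions_emmax.tsv", function(p) write_region_table(regions_emmax, p))
  emit("regions_plink.bed", function(p) write_regions_bed(regions_plink, p))
  emit("regions_emmax.bed", function(p) write_regions_bed(regions_emmax, p))

  vgrs <- pipeline_stage("intersect",
    intersect_region_sets(regions_plink, regions_emmax))
  emit("vgr.tsv", function(p)
    utils::write.table(vgrs, p, quote = FALSE, sep = "\t", row.names = FALSE))
  if (nrow(vgrs) > 0)
    emit("vgr.bed", function(p)
      write_regions_bed(vgrs, p, names = paste0("VGR_", vgrs$vgr)))

  annotation <- NULL
  if (!is.null(config$gene_path)) {
    genes <- pipeline_stage("annotation",
      read_gene_intervals(config$gene_path, config$gene_format))
    annotation <- annotate_regions(vgrs, genes, config$flank_bp)
    emit("annotation.tsv", function(p)
      utils::write.table(annotation, p, quote = FALSE, sep = "\t",
                         row.names = FALSE))
  }

  recovery <- if (!is.null(truth) && nrow(truth$regions) > 0)
    recovery_score(vgrs, truth) else NULL

  threshold <- bonferroni_threshold(config$alpha, n_markers(ds))
  if (!is.null(out_dir) && config$plot) {
    dev_ext <- if (capabilities("png")) ".png" else ".pdf"
    emit(paste0("manhattan_fst", dev_ext), function(p)
      manhattan_plot(fst, regions = regions_plink, out_path = p))
    emit(paste0("manhattan_emmax", dev_ext), function(p)
      manhattan_plot(emmax, regions = regions_emmax, out_path = p,
                     threshold = threshold))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("vgrscan")),
    seed = config$seed,
    n_samples = n_samples(ds),
    n_markers_input = qc$report$n_input,
    n_markers_qc = qc$report$n_pass,
    qc_removed = list(missingness = qc$report$n_missingness,
                      maf = qc$report$n_maf, hwe = qc$report$n_hwe),
    lambda_fisher = lambda_fisher,
    lambda_emmax = lambda_emmax,
    delta = vc$delta,
    bonferroni_threshold = threshold,
    n_regions_plink = nrow(regions_plink),
    n_regions_emmax = nrow(regions_emmax),
    n_vgr = nrow(vgrs),
    recovery = recovery,
    files = files)
  emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))

  structure(list(manifest = manifest, dataset = ds, qc_report = qc$report,
                 tracks = list(fst = fst, fisher = fisher, emmax = emmax),
                 kinship = K, vc = vc,
                 regions = list(plink = regions_plink, emmax = regions_emmax),
                 vgrs = vgrs, annotation = annotation, recovery = recovery,
                 truth = truth), class = "vgr_run")
}

#' @export
print.vgr_run <- function(x, ...) {
  m <- x$manifest
  cat("vgrscan pipeline run (seed", m$seed, ")\n")
  cat("  markers:", m$n_markers_input, "->", m$n_markers_qc, "after QC;",
      m$n_samples, "samples\n")
  cat(sprintf("  lambda: Fisher %.2f | EMMAX %.2f\n",
              m$lambda_fisher, m$lambda_emmax))
  cat("  regions:", m$n_regions_plink, "Fst-side,", m$n_regions_emmax,
      "EMMAX-side,", m$n_vgr, "dual-support VGR\n")
  if (!is.null(m$recovery))
    cat(sprintf("  recovery: sensitivity %.2f, %d false positive(s)\n",
                m$recovery$sensitivity, m$recovery$false_positive_count))
  invisible(x)
}

write_region_table <- function(regions, path) {
  out <- regions[, setdiff(names(regions), "members"), drop = FALSE]
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(NULL)
}

#' Manhattan plot of a genome scan
#'
#' Alternating-color scatter of the track statistic against cumulative
#' genome position: `-log10(p)` for p-value tracks, the raw value for Fst.
#' Called regions are shaded and a significance threshold is drawn as a
#' horizontal line at `-log10(threshold)`. The plot-coordinate geometry
#' (per-marker x positions, shaded spans, threshold height) is returned
#' invisibly so callers can inspect it.
#'
#' @param track an `assoc_track`.
#' @param regions optional [call_regions()] output to shade.
#' @param out_path optional `.png` or `.pdf` path; when NULL, plots on the
#'   active device.
#' @param threshold optional p-value threshold (drawn for p tracks).
#' @param main plot title.
#' @return (invisibly) list with `coords` (marker plot coordinates),
#'   `region_spans` (shaded x-intervals) and `threshold_y`.
#' @export
manhattan_plot <- function(track, regions = NULL, out_path = NULL,
                           threshold = NULL, main = NULL) {
  if (nrow(track) == 0) stop("empty track")
  stat <- attr(track, "statistic")
  is_p <- !is.null(stat) && grepl("_p$", stat)
  y <- if (is_p) -log10(track$value) else track$value
  ylab <- if (is_p) expression(-log[10](italic(p))) else
    expression(italic(F)[ST])

  chroms <- unique(track$chrom[order(chrom_rank(track$chrom), track$chrom)])
  offsets <- stats::setNames(numeric(length(chroms)), chroms)
  run <- 0
  for (ch in chroms) {
    offsets[ch] <- run
    run <- run + max(track$pos_bp[track$chrom == ch]) + 1
  }
  x <- track$pos_bp + offsets[track$chrom]

  region_spans <- NULL
  if (!is.null(regions) && nrow(regions) > 0)
    region_spans <- data.frame(
      xleft = regions$start_bp + offsets[regions$chrom],
      xright = regions$end_bp + offsets[regions$chrom])
  threshold_y <- if (!is.null(threshold) && is_p) -log10(threshold) else NULL

  if (!is.null(out_path)) {
    if (grepl("\\.png$", out_path))
      grDevices::png(out_path, width = 1600, height = 600, res = 120)
    else grDevices::pdf(out_path, width = 12, height = 4.5)
    on.exit(grDevices::dev.off())
  }
  col <- c("grey25", "steelblue")[1 + match(track$chrom, chroms) %% 2]
  ymax <- max(c(y[is.finite(y)], threshold_y), na.rm = TRUE)
  graphics::plot(x, y, pch = 20, cex = 0.4, col = col, xaxt = "n",
                 xlab = "chromosome", ylab = ylab,
                 ylim = c(min(0, min(y[is.finite(y)])), ymax * 1.05),
                 main = if (is.null(main)) stat else main)
  mid <- vapply(chroms, function(ch)
    mean(range(x[track$chrom == ch])), numeric(1))
  graphics::axis(1, at = mid, labels = chroms, cex.axis = 0.7, tick = FALSE)
  if (!is.null(region_spans))
    graphics::rect(region_spans$xleft, graphics::par("usr")[3],
                   region_spans$xright, graphics::par("usr")[4],
                   col = grDevices::adjustcolor("orange", 0.25), border = NA)
  if (!is.null(threshold_y))
    graphics::abline(h = threshold_y, lty = 2, col = "red")

  invisible(list(coords = data.frame(marker_id = track$marker_id, x = x,
                                     y = y),
                 region_spans = region_spans, threshold_y = threshold_y))
}
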