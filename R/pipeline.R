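# Pipeline orchestration: simulate -> call -> maps / proximal /
# interference / tetrads, with per-stage derived seeds, TSV outputs, a JSON
# reproducibility manifest, and a plain-text summary.

.pipeline_stages <- c("simulate", "call", "maps", "proximal",
                      "interference", "tetrads")

# Documented seed-splitting rule: stage k of the canonical stage list gets
# seed (master + k * 1000003) mod (2^31 - 1), so any stage can be rerun
# independently of the others.
stage_seed <- function(master_seed, stage) {
  k <- match(stage, .pipeline_stages)
  if (is.na(k)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master_seed) + k * 1000003) %% 2147483647)
}

#' Run the crossover-analysis pipeline
#'
#' Orchestrates the standard stage sequence on a simulated study:
#' `simulate` writes genotype tables and truth, `call` produces the
#' crossover call set (BED + QC), `maps` the class counts and per-arm map
#' summary, `proximal` the suppression-extent scans, `interference` the
#' per-arm interference table, and `tetrads` the Weinstein fits.  Each
#' stage reads its inputs from `out_dir`, so stages can be rerun
#' individually; a stage whose upstream artifact is missing fails naming
#' that stage.  All outputs are TSV; a JSON manifest records seeds,
#' parameters and row counts, and `summary.txt` a compact human-readable
#' report.
#'
#' @param config A [sim_config()] (required for the `simulate` stage).
#' @param stages Character vector of stages to run, in canonical order.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-stage seeds are derived by a fixed
#'   splitting rule.
#' @param call_args Optional list of overrides for
#'   [call_genotype_tables()].
#' @param n_reps Null replicates for the interference stage (default 1e5).
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = NULL, stages = .pipeline_stages, out_dir,
                         seed = 1L, call_args = list(), n_reps = 1e5) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("xomap")),
                   master_seed = seed, stages = stages,
                   stage_seeds = sapply(stages, stage_seed, master_seed = seed),
                   created = "run_pipeline")
  results <- list()
  path <- function(f) file.path(out_dir, f)
  need <- function(f, stage_needed) {
    if (!file.exists(path(f)))
      stop(sprintf("missing upstream artifact '%s': run stage '%s' first",
                   f, stage_needed))
    path(f)
  }

  if ("simulate" %in% stages) {
    if (is.null(config)) stop("simulate stage requires a sim_config")
    sim <- simulate_study(config, seed = stage_seed(seed, "simulate"))
    write_genotype_table(sim$tables, path("genotypes.tsv"))
    write.table(sim$truth$tetrads, path("truth_tetrads.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$truth$chromatids, path("truth_chromatids.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$simulate <- sim
    manifest$n_meioses <- config$n_meioses
    manifest$rows_genotypes <- sum(vapply(sim$tables, function(t)
      length(t$pos), numeric(1)))
  }

  if ("call" %in% stages) {
    tables <- read_genotype_table(need("genotypes.tsv", "simulate"))
    filt <- filter_arms(tables)
    callset <- do.call(call_genotype_tables,
                       c(list(filt$kept, excluded = filt$excluded), call_args))
    write_crossovers_bed(callset, path("calls.bed"))
    write.table(callset$chromatids, path("chromatids.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$call <- callset
    manifest$n_calls <- nrow(callset$calls)
    manifest$n_chromatids <- nrow(callset$chromatids)
    manifest$n_excluded <- nrow(callset$excluded)
    # one log line per data-dropping decision
    if (any(callset$chromatids$flagged))
      message(sum(callset$chromatids$flagged),
              " chromatid(s) flagged: close double switch dropped")
    if (nrow(callset$excluded))
      message(nrow(callset$excluded), " chromatid(s) excluded pre-calling")
  }

  needs_calls <- intersect(c("maps", "proximal", "interference", "tetrads"),
                           stages)
  if (length(needs_calls)) {
    if (!is.null(results$call)) callset <- results$call
    else {
      calls <- read_crossovers_bed(need("calls.bed", "call"))
      chrom <- read.delim(need("chromatids.tsv", "call"))
      callset <- crossover_callset(calls = calls, chromatids = chrom)
    }
  }

  if ("maps" %in% stages) {
    counts <- classify_chromatids(callset)
    summ <- summary(counts)
    write.table(cbind(arm = rownames(counts), as.data.frame(unclass(counts))),
                path("class_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    maps <- data.frame(arm = names(summ$mean_per_product$per_arm),
                       mean_co = summ$mean_per_product$per_arm,
                       map_cM = summ$mean_per_product$map_cM)
    write.table(maps, path("maps.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$maps <- list(counts = counts, summary = summ)
    manifest$total_crossovers <- summ$total_crossovers
  }

  if ("proximal" %in% stages) {
    set.seed(stage_seed(seed, "proximal"))
    rows <- list()
    for (a in sort(unique(callset$chromatids$arm))) {
      pts <- callset$calls$point[callset$calls$arm == a]
      chr <- callset$chromatids[callset$chromatids$arm == a, ]
      span <- c(min(chr$span_start), max(chr$span_end))
      if (length(pts) < 2L || diff(span) < 2e6) next
      for (side in c("centromere", "telomere")) {
        third <- proximal_third_test(pts, span, side = side, n_reps = 1e5)
        ext <- scan_effect_extent(pts, span, side = side, alpha = 1e-3)
        rows[[paste(a, side)]] <- data.frame(
          arm = a, side = side, observed_third = third$observed,
          expected_third = third$expected, p_third = third$p_value,
          extent_bp = ext$extent_bp, stringsAsFactors = FALSE)
      }
    }
    prox <- do.call(rbind, rows)
    write.table(prox, path("proximal.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$proximal <- prox
  }

  if ("interference" %in% stages) {
    intf <- interference_summary(callset, n_reps = n_reps,
                                 n_sets = min(n_reps, 1e4),
                                 seed = stage_seed(seed, "interference"))
    write.table(intf, path("interference.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$interference <- intf
  }

  if ("tetrads" %in% stages) {
    counts <- classify_chromatids(callset)
    rows <- list()
    for (a in rownames(counts)) {
      fit <- tetrad_fit(as.numeric(counts[a, ]), budget = 20000L,
                        n_starts = 10L, seed = stage_seed(seed, "tetrads"))
      rows[[a]] <- data.frame(arm = a, t(fit$E), chi_square = fit$chi_square,
                              p_value = fit$p_value, stringsAsFactors = FALSE)
    }
    tet <- do.call(rbind, rows)
    write.table(tet, path("tetrads.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$tetrads <- tet
  }

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  con <- file(path("summary.txt"), "w")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  cat("xomap pipeline summary (seed ", seed, ")\n\n", sep = "")
  if (!is.null(results$maps)) print(results$maps$summary)
  if (!is.null(results$proximal)) {
    cat("\nProximal suppression:\n"); print(results$proximal, row.names = FALSE)
  }
  if (!is.null(results$interference)) {
    cat("\nInterference:\n"); print(results$interference, row.names = FALSE)
  }
  if (!is.null(results$tetrads)) {
    cat("\nTetrad fits:\n"); print(results$tetrads, row.names = FALSE)
  }
  results$manifest <- manifest
  invisible(results)
}
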