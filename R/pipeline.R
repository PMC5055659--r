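## End-to-end pipeline over the package's stages.  Each stage reads the
## exchange files written by its predecessors and writes flat TSV/JSON
## artifacts, so a re-run with the same configuration and seed is
## byte-identical and individual stages can be re-run in isolation.

#' Pipeline analysis settings
#'
#' Thresholds and sizes shared across stages, with the package defaults:
#' PSI class cutpoints 1/3 and 2/3, confidence threshold sigma <= 0.1,
#' regime threshold 0.5, the 15-100 bp ISRE region, 100-bp averaging
#' window, FDR q < 0.05, k-mer eligibility at 100 events, and 1000
#' permutations.
#'
#' @param psi_low,psi_high PSI class cutpoints.
#' @param sigma_max confidence threshold on sigma.
#' @param regime_threshold junction/average regime threshold.
#' @param region_start,region_end ISRE region offsets (half-open).
#' @param avg_window averaging window for A (bp).
#' @param q_threshold ISRE FDR threshold.
#' @param min_events k-mer eligibility threshold.
#' @param n_perm permutations for the meta-correlation test.
#' @param sweep_W largest window of the window sweep.
#' @param n_folds cross-validation folds.
#' @param eps Junc/Avg denominator floor.
#' @return named list of settings.
#' @export
pipeline_settings <- function(psi_low = 1/3, psi_high = 2/3, sigma_max = 0.1,
                              regime_threshold = 0.5, region_start = 15L,
                              region_end = 101L, avg_window = 100L,
                              q_threshold = 0.05, min_events = 100L,
                              n_perm = 1000L, sweep_W = 384L, n_folds = 5L,
                              eps = 1e-3) {
  as.list(environment())
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) format(v, digits = 15L, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order:
#' `simulate -> features -> sweep -> regimes -> models -> isres ->
#' kmer_stats`.  Later stages read the artifacts of earlier ones from
#' `outdir`; a missing prerequisite is an error naming the stage to run
#' first.  All randomness flows from `config$seed`.
#'
#' @param config `sim_config` (defines the dataset and the seed).
#' @param outdir output directory.
#' @param stages character vector of stages to run.
#' @param settings [pipeline_settings()].
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = c("simulate", "features", "sweep",
                                    "regimes", "models", "isres",
                                    "kmer_stats"),
                         settings = pipeline_settings()) {
  all_stages <- c("simulate", "features", "sweep", "regimes", "models",
                  "isres", "kmer_stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(outdir, "sim")
  need_sim <- function(stage) {
    if (!file.exists(file.path(sim_dir, "events.tsv")))
      stop("stage '", stage, "' requires the 'simulate' stage to run first")
  }
  s <- settings

  if ("simulate" %in% stages) {
    sim <- simulate_splice_data(config)
    write_sim(sim, sim_dir)
    jsonlite::write_json(
      list(seed = config$seed, n_exons = config$n_exons,
           n_tissues = config$n_tissues, settings = s),
      file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }

  load_inputs <- function() {
    list(events = read_events(file.path(sim_dir, "events.tsv")),
         genome = read_genome(file.path(sim_dir, "genome.fa")),
         mam = read_track(file.path(sim_dir, "cons_mammal.bedgraph")),
         pri = read_track(file.path(sim_dir, "cons_primate.bedgraph")),
         psi = read_psi_table(file.path(sim_dir, "psi.tsv")))
  }
  inp <- NULL
  get_inputs <- function(stage) {
    need_sim(stage)
    if (is.null(inp)) inp <<- load_inputs()
    inp
  }

  if ("features" %in% stages) {
    d <- get_inputs("features")
    feats <- cons_features(d$events, d$mam, w = s$avg_window, eps = s$eps)
    write_tsv(feats, file.path(outdir, "features.tsv"))
    feats_pri <- cons_features(d$events, d$pri, w = s$avg_window, eps = s$eps)
    write_tsv(feats_pri, file.path(outdir, "features_primate.tsv"))
  }

  if ("sweep" %in% stages) {
    d <- get_inputs("sweep")
    sw <- window_sweep(d$events, d$mam, psi_avg(d$psi), W = s$sweep_W,
                       eps = s$eps)
    write_tsv(sw, file.path(outdir, "sweep.tsv"))
  }

  need_features <- function(stage) {
    if (!file.exists(file.path(outdir, "features.tsv")))
      stop("stage '", stage, "' requires the 'features' stage to run first")
  }

  if ("regimes" %in% stages) {
    d <- get_inputs("regimes"); need_features("regimes")
    feats <- read.delim(file.path(outdir, "features.tsv"),
                        stringsAsFactors = FALSE)
    feats_pri <- read.delim(file.path(outdir, "features_primate.tsv"),
                            stringsAsFactors = FALSE)
    lab_up <- setNames(classify_regime(feats$J_up, feats$A_up,
                                       s$regime_threshold), feats$event_id)
    lab_dn <- setNames(classify_regime(feats$J_down, feats$A_down,
                                       s$regime_threshold), feats$event_id)
    write_tsv(data.frame(event_id = feats$event_id, regime_up = lab_up,
                         regime_down = lab_dn),
              file.path(outdir, "regimes.tsv"))
    labeled <- label_and_filter(d$psi, s$sigma_max, s$psi_low, s$psi_high)
    bd <- regime_psi_breakdown(lab_up, labeled)
    write_tsv(bd$per_tissue, file.path(outdir, "regime_psi_per_tissue.tsv"))
    write_tsv(bd$overall, file.path(outdir, "regime_psi_overall.tsv"))
    write_tsv(bd$sd_across_tissues, file.path(outdir, "regime_psi_sd.tsv"))
    pb <- primate_breakdown(lab_up,
                            setNames(feats_pri$A_up, feats_pri$event_id),
                            psi_avg(d$psi), s$regime_threshold)
    write_tsv(pb, file.path(outdir, "primate_breakdown.tsv"))
    ts_up <- tissue_specificity_fraction(lab_up, d$psi, s$sigma_max,
                                         s$psi_low, s$psi_high)
    ts_dn <- tissue_specificity_fraction(lab_dn, d$psi, s$sigma_max,
                                         s$psi_low, s$psi_high)
    jsonlite::write_json(list(upstream = ts_up, downstream = ts_dn),
                         file.path(outdir, "tissue_specificity.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("models" %in% stages) {
    d <- get_inputs("models"); need_features("models")
    feats <- read.delim(file.path(outdir, "features.tsv"),
                        stringsAsFactors = FALSE)
    labeled <- label_and_filter(d$psi, s$sigma_max, s$psi_low, s$psi_high)
    sets <- list(
      junc_avg = feats[c("event_id", "R_up", "R_down")],
      junc_only = feats[c("event_id", "J_up", "J_down")],
      avg_only = feats[c("event_id", "A_up", "A_down")])
    metrics <- list()
    ja_scores <- NULL
    for (nm in names(sets)) {
      ev <- evaluate_predictor(sets[[nm]], labeled, n_folds = s$n_folds,
                               seed = config$seed)
      metrics[[paste0("auc_", nm)]] <- ev$auc
      if (nm == "junc_avg") ja_scores <- ev$scores
    }
    per_event <- tapply(ja_scores$score, ja_scores$event_id, mean)
    ie <- intermediate_psi_eval(d$psi, per_event, range = c(0.1, 0.9))
    metrics$intermediate_rho <- ie$rho
    metrics$intermediate_n <- ie$n
    de <- delta_psi_eval(d$psi, ja_scores)
    metrics$delta_psi_rho <- de$rho
    metrics$delta_psi_n <- de$n
    td <- tissue_differential_subset(d$psi, 0.10, s$sigma_max)
    metrics$n_tissue_differential <- length(td)
    jsonlite::write_json(metrics, file.path(outdir, "model_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(ja_scores, file.path(outdir, "junc_avg_scores.tsv"))
  }

  if ("isres" %in% stages || "kmer_stats" %in% stages) {
    d <- get_inputs("isres/kmer_stats")
    prof_up <- kmer_profile(d$events, d$genome, d$mam, "upstream",
                            s$region_start, s$region_end)
    prof_dn <- kmer_profile(d$events, d$genome, d$mam, "downstream",
                            s$region_start, s$region_end)
    comp_up <- composition_features(prof_up$regions)
    comp_dn <- composition_features(prof_dn$regions)
    rp <- residual_psi(psi_avg(d$psi), comp_up, comp_dn)
  }

  if ("isres" %in% stages) {
    for (side in c("upstream", "downstream")) {
      prof <- if (side == "upstream") prof_up else prof_dn
      calls <- discover_isres(prof$counts, rp$residuals, s$q_threshold)
      write_tsv(calls[calls$n_with > 0, ],
                file.path(outdir, paste0("isre_calls_", side, ".tsv")))
    }
  }

  if ("kmer_stats" %in% stages) {
    if (!file.exists(file.path(outdir, "isre_calls_upstream.tsv")))
      stop("stage 'kmer_stats' requires the 'isres' stage to run first")
    summary <- list()
    labeled <- label_and_filter(d$psi, s$sigma_max, s$psi_low, s$psi_high)
    pa <- psi_avg(d$psi)
    for (side in c("upstream", "downstream")) {
      prof <- if (side == "upstream") prof_up else prof_dn
      rec <- kmer_records(prof, rp$residuals, s$min_events)
      write_tsv(rec, file.path(outdir, paste0("kmer_records_", side, ".tsv")))
      mc <- meta_correlation(rec)
      cve <- count_vs_enrichment(prof)
      pt <- if (mc$defined)
        permutation_test(prof, pa, rp$model, n_perm = s$n_perm,
                         seed = config$seed + 1L, min_events = s$min_events)
      else list(p = NA_real_, rho_obs = NA_real_, n_kmers = mc$n)
      calls <- read.delim(file.path(outdir,
                                    paste0("isre_calls_", side, ".tsv")),
                          stringsAsFactors = FALSE)
      ise <- calls$kmer[calls$label == "ISE"]
      iss <- calls$kmer[calls$label == "ISS"]
      cmp <- ise_iss_conservation_comparison(prof, ise, iss)
      summary[[side]] <- list(
        meta_correlation = mc$rho, meta_n_kmers = mc$n,
        permutation_p = pt$p,
        count_enrichment_rho = cve$rho, count_sd = cve$count_sd,
        n_ise = length(ise), n_iss = length(iss),
        ise_iss_comparison = cmp[c("median_iss", "median_ise", "diff",
                                   "larger", "p")])
    }
    jsonlite::write_json(summary, file.path(outdir, "kmer_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(outdir)
}
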