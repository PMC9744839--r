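## End-to-end orchestration: run every stage on simulated (or provided)
## inputs, write stage outputs as TSV/GMT/BED under a run directory, and
## record a deterministic manifest (config hash, seed, output checksums).

#' Default pipeline configuration
#'
#' Stage thresholds default to the values the method states (2 SD / 15%
#' frequent-event rule, 10% / 5% exon rule, FDR 0.05, domain q < 0.1,
#' TF-filter thresholds 2 / 0.05, 0.25, 2 / 0.2, correlation difference
#' 0.2); simulation parameters come from [sim_config()]. Unknown keys are
#' rejected.
#'
#' @param ... overrides for any configuration key.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    simulate = TRUE, seed = 1L, outdir = NULL,
    sim = list(),
    n_pcs = 5, min_genes = 3, scale_pathways = TRUE,
    min_pairs = 6, fdr = 0.05, pos_frac = 0.10, neg_frac = 0.05,
    rule = "positive_only",
    sd_mult = 2, min_frac = 0.15, min_normal_n = 10, sd_floor = 0.01,
    domain_alpha = 0.1, min_overlap_bp = 1,
    max_components = 10, csf_alpha = 0.05, top_k = 100,
    mut_k = 10, mut_delta = 0.05, mut_sd_max = 0.1,
    mutation_delta_mode = "relative",
    kd_min = 0.5, kd_dpsi_cut = -0.1,
    cnv_strata = 3,
    chip_or = 2, chip_alpha = 0.05, knock_alpha = 0.25,
    network_or = 2, network_alpha = 0.2, corr_min_diff = 0.2
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(cfg))
  if (length(unknown))
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, extra)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with any subset of the [pipeline_config()] keys.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

stage_log <- function(...) message("[embryosplice] ", ...)

#' Run the full pipeline
#'
#' Simulates inputs (or fails if `simulate` is off — external-input
#' loading is delegated to the individual readers), then runs pathway
#' scoring and smoothing, embryonic pathway classification, exon
#' classification, the frequent-event caller and overlap enrichment,
#' domain enrichment, the PLSR/CSF model with mutation, knockdown and CNV
#' validation, and the TF cascade. Stage outputs are written under
#' `outdir`; `manifest.json` records the configuration hash, seed and an
#' md5 checksum per output so that identical config + seed reproduces an
#' identical manifest.
#'
#' @param config a [pipeline_config()] (or path to a JSON config).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!config$simulate)
    stop("external-input mode not wired in run_pipeline; use the module ",
         "functions with your own readers, or set simulate = TRUE")
  outdir <- config$outdir %||% tempfile("embryosplice_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage_log("simulate")
  sim <- simulate_all(do.call(sim_config,
                              c(config$sim, list(seed = config$seed))))
  dev <- sim$dev; can <- sim$cancer; ann <- sim$annotation
  reg <- sim$regulatory; truth <- sim$truth

  stage_log("pathway activity + smoothing")
  act <- score_pathway_activity(dev$expr, dev$pathways, config$min_genes)
  smo <- smooth_activity_pca(act, config$n_pcs, config$scale_pathways)
  pw_labels <- classify_embryonic_pathways(smo, dev$meta$prenatal)

  stage_log("exon classification")
  corr <- correlate_exon_pathways(dev$psi, act, config$min_pairs, config$fdr)
  exons <- classify_exons(corr, pw_labels, config$pos_frac,
                          config$neg_frac, config$fdr, config$rule)
  ep <- exons$event_id[exons$label == "EP"]
  en <- exons$event_id[exons$label == "EN"]

  stage_log("cancer frequent events + enrichment")
  calls <- call_frequent_events(can$psi_tumor, can$psi_normal,
                                config$sd_mult, config$min_frac,
                                config$min_normal_n, config$sd_floor)
  universe <- calls$event_id
  increased <- calls$event_id[calls$call %in% c("increased", "both")]
  decreased <- calls$event_id[calls$call %in% c("decreased", "both")]
  enr <- rbind(
    cbind(set = "EP_in_increased",
          overlap_enrichment(increased, ep, universe)),
    cbind(set = "EN_in_decreased",
          overlap_enrichment(decreased, en, universe)))
  enr$q <- bh_adjust(enr$p)

  stage_log("domain enrichment")
  merged <- merge_domain_intervals(ann$domain_bed)
  mapping <- map_domains_to_exons(merged, ann$exon_bed,
                                  config$min_overlap_bp)
  background <- setdiff(universe, c(ep, en))
  domains <- test_domain_enrichment(mapping, ep, en, background,
                                    config$domain_alpha)

  stage_log("PLSR model + CSF calls")
  sf_expr_dev <- dev$expr[truth$sf_ids, , drop = FALSE]
  med_ep_dev <- apply(dev$psi[ep, , drop = FALSE], 2, median, na.rm = TRUE)
  model <- fit_plsr(sf_expr_dev, med_ep_dev, config$max_components)
  csfs <- call_csfs(model, config$csf_alpha, config$top_k)

  stage_log("causal validation: mutations, knockdown, CNV")
  sf_expr_tum <- can$expr_tumor[truth$sf_ids, , drop = FALSE]
  med_ep_tum <- apply(can$psi_tumor[ep, , drop = FALSE], 2, median,
                      na.rm = TRUE)
  pred <- predict_median_ep(model, sf_expr_tum)
  mut_list <- split(can$mutations$sample_id, can$mutations$gene)
  effects <- mutation_effect(med_ep_tum, sf_expr_tum, mut_list,
                             config$mut_k, config$mut_delta,
                             config$mut_sd_max, config$mutation_delta_mode)
  coef_cmp <- compare_effect_coefficients(effects, model)
  kd <- knockdown_response(reg$kd$control_psi, reg$kd$kd_psi,
                           reg$kd$kd_expr, ep, config$kd_min,
                           config$kd_dpsi_cut, csf = csfs$csf)
  cnv <- cnv_stratified_gain(can$expr_tumor, can$cnv, csfs$csf,
                             config$cnv_strata)

  stage_log("TF regulator cascade")
  chip <- chip_filter(reg$binding, csfs$top, csfs$ncsf,
                      config$chip_or, config$chip_alpha)
  cand <- chip$tf[chip$pass]
  knock <- knockdown_filter(reg$knock_downreg, cand, csfs$top, csfs$ncsf,
                            config$knock_alpha)
  network <- network_filter(reg$binding, cand, csfs$top, csfs$ncsf,
                            config$network_or, config$network_alpha)
  corr_f <- correlation_filter(reg$tf_expr, sf_expr_tum, csfs$top,
                               csfs$ncsf, config$corr_min_diff)
  tf_final <- combine_filters(chip, knock, network, corr_f)

  stage_log("write outputs")
  w <- function(name, writer) { path <- file.path(outdir, name); writer(path); path }
  paths <- c(
    w("expression_dev.tsv", function(p) write_matrix_tsv(dev$expr, p, "gene")),
    w("psi_dev.tsv", function(p) write_matrix_tsv(dev$psi, p, "event")),
    w("pathways.gmt", function(p) write_gmt(dev$pathways, p)),
    w("pathway_labels.tsv", function(p) data.table::fwrite(
      data.frame(pathway = names(pw_labels), label = pw_labels), p, sep = "\t")),
    w("exon_labels.tsv", function(p) data.table::fwrite(exons, p, sep = "\t")),
    w("frequent_events.tsv", function(p) data.table::fwrite(calls, p, sep = "\t")),
    w("overlap_enrichment.tsv", function(p) data.table::fwrite(enr, p, sep = "\t")),
    w("domain_enrichment.tsv", function(p) data.table::fwrite(domains, p, sep = "\t")),
    w("csf_calls.tsv", function(p) data.table::fwrite(csfs$table, p, sep = "\t")),
    w("predicted_median_ep.tsv", function(p) data.table::fwrite(pred, p, sep = "\t")),
    w("mutation_effects.tsv", function(p) data.table::fwrite(effects, p, sep = "\t")),
    w("knockdown_response.tsv", function(p) data.table::fwrite(kd$table, p, sep = "\t")),
    w("tf_evidence.tsv", function(p) data.table::fwrite(tf_final, p, sep = "\t"))
  )

  cfg_plain <- unclass(config); cfg_plain$outdir <- NULL
  cfg_file <- tempfile(); on.exit(unlink(cfg_file), add = TRUE)
  jsonlite::write_json(cfg_plain, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "embryosplice",
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(tools::md5sum(paths))
  )
  names(manifest$outputs) <- basename(paths)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    outdir = outdir, manifest = manifest, truth = truth,
    pathway_labels = pw_labels, exons = exons, calls = calls,
    enrichment = enr, domains = domains, model = model, csfs = csfs,
    prediction = pred, mutation_effects = effects,
    coefficient_comparison = coef_cmp, knockdown = kd, cnv = cnv,
    tf = tf_final))
}
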