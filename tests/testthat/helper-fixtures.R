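## Shared fixtures. Heavy default-world simulations (and stages derived
## from them) are cached per seed so acceptance criteria can reuse them.

.sim_cache <- new.env(parent = emptyenv())

## a down-scaled but structurally complete world for unit tests
small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 200, n_pathways = 20, genes_per_pathway = 6,
               n_events = 300, n_sf = 80, n_csf = 20,
               n_tumor = 60, n_normal = 30,
               n_mut_csf = 3, n_mut_increase = 2,
               mut_samples_per_factor = 5,
               kd_n_csf = 5, kd_n_ncsf = 5, n_tf_decoy = 9, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

get_sim <- function(seed) {
  key <- paste0("sim", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_all(sim_config(seed = seed))
  .sim_cache[[key]]
}

## pathway activity, smoothed matrix, labels and exon calls at defaults
get_stage1 <- function(seed) {
  key <- paste0("st1_", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- get_sim(seed)
    act <- score_pathway_activity(sim$dev$expr, sim$dev$pathways)
    smo <- smooth_activity_pca(act)
    labels <- classify_embryonic_pathways(smo, sim$dev$meta$prenatal)
    corr <- correlate_exon_pathways(sim$dev$psi, act)
    exons <- classify_exons(corr, labels)
    .sim_cache[[key]] <- list(act = act, smo = smo, labels = labels,
                              exons = exons)
  }
  .sim_cache[[key]]
}

## fitted PLSR model on the developmental cohort, using planted EP events
get_model <- function(seed) {
  key <- paste0("mod", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- get_sim(seed)
    ep <- names(sim$truth$exon_labels)[sim$truth$exon_labels == "EP"]
    med_ep <- apply(sim$dev$psi[ep, , drop = FALSE], 2, median)
    .sim_cache[[key]] <- fit_plsr(sim$dev$expr[sim$truth$sf_ids, ], med_ep)
  }
  .sim_cache[[key]]
}

## tiny deterministic event table (list-column form) for PSI unit tests
toy_events <- function() {
  data.frame(
    chrom = c("chr1", "chr1"), gene_id = c("G1", "G2"),
    event_id = c("E1", "E2"),
    inclusion = I(list("T1", c("T3", "T4"))),
    total = I(list(c("T1", "T2"), c("T3", "T4", "T5")))
  )
}

write_event_file <- function(lines, path = tempfile(fileext = ".ioe")) {
  header <- "chrom\tgene_id\tevent_id\tinclusion_transcripts\ttotal_transcripts"
  writeLines(c(header, lines), path)
  path
}
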