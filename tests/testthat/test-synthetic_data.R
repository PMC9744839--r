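test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_ep = 0.6, frac_en = 0.6), "frac_ep")
  expect_error(sim_config(n_csf = 50, n_sf = 40), "n_csf")
  expect_error(sim_config(n_pathways = 0), "count")
  expect_error(sim_config(noise_sd = -1), "noise")
  expect_error(sim_config(bogus_knob = 1), "unknown")
  expect_error(generate_development(
    sim_config(n_timepoints_pre = 3, n_timepoints_post = 3)), "at least 8")
})

test_that("generators are bit-reproducible from the master seed", {
  cfg <- small_config(seed = 42)
  a <- simulate_all(cfg)
  b <- simulate_all(cfg)
  expect_identical(a$dev$expr, b$dev$expr)
  expect_identical(a$dev$psi, b$dev$psi)
  expect_identical(a$cancer$psi_tumor, b$cancer$psi_tumor)
  expect_identical(a$cancer$mutations, b$cancer$mutations)
  expect_identical(a$annotation$domain_bed, b$annotation$domain_bed)
  expect_identical(a$regulatory$binding, b$regulatory$binding)
  ## a different seed changes the draw
  expect_false(identical(a$dev$expr,
                         generate_development(small_config(seed = 43))$expr))
})

test_that("development output satisfies its contracts", {
  cfg <- small_config(seed = 2)
  dev <- generate_development(cfg)
  expect_true(all(dev$expr >= 0))
  expect_true(all(dev$psi >= 0 & dev$psi <= 1))
  ## pathway label arithmetic: round(n_pathways * frac) prenatal
  expect_equal(sum(dev$truth$pathway_labels == "prenatal"), 10)
  full <- generate_development(sim_config(seed = 5))
  expect_equal(sum(full$truth$pathway_labels == "prenatal"), 30)
  ## EP/EN/null partition the events
  expect_equal(sort(unique(dev$truth$exon_labels)), c("EN", "EP", "null"))
  expect_equal(length(dev$truth$exon_labels), cfg$n_events)
  expect_true(all(dev$truth$csf_set %in% dev$truth$sf_ids))
})

test_that("noiseless world: prenatal pathways strictly dominate prenatally", {
  cfg <- small_config(seed = 3, noise_sd = 0, psi_noise_sd = 0)
  dev <- generate_development(cfg)
  act <- score_pathway_activity(dev$expr, dev$pathways, min_genes = 1)
  pre <- dev$meta$prenatal
  for (p in names(dev$truth$pathway_labels)[
    dev$truth$pathway_labels == "prenatal"])
    expect_gt(min(act[p, pre]), max(act[p, !pre]))
})

test_that("planted-signal monotonicity: reactivation raises tumor EP inclusion", {
  med_ep <- vapply(c(0.1, 0.3, 0.5, 0.7), function(r) {
    cfg <- small_config(seed = 9, noise_sd = 0, psi_noise_sd = 0,
                        reactivation_strength = r)
    dev <- generate_development(cfg)
    can <- generate_cancer_cohort(dev$truth, cfg)
    ep <- dev$truth$exon_labels == "EP"
    mean(apply(can$psi_tumor[ep, , drop = FALSE], 2, median))
  }, numeric(1))
  expect_true(all(diff(med_ep) > 0))
})

test_that("cancer cohort: mutation referential integrity and planting rules", {
  cfg <- small_config(seed = 4)
  dev <- generate_development(cfg)
  can <- generate_cancer_cohort(dev$truth, cfg)
  tumors <- colnames(can$psi_tumor)
  expect_true(all(can$mutations$sample_id %in% tumors))
  expect_true(all(can$mutations$gene %in% dev$truth$sf_ids))
  expect_true(all(can$cnv %in% c(-1, 0, 1)))
  expect_error(generate_cancer_cohort(dev$truth,
    small_config(seed = 4, mut_targets = "NOT_A_FACTOR")),
    "mutation target")
})

test_that("a sample with all CSFs mutated reverts to the normal median (noiseless)", {
  cfg <- small_config(seed = 6, noise_sd = 0, psi_noise_sd = 0,
                      mut_samples_per_factor = 60)  # every tumor mutated
  dev <- generate_development(cfg)
  cfg$mut_targets <- dev$truth$csf_set
  can <- generate_cancer_cohort(dev$truth, cfg)
  ep <- dev$truth$exon_labels == "EP"
  mut_all <- Reduce(intersect, can$truth$mutated_samples)
  expect_gt(length(mut_all), 0)
  for (s in head(mut_all, 3))
    expect_equal(median(can$psi_tumor[ep, s]),
                 median(apply(can$psi_normal[ep, , drop = FALSE], 1, median)),
                 tolerance = 1e-10)
})

test_that("annotation: exons nest in host genes, intervals are unique", {
  cfg <- small_config(seed = 7)
  dev <- generate_development(cfg)
  ann <- generate_annotation(dev$truth, cfg)
  gene_start <- setNames(ann$tss$tss, ann$tss$gene)
  host <- dev$truth$host_gene[ann$exon_bed$name]
  expect_true(all(ann$exon_bed$start > gene_start[host]))
  expect_true(all(ann$exon_bed$start < ann$exon_bed$end))
  ## no duplicated (domain, interval) rows
  key <- with(ann$domain_bed, paste(name, chrom, start, end))
  expect_equal(anyDuplicated(key), 0)
  ## one inclusion + one exclusion transcript per event, inclusion in total
  ev <- read_events(write_event_file(with(ann$events,
    paste(chrom, gene_id, event_id, inclusion_transcripts,
          total_transcripts, sep = "\t"))))
  expect_equal(nrow(ev), cfg$n_events)
})

test_that("PSI round-trip: generator PSI -> transcript TPM -> compute_psi", {
  cfg <- small_config(seed = 8)
  dev <- generate_development(cfg)
  ann <- generate_annotation(dev$truth, cfg)
  ev <- read_events(write_event_file(with(ann$events,
    paste(chrom, gene_id, event_id, inclusion_transcripts,
          total_transcripts, sep = "\t"))))
  tpm <- psi_to_transcript_tpm(dev$psi, ann$events, total_tpm = 10)
  psi2 <- compute_psi(tpm, ev)
  expect_equal(psi2[rownames(dev$psi), ], dev$psi, tolerance = 1e-12)
})

test_that("regulatory layer: planted TF coverage and noiseless knockdown", {
  cfg <- small_config(seed = 10)
  sim <- simulate_all(cfg)
  csf <- sim$truth$csf_set
  ncsf <- setdiff(sim$truth$sf_ids, csf)
  tgt <- sim$regulatory$binding[["TF_PLANTED"]]
  expect_gte(mean(csf %in% tgt), 0.8)
  expect_lte(mean(ncsf %in% tgt), 0.10)
  ## noiseless knockdown: CSF knockdown shifts EP by exactly kd_dpsi,
  ## non-CSF knockdown leaves PSI unchanged
  cfg0 <- small_config(seed = 10, noise_sd = 0, psi_noise_sd = 0)
  sim0 <- simulate_all(cfg0)
  kd <- sim0$regulatory$kd
  ep <- sim0$truth$exon_labels == "EP"
  ctrl <- rowMeans(kd$control_psi)
  kd_csf <- intersect(names(kd$kd_psi), sim0$truth$csf_set)[1]
  kd_ncsf <- setdiff(names(kd$kd_psi), sim0$truth$csf_set)[1]
  d_csf <- kd$kd_psi[[kd_csf]][ep, 1] - ctrl[ep]
  d_ncsf <- kd$kd_psi[[kd_ncsf]][ep, 1] - ctrl[ep]
  expect_true(all(abs(d_ncsf) < 1e-12))
  expect_true(all(d_csf <= 0) && median(d_csf) < -0.15)
})
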