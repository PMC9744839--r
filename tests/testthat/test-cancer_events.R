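test_that("frequent-event caller applies the SD and fraction rules", {
  set.seed(41)
  normal <- matrix(rnorm(2 * 40, mean = 0.2, sd = 0.05), 2, 40,
                   dimnames = list(c("E1", "E2"), paste0("n", 1:40)))
  tumor <- matrix(0.2, 2, 100,
                  dimnames = list(c("E1", "E2"), paste0("t", 1:100)))
  tumor["E1", 1:20] <- 0.9     # 20% deviate up
  calls <- call_frequent_events(tumor, normal)
  expect_equal(calls$call[calls$event_id == "E1"], "increased")
  expect_equal(calls$call[calls$event_id == "E2"], "none")
  ## z = 3 deviates: mean 0.2, sd 0.05, psi 0.35
  mu <- calls$normal_mean[1]; sdv <- calls$normal_sd[1]
  expect_true(0.35 > mu + 2 * sdv)
  ## monotone in min_frac: raising the threshold never adds calls
  strict <- call_frequent_events(tumor, normal, min_frac = 0.25)
  expect_true(all(strict$call == "none" | strict$call == calls$call))
  ## invariance to tumor sample order
  perm <- sample(100)
  expect_equal(call_frequent_events(tumor[, perm], normal)$call, calls$call)
  ## too few normals -> none
  few <- call_frequent_events(tumor, normal[, 1:5, drop = FALSE])
  expect_true(all(few$call == "none"))
  expect_error(call_frequent_events(tumor[, 0], normal), "empty")
})

test_that("Fisher p agrees with hypergeometric summation on small tables", {
  set.seed(42)
  for (i in 1:60) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b + c_ + d == 0) next
    expect_equal(fisher_2x2(a, b, c_, d)$p, fisher_brute(a, b, c_, d),
                 tolerance = 1e-12)
  }
  ## cross-product odds ratio by hand
  ft <- fisher_2x2(10, 90, 5, 195)
  expect_equal(ft$or, (10 * 195) / (90 * 5))
  expect_false(ft$haldane)
  ## zero cell -> Haldane correction, flagged
  ft0 <- fisher_2x2(0, 10, 5, 185)
  expect_true(ft0$haldane)
  expect_equal(ft0$or, (0.5 * 185.5) / (10.5 * 5.5))
})

test_that("overlap enrichment builds the right table and validates inputs", {
  universe <- paste0("E", 1:300)
  query <- universe[1:100]
  reference <- universe[c(1:10, 101:105)]
  res <- overlap_enrichment(query, reference, universe)
  expect_equal(res$n_overlap, 10)
  expect_equal(res$n_query_only, 90)
  expect_equal(res$n_ref_only, 5)
  expect_equal(res$or, (10 * 195) / (90 * 5))
  expect_error(overlap_enrichment("X1", reference, universe), "subsets")
  expect_error(overlap_enrichment(query, reference, character(0)), "empty")
  ## exchangeable null: random half-splits give roughly uniform p
  set.seed(43)
  ps <- replicate(200, {
    q <- sample(universe, 150)
    r <- sample(universe, 150)
    overlap_enrichment(q, r, universe)$p
  })
  ## exact-test p-values are discrete, so check the rejection level
  ## rather than full KS uniformity
  expect_lte(mean(ps < 0.05), 0.09)
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("stage stratification: identical strata give identical ORs", {
  sim <- get_sim(1)
  truth <- sim$truth
  ep <- names(truth$exon_labels)[truth$exon_labels == "EP"]
  en <- names(truth$exon_labels)[truth$exon_labels == "EN"]
  tum <- sim$cancer$psi_tumor[, 1:40]
  stage <- setNames(rep(c("A", "B"), each = 20), colnames(tum))
  ## duplicate stratum: same samples under two labels
  tum2 <- cbind(tum[, 1:20], tum[, 1:20])
  colnames(tum2) <- paste0("s", 1:40)
  stage2 <- setNames(rep(c("A", "B"), each = 20), colnames(tum2))
  res <- stage_stratified_enrichment(tum2, sim$cancer$psi_normal, stage2,
                                     ep, en, min_n = 10)
  a <- res[res$stratum == "A", "or"]
  b <- res[res$stratum == "B", "or"]
  expect_equal(a, b)
  ## single usable stratum warns
  expect_warning(
    expect_warning(
      stage_stratified_enrichment(tum, sim$cancer$psi_normal,
                                  setNames(c(rep("A", 35), rep("B", 5)),
                                           colnames(tum)),
                                  ep, en, min_n = 10),
      "dropping strata"),
    "one usable stratum")
})

test_that("signature correlation finds the planted coupling", {
  sim <- get_sim(1)
  truth <- sim$truth
  ep <- names(truth$exon_labels)[truth$exon_labels == "EP"]
  en <- names(truth$exon_labels)[truth$exon_labels == "EN"]
  ## gene set tracking the reactivated program: prenatal pathway genes
  pre_pw <- names(truth$pathway_labels)[truth$pathway_labels == "prenatal"]
  sets <- list(prenatal_signature = unlist(sim$dev$pathways[pre_pw[1:5]],
                                           use.names = FALSE),
               empty_set = c("NOT_A_GENE"))
  res <- suppressWarnings(signature_correlation(
    sim$cancer$psi_tumor, ep, sim$cancer$expr_tumor, sets))
  expect_equal(nrow(res), 1)  # empty set skipped
  expect_gt(res$r, 0)
  expect_lt(res$q, 0.05)
  res_en <- suppressWarnings(signature_correlation(
    sim$cancer$psi_tumor, en, sim$cancer$expr_tumor, sets))
  expect_lt(res_en$r, 0)
  ## constant event-set median -> missing r
  psi_const <- sim$cancer$psi_tumor
  psi_const[ep, ] <- 0.5
  res_c <- suppressWarnings(signature_correlation(
    psi_const, ep, sim$cancer$expr_tumor, sets))
  expect_true(is.na(res_c$r))
})

test_that("phenotype-correlation enrichment recovers planted anti-correlation", {
  sim <- get_sim(1)
  truth <- sim$truth
  ep <- names(truth$exon_labels)[truth$exon_labels == "EP"]
  en <- names(truth$exon_labels)[truth$exon_labels == "EN"]
  med_ep <- apply(sim$cancer$psi_tumor[ep, ], 2, median)
  set.seed(44)
  pheno <- -med_ep + rnorm(length(med_ep), 0, 0.02)  # doubling-time analogue
  res <- correlation_set_enrichment(sim$cancer$psi_tumor, pheno, ep, en)
  neg_ep <- res[res$set == "EP" & res$sign == "negative", ]
  expect_gt(neg_ep$or, 1)
  expect_lt(neg_ep$q, 0.05)
  ## threshold 1 -> empty correlated sets, underpowered
  res1 <- correlation_set_enrichment(sim$cancer$psi_tumor, pheno, ep, en,
                                     pcc_threshold = 1)
  expect_true(all(res1$underpowered))
})
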