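## helper: expression matrix whose log2(TPM+1) equals a given design matrix
expr_from_design <- function(X) {
  out <- 2^t(X) - 1
  rownames(out) <- colnames(X)
  colnames(out) <- rownames(X)
  out
}

test_that("full-rank noiseless PLS1 equals the least-squares solution", {
  set.seed(61)
  for (rep in 1:3) {
    X <- matrix(rnorm(50), 10, 5,
                dimnames = list(paste0("s", 1:10), paste0("F", 1:5)))
    beta <- rnorm(5)
    y <- setNames(drop(X %*% beta) + 0.3, rownames(X))
    fit <- fit_plsr(expr_from_design(X), y, max_components = 5, ncomp = 5)
    ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
    expect_equal(unname(fit$coefficients), unname(ols[-1]), tolerance = 1e-8)
    ## predicting on the training matrix reproduces y exactly
    pred <- predict_median_ep(fit, expr_from_design(X))
    expect_equal(pred$predicted, unname(y), tolerance = 1e-8)
  }
})

test_that("PLSR identifies a single informative factor and is permutation-invariant", {
  set.seed(62)
  n <- 30
  X <- matrix(rnorm(n * 8, sd = 1), n, 8,
              dimnames = list(paste0("s", 1:n), paste0("F", 1:8)))
  y <- setNames(0.5 + 0.2 * X[, 3] + rnorm(n, 0, 1e-4), rownames(X))
  fit <- fit_plsr(expr_from_design(X), y)
  expect_equal(names(which.max(fit$coefficients)), "F3")
  expect_lt(fit$q[["F3"]], 0.05)
  ## permuting samples leaves coefficients unchanged
  perm <- sample(n)
  fit2 <- fit_plsr(expr_from_design(X)[, perm], y[perm])
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)
  ## per-factor affine rescale of the log-expression leaves predictions
  ## unchanged (z-scoring round trip)
  X3 <- sweep(sweep(X, 2, c(2, 1, 3, 1, 1, 0.5, 1, 1), "*"),
              2, c(0, 1, -1, 0, 2, 0, 0, 0), "+")
  fit3 <- fit_plsr(expr_from_design(X3), y)
  expect_equal(predict_median_ep(fit3, expr_from_design(X3))$predicted,
               predict_median_ep(fit, expr_from_design(X))$predicted,
               tolerance = 1e-8)
  ## guards
  expect_error(fit_plsr(expr_from_design(X[1:5, ]), y[1:5]), "at least 8")
  expect_error(fit_plsr(expr_from_design(X), setNames(rep(1, n), rownames(X))),
               "constant")
})

test_that("CSF calling applies the sign/FDR rule and top-k truncation", {
  model <- structure(list(
    factors = paste0("F", 1:4),
    coefficients = setNames(c(2, -3, 1, 0.5), paste0("F", 1:4)),
    p = setNames(c(0.001, 0.001, 0.2, 0.01), paste0("F", 1:4)),
    q = setNames(c(0.004, 0.001, 0.3, 0.02), paste0("F", 1:4))),
    class = "plsr_model")
  calls <- call_csfs(model, alpha = 0.05, top_k = 10)
  expect_setequal(calls$csf, c("F1", "F4"))
  ## negative coefficient with tiny q is not a CSF
  expect_false("F2" %in% calls$csf)
  ## top_k larger than the CSF count -> top = all CSFs
  expect_setequal(calls$top, calls$csf)
  expect_setequal(calls$ncsf, c("F2", "F3"))
  calls1 <- call_csfs(model, top_k = 1)
  expect_equal(calls1$top, "F1")  # ranked by coefficient
})

test_that("prediction validates factors and reduces to a constant on zeros", {
  set.seed(63)
  X <- matrix(rnorm(80), 16, 5,
              dimnames = list(paste0("s", 1:16), paste0("F", 1:5)))
  y <- setNames(drop(X %*% rnorm(5)) + rnorm(16, 0, 0.01), rownames(X))
  fit <- fit_plsr(expr_from_design(X), y)
  expect_error(predict_median_ep(fit, expr_from_design(X)[1:3, ]), "absent")
  zero <- matrix(0, 5, 2, dimnames = list(paste0("F", 1:5), c("a", "b")))
  pz <- predict_median_ep(fit, zero)
  expect_equal(pz$predicted[1], pz$predicted[2])
  expect_equal(pz$predicted[1], fit$intercept)
})

test_that("mutation effect: exact-duplicate matching, direction rules, determinism", {
  set.seed(64)
  sfe <- matrix(rexp(6 * 12), 6, 12,
                dimnames = list(paste0("F", 1:6), paste0("s", 1:12)))
  sfe[, "s2"] <- sfe[, "s1"]  # s2 duplicates mutant s1
  med <- setNames(c(0.4, rep(c(0.6, 0.61, 0.59), 4)[1:11]), colnames(sfe))
  eff <- mutation_effect(med, sfe, list(F1 = "s1"), k = 1)
  ## the matched set is the expression duplicate
  expect_equal(eff$background_median_ep, med[["s2"]])
  expect_equal(eff$class, "decreased")  # 0.4 vs 0.6: -33%
  ## equal medians -> untestable
  med2 <- med; med2["s1"] <- med2["s2"]
  eff2 <- mutation_effect(med2, sfe, list(F1 = "s1"), k = 1)
  expect_equal(eff2$class, "untestable")
  ## unknown mutant sample
  expect_error(mutation_effect(med, sfe, list(F1 = "nope")), "missing")
  ## permutation invariance in background order
  perm <- c("s1", sample(colnames(sfe)[-1]))
  effp <- mutation_effect(med[perm], sfe[, perm], list(F1 = "s1"), k = 3)
  eff3 <- mutation_effect(med, sfe, list(F1 = "s1"), k = 3)
  expect_equal(effp$delta, eff3$delta)
})

test_that("coefficient comparison contrasts effect groups", {
  model <- structure(list(
    coefficients = setNames(c(3, 2.5, 2, 1.8, 0.1, 0, -0.2),
                            paste0("F", 1:7))), class = "plsr_model")
  effects <- data.frame(factor = paste0("F", 1:7),
                        class = c("decreased", "decreased", "decreased",
                                  "decreased", "increased", "increased",
                                  "increased"))
  cmp <- compare_effect_coefficients(effects, model)
  expect_equal(cmp$direction, "decreased_higher")
  expect_lt(cmp$p, 0.1)
  expect_warning(
    expect_null(compare_effect_coefficients(
      effects[effects$class == "decreased", ], model)),
    "empty")
  one <- compare_effect_coefficients(effects[c(1, 5), ], model)
  expect_true(one$low_power)
})

test_that("knockdown response applies the expression filter and both-replicate rule", {
  ep <- paste0("E", 1:10)
  ctrl <- matrix(0.6, 10, 4, dimnames = list(ep, paste0("c", 1:4)))
  kd_good <- matrix(0.35, 10, 2, dimnames = list(ep, c("r1", "r2")))
  kd_onerep <- matrix(0.35, 10, 2, dimnames = list(ep, c("r1", "r2")))
  kd_onerep[, 2] <- 0.55                      # second replicate fails cut
  kd_weak <- matrix(0.35, 10, 2, dimnames = list(ep, c("r1", "r2")))
  kd_expr <- data.frame(factor = c("A", "B", "C"),
                        control_expr = c(10, 10, 10),
                        kd_expr = c(2, 3, 9))  # C fails the 50% rule
  out <- knockdown_response(ctrl, list(A = kd_good, B = kd_onerep,
                                       C = kd_weak),
                            kd_expr, ep)
  expect_setequal(out$table$factor, c("A", "B"))  # C filtered out
  expect_equal(out$table$frac_decreased[out$table$factor == "A"], 1)
  expect_equal(out$table$frac_decreased[out$table$factor == "B"], 0)
  ## CSF-vs-rest one-sided comparison
  out2 <- knockdown_response(ctrl, list(A = kd_good, B = kd_onerep),
                             kd_expr, ep, csf = "A")
  expect_lt(out2$p, 1)
})

test_that("CNV stratification handles planted gains and degenerate inputs", {
  sim <- get_sim(1)
  truth <- sim$truth
  res <- cnv_stratified_gain(sim$cancer$expr_tumor, sim$cancer$cnv,
                             truth$csf_set)
  expect_gt(mean(res$means[, 3]), mean(res$means[, 1]))
  expect_lt(res$p, 0.05)
  ## all-zero CNV -> all means zero, p in the no-shift regime
  cnv0 <- sim$cancer$cnv; cnv0[] <- 0L
  res0 <- cnv_stratified_gain(sim$cancer$expr_tumor, cnv0, truth$csf_set)
  expect_true(all(res0$means == 0))
  expect_equal(res0$p, 1)
  ## n_strata = n samples -> means are raw CNV values
  small_expr <- sim$cancer$expr_tumor[, 1:5]
  small_cnv <- sim$cancer$cnv[, 1:5]
  f <- truth$csf_set[1]
  res5 <- cnv_stratified_gain(small_expr, small_cnv, f, n_strata = 5)
  expect_setequal(as.numeric(res5$means), as.numeric(small_cnv[f, ]))
  ## invalid CNV values rejected
  bad <- small_cnv; bad[1, 1] <- 2
  expect_error(cnv_stratified_gain(small_expr, bad, f), "-1, 0, 1")
})
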