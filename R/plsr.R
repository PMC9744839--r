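## Partial least squares regression of median EP inclusion on
## splicing-factor expression, CSF calling, cross-cohort prediction, and
## the causal-validation statistics (expression-matched mutation effects,
## shRNA knockdown response, CNV stratification).
##
## PLS1 (single response) is fitted by NIPALS: latent scores T and U are
## extracted so that successive components maximize the covariance between
## the X- and Y-side scores (X = T P' + E, Y = U Q' + F, U = T B + H);
## the implied regression coefficients are mapped back to the original
## predictor scale. Component count is chosen by leave-one-out
## cross-validation; per-factor significance comes from the jackknife
## variance of the coefficients across the LOO segments.

## core PLS1 on centered/scaled X (n x p) and centered y; returns the
## coefficient vector (scaled space) for each component count 1..A
pls1_core <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  Xd <- X; yd <- y
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xd, yd))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p_ <- drop(crossprod(Xd, t_)) / tt
    q_ <- sum(yd * t_) / tt
    W[, a] <- w; P[, a] <- p_; Q[a] <- q_
    Xd <- Xd - tcrossprod(t_, p_)
    yd <- yd - q_ * t_
    a_eff <- a
  }
  coefs <- matrix(0, p, A)
  if (a_eff > 0) {
    for (a in seq_len(a_eff)) {
      Wa <- W[, seq_len(a), drop = FALSE]
      Pa <- P[, seq_len(a), drop = FALSE]
      R <- Wa %*% solve(crossprod(Pa, Wa), diag(a))
      coefs[, a] <- drop(R %*% Q[seq_len(a)])
    }
    if (a_eff < A) for (a in (a_eff + 1L):A) coefs[, a] <- coefs[, a_eff]
  }
  coefs
}

#' Fit the PLSR model of median EP inclusion on splicing-factor expression
#'
#' Predictors (log2(TPM+1) of each splicing factor) are z-scored and the
#' response centered. The component count is chosen by leave-one-out
#' cross-validation minimizing the root mean squared error of prediction
#' over 1..`max_components`; per-factor p-values come from a jackknife
#' t-statistic over the LOO segments (df = n - 1), BH-adjusted across
#' factors. Zero-variance factors are dropped with a message.
#'
#' @param sf_expr splicing-factor x sample TPM matrix.
#' @param median_ep named per-sample response (median EP inclusion).
#' @param max_components cap on the latent dimension (default 10).
#' @param ncomp optional fixed component count overriding the CV choice.
#' @return object of class `plsr_model`: per-factor coefficients on the
#'   original log-expression scale, `p`/`q`, the chosen `n_components`,
#'   the CV error curve, standardization parameters and intercept.
#' @export
fit_plsr <- function(sf_expr, median_ep, max_components = 10,
                     ncomp = NULL) {
  shared <- intersect(colnames(sf_expr), names(median_ep))
  n <- length(shared)
  if (n < 8) stop("need at least 8 samples to fit the PLSR model")
  X0 <- t(log2p1(sf_expr[, shared, drop = FALSE]))  # samples x factors
  y <- median_ep[shared]
  if (var(y) == 0) stop("response is constant")
  keep <- apply(X0, 2, var) > 0
  if (!all(keep))
    message(sum(!keep), " zero-variance factor(s) dropped")
  X0 <- X0[, keep, drop = FALSE]
  p <- ncol(X0)
  A <- max(1L, min(max_components, n - 2L, p))

  xc <- colMeans(X0); xs <- apply(X0, 2, sd)
  Xs <- scale(X0, center = xc, scale = xs)
  yc <- mean(y)

  ## leave-one-out CV: per held-out sample, refit (restandardizing on the
  ## training fold) and predict at every component count
  press <- matrix(NA_real_, n, A)
  jack <- array(NA_real_, c(n, p, A))
  for (i in seq_len(n)) {
    Xt <- X0[-i, , drop = FALSE]; yt <- y[-i]
    xct <- colMeans(Xt); xst <- apply(Xt, 2, sd)
    xst[xst == 0] <- 1
    B <- pls1_core(scale(Xt, center = xct, scale = xst), yt - mean(yt), A)
    z <- (X0[i, ] - xct) / xst
    press[i, ] <- (mean(yt) + drop(z %*% B) - y[i])^2
    jack[i, , ] <- B / xst  # original-scale coefficients per segment
  }
  rmsep <- sqrt(colMeans(press))
  if (is.null(ncomp)) ncomp <- which.min(rmsep)
  if (ncomp > A) stop("ncomp exceeds the available component range")

  B_full <- pls1_core(Xs, y - yc, A)
  coef_scaled <- B_full[, ncomp]
  coef_orig <- coef_scaled / xs
  intercept <- yc - sum(coef_orig * xc)

  bj <- jack[, , ncomp, drop = TRUE]
  if (is.null(dim(bj))) bj <- matrix(bj, ncol = p)
  bbar <- colMeans(bj)
  v_jack <- (n - 1) / n * colSums(sweep(bj, 2, bbar)^2)
  se <- sqrt(v_jack)
  tstat <- ifelse(se > 0, coef_orig / se, 0)
  pval <- 2 * pt(-abs(tstat), df = n - 1)
  pval[se == 0 & coef_orig == 0] <- 1

  structure(list(
    factors = colnames(X0),
    coefficients = setNames(coef_orig, colnames(X0)),
    coef_scaled = setNames(coef_scaled, colnames(X0)),
    se = setNames(se, colnames(X0)),
    p = setNames(pval, colnames(X0)),
    q = setNames(bh_adjust(pval), colnames(X0)),
    n_components = ncomp, max_components = A,
    cv_rmsep = rmsep,
    x_center = xc, x_scale = xs, y_center = yc,
    intercept = intercept, n_samples = n
  ), class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("PLSR model:", length(x$factors), "factors,",
      x$n_samples, "samples,", x$n_components, "component(s)\n")
  cat("  CV RMSEP at chosen rank:",
      format(x$cv_rmsep[x$n_components], digits = 4), "\n")
  cat("  factors with q < 0.05 and positive coefficient:",
      sum(x$q < 0.05 & x$coefficients > 0, na.rm = TRUE), "\n")
  invisible(x)
}

#' Call critical splicing factors from a fitted model
#'
#' A factor is a CSF when its coefficient is positive and its BH q-value
#' falls below `alpha`; CSFs are ranked by coefficient (descending) and
#' the top `top_k` form the foreground set used by the TF-regulator
#' filters. Everything else is the nCSF background.
#'
#' @param model a [fit_plsr()] result.
#' @param alpha FDR threshold (default 0.05).
#' @param top_k foreground truncation (default 100).
#' @return list with `table` (factor, coefficient, q, csf flag, rank),
#'   `csf`, `top` and `ncsf` character vectors.
#' @export
call_csfs <- function(model, alpha = 0.05, top_k = 100) {
  csf_flag <- model$coefficients > 0 & model$q < alpha
  if (!any(csf_flag)) warning("no factor passes the CSF criterion")
  tab <- data.frame(factor = model$factors,
                    coefficient = unname(model$coefficients),
                    p = unname(model$p), q = unname(model$q),
                    csf = unname(csf_flag), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$coefficient), ]
  tab$rank <- NA_integer_
  tab$rank[tab$csf] <- seq_len(sum(tab$csf))
  csf <- tab$factor[tab$csf]
  list(table = tab, csf = csf,
       top = head(csf, top_k),
       ncsf = setdiff(model$factors, head(csf, top_k)))
}

#' Predict median EP inclusion in a new cohort
#'
#' Applies the stored standardization and linear map to new
#' splicing-factor expression. Predictions are not clipped; values
#' outside [0,1] are flagged.
#'
#' @param model a [fit_plsr()] result.
#' @param new_expr factor x sample TPM matrix containing every model
#'   factor.
#' @return data.frame with per-sample `predicted` and an `out_of_range`
#'   flag.
#' @export
predict_median_ep <- function(model, new_expr) {
  missing_f <- setdiff(model$factors, rownames(new_expr))
  if (length(missing_f))
    stop("model factors absent from new expression matrix: ",
         paste(head(missing_f, 10), collapse = ", "))
  X <- t(log2p1(new_expr[model$factors, , drop = FALSE]))
  pred <- drop(X %*% model$coefficients) + model$intercept
  data.frame(sample_id = rownames(X), predicted = unname(pred),
             out_of_range = pred < 0 | pred > 1,
             stringsAsFactors = FALSE)
}

#' Expression-matched mutation effect on median EP inclusion
#'
#' For each mutated splicing factor, every mutant sample is matched to its
#' `k` nearest background samples (tumors not mutated for any factor) by
#' Euclidean distance over z-scored splicing-factor expression (ties
#' broken by sample id). Each mutant sample is contrasted against the
#' median EP of its own matched set; the per-factor effect is the median
#' of these matched-pair differences. A factor is discarded when the
#' matched sets are too variable (mean within-set SD of median EP above
#' `sd_max`), and otherwise classified `increased` / `decreased` when the
#' effect reaches `delta` (relative to the background level by default,
#' absolute PSI difference with `mode = "absolute"`); `untestable`
#' otherwise.
#'
#' @param median_ep named per-sample median EP inclusion.
#' @param sf_expr factor x sample TPM matrix.
#' @param mutations list: factor -> mutant sample ids.
#' @param k matched background size per mutant sample (default 10).
#' @param delta effect threshold (default 0.05).
#' @param sd_max background variability cutoff (default 0.1).
#' @param mode "relative" (default) or "absolute" reading of `delta`.
#' @return data.frame per factor: sample counts, background and mutant
#'   medians, delta, class.
#' @export
mutation_effect <- function(median_ep, sf_expr, mutations, k = 10,
                            delta = 0.05, sd_max = 0.1,
                            mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  samples <- colnames(sf_expr)
  mut_all <- unique(unlist(mutations, use.names = FALSE))
  if (!all(mut_all %in% samples))
    stop("mutant samples missing from the cohort: ",
         paste(setdiff(mut_all, samples), collapse = ", "))
  background <- setdiff(samples, mut_all)
  if (!length(background)) stop("no background (never-mutated) samples")
  Z <- t(scale(t(log2p1(sf_expr))))
  Z[is.na(Z)] <- 0  # constant factors carry no matching information
  rows <- lapply(names(mutations), function(f) {
    mut <- mutations[[f]]
    match_sets <- lapply(sort(mut), function(s) {
      d <- sqrt(colSums((Z[, background, drop = FALSE] - Z[, s])^2))
      background[order(d, background)[seq_len(min(k, length(background)))]]
    })
    ## matched-pair contrast: each mutant sample against the median of its
    ## own matched set, aggregated across carriers (keeps the pairing the
    ## expression matching was built to provide)
    set_med <- vapply(match_sets, function(s) median(median_ep[s]),
                      numeric(1))
    ## variability guard: within each mutant sample's matched set, the
    ## background median-EP values must be stable
    set_sd <- vapply(match_sets, function(s)
      if (length(s) < 2) 0 else sd(median_ep[s]), numeric(1))
    bg_med <- median(set_med)
    mut_med <- median(median_ep[mut])
    paired <- median(median_ep[sort(mut)] - set_med)  # robust matched-pair estimator
    dd <- if (mode == "relative") paired / bg_med else paired
    cls <- if (mean(set_sd) > sd_max) "discarded"
           else if (dd >= delta) "increased"
           else if (dd <= -delta) "decreased"
           else "untestable"
    data.frame(factor = f, n_mutant = length(mut),
               n_matched = sum(lengths(match_sets)),
               background_median_ep = bg_med, mutant_median_ep = mut_med,
               background_sd = mean(set_sd), delta = dd, class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare PLSR coefficients between mutation-effect classes
#'
#' Two-sided Wilcoxon rank-sum of the model coefficients of factors whose
#' mutation decreased vs increased median EP inclusion.
#'
#' @param effects a [mutation_effect()] table.
#' @param model a [fit_plsr()] result.
#' @return list with group sizes and medians, `p`, and a `low_power` flag
#'   (any group of size 1); `NULL` with a warning if a group is empty.
#' @export
compare_effect_coefficients <- function(effects, model) {
  dec <- effects$factor[effects$class == "decreased"]
  inc <- effects$factor[effects$class == "increased"]
  if (!length(dec) || !length(inc)) {
    warning("one of the effect groups is empty; comparison skipped")
    return(NULL)
  }
  cd <- model$coefficients[dec]; ci <- model$coefficients[inc]
  p <- suppressWarnings(wilcox.test(cd, ci)$p.value)
  list(n_decreased = length(dec), n_increased = length(inc),
       median_decreased = median(cd), median_increased = median(ci),
       direction = if (median(cd) > median(ci)) "decreased_higher"
                   else "increased_higher",
       p = p, low_power = length(dec) == 1 || length(inc) == 1)
}

#' Fraction of EP events responding to each factor knockdown
#'
#' A factor is kept only when its own expression drops by at least
#' `min_kd` relative to the control mean; for kept factors, an EP event
#' counts as decreased when its change in inclusion relative to the
#' control aggregate falls below `dpsi_cut` in both replicates. When a
#' `csf` set is supplied, a one-sided Wilcoxon rank-sum (CSF fractions
#' greater) accompanies the table.
#'
#' @param control_psi event x control-replicate PSI matrix.
#' @param kd_psi named list: factor -> event x 2 replicate PSI matrix.
#' @param kd_expr data.frame with `factor`, `control_expr`, `kd_expr`.
#' @param ep character vector of EP event ids.
#' @param min_kd minimum relative expression knockdown (default 0.5).
#' @param dpsi_cut per-replicate inclusion-change cutoff (default -0.1).
#' @param csf optional CSF set for the group comparison.
#' @return list with `table` (factor, kept, fraction decreased) and, when
#'   `csf` is given, `p` of the one-sided comparison.
#' @export
knockdown_response <- function(control_psi, kd_psi, kd_expr, ep,
                               min_kd = 0.5, dpsi_cut = -0.1, csf = NULL) {
  ep <- intersect(ep, rownames(control_psi))
  if (!length(ep)) stop("no EP event present in the control PSI matrix")
  ctrl <- apply(control_psi[ep, , drop = FALSE], 1, median, na.rm = TRUE)
  rows <- lapply(names(kd_psi), function(f) {
    m <- kd_psi[[f]]
    if (is.null(m) || ncol(m) != 2) {
      warning("factor ", f, " lacks two replicates; skipped")
      return(NULL)
    }
    ke <- kd_expr[kd_expr$factor == f, ]
    kept <- nrow(ke) == 1 &&
      (ke$control_expr - ke$kd_expr) / ke$control_expr >= min_kd
    dpsi <- m[ep, , drop = FALSE] - ctrl
    dec <- rowSums(dpsi < dpsi_cut, na.rm = FALSE) == 2
    data.frame(factor = f, kept = kept,
               n_ep = length(ep),
               frac_decreased = mean(dec, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$kept, , drop = FALSE]
  out <- list(table = tab)
  if (!is.null(csf)) {
    a <- tab$frac_decreased[tab$factor %in% csf]
    b <- tab$frac_decreased[!tab$factor %in% csf]
    if (length(a) && length(b))
      out$p <- suppressWarnings(
        wilcox.test(a, b, alternative = "greater")$p.value)
  }
  out
}

#' CNV gain stratified by CSF expression
#'
#' For each CSF, samples are split into `n_strata` equal-frequency groups
#' by that CSF's expression (ties broken by stable sample order) and the
#' mean CNV value of the CSF is computed per group. The distributions of
#' per-CSF means in the extreme strata are compared by a two-sided
#' Wilcoxon rank-sum.
#'
#' @param expr gene x sample TPM matrix.
#' @param cnv gene x sample matrix with values in -1/0/1.
#' @param csf character vector of CSF gene ids.
#' @param n_strata number of expression strata (default 3).
#' @return list with `means` (CSF x stratum matrix) and `p` comparing the
#'   top vs bottom stratum.
#' @export
cnv_stratified_gain <- function(expr, cnv, csf, n_strata = 3) {
  if (!all(unique(as.vector(cnv)) %in% c(-1, 0, 1)))
    stop("CNV values must lie in {-1, 0, 1}")
  shared <- intersect(colnames(expr), colnames(cnv))
  csf <- intersect(csf, intersect(rownames(expr), rownames(cnv)))
  means <- matrix(NA_real_, length(csf), n_strata,
                  dimnames = list(csf, paste0("S", seq_len(n_strata))))
  for (f in csf) {
    e <- expr[f, shared]
    if (length(unique(e)) < n_strata) next  # cannot form strata
    g <- cut(rank(e, ties.method = "first"), breaks = n_strata,
             labels = FALSE)
    means[f, ] <- vapply(seq_len(n_strata), function(k)
      mean(cnv[f, shared[g == k]]), numeric(1))
  }
  skipped <- rowSums(is.na(means)) == n_strata
  means <- means[!skipped, , drop = FALSE]
  p <- if (nrow(means) >= 2 &&
           (var(means[, 1]) > 0 || var(means[, n_strata]) > 0))
    suppressWarnings(wilcox.test(means[, n_strata], means[, 1])$p.value)
  else 1
  list(means = means, p = p, n_skipped = sum(skipped))
}
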