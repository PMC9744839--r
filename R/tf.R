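## Four-filter cascade for transcription factors that preferentially
## regulate critical splicing factors (CSFs) over the remaining splicing
## factors (nCSFs): promoter-binding enrichment (strict gate), knockdown
## downregulation enrichment, inferred-network target enrichment, and an
## expression-correlation contrast. All set tests route through the shared
## Fisher primitive.

tf_set_test <- function(sets, csf, ncsf) {
  rows <- lapply(names(sets), function(nm) {
    ft <- set_enrichment(sets[[nm]], csf, ncsf)
    data.frame(name = nm, n_csf_bound = ft$counts[["a"]],
               n_ncsf_bound = ft$counts[["b"]],
               or = ft$or, p = ft$p, haldane = ft$haldane,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ChIP promoter-binding filter
#'
#' Per TF, Fisher enrichment of its promoter-bound factors (within the
#' 1-kb-upstream window the binding sets are built from) for CSFs versus
#' nCSFs; BH across TFs; pass when OR > `or_min` and q < `alpha`. This is
#' the strict gate of the cascade.
#'
#' @param tf_targets named list: TF -> bound factor ids.
#' @param csf,ncsf foreground (top CSFs) and background factor sets.
#' @param or_min,alpha thresholds (defaults 2 and 0.05).
#' @return data.frame per TF: counts, OR, p, q, pass.
#' @export
chip_filter <- function(tf_targets, csf, ncsf, or_min = 2, alpha = 0.05) {
  res <- tf_set_test(tf_targets, csf, ncsf)
  names(res)[names(res) == "name"] <- "tf"
  res$q <- bh_adjust(res$p)
  res$pass <- res$or > or_min & res$q < alpha
  res
}

#' Knockdown (KnockTF-style) downregulation filter
#'
#' Per (TF, cell line) downregulated set, Fisher enrichment for CSFs;
#' one BH family over all tested pairs; a TF passes when any of its pairs
#' has OR > 1 and q < `alpha`. TFs absent from the resource are returned
#' `tested = FALSE` (they flow to the computational branch).
#'
#' @param downreg_sets named list, names `TF:cellline` -> downregulated
#'   gene ids.
#' @param candidates TFs to evaluate (those passing [chip_filter()]).
#' @param csf,ncsf factor sets.
#' @param alpha FDR threshold (default 0.25).
#' @return data.frame per candidate TF: best OR/q, pass, tested.
#' @export
knockdown_filter <- function(downreg_sets, candidates, csf, ncsf,
                             alpha = 0.25) {
  pair_tf <- sub(":.*$", "", names(downreg_sets))
  use <- pair_tf %in% candidates
  res <- if (any(use)) {
    tab <- tf_set_test(downreg_sets[use], csf, ncsf)
    tab$tf <- pair_tf[use]
    tab$q <- bh_adjust(tab$p)
    tab
  } else NULL
  rows <- lapply(candidates, function(tf) {
    sub <- if (is.null(res)) NULL else res[res$tf == tf, , drop = FALSE]
    if (is.null(sub) || nrow(sub) == 0)
      return(data.frame(tf = tf, best_or = NA_real_, best_q = NA_real_,
                        pass = FALSE, tested = FALSE,
                        stringsAsFactors = FALSE))
    ok <- sub$or > 1 & sub$q < alpha
    best <- if (any(ok)) which(ok)[which.min(sub$q[ok])] else which.min(sub$q)
    data.frame(tf = tf, best_or = sub$or[best], best_q = sub$q[best],
               pass = any(ok), tested = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Inferred-network target filter
#'
#' Fisher enrichment of externally inferred TF targets for CSFs; BH
#' across candidate TFs; pass when OR > `or_min` and q < `alpha`. Empty or
#' missing target sets are untested.
#'
#' @param inferred_targets named list: TF -> inferred target ids.
#' @param candidates TFs to evaluate.
#' @param csf,ncsf factor sets.
#' @param or_min,alpha thresholds (defaults 2 and 0.2).
#' @return data.frame per candidate TF: OR, p, q, pass, tested.
#' @export
network_filter <- function(inferred_targets, candidates, csf, ncsf,
                           or_min = 2, alpha = 0.2) {
  have <- intersect(candidates,
                    names(inferred_targets)[lengths(inferred_targets) > 0])
  res <- if (length(have)) {
    tab <- tf_set_test(inferred_targets[have], csf, ncsf)
    names(tab)[names(tab) == "name"] <- "tf"
    tab$q <- bh_adjust(tab$p)
    tab$pass <- tab$or > or_min & tab$q < alpha
    tab$tested <- TRUE
    tab
  } else NULL
  rows <- lapply(candidates, function(tf) {
    sub <- if (is.null(res)) NULL else res[res$tf == tf, , drop = FALSE]
    if (is.null(sub) || nrow(sub) == 0)
      return(data.frame(tf = tf, or = NA_real_, p = NA_real_, q = NA_real_,
                        pass = FALSE, tested = FALSE,
                        stringsAsFactors = FALSE))
    sub[, c("tf", "or", "p", "q", "pass", "tested")]
  })
  do.call(rbind, rows)
}

#' Expression-correlation contrast filter
#'
#' Per TF, the Pearson correlation of its expression with the per-sample
#' median expression of the CSFs and of the nCSFs; pass when the
#' difference `r_csf - r_ncsf` exceeds `min_diff`. Constant TF expression
#' is untested.
#'
#' @param tf_expr TF x sample TPM matrix.
#' @param sf_expr factor x sample TPM matrix (same samples).
#' @param csf,ncsf factor sets.
#' @param min_diff correlation-difference threshold (default 0.2).
#' @return data.frame per TF: r_csf, r_ncsf, diff, pass, tested.
#' @export
correlation_filter <- function(tf_expr, sf_expr, csf, ncsf,
                               min_diff = 0.2) {
  shared <- intersect(colnames(tf_expr), colnames(sf_expr))
  if (length(shared) < 10) stop("need at least 10 shared samples")
  lg_sf <- log2p1(sf_expr[, shared, drop = FALSE])
  med_csf <- apply(lg_sf[intersect(csf, rownames(lg_sf)), , drop = FALSE],
                   2, median)
  med_ncsf <- apply(lg_sf[intersect(ncsf, rownames(lg_sf)), , drop = FALSE],
                    2, median)
  lg_tf <- log2p1(tf_expr[, shared, drop = FALSE])
  rows <- lapply(rownames(lg_tf), function(tf) {
    v <- lg_tf[tf, ]
    if (var(v) == 0)
      return(data.frame(tf = tf, r_csf = NA_real_, r_ncsf = NA_real_,
                        diff = NA_real_, pass = FALSE, tested = FALSE,
                        stringsAsFactors = FALSE))
    r1 <- cor(v, med_csf); r2 <- cor(v, med_ncsf)
    data.frame(tf = tf, r_csf = r1, r_ncsf = r2, diff = r1 - r2,
               pass = (r1 - r2) > min_diff, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Combine the four filters into the final regulator call
#'
#' A TF is a proposed regulator when it passes the ChIP gate and either
#' the knockdown filter or both computational filters (network and
#' correlation). The full evidence table is returned for every candidate
#' regardless of outcome.
#'
#' @param chip,knock,network,corr the four filter tables; `chip` must
#'   cover every candidate.
#' @return data.frame per TF with the per-filter pass flags and
#'   `final_pass`.
#' @export
combine_filters <- function(chip, knock, network, corr) {
  tfs <- chip$tf
  get_flag <- function(tab, col = "pass") {
    v <- tab[[col]][match(tfs, tab$tf)]
    v[is.na(v)] <- FALSE
    v
  }
  chip_pass <- chip$pass
  knock_pass <- get_flag(knock)
  net_pass <- get_flag(network)
  corr_pass <- get_flag(corr)
  data.frame(
    tf = tfs,
    chip_pass = chip_pass, knock_pass = knock_pass,
    knock_tested = get_flag(knock, "tested"),
    network_pass = net_pass, network_tested = get_flag(network, "tested"),
    corr_pass = corr_pass,
    final_pass = chip_pass & (knock_pass | (net_pass & corr_pass)),
    stringsAsFactors = FALSE)
}
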