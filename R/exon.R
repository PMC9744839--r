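## Exon-pathway correlation screen and the EP/EN calling rule.

#' Correlate exon inclusion with pathway activity
#'
#' Pearson correlation of each event's PSI with each pathway's activity
#' across the shared timepoint columns, using pairwise-complete
#' observations. Pairs with fewer than `min_pairs` complete observations
#' or a zero-variance operand get a missing r and are excluded from that
#' exon's multiple-testing family. BH adjustment is applied per exon over
#' its tested pathways (the per-exon family mirrors correcting each exon
#' for the number of pathways screened).
#'
#' @param psi event x timepoint PSI matrix (NA allowed).
#' @param activity pathway x timepoint matrix, same columns as `psi`.
#' @param min_pairs minimum complete pairs per correlation (default 6,
#'   must be >= 5).
#' @param fdr recorded FDR threshold the q-values are meant to be compared
#'   to (default 0.05).
#' @return object of class `exon_pathway_corr`: list of event x pathway
#'   matrices `r`, `p`, `q`, `n`, plus the `fdr` used.
#' @export
correlate_exon_pathways <- function(psi, activity, min_pairs = 6,
                                    fdr = 0.05) {
  if (min_pairs < 5) stop("min_pairs must be at least 5")
  if (!identical(colnames(psi), colnames(activity)))
    stop("psi and activity must share aligned timepoint columns")
  n_tp <- ncol(psi)
  act_t <- t(activity)

  r <- matrix(NA_real_, nrow(psi), nrow(activity),
              dimnames = list(rownames(psi), rownames(activity)))
  n <- matrix(0L, nrow(psi), nrow(activity), dimnames = dimnames(r))

  complete <- !apply(is.na(psi), 1, any)
  act_var0 <- apply(activity, 1, var) == 0
  if (any(complete)) {
    pc <- t(psi[complete, , drop = FALSE])
    psi_var0 <- apply(pc, 2, var) == 0
    rr <- suppressWarnings(cor(pc, act_t))
    rr[psi_var0, ] <- NA_real_
    rr[, act_var0] <- NA_real_
    r[complete, ] <- rr
    n[complete, ] <- n_tp
  }
  for (i in which(!complete)) {
    ok <- !is.na(psi[i, ])
    for (j in seq_len(nrow(activity))) {
      m <- sum(ok)
      n[i, j] <- m
      if (m < min_pairs) next
      x <- psi[i, ok]; y <- activity[j, ok]
      if (var(x) == 0 || var(y) == 0) next
      r[i, j] <- cor(x, y)
    }
  }
  r[n < min_pairs] <- NA_real_  # NA pairs drop out of the BH family below
  p <- matrix(cor_pval(as.vector(r), as.vector(n)), nrow(r),
              dimnames = dimnames(r))
  q <- t(apply(p, 1, bh_adjust))
  dimnames(q) <- dimnames(p)
  structure(list(r = r, p = p, q = q, n = n, fdr = fdr),
            class = "exon_pathway_corr")
}

#' Call embryonic-positive and embryonic-negative exons
#'
#' An exon is EP when a sufficient fraction of the embryonic-positive
#' pathways is significantly positively correlated with its inclusion
#' (`>= pos_frac`) while significant negative correlations stay rare
#' (`<= neg_frac`); EN mirrors the rule with the signs swapped. Under
#' `rule = "positive_only"` (default) both fractions are evaluated on the
#' embryonic-positive pathways; under `rule = "cross_class"` the
#' `neg_frac` cap is evaluated on the embryonic-negative pathways instead.
#' Raw counts for both readings are emitted for audit.
#'
#' @param corr an [correlate_exon_pathways()] result.
#' @param pathway_labels named vector from
#'   [classify_embryonic_pathways()].
#' @param pos_frac,neg_frac fraction thresholds (defaults 0.10 / 0.05);
#'   `pos_frac` must exceed `neg_frac`.
#' @param fdr significance threshold on the per-exon q-values.
#' @param rule which pathways carry the `neg_frac` cap (see above).
#' @return data.frame per event: label (`EP`/`EN`/`none`) and the
#'   significant-correlation counts per pathway class and sign.
#' @export
classify_exons <- function(corr, pathway_labels, pos_frac = 0.10,
                           neg_frac = 0.05, fdr = 0.05,
                           rule = c("positive_only", "cross_class")) {
  rule <- match.arg(rule)
  if (pos_frac <= neg_frac)
    stop("pos_frac must exceed neg_frac; the rule would be vacuous")
  pw <- intersect(colnames(corr$q), names(pathway_labels))
  pos_pw <- pw[pathway_labels[pw] == "embryonic_positive"]
  neg_pw <- pw[pathway_labels[pw] == "embryonic_negative"]
  if (!length(pos_pw) || !length(neg_pw))
    stop("both embryonic pathway classes must be represented")

  sig_pos <- corr$q < fdr & corr$r > 0
  sig_neg <- corr$q < fdr & corr$r < 0
  count <- function(sig, cols) rowSums(sig[, cols, drop = FALSE], na.rm = TRUE)
  tested <- function(cols) rowSums(!is.na(corr$q[, cols, drop = FALSE]))

  n_pos_sigpos <- count(sig_pos, pos_pw)
  n_pos_signeg <- count(sig_neg, pos_pw)
  n_neg_sigpos <- count(sig_pos, neg_pw)
  n_neg_signeg <- count(sig_neg, neg_pw)
  den_pos <- pmax(tested(pos_pw), 1L)
  den_neg <- pmax(tested(neg_pw), 1L)

  if (rule == "positive_only") {
    ep <- n_pos_sigpos / den_pos >= pos_frac &
      n_pos_signeg / den_pos <= neg_frac
    en <- n_pos_signeg / den_pos >= pos_frac &
      n_pos_sigpos / den_pos <= neg_frac
  } else {
    ep <- n_pos_sigpos / den_pos >= pos_frac &
      n_neg_sigpos / den_neg <= neg_frac
    en <- n_pos_signeg / den_pos >= pos_frac &
      n_neg_signeg / den_neg <= neg_frac
  }
  label <- ifelse(ep & !en, "EP", ifelse(en & !ep, "EN", "none"))
  data.frame(event_id = rownames(corr$q), label = label,
             n_pos_sigpos = n_pos_sigpos, n_pos_signeg = n_pos_signeg,
             n_neg_sigpos = n_neg_sigpos, n_neg_signeg = n_neg_signeg,
             n_pos_tested = den_pos, n_neg_tested = den_neg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation of exon inclusion with host-gene expression
#'
#' Per event, Pearson r between PSI and log2(TPM+1) of the host gene over
#' samples with non-missing PSI; missing (with a warning) when the host
#' gene is absent, and missing when either vector is constant.
#'
#' @param psi event x sample PSI matrix.
#' @param expr gene x sample TPM matrix, same samples.
#' @param events data.frame with `event_id` and `gene_id`.
#' @return named numeric vector of per-event correlations.
#' @export
host_gene_coupling <- function(psi, expr, events) {
  stopifnot(identical(colnames(psi), colnames(expr)))
  out <- setNames(rep(NA_real_, nrow(events)), events$event_id)
  absent <- setdiff(unique(events$gene_id), rownames(expr))
  if (length(absent))
    warning("host gene(s) absent from expression matrix: ",
            paste(head(absent, 5), collapse = ", "))
  lg <- log2p1(expr)
  for (i in seq_len(nrow(events))) {
    g <- events$gene_id[i]; e <- events$event_id[i]
    if (!g %in% rownames(lg) || !e %in% rownames(psi)) next
    ok <- !is.na(psi[e, ])
    if (sum(ok) < 3) next
    x <- psi[e, ok]; y <- lg[g, ok]
    if (var(x) == 0 || var(y) == 0) next
    out[e] <- cor(x, y)
  }
  out
}
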