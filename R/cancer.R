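## Tumor-vs-normal frequent-event caller (2-SD / 15% rule), overlap
## enrichment with the developmental EP/EN sets, and the signature /
## phenotype correlation analyses.

#' Call frequently increased or decreased splicing events in tumors
#'
#' For each event, the normal-cohort mean and SD are computed from
#' non-missing normal PSIs (events with fewer than `min_normal_n` values
#' are skipped; SDs below `sd_floor` are floored). A tumor deviates up
#' when its PSI exceeds mean + `sd_mult` SD, down when below mean -
#' `sd_mult` SD; deviation fractions are computed over tumors with
#' non-missing PSI and a direction is called when its fraction reaches
#' `min_frac`. Both directions can pass, giving call `both`.
#'
#' @param tumor,normal event x sample PSI matrices over a shared event
#'   index.
#' @param sd_mult deviation threshold in normal SDs (default 2).
#' @param min_frac minimum deviating tumor fraction per direction
#'   (default 0.15).
#' @param min_normal_n minimum non-missing normal samples (default 10).
#' @param sd_floor lower bound on the normal SD (default 0.01).
#' @return data.frame per event: normal mean/SD, deviation counts and
#'   fractions, and `call` in increased/decreased/both/none.
#' @export
call_frequent_events <- function(tumor, normal, sd_mult = 2,
                                 min_frac = 0.15, min_normal_n = 10,
                                 sd_floor = 0.01) {
  if (ncol(tumor) == 0 || ncol(normal) == 0) stop("empty cohort")
  if (!identical(rownames(tumor), rownames(normal)))
    stop("tumor and normal must share the event index")
  n_norm <- rowSums(!is.na(normal))
  mu <- rowMeans(normal, na.rm = TRUE)
  sdv <- apply(normal, 1, sd, na.rm = TRUE)
  sdv <- pmax(sdv, sd_floor)
  up <- tumor > mu + sd_mult * sdv
  dn <- tumor < mu - sd_mult * sdv
  n_tum <- rowSums(!is.na(tumor))
  n_up <- rowSums(up, na.rm = TRUE)
  n_dn <- rowSums(dn, na.rm = TRUE)
  frac_up <- ifelse(n_tum > 0, n_up / n_tum, NA_real_)
  frac_dn <- ifelse(n_tum > 0, n_dn / n_tum, NA_real_)
  usable <- n_norm >= min_normal_n & n_tum > 0
  call <- rep("none", nrow(tumor))
  inc <- usable & frac_up >= min_frac
  dec <- usable & frac_dn >= min_frac
  call[inc & !dec] <- "increased"
  call[dec & !inc] <- "decreased"
  call[inc & dec] <- "both"
  data.frame(event_id = rownames(tumor),
             normal_mean = mu, normal_sd = sdv, n_normal = n_norm,
             n_up = n_up, n_down = n_dn,
             frac_up = frac_up, frac_down = frac_dn,
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Stage-stratified overlap enrichment
#'
#' Splits the tumor cohort by stage, re-runs the frequent-event caller per
#' stratum against the shared normals, and reports the EP-in-increased and
#' EN-in-decreased overlap enrichment side by side. Strata below `min_n`
#' tumors are dropped with a warning.
#'
#' @param tumor,normal PSI matrices.
#' @param stage named character vector of stage labels per tumor sample.
#' @param ep,en developmental event sets.
#' @param universe event universe (default: all events in `tumor`).
#' @param min_n minimum tumors per stratum (default 10).
#' @param ... passed to [call_frequent_events()].
#' @return data.frame with one row per (stratum, set) enrichment.
#' @export
stage_stratified_enrichment <- function(tumor, normal, stage, ep, en,
                                        universe = rownames(tumor),
                                        min_n = 10, ...) {
  stage <- stage[colnames(tumor)]
  strata <- split(colnames(tumor), stage)
  small <- lengths(strata) < min_n
  if (any(small)) {
    warning("dropping strata below ", min_n, " tumors: ",
            paste(names(strata)[small], collapse = ", "))
    strata <- strata[!small]
  }
  if (length(strata) == 0) stop("no usable stratum")
  if (length(strata) == 1)
    warning("only one usable stratum; no cross-stage contrast possible")
  out <- lapply(names(strata), function(s) {
    calls <- call_frequent_events(tumor[, strata[[s]], drop = FALSE],
                                  normal, ...)
    increased <- calls$event_id[calls$call %in% c("increased", "both")]
    decreased <- calls$event_id[calls$call %in% c("decreased", "both")]
    rbind(
      cbind(stratum = s, set = "EP_in_increased",
            overlap_enrichment(increased, intersect(ep, universe), universe)),
      cbind(stratum = s, set = "EN_in_decreased",
            overlap_enrichment(decreased, intersect(en, universe), universe)))
  })
  res <- do.call(rbind, out)
  res$q <- stats::ave(res$p, res$set, FUN = bh_adjust)
  res
}

#' Correlate event-set inclusion with gene-set expression signatures
#'
#' Per sample: the median PSI over an event set and the mean log2(TPM+1)
#' over each gene set; then Pearson correlation across samples, BH
#' adjusted across gene sets. Gene sets with no matched genes are skipped
#' with a warning; a constant median-PSI profile gives missing r.
#'
#' @param psi event x sample PSI matrix.
#' @param event_set character vector of event ids.
#' @param expr gene x sample TPM matrix (same samples).
#' @param gene_sets named list of gene-id vectors.
#' @param min_samples minimum shared samples (default 10).
#' @return data.frame per gene set: r, p, q, n genes matched.
#' @export
signature_correlation <- function(psi, event_set, expr, gene_sets,
                                  min_samples = 10) {
  shared <- intersect(colnames(psi), colnames(expr))
  if (length(shared) < min_samples)
    stop("need at least ", min_samples, " shared samples")
  med_psi <- apply(psi[intersect(event_set, rownames(psi)), shared,
                       drop = FALSE], 2, median, na.rm = TRUE)
  lg <- log2p1(expr[, shared, drop = FALSE])
  rows <- lapply(names(gene_sets), function(nm) {
    g <- intersect(gene_sets[[nm]], rownames(lg))
    if (length(g) == 0) {
      warning("gene set '", nm, "' has no matched genes; skipped")
      return(NULL)
    }
    score <- colMeans(lg[g, , drop = FALSE])
    r <- if (var(med_psi) == 0 || var(score) == 0) NA_real_ else
      cor(med_psi, score)
    data.frame(gene_set = nm, n_genes = length(g), r = r,
               p = cor_pval(r, length(shared)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no gene set matched the expression matrix")
  res$q <- bh_adjust(res$p)
  res
}

#' Enrichment of EP/EN events among phenotype-correlated events
#'
#' Correlates each event's PSI with a per-sample phenotype (e.g. cell-line
#' doubling time), splits events into positively (`r > pcc_threshold`) and
#' negatively (`r < -pcc_threshold`) correlated sets, and tests EP and EN
#' enrichment in each over the universe of events with a computable
#' correlation. Flags the result underpowered when fewer than 2 events
#' pass a threshold.
#'
#' @param psi event x sample PSI matrix.
#' @param phenotype named numeric vector per sample.
#' @param ep,en event sets.
#' @param pcc_threshold absolute correlation cutoff (default 0.5).
#' @return data.frame per (set, sign): enrichment stats plus
#'   `underpowered` flag; BH across the four tests.
#' @export
correlation_set_enrichment <- function(psi, phenotype, ep, en,
                                       pcc_threshold = 0.5) {
  shared <- intersect(colnames(psi), names(phenotype))
  if (length(shared) < 10) stop("need at least 10 samples with phenotype")
  psi <- psi[, shared, drop = FALSE]
  ph <- phenotype[shared]
  r <- apply(psi, 1, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 5 || var(v[ok]) == 0 || var(ph[ok]) == 0) return(NA_real_)
    cor(v[ok], ph[ok])
  })
  universe <- names(r)[!is.na(r)]
  pos_set <- universe[r[universe] > pcc_threshold]
  neg_set <- universe[r[universe] < -pcc_threshold]
  underpowered <- c(pos = length(pos_set) < 2, neg = length(neg_set) < 2)
  rows <- list(
    cbind(set = "EP", sign = "negative",
          overlap_enrichment(intersect(ep, universe), neg_set, universe)),
    cbind(set = "EP", sign = "positive",
          overlap_enrichment(intersect(ep, universe), pos_set, universe)),
    cbind(set = "EN", sign = "negative",
          overlap_enrichment(intersect(en, universe), neg_set, universe)),
    cbind(set = "EN", sign = "positive",
          overlap_enrichment(intersect(en, universe), pos_set, universe)))
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$underpowered <- underpowered[ifelse(res$sign == "positive", "pos", "neg")]
  res
}
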