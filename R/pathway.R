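## Pathway activity over developmental timepoints, PC-space smoothing, and
## the two-way embryonic pathway classification.

#' Score pathway activity
#'
#' Activity of pathway p in sample s is the median of log2(TPM+1) over the
#' pathway's genes present in the expression matrix. Pathways matching
#' fewer than `min_genes` genes are dropped with a warning.
#'
#' @param expr gene x sample TPM matrix (nonnegative).
#' @param pathways named list of gene-id vectors.
#' @param min_genes minimum matched genes per pathway (default 3).
#' @return pathway x sample activity matrix.
#' @export
score_pathway_activity <- function(expr, pathways, min_genes = 3) {
  if (any(expr < 0, na.rm = TRUE)) stop("expression must be nonnegative")
  lg <- log2p1(expr)
  matched <- lapply(pathways, function(g) intersect(g, rownames(expr)))
  keep <- lengths(matched) >= min_genes
  if (!all(keep))
    warning(sum(!keep), " pathway(s) dropped (fewer than ", min_genes,
            " matched genes): ",
            paste(head(names(pathways)[!keep], 5), collapse = ", "))
  if (!any(keep)) stop("no pathway has at least ", min_genes, " matched genes")
  act <- t(vapply(matched[keep], function(g)
    apply(lg[g, , drop = FALSE], 2, median), numeric(ncol(expr))))
  rownames(act) <- names(pathways)[keep]
  act
}

#' Smooth pathway activity in principal-component space
#'
#' Runs PCA with timepoints as observations and pathways as variables
#' (each pathway row standardized across timepoints beforehand, so
#' loadings reflect temporal shape rather than magnitude), then replaces
#' the activity of pathway p at timepoint t with the cosine similarity
#' between p's loading vector over the first `n_pcs` PCs and t's score
#' vector over the same PCs. Values are therefore bounded in [-1, 1]; a
#' zero loading or score vector yields 0.
#'
#' @param activity pathway x timepoint matrix from
#'   [score_pathway_activity()].
#' @param n_pcs number of principal components (default 5).
#' @param scale_pathways standardize pathway rows before PCA (default
#'   TRUE).
#' @return pathway x timepoint matrix of cosine similarities, with
#'   attribute `n_pcs`; constant pathway rows are dropped with a warning.
#' @export
smooth_activity_pca <- function(activity, n_pcs = 5, scale_pathways = TRUE) {
  rv <- apply(activity, 1, var)
  if (any(rv == 0)) {
    warning(sum(rv == 0), " constant pathway row(s) dropped before PCA")
    activity <- activity[rv > 0, , drop = FALSE]
  }
  if (nrow(activity) < 2) stop("need at least 2 non-constant pathways")
  if (n_pcs > min(dim(activity)) - 1)
    stop("n_pcs must be at most min(#pathways, #timepoints) - 1")
  x <- t(activity)                       # timepoints as observations
  pr <- prcomp(x, center = TRUE, scale. = scale_pathways)
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]       # timepoints x PCs
  loadings <- pr$rotation[, seq_len(n_pcs), drop = FALSE]  # pathways x PCs
  out <- matrix(0, nrow(activity), ncol(activity),
                dimnames = dimnames(activity))
  for (p in seq_len(nrow(out)))
    for (t in seq_len(ncol(out)))
      out[p, t] <- cosine_sim(loadings[p, ], scores[t, ])
  attr(out, "n_pcs") <- n_pcs
  out
}

#' Classify pathways as embryonic positive or negative
#'
#' Ward-linkage hierarchical clustering (Euclidean distance) of the
#' smoothed pathway rows, cut at two clusters. The cluster with higher
#' mean smoothed activity over the prenatal timepoints is labeled
#' `embryonic_positive`, the other `embryonic_negative`; an exact tie goes
#' to the smaller cluster (with a message).
#'
#' @param smoothed pathway x timepoint matrix from
#'   [smooth_activity_pca()].
#' @param prenatal logical vector flagging prenatal timepoint columns.
#' @return named character vector over pathways with values
#'   `embryonic_positive` / `embryonic_negative`.
#' @export
classify_embryonic_pathways <- function(smoothed, prenatal) {
  stopifnot(length(prenatal) == ncol(smoothed))
  if (!any(prenatal) || all(prenatal))
    stop("both prenatal and postnatal timepoints must be present")
  d <- dist(smoothed)
  if (all(d == 0))
    stop("all smoothed pathway rows identical; provide more timepoints")
  cl <- cutree(hclust(d, method = "ward.D2"), k = 2)
  pre_mean <- vapply(1:2, function(k)
    mean(smoothed[cl == k, prenatal, drop = FALSE]), numeric(1))
  if (pre_mean[1] == pre_mean[2]) {
    message("prenatal-activity tie; labeling the smaller cluster positive")
    pos <- which.min(tabulate(cl, 2))
  } else pos <- which.max(pre_mean)
  labels <- ifelse(cl == pos, "embryonic_positive", "embryonic_negative")
  setNames(labels, rownames(smoothed))
}
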