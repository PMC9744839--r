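## Single 2x2 enrichment primitive shared by every Fisher-based test in the
## package (cancer-event overlap, protein domains, all four TF filters).

#' Two-by-two Fisher enrichment with cross-product odds ratio
#'
#' Computes the two-sided Fisher exact p-value for a 2x2 contingency table
#' together with the unconditional (cross-product) sample odds ratio
#' `(a*d)/(b*c)` and a normal-approximation 95% confidence interval on the
#' log odds ratio. When any cell is zero the Haldane correction (+0.5 to all
#' four cells) is applied to the odds ratio and its CI — never to the exact
#' p-value — and the `haldane` flag is set.
#'
#' @param a,b,c,d cell counts: `a` = in-query & in-reference, `b` = in-query
#'   only, `c` = in-reference only, `d` = in neither.
#' @return list with `or`, `ci_lo`, `ci_hi`, `p`, `haldane`, `counts`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  haldane <- any(counts == 0)
  cc <- if (haldane) counts + 0.5 else counts
  or <- (cc[["a"]] * cc[["d"]]) / (cc[["b"]] * cc[["c"]])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  list(or = unname(or), ci_lo = ci[1], ci_hi = ci[2], p = p,
       haldane = haldane, counts = counts)
}

#' Overlap enrichment of two event sets over a universe
#'
#' Builds the 2x2 table (in/out of `query` crossed with in/out of
#' `reference`) over `universe` and hands it to [fisher_2x2()]. Used for the
#' tumor-reactivation overlap tests and, indirectly, for every set-based
#' filter in the package.
#'
#' @param query,reference character vectors, subsets of `universe`.
#' @param universe character vector, the full event universe.
#' @return one-row data.frame: counts, odds ratio, CI, p.
#' @export
overlap_enrichment <- function(query, reference, universe) {
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query); reference <- unique(reference)
  if (!all(query %in% universe) || !all(reference %in% universe))
    stop("query and reference must be subsets of the universe")
  inq <- universe %in% query
  inr <- universe %in% reference
  a <- sum(inq & inr); b <- sum(inq & !inr)
  c_ <- sum(!inq & inr); d <- sum(!inq & !inr)
  ft <- fisher_2x2(a, b, c_, d)
  data.frame(
    n_overlap = a, n_query_only = b, n_ref_only = c_, n_neither = d,
    or = ft$or, ci_lo = ft$ci_lo, ci_hi = ft$ci_hi, p = ft$p,
    haldane = ft$haldane
  )
}

## enrichment of a target set for foreground vs background membership:
## table is (in/out of set) x (foreground/background); fg+bg = universe
set_enrichment <- function(set, fg, bg) {
  a <- sum(fg %in% set); b <- sum(bg %in% set)
  c_ <- length(fg) - a; d <- length(bg) - b
  fisher_2x2(a, b, c_, d)
}
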