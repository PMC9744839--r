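#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree dist fisher.test hclust mad median p.adjust
#'   pnorm prcomp pt qlogis plogis quantile rbeta rbinom rnorm runif sd
#'   setNames var wilcox.test complete.cases
#' @importFrom utils head modifyList
NULL

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

log2p1 <- function(x) log2(x + 1)

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around [stats::p.adjust()] kept as a single named entry point
#' so every multiple-testing family in the package routes through one
#' implementation (checked against a brute-force step-up oracle in the tests).
#' `NA` p-values are excluded from the family and returned as `NA`.
#'
#' @param p numeric vector of p-values, `NA` allowed.
#' @return numeric vector of BH-adjusted q-values, same length and names.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

## cosine similarity; zero-vector operand => 0 by convention
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

## Pearson r -> two-sided p via the t distribution (n = complete pairs)
cor_pval <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  rr <- pmin(pmax(r[ok], -1), 1)
  tt <- rr * sqrt((n[ok] - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n[ok] - 2)
  p
}

## deterministic sub-stream seeding: one master seed, fixed label offsets,
## so adding a generator never perturbs the streams of existing ones
seed_offsets <- c(
  development = 11L, cancer = 23L, annotation = 37L, regulatory = 51L,
  pipeline = 67L
)

set_substream <- function(seed, label) {
  off <- seed_offsets[[label]]
  set.seed((as.integer(seed) %% 1000000L) * 101L + off)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
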