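## Protein-domain genomic intervals: per-domain merging, overlap mapping
## onto exon coordinates, and the EP/EN enrichment test. Coordinates are
## 0-based half-open throughout; strand is ignored (domains are
## genome-projected).

bed_to_iranges <- function(start, end) {
  ## half-open [start, end) -> closed 1-based [start+1, end]
  IRanges::IRanges(start = start + 1L, end = end)
}

#' Merge domain intervals per domain
#'
#' Unions the intervals of each (domain, chromosome): overlapping and
#' book-ended (touching) intervals collapse into one. Removes the
#' redundancy created by one domain mapping to multiple transcripts.
#'
#' @param track data.frame with `chrom`, `start`, `end`, `name` (domain)
#'   and optionally `strand` (ignored).
#' @return merged data.frame in the same layout, sorted by domain,
#'   chromosome, start.
#' @export
merge_domain_intervals <- function(track) {
  if (any(track$start < 0)) stop("negative coordinates")
  if (any(track$start >= track$end)) stop("intervals must satisfy start < end")
  key <- split(seq_len(nrow(track)), list(track$name, track$chrom),
               drop = TRUE)
  merged <- lapply(names(key), function(k) {
    i <- key[[k]]
    red <- IRanges::reduce(bed_to_iranges(track$start[i], track$end[i]))
    data.frame(chrom = track$chrom[i[1]],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               name = track$name[i[1]],
               score = 0, strand = "+", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out[order(out$name, out$chrom, out$start), , drop = FALSE]
}

#' Map domains onto exon intervals
#'
#' Assigns a domain to an event when their genomic intervals overlap by at
#' least `min_overlap_bp` bases. Expects a merged track.
#'
#' @param track merged domain data.frame ([merge_domain_intervals()]).
#' @param exons data.frame with `chrom`, `start`, `end`, `name` (event id).
#' @param min_overlap_bp minimum overlap (default 1 = any overlap).
#' @return named list: event id -> character vector of domain names
#'   (empty vector when none).
#' @export
map_domains_to_exons <- function(track, exons, min_overlap_bp = 1) {
  out <- setNames(vector("list", nrow(exons)), exons$name)
  for (i in seq_along(out)) out[[i]] <- character(0)
  for (chr in unique(exons$chrom)) {
    ei <- which(exons$chrom == chr)
    ti <- which(track$chrom == chr)
    if (!length(ti)) next
    hits <- IRanges::findOverlaps(
      bed_to_iranges(exons$start[ei], exons$end[ei]),
      bed_to_iranges(track$start[ti], track$end[ti]),
      minoverlap = min_overlap_bp)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (k in seq_along(qh)) {
      ev <- exons$name[ei[qh[k]]]
      out[[ev]] <- union(out[[ev]], track$name[ti[sh[k]]])
    }
  }
  out
}

#' Per-domain enrichment among EP and EN exons
#'
#' For each domain and each class (EP, EN), builds the 2x2 table of
#' class-vs-background crossed with domain presence, computes the Fisher
#' exact p and cross-product odds ratio, and BH-adjusts within each class
#' across domains. A domain is flagged enriched when OR > 1 and
#' q < `alpha`.
#'
#' @param mapping event -> domains list from [map_domains_to_exons()].
#' @param ep,en,background disjoint event-id sets; `background` plays the
#'   control role of the remaining alternative exons.
#' @param alpha enrichment q-value cutoff (default 0.1).
#' @return data.frame per (domain, class): counts, OR, p, q, `enriched`.
#' @export
test_domain_enrichment <- function(mapping, ep, en, background,
                                   alpha = 0.1) {
  domains <- sort(unique(unlist(mapping, use.names = FALSE)))
  if (!length(domains)) stop("no domain maps to any exon")
  has_domain <- function(set, d)
    sum(vapply(mapping[intersect(set, names(mapping))],
               function(x) d %in% x, logical(1)))
  rows <- list()
  for (cls in c("EP", "EN")) {
    set <- if (cls == "EP") ep else en
    for (d in domains) {
      a <- has_domain(set, d)
      b <- has_domain(background, d)
      ft <- fisher_2x2(a, length(set) - a, b, length(background) - b)
      rows[[length(rows) + 1L]] <- data.frame(
        domain = d, class = cls,
        n_class_with = a, n_class = length(set),
        n_bg_with = b, n_bg = length(background),
        or = ft$or, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- stats::ave(res$p, res$class, FUN = bh_adjust)
  res$enriched <- res$or > 1 & res$q < alpha
  res
}
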