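## Exon-skip PSI quantification from transcript TPMs: the in-repo
## replacement for an external inclusion-level caller. PSI is the ratio of
## summed inclusion-transcript TPM to summed total-transcript TPM.

#' Read an exon-skip event annotation file
#'
#' Tab-separated with header: `chrom gene_id event_id
#' inclusion_transcripts total_transcripts`, transcript lists comma-joined
#' (an ioe-like dialect). Duplicate event ids, inclusion sets that are not
#' proper subsets of the total set, and malformed lines are rejected with
#' the offending line number.
#'
#' @param path file path.
#' @return data.frame with one row per event; `inclusion` and `total` are
#'   list-columns of transcript id vectors.
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = "character")
  need <- c("chrom", "gene_id", "event_id",
            "inclusion_transcripts", "total_transcripts")
  if (!all(need %in% names(dt)))
    stop("event file must have columns: ", paste(need, collapse = ", "))
  if (nrow(dt) == 0)
    return(data.frame(chrom = character(), gene_id = character(),
                      event_id = character(),
                      inclusion = I(list()), total = I(list())))
  split_tx <- function(x) {
    out <- strsplit(x, ",", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  inc <- split_tx(dt$inclusion_transcripts)
  tot <- split_tx(dt$total_transcripts)
  for (i in seq_len(nrow(dt))) {
    line <- i + 1L  # header is line 1
    if (!nzchar(dt$event_id[i]) || length(inc[[i]]) == 0 ||
        length(tot[[i]]) == 0)
      stop("malformed event record at line ", line)
    if (length(tot[[i]]) < 2)
      stop("line ", line, ": total transcript set must have >= 2 members")
    if (!all(inc[[i]] %in% tot[[i]]) ||
        length(inc[[i]]) >= length(tot[[i]]))
      stop("line ", line,
           ": inclusion transcripts must be a proper subset of the total set")
  }
  if (anyDuplicated(dt$event_id))
    stop("duplicated event ids: ",
         paste(unique(dt$event_id[duplicated(dt$event_id)]), collapse = ", "))
  data.frame(chrom = dt$chrom, gene_id = dt$gene_id,
             event_id = dt$event_id,
             inclusion = I(inc), total = I(tot),
             stringsAsFactors = FALSE)
}

#' Compute PSI from transcript TPMs
#'
#' For each event and sample, PSI is the sum of TPM over the inclusion
#' transcripts divided by the sum over the total transcripts. Events whose
#' total TPM in a sample falls below `min_total_tpm` are reported missing
#' (`NA`) in that sample — lowly expressed events carry no reliable
#' inclusion estimate.
#'
#' @param tpm transcript x sample TPM matrix.
#' @param events event table from [read_events()].
#' @param min_total_tpm minimum total-transcript TPM; default 1.
#' @return event x sample PSI matrix in `[0,1]` with `NA` for masked
#'   entries.
#' @export
compute_psi <- function(tpm, events, min_total_tpm = 1) {
  all_tx <- unique(unlist(events$total, use.names = FALSE))
  missing_tx <- setdiff(all_tx, rownames(tpm))
  if (length(missing_tx))
    stop("transcripts absent from the TPM matrix: ",
         paste(head(missing_tx, 10), collapse = ", "),
         if (length(missing_tx) > 10) " ...")
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be nonnegative")
  n_s <- ncol(tpm)
  psi <- matrix(NA_real_, nrow(events), n_s,
                dimnames = list(events$event_id, colnames(tpm)))
  for (i in seq_len(nrow(events))) {
    inc <- colSums(tpm[events$inclusion[[i]], , drop = FALSE])
    tot <- colSums(tpm[events$total[[i]], , drop = FALSE])
    v <- inc / tot
    v[tot < min_total_tpm | tot == 0] <- NA_real_
    psi[i, ] <- v
  }
  psi
}

#' Per-event PSI difference between two sample groups
#'
#' Aggregates each group per event (mean or median, missing values
#' skipped) and returns group `a` minus group `b`; `NA` when either side
#' is entirely missing for an event.
#'
#' @param a,b PSI matrices (events x samples) over a shared event index.
#' @param aggregate "median" (default) or "mean".
#' @return named numeric vector of per-event differences.
#' @export
delta_psi <- function(a, b, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (ncol(a) == 0 || ncol(b) == 0) stop("empty sample group")
  if (!identical(rownames(a), rownames(b)))
    stop("event indexes of the two groups differ")
  f <- if (aggregate == "median") {
    function(m) apply(m, 1, median, na.rm = TRUE)
  } else {
    function(m) rowMeans(m, na.rm = TRUE)
  }
  da <- suppressWarnings(f(a))
  db <- suppressWarnings(f(b))
  out <- da - db
  out[is.nan(out)] <- NA_real_
  out
}
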