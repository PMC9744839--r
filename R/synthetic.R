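## Synthetic-data generator with planted ground truth.
##
## The stated world: a developmental time course in which two mutually
## exclusive latent programs (prenatal / postnatal) switch logistically at
## the pre/post-natal boundary; pathway genes load on one program each;
## critical splicing factors (CSFs) track the prenatal program; EP exon
## inclusion follows an inverse-logit link on a weighted sum of CSF
## log-expression (EN mirrored, null events flat); tumors partially
## re-express the prenatal program while matched normals stay postnatal.
## Planted extras: nonsense mutations that null a CSF's splicing effect,
## effect-increasing decoy mutations, CNV gains biased to high-reactivation
## tumors, a protein domain enriched on EP exons, and a TF whose binding /
## knockdown / expression signatures point at the CSFs.

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic world. Every
#' field has a default chosen once to mirror the scale of a desk-size
#' developmental + tumor cohort study; the methods vignette records the
#' reasoning. Unknown fields are rejected.
#'
#' @param n_genes number of non-splicing-factor genes in the expression
#'   matrix (pathway genes are drawn from these).
#' @param n_pathways,genes_per_pathway pathway count and size.
#' @param frac_prenatal_pathways fraction of pathways assigned to the
#'   prenatal program.
#' @param n_timepoints_pre,n_timepoints_post developmental timepoints before
#'   and after the boundary (their sum must be at least 8).
#' @param n_events number of exon-skip events; `frac_ep`/`frac_en` give the
#'   planted EP and EN fractions (rest are null events).
#' @param n_sf,n_csf number of annotated splicing factors and of planted
#'   critical splicing factors among them.
#' @param n_tumor,n_normal cancer-cohort sizes.
#' @param reactivation_strength mean fraction of the prenatal program
#'   re-expressed in tumors (0 = none; per-tumor strengths are Beta
#'   distributed around this mean).
#' @param noise_sd Gaussian noise SD on log2(TPM+1).
#' @param psi_noise_sd Gaussian noise SD on logit(PSI).
#' @param seed master seed; every generator derives a fixed sub-stream.
#' @param ... optional advanced knobs overriding the shape of the planted
#'   world: `switch_steepness`, `expr_base`, `expr_amp`, `psi_beta`,
#'   `ep_base_psi`, `en_base_psi`, `pathway_switch_sd`,
#'   `pathway_steepness_jitter`, `pathway_dynamics_scale` (amplitude of
#'   pathway-specific temporal dynamics, as a multiple of `noise_sd`),
#'   `n_mut_csf`, `n_mut_increase`,
#'   `mut_samples_per_factor`, `mut_increase_logit`, `mut_targets`,
#'   `cnv_base_rate`, `cnv_gain_slope`, `n_tf_decoy`, `tf_bind_frac_csf`,
#'   `tf_bind_frac_ncsf`, `kd_n_csf`, `kd_n_ncsf`, `kd_dpsi`,
#'   `kd_expr_frac`, `kd_cell_drive`, `domain_frac_ep`, `domain_frac_bg`,
#'   `n_decoy_domains`.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       n_pathways = 60,
                       genes_per_pathway = 10,
                       frac_prenatal_pathways = 0.5,
                       n_timepoints_pre = 12,
                       n_timepoints_post = 20,
                       n_events = 2000,
                       frac_ep = 0.15,
                       frac_en = 0.15,
                       n_sf = 442,
                       n_csf = 100,
                       n_tumor = 150,
                       n_normal = 60,
                       reactivation_strength = 0.5,
                       noise_sd = 0.5,
                       psi_noise_sd = 0.5,
                       seed = 1L,
                       ...) {
  advanced <- list(
    switch_steepness = 1.5, expr_base = 5, expr_amp = 3,
    psi_beta = 2.5, ep_base_psi = 0.2, en_base_psi = 0.8,
    pathway_switch_sd = 2, pathway_steepness_jitter = 0.3,
    pathway_dynamics_scale = 2, event_slope_jitter = 0.8,
    n_mut_csf = 5, n_mut_increase = 5, mut_samples_per_factor = 8,
    mut_increase_logit = 1.0, mut_targets = NULL,
    cnv_base_rate = 0.05, cnv_gain_slope = 0.4,
    n_tf_decoy = 19, tf_bind_frac_csf = 0.85, tf_bind_frac_ncsf = 0.05,
    kd_n_csf = 15, kd_n_ncsf = 15, kd_dpsi = -0.2, kd_expr_frac = 0.2,
    kd_cell_drive = 0.6,
    domain_frac_ep = 0.5, domain_frac_bg = 0.05, n_decoy_domains = 10
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(advanced))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  advanced <- modifyList(advanced, extra)
  cfg <- c(list(
    n_genes = n_genes, n_pathways = n_pathways,
    genes_per_pathway = genes_per_pathway,
    frac_prenatal_pathways = frac_prenatal_pathways,
    n_timepoints_pre = n_timepoints_pre,
    n_timepoints_post = n_timepoints_post,
    n_events = n_events, frac_ep = frac_ep, frac_en = frac_en,
    n_sf = n_sf, n_csf = n_csf, n_tumor = n_tumor, n_normal = n_normal,
    reactivation_strength = reactivation_strength,
    noise_sd = noise_sd, psi_noise_sd = psi_noise_sd,
    seed = as.integer(seed)
  ), advanced)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genes", "n_pathways", "genes_per_pathway",
              "n_timepoints_pre", "n_timepoints_post", "n_events",
              "n_sf", "n_csf", "n_tumor", "n_normal")
  for (f in counts)
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("config field '", f, "' must be a count >= 1")
  if (cfg$frac_ep + cfg$frac_en > 1)
    stop("frac_ep + frac_en must not exceed 1")
  if (cfg$frac_prenatal_pathways <= 0 || cfg$frac_prenatal_pathways >= 1)
    stop("frac_prenatal_pathways must lie in (0,1)")
  if (cfg$n_csf > cfg$n_sf) stop("n_csf must not exceed n_sf")
  if (cfg$reactivation_strength < 0) stop("reactivation_strength must be >= 0")
  if (cfg$noise_sd < 0 || cfg$psi_noise_sd < 0) stop("noise SDs must be >= 0")
  if (cfg$n_pathways * cfg$genes_per_pathway > cfg$n_genes)
    stop("n_genes too small to fill the pathways")
  invisible(cfg)
}

## logistic prenatal program activity over the ordered timepoints;
## `offset` shifts the switch time, `steep` overrides the steepness --
## individual pathways switch off at slightly staggered developmental
## times around the shared pre/post boundary
program_activity <- function(cfg, offset = 0, steep = NULL) {
  tt <- seq_len(cfg$n_timepoints_pre + cfg$n_timepoints_post)
  center <- cfg$n_timepoints_pre + 0.5 + offset
  s <- steep %||% cfg$switch_steepness
  1 / (1 + exp(s * (tt - center)))
}

gene_ids <- function(n) sprintf("G%05d", seq_len(n))
sf_ids <- function(n) sprintf("SF%04d", seq_len(n))
event_ids <- function(n) sprintf("EV%05d", seq_len(n))

## log2-scale latent expression -> TPM
to_tpm <- function(log2_expr) pmax(2^log2_expr - 1, 0)

## weighted CSF signal for one expression matrix (factors x samples):
## z_f = (log2 expr - factor baseline) / amplitude, combined with the
## planted weights; `nulled` is an optional factors x samples logical
## matrix marking mutation-nulled contributions
## a nonsense mutation decouples the factor from the embryonic program:
## its contribution is replaced by a baseline-level fluctuation, so at zero
## reactivation mutated samples stay distributionally identical to normals
## (and exactly zero in a noiseless world)
csf_signal <- function(sf_log2, truth, cfg, nulled = NULL) {
  w <- truth$csf_weights
  z <- (sf_log2[names(w), , drop = FALSE] -
          truth$sf_base[names(w)]) / cfg$expr_amp
  if (!is.null(nulled)) {
    nn <- nulled[names(w), , drop = FALSE]
    z[nn] <- rnorm(sum(nn), 0, cfg$noise_sd / cfg$expr_amp)
  }
  drop(crossprod(z, w))
}

## planted PSI matrix given per-sample drive (weighted CSF signal)
planted_psi <- function(truth, cfg, drive, sample_ids, ep_boost = NULL) {
  n_ev <- length(truth$event_alpha)
  labs <- truth$exon_labels
  slope <- truth$event_slope *
    ifelse(labs == "EP", cfg$psi_beta,
           ifelse(labs == "EN", -cfg$psi_beta, 0))
  eta <- outer(slope, drive) + truth$event_alpha
  if (!is.null(ep_boost))  # per-sample logit shift applied to EP rows only
    eta[labs == "EP", ] <- eta[labs == "EP", , drop = FALSE] +
      matrix(ep_boost, sum(labs == "EP"), length(drive), byrow = TRUE)
  eta <- eta + matrix(rnorm(n_ev * length(drive), 0, cfg$psi_noise_sd),
                      n_ev, length(drive))
  psi <- inv_logit(eta)
  dimnames(psi) <- list(names(truth$event_alpha), sample_ids)
  psi
}

#' Generate the developmental time course
#'
#' Produces the developmental transcript/gene expression matrix, the exon
#' PSI matrix, the pathway gene sets and the planted ground truth. The two
#' latent programs switch logistically at the pre/post-natal boundary.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (gene x timepoint TPM), `psi`
#'   (event x timepoint), `pathways` (named list), `meta` (sample metadata
#'   with a `prenatal` flag), `events` (event/host-gene table) and `truth`.
#' @export
generate_development <- function(cfg) {
  validate_sim_config(cfg)
  n_tp <- cfg$n_timepoints_pre + cfg$n_timepoints_post
  if (n_tp < 8)
    stop("need at least 8 developmental timepoints for the PC smoothing step")
  set_substream(cfg$seed, "development")

  tp_ids <- sprintf("TP%02d", seq_len(n_tp))
  prenatal <- seq_len(n_tp) <= cfg$n_timepoints_pre
  A <- program_activity(cfg)

  ## pathways and their program assignment
  genes <- gene_ids(cfg$n_genes)
  pw_ids <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  pw_members <- split(
    genes[seq_len(cfg$n_pathways * cfg$genes_per_pathway)],
    rep(pw_ids, each = cfg$genes_per_pathway))
  pw_members <- pw_members[pw_ids]
  n_pre_pw <- round(cfg$n_pathways * cfg$frac_prenatal_pathways)
  pre_pw <- sample(pw_ids, n_pre_pw)
  pathway_labels <- setNames(
    ifelse(pw_ids %in% pre_pw, "prenatal", "postnatal"), pw_ids)

  ## per-gene program membership
  gene_program <- setNames(rep("none", cfg$n_genes), genes)
  for (p in pw_ids) gene_program[pw_members[[p]]] <- pathway_labels[[p]]

  gene_base <- setNames(rnorm(cfg$n_genes, cfg$expr_base, 1), genes)
  ## pathways switch at staggered times around the shared boundary
  pw_offset <- rnorm(cfg$n_pathways, 0, cfg$pathway_switch_sd)
  pw_steep <- cfg$switch_steepness *
    runif(cfg$n_pathways, 1 - cfg$pathway_steepness_jitter,
          1 + cfg$pathway_steepness_jitter)
  pw_curve <- t(vapply(seq_len(cfg$n_pathways), function(i) {
    a <- program_activity(cfg, pw_offset[i], pw_steep[i])
    if (pathway_labels[[pw_ids[i]]] == "prenatal") a else 1 - a
  }, numeric(n_tp)))
  rownames(pw_curve) <- pw_ids
  ## pathway-specific temporal dynamics beyond the global switch: a smooth
  ## AR(1) component shared by the pathway's genes, scaled with noise_sd so
  ## a noiseless world stays fully deterministic
  wig_sd <- cfg$pathway_dynamics_scale * cfg$noise_sd
  pw_wig <- t(vapply(seq_len(cfg$n_pathways), function(i) {
    e <- rnorm(n_tp)
    v <- as.numeric(stats::filter(e, 0.8, method = "recursive"))
    if (sd(v) > 0 && wig_sd > 0) v / sd(v) * wig_sd else v * 0
  }, numeric(n_tp)))
  rownames(pw_wig) <- pw_ids
  gene_curve <- matrix(0, cfg$n_genes, n_tp, dimnames = list(genes, tp_ids))
  gene_wig <- matrix(0, cfg$n_genes, n_tp, dimnames = list(genes, tp_ids))
  for (p in pw_ids) {
    gene_curve[pw_members[[p]], ] <- matrix(pw_curve[p, ],
                                            length(pw_members[[p]]), n_tp,
                                            byrow = TRUE)
    gene_wig[pw_members[[p]], ] <- matrix(pw_wig[p, ],
                                          length(pw_members[[p]]), n_tp,
                                          byrow = TRUE)
  }
  gene_mu <- gene_base + cfg$expr_amp * gene_curve + gene_wig
  gene_log2 <- gene_mu + matrix(rnorm(length(gene_mu), 0, cfg$noise_sd),
                                nrow = nrow(gene_mu))
  dimnames(gene_log2) <- list(genes, tp_ids)

  ## splicing factors: CSFs track the prenatal program
  sfs <- sf_ids(cfg$n_sf)
  csf <- sort(sample(sfs, cfg$n_csf))
  sf_base <- setNames(rnorm(cfg$n_sf, cfg$expr_base, 1), sfs)
  sf_mu <- sf_base + cfg$expr_amp * outer(as.numeric(sfs %in% csf), A)
  sf_log2 <- sf_mu + matrix(rnorm(length(sf_mu), 0, cfg$noise_sd),
                            nrow = nrow(sf_mu))
  dimnames(sf_log2) <- list(sfs, tp_ids)

  ## concentrated CSF weights: the future mutation targets carry most of
  ## the splicing drive so that nulling one is detectable
  n_major <- min(cfg$n_mut_csf, cfg$n_csf)
  majors <- sample(csf, n_major)
  w <- setNames(rep(0.1 / max(cfg$n_csf - n_major, 1), cfg$n_csf), csf)
  if (cfg$n_csf == n_major) w[] <- 0
  w[majors] <- 0.9 / n_major
  w <- w / sum(w)

  ## exon-skip events
  ev <- event_ids(cfg$n_events)
  n_ep <- round(cfg$n_events * cfg$frac_ep)
  n_en <- round(cfg$n_events * cfg$frac_en)
  lab <- rep("null", cfg$n_events)
  lab[sample(cfg$n_events, n_ep + n_en)] <- c(rep("EP", n_ep), rep("EN", n_en))
  exon_labels <- setNames(lab, ev)
  alpha <- ifelse(lab == "EP", logit(cfg$ep_base_psi),
                  ifelse(lab == "EN", logit(cfg$en_base_psi),
                         rnorm(cfg$n_events, 0, 0.7)))
  event_alpha <- setNames(alpha, ev)
  ## per-event regulator sensitivity: exons respond to the splicing drive
  ## with different gains, so tumor reactivation has graded penetrance
  jit <- cfg$event_slope_jitter
  event_slope <- setNames(runif(cfg$n_events, 1 - jit, 1 + jit), ev)
  host <- setNames(sample(genes, cfg$n_events, replace = TRUE), ev)

  truth <- list(
    pathway_labels = pathway_labels,
    exon_labels = exon_labels,
    event_alpha = event_alpha,
    event_slope = event_slope,
    host_gene = host,
    sf_ids = sfs, csf_set = csf, csf_weights = w,
    mut_csf_candidates = majors,
    sf_base = sf_base, gene_base = gene_base,
    gene_program = gene_program
  )

  drive <- csf_signal(sf_log2, truth, cfg)
  psi <- planted_psi(truth, cfg, drive, tp_ids)

  expr <- to_tpm(rbind(gene_log2, sf_log2))
  meta <- data.frame(sample_id = tp_ids, cohort = "development",
                     timepoint = seq_len(n_tp), prenatal = prenatal,
                     stringsAsFactors = FALSE)
  list(expr = expr, psi = psi, pathways = pw_members, meta = meta,
       events = data.frame(event_id = ev, gene_id = unname(host),
                           label = lab, stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate matched tumor and normal cohorts
#'
#' Normal samples sit in the postnatal state; each tumor re-expresses the
#' prenatal program with a per-sample strength drawn around
#' `reactivation_strength` (Beta(8m, 8(1-m))). A planted subset of
#' splicing factors carries nonsense mutations: mutations in CSF targets
#' null that factor's contribution to the EP drive in the carrier samples;
#' mutations in "increase" decoy factors add a reactivation-proportional
#' boost. CNV gains are assigned preferentially to CSFs in
#' high-reactivation tumors; the stage label grows with reactivation.
#'
#' @param truth ground truth from [generate_development()].
#' @param cfg the same [sim_config()].
#' @return list with `expr_tumor`, `expr_normal`, `psi_tumor`,
#'   `psi_normal`, `mutations` (MAF-like data.frame), `cnv`
#'   (gene x tumor matrix in -1/0/1), `meta` (per-sample cohort and stage)
#'   and the updated `truth` (adds `tumor_r`, `mutated_samples`,
#'   `mut_direction`).
#' @export
generate_cancer_cohort <- function(truth, cfg) {
  validate_sim_config(cfg)
  set_substream(cfg$seed, "cancer")
  sfs <- truth$sf_ids; csf <- truth$csf_set
  genes <- names(truth$gene_base)
  tum <- sprintf("T%03d", seq_len(cfg$n_tumor))
  nor <- sprintf("N%03d", seq_len(cfg$n_normal))

  m <- cfg$reactivation_strength
  r <- if (m <= 0) rep(0, cfg$n_tumor) else
    rbeta(cfg$n_tumor, 8 * m, 8 * (1 - m))
  names(r) <- tum

  make_expr <- function(rvec, ids) {
    load <- cbind(prenatal = rvec, postnatal = 1 - rvec, none = rep(0, length(rvec)))
    g <- truth$gene_base +
      cfg$expr_amp * t(load[, truth$gene_program, drop = FALSE])
    s <- truth$sf_base + cfg$expr_amp * outer(as.numeric(sfs %in% csf), rvec)
    x <- rbind(g, s)
    x <- x + matrix(rnorm(length(x), 0, cfg$noise_sd), nrow = nrow(x))
    dimnames(x) <- list(c(genes, sfs), ids)
    x
  }
  log2_tumor <- make_expr(r, tum)
  log2_normal <- make_expr(rep(0, cfg$n_normal), nor)

  ## planted nonsense mutations
  targets <- cfg$mut_targets
  if (is.null(targets)) {
    n_inc <- min(cfg$n_mut_increase, cfg$n_sf - cfg$n_csf)
    targets <- c(truth$mut_csf_candidates,
                 sample(setdiff(sfs, csf), n_inc))
  }
  if (!all(targets %in% sfs))
    stop("mutation target not in factor list: ",
         paste(setdiff(targets, sfs), collapse = ", "))
  mutated_samples <- lapply(setNames(targets, targets), function(f)
    sort(sample(tum, min(cfg$mut_samples_per_factor, cfg$n_tumor))))
  mut_direction <- setNames(
    ifelse(targets %in% csf, "null_effect", "increase"), targets)

  nulled <- matrix(FALSE, length(sfs), cfg$n_tumor, dimnames = list(sfs, tum))
  boost <- rep(0, cfg$n_tumor); names(boost) <- tum
  for (f in targets) {
    smp <- mutated_samples[[f]]
    if (mut_direction[[f]] == "null_effect") nulled[f, smp] <- TRUE
    else boost[smp] <- boost[smp] + cfg$mut_increase_logit * r[smp]
  }

  drive_t <- csf_signal(log2_tumor, truth, cfg, nulled = nulled)
  drive_n <- csf_signal(log2_normal, truth, cfg)
  psi_tumor <- planted_psi(truth, cfg, drive_t, tum, ep_boost = boost)
  psi_normal <- planted_psi(truth, cfg, drive_n, nor)

  n_mut_rows <- sum(lengths(mutated_samples))
  mutations <- data.frame(
    sample_id = as.character(unlist(mutated_samples, use.names = FALSE)),
    gene = rep(names(mutated_samples), lengths(mutated_samples)),
    variant_class = rep("Nonsense_Mutation", n_mut_rows),
    stringsAsFactors = FALSE
  )

  ## CNV over splicing-factor genes: gains biased to CSFs in
  ## high-reactivation tumors
  p_gain <- matrix(cfg$cnv_base_rate, length(sfs), cfg$n_tumor,
                   dimnames = list(sfs, tum))
  p_gain[csf, ] <- p_gain[csf, ] +
    cfg$cnv_gain_slope * matrix(r, length(csf), cfg$n_tumor, byrow = TRUE)
  cnv <- matrix(rbinom(length(p_gain), 1, pmin(p_gain, 1)),
                nrow = nrow(p_gain), dimnames = dimnames(p_gain))
  loss <- matrix(rbinom(length(p_gain), 1, cfg$cnv_base_rate),
                 nrow = nrow(p_gain))
  cnv[cnv == 0 & loss == 1] <- -1L

  ## ordinal stage by reactivation tertile
  stage <- if (length(unique(r)) < 3) rep("I", cfg$n_tumor) else
    c("I", "II", "III")[cut(rank(r, ties.method = "first"),
                            breaks = 3, labels = FALSE)]
  meta <- rbind(
    data.frame(sample_id = tum, cohort = "tumor", stage = stage,
               stringsAsFactors = FALSE),
    data.frame(sample_id = nor, cohort = "normal", stage = NA,
               stringsAsFactors = FALSE))

  truth$tumor_r <- r
  truth$mutated_samples <- mutated_samples
  truth$mut_direction <- mut_direction
  list(expr_tumor = to_tpm(log2_tumor), expr_normal = to_tpm(log2_normal),
       psi_tumor = psi_tumor, psi_normal = psi_normal,
       mutations = mutations, cnv = cnv, meta = meta, truth = truth)
}

#' Generate the toy genome annotation
#'
#' Lays out one locus per gene on a single chromosome, places each event's
#' skipped exon inside its host gene, assigns an inclusion and an exclusion
#' transcript per event, and plants one protein domain on a configurable
#' fraction of EP exons (background rate elsewhere) together with decoy
#' domains. All intervals are 0-based half-open.
#'
#' @param truth ground truth from [generate_development()].
#' @param cfg the same [sim_config()].
#' @return list with `events` (event annotation data.frame whose transcript
#'   sets are comma-joined strings), `exon_bed`, `domain_bed`, `tss`
#'   (gene, chrom, tss, strand) and updated `truth` (adds
#'   `domain_planted`).
#' @export
generate_annotation <- function(truth, cfg) {
  validate_sim_config(cfg)
  set_substream(cfg$seed, "annotation")
  genes <- names(truth$gene_base)
  ev <- names(truth$exon_labels)
  host <- truth$host_gene

  per_gene <- table(factor(host, levels = genes))
  slot_width <- 300
  gene_len <- pmax(5000, 2000 + max(per_gene) * slot_width + 500)
  gene_start <- setNames((seq_along(genes) - 1) * (gene_len + 5000), genes)

  ## slot index of each event within its host gene
  slot <- stats::ave(seq_along(ev), host, FUN = seq_along)
  exon_start <- unname(gene_start[host]) + 1000 + (slot - 1) * slot_width
  exon_bed <- data.frame(
    chrom = "chr1", start = exon_start, end = exon_start + 200,
    name = ev, score = 0, strand = "+", stringsAsFactors = FALSE)

  events <- data.frame(
    chrom = "chr1", gene_id = unname(host), event_id = ev,
    inclusion_transcripts = paste0(ev, "_T1"),
    total_transcripts = paste(paste0(ev, "_T1"), paste0(ev, "_T2"), sep = ","),
    stringsAsFactors = FALSE)

  tss <- data.frame(gene = genes, chrom = "chr1",
                    tss = unname(gene_start), strand = "+",
                    stringsAsFactors = FALSE)

  ## planted domain: overlaps domain_frac_ep of EP exons, background rate
  ## elsewhere; decoy domains at background rate everywhere
  ep_ev <- ev[truth$exon_labels == "EP"]
  other_ev <- setdiff(ev, ep_ev)
  dom_hits <- function(event_subset, frac)
    sample(event_subset, round(length(event_subset) * frac))
  dom_interval <- function(evs, nm) {
    i <- match(evs, exon_bed$name)
    data.frame(chrom = "chr1", start = exon_bed$start[i] + 50,
               end = exon_bed$start[i] + 150, name = nm, score = 0,
               strand = "+", stringsAsFactors = FALSE)
  }
  planted <- rbind(
    dom_interval(dom_hits(ep_ev, cfg$domain_frac_ep), "DOM_PLANTED"),
    dom_interval(dom_hits(other_ev, cfg$domain_frac_bg), "DOM_PLANTED"))
  decoys <- do.call(rbind, lapply(seq_len(cfg$n_decoy_domains), function(k)
    dom_interval(dom_hits(ev, cfg$domain_frac_bg), sprintf("DOM_D%02d", k))))
  domain_bed <- unique(rbind(planted, decoys))
  rownames(domain_bed) <- NULL

  truth$domain_planted <- c(DOM_PLANTED = "EP")
  list(events = events, exon_bed = exon_bed, domain_bed = domain_bed,
       tss = tss, truth = truth)
}

#' Generate the regulatory layer: TF targets and knockdown experiments
#'
#' Plants one transcription factor whose promoter-binding targets cover
#' most CSFs and few non-CSFs, whose knockdown signature downregulates
#' those targets, and whose expression tracks the reactivated program in
#' tumors; decoy TFs get random target sets and flat expression. Also
#' builds per-factor shRNA-style knockdown PSI matrices (two replicates
#' plus shared controls) in which removing a CSF lowers EP inclusion by
#' `kd_dpsi` PSI units and removing a non-CSF does nothing.
#'
#' @param truth ground truth carrying `tumor_r` (run
#'   [generate_cancer_cohort()] first for TF expression rows; without it,
#'   TF expression is generated over the developmental timepoints).
#' @param cfg the same [sim_config()].
#' @return list with `binding` (TF -> bound factors, GMT-style list),
#'   `knock_downreg` (named "TF:cell" -> downregulated genes),
#'   `tf_expr` (TF x sample matrix, TPM), `kd` (list: `control_psi`,
#'   `kd_psi` named list of event x 2 matrices, `kd_expr` data.frame with
#'   per-factor control and knockdown expression), and updated `truth`
#'   (adds `tf_targets`, `planted_tf`, `kd_factors`).
#' @export
generate_regulatory_layer <- function(truth, cfg) {
  validate_sim_config(cfg)
  if (is.null(truth$csf_set)) stop("run generate_development first")
  set_substream(cfg$seed, "regulatory")
  csf <- truth$csf_set
  ncsf <- setdiff(truth$sf_ids, csf)

  tf_ids <- c("TF_PLANTED", sprintf("TF_D%02d", seq_len(cfg$n_tf_decoy)))
  n_bind <- round(cfg$tf_bind_frac_csf * length(csf)) +
    round(cfg$tf_bind_frac_ncsf * length(ncsf))
  binding <- vector("list", length(tf_ids)); names(binding) <- tf_ids
  binding[["TF_PLANTED"]] <- sort(c(
    sample(csf, round(cfg$tf_bind_frac_csf * length(csf))),
    sample(ncsf, round(cfg$tf_bind_frac_ncsf * length(ncsf)))))
  for (tf in tf_ids[-1])
    binding[[tf]] <- sort(sample(truth$sf_ids, n_bind))

  ## knockdown (KnockTF-style) downregulated sets per TF:cell-line
  knock <- list()
  knock[["TF_PLANTED:cellA"]] <- binding[["TF_PLANTED"]]
  for (tf in tf_ids[-1])
    knock[[paste0(tf, ":cellA")]] <- sort(sample(truth$sf_ids, n_bind))

  ## TF expression: planted TF tracks the reactivated prenatal program
  if (!is.null(truth$tumor_r)) {
    rvec <- truth$tumor_r
    smp <- names(rvec)
  } else {
    rvec <- program_activity(cfg)
    smp <- sprintf("TP%02d", seq_along(rvec))
  }
  tf_mu <- cfg$expr_base +
    cfg$expr_amp * outer(as.numeric(tf_ids == "TF_PLANTED"), rvec)
  tf_log2 <- tf_mu + matrix(rnorm(length(tf_mu), 0, cfg$noise_sd),
                            nrow = length(tf_ids))
  dimnames(tf_log2) <- list(tf_ids, smp)

  ## shRNA-style knockdown: controls at a fixed cell drive, per-factor
  ## knockdowns of a CSF subtract kd_dpsi from EP inclusion
  kd_factors <- c(sample(csf, min(cfg$kd_n_csf, length(csf))),
                  sample(ncsf, min(cfg$kd_n_ncsf, length(ncsf))))
  labs <- truth$exon_labels
  slope <- truth$event_slope *
    ifelse(labs == "EP", cfg$psi_beta,
           ifelse(labs == "EN", -cfg$psi_beta, 0))
  ctrl_mu <- inv_logit(truth$event_alpha + slope * cfg$kd_cell_drive)
  noisy_psi <- function(mu, ids) {
    eta <- logit(pmin(pmax(mu, 1e-6), 1 - 1e-6))
    m <- vapply(ids, function(i)
      inv_logit(eta + rnorm(length(eta), 0, cfg$psi_noise_sd)),
      numeric(length(eta)))
    rownames(m) <- names(truth$event_alpha)
    m
  }
  control_psi <- noisy_psi(ctrl_mu, sprintf("CTRL_%d", 1:4))
  kd_psi <- lapply(setNames(kd_factors, kd_factors), function(f) {
    mu <- ctrl_mu
    if (f %in% csf) {
      shift <- ifelse(labs == "EP", cfg$kd_dpsi,
                      ifelse(labs == "EN", -cfg$kd_dpsi, 0))
      mu <- pmin(pmax(mu + shift, 0), 1)
    }
    noisy_psi(mu, paste0(f, "_kd", 1:2))
  })
  kd_expr <- data.frame(
    factor = kd_factors,
    control_expr = 2^cfg$expr_base,
    kd_expr = cfg$kd_expr_frac * 2^cfg$expr_base,
    stringsAsFactors = FALSE)

  truth$tf_targets <- binding
  truth$planted_tf <- "TF_PLANTED"
  truth$kd_factors <- kd_factors
  list(binding = binding, knock_downreg = knock,
       tf_expr = to_tpm(tf_log2),
       kd = list(control_psi = control_psi, kd_psi = kd_psi,
                 kd_expr = kd_expr),
       truth = truth)
}

#' Run every generator in sequence
#'
#' Convenience wrapper threading the ground truth through all four
#' generators.
#'
#' @param cfg a [sim_config()].
#' @return list with `dev`, `cancer`, `annotation`, `regulatory`, `truth`
#'   and the `config`.
#' @export
simulate_all <- function(cfg = sim_config()) {
  dev <- generate_development(cfg)
  can <- generate_cancer_cohort(dev$truth, cfg)
  ann <- generate_annotation(can$truth, cfg)
  reg <- generate_regulatory_layer(ann$truth, cfg)
  list(dev = dev, cancer = can, annotation = ann, regulatory = reg,
       truth = reg$truth, config = cfg)
}

#' Expand a PSI matrix into per-transcript TPMs
#'
#' Distributes a per-gene total TPM between each event's inclusion and
#' exclusion transcript so that the inclusion/total ratio reproduces the
#' PSI matrix — the round-trip used to exercise the PSI quantifier against
#' the generator's planted inclusion levels.
#'
#' @param psi event x sample PSI matrix.
#' @param events event annotation data.frame from [generate_annotation()].
#' @param total_tpm total transcript TPM per event (scalar or per-event
#'   vector).
#' @return transcript x sample TPM matrix.
#' @export
psi_to_transcript_tpm <- function(psi, events, total_tpm = 10) {
  stopifnot(all(events$event_id %in% rownames(psi)))
  psi <- psi[events$event_id, , drop = FALSE]
  total <- rep_len(total_tpm, nrow(psi))
  inc <- psi * total
  exc <- (1 - psi) * total
  out <- rbind(inc, exc)
  rownames(out) <- c(events$inclusion_transcripts,
                     paste0(events$event_id, "_T2"))
  out
}
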