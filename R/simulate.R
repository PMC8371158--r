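# Multi-batch simulator with known ground truth. An observed log2 signal is
#
#   y = baseline_m + subject_m(sample) + effect_m * phenotype(sample)
#       + drift_{m,b}(run position)                  (within-batch drift)
#       + shift_{m,b}                                (additive batch offset)
#       + noise                                      (residual, log2 scale)
#
# exponentiated to the raw scale. Drift and batch shifts are
# factor-structured: a small number of latent instrument factors (column
# fouling, source condition, tuning state, ...) act on every metabolite
# through fixed chemistry-determined loadings, so the unwanted variation
# has small linear dimension across the study — the regime the
# removal-of-unwanted-variation model posits. Replicate measurements
# (short, batch, pooled QC) duplicate the same sample's biology but receive
# their own drift, offset and noise at their actual run positions, exactly
# as on an instrument. The emitted ground truth separates the biology-only
# signal from every unwanted term so any pipeline stage can be
# benchmarked.

#' Simulation configuration
#'
#' Defaults describe a mid-sized study of 6 batches in the 8 x 11 replicate
#' design with a 100-metabolite targeted panel: baseline log2 abundances
#' around 20 with substantial between-subject biological variation, drift
#' of mixed shape (latent linear and smooth nonlinear trends acting through
#' per-metabolite loadings), batch shifts on the scale of the jumps seen in
#' multi-batch run plots, 39% phenotype prevalence, 10% of metabolites
#' carrying a moderate (0.4 log2) phenotype effect, and small technical
#' noise typical of targeted LC-MS replicates.
#'
#' @param design A [design_config()]; defaults to 6 batches of the standard
#'   8 x 11 grid with 5 batch replicates.
#' @param n_metabolites Number of metabolites (default 100, a typical
#'   targeted acquisition panel).
#' @param baseline_mean,baseline_sd Per-metabolite baseline log2 level
#'   distribution (defaults 20, 2).
#' @param subject_sd Between-individual biological SD per metabolite on the
#'   log2 scale (default 0.4, roughly a 30% CV between people); replicate
#'   measurements of one individual share the same subject profile, pooled
#'   QC measurements carry none.
#' @param drift Latent drift shape: `"none"`, `"linear"`, `"smooth"` or
#'   `"mixed"` (default; latent factors are split between linear and smooth
#'   trends, so each metabolite's drift is a loading-weighted mix).
#' @param drift_scale Per-metabolite drift scale over a batch (log2 units,
#'   default 1.2).
#' @param smooth_amplitude Amplitude scale of smooth nonlinear latent
#'   trends (default 1.2).
#' @param batch_shift_sd Per-metabolite SD of the additive batch offsets
#'   (default 1.5 log2 units).
#' @param n_unwanted_factors Number of latent instrument factors driving
#'   drift and batch shifts through fixed per-metabolite loadings
#'   (default 5, the unwanted dimension the normalization defaults assume).
#' @param rough_scale Per-metabolite scale of short-timescale irregular
#'   instrument fluctuation (abrupt jumps and wiggles on the order of ten
#'   runs, which a smooth fit against run order cannot capture; default
#'   0.4). Also factor-structured.
#' @param phenotype_fraction Fraction of individuals labelled positive
#'   (default 0.39).
#' @param n_affected Metabolites carrying the biological effect
#'   (default 10).
#' @param effect_size Log2 shift for affected metabolites in positive
#'   individuals (default 0.4, one between-subject SD — a moderately strong
#'   clinical biomarker).
#' @param noise_sd Residual SD on the log2 scale (default 0.1).
#' @param missing_rate Probability that an entry is missing (default 0).
#' @param seed Integer seed (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(design = NULL, n_metabolites = 100,
                       baseline_mean = 20, baseline_sd = 2, subject_sd = 0.4,
                       drift = c("mixed", "none", "linear", "smooth"),
                       drift_scale = 1.2, smooth_amplitude = 1.2,
                       batch_shift_sd = 1.5, n_unwanted_factors = 5,
                       rough_scale = 0.4, phenotype_fraction = 0.39,
                       n_affected = 10, effect_size = 0.4, noise_sd = 0.1,
                       missing_rate = 0, seed = 1L) {
  drift <- match.arg(drift)
  seed <- as.integer(seed)
  design <- design %||% design_config(n_batches = 6, seed = seed)
  if (!inherits(design, "design_config")) stopf("`design` must be a design_config")
  if (!is_count(n_metabolites, min = 1)) stopf("n_metabolites must be >= 1")
  if (!is_fraction(phenotype_fraction)) stopf("phenotype_fraction must be in [0,1]")
  if (!is_count(n_affected) || n_affected > n_metabolites)
    stopf("n_affected must be a count <= n_metabolites")
  for (nm in c("baseline_sd", "subject_sd", "drift_scale", "smooth_amplitude",
               "batch_shift_sd", "rough_scale", "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0) stopf("%s must be >= 0", nm)
  }
  if (!is_fraction(missing_rate)) stopf("missing_rate must be in [0,1]")
  if (!is_count(n_unwanted_factors, min = 1))
    stopf("n_unwanted_factors must be a count >= 1")
  structure(list(design = design, n_metabolites = n_metabolites,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 subject_sd = subject_sd,
                 drift = drift, drift_scale = drift_scale,
                 smooth_amplitude = smooth_amplitude,
                 batch_shift_sd = batch_shift_sd,
                 n_unwanted_factors = n_unwanted_factors,
                 rough_scale = rough_scale,
                 phenotype_fraction = phenotype_fraction,
                 n_affected = n_affected, effect_size = effect_size,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a multi-batch experiment
#'
#' Generates the replicate design, then draws baseline levels, phenotype
#' labels, per-(metabolite, batch) drift curves, batch offsets and noise,
#' and assembles raw-scale per-batch assays together with the ground truth.
#' Deterministic for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return List with `batches` (list of raw-scale `hruv_assay`), `design`
#'   (the design sheet) and `truth` (`sim_truth`: `clean_log2` biology-only
#'   matrix, `drift` per-batch metabolite-by-run matrices, `offsets`,
#'   `affected`, `phenotype`, `config`).
#' @export
simulate_experiment <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stopf("`config` must be a sim_config")
  design <- generate_design(config$design)
  with_seed(config$seed + 1L, simulate_impl(config, design))
}

simulate_impl <- function(cfg, design) {
  mets <- sprintf("met%03d", seq_len(cfg$n_metabolites))
  nm <- cfg$n_metabolites
  baseline <- stats::rnorm(nm, cfg$baseline_mean, cfg$baseline_sd)
  affected <- if (cfg$n_affected > 0) sort(sample(mets, cfg$n_affected))
  else character()
  sample_ids <- unique(design$sample_id[design$sample_type == "individual"])
  phenotype <- stats::setNames(
    stats::rbinom(length(sample_ids), 1L, cfg$phenotype_fraction), sample_ids)
  # per-individual biological profile, shared by all of that individual's
  # replicate measurements; the pooled QC mixture carries none
  subject <- matrix(stats::rnorm(nm * length(sample_ids), 0, cfg$subject_sd),
                    nrow = nm, dimnames = list(mets, sample_ids))
  # latent instrument factors: fixed per-metabolite loadings, scaled so the
  # per-metabolite drift and offset magnitudes match the configured scales
  q <- cfg$n_unwanted_factors
  lambda <- matrix(stats::rnorm(nm * q), nrow = nm,
                   dimnames = list(mets, sprintf("uv%d", seq_len(q))))
  factor_kind <- switch(cfg$drift,
    none = rep("none", q),
    linear = rep("linear", q),
    smooth = rep("smooth", q),
    mixed = sample(rep_len(c("linear", "smooth"), q)))
  batch_ids <- unique(design$batch)
  u <- matrix(stats::rnorm(q * length(batch_ids), 0,
                           cfg$batch_shift_sd / sqrt(q)), nrow = q)
  offsets <- lambda %*% u
  dimnames(offsets) <- list(mets, as.character(batch_ids))
  batches <- vector("list", length(batch_ids))
  drift_curves <- vector("list", length(batch_ids))
  clean_cols <- list()
  for (bi in seq_along(batch_ids)) {
    b <- batch_ids[bi]
    ann <- design_annotation(design[design$batch == b, ])
    S <- nrow(ann)
    tt <- (seq_len(S) - 1) / max(S - 1, 1)   # within-batch position in [0,1]
    G <- vapply(seq_len(q), function(j) {
      switch(factor_kind[j],
        none = rep(0, S),
        linear = stats::rnorm(1, 0, cfg$drift_scale / sqrt(q)) * (tt - 0.5),
        smooth = smooth_curve(tt, cfg$smooth_amplitude / sqrt(q)))
    }, numeric(S))
    # short-timescale irregular fluctuation: moving-average process with a
    # ~8-run correlation length, invisible to a wide smoother but captured
    # by replicate pairs sitting ~11 runs apart
    H <- vapply(seq_len(q), function(j) {
      rough_process(S, cfg$rough_scale / sqrt(q))
    }, numeric(S))
    dr <- lambda %*% t(G + H)
    dimnames(dr) <- list(mets, NULL)
    ph <- phenotype[ann$sample_id]
    eff_rows <- mets %in% affected
    bio <- matrix(baseline, nrow = nm, ncol = S,
                  dimnames = list(mets, ann$measurement_id))
    is_sample <- ann$sample_id %in% sample_ids
    bio[, is_sample] <- bio[, is_sample, drop = FALSE] +
      subject[, ann$sample_id[is_sample], drop = FALSE]
    bio[eff_rows, ] <- bio[eff_rows, , drop = FALSE] +
      cfg$effect_size * rep(ifelse(is.na(ph), 0, ph), each = sum(eff_rows))
    noise <- matrix(stats::rnorm(nm * S, 0, cfg$noise_sd), nrow = nm)
    log2v <- bio + dr + offsets[, bi] + noise
    vals <- 2^log2v
    miss <- matrix(stats::runif(nm * S) < cfg$missing_rate, nrow = nm)
    vals[miss] <- NA
    dimnames(vals) <- dimnames(bio)
    batches[[bi]] <- hruv_assay(vals, ann, scale = "raw", missing = miss)
    colnames(dr) <- ann$measurement_id
    drift_curves[[bi]] <- dr
    clean_cols[[bi]] <- bio
  }
  names(batches) <- as.character(batch_ids)
  names(drift_curves) <- as.character(batch_ids)
  truth <- structure(list(clean_log2 = do.call(cbind, clean_cols),
                          drift = drift_curves, offsets = offsets,
                          affected = affected, phenotype = phenotype,
                          config = cfg),
                     class = "sim_truth")
  list(batches = batches, design = design, truth = truth)
}

# random smooth within-batch trend: a slow sinusoid (half to one cycle per
# batch, the timescale of column fouling and tuning drift) plus a centred
# quadratic; curved enough that a purely linear corrector cannot remove it
rough_process <- function(S, scale) {
  if (scale == 0) return(rep(0, S))
  z <- stats::rnorm(S + 8)
  h <- as.numeric(stats::filter(z, rep(1, 8) / sqrt(8), sides = 1))[9:(S + 8)]
  scale * (h - mean(h))
}

smooth_curve <- function(tt, amplitude) {
  a <- stats::rnorm(1, 0, amplitude)
  f <- sample(c(0.5, 0.75, 1), 1)
  phi <- stats::runif(1, 0, 2 * pi)
  q <- stats::rnorm(1, 0, amplitude / 2)
  y <- a * sin(2 * pi * f * tt + phi) + q * ((tt - 0.5)^2 - 1 / 12)
  y - mean(y)
}

#' Ground-truth recovery metrics
#'
#' Compares a normalized assay against the simulator's biology-only signal:
#' root-mean-square error after per-metabolite recentring (normalization is
#' defined up to a per-metabolite location), mean absolute residual
#' correlation with run order within batches (residual drift), the median
#' between-batch SD of per-metabolite residual means (residual batch
#' offset), and the recovered phenotype effect on the affected metabolites.
#'
#' @param x Normalized `hruv_assay` (log2 scale).
#' @param truth The `sim_truth` from [simulate_experiment()].
#' @return A `truth_metrics` list with `rmse`, `residual_drift_cor`,
#'   `residual_batch_offset`, `effect_recovered` (per affected metabolite),
#'   `effect_size_true`.
#' @export
truth_metrics <- function(x, truth) {
  assert_assay(x)
  if (!inherits(truth, "sim_truth")) stopf("`truth` must be a sim_truth")
  ids <- x$annotation$measurement_id
  if (!all(ids %in% colnames(truth$clean_log2)))
    stopf("measurement ids do not match the simulation truth")
  mets <- rownames(x$values)
  clean <- truth$clean_log2[mets, ids, drop = FALSE]
  v <- x$values
  resid <- v - clean
  resid_c <- resid - rowMeans(resid, na.rm = TRUE)
  rmse <- sqrt(mean(resid_c^2, na.rm = TRUE))
  ann <- x$annotation
  cors <- c(); batch_means <- NULL
  for (b in unique(ann$batch)) {
    idx <- which(ann$batch == b)
    pos <- rank(ann$run_index[idx])
    cc <- apply(resid[, idx, drop = FALSE], 1L, function(r) {
      ok <- !is.na(r)
      if (sum(ok) < 3 || stats::sd(r[ok]) == 0) return(NA_real_)
      stats::cor(r[ok], pos[ok])
    })
    cors <- c(cors, cc)
    batch_means <- cbind(batch_means,
                         rowMeans(resid[, idx, drop = FALSE], na.rm = TRUE))
  }
  offset_sd <- apply(batch_means, 1L, stats::sd)
  eff <- effect_estimate(x, truth)
  structure(list(rmse = rmse,
                 residual_drift_cor = mean(abs(cors), na.rm = TRUE),
                 residual_batch_offset = stats::median(offset_sd, na.rm = TRUE),
                 effect_recovered = eff,
                 effect_size_true = truth$config$effect_size),
            class = "truth_metrics")
}

# phenotype-positive minus phenotype-negative mean, per affected metabolite,
# over one measurement per distinct individual
effect_estimate <- function(x, truth) {
  ann <- x$annotation
  ind <- which(ann$sample_type == "individual")
  ind <- ind[!duplicated(ann$sample_id[ind])]
  ph <- truth$phenotype[ann$sample_id[ind]]
  mets <- intersect(truth$affected, rownames(x$values))
  if (!length(mets) || length(unique(ph)) < 2)
    return(stats::setNames(numeric(0), character(0)))
  v <- x$values
  vapply(mets, function(m) {
    mean(v[m, ind[ph == 1]], na.rm = TRUE) -
      mean(v[m, ind[ph == 0]], na.rm = TRUE)
  }, numeric(1))
}

#' @export
print.truth_metrics <- function(x, ...) {
  cat("Ground-truth recovery\n")
  cat(sprintf("  RMSE vs clean signal: %.4f\n", x$rmse))
  cat(sprintf("  mean |cor(residual, run)|: %.3f\n", x$residual_drift_cor))
  cat(sprintf("  median residual batch-offset SD: %.4f\n",
              x$residual_batch_offset))
  if (length(x$effect_recovered))
    cat(sprintf("  recovered effect: mean %.3f (true %.2f)\n",
                mean(x$effect_recovered), x$effect_size_true))
  invisible(x)
}
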