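#' Simulation configuration for Fluidigm-style qRT-PCR studies
#'
#' Builds and validates the configuration object consumed by
#' [generate_study()]. Defaults describe a blood miRNA validation cohort:
#' 120 samples in three groups (74 NSCLC, 26 COPD, 20 unaffected controls),
#' 235 target assays plus five endogenous controls, all measured in
#' triplicate on a platform with a 25-cycle linear range of detection.
#'
#' The measurement model is additive on the Ct (log2 abundance) scale.
#' For sample \eqn{s} in group \eqn{g} and assay \eqn{a}, the merged
#' (biological) value is
#' \deqn{Ct(a, s) = baseline_a + effect_a(g) + L_s + \epsilon_{as}}
#' where \eqn{L_s \sim N(0, loading\_sd^2)} is a per-sample offset shared by
#' every assay (RNA input / efficiency), and \eqn{\epsilon} is per-assay
#' noise with SD `sample_sd` for targets. Endogenous controls never carry a
#' group effect, and their per-assay noise SD is chosen so that the
#' *observed* SD of the merged control Ct matches the profile's `sd_ct`
#' (i.e. `sd_ct` is a total SD, loading included). Each replicate equals
#' the merged value plus `N(0, replicate_sd^2)`.
#'
#' Wells fail with probability `dropout_base` plus a logistic term in the
#' well's Ct that switches on roughly five cycles below `ct_ceiling` and
#' reaches one half at the ceiling, so low-abundance targets fail more
#' often. A failed well either reports no Ct at all or reports its Ct with
#' a quality score drawn from the "failed" Beta distribution (peaked near
#' 0.4); passing wells draw their quality from the "good" Beta distribution
#' (peaked near 0.9). Both distributions straddle the 0.65 quality
#' threshold used downstream.
#'
#' @param n_per_group Named integer vector of samples per group. Order
#'   matters: the first group is the disease group of the headline
#'   contrasts.
#' @param n_assays Number of target assays (endogenous controls are added
#'   on top).
#' @param control_profiles Data frame with columns `name`, `mean_ct`,
#'   `sd_ct` describing the endogenous controls. Defaults place RNU48,
#'   RNU44 and RNU6B at their reported abundance tiers (means 8, 12 and
#'   20.9 cycles with SDs 1.4, 2.1 and 2.0) and RNU24 / RPL21 at the low
#'   end of the dynamic range.
#' @param n_planted Number of truly differential target assays per
#'   contrast: the first `n_planted` targets receive a shift specific to
#'   the first group, the next `n_planted` a shift specific to the second.
#' @param effect_size Magnitude of every planted shift, in cycles.
#' @param baseline_range Range (cycles) of the uniform distribution of
#'   target baselines. The default upper end lies above the detection
#'   ceiling so that a realistic fraction of the panel fails curation.
#' @param sample_sd Per-assay biological + technical SD (cycles) of a
#'   target's merged Ct.
#' @param loading_sd SD (cycles) of the per-sample shared offset. Must be
#'   smaller than every control `sd_ct`.
#' @param replicate_sd Within-triplicate SD (cycles).
#' @param dropout_base Baseline probability that a well fails outright.
#' @param quality_good,quality_fail Length-2 numeric vectors `(alpha,
#'   beta)` of the Beta distributions of quality scores for passing and
#'   failed wells.
#' @param ct_ceiling Cycles beyond which wells are increasingly censored;
#'   must exceed every control mean.
#' @param seed Integer seed; identical seeds give byte-identical studies.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_study()], [generate_screening_stats()]
#' @export
simulation_config <- function(n_per_group = c(NSCLC = 74L, COPD = 26L, control = 20L),
                              n_assays = 235L,
                              control_profiles = default_control_profiles(),
                              n_planted = 30L,
                              effect_size = 1.5,
                              baseline_range = c(12, 27),
                              sample_sd = 1.0,
                              loading_sd = 0.5,
                              replicate_sd = 0.25,
                              dropout_base = 0.01,
                              quality_good = c(9, 1.8),
                              quality_fail = c(2.6, 4),
                              ct_ceiling = 25,
                              seed = 1L) {
  cfg <- list(n_per_group = n_per_group, n_assays = as.integer(n_assays),
              control_profiles = control_profiles,
              n_planted = as.integer(n_planted), effect_size = effect_size,
              baseline_range = baseline_range, sample_sd = sample_sd,
              loading_sd = loading_sd, replicate_sd = replicate_sd,
              dropout_base = dropout_base, quality_good = quality_good,
              quality_fail = quality_fail, ct_ceiling = ct_ceiling,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Endogenous control abundance profiles
#'
#' The default abundance tiers of the five endogenous controls. RNU48,
#' RNU44 and RNU6B use their reported means and SDs (8 +/- 1.4, 12 +/- 2.1
#' and 20.9 +/- 2.0 cycles); RNU24 and RPL21, described only as low
#' abundant, are placed once near the upper end of the dynamic range.
#'
#' @return Data frame with columns `name`, `mean_ct`, `sd_ct`.
#' @export
default_control_profiles <- function() {
  data.frame(
    name    = c("RNU48", "RNU44", "RNU6B", "RNU24", "RPL21"),
    mean_ct = c(8,       12,      20.9,    20.5,    21.2),
    sd_ct   = c(1.4,     2.1,     2.0,     1.5,     1.6),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid simulation config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (length(cfg$n_per_group) < 2 || is.null(names(cfg$n_per_group)) ||
      any(!nzchar(names(cfg$n_per_group))))
    fail("n_per_group", "must be a named vector with at least two groups")
  if (any(cfg$n_per_group < 2)) fail("n_per_group", "every group needs >= 2 samples")
  if (cfg$n_assays < 1) fail("n_assays", "must be positive")
  cp <- cfg$control_profiles
  if (!is.data.frame(cp) || !all(c("name", "mean_ct", "sd_ct") %in% names(cp)))
    fail("control_profiles", "needs columns name, mean_ct, sd_ct")
  if (any(cp$sd_ct <= 0)) fail("control_profiles", "all sd_ct must be > 0")
  if (cfg$n_planted < 0 || 2 * cfg$n_planted > cfg$n_assays)
    fail("n_planted", "needs 0 <= 2*n_planted <= n_assays")
  if (cfg$effect_size < 0) fail("effect_size", "must be >= 0")
  if (length(cfg$baseline_range) != 2 || diff(cfg$baseline_range) < 0)
    fail("baseline_range", "must be an increasing length-2 range")
  for (f in c("sample_sd", "replicate_sd"))
    if (cfg[[f]] < 0) fail(f, "must be >= 0")
  if (cfg$loading_sd < 0) fail("loading_sd", "must be >= 0")
  if (any(cp$sd_ct <= cfg$loading_sd))
    fail("loading_sd", "must be smaller than every control sd_ct")
  if (cfg$dropout_base < 0 || cfg$dropout_base > 1)
    fail("dropout_base", "must be a probability in [0, 1]")
  for (f in c("quality_good", "quality_fail"))
    if (length(cfg[[f]]) != 2 || any(cfg[[f]] <= 0))
      fail(f, "must be two positive Beta parameters")
  if (cfg$ct_ceiling <= max(cp$mean_ct))
    fail("ct_ceiling", "must exceed every control mean")
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

#' Generate a synthetic Fluidigm-style validation study
#'
#' Simulates a complete well-level qRT-PCR dataset with known ground
#' truth: every sample x assay cell is measured in triplicate, endogenous
#' controls carry no group effect, a configured subset of target assays
#' carries planted group shifts of known sign and magnitude, and wells
#' fail at a rate that grows with Ct (see [simulation_config()] for the
#' generative model).
#'
#' @param config A `sim_config` object.
#' @return A list of class `sim_study` with components:
#' \describe{
#'   \item{wells}{Long-format data frame: `sample_id`, `assay_id`,
#'     `replicate` (1-3), `ct` (NA for failed amplification), `quality`.}
#'   \item{samples}{Annotation: `sample_id`, `group`, `kit`, `plate`.}
#'   \item{truth}{Ground truth per assay: baseline Ct, per-group effects,
#'     signed per-contrast shifts (`shift_<A>_vs_<B>`), planted flags, and
#'     an `is_control` flag. Non-planted shifts are exactly 0; planted
#'     shifts have magnitude `effect_size`.}
#' }
#' @export
generate_study <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(simulation_config, config)
  }
  validate_sim_config(config)
  set.seed(config$seed)

  groups <- names(config$n_per_group)
  n_samples <- sum(config$n_per_group)
  sample_id <- sprintf("S%03d", seq_len(n_samples))
  group <- rep(groups, times = config$n_per_group)
  samples <- data.frame(sample_id = sample_id, group = group,
                        kit = assign_kits(config$n_per_group),
                        plate = paste0("P", 1 + (seq_len(n_samples) - 1L) %% 2L),
                        stringsAsFactors = FALSE)

  n_tgt <- config$n_assays
  tgt_id <- sprintf("mir-%03d", seq_len(n_tgt))
  ctrl <- config$control_profiles
  assay_id <- c(tgt_id, ctrl$name)
  n_assay <- length(assay_id)

  baseline <- c(runif(n_tgt, config$baseline_range[1], config$baseline_range[2]),
                ctrl$mean_ct)

  ## per-group effects: first n_planted targets shift in group 1, the next
  ## n_planted in group 2; signs alternate so both directions occur
  effect <- matrix(0, n_assay, length(groups), dimnames = list(assay_id, groups))
  np <- config$n_planted
  if (np > 0) {
    signs1 <- rep_len(c(1, -1), np) * config$effect_size
    effect[seq_len(np), 1] <- signs1
    if (length(groups) >= 2) {
      signs2 <- rep_len(c(-1, 1), np) * config$effect_size
      effect[np + seq_len(np), 2] <- signs2
    }
  }

  ## control noise: profile sd_ct is the observed total, loading included
  assay_sd <- c(rep(config$sample_sd, n_tgt),
                sqrt(ctrl$sd_ct^2 - config$loading_sd^2))

  loading <- rnorm(n_samples, 0, config$loading_sd)
  noise <- matrix(rnorm(n_assay * n_samples), n_assay, n_samples) * assay_sd
  merged <- baseline + effect[, match(group, groups)] + noise +
    rep(loading, each = n_assay)
  dimnames(merged) <- list(assay_id, sample_id)

  ## triplicate wells in long format
  n_wells <- n_assay * n_samples * 3L
  wells <- data.frame(
    sample_id = rep(rep(sample_id, each = n_assay), times = 3L),
    assay_id  = rep(assay_id, times = n_samples * 3L),
    replicate = rep(1:3, each = n_assay * n_samples),
    ct        = as.vector(merged) + rnorm(n_wells, 0, config$replicate_sd),
    stringsAsFactors = FALSE
  )

  ## dropout_base = 0 models an ideal instrument: no well failures at all
  p_fail <- if (config$dropout_base > 0)
    config$dropout_base + (1 - config$dropout_base) *
      stats::plogis((wells$ct - config$ct_ceiling) / 1.5)
  else rep(0, n_wells)
  failed <- stats::runif(n_wells) < p_fail
  no_amp <- failed & (stats::runif(n_wells) < 0.5)
  wells$ct[no_amp] <- NA_real_
  wells$quality <- ifelse(failed,
                          stats::rbeta(n_wells, config$quality_fail[1], config$quality_fail[2]),
                          stats::rbeta(n_wells, config$quality_good[1], config$quality_good[2]))
  wells <- wells[order(wells$sample_id, wells$assay_id, wells$replicate), ]
  rownames(wells) <- NULL

  truth <- data.frame(assay_id = assay_id, baseline = baseline,
                      is_control = assay_id %in% ctrl$name,
                      stringsAsFactors = FALSE)
  for (g in groups) truth[[paste0("effect_", g)]] <- effect[, g]
  contrasts <- list(c(groups[1], groups[length(groups)]))
  if (length(groups) >= 3) contrasts <- c(contrasts, list(c(groups[1], groups[2])))
  for (cn in contrasts) {
    shift <- effect[, cn[1]] - effect[, cn[2]]
    truth[[paste0("shift_", cn[1], "_vs_", cn[2])]] <- shift
    truth[[paste0("planted_", cn[1], "_vs_", cn[2])]] <- shift != 0
  }

  structure(list(wells = wells, samples = samples, truth = truth,
                 config = config),
            class = "sim_study")
}

## Kit assignment mirrors the two-extraction-kit design: the default
## 74/26/20 cohort reproduces the reported split (40 NSCLC + 10 controls on
## PAXgene, the rest on miRNeasy); other designs split each group in half.
assign_kits <- function(n_per_group) {
  groups <- names(n_per_group)
  default <- identical(unname(n_per_group[groups]),
                       c(74L, 26L, 20L)) &&
    identical(groups, c("NSCLC", "COPD", "control"))
  n_pax <- if (default) c(40L, 0L, 10L) else pmin(n_per_group, n_per_group %/% 2L)
  unlist(lapply(seq_along(groups), function(i) {
    rep(c("PAXgene", "miRNeasy"),
        times = c(n_pax[i], n_per_group[i] - n_pax[i]))
  }), use.names = FALSE)
}

#' Simulate a screening-study statistics table
#'
#' Produces the per-assay summary a microarray screening study would
#' report for the same panel: an AUC whose deviation from 0.5 carries the
#' sign of the true group shift plus Gaussian reporting noise, and a
#' p-value from a z-statistic centred on the scaled shift with unit
#' sampling noise (so unplanted assays have uniform p-values and planted
#' assays concentrate at small p).
#'
#' @param truth Ground-truth table from [generate_study()].
#' @param noise_sd SD of the noise added to the screening AUC (>= 0).
#'   With `noise_sd = 0` the AUC direction of every planted assay equals
#'   the true shift direction exactly, and unplanted assays sit at exactly
#'   0.5 (no direction).
#' @param seed Integer seed.
#' @param shift_col Name of the shift column of `truth` to use; defaults
#'   to the first `shift_*` column (the disease-vs-control contrast).
#' @param z_scale Cycles-to-z conversion for the screening p-value.
#' @return Data frame of class `screening_stats`: `assay_id`, `old_id`,
#'   `screen_auc`, `screen_p`. Endogenous controls are not reported.
#' @export
generate_screening_stats <- function(truth, noise_sd = 0.05, seed = 1L,
                                     shift_col = NULL, z_scale = 2.5) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(shift_col)) {
    shift_col <- grep("^shift_", names(truth), value = TRUE)[1]
    if (is.na(shift_col)) stop("truth has no shift_* column", call. = FALSE)
  }
  set.seed(seed)
  tt <- truth[!truth$is_control, , drop = FALSE]
  shift <- tt[[shift_col]]
  auc <- stats::pnorm(shift / sqrt(2)) + stats::rnorm(nrow(tt), 0, noise_sd)
  auc <- pmin(pmax(auc, 0.001), 0.999)
  z <- shift * z_scale + stats::rnorm(nrow(tt))
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(assay_id = tt$assay_id, old_id = tt$assay_id,
                    screen_auc = auc, screen_p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("screening_stats", "data.frame")
  out
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Synthetic qRT-PCR study: %d samples (%s), %d assays x 3 replicates\n",
              nrow(x$samples),
              paste(sprintf("%s=%d", names(x$config$n_per_group),
                            x$config$n_per_group), collapse = "/"),
              nrow(x$truth)))
  cat(sprintf("  wells: %d (%.1f%% missing Ct)\n", nrow(x$wells),
              100 * mean(is.na(x$wells$ct))))
  invisible(x)
}
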