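#' Configuration of a full validation run
#'
#' Either a simulation configuration (synthetic-data mode) or paths to a
#' well table and sample annotation (file mode) — exactly one of the two —
#' plus the curation thresholds, the endogenous-control candidates and
#' chosen reference, the contrasts, and the classifier settings.
#'
#' @param simulation A `sim_config`, or `NULL` in file mode.
#' @param wells_path,samples_path Input TSVs in file mode.
#' @param screening_path Optional screening statistics TSV (file mode); in
#'   simulation mode a screening table is generated from the ground truth
#'   with `screening_noise_sd`.
#' @param mapping_path Optional identifier-mapping TSV.
#' @param ct_limit,quality_min,na_limit Curation thresholds (defaults 25
#'   cycles, 0.65, 10 NAs).
#' @param candidates Candidate endogenous controls.
#' @param reference Control used for delta-Ct normalization (default
#'   RNU44).
#' @param contrasts List of length-2 character vectors; the first group of
#'   each is the positive (disease) group.
#' @param alpha Significance level for concordance and Venn partitions.
#' @param screening_noise_sd AUC noise of the simulated screening table.
#' @param classifier A `classifier_config`.
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed; per-stage seeds are derived from it so adding
#'   a stage never perturbs earlier stages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulation = NULL,
                       wells_path = NULL, samples_path = NULL,
                       screening_path = NULL, mapping_path = NULL,
                       ct_limit = 25, quality_min = 0.65, na_limit = 10,
                       candidates = c("RNU6B", "RNU24", "RNU44", "RNU48", "RPL21"),
                       reference = "RNU44",
                       contrasts = list(c("NSCLC", "control"), c("NSCLC", "COPD")),
                       alpha = 0.05,
                       screening_noise_sd = 0.05,
                       classifier = classifier_config(),
                       out_dir = tempfile("mirct_run_"),
                       seed = 1L) {
  file_mode <- !is.null(wells_path) || !is.null(samples_path)
  if (is.null(simulation) && !file_mode)
    stop("run_config: provide either a simulation config or input paths",
         call. = FALSE)
  if (!is.null(simulation) && file_mode)
    stop("run_config: simulation config and input paths are mutually exclusive",
         call. = FALSE)
  if (file_mode) {
    for (p in c(wells_path, samples_path, screening_path, mapping_path))
      if (!is.null(p) && !file.exists(p))
        stop(sprintf("run_config: input file not found: %s", p), call. = FALSE)
    if (is.null(wells_path) || is.null(samples_path))
      stop("run_config: file mode needs both wells_path and samples_path",
           call. = FALSE)
  }
  structure(list(simulation = simulation, wells_path = wells_path,
                 samples_path = samples_path, screening_path = screening_path,
                 mapping_path = mapping_path, ct_limit = ct_limit,
                 quality_min = quality_min, na_limit = na_limit,
                 candidates = candidates, reference = reference,
                 contrasts = contrasts, alpha = alpha,
                 screening_noise_sd = screening_noise_sd,
                 classifier = classifier, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the complete validation analysis
#'
#' Orchestrates simulate (or load) -> curate -> control evaluation and
#' delta-Ct normalization -> differential statistics -> screening
#' concordance -> SVM classification, writing every stage's tables as TSV
#' into `config$out_dir` together with a JSON manifest (configuration
#' hash, master seed, per-stage seeds, and row/column bookkeeping).
#' Rerunning with the same configuration reproduces identical artifacts.
#'
#' @param config A `run_config`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every stage result (`study`, `curated`,
#'   `controls`, `delta`, `diff` per contrast, `anova`, `venn`,
#'   `concordance`, `classification`, `permutation`, `manifest`).
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 8)

  ## -- stage 1: data ---------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- stage_seed[1]
    study <- generate_study(sim)
    wells <- study$wells; samples <- study$samples
    screening <- generate_screening_stats(study$truth,
                                          noise_sd = config$screening_noise_sd,
                                          seed = stage_seed[2])
    write_tsv(study$truth, file.path(config$out_dir, "truth.tsv"))
  } else {
    study <- NULL
    wells <- read_wells(config$wells_path)
    samples <- read_samples(config$samples_path)
    screening <- if (!is.null(config$screening_path))
      read_screening(config$screening_path) else NULL
  }
  if (!is.null(config$mapping_path) && !is.null(screening)) {
    mm <- match_identifiers(screening, unique(wells$assay_id),
                            read_mapping(config$mapping_path))
    screening <- mm$matched
    screening$assay_id <- screening$matched_id
  }
  write_tsv(wells, file.path(config$out_dir, "wells.tsv"))
  write_tsv(samples, file.path(config$out_dir, "samples.tsv"))
  if (!is.null(screening))
    write_tsv(screening, file.path(config$out_dir, "screening.tsv"))
  say("data: %d wells, %d samples", nrow(wells), nrow(samples))

  ## -- stage 2: curation -----------------------------------------------
  curated <- curate_matrix(wells, na_limit = config$na_limit,
                           ct_limit = config$ct_limit,
                           quality_min = config$quality_min)
  panel <- expressed_panel(curated, controls = config$candidates)
  write_tsv(curated$values, file.path(config$out_dir, "curated_matrix.tsv"),
            rownames_as = "assay_id")
  write_tsv(curated$dropped_assays, file.path(config$out_dir, "dropped_assays.tsv"))
  say("curation: %d of %d assays retained (%d in expressed panel)",
      nrow(curated$values), length(unique(wells$assay_id)), length(panel))

  ## -- stage 3: normalization ------------------------------------------
  cand <- intersect(config$candidates, rownames(curated$values))
  controls <- rank_controls(curated, samples, cand, screening = screening,
                            contrast = config$contrasts[[1]])
  write_tsv(as.data.frame(controls),
            file.path(config$out_dir, "control_stability.tsv"))
  delta <- delta_ct(curated, config$reference)
  dv <- delta$values[setdiff(rownames(delta$values), cand), , drop = FALSE]
  delta_panel <- structure(list(values = dv, reference = delta$reference),
                           class = "delta_ct")
  write_tsv(delta_panel$values, file.path(config$out_dir, "delta_ct.tsv"),
            rownames_as = "assay_id")
  say("normalization: reference %s; %d candidate controls ranked",
      config$reference, length(cand))

  ## -- stage 4: differential -------------------------------------------
  diffs <- list()
  for (cn in config$contrasts) {
    key <- paste0(cn[1], "_vs_", cn[2])
    diffs[[key]] <- two_group_stats(delta_panel, samples, cn)
    write_tsv(as.data.frame(diffs[[key]]),
              file.path(config$out_dir, paste0("diff_", key, ".tsv")))
  }
  g <- samples$group[match(colnames(dv), samples$sample_id)]
  anova_tab <- if (length(unique(g)) >= 3) {
    at <- anova_three_group(delta_panel, samples)
    write_tsv(at, file.path(config$out_dir, "anova.tsv"))
    at
  } else NULL
  venn <- if (length(diffs) >= 2) {
    vp <- venn_partition(diffs[[1]], diffs[[2]], alpha = config$alpha)
    write_tsv(vp$overlaps, file.path(config$out_dir, "venn_overlaps.tsv"))
    vp
  } else NULL
  say("differential: %d contrasts%s", length(diffs),
      if (!is.null(anova_tab)) " + three-group ANOVA" else "")

  ## -- stage 5: concordance --------------------------------------------
  concord <- NULL
  if (!is.null(screening)) {
    concord <- directional_concordance(screening, diffs[[1]],
                                       alpha = config$alpha)
    ac <- auc_correlation(screening, diffs[[1]])
    write_tsv(ac$pairs, file.path(config$out_dir, "auc_pairs.tsv"))
    summary_df <- data.frame(
      n_matched = concord$n_matched, n_significant = concord$n_significant,
      n_concordant = concord$n_concordant,
      percent_concordant = concord$percent_concordant,
      binom_p = concord$binom_p, fisher_p = concord$fisher_p,
      auc_cor_r = ac$r, auc_cor_p = ac$p)
    write_tsv(summary_df, file.path(config$out_dir, "concordance.tsv"))
    concord$auc_cor <- ac
    say("concordance: %d/%d concordant (%.1f%%), AUC correlation %.3f",
        concord$n_concordant, concord$n_significant,
        concord$percent_concordant, ac$r)
  }

  ## -- stage 6: classification -----------------------------------------
  clf_cfg <- config$classifier
  clf_cfg$seed <- stage_seed[3]
  clf <- cross_validate(delta_panel, samples, config$contrasts[[1]], clf_cfg)
  perm <- if (clf_cfg$n_permutations > 0)
    permutation_null(delta_panel, samples, config$contrasts[[1]], clf_cfg,
                     observed = clf) else NULL
  clf_tab <- do.call(rbind, lapply(names(clf$panels), function(k) {
    m <- clf$panels[[k]]$metrics
    cbind(panel_size = as.integer(k), m,
          p_permutation = if (is.null(perm)) NA_real_
                          else perm$panels[[k]]$p_empirical)
  }))
  write_tsv(clf_tab, file.path(config$out_dir, "classification.tsv"))
  say("classification: panel sizes %s evaluated",
      paste(names(clf$panels), collapse = ", "))

  ## -- manifest ----------------------------------------------------------
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(serializable_config(config), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    master_seed = config$seed, stage_seeds = stage_seed,
    n_wells = nrow(wells), n_samples = nrow(samples),
    n_assays_raw = length(unique(wells$assay_id)),
    n_assays_curated = nrow(curated$values),
    n_panel = length(panel), reference = config$reference)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(study = study, curated = curated, panel = panel,
                 controls = controls, delta = delta_panel, diff = diffs,
                 anova = anova_tab, venn = venn, concordance = concord,
                 classification = clf, permutation = perm,
                 manifest = manifest))
}

## Strip non-serializable pieces (classed lists become plain lists). The
## output directory is location, not configuration: it is excluded so the
## manifest hash identifies the analysis, not where it was written.
serializable_config <- function(config) {
  x <- unclass(config)
  x$simulation <- if (!is.null(x$simulation)) unclass(x$simulation)
  x$classifier <- unclass(x$classifier)
  x$out_dir <- NULL
  x
}
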