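mk_screen <- function(ids, auc, p, old = ids) {
  x <- data.frame(assay_id = ids, old_id = old, screen_auc = auc,
                  screen_p = p, stringsAsFactors = FALSE)
  class(x) <- c("screening_stats", "data.frame")
  x
}

mk_valid <- function(ids, auc, p = rep(0.01, length(ids))) {
  st <- data.frame(assay_id = ids, p_t = p, q_t = bh_adjust(p), auc = auc,
                   stringsAsFactors = FALSE)
  class(st) <- c("marker_stats", "data.frame")
  st
}

test_that("identifier matching applies mappings and logs the unmatched", {
  scr <- mk_screen(c("mir-a", "mir-b", "mir-x"), rep(0.6, 3), rep(0.01, 3))
  # identity
  m <- match_identifiers(scr, c("mir-a", "mir-b", "mir-x"))
  expect_equal(nrow(m$matched), 3)
  expect_length(m$unmatched, 0)
  # old->new renaming
  map <- data.frame(old_id = "mir-x", new_id = "mir-x-5p")
  m <- match_identifiers(scr, c("mir-x-5p"), mapping = map)
  expect_equal(m$matched$matched_id, "mir-x-5p")
  expect_setequal(m$unmatched, c("mir-a", "mir-b"))
  # 3 screening ids, 2 mappable
  map2 <- data.frame(old_id = c("mir-a", "mir-b"), new_id = c("v1", "v2"))
  m <- match_identifiers(scr, c("v1", "v2"), mapping = map2)
  expect_equal(nrow(m$matched), 2)
  expect_equal(m$unmatched, "mir-x")
  # many-to-one collision needs the explicit flag
  map3 <- data.frame(old_id = c("mir-a", "mir-b"), new_id = c("v1", "v1"))
  expect_error(match_identifiers(scr, "v1", mapping = map3), "many_to_one")
  m <- match_identifiers(scr, "v1", mapping = map3, allow_many_to_one = TRUE)
  expect_equal(nrow(m$matched), 2)
})

test_that("directional concordance reproduces the worked cohort counts", {
  # 62 screening-significant, 56 with the same dys-regulation direction
  ids <- sprintf("m%03d", 1:128)
  s_p <- c(rep(0.001, 62), rep(0.8, 66))
  s_auc <- rep(0.7, 128)
  v_auc <- c(rep(0.8, 56), rep(0.2, 6), rep(0.55, 66))
  rep1 <- directional_concordance(mk_screen(ids, s_auc, s_p),
                                  mk_valid(ids, v_auc))
  expect_equal(rep1$n_significant, 62)
  expect_equal(rep1$n_concordant, 56)
  expect_equal(round(rep1$percent_concordant, 1), 90.3)
  expect_lt(rep1$binom_p, 1e-9)
  expect_equal(rep1$discordant$assay_id, ids[57:62])

  # 46 significant, 33 concordant
  s_p2 <- c(rep(0.001, 46), rep(0.8, 82))
  v_auc2 <- c(rep(0.8, 33), rep(0.2, 13), rep(0.55, 82))
  rep2 <- directional_concordance(mk_screen(ids, s_auc, s_p2),
                                  mk_valid(ids, v_auc2))
  expect_equal(round(rep2$percent_concordant, 1), 71.7)
})

test_that("all-concordant and edge cases give closed-form answers", {
  ids <- paste0("m", 1:10)
  r <- directional_concordance(mk_screen(ids, rep(0.8, 10), rep(0.01, 10)),
                               mk_valid(ids, rep(0.9, 10)))
  expect_equal(r$percent_concordant, 100)
  expect_equal(r$binom_p, min(1, 2 * 0.5^10), tolerance = 1e-12)
  # AUC exactly 0.5 has no direction: excluded and counted
  r2 <- directional_concordance(mk_screen(ids, c(0.5, rep(0.8, 9)),
                                          rep(0.01, 10)),
                                mk_valid(ids, rep(0.9, 10)))
  expect_equal(r2$n_indeterminate, 1)
  expect_equal(r2$percent_concordant, 100)
  # zero significant: flagged, percent undefined
  r3 <- directional_concordance(mk_screen(ids, rep(0.8, 10), rep(0.9, 10)),
                                mk_valid(ids, rep(0.9, 10)))
  expect_true(is.na(r3$percent_concordant))
  expect_equal(r3$note, "no screening-significant assays")
})

test_that("concordance is invariant to monotone AUC transforms fixing 0.5", {
  set.seed(1)
  ids <- paste0("m", 1:60)
  s_auc <- runif(60, 0.1, 0.9); v_auc <- runif(60, 0.1, 0.9)
  scr <- mk_screen(ids, s_auc, rep(0.01, 60))
  r1 <- directional_concordance(scr, mk_valid(ids, v_auc))
  squash <- function(a) 0.5 + 0.3 * tanh(3 * (a - 0.5))  # monotone, fixes 0.5
  r2 <- directional_concordance(mk_screen(ids, squash(s_auc), rep(0.01, 60)),
                                mk_valid(ids, squash(v_auc)))
  expect_equal(r1$percent_concordant, r2$percent_concordant)
  expect_equal(r1$n_concordant, r2$n_concordant)
})

test_that("binomial p is maximal at an even split", {
  n <- 40
  p_at <- vapply(0:n, function(k) binom.test(k, n, 0.5)$p.value, 0)
  expect_equal(which.max(p_at) - 1, n / 2)
})

test_that("AUC correlation matches the direct Pearson formula", {
  ids <- paste0("m", 1:5)
  s <- c(0.1, 0.3, 0.5, 0.7, 0.9); v <- c(0.2, 0.3, 0.4, 0.8, 0.7)
  res <- auc_correlation(mk_screen(ids, s, rep(0.01, 5)), mk_valid(ids, v))
  r_hand <- sum((s - mean(s)) * (v - mean(v))) /
    sqrt(sum((s - mean(s))^2) * sum((v - mean(v))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$n, 5)
  # perfect and anti-concordance
  expect_equal(auc_correlation(mk_screen(ids, s, rep(0.01, 5)),
                               mk_valid(ids, s))$r, 1)
  expect_equal(auc_correlation(mk_screen(ids, s, rep(0.01, 5)),
                               mk_valid(ids, 1 - s))$r, -1)
  expect_error(auc_correlation(mk_screen(ids, rep(0.5, 5), rep(0.01, 5)),
                               mk_valid(ids, s)), "zero variance")
})

test_that("noiseless screening makes planted markers fully concordant", {
  cfg <- tiny_config(n_per_group = c(NSCLC = 16L, control = 16L),
                     n_assays = 30L, n_planted = 10L, effect_size = 4,
                     loading_sd = 0.1, seed = 2L)
  st <- generate_study(cfg)
  cur <- curate_matrix(st$wells)
  scr <- generate_screening_stats(st$truth, noise_sd = 0, seed = 2L)
  ms <- two_group_stats(cur$values[grep("^mir", rownames(cur$values)), ],
                        st$samples, c("NSCLC", "control"))
  r <- directional_concordance(scr, ms)
  expect_equal(r$percent_concordant, 100)
})

test_that("subset comparison: identical subsets correlate perfectly", {
  st <- generate_study(tiny_config(n_per_group = c(NSCLC = 10L, control = 10L),
                                   seed = 3L))
  cur <- curate_matrix(st$wells)
  res <- subset_comparison(cur, cur, st$samples, st$samples,
                           c("NSCLC", "control"))
  expect_equal(res$ct_cor$r, 1, tolerance = 1e-12)
  expect_equal(res$auc_cor$r, 1, tolerance = 1e-12)
  # missing contrast group in one subset: AUC variant skipped with warning
  g2 <- st$samples; g2$group <- "NSCLC"
  expect_warning(res2 <- subset_comparison(cur, cur, st$samples, g2,
                                           c("NSCLC", "control")), "skipped")
  expect_null(res2$auc_cor)
})

test_that("subset agreement strengthens as noise shrinks and vanishes under
           independent truths", {
  base_cfg <- function(noise, seed)
    simulation_config(n_per_group = c(NSCLC = 20L, control = 20L),
                      n_assays = 50L, n_planted = 10L, effect_size = 2,
                      baseline_range = c(12, 20), sample_sd = noise,
                      dropout_base = 0, seed = seed)
  # one study per seed, split by extraction kit: same truth, independent noise
  cor_at <- function(noise) {
    mean(vapply(1:4, function(s) {
      st <- generate_study(base_cfg(noise, s))
      pax <- st$samples$sample_id[st$samples$kit == "PAXgene"]
      wa <- st$wells[st$wells$sample_id %in% pax, ]
      wb <- st$wells[!st$wells$sample_id %in% pax, ]
      subset_comparison(curate_matrix(wa), curate_matrix(wb),
                        st$samples, st$samples,
                        c("NSCLC", "control"))$ct_cor$r
    }, 0))
  }
  cors <- vapply(c(3, 1, 0.2), cor_at, 0)
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.95)

  # independent truths (no planted structure): mean correlation near zero
  null_cfg <- function(seed)
    simulation_config(n_per_group = c(NSCLC = 20L, control = 20L),
                      n_assays = 50L, n_planted = 0L,
                      baseline_range = c(12, 20), sample_sd = 1,
                      dropout_base = 0, seed = seed)
  rs <- vapply(1:40, function(s) {
    a <- generate_study(null_cfg(s))
    b <- generate_study(null_cfg(s + 500L))
    ma <- curate_matrix(a$wells)$values
    mb <- curate_matrix(b$wells)$values
    shared <- intersect(rownames(ma), rownames(mb))
    # remove the shared baseline construction by comparing residual means
    cor(rowMeans(ma[shared, ]) - a$truth$baseline[match(shared, a$truth$assay_id)],
        rowMeans(mb[shared, ]) - b$truth$baseline[match(shared, b$truth$assay_id)])
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})
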