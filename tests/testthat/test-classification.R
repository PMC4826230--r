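sep_matrix <- function(n_per = 12, n_assays = 6, gap = 20, noise = 0.1,
                       seed = 1) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(2 * n_per))
  m <- matrix(rnorm(n_assays * 2 * n_per, 0, noise), n_assays,
              dimnames = list(paste0("a", seq_len(n_assays)), samples))
  m[, seq_len(n_per)] <- m[, seq_len(n_per)] + gap
  list(values = m,
       groups = ann(samples, rep(c("case", "ctrl"), each = n_per)))
}

test_that("forward filter selection equals an independent p-value sort", {
  set.seed(2)
  x <- matrix(rnorm(30 * 20), 30, 20, dimnames = list(NULL, paste0("f", 1:20)))
  y <- rep(c("A", "B"), each = 15)
  x[y == "A", 3] <- x[y == "A", 3] + 3    # one dominant marker
  expect_equal(forward_filter_select(x, y, 1, positive = "A"), "f3")
  sel <- forward_filter_select(x, y, 5, positive = "A")
  p_ref <- vapply(1:20, function(j)
    t.test(x[y == "A", j], x[y == "B", j])$p.value, 0)
  expect_equal(sel, colnames(x)[order(p_ref)][1:5])
  # k = all assays returns the full ranked panel
  expect_setequal(forward_filter_select(x, y, 20, positive = "A"),
                  colnames(x))
  expect_error(forward_filter_select(x, y, 21), "exceeds")
})

test_that("the SVM separates a separable toy perfectly", {
  d <- sep_matrix()
  cfg <- classifier_config(panel_sizes = 2L, n_repetitions = 2L,
                           n_folds = 4L, n_permutations = 0L, seed = 3L)
  res <- cross_validate(d$values, d$groups, c("case", "ctrl"), cfg)
  m <- res$panels[["2"]]$metrics
  expect_equal(m$mean[m$metric == "accuracy"], 100)
  expect_equal(m$mean[m$metric == "auc"], 1.0)
  expect_true(all(m$ci_lo <= m$mean & m$mean <= m$ci_hi))
})

test_that("cross-validation is deterministic under a fixed seed", {
  st <- generate_study(tiny_config(seed = 4L))
  cur <- curate_matrix(st$wells)
  d <- delta_ct(cur, "RNU44")
  cfg <- classifier_config(panel_sizes = c(3L, 5L), n_repetitions = 2L,
                           n_folds = 4L, n_permutations = 2L, seed = 5L)
  r1 <- cross_validate(d, st$samples, c("NSCLC", "control"), cfg)
  r2 <- cross_validate(d, st$samples, c("NSCLC", "control"), cfg)
  expect_identical(r1$panels[["3"]]$per_rep, r2$panels[["3"]]$per_rep)
  p1 <- permutation_null(d, st$samples, c("NSCLC", "control"), cfg, observed = r1)
  p2 <- permutation_null(d, st$samples, c("NSCLC", "control"), cfg, observed = r1)
  expect_identical(p1$panels[["5"]]$null, p2$panels[["5"]]$null)
})

test_that("sensitivity and specificity follow the declared positive class", {
  d <- sep_matrix(n_per = 10, noise = 3, gap = 2, seed = 6)
  cfg <- classifier_config(panel_sizes = 3L, n_repetitions = 2L,
                           n_folds = 5L, n_permutations = 0L, seed = 7L)
  r_ab <- cross_validate(d$values, d$groups, c("case", "ctrl"), cfg)
  r_ba <- cross_validate(d$values, d$groups, c("ctrl", "case"), cfg)
  g <- function(r, met) {
    m <- r$panels[["3"]]$metrics
    m$mean[m$metric == met]
  }
  expect_equal(g(r_ab, "accuracy"), g(r_ba, "accuracy"), tolerance = 8)
  # swapping the contrast swaps the roles of the two error rates
  expect_equal(g(r_ab, "sensitivity"), g(r_ba, "specificity"), tolerance = 12)
})

test_that("strongly planted data beats every permutation (add-one rule)", {
  d <- sep_matrix(n_per = 10, n_assays = 5, gap = 10, noise = 0.5, seed = 8)
  cfg <- classifier_config(panel_sizes = 2L, n_repetitions = 1L,
                           n_folds = 4L, n_permutations = 5L, seed = 9L)
  pn <- permutation_null(d$values, d$groups, c("case", "ctrl"), cfg)
  expect_equal(pn$panels[["2"]]$p_empirical, 1 / 6, tolerance = 1e-12)
  expect_equal(pn$panels[["2"]]$observed_accuracy, 100)
  expect_true(all(pn$panels[["2"]]$null$accuracy < 100))
})

test_that("panel growth does not degrade AUC on planted data", {
  cfg <- tiny_config(n_per_group = c(NSCLC = 24L, control = 24L),
                     n_assays = 60L, n_planted = 15L, effect_size = 2.5,
                     baseline_range = c(12, 20), dropout_base = 0, seed = 10L)
  st <- generate_study(cfg)
  cur <- curate_matrix(st$wells)
  d <- delta_ct(cur, "RNU48")
  ccfg <- classifier_config(panel_sizes = c(5L, 10L, 30L),
                            n_repetitions = 3L, n_folds = 6L,
                            n_permutations = 0L, seed = 11L)
  res <- cross_validate(d, st$samples, c("NSCLC", "control"), ccfg)
  aucs <- vapply(c("5", "10", "30"), function(k) {
    m <- res$panels[[k]]$metrics
    m$mean[m$metric == "auc"]
  }, 0)
  sds <- vapply(c("5", "10", "30"), function(k)
    sd(res$panels[[k]]$per_rep[, "auc"]), 0)
  # nondecreasing within the CI overlap of the repetition spread
  expect_gte(aucs["10"], aucs["5"] - 1.96 * max(sds))
  expect_gte(aucs["30"], aucs["10"] - 1.96 * max(sds))
})

test_that("degenerate fold designs raise the advisory error", {
  d <- sep_matrix(n_per = 4, seed = 12)
  # a class with a single sample must be absent from one training fold
  g1 <- d$groups
  g1$group <- c(rep("case", 7), "ctrl")
  cfg <- classifier_config(panel_sizes = 2L, n_repetitions = 1L,
                           n_folds = 3L, n_permutations = 0L, seed = 13L)
  expect_error(cross_validate(d$values, g1, c("case", "ctrl"), cfg),
               "reduce n_folds")
  expect_error(cross_validate(d$values, d$groups, c("case", "ctrl"),
                              classifier_config(panel_sizes = 20L)),
               "exceeds")
  expect_error(cross_validate(d$values, d$groups, c("case", "missing"), cfg),
               "present")
})

test_that("selection frequencies concentrate on the planted markers", {
  d <- sep_matrix(n_per = 12, n_assays = 10, gap = 0, noise = 1, seed = 14)
  d$values[1:2, d$groups$group == "case"] <-
    d$values[1:2, d$groups$group == "case"] + 4
  cfg <- classifier_config(panel_sizes = 2L, n_repetitions = 2L,
                           n_folds = 4L, n_permutations = 0L, seed = 15L)
  res <- cross_validate(d$values, d$groups, c("case", "ctrl"), cfg)
  freq <- res$panels[["2"]]$selection_freq
  expect_setequal(names(freq)[freq > 0.9], c("a1", "a2"))
})
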