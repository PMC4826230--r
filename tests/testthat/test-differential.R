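test_that("AUC matches limits and the pair-counting definition", {
  lab <- c("P", "P", "N", "N")
  expect_equal(auc(c(3, 4, 1, 2), lab, positive = "P"), 1.0)
  expect_equal(auc(c(1, 2, 1, 2), lab, positive = "P"), 0.5)
  # ties counted one half, checked against exhaustive enumeration
  v <- c(1, 2, 3, 2, 3, 4); l <- rep(c("P", "N"), each = 3)
  expect_equal(auc(v, l, positive = "P"), oracle_auc(v[1:3], v[4:6]))
  expect_error(auc(c(1, 2), c("P", "P"), positive = "P"), "non-empty")
})

test_that("AUC orientations of one contrast sum to one", {
  set.seed(1)
  for (trial in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    v <- sample(1:6, n1 + n2, replace = TRUE)  # ties likely
    l <- c(rep("A", n1), rep("B", n2))
    expect_equal(auc(v, l, positive = "A") + auc(v, l, positive = "B"), 1)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (trial in 1:25) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)  # cross-check
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))  # monotone in sorted order
  }
})

test_that("two-group statistics behave on degenerate and planted assays", {
  samples <- sprintf("s%02d", 1:30)
  g <- ann(samples, rep(c("A", "B"), each = 15))
  set.seed(3)
  m <- rbind(flat = rep(c(1:15), 2),
             planted = c(rnorm(15, 5), rnorm(15, 0)),
             noise = rnorm(30))
  colnames(m) <- samples
  st <- two_group_stats(m, g, c("A", "B"))
  i <- match(c("flat", "planted", "noise"), st$assay_id)
  expect_equal(st$p_t[i[1]], 1, tolerance = 1e-10)
  expect_equal(st$auc[i[1]], 0.5)
  expect_true(is.na(st$direction[i[1]]))
  expect_lt(st$p_t[i[2]], 1e-6)
  expect_equal(st$direction[i[2]], "down_in_A")  # higher values = higher dCt
  expect_true(all(st$q_t >= st$p_t - 1e-15))
  expect_error(two_group_stats(m, g, c("A", "C")), "absent")
})

test_that("statistics are invariant to joint permutation of samples", {
  set.seed(4)
  samples <- sprintf("s%02d", 1:24)
  m <- matrix(rnorm(10 * 24), 10, 24,
              dimnames = list(paste0("a", 1:10), samples))
  g <- ann(samples, rep(c("A", "B"), times = c(10, 14)))
  st1 <- two_group_stats(m, g, c("A", "B"))
  perm <- sample(24)
  st2 <- two_group_stats(m[, perm], g, c("A", "B"))
  expect_equal(st1$p_t, st2$p_t, tolerance = 1e-12)
  expect_equal(st1$auc, st2$auc, tolerance = 1e-12)
})

test_that("Welch and Student variants agree with stats:: on single assays", {
  set.seed(5)
  x <- rnorm(12, 1); y <- rnorm(20, 0, 2)
  m <- matrix(c(x, y), 1, dimnames = list("a", sprintf("s%02d", 1:32)))
  g <- ann(colnames(m), rep(c("A", "B"), times = c(12, 20)))
  st <- two_group_stats(m, g, c("A", "B"))
  expect_equal(st$p_t, t.test(x, y)$p.value, tolerance = 1e-12)
  expect_equal(st$p_t_student, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(st$p_w, wilcox.test(x, y, exact = FALSE)$p.value,
               tolerance = 1e-12)
  # F = t^2 identity: the equal-variance t matches one-way ANOVA
  expect_equal(st$p_t_student,
               stats::oneway.test(v ~ grp, var.equal = TRUE,
                 data = data.frame(v = c(x, y),
                                   grp = rep(c("A", "B"), c(12, 20))))$p.value,
               tolerance = 1e-12)
})

test_that("three-group ANOVA matches stats::oneway.test per assay", {
  set.seed(6)
  samples <- sprintf("s%02d", 1:27)
  g <- rep(c("A", "B", "C"), each = 9)
  m <- matrix(rnorm(8 * 27), 8, 27, dimnames = list(paste0("a", 1:8), samples))
  m[1, g == "C"] <- m[1, g == "C"] + 5   # strong planted shift
  res <- anova_three_group(m, ann(samples, g))
  for (i in 1:8) {
    ref <- stats::oneway.test(m[i, ] ~ g, var.equal = TRUE)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(res$f[i], unname(ref$statistic), tolerance = 1e-10)
  }
  expect_lt(res$p[1], 1e-4)
  expect_equal(res$highest_mean_group[1], "C")
  # identical group distributions: p ~ 1
  g3 <- rep(c("A", "B", "C"), each = 9)
  same <- matrix(rep(rep(c(1, 2, 3), 9), 2), 2, 27, byrow = TRUE,
                 dimnames = list(c("f1", "f2"), samples))
  rsame <- anova_three_group(same, ann(samples, g3))
  expect_true(all(rsame$p > 0.9))
  expect_error(anova_three_group(m, ann(samples, rep(c("A", "B"), c(13, 14)))),
               ">= 3 groups")
})

test_that("Venn partition equals exhaustive set algebra", {
  set.seed(7)
  ids <- paste0("a", 1:40)
  mk <- function(p, aucs) {
    st <- data.frame(assay_id = ids, p_t = p, q_t = bh_adjust(p), auc = aucs,
                     stringsAsFactors = FALSE)
    class(st) <- c("marker_stats", "data.frame")
    st
  }
  for (trial in 1:5) {
    pA <- runif(40)^3; pB <- runif(40)^3
    aA <- runif(40); aB <- runif(40)
    vp <- venn_partition(mk(pA, aA), mk(pB, aB), alpha = 0.1,
                         use_adjusted = FALSE)
    up_A <- ids[pA < 0.1 & aA < 0.5]; down_A <- ids[pA < 0.1 & aA > 0.5]
    up_B <- ids[pB < 0.1 & aB < 0.5]; down_B <- ids[pB < 0.1 & aB > 0.5]
    expect_setequal(vp$sets$up_A, up_A)
    expect_setequal(vp$sets$down_B, down_B)
    expect_length(intersect(vp$sets$up_A, vp$sets$down_A), 0)
    o <- vp$overlaps
    expect_equal(o$n[o$set1 == "up_A" & o$set2 == "down_B"],
                 length(intersect(up_A, down_B)))
    expect_equal(o$n[o$set1 == "up_A" & o$set2 == "up_B"],
                 length(intersect(up_A, up_B)))
    expect_true(all(o$n <= pmin(lengths(vp$sets)[o$set1],
                                lengths(vp$sets)[o$set2])))
  }
  # disjoint planted sets: no cross-contrast overlap; same sets: full overlap
  pA <- c(rep(1e-6, 10), rep(0.9, 30)); aA <- c(rep(0.9, 10), rep(0.5, 30))
  pB <- c(rep(0.9, 30), rep(1e-6, 10)); aB <- c(rep(0.5, 30), rep(0.9, 10))
  vp <- venn_partition(mk(pA, aA), mk(pB, aB), alpha = 0.05)
  expect_true(all(vp$overlaps$n == 0))
  vp2 <- venn_partition(mk(pA, aA), mk(pA, aA), alpha = 0.05)
  expect_equal(vp2$overlaps$n[vp2$overlaps$set1 == "down_A" &
                              vp2$overlaps$set2 == "down_B"], 10)
})
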