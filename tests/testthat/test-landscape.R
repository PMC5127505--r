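# planted three-profile score matrix used across clustering tests
planted_matrix <- function(n_per = 30L, noise = 0.3, seed = 2L,
                           conditions = default_conditions()) {
  profiles <- default_class_effects_for_tests(conditions)
  set.seed(seed)
  rows <- list(); labels <- character()
  for (cls in rownames(profiles)) {
    for (i in seq_len(n_per)) {
      rows[[length(rows) + 1L]] <- profiles[cls, ] + rnorm(ncol(profiles), 0, noise)
      labels <- c(labels, cls)
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("v%03d", seq_len(nrow(m)))
  colnames(m) <- conditions
  list(scores = m, labels = setNames(labels, rownames(m)))
}

default_class_effects_for_tests <- function(conditions) {
  m <- matrix(0, 3, length(conditions),
              dimnames = list(c("Class1", "Class2", "Class3"), conditions))
  m["Class1", c("Gal", "MPA", "Formamide")] <- c(2, 1, -2)
  m["Class2", c("Gal", "Formamide")] <- c(1, 1)
  m["Class3", c("Gal", "Spt", "MPA", "Mn", "Caffeine", "Cyclohex")] <-
    c(2, 2, -2, -2, -2, -2)
  m
}

test_that("centered-correlation distance has its analytic fixed points", {
  x <- c(1, 3, -2, 0.5, 4)
  expect_equal(centered_correlation_distance(x, x), 0)
  expect_equal(centered_correlation_distance(x, -x), 2)
  # two shared conditions are the minimum; one is not enough
  expect_equal(centered_correlation_distance(c(1, NA, NA, NA, 2),
                                             c(1, NA, NA, NA, 2)), 0)
  expect_true(is.na(centered_correlation_distance(c(1, NA, NA, NA, 2),
                                                  c(1, NA, NA, NA, NA))))
  expect_true(is.na(centered_correlation_distance(rep(1, 5), x)))
})

test_that("distance agrees with a direct formula recomputation", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(14); y <- rnorm(14)
    direct <- 1 - sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(centered_correlation_distance(x, y), direct,
                 tolerance = 1e-12)
  }
})

test_that("duplicated profiles merge first at height zero", {
  pm <- planted_matrix(n_per = 4L, noise = 0.4)
  m <- rbind(pm$scores, dup1 = pm$scores[1, ], dup2 = pm$scores[1, ])
  rownames(m)[nrow(m) - 1:0] <- c("v001_dup", "v001_dup2")
  hc <- hier_cluster(m, min_signal = 0)
  expect_equal(min(hc$height), 0, tolerance = 1e-12)
})

test_that("three planted profile classes are recovered near-perfectly", {
  pm <- planted_matrix(n_per = 30L, noise = 0.3)
  hc <- hier_cluster(pm$scores)
  ca <- assign_classes(hc)
  expect_equal(ca$k, 3L)
  clustered <- names(ca$labels)[ca$labels != "unassigned"]
  expect_gte(adjusted_rand(ca$labels[clustered], pm$labels[clustered]), 0.9)
})

test_that("the dendrogram is invariant to input row order", {
  pm <- planted_matrix(n_per = 10L, noise = 0.3, seed = 6L)
  hc1 <- hier_cluster(pm$scores)
  set.seed(1)
  perm <- sample(nrow(pm$scores))
  hc2 <- hier_cluster(pm$scores[perm, ])
  expect_equal(hc1$height, hc2$height)
  expect_identical(hc1$labels, hc2$labels)
  expect_identical(stats::cutree(hc1, 3), stats::cutree(hc2, 3))
})

test_that("anchors name the clusters they fall in", {
  pm <- planted_matrix(n_per = 20L, noise = 0.3, seed = 4L)
  m <- pm$scores
  # place spike-in anchors on their class profiles
  prof <- default_class_effects_for_tests(colnames(m))
  set.seed(8)
  anchors <- rbind(
    H1085Y = prof["Class1", ] + rnorm(14, 0, 0.2),
    H1085Q = prof["Class1", ] + rnorm(14, 0, 0.2),
    F1086S = prof["Class1", ] + rnorm(14, 0, 0.2),
    G1097D = prof["Class3", ] + rnorm(14, 0, 0.2),
    E1103G = prof["Class3", ] + rnorm(14, 0, 0.2))
  m <- rbind(m, anchors)
  ca <- assign_classes(hier_cluster(m))
  expect_true(ca$anchor_consistent)
  expect_equal(unname(ca$labels["E1103G"]), "Class3")
  expect_equal(unname(ca$labels["H1085Y"]), "Class1")
  # the gain-of-function anchors co-cluster with planted Class3 members
  cl3 <- names(pm$labels)[pm$labels == "Class3"]
  expect_equal(unname(sort(table(ca$labels[cl3]), decreasing = TRUE))[1],
               as.integer(sum(ca$labels[cl3] == "Class3")))
})

test_that("a single planted profile collapses to one class", {
  set.seed(12)
  m <- matrix(rep(c(2, -2, 1, 0, 0, 0), each = 12), nrow = 12) +
    rnorm(72, 0, 0.05)
  rownames(m) <- sprintf("v%02d", 1:12)
  colnames(m) <- default_conditions()[1:6]
  hc <- hier_cluster(m)
  ca <- assign_classes(hc)
  expect_equal(ca$k, 1L)
  expect_true(all(ca$labels == "Class1"))
  expect_true(isTRUE(ca$degenerate))
})

test_that("class-condition t test matches the pooled-variance formula", {
  a <- c(0, 0, 0, 0) + c(0.01, -0.01, 0.02, -0.02)
  b <- c(1, 1, 1, 1) + c(-0.015, 0.015, -0.005, 0.005)
  m <- matrix(c(a, b), ncol = 1, dimnames = list(sprintf("v%d", 1:8), "Mn"))
  labels <- setNames(rep(c("Class1", "Class3"), each = 4), rownames(m))
  got <- class_condition_test(m, labels, "Mn", "Class1", "Class3")
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(got$t, t_hand)
  expect_equal(got$df, 6)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 6))
  # identical groups give t = 0, p = 1
  same <- class_condition_test(
    matrix(c(a, a), ncol = 1, dimnames = list(sprintf("v%d", 1:8), "Mn")),
    labels, "Mn", "Class1", "Class3")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("gain-of-function class scores lower on Mn than loss-of-function", {
  pm <- planted_matrix(n_per = 25L, noise = 0.3, seed = 10L)
  got <- class_condition_test(pm$scores, pm$labels, "Mn", "Class3", "Class1")
  expect_lt(got$mean_a, got$mean_b)
  expect_lt(got$p, 0.01)
})

test_that("TSS bin deltas behave like differences of distributions", {
  wt <- c(0.05, 0.1, 0.2, 0.3, 0.25, 0.1)
  expect_equal(tss_fraction_change(wt, wt), rep(0, 6))
  up <- c(0.25, 0.25, 0.2, 0.15, 0.1, 0.05)
  d <- tss_fraction_change(up, wt)
  expect_equal(sum(d), 0)
  expect_true(all(d[1:2] > 0))
  expect_error(tss_fraction_change(wt[1:5], wt), "mismatch")
  expect_error(tss_fraction_change(wt * 2, wt), "summing to 1")
})

test_that("helical propensity regression recovers exact linear relations", {
  scale <- c(A = 0, S = 0.5, K = 0.26, V = 0.61, N = 0.65, G = 1.0,
             C = 0.68, D = 0.69, E = 0.4, F = 0.54, H = 0.61, I = 0.41,
             L = 0.21, M = 0.24, P = 3.16, Q = 0.39, R = 0.21, T = 0.66,
             W = 0.49, Y = 0.53)
  region_ids <- default_evs$programmed$variant_id[
    default_evs$programmed$residue %in% 1090:1096]
  p <- parse_variant_id(region_ids)
  x <- scale[p$mut_aa] - scale[p$wt_aa]
  scores <- setNames(2 * x, region_ids)
  fit <- helical_propensity_regression(scores, scale)
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$n, length(region_ids))

  # excluding V1094 drops exactly that residue's scored variants
  fit2 <- helical_propensity_regression(scores, scale, exclude = 1094)
  n_v1094 <- sum(p$residue == 1094)
  expect_equal(fit$n - fit2$n, n_v1094)

  # constant scores: no correlation to report, zero slope
  fit3 <- helical_propensity_regression(
    setNames(rep(1, length(region_ids)), region_ids), scale)
  expect_true(is.na(fit3$r))
  expect_equal(fit3$slope, 0)
})
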