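# Small hand-built count fixture: 1 condition x 2 replicates + pool.
fixture_counts <- function(v_pool = c(v1 = 1000L, v2 = 1000L),
                           v_sel = c(v1 = 2000L, v2 = 500L),
                           wt_pool = 8000L, wt_sel = 7500L,
                           condition = "condA") {
  rbind(
    data.frame(sample = "SC-Leu_rep1", condition = "SC-Leu", replicate = 1L,
               role = "unselected", variant_id = c(names(v_pool), "WT"),
               count = c(unname(v_pool), wt_pool)),
    data.frame(sample = paste0(condition, "_rep1"), condition = condition,
               replicate = 1L, role = "selected",
               variant_id = c(names(v_sel), "WT"),
               count = c(unname(v_sel), wt_sel)))
}

test_that("allele frequencies divide by per-sample mapped reads", {
  counts <- data.frame(sample = "s", variant_id = c("a", "b", "WT"),
                       count = c(50L, 150L, 800L))
  fr <- allele_frequencies(counts)
  expect_equal(fr$freq, c(0.05, 0.15, 0.8))
  fr10 <- allele_frequencies(transform(counts, count = count * 10L))
  expect_equal(fr10$freq, fr$freq)
  expect_error(allele_frequencies(data.frame(sample = "s", variant_id = "a",
                                             count = 0L)), "zero mapped")
})

test_that("phenotype score is the WT-normalized log2 frequency change", {
  expect_equal(phenotype_score(0.04, 0.01, 0.5, 0.5), 2)
  # mutant and wild type changing by the same factor score zero
  expect_equal(phenotype_score(0.02, 0.01, 0.9, 0.45), 0)
  # swapping selected and unselected negates the score
  s <- phenotype_score(0.03, 0.01, 0.4, 0.5)
  expect_equal(phenotype_score(0.01, 0.03, 0.5, 0.4), -s)
  expect_error(phenotype_score(0.1, 0, 0.5, 0.5), "pseudocount")
})

test_that("pool filter drops variants below 200 pool reads everywhere", {
  counts <- fixture_counts(v_pool = c(v1 = 199L, v2 = 200L),
                           v_sel = c(v1 = 5000L, v2 = 5000L))
  flt <- apply_filters(counts)
  expect_false(flt$keep[flt$variant_id == "v1"])
  expect_true(flt$keep[flt$variant_id == "v2"])
})

test_that("condition filter masks only when both samples are below 50 reads", {
  counts <- fixture_counts(v_pool = c(v1 = 300L, v2 = 300L, v3 = 230L),
                           v_sel = c(v1 = 40L, v2 = 60L, v3 = 10L))
  counts$count[counts$role == "unselected" & counts$variant_id == "v1"] <- 30L
  counts$count[counts$role == "unselected" & counts$variant_id == "v2"] <- 30L
  # v1: 40 selected, 30 unselected -> both below 50 -> masked (and pool fails)
  # v2: 60 selected, 30 unselected -> retained by the both-below rule
  # v3: 10 selected, 230 unselected -> retained
  flt <- apply_filters(counts, filter_config(min_pool_reads = 0L))
  expect_false(flt$cell_pass[flt$variant_id == "v1"])
  expect_true(flt$cell_pass[flt$variant_id == "v2"])
  expect_true(flt$cell_pass[flt$variant_id == "v3"])
  # stricter either-side rule also masks v2 and v3
  flt2 <- apply_filters(counts, filter_config(min_pool_reads = 0L,
                                              rule = "either"))
  expect_false(any(flt2$cell_pass[flt2$variant_id %in% c("v1", "v2", "v3")]))
})

test_that("raising thresholds never unmasks a cell", {
  counts <- fixture_counts(v_pool = c(v1 = 250L, v2 = 45L, v3 = 600L),
                           v_sel = c(v1 = 30L, v2 = 80L, v3 = 20L))
  f1 <- apply_filters(counts, filter_config(200L, 50L))
  f2 <- apply_filters(counts, filter_config(300L, 100L))
  expect_true(all(f1$keep | !f2$keep))
})

test_that("score_screen recovers a planted two-fold enrichment", {
  counts <- fixture_counts(v_pool = c(v1 = 1000L, v2 = 1000L),
                           v_sel = c(v1 = 2000L, v2 = 500L),
                           wt_pool = 8000L, wt_sel = 7500L)
  rs <- score_screen(counts, pseudocount = 0)
  s <- setNames(rs$score, rs$variant_id)
  f_tot_sel <- 10000; f_tot_un <- 10000
  expected_v1 <- log2((2000 / f_tot_sel) / (1000 / f_tot_un)) -
    log2((7500 / f_tot_sel) / (8000 / f_tot_un))
  expect_equal(unname(s["v1"]), expected_v1)
  expect_true(all(rs$keep))
})

test_that("scores are invariant to sequencing depth scaling", {
  counts <- fixture_counts()
  rs1 <- score_screen(counts)
  counts10 <- transform(counts, count = count * 10L)
  rs10 <- score_screen(counts10)
  expect_equal(rs10$score, rs1$score, tolerance = 0.005)
  # exact invariance without the pseudocount
  expect_equal(score_screen(counts10, pseudocount = 0)$score,
               score_screen(counts, pseudocount = 0)$score)
})

test_that("replicate aggregation takes the median of unmasked scores", {
  rs <- data.frame(
    variant_id = rep("v1", 3), condition = rep("condA", 3),
    replicate = 1:3, score = c(1, 2, 9), keep = TRUE)
  sm <- aggregate_replicates(rs)
  expect_equal(unname(sm$scores["v1", "condA"]), 2)
  rs$keep[3] <- FALSE
  sm2 <- aggregate_replicates(rs)
  expect_equal(unname(sm2$scores["v1", "condA"]), 1.5)
  # permuting replicate order changes nothing
  sm3 <- aggregate_replicates(rs[c(3, 1, 2), ])
  expect_equal(sm3$scores, sm2$scores)
  # all replicates masked -> absent
  rs$keep <- FALSE
  sm4 <- aggregate_replicates(rs)
  expect_equal(unname(sm4$mask["v1", "condA"]), "absent")
})

test_that("lethality threshold lands in the gap of separable calibrations", {
  scores <- c(setNames(seq(0.5, 2, length.out = 10), paste0("v", 1:10)),
              setNames(seq(-8, -5, length.out = 4), paste0("l", 1:4)))
  model <- calibrate_lethality(scores, paste0("v", 1:10), paste0("l", 1:4))
  expect_equal(model$balanced_error, 0)
  expect_equal(model$threshold, (-5 + 0.5) / 2)
})

test_that("threshold matches a brute-force grid scan on overlapping sets", {
  set.seed(101)
  v <- setNames(rnorm(163, 0, 1), paste0("v", 1:163))
  l <- setNames(rnorm(16, -4, 1.5), paste0("l", 1:16))
  scores <- c(v, l)
  model <- calibrate_lethality(scores, names(v), names(l))
  grid <- seq(min(scores) - 0.1, max(scores) + 0.1, length.out = 20001)
  err <- vapply(grid, function(t) (mean(v < t) + mean(l >= t)) / 2, 0)
  expect_equal((mean(v < model$threshold) + mean(l >= model$threshold)) / 2,
               min(err))
})

test_that("classification uses a strict below-threshold rule", {
  model <- structure(list(threshold = -2), class = "lethality_model")
  got <- classify_fitness(c(a = -2.5, b = -2, c = 0), model)
  expect_equal(unname(got), c("predicted_lethal", "viable", "viable"))
})

test_that("planted lethal variants are recalled from a simulated screen", {
  ids <- paste0("v", sprintf("%03d", 1:200))
  lethal <- paste0("v", sprintf("%03d", 1:20))
  eff <- matrix(0, 200, 1, dimnames = list(ids, "FOA"))
  set.seed(7)
  eff[lethal, 1] <- rnorm(20, -6, 0.3)
  eff[setdiff(ids, lethal), 1] <- rnorm(180, 0, 0.3)
  fr <- setNames(rep(0.9 / 200, 200), ids)
  sc <- simulated_screen(fr, eff, depth = 1e5, n_replicates = 3L, seed = 31L)
  sm <- aggregate_replicates(score_screen(simulate_selection(sc)))
  fit <- sm$scores[, "FOA"]
  # calibrate on a subset of known labels, then classify the rest
  known_v <- setdiff(ids, lethal)[1:163]
  known_l <- lethal[1:16]
  model <- calibrate_lethality(fit, known_v, known_l)
  calls <- classify_fitness(fit, model)
  recall <- mean(calls[lethal] == "predicted_lethal", na.rm = TRUE)
  expect_gte(recall, 0.95)
})
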