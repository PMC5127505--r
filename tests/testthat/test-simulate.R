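make_small_screen <- function(effects_list = NULL, depth = 1e5, n_rep = 1L,
                              seed = 11L) {
  fr <- c(v1 = 0.05, v2 = 0.10, v3 = 0.25)
  eff <- matrix(0, 3, 2, dimnames = list(names(fr), c("condA", "condB")))
  if (!is.null(effects_list))
    for (nm in names(effects_list)) eff[nm, ] <- effects_list[[nm]]
  simulated_screen(fr, eff, depth = depth, n_replicates = n_rep, seed = seed)
}

test_that("per-sample counts always sum to the configured depth", {
  sc <- make_small_screen(depth = 5000, n_rep = 2L)
  counts <- simulate_selection(sc)
  sums <- tapply(counts$count, counts$sample, sum)
  expect_true(all(sums == 5000))
  # samples: 2 pools + 2 conditions x 2 replicates
  expect_length(sums, 6L)
})

test_that("neutral effects leave selected frequencies at pool frequencies", {
  sc <- make_small_screen(depth = 2e6)
  counts <- simulate_selection(sc)
  sel <- counts[counts$condition == "condA", ]
  f <- setNames(sel$count / sum(sel$count), sel$variant_id)
  pool_f <- c(sc$pool_fractions, WT = 1 - sum(sc$pool_fractions))
  se <- sqrt(pool_f * (1 - pool_f) / 2e6)
  expect_true(all(abs(f[names(pool_f)] - pool_f) < 4 * se))
})

test_that("a +1 log2 effect doubles the frequency ratio to wild type", {
  sc <- make_small_screen(list(v1 = c(1, 1)), depth = 1e7)
  counts <- simulate_selection(sc)
  get <- function(cond, id) counts$count[counts$condition == cond &
                                           counts$variant_id == id]
  ratio_sel <- get("condA", "v1") / get("condA", "WT")
  ratio_pool <- get("SC-Leu", "v1") / get("SC-Leu", "WT")
  expect_equal(ratio_sel / ratio_pool, 2, tolerance = 0.02)
})

test_that("raising a true effect raises the expected selected frequency", {
  lows <- simulate_selection(make_small_screen(list(v2 = c(0.5, 0.5)),
                                               depth = 2e6))
  highs <- simulate_selection(make_small_screen(list(v2 = c(1.5, 1.5)),
                                                depth = 2e6))
  lo <- lows$count[lows$condition == "condA" & lows$variant_id == "v2"]
  hi <- highs$count[highs$condition == "condA" & highs$variant_id == "v2"]
  expect_gt(hi, lo)
})

test_that("selection is deterministic under a fixed seed", {
  c1 <- simulate_selection(make_small_screen(seed = 99L))
  c2 <- simulate_selection(make_small_screen(seed = 99L))
  expect_identical(c1, c2)
})

test_that("pool frequencies are recovered within binomial error at high depth", {
  fr <- make_library(default_ref, default_evs, "uniform", wt_fraction = 0.1)
  eff <- matrix(0, length(fr), 1, dimnames = list(names(fr), "c1"))
  sc <- simulated_screen(fr, eff, depth = 1e6, n_replicates = 1L, seed = 3L)
  counts <- simulate_selection(sc)
  pool <- counts[counts$role == "unselected", ]
  obs <- setNames(pool$count / 1e6, pool$variant_id)[names(fr)]
  se <- sqrt(fr * (1 - fr) / 1e6)
  ok <- abs(obs - fr) <= 3 * se
  expect_gte(mean(ok), 0.99)
})

test_that("class-structured effects carry the planted signatures", {
  cfg <- class_profile_config(seed = 5L)
  te <- simulate_true_effects(c("A1090C", "A1090D", "H1085Y", "E1103G"), cfg)
  # spike-in anchors keep their known classes
  expect_equal(unname(te$classes["H1085Y"]), "Class1")
  expect_equal(unname(te$classes["E1103G"]), "Class3")
  # gain-of-function signature: Spt- (positive) and MPA-sensitive (negative)
  expect_gt(te$effects["E1103G", "Spt"], 0)
  expect_lt(te$effects["E1103G", "MPA"], 0)
  # loss-of-function signature: formamide-sensitive
  expect_lt(te$effects["H1085Y", "Formamide"], 0)
})

test_that("config invariants are enforced", {
  expect_error(class_profile_config(class_proportions = c(Class1 = 0.5)),
               "sum to 1")
  expect_error(class_profile_config(noise_sd = -1), "noise_sd")
  expect_error(simulated_screen(c(v1 = 0.5, v2 = 0.6),
                                matrix(0, 2, 1, dimnames = list(c("v1", "v2"), "c")),
                                depth = 10),
               "sum to <= 1")
  expect_error(make_small_screen(depth = 0), "depth")
})
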