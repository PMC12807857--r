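# The asymmetric-inheritance statistic: integrated density, orientation,
# the (P1 - P2)/(P1 + P2) score, classification and reporting.

test_that("integrated density is a sum with the expected invariances", {
  g <- voxel_grid(array(2, c(4, 5, 5)), c(1, 1, 1), channel_names = "cargo")
  mask <- array(FALSE, c(4, 5, 5)); mask[1:2, 1:3, 1:3] <- TRUE
  expect_equal(integrated_density(g, mask, "cargo"), 2 * sum(mask))
  # additivity over disjoint masks
  a <- array(FALSE, c(4, 5, 5)); a[1, , ] <- TRUE
  b <- array(FALSE, c(4, 5, 5)); b[3, , ] <- TRUE
  gr <- voxel_grid(array(runif(100), c(4, 5, 5)), c(1, 1, 1),
                   channel_names = "cargo")
  expect_equal(integrated_density(gr, a | b, "cargo"),
               integrated_density(gr, a, "cargo") +
                 integrated_density(gr, b, "cargo"))
  # invariant under intensity permutation within the mask
  perm <- gr
  v <- perm$data[, , , 1][a]
  perm$data[, , , 1][a] <- sample(v)
  expect_equal(integrated_density(perm, a, "cargo"),
               integrated_density(gr, a, "cargo"))
  expect_warning(z <- integrated_density(g, mask & FALSE, "cargo"), "empty")
  expect_equal(z, 0)
  expect_error(integrated_density(g, mask[1:2, , , drop = FALSE], "cargo"),
               "geometry")
})

test_that("pair orientation follows the reference marker when present", {
  expect_equal(orient_pair(3, 7), c(P1 = 7, P2 = 3))
  # reference-high daughter has less cargo: the score goes negative
  p <- orient_pair(2, 8, ref_a = 100, ref_b = 10)
  expect_equal(p, c(P1 = 2, P2 = 8))
  expect_lt(asymmetry_score(p["P1"], p["P2"]), 0)
  # orientation is well defined: swapping the daughters changes nothing
  q <- orient_pair(8, 2, ref_a = 10, ref_b = 100)
  expect_equal(q, p)
  expect_message(tie <- orient_pair(2, 8, ref_a = 5, ref_b = 5), "tie")
  expect_equal(tie, c(P1 = 8, P2 = 2))
})

test_that("the score is the normalized difference of daughter densities", {
  expect_equal(asymmetry_score(1.5, 1.0), 0.2)
  expect_equal(asymmetry_score(3, 1), 0.5)
  for (c0 in c(0.1, 1, 37)) expect_equal(asymmetry_score(c0, c0), 0)
  expect_true(is.na(asymmetry_score(0, 0)))
  # antisymmetry and scale invariance
  expect_equal(asymmetry_score(2, 5), -asymmetry_score(5, 2))
  expect_equal(asymmetry_score(7 * 2, 7 * 5), asymmetry_score(2, 5))
  # threshold <-> ratio equivalence: s = 0.2 iff P1/P2 = 1.5
  s <- 0.2
  expect_equal((1 + s) / (1 - s), 1.5)
  expect_equal(asymmetry_score(1.5 * 11, 11), 0.2)
})

test_that("classification uses strict inequalities at the 0.2 boundary", {
  expect_equal(classify_pair(0.2), "symmetric")
  expect_equal(classify_pair(-0.2), "symmetric")
  expect_equal(classify_pair(0.2000001), "asymmetric")
  expect_equal(classify_pair(-0.3), "asymmetric")
  expect_equal(classify_pair(0), "symmetric")
  expect_equal(classify_pair(NA_real_), "degenerate")
  expect_equal(classify_pair(0.25, threshold = 0.3), "symmetric")
})

test_that("measure_pair and pair_report summarize groups correctly", {
  pr <- make_daughter_pair(0.75, total_cargo = 1e4, noise = FALSE, seed = 3)
  row <- measure_pair(pr$grid, pr$mask1, pr$mask2, "cargo", group = "wt")
  expect_equal(row$score, 0.5, tolerance = 1e-6)
  expect_equal(row$classification, "asymmetric")
  expect_error(measure_pair(pr$grid, pr$mask1, pr$mask1, "cargo"), "disjoint")

  pairs <- data.frame(
    group = rep(c("a", "b"), each = 4),
    score = c(0.5, 0.5, 0.0, 0.0, 0, 0, 0, NA),
    classification = c("asymmetric", "asymmetric", "symmetric", "symmetric",
                       "symmetric", "symmetric", "symmetric", "degenerate"))
  rep_ <- pair_report(pairs)
  expect_equal(rep_$fraction_asymmetric[rep_$group == "a"], 0.5)
  expect_equal(rep_$fraction_asymmetric[rep_$group == "b"], 0)
  expect_equal(rep_$n_degenerate[rep_$group == "b"], 1)
  # brute-force recomputation of the fractions agrees
  for (g in c("a", "b")) {
    d <- pairs[pairs$group == g & pairs$classification != "degenerate", ]
    expect_equal(rep_$fraction_asymmetric[rep_$group == g],
                 sum(d$classification == "asymmetric") / nrow(d))
  }
  allbad <- data.frame(group = "x", score = NA_real_,
                       classification = "degenerate")
  expect_error(pair_report(allbad), "degenerate")
})

test_that("scores are recovered within 0.05 on noisy synthetic pairs", {
  for (f in c(0.5, 0.6, 0.75)) {
    pr <- make_daughter_pair(f, total_cargo = 2e5, noise = TRUE, seed = 17)
    row <- measure_pair(pr$grid, pr$mask1, pr$mask2, "cargo")
    expect_lt(abs(row$score - abs(2 * f - 1)), 0.05)
  }
})
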