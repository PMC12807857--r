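# Proteomic-ruler copy numbers and the differential-inheritance filter.

test_that("a histone-only table self-calibrates to the DNA mass", {
  q <- data.frame(protein_id = c("H1", "H2"), is_histone = TRUE,
                  molar_mass = c(14000, 21000), s1 = c(3e6, 5e6))
  cfg <- ruler_config()
  cn <- copy_numbers(q, config = cfg)
  hist_mass <- sum(cn$copies[, "s1"] * q$molar_mass) / cfg$avogadro
  expect_equal(hist_mass, cn$m_dna_g, tolerance = 1e-9)
  expect_equal(sum(cn$mass_fraction[, "s1"]), 1, tolerance = 1e-12)
})

test_that("copy numbers follow the ruler formula and its invariances", {
  q <- data.frame(protein_id = c("H1", "P1", "P2"),
                  is_histone = c(TRUE, FALSE, FALSE),
                  molar_mass = c(15000, 20000, 40000),
                  s1 = c(1e6, 4e4, 4e4), s2 = c(2e6, 8e4, 6e4))
  cn <- copy_numbers(q)
  # equal intensity, molar-mass ratio 2:1 -> copy ratio 1:2
  expect_equal(cn$copies["P1", "s1"] / cn$copies["P2", "s1"], 2)
  # direct substitution into the formula
  m_dna <- 2.7e9 * 2 * 615.8771 / 6.02214076e23
  expect_equal(cn$copies["P1", "s1"],
               (4e4 / 1e6) * m_dna * 6.02214076e23 / 20000, tolerance = 1e-12)
  # global per-sample scaling leaves copies unchanged
  q2 <- q; q2$s1 <- q2$s1 * 123.4
  expect_equal(copy_numbers(q2)$copies, cn$copies, tolerance = 1e-12)
  # copies scale linearly with ploidy
  cn4 <- copy_numbers(q, config = ruler_config(ploidy = 4))
  expect_equal(cn4$copies, cn$copies * 2, tolerance = 1e-12)
})

test_that("samples without histone signal are flagged uncomputable", {
  q <- data.frame(protein_id = c("H1", "P1"), is_histone = c(TRUE, FALSE),
                  molar_mass = c(15000, 30000),
                  s1 = c(1e6, 5e4), s2 = c(0, 5e4))
  expect_warning(cn <- copy_numbers(q), "no histone signal")
  expect_equal(cn$uncomputable, "s2")
  expect_true(all(is.na(cn$copies[, "s2"])))
  expect_false(anyNA(cn$copies[, "s1"]))
})

test_that("identical groups are null and planted effects are detected", {
  m <- matrix(rep(c(100, 200, 400), each = 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"),
                              c("A1", "A2", "B1", "B2")))
  res <- differential_inheritance(m, c("A1", "A2"), c("B1", "B2"))
  expect_equal(res$fold_change, rep(1, 3))
  expect_equal(res$p_value, rep(1, 3))
  expect_false(any(res$significant))

  sim <- simulate_protein_table(n_proteins = 120, n_effect = 10,
                                effect_fold = 2, sd_log2 = 0.1,
                                n_per_group = 4, seed = 5)
  cn <- copy_numbers(sim$quant)
  res2 <- differential_inheritance(cn, sim$group_a, sim$group_b)
  hits <- res2$protein_id[res2$significant]
  expect_true(all(sim$truth$protein_id %in% hits))
  expect_lte(sum(!(hits %in% sim$truth$protein_id)), 2)
  # permutation oracle on one planted protein: group labels matter
  p0 <- sim$truth$protein_id[1]
  vals <- log2(cn$copies[p0, c(sim$group_a, sim$group_b)])
  obs <- abs(mean(vals[1:4]) - mean(vals[5:8]))
  combos <- utils::combn(8, 4)
  perm <- apply(combos, 2, function(i) abs(mean(vals[i]) - mean(vals[-i])))
  expect_lte(mean(perm >= obs - 1e-12), 0.05)
})

test_that("the significance gate needs both the p-value and the fold change", {
  set.seed(9)
  base <- 2^rnorm(4, 10, 0.01)
  m <- rbind(strong_p_small_fc = c(base * 1.4, base),
             strong_both = c(base * 4, base),
             big_fc_no_p = c(2^(10 + c(3, -3, 2, -2)), 2^(10 + c(1, -1, 2, -2))))
  colnames(m) <- c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4")
  res <- differential_inheritance(m, paste0("A", 1:4), paste0("B", 1:4))
  r <- function(id) res[res$protein_id == id, ]
  expect_lt(r("strong_p_small_fc")$p_value, 0.05)
  expect_false(r("strong_p_small_fc")$significant)  # FC gate fails at 1.4
  expect_true(r("strong_both")$significant)
  expect_false(r("big_fc_no_p")$significant)
  # brute-force reapplication of the two gates
  expect_equal(res$significant,
               res$p_value < 0.05 &
                 (res$fold_change > 1.5 | res$fold_change < 1 / 1.5))
})

test_that("swapping the groups inverts fold changes, preserving significance", {
  sim <- simulate_protein_table(n_proteins = 60, n_effect = 6, seed = 13)
  cn <- copy_numbers(sim$quant)
  ab <- differential_inheritance(cn, sim$group_a, sim$group_b)
  ba <- differential_inheritance(cn, sim$group_b, sim$group_a)
  expect_equal(ba$fold_change, 1 / ab$fold_change, tolerance = 1e-12)
  expect_equal(ba$p_value, ab$p_value, tolerance = 1e-12)
  expect_equal(ba$significant, ab$significant)
})

test_that("zeros are excluded and sparse proteins are not testable", {
  m <- matrix(c(0, 8, 9, 8.5, 8, 9, 8.5, 9,
                0, 0, 0, 4, 5, 6, 4, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("pz", "sparse"),
                              c(paste0("A", 1:4), paste0("B", 1:4))))
  res <- differential_inheritance(m, paste0("A", 1:4), paste0("B", 1:4))
  expect_equal(res[res$protein_id == "pz", "n_a"], 3)  # one zero dropped
  expect_true(res[res$protein_id == "pz", "testable"])
  expect_equal(res[res$protein_id == "sparse", "n_a"], 1)
  expect_false(res[res$protein_id == "sparse", "testable"])
  expect_false(res[res$protein_id == "sparse", "significant"])
})
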