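# Cross-criterion congruence and the neighbourhood effect.

test_that("label harmonization undoes arbitrary group naming", {
  tab <- data.frame(
    id = paste0("t", 1:6),
    ref = c("S1", "S1", "S2", "S2", "intermediate", "S1"),
    other = c("B", "B", "A", "A", "intermediate", "B"),
    stringsAsFactors = FALSE)
  h <- harmonize_labels(tab, reference = "ref")
  expect_equal(h$other, c("S1", "S1", "S2", "S2", "intermediate", "S1"))
  # identical tables stay identical
  tab2 <- data.frame(id = tab$id, a = tab$ref, b = tab$ref)
  expect_equal(harmonize_labels(tab2), tab2)
  # a criterion without two pure labels cannot be mapped
  tab3 <- data.frame(id = c("x", "y"), a = c("S1", "S2"),
                     b = c("intermediate", "intermediate"))
  expect_error(harmonize_labels(tab3), "pure labels")
  # two pure labels but no individual pure under both criteria
  tab4 <- data.frame(id = paste0("t", 1:4),
                     a = c("S1", "S2", "intermediate", "intermediate"),
                     b = c("intermediate", "intermediate", "X", "Y"))
  expect_error(harmonize_labels(tab4), "degenerate")
})

test_that("optimal 2x2 pairing always reaches at least half agreement", {
  set.seed(31)
  for (i in 1:10) {
    tab <- data.frame(
      id = paste0("t", 1:200),
      ref = sample(c("S1", "S2"), 200, replace = TRUE),
      other = sample(c("x", "y"), 200, replace = TRUE),
      stringsAsFactors = FALSE)
    h <- harmonize_labels(tab, reference = "ref")
    expect_gte(mean(h$other == h$ref), 0.5)
  }
})

test_that("congruence summary partitions individuals correctly", {
  tab <- data.frame(
    id = paste0("t", 1:6),
    c1 = c("S1", "S1", "S1", "S2", "S1", NA),
    c2 = c("S1", "S2", "intermediate", "S2", "S1", "S1"),
    c3 = c("S1", "S1", "S1", "S2", "intermediate", "S1"),
    stringsAsFactors = FALSE)
  rep <- congruence_summary(tab)
  expect_equal(rep$n_consistent, 2)               # t1, t4
  expect_equal(rep$n_inversions, 1)               # t2 (S1 vs S2 pure conflict)
  expect_equal(rep$n_intermediate_discrepancies, 2)  # t3, t5
  expect_equal(rep$n_missing, 1)                  # t6
  expect_equal(rep$n_consistent + rep$n_inversions +
                 rep$n_intermediate_discrepancies + rep$n_missing, 6)
  expect_equal(rep$frac_discrepancies_from_intermediates, 2 / 3)
  expect_equal(unname(rep$consistent_by_species[c("S1", "S2")]), c(1, 1))
  # all-identical table: fully consistent, no inversions
  tab2 <- data.frame(id = c("a", "b"), c1 = c("S1", "S2"),
                     c2 = c("S1", "S2"))
  rep2 <- congruence_summary(tab2)
  expect_equal(rep2$n_consistent, 2)
  expect_equal(rep2$n_inversions, 0)
})

test_that("allospecific fraction counts neighbours within the radius", {
  coords <- data.frame(id = c("f", "a10", "c50", "a100"),
                       x = c(0, 10, 50, 100), y = 0)
  labels <- c(f = "S1", a10 = "S2", c50 = "S1", a100 = "S2")
  fr <- allospecific_fraction(coords, labels, radius = 69)
  expect_equal(unname(fr["f"]), 0.5)  # allo at 10, con at 50; 100 m outside
  # isolated focal is undefined
  coords2 <- rbind(coords, data.frame(id = "far", x = 1e6, y = 0))
  fr2 <- allospecific_fraction(coords2, c(labels, far = "S1"), radius = 69)
  expect_true(is.na(fr2["far"]))
  # intermediates excluded as neighbours and as focals
  labs3 <- c(f = "S1", a10 = "intermediate", c50 = "S1", a100 = "S2")
  fr3 <- allospecific_fraction(coords, labs3, radius = 69)
  expect_equal(unname(fr3["f"]), 0)
  expect_false("a10" %in% names(fr3))
  expect_error(allospecific_fraction(coords, labels, radius = -1), "radius")
})

test_that("allospecific fraction is invariant to relabelling the species", {
  set.seed(33)
  coords <- data.frame(id = paste0("t", 1:100),
                       x = runif(100, 0, 200), y = runif(100, 0, 200))
  lab <- setNames(sample(c("S1", "S2"), 100, replace = TRUE), coords$id)
  swap <- c(S1 = "S2", S2 = "S1")
  f1 <- allospecific_fraction(coords, lab, 60)
  f2 <- allospecific_fraction(coords, setNames(swap[lab], names(lab)), 60)
  expect_equal(f1, f2)
})

test_that("a uniformly mixed 50:50 stand has mean fraction near one half", {
  set.seed(34)
  coords <- data.frame(id = paste0("t", 1:300),
                       x = runif(300, 0, 100), y = runif(300, 0, 100))
  lab <- setNames(rep(c("S1", "S2"), 150), coords$id)
  fr <- allospecific_fraction(coords, lab, radius = 500)
  expect_lt(abs(mean(fr, na.rm = TRUE) - 0.5), 0.02)
})

test_that("logistic congruence test handles constant and separated inputs", {
  r0 <- congruence_glm(c(0, 1, 0, 1), c(0.3, 0.3, 0.3, 0.3))
  expect_equal(r0$chisq, 0)
  expect_equal(r0$p_value, 1)
  expect_error(congruence_glm(c(1, 1, 1), c(0.1, 0.2, 0.3)), "both outcome")
  sep <- congruence_glm(c(rep(0, 10), rep(1, 10)),
                        c(runif(10, 0, 0.2), runif(10, 0.8, 1)))
  expect_true(sep$unreliable)
  expect_equal(sep$df, 1L)
})

test_that("the likelihood-ratio test is calibrated under the null", {
  set.seed(35)
  n_rep <- 500
  stats <- replicate(n_rep, {
    x <- runif(200)
    y <- rbinom(200, 1, 0.5)
    t <- congruence_glm(y, x)
    c(t$chisq, t$p_value)
  })
  expect_lt(abs(mean(stats[1, ]) - 1), 0.2)          # E[chi2_1] = 1
  rate <- mean(stats[2, ] < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
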