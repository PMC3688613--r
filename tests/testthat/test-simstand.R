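# Synthetic stand generator: geometry, genotypes, mating, reference labels.

test_that("stand generation respects counts, extent and frequency invariants", {
  st <- generate_stand(n_A = 40, n_B = 25, n_loci = 6, alleles_per_locus = 8,
                       extent = c(100, 80), seed = 3)
  ind <- st$individuals
  expect_equal(nrow(ind), 65)
  expect_equal(sum(ind$species == "A"), 40)
  expect_false(any(duplicated(ind$id)))
  expect_true(all(ind$x >= 0 & ind$x <= 100))
  expect_true(all(ind$y >= 0 & ind$y <= 80))
  for (sp in c("A", "B", "pooled"))
    expect_true(all(abs(rowSums(st$allele_freqs[[sp]]) - 1) < 1e-9))
  expect_equal(dim(st$genotypes), c(65, 12))
})

test_that("single-species and zero-differentiation edge cases", {
  st <- generate_stand(n_A = 0, n_B = 50, seed = 1)
  expect_true(all(st$individuals$species == "B"))
  st0 <- generate_stand(n_A = 20, n_B = 20, differentiation = 0, seed = 2)
  expect_equal(st0$allele_freqs$A, st0$allele_freqs$B)
})

test_that("generator rejects malformed arguments", {
  expect_error(generate_stand(n_A = 1, n_B = 0), "at least 2")
  expect_error(generate_stand(extent = c(-5, 10)), "extent")
  expect_error(generate_stand(differentiation = 1.2), "differentiation")
  expect_error(simulate_mating(small_stand(), n_mothers = 5,
                               dispersal_scale = 0),
               "dispersal_scale")
  expect_error(simulate_mating(small_stand(), n_mothers = 1000), "n_mothers")
})

test_that("hybrid-index separation between species grows with differentiation", {
  sep <- vapply(c(0.1, 0.9), function(d) {
    gaps <- vapply(1:20, function(s) {
      st <- generate_stand(n_A = 100, n_B = 100, differentiation = d,
                           seed = 1000 + s)
      h <- hybrid_index(st$genotypes, st$allele_freqs$A, st$allele_freqs$B)
      mean(h[st$individuals$species == "A"]) -
        mean(h[st$individuals$species == "B"])
    }, numeric(1))
    mean(gaps)
  }, numeric(1))
  expect_gt(sep[2], sep[1])
  expect_gt(sep[2], 0.5)
})

test_that("mendelian offspring draws one allele from each parent", {
  off <- mendelian_offspring(c(1L, 1L), c(2L, 2L), seed = 1)
  expect_setequal(off, c(1L, 2L))
  # heterozygote x heterozygote: homozygote (1,1) frequency ~ 1/4
  set.seed(9)
  n11 <- sum(replicate(4000, {
    o <- mendelian_offspring(c(1L, 2L), c(1L, 2L))
    all(o == 1L)
  }))
  expect_lt(abs(n11 / 4000 - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  # error rate 1: alleles follow the locus frequency vector
  f <- matrix(c(1, 0, 0), 1, 3)
  o <- mendelian_offspring(c(2L, 2L), c(3L, 3L), error_rate = 1, freqs = f,
                           seed = 2)
  expect_true(all(o == 1L))
})

test_that("mendelian consistency holds for every offspring at error 0", {
  st <- small_stand(seed = 4)
  pr <- simulate_mating(st, n_mothers = 8, offspring_per_mother = 12,
                        immigration = 0, seed = 5)
  ped <- pr$pedigree
  for (i in seq_len(nrow(ped))) {
    o <- pr$genotypes[ped$offspring_id[i], ]
    m <- st$genotypes[ped$mother_id[i], ]
    f <- st$genotypes[ped$true_father_id[i], ]
    for (l in seq_len(st$n_loci)) {
      cols <- c(2 * l - 1, 2 * l)
      expect_true(o[cols[1]] %in% m[cols])
      expect_true(o[cols[2]] %in% f[cols])
    }
  }
})

test_that("mating respects compatibility and immigration limits", {
  st <- small_stand(seed = 6)
  sp <- setNames(st$individuals$species, st$individuals$id)
  pr0 <- simulate_mating(st, n_mothers = 10, offspring_per_mother = 10,
                         compatibility = 0, immigration = 0, seed = 7)
  internal <- pr0$pedigree$true_father_id != "EXTERNAL"
  expect_true(all(internal))
  expect_true(all(sp[pr0$pedigree$mother_id] ==
                    sp[pr0$pedigree$true_father_id]))
  expect_false(any(pr0$pedigree$mother_id == pr0$pedigree$true_father_id))
  pr1 <- simulate_mating(st, n_mothers = 5, offspring_per_mother = 10,
                         immigration = 1, seed = 8)
  expect_true(all(pr1$pedigree$true_father_id == "EXTERNAL"))
})

test_that("with a flat kernel and one species the father draw is uniform", {
  st <- generate_stand(n_A = 25, n_B = 0, seed = 9)
  pr <- simulate_mating(st, n_mothers = 1, offspring_per_mother = 5000,
                        dispersal_scale = 1e9, compatibility = 1,
                        immigration = 0, seed = 10)
  counts <- table(pr$pedigree$true_father_id)
  expect_equal(length(counts), 24)  # every adult except the mother
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("realized interspecific mating fraction is monotone in compatibility", {
  st <- generate_stand(n_A = 60, n_B = 60, seed = 11)
  sp <- setNames(st$individuals$species, st$individuals$id)
  hyb <- vapply(c(0, 0.1, 0.5, 1), function(cmp) {
    pr <- simulate_mating(st, n_mothers = 20, offspring_per_mother = 30,
                          compatibility = cmp, immigration = 0, seed = 12)
    mean(sp[pr$pedigree$mother_id] != sp[pr$pedigree$true_father_id])
  }, numeric(1))
  expect_true(all(diff(hyb) >= 0))
  expect_equal(hyb[1], 0)
})

test_that("mothers with more allospecific neighbours sire more hybrids", {
  pos <- 0L
  for (s in 1:10) {
    st <- generate_stand(n_A = 90, n_B = 60, seed = 300 + s)
    sp <- setNames(st$individuals$species, st$individuals$id)
    pr <- simulate_mating(st, n_mothers = 40, offspring_per_mother = 30,
                          compatibility = 0.2, immigration = 0,
                          seed = 400 + s)
    frac <- allospecific_fraction(st$individuals,
                                  setNames(ifelse(sp == "A", "S1", "S2"),
                                           names(sp)),
                                  radius = 69)
    ped <- pr$pedigree
    hyb_by_mother <- tapply(sp[ped$mother_id] != sp[ped$true_father_id],
                            ped$mother_id, mean)
    rho <- stats::cor(hyb_by_mother,
                      frac[names(hyb_by_mother)],
                      method = "spearman", use = "complete.obs")
    if (!is.na(rho) && rho > 0) pos <- pos + 1L
  }
  expect_gte(pos, 9L)
})

test_that("identical seeds reproduce stands and progeny exactly", {
  st1 <- generate_stand(n_A = 15, n_B = 15, seed = 42)
  st2 <- generate_stand(n_A = 15, n_B = 15, seed = 42)
  expect_identical(st1, st2)
  pr1 <- simulate_mating(st1, n_mothers = 5, offspring_per_mother = 8,
                         seed = 43)
  pr2 <- simulate_mating(st2, n_mothers = 5, offspring_per_mother = 8,
                         seed = 43)
  expect_identical(pr1, pr2)
})

test_that("reference assignments behave at the noise-free and all-A limits", {
  st <- small_stand(seed = 13)
  a0 <- synthetic_reference_assignments(st, trait_noise = 0, seed = 14)
  expect_false(any(a0$morphology == "intermediate"))
  expect_equal(a0$morphology,
               ifelse(st$individuals$species == "A", "S1", "S2"))
  stA <- generate_stand(n_A = 30, n_B = 0, differentiation = 0.9, seed = 15)
  aA <- synthetic_reference_assignments(stA, seed = 16)
  expect_true(all(aA$genotype == "S1"))
  expect_error(synthetic_reference_assignments(st,
                                               hybrid_thresholds = c(0.9, 0.1)))
})

test_that("F1 hybrids land in the intermediate band of the hybrid index", {
  st <- generate_stand(n_A = 60, n_B = 60, differentiation = 0.9, seed = 17)
  sp <- st$individuals$species
  A_ids <- which(sp == "A")
  B_ids <- which(sp == "B")
  set.seed(18)
  f1 <- t(vapply(1:200, function(i)
    mendelian_offspring(st$genotypes[sample(A_ids, 1), ],
                        st$genotypes[sample(B_ids, 1), ]),
    integer(ncol(st$genotypes))))
  h <- hybrid_index(f1, st$allele_freqs$A, st$allele_freqs$B)
  expect_gte(mean(h > 0.1 & h < 0.9), 0.95)
})
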