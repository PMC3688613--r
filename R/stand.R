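#' Generate a synthetic two-species forest stand
#'
#' Creates a mapped stand of adult trees belonging to two sympatric species,
#' with spatial positions uniform over a rectangle and unlinked multilocus
#' codominant (SSR-like) genotypes. Per-locus allele frequencies for the two
#' species are built from a shared Dirichlet draw that is mixed towards
#' opposite allele-rank orderings, so expected between-species differentiation
#' increases monotonically with `differentiation` (0 = identical frequencies,
#' 1 = fully rank-reversed).
#'
#' The defaults emulate a 5 ha mixed oak stand of 298 adults at unequal
#' species abundance, genotyped at 12 loci.
#'
#' @param n_A,n_B number of adults of species A and B (`n_A + n_B >= 2`).
#' @param n_loci number of unlinked loci.
#' @param alleles_per_locus number of alleles segregating at each locus.
#' @param differentiation between-species differentiation knob in `[0, 1]`.
#' @param extent rectangle `(width, height)` in metres.
#' @param segregation spatial segregation of the species in `[0, 1)`:
#'   species labels follow a noisy west-east gradient (0 = labels spatially
#'   random, values near 1 = sharply segregated patches). Mixed oak stands
#'   show strong small-scale segregation, which is what makes allospecific
#'   neighbourhoods vary between trees; positions themselves stay uniform.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `"stand"`: a list with elements
#'   `individuals` (data frame `id, x, y, species`), `genotypes` (integer
#'   matrix, two columns per locus, rownames = ids), `allele_freqs` (list of
#'   per-species locus-by-allele frequency matrices plus the abundance-pooled
#'   `pooled` matrix), `extent`, `n_loci`, `alleles_per_locus`.
#' @examples
#' st <- generate_stand(n_A = 30, n_B = 20, seed = 1)
#' st
#' @export
generate_stand <- function(n_A = 178, n_B = 120, n_loci = 12,
                           alleles_per_locus = 10, differentiation = 0.8,
                           extent = c(250, 200), segregation = 0.8,
                           seed = NULL) {
  stopifnot(n_A >= 0, n_B >= 0, n_loci >= 1, alleles_per_locus >= 2)
  if (n_A + n_B < 2) stop("need at least 2 adults")
  if (any(extent <= 0)) stop("extent must be positive")
  if (differentiation < 0 || differentiation > 1)
    stop("differentiation must be in [0, 1]")
  if (segregation < 0 || segregation >= 1)
    stop("segregation must be in [0, 1)")
  with_seed_(seed, {
    n <- n_A + n_B
    k <- alleles_per_locus
    ids <- sprintf("t%03d", seq_len(n))
    x <- stats::runif(n, 0, extent[1])
    y <- stats::runif(n, 0, extent[2])
    # species labels along a noisy spatial gradient: the n_A lowest scores
    # become species A, so counts are exact and segregation only reshuffles
    # who is where
    score <- x / extent[1] +
      stats::rnorm(n, 0, (1 - segregation) / max(segregation, 1e-9))
    species <- rep("B", n)
    species[order(score)[seq_len(n_A)]] <- "A"
    ind <- data.frame(
      id = ids, x = x, y = y, species = species,
      stringsAsFactors = FALSE
    )
    # per-locus frequencies: shared base, species pulled to opposite rank orders
    fA <- matrix(0, n_loci, k)
    fB <- matrix(0, n_loci, k)
    for (l in seq_len(n_loci)) {
      base <- as.numeric(rdirichlet_(1L, rep(1, k)))
      s <- sort(base, decreasing = TRUE)
      fA[l, ] <- (1 - differentiation) * base + differentiation * s
      fB[l, ] <- (1 - differentiation) * base + differentiation * rev(s)
    }
    pooled <- (n_A * fA + n_B * fB) / n
    geno <- matrix(NA_integer_, n, 2L * n_loci)
    rownames(geno) <- ids
    colnames(geno) <- paste0(rep(sprintf("L%02d", seq_len(n_loci)), each = 2),
                             c(".1", ".2"))
    for (l in seq_len(n_loci)) {
      cols <- c(2L * l - 1L, 2L * l)
      if (n_A > 0)
        geno[species == "A", cols] <-
          sample.int(k, 2L * n_A, replace = TRUE, prob = fA[l, ])
      if (n_B > 0)
        geno[species == "B", cols] <-
          sample.int(k, 2L * n_B, replace = TRUE, prob = fB[l, ])
    }
    structure(list(
      individuals = ind, genotypes = geno,
      allele_freqs = list(A = fA, B = fB, pooled = pooled),
      extent = extent, n_loci = n_loci, alleles_per_locus = k
    ), class = "stand")
  })
}

#' @export
print.stand <- function(x, ...) {
  tab <- table(x$individuals$species)
  cat(sprintf("Synthetic stand: %d adults (%s) on %g x %g m\n",
              nrow(x$individuals),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$extent[1], x$extent[2]))
  cat(sprintf("%d loci, %d alleles each\n", x$n_loci, x$alleles_per_locus))
  invisible(x)
}

#' Draw a Mendelian offspring genotype
#'
#' One allele sampled uniformly from each parent at every locus; each
#' transmitted allele is independently replaced, with probability
#' `error_rate`, by a random allele drawn from the locus frequency vector
#' (mimicking genotyping error / mutation).
#'
#' @param mother,father integer genotype vectors (two entries per locus, the
#'   layout of `stand$genotypes` rows).
#' @param error_rate per-allele replacement probability in `[0, 1]`.
#' @param freqs locus-by-allele frequency matrix used for error replacement
#'   draws; required when `error_rate > 0`.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return integer genotype vector of the same layout.
#' @export
mendelian_offspring <- function(mother, father, error_rate = 0, freqs = NULL,
                                seed = NULL) {
  stopifnot(length(mother) == length(father), length(mother) %% 2 == 0)
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (error_rate > 0 && is.null(freqs))
    stop("freqs required when error_rate > 0")
  with_seed_(seed, {
    n_loci <- length(mother) / 2L
    off <- integer(2L * n_loci)
    m1 <- 2L * seq_len(n_loci) - 1L
    pick_m <- m1 + (stats::runif(n_loci) < 0.5)
    pick_f <- m1 + (stats::runif(n_loci) < 0.5)
    off[m1] <- mother[pick_m]
    off[m1 + 1L] <- father[pick_f]
    if (error_rate > 0) {
      err <- which(stats::runif(2L * n_loci) < error_rate)
      for (j in err) {
        l <- ceiling(j / 2)
        off[j] <- sample.int(ncol(freqs), 1L, prob = freqs[l, ])
      }
    }
    off
  })
}

#' Simulate open-pollinated mating and progeny in a stand
#'
#' Samples `n_mothers` mother trees without replacement and, for each
#' offspring, draws a father. With probability `immigration` the father is
#' external to the stand (token `"EXTERNAL"`; the paternal gamete is drawn
#' from species-level allele frequencies, the donor species weighted by stand
#' abundance times compatibility with the mother). Otherwise father `j` is
#' drawn among the other adults with weight
#' `exp(-d_ij / dispersal_scale) * (1 if conspecific else compatibility)`.
#' Selfing is excluded. Offspring genotypes follow [mendelian_offspring()].
#'
#' @param stand a [generate_stand()] object.
#' @param n_mothers number of mother trees sampled (`<=` number of adults).
#' @param offspring_per_mother progeny array size per mother.
#' @param dispersal_scale exponential pollen-dispersal scale in metres.
#' @param compatibility relative weight of allospecific fathers in `[0, 1]`
#'   (0 = complete reproductive isolation, 1 = no barrier).
#' @param immigration probability that an offspring's father is outside the
#'   stand.
#' @param error_rate per-allele genotyping error passed to
#'   [mendelian_offspring()].
#' @param seed integer seed.
#' @return An object of class `"progeny"`: list with `pedigree` (data frame
#'   `offspring_id, mother_id, true_father_id`), `genotypes` (integer matrix
#'   over offspring), and `mothers` (sampled mother ids).
#' @examples
#' st <- generate_stand(n_A = 30, n_B = 20, seed = 1)
#' pr <- simulate_mating(st, n_mothers = 10, offspring_per_mother = 20, seed = 2)
#' head(pr$pedigree)
#' @export
simulate_mating <- function(stand, n_mothers = 51, offspring_per_mother = 60,
                            dispersal_scale = 69, compatibility = 0.2,
                            immigration = 0.45, error_rate = 0, seed = NULL) {
  stopifnot(inherits(stand, "stand"))
  ind <- stand$individuals
  n <- nrow(ind)
  if (n_mothers > n) stop("n_mothers exceeds number of adults")
  for (r in c(compatibility, immigration, error_rate))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  if (dispersal_scale <= 0) stop("dispersal_scale must be positive")
  with_seed_(seed, {
    mothers <- sort(sample.int(n, n_mothers))
    D <- as.matrix(stats::dist(cbind(ind$x, ind$y)))
    same_sp <- outer(ind$species, ind$species, "==")
    n_off <- n_mothers * offspring_per_mother
    off_id <- sprintf("o%05d", seq_len(n_off))
    mo_id <- character(n_off)
    fa_id <- character(n_off)
    geno <- matrix(NA_integer_, n_off, 2L * stand$n_loci,
                   dimnames = list(off_id, colnames(stand$genotypes)))
    abund <- table(factor(ind$species, levels = c("A", "B")))
    row_i <- 0L
    for (m in mothers) {
      w <- exp(-D[m, ] / dispersal_scale) *
        ifelse(same_sp[m, ], 1, compatibility)
      w[m] <- 0  # no selfing
      if (immigration < 1 && sum(w) <= 0)
        stop("degenerate parameters: no eligible father for mother ",
             ind$id[m])
      # external pollen donor species: abundance x compatibility with mother
      sp_w <- as.numeric(abund) *
        ifelse(c("A", "B") == ind$species[m], 1, compatibility)
      if (sum(sp_w) <= 0) sp_w <- as.numeric(abund)
      for (o in seq_len(offspring_per_mother)) {
        row_i <- row_i + 1L
        mo_id[row_i] <- ind$id[m]
        if (stats::runif(1) < immigration) {
          fa_id[row_i] <- "EXTERNAL"
          sp <- sample(c("A", "B"), 1L, prob = sp_w)
          fg <- external_gamete_(stand, sp)
          # encode the fixed paternal gamete as a homozygous pseudo-father
          fat <- rep(fg, each = 2L)
          geno[row_i, ] <- mendelian_offspring(
            stand$genotypes[m, ], fat, error_rate,
            freqs = stand$allele_freqs$pooled)
        } else {
          f <- sample.int(n, 1L, prob = w)
          fa_id[row_i] <- ind$id[f]
          geno[row_i, ] <- mendelian_offspring(
            stand$genotypes[m, ], stand$genotypes[f, ], error_rate,
            freqs = stand$allele_freqs$pooled)
        }
      }
    }
    structure(list(
      pedigree = data.frame(offspring_id = off_id, mother_id = mo_id,
                            true_father_id = fa_id, stringsAsFactors = FALSE),
      genotypes = geno,
      mothers = ind$id[mothers]
    ), class = "progeny")
  })
}

# one paternal gamete (allele per locus) from a species' frequency matrix
external_gamete_ <- function(stand, species) {
  f <- stand$allele_freqs[[species]]
  vapply(seq_len(stand$n_loci),
         function(l) sample.int(ncol(f), 1L, prob = f[l, ]), integer(1))
}

#' @export
print.progeny <- function(x, ...) {
  cat(sprintf("Progeny set: %d offspring from %d mothers (%d external-father)\n",
              nrow(x$pedigree), length(x$mothers),
              sum(x$pedigree$true_father_id == "EXTERNAL")))
  invisible(x)
}

#' Likelihood-weighted hybrid index
#'
#' For every individual, the fraction of its alleles that are more likely
#' under species A's frequencies than species B's, each allele weighted by
#' `|log(p_A / p_B)|` (frequencies floored at 1e-4). 1 = pure A signal,
#' 0 = pure B, 0.5 = balanced (an F1, or no information — when the total
#' weight is ~0 the index is defined as 0.5).
#'
#' @param genotypes integer genotype matrix (two columns per locus).
#' @param freq_A,freq_B locus-by-allele frequency matrices.
#' @return numeric vector of indices in `[0, 1]`, named by rownames.
#' @export
hybrid_index <- function(genotypes, freq_A, freq_B) {
  n_loci <- ncol(genotypes) / 2L
  fl <- function(f) pmax(f, 1e-4)
  h <- numeric(nrow(genotypes))
  for (i in seq_len(nrow(genotypes))) {
    wsum <- 0; asum <- 0
    for (l in seq_len(n_loci)) {
      for (a in genotypes[i, c(2L * l - 1L, 2L * l)]) {
        if (is.na(a)) next
        pa <- fl(freq_A[l, a]); pb <- fl(freq_B[l, a])
        w <- abs(log(pa) - log(pb))
        wsum <- wsum + w
        if (pa > pb) asum <- asum + w
      }
    }
    h[i] <- if (wsum < 1e-8) 0.5 else asum / wsum
  }
  names(h) <- rownames(genotypes)
  h
}

#' Reference species assignments for a synthetic stand
#'
#' Stand-in for external genotype- and morphology-based assignments on real
#' data. Morphology-like labels come from a 1-D trait (species mean 0 for A,
#' 1 for B) plus Gaussian noise, cut at 1/3 and 2/3; genotype-like labels
#' threshold the likelihood-weighted [hybrid_index()] at
#' `hybrid_thresholds = (low, high)`: index `> high` gives S1, `< low` gives
#' S2, the middle band is intermediate.
#'
#' @param stand a [generate_stand()] object.
#' @param trait_noise standard deviation of the morphology trait noise.
#' @param hybrid_thresholds numeric `(low, high)`, `0 <= low < high <= 1`.
#' @param seed integer seed.
#' @return data frame `id, genotype, morphology` with labels in
#'   `{"S1", "S2", "intermediate"}`.
#' @export
synthetic_reference_assignments <- function(stand, trait_noise = 0.15,
                                            hybrid_thresholds = c(0.2, 0.8),
                                            seed = NULL) {
  lo <- hybrid_thresholds[1]; hi <- hybrid_thresholds[2]
  if (!(lo >= 0 && lo < hi && hi <= 1))
    stop("need 0 <= low < high <= 1")
  with_seed_(seed, {
    ind <- stand$individuals
    trait <- ifelse(ind$species == "A", 0, 1) +
      stats::rnorm(nrow(ind), 0, trait_noise)
    morph <- ifelse(trait < 1 / 3, "S1",
                    ifelse(trait > 2 / 3, "S2", "intermediate"))
    if (length(unique(ind$species)) == 1L) {
      # monomorphic stand: a genotype classifier has no second cluster to
      # separate, everyone gets the single species' label
      geno <- rep(if (ind$species[1] == "A") "S1" else "S2", nrow(ind))
    } else {
      h <- hybrid_index(stand$genotypes, stand$allele_freqs$A,
                        stand$allele_freqs$B)
      geno <- ifelse(h > hi, "S1", ifelse(h < lo, "S2", "intermediate"))
    }
    data.frame(id = ind$id, genotype = unname(geno), morphology = morph,
               stringsAsFactors = FALSE)
  })
}
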