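# End-to-end synthetic pipeline: stand -> progeny -> paternity -> mating
# network -> C-SBM -> classification -> relatedness network -> congruence.

#' Known-unrelated, half-sib and full-sib offspring pairs from a pedigree
#'
#' Samples offspring pairs by relationship category from a true pedigree
#' (pairs sharing neither parent / exactly one / both), for calibrating the
#' relatedness threshold. Offspring with external fathers are treated as
#' sharing no father.
#'
#' @param pedigree data frame `offspring_id, mother_id, true_father_id`.
#' @param n_pairs pairs to sample per category (fewer if not available).
#' @param seed integer seed.
#' @return list of two-column id matrices: `unrelated`, `halfsib`,
#'   `fullsib` (entries may have zero rows).
#' @export
pedigree_pairs <- function(pedigree, n_pairs = 500, seed = NULL) {
  with_seed_(seed, {
    n <- nrow(pedigree)
    mo <- pedigree$mother_id
    fa <- pedigree$true_father_id
    fa[fa == "EXTERNAL"] <- paste0("EXT", seq_len(sum(fa == "EXTERNAL")))
    pick <- function(cond_fun, m) {
      out <- matrix(character(0), 0, 2)
      tries <- 0L
      while (nrow(out) < m && tries < 50L * m) {
        tries <- tries + 1L
        ij <- sample.int(n, 2)
        if (cond_fun(ij[1], ij[2]))
          out <- rbind(out, pedigree$offspring_id[ij])
      }
      out
    }
    list(
      unrelated = pick(function(i, j) mo[i] != mo[j] && fa[i] != fa[j],
                       n_pairs),
      halfsib = pick(function(i, j) xor(mo[i] == mo[j], fa[i] == fa[j]),
                     n_pairs),
      fullsib = pick(function(i, j) mo[i] == mo[j] && fa[i] == fa[j],
                     n_pairs)
    )
  })
}

#' Run the full species-delimitation pipeline on a synthetic stand
#'
#' Chains every stage: stand generation, open-pollinated mating, exclusion
#' paternity, mating-network construction, C-SBM fit (Q = 3) and triangular
#' classification, adult relatedness estimation with threshold calibration
#' on known-unrelated offspring pairs, relatedness-network C-SBM and
#' classification, synthetic genotype/morphology reference assignments,
#' label harmonization, congruence summary, and the allospecific-
#' neighbourhood logistic regression. All outputs are plain text and
#' deterministic given `seed` (no timestamps), so two runs with the same
#' configuration are byte-identical.
#'
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param n_A,n_B,n_loci,alleles_per_locus,differentiation,extent see
#'   [generate_stand()].
#' @param n_mothers,offspring_per_mother,dispersal_scale,compatibility,immigration,error_rate
#'   see [simulate_mating()].
#' @param Q_scan range of Q for the model scan; `Q_select` optional manual
#'   override (default 3, the two-species reading).
#' @param epsilon classification tolerance, see [classify_memberships()].
#' @param radius neighbourhood radius in metres.
#' @param threshold_fallback relatedness threshold used if calibration is
#'   impossible (default 0.22).
#' @param n_restarts C-SBM restarts.
#' @param seed master integer seed, fanned out to per-stage substreams.
#' @return invisibly, a list with all intermediate objects: `stand`,
#'   `progeny`, `paternity`, `mating_network`, `mating_scan`, `mating_fit`,
#'   `relmatrix`, `calibration`, `relatedness_network`, `relatedness_fit`,
#'   `assignments` (harmonized table), `congruence`, `neighborhood`.
#' @export
run_pipeline <- function(out_dir = NULL,
                         n_A = 178, n_B = 120, n_loci = 12,
                         alleles_per_locus = 10, differentiation = 0.8,
                         extent = c(250, 200),
                         n_mothers = 51, offspring_per_mother = 60,
                         dispersal_scale = 69, compatibility = 0.2,
                         immigration = 0.45, error_rate = 0,
                         Q_scan = c(2, 4), Q_select = 3,
                         epsilon = 0.05, radius = 69,
                         threshold_fallback = 0.22,
                         n_restarts = 5, seed = 1) {
  cfg <- list(n_A = n_A, n_B = n_B, n_loci = n_loci,
              alleles_per_locus = alleles_per_locus,
              differentiation = differentiation, extent = extent,
              n_mothers = n_mothers,
              offspring_per_mother = offspring_per_mother,
              dispersal_scale = dispersal_scale,
              compatibility = compatibility, immigration = immigration,
              error_rate = error_rate, Q_scan = Q_scan,
              Q_select = Q_select, epsilon = epsilon, radius = radius,
              threshold_fallback = threshold_fallback,
              n_restarts = n_restarts, seed = seed)

  stand <- generate_stand(n_A, n_B, n_loci, alleles_per_locus,
                          differentiation, extent,
                          seed = derive_seed(seed, 1))
  progeny <- simulate_mating(stand, n_mothers, offspring_per_mother,
                             dispersal_scale, compatibility, immigration,
                             error_rate, seed = derive_seed(seed, 2))
  pat <- assign_paternity(progeny, stand$genotypes)
  gmat <- build_mating_network(pat)
  scan <- csbm_scan(gmat, Q_min = Q_scan[1], Q_max = Q_scan[2],
                    select = Q_select, n_restarts = n_restarts,
                    seed = derive_seed(seed, 3))
  fit_b <- selected_fit(scan)
  cls_b <- classify_memberships(fit_b, epsilon, criterion = "interfertility")

  relm <- estimate_relatedness(stand$genotypes,
                               stand$allele_freqs$pooled)
  pp <- pedigree_pairs(progeny$pedigree, n_pairs = 500,
                       seed = derive_seed(seed, 4))
  cal <- tryCatch({
    off_rel <- function(pairs) {
      if (nrow(pairs) == 0) return(NULL)
      relatedness_dyads(progeny$genotypes[pairs[, 1], , drop = FALSE],
                        progeny$genotypes[pairs[, 2], , drop = FALSE],
                        stand$allele_freqs$pooled)
    }
    calibrate_threshold(off_rel(pp$unrelated), off_rel(pp$halfsib),
                        off_rel(pp$fullsib))
  }, error = function(e) NULL)
  thr <- if (is.null(cal)) threshold_fallback else cal$threshold
  grel <- build_relatedness_network(relm, thr)
  # a max-calibrated threshold from a moment estimator has a heavy upper
  # tail and can land above every adult pair value; fall back to the
  # reference threshold rather than analysing a degenerate network
  if (igraph::vcount(grel) < 10) {
    warning("calibrated threshold ", signif(thr, 3), " leaves a degenerate ",
            "relatedness network; falling back to ", threshold_fallback)
    thr <- threshold_fallback
    grel <- build_relatedness_network(relm, thr)
  }
  fit_p <- csbm(grel, Q = 3, n_restarts = n_restarts,
                seed = derive_seed(seed, 5))
  cls_p <- classify_memberships(fit_p, epsilon, criterion = "relatedness")

  refs <- synthetic_reference_assignments(stand,
                                          seed = derive_seed(seed, 6))
  tab <- data.frame(id = stand$individuals$id, stringsAsFactors = FALSE)
  tab$interfertility <- cls_b$label[match(tab$id, cls_b$id)]
  tab$relatedness <- cls_p$label[match(tab$id, cls_p$id)]
  tab$genotype <- refs$genotype[match(tab$id, refs$id)]
  tab$morphology <- refs$morphology[match(tab$id, refs$id)]
  tab_h <- harmonize_labels(tab[stats::complete.cases(tab), ],
                            reference = "genotype")
  cong <- congruence_summary(tab_h)

  # the neighbourhood test: restrict to individuals whose genotype and
  # morphology assignments agree on a pure label, then ask whether the
  # interfertility label matches that consensus
  consensus_ok <- tab_h$genotype == tab_h$morphology &
    tab_h$genotype != "intermediate"
  gm <- tab_h[consensus_ok, ]
  labels <- stats::setNames(tab_h$genotype, tab_h$id)
  frac <- allospecific_fraction(stand$individuals, labels, radius)
  congruent <- gm$interfertility == gm$genotype
  nb <- tryCatch(
    congruence_glm(congruent, frac[match(gm$id, names(frac))]),
    error = function(e) NULL)

  res <- list(config = cfg, stand = stand, progeny = progeny,
              paternity = pat, mating_network = gmat, mating_scan = scan,
              mating_fit = fit_b, relmatrix = relm, calibration = cal,
              relatedness_network = grel, relatedness_fit = fit_p,
              assignments = tab_h, congruence = cong, neighborhood = nb)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(out_dir, f)
    jsonlite::write_json(cfg, fp("config.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    write_genotypes(stand$genotypes, fp("adult_genotypes.csv"))
    write_coordinates(stand, fp("coordinates.csv"))
    write_pedigree(progeny$pedigree, fp("pedigree.csv"))
    write_network(gmat, fp("mating_network.csv"))
    write_network(gmat, fp("mating_network.net"))
    write_fit_json(fit_b, fp("mating_fit.json"))
    write_relatedness(relm, fp("relatedness.csv"))
    write_network(grel, fp("relatedness_network.csv"))
    write_network(grel, fp("relatedness_network.net"))
    write_fit_json(fit_p, fp("relatedness_fit.json"))
    write_assignments(tab_h, fp("assignments.csv"))
    report <- list(
      n_mating_events = igraph::graph_attr(gmat, "n_mating_events"),
      n_selfing_dropped = igraph::graph_attr(gmat, "n_selfing_dropped"),
      mating_nodes = igraph::vcount(gmat),
      mating_links = igraph::ecount(gmat),
      relatedness_threshold = thr,
      relatedness_links = igraph::ecount(grel),
      paternity = as.list(table(pat$category)),
      congruence = list(
        n = cong$n, consistent = cong$n_consistent,
        inversions = cong$n_inversions,
        intermediate_any = cong$n_intermediate_any,
        frac_discrepancies_from_intermediates =
          cong$frac_discrepancies_from_intermediates),
      neighborhood = if (!is.null(nb))
        list(chisq = nb$chisq, df = nb$df, p = nb$p_value,
             slope = nb$slope, group_means = as.list(nb$group_means))
    )
    jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(res)
}
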