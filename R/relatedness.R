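# Pairwise relatedness (Queller-Goodnight moment estimator), threshold
# calibration on known-unrelated pairs, and the relatedness network.

# Per-locus QG terms for paired allele vectors (a1,a2 = focal x; b1,b2 = y),
# with reference frequencies p1..p4 for the four alleles. Returns the
# locus-wise numerator/denominator of the estimate with x focal and with y
# focal. All inputs are equal-length vectors (one element per pair).
qg_terms_ <- function(a1, a2, b1, b2, pa1, pa2, pb1, pb2) {
  s <- 0.5 * ((a1 == b1) + (a1 == b2) + (a2 == b1) + (a2 == b2))
  list(num_x = s - pa1 - pa2, den_x = 1 + (a1 == a2) - pa1 - pa2,
       num_y = s - pb1 - pb2, den_y = 1 + (b1 == b2) - pb1 - pb2)
}

# Symmetrised QG relatedness for matched pairs of genotype rows.
# g1, g2: genotype matrices (one dyad per row). Numerators and denominators
# are summed over loci before division, then the two directions averaged.
qg_pairs_ <- function(g1, g2, freqs, min_loci = 1L) {
  n <- nrow(g1)
  n_loci <- ncol(g1) / 2L
  nx <- dx <- ny <- dy <- numeric(n)
  used <- integer(n)
  for (l in seq_len(n_loci)) {
    c1 <- 2L * l - 1L; c2 <- 2L * l
    a1 <- g1[, c1]; a2 <- g1[, c2]; b1 <- g2[, c1]; b2 <- g2[, c2]
    ok <- !(is.na(a1) | is.na(a2) | is.na(b1) | is.na(b2))
    if (!any(ok)) next
    f <- freqs[l, ]
    t <- qg_terms_(a1[ok], a2[ok], b1[ok], b2[ok],
                   f[a1[ok]], f[a2[ok]], f[b1[ok]], f[b2[ok]])
    nx[ok] <- nx[ok] + t$num_x; dx[ok] <- dx[ok] + t$den_x
    ny[ok] <- ny[ok] + t$num_y; dy[ok] <- dy[ok] + t$den_y
    used[ok] <- used[ok] + 1L
  }
  r <- 0.5 * (nx / dx + ny / dy)
  r[used < min_loci | !is.finite(r)] <- NA_real_
  list(r = r, n_loci = used)
}

#' Estimate pairwise relatedness among individuals
#'
#' Computes the Queller-Goodnight moment estimator for every pair of rows of
#' a genotype matrix: per direction, numerators and denominators are summed
#' over informative loci before division, then the two directions are
#' averaged, giving an exactly symmetric estimate (possibly negative, as for
#' any moment estimator). Pairs with fewer than `min_loci` loci informative
#' in both individuals, or a zero summed denominator, are left missing.
#'
#' @param genotypes integer genotype matrix (two columns per locus),
#'   rownames = individual ids.
#' @param allele_freqs locus-by-allele reference frequency matrix; `NULL`
#'   computes frequencies from the sample itself.
#' @param estimator estimator name; `"qg"` (Queller-Goodnight) is the only
#'   built-in. Externally computed matrices can be imported with
#'   [read_relatedness()].
#' @param min_loci minimum informative loci per pair (default 6, half a
#'   12-locus panel).
#' @return object of class `"relmatrix"`: list with `r` (symmetric matrix,
#'   `NA` diagonal), `n_loci` (per-pair informative locus counts) and `ids`.
#' @examples
#' f <- matrix(c(0.25, 0.75), 1, 2)
#' g <- rbind(i = c(1L, 1L), j = c(1L, 1L))
#' estimate_relatedness(g, f, min_loci = 1)$r["i", "j"]  # exactly 1
#' @export
estimate_relatedness <- function(genotypes, allele_freqs = NULL,
                                 estimator = "qg", min_loci = 6) {
  estimator <- match.arg(estimator, "qg")
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(genotypes)))
  if (is.null(allele_freqs)) allele_freqs <- sample_freqs_(genotypes)
  n <- nrow(genotypes)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- qg_pairs_(genotypes[ut[, 1], , drop = FALSE],
                   genotypes[ut[, 2], , drop = FALSE],
                   allele_freqs, min_loci)
  R <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  L <- matrix(0L, n, n, dimnames = list(ids, ids))
  R[ut] <- res$r; R[ut[, 2:1, drop = FALSE]] <- res$r
  L[ut] <- res$n_loci; L[ut[, 2:1, drop = FALSE]] <- res$n_loci
  structure(list(r = R, n_loci = L, ids = ids), class = "relmatrix")
}

#' @export
print.relmatrix <- function(x, ...) {
  n <- length(x$ids)
  vals <- x$r[upper.tri(x$r)]
  cat(sprintf("Relatedness matrix: %d individuals, %d/%d pairs estimated\n",
              n, sum(!is.na(vals)), length(vals)))
  if (any(!is.na(vals)))
    cat(sprintf("  range %.3f .. %.3f, mean %.3f\n",
                min(vals, na.rm = TRUE), max(vals, na.rm = TRUE),
                mean(vals, na.rm = TRUE)))
  invisible(x)
}

# allele frequencies observed in a genotype matrix
sample_freqs_ <- function(genotypes) {
  n_loci <- ncol(genotypes) / 2L
  k <- max(genotypes, na.rm = TRUE)
  f <- matrix(0, n_loci, k)
  for (l in seq_len(n_loci)) {
    a <- c(genotypes[, 2L * l - 1L], genotypes[, 2L * l])
    tb <- tabulate(a[!is.na(a)], nbins = k)
    f[l, ] <- tb / sum(tb)
  }
  f
}

#' Simulate genotyped dyads of known relationship
#'
#' Draws parental genotypes locus-wise from the given allele frequencies and
#' produces offspring dyads: `"unrelated"` (no shared parent), `"halfsib"`
#' (shared father, independent mothers) or `"fullsib"` (both parents shared).
#' Used to calibrate the relatedness estimator and its threshold.
#'
#' @param n_dyads number of pairs.
#' @param relationship `"unrelated"`, `"halfsib"` or `"fullsib"`.
#' @param n_loci,alleles_per_locus genotyping panel (defaults 12 x 10).
#' @param freqs optional locus-by-allele frequency matrix (default uniform).
#' @param seed integer seed.
#' @return list of two genotype matrices `g1`, `g2` (row i of each = dyad i)
#'   and the `freqs` used.
#' @export
simulate_dyads <- function(n_dyads, relationship = c("unrelated", "halfsib",
                                                     "fullsib"),
                           n_loci = 12, alleles_per_locus = 10, freqs = NULL,
                           seed = NULL) {
  relationship <- match.arg(relationship)
  k <- alleles_per_locus
  if (is.null(freqs)) freqs <- matrix(1 / k, n_loci, k)
  with_seed_(seed, {
    draw <- function() {
      g <- matrix(NA_integer_, n_dyads, 2L * n_loci)
      for (l in seq_len(n_loci))
        g[, c(2L * l - 1L, 2L * l)] <-
          sample.int(ncol(freqs), 2L * n_dyads, replace = TRUE,
                     prob = freqs[l, ])
      g
    }
    cross <- function(mo, fa) {
      g <- matrix(NA_integer_, n_dyads, 2L * n_loci)
      for (i in seq_len(n_dyads))
        g[i, ] <- mendelian_offspring(mo[i, ], fa[i, ])
      g
    }
    fa1 <- draw(); mo1 <- draw()
    fa2 <- switch(relationship, unrelated = draw(), halfsib = fa1,
                  fullsib = fa1)
    mo2 <- switch(relationship, unrelated = draw(), halfsib = draw(),
                  fullsib = mo1)
    list(g1 = cross(mo1, fa1), g2 = cross(mo2, fa2), freqs = freqs)
  })
}

#' Relatedness estimates for matched dyads
#'
#' Convenience wrapper around the Queller-Goodnight estimator for paired
#' genotype matrices (row i of `g1` vs row i of `g2`), as produced by
#' [simulate_dyads()].
#'
#' @inheritParams estimate_relatedness
#' @param g1,g2 genotype matrices of equal dimensions.
#' @return numeric vector of symmetrised estimates (`NA` where undefined).
#' @export
relatedness_dyads <- function(g1, g2, allele_freqs, min_loci = 6) {
  qg_pairs_(g1, g2, allele_freqs, min_loci)$r
}

#' Calibrate the relatedness threshold on known-unrelated pairs
#'
#' The threshold separating "related" from "unrelated" is set to the maximum
#' estimate observed among pairs known to share neither parent (on real oak
#' data this procedure gave 0.22). Optional half-sib and full-sib validation
#' sets are summarised alongside.
#'
#' @param unrelated numeric vector of relatedness estimates for known
#'   unrelated pairs, or (with `relmatrix` supplied) a two-column matrix of
#'   id pairs.
#' @param halfsib,fullsib optional validation sets, same form as `unrelated`.
#' @param relmatrix optional [estimate_relatedness()] object from which id
#'   pairs are looked up.
#' @return object of class `"threshold_calibration"`: list with `threshold`,
#'   `n_unrelated_pairs`, and a `summary` data frame (mean and quantiles per
#'   supplied set).
#' @examples
#' calibrate_threshold(c(0.10, 0.05, 0.22))$threshold  # 0.22
#' @export
calibrate_threshold <- function(unrelated, halfsib = NULL, fullsib = NULL,
                                relmatrix = NULL) {
  grab <- function(x) {
    if (is.null(x)) return(NULL)
    if (!is.null(relmatrix) && (is.matrix(x) || is.data.frame(x))) {
      x <- as.matrix(x)
      return(relmatrix$r[cbind(as.character(x[, 1]), as.character(x[, 2]))])
    }
    as.numeric(x)
  }
  u <- grab(unrelated); u <- u[!is.na(u)]
  if (length(u) == 0L)
    stop("no unrelated calibration pair with a defined estimate; ",
         "use the fallback default threshold 0.22")
  sets <- list(unrelated = u, halfsib = grab(halfsib),
               fullsib = grab(fullsib))
  sets <- sets[!vapply(sets, is.null, logical(1))]
  smry <- do.call(rbind, lapply(names(sets), function(nm) {
    v <- sets[[nm]][!is.na(sets[[nm]])]
    data.frame(set = nm, n = length(v), mean = mean(v),
               q05 = unname(stats::quantile(v, 0.05)),
               median = stats::median(v),
               q95 = unname(stats::quantile(v, 0.95)), max = max(v))
  }))
  structure(list(threshold = max(u), n_unrelated_pairs = length(u),
                 summary = smry),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf(
    "Relatedness threshold: %.4f (max over %d known-unrelated pairs)\n",
    x$threshold, x$n_unrelated_pairs))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Build the relatedness network
#'
#' Links every pair of individuals whose relatedness estimate is strictly
#' greater than the threshold. Missing pairs contribute no edge; individuals
#' incident to no edge are dropped from the node set and reported in the
#' `isolated` graph attribute.
#'
#' @param relmatrix an [estimate_relatedness()] object (or a plain symmetric
#'   matrix with dimnames).
#' @param threshold relatedness threshold (e.g. from [calibrate_threshold()];
#'   0.22 is the fallback calibrated on real oak data).
#' @return undirected simple [igraph::graph]; attribute `isolated` holds the
#'   ids present in the matrix but incident to no edge.
#' @export
build_relatedness_network <- function(relmatrix, threshold = 0.22) {
  R <- if (inherits(relmatrix, "relmatrix")) relmatrix$r else relmatrix
  if (!is.finite(threshold)) stop("threshold must be finite")
  ids <- rownames(R)
  ut <- which(upper.tri(R) & !is.na(R) & R > threshold, arr.ind = TRUE)
  pairs <- data.frame(a = ids[ut[, 1]], b = ids[ut[, 2]],
                      stringsAsFactors = FALSE)
  g <- if (nrow(pairs) == 0L)
    igraph::make_empty_graph(0, directed = FALSE)
  else
    igraph::graph_from_data_frame(pairs, directed = FALSE)
  igraph::set_graph_attr(g, "isolated",
                         setdiff(ids, igraph::V(g)$name))
}
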