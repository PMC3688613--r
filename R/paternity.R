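# Exclusion-based paternity assignment and the mating network.

# feasible paternal allele set at one locus, given offspring and mother pairs;
# returns integer vector (possibly length 2), or NULL if the locus is
# uninformative (missing data), or NA if mother and offspring are incompatible
feasible_paternal_ <- function(o, m) {
  if (anyNA(o) || anyNA(m)) return(NULL)
  in1 <- o[1] %in% m
  in2 <- o[2] %in% m
  if (in1 && in2) unique(o)
  else if (in1) o[2]
  else if (in2) o[1]
  else NA_integer_
}

#' Assign a father to one offspring by multilocus exclusion
#'
#' At each locus the feasible paternal allele set is obtained by subtracting
#' one maternal contribution from the offspring genotype (if the offspring
#' shares both alleles with the mother, either may be paternal). A candidate
#' is compatible at a locus if he carries any feasible paternal allele;
#' candidates mismatching at more than `max_mismatch` loci are excluded.
#' Loci with missing data in offspring, mother or candidate are skipped for
#' that comparison.
#'
#' @param offspring,mother integer genotype vectors (two entries per locus).
#' @param candidates integer genotype matrix, one row per candidate father,
#'   rownames = candidate ids.
#' @param max_mismatch tolerated mismatching loci per candidate (default 0,
#'   strict exclusion; set to 1 to absorb one genotyping error).
#' @return list with `category` (`"single"`, `"multiple"` or `"none"`),
#'   `father_id` (id if `category == "single"`, else `NA`), `n_compatible`,
#'   `mismatches_allowed`, `mother_mismatch_loci` (count of loci at which the
#'   offspring is incompatible with its own mother) and `pedigree_error`
#'   (`TRUE` when that count exceeds `max_mismatch`; such records should be
#'   excluded downstream).
#' @examples
#' # allele 3 must be paternal; the candidate carries it
#' exclusion_paternity(c(1L, 3L), c(1L, 2L), rbind(c1 = c(3L, 4L)))
#' @export
exclusion_paternity <- function(offspring, mother, candidates,
                                max_mismatch = 0) {
  stopifnot(is.matrix(candidates), ncol(candidates) == length(offspring))
  n_loci <- length(offspring) / 2L
  mism <- integer(nrow(candidates))
  mom_bad <- 0L
  for (l in seq_len(n_loci)) {
    cols <- c(2L * l - 1L, 2L * l)
    feas <- feasible_paternal_(offspring[cols], mother[cols])
    if (is.null(feas)) next
    if (anyNA(feas)) { mom_bad <- mom_bad + 1L; next }
    c1 <- candidates[, cols[1]]; c2 <- candidates[, cols[2]]
    ok <- (c1 %in% feas) | (c2 %in% feas)
    ok[is.na(c1) | is.na(c2)] <- TRUE  # missing candidate locus: skip
    mism <- mism + !ok
  }
  surv <- which(mism <= max_mismatch)
  cat_ <- if (length(surv) == 0L) "none"
          else if (length(surv) == 1L) "single" else "multiple"
  list(category = cat_,
       father_id = if (cat_ == "single") rownames(candidates)[surv] else NA_character_,
       n_compatible = length(surv),
       mismatches_allowed = max_mismatch,
       mother_mismatch_loci = mom_bad,
       pedigree_error = mom_bad > max_mismatch)
}

#' Exclusion paternity for a whole progeny set
#'
#' Runs [exclusion_paternity()] for every offspring against all adults of the
#' stand except its mother.
#'
#' @param progeny a [simulate_mating()] object, or a list with elements
#'   `pedigree` (data frame `offspring_id, mother_id`) and `genotypes`
#'   (offspring genotype matrix with matching rownames).
#' @param adult_genotypes adult genotype matrix, rownames = adult ids.
#' @param max_mismatch see [exclusion_paternity()].
#' @return data frame with one row per offspring: `offspring_id, mother_id,
#'   category, father_id, n_compatible, mother_mismatch_loci, pedigree_error`.
#' @export
assign_paternity <- function(progeny, adult_genotypes, max_mismatch = 0) {
  ped <- progeny$pedigree
  og <- progeny$genotypes
  n <- nrow(ped)
  out <- data.frame(
    offspring_id = ped$offspring_id, mother_id = ped$mother_id,
    category = character(n), father_id = NA_character_,
    n_compatible = integer(n), mother_mismatch_loci = integer(n),
    pedigree_error = logical(n), stringsAsFactors = FALSE)
  for (mid in unique(ped$mother_id)) {
    cand <- adult_genotypes[setdiff(rownames(adult_genotypes), mid), ,
                            drop = FALSE]
    mg <- adult_genotypes[mid, ]
    for (i in which(ped$mother_id == mid)) {
      a <- exclusion_paternity(og[ped$offspring_id[i], ], mg, cand,
                               max_mismatch)
      out$category[i] <- a$category
      out$father_id[i] <- a$father_id
      out$n_compatible[i] <- a$n_compatible
      out$mother_mismatch_loci[i] <- a$mother_mismatch_loci
      out$pedigree_error[i] <- a$pedigree_error
    }
  }
  out
}

#' Build the mating network from paternity assignments
#'
#' One edge per unique unordered (mother, father) couple over assignments
#' with a single compatible father; offspring with multiple or no compatible
#' fathers contribute nothing, as do records flagged as pedigree errors.
#' Selfing couples (mother = father) are dropped and counted. Nodes are the
#' adults incident to at least one edge.
#'
#' @param assignments data frame as returned by [assign_paternity()] (needs
#'   columns `mother_id`, `father_id`, `category`; `pedigree_error` honoured
#'   if present).
#' @return an undirected simple [igraph::graph] with graph attributes
#'   `n_mating_events` (single-father offspring used) and
#'   `n_selfing_dropped`.
#' @examples
#' a <- data.frame(mother_id = c("m1", "m1", "m2"),
#'                 father_id = c("f1", "f1", "f3"),
#'                 category = "single")
#' igraph::ecount(build_mating_network(a))  # 2 unique couples
#' @export
build_mating_network <- function(assignments) {
  keep <- assignments$category == "single"
  if (!is.null(assignments$pedigree_error))
    keep <- keep & !assignments$pedigree_error
  mo <- assignments$mother_id[keep]
  fa <- assignments$father_id[keep]
  self <- mo == fa
  n_self <- sum(self)
  mo <- mo[!self]; fa <- fa[!self]
  pairs <- unique(data.frame(
    a = pmin(mo, fa), b = pmax(mo, fa), stringsAsFactors = FALSE))
  g <- if (nrow(pairs) == 0L)
    igraph::make_empty_graph(0, directed = FALSE)
  else
    igraph::graph_from_data_frame(pairs, directed = FALSE)
  g <- igraph::set_graph_attr(g, "n_mating_events", sum(keep) - n_self)
  igraph::set_graph_attr(g, "n_selfing_dropped", n_self)
}
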