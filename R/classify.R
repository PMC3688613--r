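# Turning a Q = 3 C-SBM fit into species assignments.

#' Classify individuals from a Q = 3 C-SBM fit
#'
#' Applies the triangular rule: a node is assigned to species 1 when its
#' mixture involves only EHN0 and EHN1 (its EHN2 weight is at most
#' `epsilon`), i.e. it lies on the EHN0-EHN1 edge of the membership
#' triangle; symmetrically for species 2. All other nodes — genuinely mixed
#' reproductive behaviour — are intermediate. Nodes whose both species
#' weights fall below `epsilon` sit near the EHN0 vertex (few links); they
#' are still assigned to whichever species EHN dominates their mixture — a
#' tree connected through a single mating event is connected to one species
#' — but flagged `low_information = TRUE`; exact ties remain intermediate.
#'
#' @param fit a [csbm()] fit with exactly 3 EHNs.
#' @param epsilon absolute membership tolerance for "on the edge"
#'   (`0 <= epsilon < 0.5`, default 0.05).
#' @param criterion tag recorded in the output (e.g. `"interfertility"`,
#'   `"relatedness"`).
#' @return data frame `id, label, u0, u1, u2, low_information, criterion`
#'   with `label` in `{"S1", "S2", "intermediate"}`.
#' @export
classify_memberships <- function(fit, epsilon = 0.05,
                                 criterion = "interfertility") {
  stopifnot(inherits(fit, "csbm"))
  if (fit$Q != 3)
    stop("classification rule requires a Q = 3 fit (EHN0 + two species ",
         "EHNs); re-fit with Q = 3 or extend the rule")
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must be in [0, 0.5)")
  U <- species_u_(fit)
  u1 <- U[, 2]; u2 <- U[, 3]
  low <- u1 <= epsilon & u2 <= epsilon
  # a node is on the EHN0-EHN1 edge (species 1) when its EHN2 weight is
  # negligible, however close to the EHN0 vertex it sits; weakly connected
  # nodes (both species weights small) are still assigned by whichever
  # species EHN dominates, but flagged low-information; exact ties stay
  # intermediate
  label <- ifelse(u2 <= epsilon & u1 > u2, "S1",
                  ifelse(u1 <= epsilon & u2 > u1, "S2", "intermediate"))
  data.frame(id = rownames(U), label = label, u0 = U[, 1], u1 = u1, u2 = u2,
             low_information = low, criterion = criterion,
             row.names = NULL, stringsAsFactors = FALSE)
}

# identify EHN0 by its zero B row (never by index alone); return U with
# columns ordered (EHN0, species 1, species 2)
species_u_ <- function(fit) {
  rs <- rowSums(abs(fit$B))
  zero <- which(rs <= 1e-8)
  i0 <- if (length(zero) > 0) zero[1] else which.min(rs)
  perm <- c(i0, setdiff(seq_len(fit$Q), i0))
  fit$U[, perm, drop = FALSE]
}

#' Ternary coordinates of the nodes of a Q = 3 fit
#'
#' Standard barycentric embedding: EHN0 at (0, 0), EHN1 at (1, 0), EHN2 at
#' (1/2, sqrt(3)/2). A node's position is its membership-weighted average of
#' the three vertices.
#'
#' @param fit a [csbm()] fit with `Q = 3`.
#' @return two-column matrix (`x`, `y`), rownames = node ids.
#' @export
ternary_coordinates <- function(fit) {
  stopifnot(inherits(fit, "csbm"))
  if (fit$Q != 3) stop("ternary coordinates require Q = 3")
  U <- species_u_(fit)
  verts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  xy <- U %*% verts
  colnames(xy) <- c("x", "y")
  rownames(xy) <- rownames(U)
  xy
}
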