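# Standard modelling methods for "csbm" fits.

#' @export
print.csbm <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Continuous stochastic block model: %d nodes, %d edges, Q = %d EHNs\n",
    x$n, x$n_edges, x$Q))
  cat(sprintf("logL = %.*f, AIC = %.*f (k = %d)%s\n", digits, x$logL,
              digits, x$aic, x$df,
              if (x$converged) "" else "  [not converged]"))
  cat("EHN connectivity matrix B:\n")
  print(round(x$B, digits))
  invisible(x)
}

#' @export
summary.csbm <- function(object, ...) {
  mean_u <- colMeans(object$U)
  dom <- colnames(object$U)[max.col(object$U, ties.method = "first")]
  structure(list(fit = object, mean_membership = mean_u,
                 dominant = table(factor(dom, levels = colnames(object$U)))),
            class = "summary.csbm")
}

#' @export
print.summary.csbm <- function(x, ...) {
  print(x$fit)
  cat("\nMean membership per EHN:\n")
  print(round(x$mean_membership, 3))
  cat("Nodes by dominant EHN:\n")
  print(x$dominant)
  invisible(x)
}

#' @export
coef.csbm <- function(object, ...) {
  list(U = object$U, B = object$B)
}

#' @export
logLik.csbm <- function(object, ...) {
  structure(object$logL, df = object$df,
            nobs = object$n * (object$n - 1) / 2, class = "logLik")
}

#' Fitted edge probabilities of a C-SBM
#'
#' @param object a [csbm()] fit.
#' @param ... unused.
#' @return symmetric n-by-n matrix of `pi_ij` (diagonal `NA`).
#' @export
fitted.csbm <- function(object, ...) {
  P <- object$U %*% object$B %*% t(object$U)
  dimnames(P) <- list(object$nodes, object$nodes)
  diag(P) <- NA_real_
  P
}

#' Predict edge probabilities for node pairs
#'
#' @param object a [csbm()] fit.
#' @param pairs optional two-column matrix/data frame of node ids; `NULL`
#'   returns the full [fitted()] matrix.
#' @param ... unused.
#' @return numeric vector of probabilities (or the full matrix).
#' @export
predict.csbm <- function(object, pairs = NULL, ...) {
  P <- fitted(object)
  if (is.null(pairs)) return(P)
  pairs <- as.matrix(pairs)
  P[cbind(as.character(pairs[, 1]), as.character(pairs[, 2]))]
}

#' Residuals of a C-SBM fit
#'
#' @param object a [csbm()] fit (must retain its network).
#' @param type `"response"` (`X - pi`) or `"pearson"`
#'   (`(X - pi) / sqrt(pi (1 - pi))`).
#' @param ... unused.
#' @return symmetric residual matrix, diagonal `NA`.
#' @export
residuals.csbm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  if (is.null(object$network))
    stop("fit does not retain its network; residuals unavailable")
  X <- as_adjacency_(object$network)
  P <- object$U %*% object$B %*% t(object$U)
  P <- pmin(pmax(P, PI_CLIP), 1 - PI_CLIP)
  R <- X - P
  if (type == "pearson") R <- R / sqrt(P * (1 - P))
  dimnames(R) <- list(object$nodes, object$nodes)
  diag(R) <- NA_real_
  R
}

#' Simulate networks from a fitted C-SBM
#'
#' Draws independent Bernoulli edges with the fitted probabilities.
#'
#' @param object a [csbm()] fit.
#' @param nsim number of networks.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [igraph::graph] objects with the fit's node names.
#' @export
simulate.csbm <- function(object, nsim = 1, seed = NULL, ...) {
  P <- object$U %*% object$B %*% t(object$U)
  n <- object$n
  ut <- upper.tri(P)
  with_seed_(seed, {
    lapply(seq_len(nsim), function(s) {
      A <- matrix(0L, n, n)
      A[ut] <- stats::rbinom(sum(ut), 1L, P[ut])
      A <- A + t(A)
      dimnames(A) <- list(object$nodes, object$nodes)
      igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    })
  })
}

#' Triangular (ternary) plot of a Q = 3 C-SBM fit
#'
#' Places every node inside the triangle whose vertices are the three EHNs;
#' the closer a node sits to a vertex, the larger that EHN's share of its
#' membership mixture. Nodes are coloured by their [classify_memberships()]
#' label.
#'
#' @param x a [csbm()] fit with `Q = 3`.
#' @param epsilon classification tolerance passed to
#'   [classify_memberships()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the ternary coordinates.
#' @export
plot.csbm <- function(x, epsilon = 0.05, ...) {
  if (x$Q != 3)
    stop("ternary plot requires a Q = 3 fit")
  xy <- ternary_coordinates(x)
  lab <- classify_memberships(x, epsilon = epsilon)$label
  col <- c(S1 = "forestgreen", S2 = "goldenrod", intermediate = "black")[lab]
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.08, sqrt(3) / 2 + 0.05),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", ...)
  graphics::polygon(tri[, 1], tri[, 2], border = "grey40")
  graphics::text(tri[c(1, 2), 1], tri[c(1, 2), 2] - 0.045,
                 c("EHN0", "EHN1"))
  graphics::text(tri[3, 1], tri[3, 2] + 0.045, "EHN2")
  graphics::points(xy[, 1], xy[, 2], pch = 19, cex = 0.6, col = col)
  invisible(xy)
}
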