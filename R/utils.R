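# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. `seed = NULL`
#' leaves the RNG stream untouched.
#' @noRd
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fan a single user seed out into per-stage substreams
#'
#' Deterministic, stays below 2^31 so the result is a valid `set.seed()` input.
#' @noRd
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  # keep everything in doubles (exact below 2^53), reduce mod 2^31 - 1 at the
  # end so the result is always a valid set.seed() input
  v <- ((as.double(seed) %% 2147483647) * 7919 +
          as.double(stream) * 104729) %% 2147483647
  as.integer(v)
}

#' Dirichlet draws via independent gammas
#' @noRd
rdirichlet_ <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Euclidean projection of each row of a matrix onto the probability simplex
#'
#' Duchi et al. sort-based algorithm, vectorised over rows.
#' @noRd
project_simplex_rows <- function(M) {
  n <- nrow(M); k <- ncol(M)
  if (k == 1L) return(matrix(1, n, 1L))
  # row-wise descending sort without per-row apply
  S <- matrix(M[order(row(M), -M)], n, k, byrow = TRUE)
  cs <- S
  for (j in 2:k) cs[, j] <- cs[, j - 1L] + S[, j]
  js <- matrix(seq_len(k), n, k, byrow = TRUE)
  rho <- rowSums(S - (cs - 1) / js > 0)
  theta <- (cs[cbind(seq_len(n), rho)] - 1) / rho
  out <- pmax(M - theta, 0)
  out / rowSums(out)  # guard against numeric drift
}

`%||%` <- function(a, b) if (is.null(a)) b else a
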