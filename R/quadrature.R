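#' Gauss-Hermite rule for the standard normal distribution
#'
#' Probabilists' Gauss-Hermite nodes and weights: with `M` points the rule
#' integrates polynomials up to degree `2M - 1` exactly against the N(0, 1)
#' density, and the weights sum to one.
#'
#' @param M number of integration points (>= 1).
#' @return list with `nodes` and `weights`, each of length `M`.
#' @examples
#' gauss_hermite_rule(2)  # nodes -1, 1; weights 1/2, 1/2
#' @export
gauss_hermite_rule <- function(M) {
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("'M' must be a positive integer")
  gq <- statmod::gauss.quad.prob(M, dist = "normal", mu = 0, sigma = 1)
  list(nodes = gq$nodes, weights = gq$weights)
}

#' Tensor-product quadrature grid for a multivariate normal latent
#' distribution
#'
#' Builds the `M^p` product grid of a 1-D Gauss-Hermite rule and maps it
#' onto the latent scale with `mean + chol(covariance) %*% z`, so the
#' product weights remain those of the standard-normal rule (the latent
#' density is absorbed into the transform, never into the integrand). The
#' weighted node mean equals `mean` and the weighted node covariance equals
#' `covariance` exactly for `M >= 2`.
#'
#' Integration in more than three latent dimensions is refused: the grid
#' grows as `M^p` and tensor-product quadrature is no longer practical.
#'
#' @param M points per dimension.
#' @param mean latent mean vector (length `p`).
#' @param covariance symmetric positive definite `p x p` matrix.
#' @return an object of class `lvcrm_grid` with latent-scale `nodes`
#'   (`M^p x p`), `weights`, the standard-normal `std_nodes`, and the
#'   transform used.
#' @examples
#' g <- product_grid(5, c(0, 0), matrix(c(1, .3, .3, 1), 2))
#' colSums(g$weights * g$nodes)  # ~ c(0, 0)
#' @export
product_grid <- function(M, mean = 0, covariance = diag(length(mean))) {
  mean <- as.numeric(mean)
  p <- length(mean)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-10)))
    stop("covariance must be symmetric")
  if (p > 3)
    stop("tensor-product quadrature is limited to p <= 3 latent dimensions")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("covariance must be positive definite")
  rule <- gauss_hermite_rule(M)
  ix <- as.matrix(do.call(expand.grid, rep(list(seq_len(M)), p)))
  std <- matrix(rule$nodes[ix], ncol = p)
  w <- apply(matrix(rule$weights[ix], ncol = p), 1, prod)
  Lt <- chol(covariance)              # upper triangular, cov = t(Lt) %*% Lt
  nodes <- sweep(std %*% Lt, 2, mean, "+")
  structure(list(nodes = nodes, weights = w, std_nodes = std,
                 M = M, p = p, mean = mean, covariance = covariance),
            class = "lvcrm_grid")
}

#' @export
print.lvcrm_grid <- function(x, ...) {
  cat("Gauss-Hermite product grid: M =", x$M, "per dimension, p =", x$p,
      "(", nrow(x$nodes), "nodes )\n")
  wc <- stats::cov.wt(x$nodes, x$weights, method = "ML")
  cat("  covariance reproduction error:",
      format(max(abs(wc$cov - x$covariance)), digits = 3), "\n")
  invisible(x)
}

#' Integrate a function over the latent distribution
#'
#' Computes \eqn{\sum_j \omega_j g(\eta^*_j)} over a [product_grid()].
#'
#' @param g function of a latent vector (length `p`); may also accept the
#'   full node matrix (`vectorized = TRUE`, one value per row).
#' @param grid an `lvcrm_grid`.
#' @param vectorized if `TRUE`, `g` is called once with the node matrix.
#' @return the quadrature approximation of `E[g(eta)]`.
#' @export
quad_integrate <- function(g, grid, vectorized = FALSE) {
  stopifnot(inherits(grid, "lvcrm_grid"))
  vals <- if (vectorized) g(grid$nodes)
  else apply(grid$nodes, 1, function(row) g(row))
  if (any(!is.finite(vals)))
    stop("integrand is not finite at node(s) ",
         paste(utils::head(which(!is.finite(vals)), 5), collapse = ", "))
  sum(grid$weights * vals)
}
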