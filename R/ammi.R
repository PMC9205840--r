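#' AMMI decomposition of a trials x genotypes table
#'
#' Additive main effects and multiplicative interaction model: the complete
#' two-way table is decomposed into the grand mean, environment (trial) and
#' genotype main effects, and a singular value decomposition of the
#' double-centered residual
#' \deqn{y_{ji} = \mu + e_j + g_i + \sum_k \lambda_k u_{jk} v_{ik}}
#' with environment scores \eqn{u_{jk}} and genotype scores \eqn{v_{ik}}.
#' Each singular-vector pair is oriented so that the environment score with
#' the largest magnitude is positive, making the output deterministic across
#' linear-algebra backends.
#'
#' @param x complete numeric matrix, trials in rows, genotypes in columns
#'   (impute first, e.g. with [impute_additive()]).
#' @param K number of multiplicative components to retain
#'   (default `min(dim) - 1`, the full interaction space).
#' @return object of class `ammi_fit`: grand mean `mu`, `env_effects`,
#'   `gen_effects`, singular values `lambda`, `env_scores` (trials x K),
#'   `genotype_scores` (genotypes x K), `interaction` (the double-centered
#'   residual matrix), `K`.
#' @export
fit_ammi <- function(x, K = NULL) {
  x <- as.matrix(x)
  stop_if(anyNA(x), "matrix has missing cells; impute first ",
          "(see impute_additive)")
  stop_if(nrow(x) < 2 || ncol(x) < 2, "need at least a 2 x 2 table")
  kmax <- min(dim(x)) - 1L
  if (is.null(K)) K <- kmax
  stop_if(K < 1 || K > kmax, "K must be in 1..", kmax)
  mu <- mean(x)
  e <- rowMeans(x) - mu
  g <- colMeans(x) - mu
  R <- x - mu - outer(e, rep(1, ncol(x))) - outer(rep(1, nrow(x)), g)
  s <- svd(R)
  lambda <- s$d[seq_len(kmax)]
  U <- s$u[, seq_len(kmax), drop = FALSE]
  V <- s$v[, seq_len(kmax), drop = FALSE]
  for (k in seq_len(kmax)) {       # deterministic sign: max |env score| > 0
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) { U[, k] <- -U[, k]; V[, k] <- -V[, k] }
  }
  dimnames(U) <- list(rownames(x), paste0("AMMI", seq_len(kmax)))
  dimnames(V) <- list(colnames(x), paste0("AMMI", seq_len(kmax)))
  structure(list(mu = mu, env_effects = e, gen_effects = g,
                 lambda = lambda, env_scores = U, genotype_scores = V,
                 interaction = R, K = as.integer(K)),
            class = "ammi_fit")
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat("AMMI fit:", nrow(x$env_scores), "environments x",
      nrow(x$genotype_scores), "genotypes, K =", x$K, "\n")
  ss <- x$lambda^2
  tab <- data.frame(component = seq_along(ss), lambda = x$lambda,
                    ss = ss, pct = 100 * ss / max(sum(ss), .Machine$double.eps))
  print(utils::head(tab, x$K), row.names = FALSE, digits = 4)
  cat("Total interaction SS:", format(sum(ss)), "\n")
  invisible(x)
}

#' Biplot scores from an AMMI fit
#'
#' Under `"genotype"` scaling the genotype scores are singular vector times
#' singular value (\eqn{\lambda_k v_{ik}}) and environment scores are the
#' bare singular vectors, so squared genotype score lengths equal genotype
#' interaction sums of squares.  Under `"symmetric"` scaling both sides get
#' \eqn{\sqrt{\lambda_k}}.
#'
#' @param fit an [fit_ammi()] object.
#' @param scaling `"genotype"` or `"symmetric"`.
#' @param K components to return (default `fit$K`).
#' @return list with matrices `genotypes` and `environments`.
#' @export
biplot_scores <- function(fit, scaling = c("genotype", "symmetric"),
                          K = NULL) {
  stopifnot(inherits(fit, "ammi_fit"))
  scaling <- match.arg(scaling)
  if (is.null(K)) K <- fit$K
  stop_if(K > length(fit$lambda), "K exceeds available components")
  ks <- seq_len(K)
  lam <- fit$lambda[ks]
  U <- fit$env_scores[, ks, drop = FALSE]
  V <- fit$genotype_scores[, ks, drop = FALSE]
  if (scaling == "genotype")
    list(genotypes = V %*% diag(lam, K), environments = U)
  else
    list(genotypes = V %*% diag(sqrt(lam), K),
         environments = U %*% diag(sqrt(lam), K))
}
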