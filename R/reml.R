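#' Weighted REML estimation of variance components
#'
#' Restricted maximum likelihood for linear mixed models of the form
#' \deqn{y = X\beta + \sum_k Z_k u_k + e,\qquad u_k \sim N(0, \sigma^2_k I)}
#' with, optionally, one unstructured random block: genotype-specific
#' effects per group (adaptation zone) with an unstructured group x group
#' covariance \eqn{\Sigma_z}, independent across genotypes.  The residual is
#' either `diag(1/weights)` with the residual scale fixed at 1 — the
#' convention of a two-stage weighted analysis, where the first-stage
#' standard errors carry the within-trial error — or an i.i.d. residual
#' with a free variance when no weights are given.
#'
#' Variances are maximized by L-BFGS-B with analytic gradients
#' (`-0.5 (tr(P A_k) - y'P A_k P y)`) and a lower bound at zero; estimates
#' at the boundary are flagged.  The unstructured block is parameterized by
#' its Cholesky factor (positive semidefinite by construction) and
#' optimized with numerical gradients and multiple seeded restarts.
#' Component standard errors come from the inverse Fisher information
#' \eqn{I_{jk} = tr(P A_j P A_k)/2}.
#'
#' @param data data frame with the response, factor and weight columns.
#' @param response name of the response column.
#' @param fixed character vector of factor columns crossed into the fixed
#'   intercepts (e.g. `c("location", "year")` for per-trial intercepts).
#' @param random list of random terms: each a character vector of factor
#'   columns to cross (e.g. `c("genotype", "location")`), or a numeric
#'   design matrix with n rows.  Term names default to the crossed column
#'   names.
#' @param us_block optional list `list(unit = "genotype", group = "zone")`
#'   requesting the unstructured group-covariance block.
#' @param weights name of a positive weight column, or `NULL` for an
#'   i.i.d. residual with estimated variance.
#' @param n_restarts random restarts for fits with an unstructured block.
#' @param control list: `maxit` (default 400), `reltol` (1e-10), `se`
#'   (compute component standard errors, default TRUE).
#' @return object of class `vc_fit`: `components` (named vector; includes
#'   `residual` when estimated), `se`, `sigma_z` (the unstructured matrix,
#'   if any), `loglik` (restricted), `boundary` (names of components at 0),
#'   `convergence`, `n`, plus internal state for [ranef.vc_fit()].
#' @export
reml_fit <- function(data, response, fixed, random = list(),
                     us_block = NULL, weights = NULL,
                     n_restarts = 3, control = list()) {
  ctrl <- utils::modifyList(list(maxit = 400, reltol = 1e-10, se = TRUE),
                            control)
  y <- data[[response]]
  stop_if(is.null(y), "no column '", response, "'")
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  stop_if(n < 3, "too few observations")

  fixed_f <- interaction(data[fixed], drop = TRUE)
  X <- if (nlevels(fixed_f) < 2) matrix(1, n, 1) else {
    M <- stats::model.matrix(~ 0 + fixed_f)
    colnames(M) <- levels(fixed_f)
    M
  }
  stop_if(qr(X)$rank < ncol(X), "singular fixed-effect design")

  # random-term designs -> symmetric n x n contribution matrices A_k
  Zs <- list()
  for (i in seq_along(random)) {
    r <- random[[i]]
    if (is.matrix(r)) {
      stop_if(nrow(r) != n, "design matrix rows must match observations")
      nm <- names(random)[i] %||% paste0("term", i)
      Zs[[nm]] <- r
    } else {
      f <- interaction(data[r], drop = TRUE)
      stop_if(nlevels(f) < 2, "degenerate random factor: ",
              paste(r, collapse = ":"))
      nm <- if (!is.null(names(random)) && nzchar(names(random)[i]))
        names(random)[i] else paste(r, collapse = ":")
      Z <- stats::model.matrix(~ 0 + f)
      colnames(Z) <- levels(f)
      Zs[[nm]] <- Z
    }
  }
  A <- lapply(Zs, tcrossprod)

  w <- NULL
  if (!is.null(weights)) {
    w <- data[[weights]]
    stop_if(is.null(w) || any(!is.finite(w)) || any(w <= 0),
            "weights must be positive")
  }
  resid_free <- is.null(w)
  R0 <- if (resid_free) matrix(0, n, n) else diag(1 / w)

  # unstructured block: per-group genotype indicators G_z
  Gz <- NULL; kz <- 0L
  if (!is.null(us_block)) {
    uf <- factor(data[[us_block$unit]])
    gf <- factor(data[[us_block$group]])
    kz <- nlevels(gf)
    stop_if(kz < 2, "unstructured block needs >= 2 groups")
    Zu <- stats::model.matrix(~ 0 + uf)
    colnames(Zu) <- levels(uf)
    Gz <- lapply(levels(gf), function(g) Zu * (gf == g))
    names(Gz) <- levels(gf)
    grp_tab <- table(gf, uf)
  }

  # work on a standardized response so the optimizer is well conditioned
  s2 <- stats::var(stats::resid(stats::lm.fit(X, y)))
  if (!is.finite(s2) || s2 <= 0) s2 <- stats::var(y) + 1e-8
  ys <- y / sqrt(s2)
  R0s <- if (resid_free) R0 else R0 / s2   # diag(1/w)/s2: fixed part

  k_iid <- length(A) + as.integer(resid_free)
  nms <- c(names(A), if (resid_free) "residual")
  Afull <- c(A, if (resid_free) list(residual = diag(n)))

  build_V <- function(v_iid, Lmat = NULL) {
    V <- R0s
    for (k in seq_along(Afull)) V <- V + v_iid[k] * Afull[[k]]
    if (!is.null(Lmat)) {
      # V_us = sum_c H_c H_c' with H_c = sum_z L[z,c] G_z  (Sigma = LL')
      for (cc in seq_len(kz)) {
        H <- 0
        for (z in seq_len(kz)) if (Lmat[z, cc] != 0)
          H <- H + Lmat[z, cc] * Gz[[z]]
        if (!identical(H, 0)) V <- V + tcrossprod(H)
      }
    }
    V
  }

  # restricted log-likelihood (cheap, no P) and full version (with the
  # projection matrix P, needed for gradients, BLUPs and information)
  remll_value <- function(V) {
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Liy <- forwardsolve(t(cV), ys)
    LiX <- forwardsolve(t(cV), X)
    XtViX <- crossprod(LiX)
    cX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    b <- forwardsolve(t(cX), crossprod(LiX, Liy))
    -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
              sum(Liy^2) - sum(b^2))
  }
  remll <- function(V) {
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    cX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    P <- Vi - ViX %*% chol2inv(cX) %*% t(ViX)
    Py <- P %*% ys
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                    sum(ys * Py))
    list(ll = ll, P = P, Py = Py)
  }

  if (is.null(us_block)) {
    # ---- analytic-gradient path (iid components only) ----------------
    env <- new.env()
    eval_at <- function(v) {
      if (!is.null(env$v) && identical(env$v, v)) return(env$res)
      res <- remll(build_V(v))
      env$v <- v; env$res <- res
      res
    }
    fn <- function(v) {
      r <- eval_at(v)
      if (is.null(r) || !is.finite(r$ll)) return(1e10)
      -r$ll
    }
    gr <- function(v) {
      r <- eval_at(v)
      if (is.null(r)) return(rep(0, length(v)))
      vapply(Afull, function(Ak)
        0.5 * (sum(r$P * Ak) - sum(r$Py * (Ak %*% r$Py))), 0)
    }
    start <- rep(if (resid_free) 0.5 else 0.3, k_iid)
    opt <- stats::optim(start, fn, gr, method = "L-BFGS-B",
                        lower = rep(0, k_iid),
                        control = list(maxit = ctrl$maxit,
                                       factr = ctrl$reltol / 1e-15))
    if (opt$convergence > 1) {
      # line-search breakdowns near the optimum: polish without gradients
      # (Nelder-Mead respects the bound via the penalty in fn)
      fn_pos <- function(v) if (any(v < 0)) 1e10 else fn(v)
      opt2 <- stats::optim(pmax(opt$par, 0), fn_pos, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-12))
      if (opt2$value <= opt$value + 1e-6) {
        opt2$par <- pmax(opt2$par, 0)
        opt <- opt2
      }
    }
    stop_if(opt$convergence > 1,
            "REML did not converge (code ", opt$convergence, ": ",
            opt$message, "; ", opt$counts[1], " evaluations)")
    v_hat <- opt$par
    L_hat <- NULL
    final <- remll(build_V(v_hat))
  } else {
    # ---- unstructured block: analytic gradients, seeded restarts -----
    # iid variances on log scale (positivity); Sigma_z = L L' via its
    # Cholesky factor, unconstrained.  Gradient of -loglik wrt L is
    # (T - Q) L, where T[z,z'] = tr(P G_z G_{z'}') and
    # Q[z,z'] = (G_z'Py) . (G_{z'}'Py).
    lt <- which(lower.tri(diag(kz), diag = TRUE))
    nL <- length(lt)
    make_L <- function(th) { M <- matrix(0, kz, kz); M[lt] <- th; M }
    env <- new.env()
    eval_full <- function(par) {
      if (!is.null(env$par) && identical(env$par, par)) return(env$res)
      v <- exp(par[seq_len(k_iid)])
      Lmat <- make_L(par[-seq_len(k_iid)])
      r <- remll(build_V(v, Lmat))
      res <- if (is.null(r) || !is.finite(r$ll)) NULL else
        c(r, list(v = v, Lmat = Lmat))
      env$par <- par; env$res <- res
      res
    }
    fn <- function(par) {
      v <- exp(par[seq_len(k_iid)])
      ll <- remll_value(build_V(v, make_L(par[-seq_len(k_iid)])))
      if (is.null(ll) || !is.finite(ll)) 1e10 else -ll
    }
    gr <- function(par) {
      r <- eval_full(par)
      if (is.null(r)) return(rep(0, length(par)))
      g_iid <- vapply(seq_along(Afull), function(k)
        r$v[k] * 0.5 * (sum(r$P * Afull[[k]]) -
                          sum(r$Py * (Afull[[k]] %*% r$Py))), 0)
      a <- vapply(Gz, function(G) drop(crossprod(G, r$Py)),
                  numeric(ncol(Gz[[1]])))
      Q <- crossprod(a)
      Tm <- matrix(0, kz, kz)
      for (z in seq_len(kz)) {
        Cz <- r$P %*% Gz[[z]]
        for (zp in seq_len(kz)) Tm[z, zp] <- sum(Gz[[zp]] * Cz)
      }
      GL <- (Tm - Q) %*% r$Lmat
      c(g_iid, GL[lt])
    }
    best <- NULL
    for (rs in seq_len(max(1, n_restarts))) {
      L0 <- diag(0.3 + 0.2 * (rs - 1), kz)
      st <- c(log(rep(0.3, k_iid)),
              L0[lt] + stats::rnorm(nL, 0, 0.02 * (rs > 1)))
      o <- tryCatch(stats::optim(st, fn, gr, method = "BFGS",
                                 control = list(maxit = ctrl$maxit,
                                                reltol = 1e-10)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    stop_if(is.null(best), "REML with unstructured block failed")
    opt <- best
    v_hat <- exp(opt$par[seq_len(k_iid)])
    L_hat <- make_L(opt$par[-seq_len(k_iid)])
    final <- remll(build_V(v_hat, L_hat))
  }

  # back to the original response scale
  comps <- stats::setNames(v_hat * s2, nms)
  sigma_z <- if (!is.null(L_hat)) tcrossprod(L_hat) * s2 else NULL
  if (!is.null(sigma_z)) dimnames(sigma_z) <- list(names(Gz), names(Gz))
  boundary <- nms[v_hat < 1e-8]
  comps[v_hat < 1e-8] <- 0

  se <- rep(NA_real_, length(comps))
  if (ctrl$se && is.null(us_block) && length(Afull)) {
    M <- lapply(Afull, function(Ak) final$P %*% Ak)
    info <- matrix(0, k_iid, k_iid)
    for (j in seq_len(k_iid)) for (k in j:k_iid)
      info[j, k] <- info[k, j] <- 0.5 * sum(M[[j]] * t(M[[k]]))
    cv <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0)) * s2
  }
  names(se) <- nms

  # restricted log-likelihood on the original scale (with the 2*pi term,
  # so it is directly comparable with other software)
  ll <- final$ll - 0.5 * (n - ncol(X)) * (log(s2) + log(2 * pi))

  structure(list(components = comps, se = se, sigma_z = sigma_z,
                 loglik = ll, boundary = boundary,
                 convergence = opt$convergence, n = n,
                 model = "custom",
                 .state = list(ys = ys, s2 = s2, Py = final$Py, Zs = Zs,
                               v_hat = v_hat, L_hat = L_hat, Gz = Gz,
                               us_block = us_block)),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("Weighted REML fit (", x$model, "), n = ", x$n, "\n", sep = "")
  tab <- data.frame(component = names(x$components),
                    estimate = unname(x$components),
                    se = unname(x$se))
  print(tab, row.names = FALSE, digits = 5)
  if (!is.null(x$sigma_z)) {
    cat("Unstructured group covariance:\n")
    print(round(x$sigma_z, 2))
  }
  if (length(x$boundary))
    cat("At boundary:", paste(x$boundary, collapse = ", "), "\n")
  cat("Restricted log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' @export
summary.vc_fit <- function(object, ...) {
  object
}

#' Random-effect BLUPs from a REML fit
#'
#' Empirical best linear unbiased predictions \eqn{\hat u_k = \sigma^2_k
#' Z_k' P y} for an i.i.d. term, or \eqn{(\mathrm{I} \otimes \Sigma_z) Z' P
#' y} for the unstructured block.
#'
#' @param fit a [reml_fit()] object.
#' @param term component name, or `"us"` for the unstructured block.
#' @return named vector of BLUPs (for `"us"`: a unit x group matrix).
#' @export
ranef_vc <- function(fit, term) {
  stopifnot(inherits(fit, "vc_fit"))
  st <- fit$.state
  if (identical(term, "us")) {
    stop_if(is.null(st$Gz), "fit has no unstructured block")
    S <- tcrossprod(st$L_hat)
    a <- vapply(st$Gz, function(G) drop(crossprod(G, st$Py)),
                numeric(ncol(st$Gz[[1]])))   # units x groups
    u <- a %*% S * sqrt(st$s2)               # back to the response scale
    dimnames(u) <- list(colnames(st$Gz[[1]]), names(st$Gz))
    return(u)
  }
  k <- match(term, names(st$Zs))
  stop_if(is.na(k), "unknown term '", term, "'")
  Z <- st$Zs[[k]]
  u <- st$v_hat[k] * drop(crossprod(Z, st$Py)) * sqrt(st$s2)
  stats::setNames(u, colnames(Z))
}
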