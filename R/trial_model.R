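#' Per-trial spatial mixed model for adjusted genotype means
#'
#' Fits, by REML, the single-trial row-column model
#' \deqn{y_{irc} = \mu + R_r + C_c + G_i + e_{irc}}
#' with fixed genotype effects, independent random row and column effects
#' (variances \eqn{\sigma^2_r}, \eqn{\sigma^2_c}) and a residual with
#' separable first-order autoregressive (AR1xAR1) correlation along rows and
#' columns, and returns generalized-least-squares adjusted genotype means
#' (BLUEs) with their standard errors and weights \eqn{1/SE^2}.
#'
#' Variance parameters are optimized on an unconstrained scale
#' (log-variances, atanh-correlations) so the restricted likelihood stays
#' smooth near boundaries; variance estimates below 1e-10 are reported as 0
#' and flagged as boundary.  Plots with missing response are dropped and the
#' AR1 correlations are computed from the observed row/column coordinates by
#' distance-powered correlation.  Supplying `varcomp` skips estimation and
#' computes the GLS solution at the given parameter values.
#'
#' @param plots data frame with columns `genotype`, `row`, `col` and the
#'   response named by `trait`.
#' @param trait name of the response column.
#' @param random_rowcol include random row and column main effects.
#' @param spatial estimate AR1 correlations (otherwise fixed at 0, i.e.
#'   independent residuals).
#' @param nugget add an independent measurement-error variance on top of the
#'   spatially correlated residual.
#' @param varcomp optional named list/vector (`var_row`, `var_col`,
#'   `var_plot`, `rho_row`, `rho_col`, optionally `var_nugget`) of fixed
#'   variance parameters; skips REML.
#' @param control list: `maxit` (default 200) and `reltol` (default 1e-8)
#'   for the optimizer.
#' @return object of class `trial_fit`: list with `blues` (genotype, blue,
#'   se, weight), `varcomp`, `boundary` flags, `loglik` (restricted),
#'   `convergence`, `n_plots`.
#' @export
fit_trial_model <- function(plots, trait = "value", random_rowcol = TRUE,
                            spatial = TRUE, nugget = FALSE, varcomp = NULL,
                            control = list()) {
  need <- c("genotype", "row", "col", trait)
  stop_if(!all(need %in% names(plots)),
          "plots needs columns: ", paste(need, collapse = ", "))
  plots <- plots[!is.na(plots[[trait]]), , drop = FALSE]
  stop_if(nrow(plots) < 3, "too few observed plots")
  stop_if(anyDuplicated(plots[c("row", "col")]) > 0,
          "duplicate plot coordinates")
  all_gen <- unique(as.character(plots$genotype))
  stop_if(length(all_gen) < 2, "need >= 2 genotypes")

  y <- plots[[trait]]
  n <- length(y)
  gf <- factor(plots$genotype)
  X <- stats::model.matrix(~ 0 + gf)
  colnames(X) <- levels(gf)
  r <- as.integer(plots$row); cc <- as.integer(plots$col)
  Zr <- outer(r, r, "==") * 1
  Zc <- outer(cc, cc, "==") * 1
  dr <- abs(outer(r, r, "-")); dc <- abs(outer(cc, cc, "-"))

  ctrl <- utils::modifyList(list(maxit = 200, reltol = 1e-8), control)

  build_V <- function(vr, vc, ve, rr, rc, vn = 0) {
    V <- ve * (rr^dr) * (rc^dc)
    if (random_rowcol) V <- V + vr * Zr + vc * Zc
    if (nugget) V <- V + diag(vn, n)
    V
  }
  gls <- function(V) {
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    XtViX <- crossprod(X, Vi_X)
    cX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    beta <- backsolve(cX, forwardsolve(t(cX), crossprod(X, Vi_y)))
    Cb <- chol2inv(cX)
    resid <- y - X %*% beta
    Vi_r <- backsolve(cV, forwardsolve(t(cV), resid))
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                    sum(resid * Vi_r) + (n - ncol(X)) * log(2 * pi))
    list(beta = drop(beta), se = sqrt(diag(Cb)), loglik = ll)
  }

  if (is.null(varcomp)) {
    ve0 <- stats::var(stats::resid(stats::lm(y ~ gf)))
    if (!is.finite(ve0) || ve0 <= 0) ve0 <- stats::var(y) + 1e-8
    par <- c(log(0.1 * ve0), log(0.1 * ve0), log(ve0), 0, 0)
    if (nugget) par <- c(par, log(0.1 * ve0))
    free <- c(random_rowcol, random_rowcol, TRUE, spatial, spatial,
              if (nugget) TRUE)
    p0 <- par
    negll <- function(th) {
      p <- p0; p[free] <- th
      V <- build_V(exp(p[1]), exp(p[2]), exp(p[3]),
                   tanh(p[4]), tanh(p[5]), if (nugget) exp(p[6]) else 0)
      g <- gls(V)
      if (is.null(g) || !is.finite(g$loglik)) return(1e10)
      -g$loglik
    }
    opt <- stats::optim(par[free], negll, method = "Nelder-Mead",
                        control = list(maxit = ctrl$maxit * 10,
                                       reltol = ctrl$reltol))
    opt <- stats::optim(opt$par, negll, method = "BFGS",
                        control = list(maxit = ctrl$maxit,
                                       reltol = ctrl$reltol))
    stop_if(opt$convergence != 0 && opt$convergence != 1,
            "trial model did not converge (optim code ", opt$convergence,
            ", ", opt$counts[1], " evaluations, nll ", signif(opt$value, 8),
            ")")
    p <- p0; p[free] <- opt$par
    vc <- c(var_row = if (random_rowcol) exp(p[1]) else 0,
            var_col = if (random_rowcol) exp(p[2]) else 0,
            var_plot = exp(p[3]),
            rho_row = if (spatial) tanh(p[4]) else 0,
            rho_col = if (spatial) tanh(p[5]) else 0)
    if (nugget) vc["var_nugget"] <- exp(p[6])
    conv <- TRUE
  } else {
    vc <- unlist(varcomp)
    for (nm in c("var_row", "var_col", "rho_row", "rho_col", "var_nugget"))
      if (!nm %in% names(vc)) vc[nm] <- 0
    stop_if(!"var_plot" %in% names(vc), "varcomp needs var_plot")
    conv <- NA
  }

  boundary <- names(vc)[grepl("^var", names(vc)) & vc < 1e-10]
  vc[grepl("^var", names(vc)) & vc < 1e-10] <- 0
  V <- build_V(vc["var_row"], vc["var_col"], vc["var_plot"],
               vc["rho_row"], vc["rho_col"],
               if ("var_nugget" %in% names(vc)) vc["var_nugget"] else 0)
  if (all(V == 0)) V <- diag(1e-12, n)   # degenerate: no noise at all
  g <- gls(V)
  stop_if(is.null(g), "variance parameters give a singular covariance")

  omitted <- setdiff(all_gen, levels(gf))
  if (length(omitted))
    warning("genotypes omitted (no observed plots): ",
            paste(omitted, collapse = ", "))
  blues <- data.frame(genotype = colnames(X), blue = g$beta, se = g$se,
                      weight = 1 / g$se^2, stringsAsFactors = FALSE)
  rownames(blues) <- NULL
  structure(list(blues = blues, varcomp = vc, boundary = boundary,
                 loglik = g$loglik, convergence = conv, n_plots = n),
            class = "trial_fit")
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("Single-trial spatial model (", x$n_plots, " plots, ",
      nrow(x$blues), " genotypes)\n", sep = "")
  cat("Variance parameters:\n")
  print(round(x$varcomp, 4))
  if (length(x$boundary))
    cat("At boundary:", paste(x$boundary, collapse = ", "), "\n")
  cat("Restricted log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' @export
coef.trial_fit <- function(object, ...) {
  stats::setNames(object$blues$blue, object$blues$genotype)
}

#' Adjusted genotype means for every trial in a network
#'
#' Applies [fit_trial_model()] to each trial of a plot-level table and
#' concatenates the per-trial BLUEs.  Per-trial failures are recorded as
#' flagged rows rather than aborting the batch.
#'
#' @param plots plot table with a `trial` column plus the columns required
#'   by [fit_trial_model()].
#' @param trait response column name.
#' @param ... passed to [fit_trial_model()].
#' @return data frame (trial, genotype, blue, se, weight, ok); failed trials
#'   contribute a single row with `ok = FALSE` and NA estimates.  The error
#'   messages are kept in `attr(, "failures")`.
#' @export
blues_for_network <- function(plots, trait = "value", ...) {
  stop_if(!"trial" %in% names(plots), "plots needs a trial column")
  ids <- unique(as.character(plots$trial))
  stop_if(length(ids) < 1, "no trials")
  failures <- character()
  out <- lapply(ids, function(id) {
    sub <- plots[plots$trial == id, , drop = FALSE]
    fit <- tryCatch(fit_trial_model(sub, trait = trait, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[id]] <<- conditionMessage(fit)
      return(data.frame(trial = id, genotype = NA_character_,
                        blue = NA_real_, se = NA_real_, weight = NA_real_,
                        ok = FALSE, stringsAsFactors = FALSE))
    }
    cbind(trial = id, fit$blues, ok = TRUE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
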