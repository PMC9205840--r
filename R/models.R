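#' G x E variance-component models for a trial network
#'
#' Wrappers binding the standard term structures to [reml_fit()], all with
#' per-trial fixed intercepts and the two-stage weighted-residual
#' convention (residual = `diag(1/weight)`, scale fixed at 1):
#'
#' * `fit_model2()`: genotype main effect plus the G x E decomposition into
#'   genotype-by-location, genotype-by-year and
#'   genotype-by-location-by-year components.
#' * `fit_model4()`: the two-way reference model without zones — genotype
#'   main effect plus genotype-by-trial interaction.
#' * `fit_model5()`: genotype-by-zone effects with an unstructured zone
#'   covariance (borrowing information between zones) plus residual
#'   genotype-by-trial interaction within zones.
#' * `fit_model6()`: the full selection-response decomposition — G, G x Z,
#'   G x L(Z), G x Y, G x Z x Y, G x L(Z) x Y.
#'
#' @param data trial-network table with columns `genotype`, `location`,
#'   `year` (and `zone` where needed), the response and the weight.
#' @param response,weights column names (weights may be `NULL` for an
#'   estimated i.i.d. residual).
#' @param zone name of the zone column (models 5 and 6).
#' @param ... passed to [reml_fit()].
#' @return a `vc_fit` (see [reml_fit()]) with `model` set.
#' @name gxe_models
NULL

check_zone <- function(data, zone) {
  stop_if(!zone %in% names(data), "no column '", zone, "'")
  nl <- rowSums(table(data[[zone]], data$location) > 0)
  if (any(nl < 2))
    warning("zone(s) with < 2 locations: ",
            paste(names(nl)[nl < 2], collapse = ", "),
            " (components weakly identified)")
}

#' @rdname gxe_models
#' @export
fit_model2 <- function(data, response = "yield", weights = "weight", ...) {
  fit <- reml_fit(data, response, fixed = c("location", "year"),
                  random = list(G = "genotype",
                                GL = c("genotype", "location"),
                                GY = c("genotype", "year"),
                                GLY = c("genotype", "location", "year")),
                  weights = weights, ...)
  fit$model <- "model2"
  fit
}

#' @rdname gxe_models
#' @export
fit_model4 <- function(data, response = "yield", weights = "weight", ...) {
  data$trial_f <- interaction(data$location, data$year, drop = TRUE)
  fit <- reml_fit(data, response, fixed = "trial_f",
                  random = list(G = "genotype",
                                GE = c("genotype", "trial_f")),
                  weights = weights, ...)
  fit$model <- "model4"
  fit
}

#' @rdname gxe_models
#' @export
fit_model5 <- function(data, response = "yield", weights = "weight",
                       zone = "zone", ...) {
  check_zone(data, zone)
  data$trial_f <- interaction(data$location, data$year, drop = TRUE)
  data$zone_f <- factor(data[[zone]])
  fit <- reml_fit(data, response, fixed = "trial_f",
                  random = list(GE = c("genotype", "trial_f")),
                  us_block = list(unit = "genotype", group = "zone_f"),
                  weights = weights, ...)
  fit$model <- "model5"
  fit
}

#' @rdname gxe_models
#' @export
fit_model6 <- function(data, response = "yield", weights = "weight",
                       zone = "zone", ...) {
  check_zone(data, zone)
  fit <- reml_fit(data, response, fixed = c("location", "year"),
                  random = list(G = "genotype",
                                GZ = c("genotype", zone),
                                `GL(Z)` = c("genotype", "location"),
                                GY = c("genotype", "year"),
                                GZY = c("genotype", zone, "year"),
                                `GL(Z)Y` = c("genotype", "location", "year")),
                  weights = weights, ...)
  fit$model <- "model6"
  fit
}

#' Percent of G x E by source
#'
#' Shares (in percent, 2 decimals) of the genotype-by-year,
#' genotype-by-location and genotype-by-location-by-year components in the
#' total G x E variance of a two-way decomposition.
#'
#' @param fit a `fit_model2()` result, or a named numeric vector with
#'   elements `GY`, `GL`, `GLY`.
#' @return named numeric vector (GY, GL, GLY) summing to 100 within
#'   rounding, or NA if the total is zero.
#' @export
percent_gxe <- function(fit) {
  comps <- if (inherits(fit, "vc_fit")) fit$components else fit
  stop_if(!all(c("GY", "GL", "GLY") %in% names(comps)),
          "need components GY, GL, GLY")
  v <- comps[c("GY", "GL", "GLY")]
  tot <- sum(v)
  if (tot == 0) return(stats::setNames(rep(NA_real_, 3), names(v)))
  round(100 * v / tot, 2)
}

#' Share of G x L captured by adaptation zones
#'
#' GZ / (GZ + GL(Z)) from a zone-nested decomposition: the fraction of the
#' genotype-by-location variance explained by genotype-by-zone effects.
#' Truncated (floored) at 2 decimals, the convention used when reporting
#' such shares.
#'
#' @param fit a `fit_model6()` result, or a named numeric vector with
#'   elements `GZ` and `GL(Z)`.
#' @return the truncated ratio in [0, 1], or NA if both components are 0.
#' @export
gz_share <- function(fit) {
  comps <- if (inherits(fit, "vc_fit")) fit$components else fit
  stop_if(!all(c("GZ", "GL(Z)") %in% names(comps)),
          "need components GZ and GL(Z)")
  gz <- comps[["GZ"]]; glz <- comps[["GL(Z)"]]
  if (gz + glz == 0) return(NA_real_)
  trunc(100 * gz / (gz + glz)) / 100
}

# Model 3: random genotype intercept + random genotype slope on a scaled
# covariable; residual variance free (unweighted single-stage analysis)
fit_model3 <- function(data, response, z, extra_slopes = list(), ...) {
  gf <- factor(data$genotype)
  Zg <- stats::model.matrix(~ 0 + gf)
  random <- list(G = "genotype", slope = Zg * z)
  if (length(extra_slopes))
    for (nm in names(extra_slopes))
      random[[nm]] <- Zg * extra_slopes[[nm]]
  data$trial_f <- interaction(data$location, data$year, drop = TRUE)
  reml_fit(data, response, fixed = "trial_f", random = random,
           weights = NULL, ...)
}

#' Scan environmental covariables by factorial regression
#'
#' Fits, for each covariable, a random-coefficient model with a random
#' genotype intercept and a random genotype slope on the (unit-variance
#' scaled) covariable, and tests the slope variance against the no-slope
#' null with a likelihood-ratio test on the 50:50 mixture
#' \eqn{\chi^2_0/\chi^2_1} reference (the component is tested on its
#' boundary).  Covariables are ranked by residual variance.
#'
#' @param data trial-network table (columns `genotype`, `location`, `year`,
#'   response); covariable rows must align with `data` rows.
#' @param covariables data frame or matrix of genotype-by-trial covariable
#'   values, one column per covariable, rows aligned with `data`.
#' @param response response column name.
#' @param extra_slopes named list of already-selected covariable vectors to
#'   condition on (used by [forward_select()]).
#' @param ... passed to [reml_fit()].
#' @return data frame (one row per covariable): `covariable`,
#'   `slope_var`, `resid_var`, `lrt`, `p`, ordered by residual variance.
#'   Constant covariables are skipped with a warning.
#' @export
factorial_regression_scan <- function(data, covariables, response = "yield",
                                      extra_slopes = list(), ...) {
  covariables <- as.data.frame(covariables)
  stop_if(ncol(covariables) < 1, "need at least one covariable")
  stop_if(nrow(covariables) != nrow(data),
          "covariable rows must align with data rows")
  null_fit <- fit_model3(data, response, z = rep(0, nrow(data)),
                         extra_slopes = extra_slopes, ...)
  # a zero slope column is dropped implicitly: its A matrix is 0
  out <- lapply(names(covariables), function(nm) {
    z <- covariables[[nm]]
    if (stats::sd(z, na.rm = TRUE) == 0 || anyNA(z)) {
      warning("skipping constant or incomplete covariable: ", nm)
      return(NULL)
    }
    z <- as.numeric(scale(z))
    fit <- fit_model3(data, response, z = z, extra_slopes = extra_slopes,
                      ...)
    lrt <- max(0, 2 * (fit$loglik - null_fit$loglik))
    data.frame(covariable = nm,
               slope_var = unname(fit$components["slope"]),
               resid_var = unname(fit$components["residual"]),
               lrt = lrt,
               p = 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  stop_if(is.null(out), "no usable covariables")
  out[order(out$resid_var), , drop = FALSE]
}

#' Forward selection of environmental covariables
#'
#' Repeatedly scans the remaining covariables with
#' [factorial_regression_scan()], conditioning on the slopes already
#' selected, and adds the covariable with the smallest residual variance
#' among those passing the mixture likelihood-ratio test, until none
#' passes.
#'
#' @inheritParams factorial_regression_scan
#' @param alpha significance threshold for the mixture LRT (default 0.05).
#' @param max_steps safety cap on the number of selected covariables.
#' @return character vector of selected covariable names, in selection
#'   order, with the final scan table in `attr(, "scans")`.
#' @export
forward_select <- function(data, covariables, response = "yield",
                           alpha = 0.05, max_steps = ncol(covariables),
                           ...) {
  covariables <- as.data.frame(covariables)
  selected <- character()
  slopes <- list()
  scans <- list()
  repeat {
    remaining <- setdiff(names(covariables), selected)
    if (!length(remaining) || length(selected) >= max_steps) break
    sc <- factorial_regression_scan(data, covariables[remaining],
                                    response, extra_slopes = slopes, ...)
    scans[[length(scans) + 1L]] <- sc
    ok <- sc[sc$p < alpha, , drop = FALSE]
    if (!nrow(ok)) break
    pick <- ok$covariable[1]
    selected <- c(selected, pick)
    slopes[[pick]] <- as.numeric(scale(covariables[[pick]]))
  }
  attr(selected, "scans") <- scans
  selected
}

#' Leave-one-year-out cross-validation of zone models
#'
#' For each held-out year, fits the genotype-main-effect benchmark
#' (model 4) and the zone model (model 5) on the remaining years and
#' predicts the held-out trials: model 4 predicts the genotype main-effect
#' BLUP, model 5 the zone-specific genotype BLUP of the trial's zone.  The
#' accuracy of a trial is the Pearson correlation between predictions and
#' its observed values across genotypes (NA for trials with fewer than 3
#' observed genotypes or constant predictions).
#'
#' @param data trial-network table (columns `genotype`, `location`, `year`,
#'   `zone`, response, weight).
#' @param response,weights,zone column names.
#' @param ... passed to the model fitters.
#' @return object of class `loyo_cv`: `trials` (trial, year, zone,
#'   accuracy_main, accuracy_zone, n_genotypes), `zone_means`, and overall
#'   means.
#' @export
loyo_cv <- function(data, response = "yield", weights = "weight",
                    zone = "zone", ...) {
  years <- sort(unique(as.character(data$year)))
  stop_if(length(years) < 2, "need >= 2 years")
  data$trial_id <- paste(data$location, data$year, sep = ".")
  rows <- list()
  for (yr in years) {
    train <- data[data$year != yr, , drop = FALSE]
    test <- data[data$year == yr, , drop = FALSE]
    m4 <- fit_model4(train, response, weights, ...)
    m5 <- fit_model5(train, response, weights, zone = zone, ...)
    g_blup <- ranef_vc(m4, "G")
    gz_blup <- ranef_vc(m5, "us")
    for (tid in unique(test$trial_id)) {
      tt <- test[test$trial_id == tid & !is.na(test[[response]]), ]
      zn <- as.character(tt[[zone]][1])
      p4 <- unname(g_blup[as.character(tt$genotype)])
      p5 <- if (zn %in% colnames(gz_blup))
        unname(gz_blup[as.character(tt$genotype), zn]) else
          rep(NA_real_, nrow(tt))
      acc <- function(p) {
        if (nrow(tt) < 3 || anyNA(p) || stats::sd(p) == 0 ||
              stats::sd(tt[[response]]) == 0) return(NA_real_)
        stats::cor(p, tt[[response]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tid, year = yr, zone = zn,
        accuracy_main = acc(p4), accuracy_zone = acc(p5),
        n_genotypes = nrow(tt), stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  zone_means <- stats::aggregate(
    trials[c("accuracy_main", "accuracy_zone")],
    by = list(zone = trials$zone), FUN = mean, na.rm = TRUE)
  structure(list(trials = trials, zone_means = zone_means,
                 mean_main = mean(trials$accuracy_main, na.rm = TRUE),
                 mean_zone = mean(trials$accuracy_zone, na.rm = TRUE)),
            class = "loyo_cv")
}

#' @export
print.loyo_cv <- function(x, ...) {
  cat("Leave-one-year-out cross-validation over", nrow(x$trials),
      "trials\n")
  cat("Mean accuracy, genotype-main model:",
      format(x$mean_main, digits = 3),
      "| zone model:", format(x$mean_zone, digits = 3), "\n")
  print(x$zone_means, row.names = FALSE, digits = 3)
  invisible(x)
}
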