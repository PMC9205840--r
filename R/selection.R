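#' Inputs for the correlated-vs-direct response comparison
#'
#' Bundles the six variance components of the zone-nested decomposition
#' with the design constants: the median numbers of locations per zone
#' (`nl`), years (`ny`) and zones (`nz`) in which genotypes were present.
#'
#' @param var_g,var_gz,var_glz,var_gy,var_gzy,var_glzy variance components
#'   for G, GxZ, GxL(Z), GxY, GxZxY, GxL(Z)xY (trait units squared).
#' @param nl,ny,nz design constants (>= 1).
#' @return object of class `selection_inputs`.
#' @export
selection_inputs <- function(var_g, var_gz, var_glz, var_gy, var_gzy,
                             var_glzy, nl, ny, nz) {
  v <- c(var_g = var_g, var_gz = var_gz, var_glz = var_glz,
         var_gy = var_gy, var_gzy = var_gzy, var_glzy = var_glzy)
  stop_if(any(!is.finite(v)) || any(v < 0), "variances must be >= 0")
  stop_if(any(c(nl, ny, nz) < 1), "nl, ny, nz must be >= 1")
  structure(list(var_g = var_g, var_gz = var_gz, var_glz = var_glz,
                 var_gy = var_gy, var_gzy = var_gzy, var_glzy = var_glzy,
                 nl = nl, ny = ny, nz = nz),
            class = "selection_inputs")
}

#' Genetic correlation between undivided and zone-level response
#'
#' \deqn{\rho_g = \sigma^2_g / \sqrt{\sigma^2_g (\sigma^2_g +
#' \sigma^2_{gz})}}
#' The correlation between a genotype's performance averaged over the
#' undivided set of environments and its performance within a zone; equal
#' to 1 when there is no genotype-by-zone interaction.
#'
#' @param var_g,var_gz genotype main and genotype-by-zone variances.
#' @return the correlation in (0, 1]; NA if `var_g` is 0.
#' @export
genetic_correlation <- function(var_g, var_gz) {
  stop_if(var_g < 0 || var_gz < 0, "variances must be >= 0")
  if (var_g == 0) return(NA_real_)
  var_g / sqrt(var_g * (var_g + var_gz))
}

#' Heritability of genotype means, undivided or divided
#'
#' Line-mean repeatability for selection across the undivided target
#' population of environments
#' \deqn{H^2_{U} = \sigma^2_g \Big/ \Big(\sigma^2_g +
#'   \tfrac{\sigma^2_{gz}}{nz} + \tfrac{\sigma^2_{gl(z)}}{nl\,nz} +
#'   \tfrac{\sigma^2_{gy}}{ny} + \tfrac{\sigma^2_{gzy}}{ny\,nz} +
#'   \tfrac{\sigma^2_{gl(z)y}}{nl\,nz\,ny}\Big)}
#' or within zones (divided), where the genotype-by-zone variance joins
#' the genetic signal:
#' \deqn{H^2_{D} = (\sigma^2_g + \sigma^2_{gz}) \Big/
#'   \Big(\sigma^2_g + \sigma^2_{gz} + \tfrac{\sigma^2_{gl(z)}}{nl} +
#'   \tfrac{\sigma^2_{gy}}{ny} + \tfrac{\sigma^2_{gzy}}{ny} +
#'   \tfrac{\sigma^2_{gl(z)y}}{nl\,ny}\Big)}
#'
#' @param inputs a [selection_inputs()] object.
#' @param divided `TRUE` for the within-zone (divided) heritability.
#' @return heritability in [0, 1].
#' @export
heritability <- function(inputs, divided = FALSE) {
  stopifnot(inherits(inputs, "selection_inputs"))
  with(inputs, {
    if (divided) {
      (var_g + var_gz) /
        (var_g + var_gz + var_glz / nl + var_gy / ny + var_gzy / ny +
           var_glzy / (nl * ny))
    } else {
      var_g /
        (var_g + var_gz / nz + var_glz / (nl * nz) + var_gy / ny +
           var_gzy / (ny * nz) + var_glzy / (nl * nz * ny))
    }
  })
}

#' Correlated vs. direct response to selection
#'
#' \deqn{CR/DR = \rho_g \sqrt{H^2_{Undivided} / H^2_{Divided}}}
#' Ratios below 1 indicate a larger response when selecting within
#' adaptation zones, so subdividing the target population of environments
#' pays off; ratios above 1 favour selection across the undivided set.
#'
#' @param inputs a [selection_inputs()] object.
#' @return object of class `selection_summary`: `rho_g`, `h2_undivided`,
#'   `h2_divided`, `cr_dr`, and the inputs.
#' @export
cr_dr <- function(inputs) {
  stopifnot(inherits(inputs, "selection_inputs"))
  rho <- genetic_correlation(inputs$var_g, inputs$var_gz)
  h2u <- heritability(inputs, divided = FALSE)
  h2d <- heritability(inputs, divided = TRUE)
  structure(list(rho_g = rho, h2_undivided = h2u, h2_divided = h2d,
                 cr_dr = rho * sqrt(h2u / h2d), inputs = inputs),
            class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("Correlated vs. direct response to selection\n")
  cat(sprintf("  rho_g          %.5f\n", x$rho_g))
  cat(sprintf("  H2 (undivided) %.5f\n", x$h2_undivided))
  cat(sprintf("  H2 (divided)   %.5f\n", x$h2_divided))
  cat(sprintf("  CR/DR          %.5f\n", x$cr_dr))
  cat(if (is.na(x$cr_dr)) "" else if (x$cr_dr < 1)
    "  CR/DR < 1: subdividing into adaptation zones pays off\n"
    else "  CR/DR >= 1: selection across the undivided set is favoured\n")
  invisible(x)
}

#' Median design counts per genotype
#'
#' Per genotype, counts the number of distinct locations per zone (then
#' takes the median over its zones), years, and zones in which the
#' genotype was observed; returns the medians over genotypes.  Medians are
#' lower medians (the lower of the two middle values for even counts),
#' since these are integer-valued design constants.
#'
#' @param data trial-network table with columns `genotype`, `location`,
#'   `year`, and a zone column.
#' @param zone zone column name.
#' @return named vector `c(nl, ny, nz)`.
#' @export
median_counts <- function(data, zone = "zone") {
  stop_if(!zone %in% names(data), "no column '", zone, "'")
  per_gen <- split(data, data$genotype)
  nl_g <- vapply(per_gen, function(d)
    lower_median(tapply(d$location, d[[zone]],
                        function(l) length(unique(l)))), 0)
  ny_g <- vapply(per_gen, function(d) length(unique(d$year)), 0)
  nz_g <- vapply(per_gen, function(d) length(unique(d[[zone]])), 0)
  c(nl = unname(lower_median(nl_g)), ny = unname(lower_median(ny_g)),
    nz = unname(lower_median(nz_g)))
}

#' Selection summary from a zone-nested REML fit
#'
#' Convenience wrapper: takes the six components of a `fit_model6()`
#' result and the median design counts of the data and evaluates
#' [cr_dr()].
#'
#' @param fit a `fit_model6()` result.
#' @param data the table the model was fitted to.
#' @param zone zone column name.
#' @return a `selection_summary` (see [cr_dr()]).
#' @export
selection_from_fit <- function(fit, data, zone = "zone") {
  stopifnot(inherits(fit, "vc_fit"))
  cm <- fit$components
  need <- c("G", "GZ", "GL(Z)", "GY", "GZY", "GL(Z)Y")
  stop_if(!all(need %in% names(cm)), "fit lacks zone-nested components")
  n <- median_counts(data, zone)
  cr_dr(selection_inputs(cm[["G"]], cm[["GZ"]], cm[["GL(Z)"]],
                         cm[["GY"]], cm[["GZY"]], cm[["GL(Z)Y"]],
                         nl = n[["nl"]], ny = n[["ny"]], nz = n[["nz"]]))
}
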