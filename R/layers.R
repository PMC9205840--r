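#' Additive imputation of a trials x genotypes matrix
#'
#' Fills missing cells with fitted values from a two-way additive model with
#' fixed genotype and trial (environment) effects, estimated by least
#' squares on the observed cells.  Observed cells are left untouched, so the
#' operation is idempotent.
#'
#' @param x numeric matrix (trials in rows, genotypes in columns) with
#'   dimnames; may contain `NA`.
#' @return the matrix with missing cells imputed.
#' @export
impute_additive <- function(x) {
  x <- as.matrix(x)
  if (!anyNA(x)) return(x)
  obs <- !is.na(x)
  bad_r <- rowSums(obs) == 0; bad_c <- colSums(obs) == 0
  stop_if(any(bad_r), "no observed cells in row(s): ",
          paste(rownames(x)[bad_r] %||% which(bad_r), collapse = ", "))
  stop_if(any(bad_c), "no observed cells in column(s): ",
          paste(colnames(x)[bad_c] %||% which(bad_c), collapse = ", "))
  idx <- which(obs, arr.ind = TRUE)
  rf <- factor(idx[, 1], levels = seq_len(nrow(x)))
  cf <- factor(idx[, 2], levels = seq_len(ncol(x)))
  fit <- stats::lm(x[obs] ~ rf + cf)
  midx <- which(!obs, arr.ind = TRUE)
  pred <- stats::predict(fit, newdata = data.frame(
    rf = factor(midx[, 1], levels = levels(rf)),
    cf = factor(midx[, 2], levels = levels(cf))))
  x[!obs] <- pred
  x
}

#' Standardize matrix rows to zero mean and unit variance
#'
#' Centers and scales each row (trial) to mean 0 and sample standard
#' deviation 1 (n-1 denominator).  Removing trial means before a SOM
#' analysis focuses the classification on genotypic contrasts within trials
#' rather than on environmental main effects.
#'
#' @param x numeric matrix (trials x variables).
#' @param on_constant `"error"` (default) or `"drop"`: what to do with rows
#'   whose observed values are constant (zero variance).
#' @return the row-standardized matrix (possibly with rows dropped).
#' @export
scale_rows <- function(x, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  x <- as.matrix(x)
  m <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1, stats::sd, na.rm = TRUE)
  const <- !is.finite(s) | s == 0
  if (any(const)) {
    lab <- paste(rownames(x)[const] %||% which(const), collapse = ", ")
    if (on_constant == "error") stop("constant row(s): ", lab, call. = FALSE)
    warning("dropping constant row(s): ", lab)
    x <- x[!const, , drop = FALSE]; m <- m[!const]; s <- s[!const]
  }
  (x - m) / s
}

#' Construct a multi-layer stack
#'
#' A layer stack bundles named object x variable matrices sharing a common
#' object index (trials), each with a distance metric
#' (`"sumsquares"` or `"tanimoto"`) and a nonnegative user weight.  In the
#' combined distance each layer's raw distance is divided by its number of
#' variables before weighting, so weights are comparable across layers of
#' different widths.
#'
#' @param layers named list of numeric matrices with identical row sets.
#' @param metrics character vector (recycled) of per-layer metrics.
#' @param weights numeric vector (recycled) of per-layer weights.
#' @return object of class `layer_stack`.
#' @export
layer_stack <- function(layers, metrics = "sumsquares", weights = 1) {
  stop_if(length(layers) == 0, "empty layer list")
  stop_if(is.null(names(layers)) || any(names(layers) == ""),
          "layers must be named")
  layers <- lapply(layers, as.matrix)
  objs <- rownames(layers[[1]])
  stop_if(is.null(objs), "layer matrices need row names (object ids)")
  for (l in layers)
    stop_if(!identical(rownames(l), objs),
            "all layers must share the same object index")
  metrics <- rep_len(match.arg(metrics, c("sumsquares", "tanimoto"),
                               several.ok = TRUE), length(layers))
  weights <- rep_len(as.numeric(weights), length(layers))
  stop_if(any(weights < 0) || all(weights == 0),
          "weights must be >= 0 and not all zero")
  structure(list(layers = layers, metrics = metrics, weights = weights,
                 objects = objs),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("Layer stack:", length(x$layers), "layers,",
      length(x$objects), "objects\n")
  df <- data.frame(layer = names(x$layers),
                   vars = vapply(x$layers, ncol, 0L),
                   metric = x$metrics, weight = x$weights)
  print(df, row.names = FALSE)
  invisible(x)
}

align_traits <- function(traits) {
  common <- Reduce(intersect, lapply(traits, rownames))
  stop_if(length(common) == 0, "trait matrices share no trials")
  if (any(vapply(traits, nrow, 0L) != length(common)))
    warning("trait matrices aligned by trial intersection (",
            length(common), " trials)")
  lapply(traits, function(m) m[common, , drop = FALSE])
}

one_hot_binary <- function(scores, objects) {
  stop_if(is.null(names(scores)), "binary scores must be named by trial")
  miss <- setdiff(objects, names(scores))
  stop_if(length(miss) > 0, "binary scores missing for: ",
          paste(miss, collapse = ", "))
  s <- as.character(scores[objects])
  cbind(high = as.numeric(s == "high"), low = as.numeric(s == "low"))
}

#' Build a per-trait layer stack
#'
#' One layer per continuous trait (trials x genotypes, sum-of-squares
#' metric) plus, optionally, a one-hot binary incidence layer (Tanimoto
#' metric).  The default weights follow the convention of weighting the
#' target trait highest; for a yield / oil / flowering / incidence set the
#' defaults are 3 / 2 / 1 / 1.
#'
#' @param traits named list of trials x genotypes matrices (imputed and
#'   row-scaled).
#' @param binary_scores optional named character vector (trial ->
#'   `"high"`/`"low"`).
#' @param weights named numeric: one weight per trait, plus `binary` if
#'   `binary_scores` is given.  Defaults to 1 per layer, or to the 3/2/1/1
#'   convention when the traits are named yield, oil, flowering.
#' @return a [layer_stack()] with the trials as objects.
#' @export
build_trait_layers <- function(traits, binary_scores = NULL, weights = NULL) {
  stop_if(length(traits) == 0, "no trait matrices")
  traits <- align_traits(lapply(traits, as.matrix))
  nm <- names(traits)
  if (is.null(weights)) {
    # default convention: yield 3, oil 2, flowering 1, binary incidence 1;
    # any other trait gets weight 1
    defaults <- c(yield = 3, oil = 2, flowering = 1)
    weights <- ifelse(nm %in% names(defaults), defaults[nm], 1)
    names(weights) <- nm
    if (!is.null(binary_scores)) weights <- c(weights, binary = 1)
  }
  stop_if(!all(nm %in% names(weights)), "weights must cover all traits")
  layers <- traits
  metrics <- rep("sumsquares", length(traits))
  w <- as.numeric(weights[nm])
  if (!is.null(binary_scores)) {
    layers$binary <- one_hot_binary(binary_scores, rownames(traits[[1]]))
    rownames(layers$binary) <- rownames(traits[[1]])
    metrics <- c(metrics, "tanimoto")
    w <- c(w, as.numeric(weights["binary"] %||% 1))
    if (is.na(w[length(w)])) w[length(w)] <- 1
  }
  layer_stack(layers, metrics, w)
}

#' Build a per-genotype layer stack
#'
#' One layer per genotype (trials x traits), interpreting each genotype as a
#' bio-assay of environmental quality.  Genotype layers are weighted by the
#' supplied genotype weights (typically interaction sums of squares from
#' [genotype_weights_from_ammi()]); an optional binary incidence layer gets
#' a weight equal to the mean genotype weight.
#'
#' @param traits named list of trials x genotypes matrices (imputed,
#'   row-scaled); all must share genotype columns.
#' @param genotype_weights named numeric vector (genotype -> weight); 1 for
#'   all genotypes if `NULL`.
#' @param binary_scores optional named character vector (trial ->
#'   `"high"`/`"low"`).
#' @return a [layer_stack()] with one layer per genotype (+ `binary`).
#' @export
build_genotype_layers <- function(traits, genotype_weights = NULL,
                                  binary_scores = NULL) {
  stop_if(length(traits) == 0, "no trait matrices")
  traits <- align_traits(lapply(traits, as.matrix))
  gens <- Reduce(intersect, lapply(traits, colnames))
  stop_if(length(gens) == 0, "trait matrices share no genotypes")
  if (is.null(genotype_weights))
    genotype_weights <- stats::setNames(rep(1, length(gens)), gens)
  stop_if(!all(gens %in% names(genotype_weights)),
          "genotype_weights must cover all genotypes")
  trials <- rownames(traits[[1]])
  layers <- lapply(gens, function(g) {
    m <- vapply(traits, function(tm) tm[, g], numeric(length(trials)))
    m <- matrix(m, nrow = length(trials),
                dimnames = list(trials, names(traits)))
    m
  })
  names(layers) <- gens
  metrics <- rep("sumsquares", length(gens))
  w <- as.numeric(genotype_weights[gens])
  if (!is.null(binary_scores)) {
    layers$binary <- one_hot_binary(binary_scores, trials)
    rownames(layers$binary) <- trials
    metrics <- c(metrics, "tanimoto")
    w <- c(w, mean(as.numeric(genotype_weights[gens])))
  }
  layer_stack(layers, metrics, w)
}

#' Genotype interaction weights from an AMMI fit
#'
#' The weight of genotype *i* is its interaction sum of squares in the
#' rank-K AMMI approximation, \eqn{\sum_{k \le K} (\lambda_k v_{ik})^2},
#' i.e. the squared length of the genotype's biplot vector under genotype
#' scaling.  Used to weight genotype layers by their contribution to G x E.
#'
#' @param fit an [fit_ammi()] object.
#' @param K number of multiplicative components (default 2, an "AMMI-2").
#' @return named numeric vector genotype -> weight.
#' @export
genotype_weights_from_ammi <- function(fit, K = 2) {
  stopifnot(inherits(fit, "ammi_fit"))
  stop_if(K > length(fit$lambda), "K = ", K, " exceeds the ",
          length(fit$lambda), " available components")
  sc <- fit$genotype_scores[, seq_len(K), drop = FALSE] %*%
    diag(fit$lambda[seq_len(K)], K)
  stats::setNames(rowSums(sc^2), rownames(fit$genotype_scores))
}
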