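#' Aggregate SOM units into environment types
#'
#' Hierarchically clusters the trained prototypes under the same weighted
#' combined distance used for training and cuts the dendrogram at `k_et`
#' clusters; every trial inherits the environment type (ET) of its winning
#' unit.
#'
#' @param model a trained [train_som()] model.
#' @param stack the [layer_stack()] the model was trained on.
#' @param k_et number of environment types (default 6).
#' @param linkage hclust linkage (default Ward).
#' @return object of class `et_assignment`: `unit_et` (unit -> ET),
#'   `trial_et` (named vector trial -> ET), `hclust` (prototype
#'   dendrogram), `k_et`.
#' @export
cluster_prototypes <- function(model, stack, k_et = 6,
                               linkage = "ward.D2") {
  stopifnot(inherits(model, "mlsom"))
  n_units <- nrow(model$codebooks[[1]])
  stop_if(k_et > n_units, "k_et exceeds the number of units")
  D <- combined_dist_matrix(model$codebooks, model$codebooks,
                            model$metrics, model$weights)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  unit_et <- stats::cutree(hc, k = k_et)
  mp <- map_objects(model, stack)
  trial_et <- stats::setNames(unit_et[mp$assignment$unit],
                              mp$assignment$object)
  structure(list(unit_et = unit_et, trial_et = trial_et, hclust = hc,
                 k_et = as.integer(k_et),
                 assignment = mp$assignment),
            class = "et_assignment")
}

#' @export
print.et_assignment <- function(x, ...) {
  cat("Environment types:", x$k_et, "ETs over",
      length(x$trial_et), "trials\n")
  print(table(ET = x$trial_et))
  invisible(x)
}

#' Geographic clustering of trials
#'
#' Clusters trials on latitude and longitude with a SOM built from two
#' single-variable layers (equal weights); the occupied units are the
#' geographic clusters.  The grid is the most-square factorization of the
#' requested cluster count.
#'
#' @param lat,lon coordinates in degrees, one per trial.
#' @param n_clusters target number of clusters.
#' @param trial_ids optional trial identifiers (defaults to seq_along).
#' @param rlen,seed passed to [train_som()].
#' @return object of class `geo_clusters`: `cluster` (named vector trial ->
#'   cluster), `n_clusters` (occupied), `centers` (cluster lat/lon means).
#' @export
geo_cluster <- function(lat, lon, n_clusters, trial_ids = NULL,
                        rlen = 100, seed = NULL) {
  stop_if(any(!is.finite(lat)) || any(!is.finite(lon)),
          "coordinates must be finite")
  stop_if(length(lat) != length(lon), "lat/lon length mismatch")
  if (is.null(trial_ids)) trial_ids <- as.character(seq_along(lat))
  n_distinct <- nrow(unique(cbind(lat, lon)))
  k <- n_clusters
  if (n_distinct < n_clusters) {
    warning("fewer distinct coordinates (", n_distinct,
            ") than requested clusters; reducing")
    k <- n_distinct
  }
  dims <- grid_dims(k)
  stack <- layer_stack(
    list(latitude = matrix(lat, ncol = 1, dimnames = list(trial_ids, "lat")),
         longitude = matrix(lon, ncol = 1, dimnames = list(trial_ids, "lon"))),
    metrics = "sumsquares", weights = c(1, 1))
  model <- train_som(stack, som_grid(dims["nx"], dims["ny"]),
                     rlen = rlen, mode = "batch", seed = seed)
  mp <- map_objects(model, stack)
  occ <- sort(unique(mp$assignment$unit))
  cl <- match(mp$assignment$unit, occ)
  names(cl) <- trial_ids
  centers <- data.frame(
    cluster = seq_along(occ),
    latitude = tapply(lat, cl, mean),
    longitude = tapply(lon, cl, mean))
  structure(list(cluster = cl, n_clusters = length(occ),
                 centers = centers, model = model),
            class = "geo_clusters")
}

#' @export
print.geo_clusters <- function(x, ...) {
  cat("Geographic clustering:", x$n_clusters, "occupied clusters over",
      length(x$cluster), "trials\n")
  invisible(x)
}

#' Environment-type frequency table per geographic cluster
#'
#' Counts trials of each environment type within each geographic cluster
#' (pooled across years) and the corresponding row-wise relative
#' frequencies.
#'
#' @param trial_et named vector trial -> ET.
#' @param geo named vector trial -> geographic cluster (or a
#'   [geo_cluster()] object).
#' @return object of class `et_freq`: integer `counts` (clusters x ETs) and
#'   `freq` (rows sum to 1).
#' @export
et_frequency <- function(trial_et, geo) {
  if (inherits(geo, "geo_clusters")) geo <- geo$cluster
  common <- intersect(names(trial_et), names(geo))
  stop_if(length(common) == 0, "no shared trials between ETs and clusters")
  counts <- table(cluster = geo[common], ET = trial_et[common])
  counts <- matrix(as.integer(counts), nrow(counts),
                   dimnames = dimnames(counts))
  freq <- counts / rowSums(counts)
  structure(list(counts = counts, freq = freq), class = "et_freq")
}

#' Chi-square distance between ET count profiles
#'
#' Correspondence-analysis chi-square distance between two rows of a
#' frequency table: \eqn{d^2 = \sum_j (p_{aj} - p_{bj})^2 / m_j} with
#' \eqn{p} the row profiles and \eqn{m_j} the overall column (ET) masses.
#' ETs with zero overall mass are dropped from the sum with a warning.
#' With equal masses the distance is proportional to the Euclidean distance
#' between profiles.
#'
#' @param counts_a,counts_b nonnegative count vectors with positive totals.
#' @param column_masses overall ET masses (default: from the pooled
#'   counts).
#' @return the distance d (not squared).
#' @export
chi_square_distance <- function(counts_a, counts_b, column_masses = NULL) {
  stop_if(any(counts_a < 0) || any(counts_b < 0), "counts must be >= 0")
  stop_if(sum(counts_a) == 0 || sum(counts_b) == 0,
          "row totals must be positive")
  if (is.null(column_masses)) {
    tot <- counts_a + counts_b
    column_masses <- tot / sum(tot)
  }
  pa <- counts_a / sum(counts_a)
  pb <- counts_b / sum(counts_b)
  zero <- column_masses == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " ET(s) with zero overall mass")
    pa <- pa[!zero]; pb <- pb[!zero]; column_masses <- column_masses[!zero]
  }
  sqrt(sum((pa - pb)^2 / column_masses))
}

# full chi-square distance matrix between the rows of a count table
chisq_profile_dist <- function(counts, weighting = c("mass", "none")) {
  weighting <- match.arg(weighting)
  counts <- as.matrix(counts)
  masses <- colSums(counts) / sum(counts)
  if (weighting == "none") masses <- rep(1, ncol(counts))
  P <- counts / rowSums(counts)
  n <- nrow(counts)
  D <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  zero <- masses == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " ET(s) with zero overall mass")
    P <- P[, !zero, drop = FALSE]; masses <- masses[!zero]
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sqrt(sum((P[i, ] - P[j, ])^2 / masses))
  stats::as.dist(D)
}

#' Adaptation zones from ET frequency profiles
#'
#' Ward clustering of geographic clusters on chi-square distances between
#' their environment-type frequency profiles, cut at `k_zones`.  Geographic
#' clusters with similar ET distributions across years land in the same
#' adaptation zone.
#'
#' @param freq an [et_frequency()] object (or a count matrix).
#' @param k_zones number of adaptation zones (default 4).
#' @param weighting `"mass"` for correspondence-analysis column-mass
#'   weighting (default) or `"none"` for plain profile differences.
#' @param linkage hclust linkage (default Ward).
#' @return object of class `zone_assignment`: `cluster_zone` (geo cluster
#'   -> zone), `hclust`, `k_zones`, `degenerate` flag (all merge heights
#'   zero).
#' @export
cluster_zones <- function(freq, k_zones = 4, weighting = "mass",
                          linkage = "ward.D2") {
  counts <- if (inherits(freq, "et_freq")) freq$counts else as.matrix(freq)
  stop_if(k_zones > nrow(counts),
          "k_zones exceeds the number of geographic clusters")
  D <- chisq_profile_dist(counts, weighting)
  hc <- stats::hclust(D, method = linkage)
  degenerate <- all(hc$height < 1e-12)
  if (degenerate && k_zones > 1)
    warning("all profiles identical: forced split into ", k_zones,
            " zones is arbitrary")
  cz <- stats::cutree(hc, k = k_zones)
  names(cz) <- rownames(counts)
  structure(list(cluster_zone = cz, hclust = hc,
                 k_zones = as.integer(k_zones), degenerate = degenerate),
            class = "zone_assignment")
}

#' @export
print.zone_assignment <- function(x, ...) {
  cat("Adaptation zones:", x$k_zones, "zones over",
      length(x$cluster_zone), "geographic clusters\n")
  print(table(zone = x$cluster_zone))
  invisible(x)
}

#' Trial-level zone labels
#'
#' @param zones a [cluster_zones()] result.
#' @param geo named vector trial -> geographic cluster (or a
#'   [geo_cluster()] object).
#' @return named vector trial -> zone.
#' @export
trial_zones <- function(zones, geo) {
  stopifnot(inherits(zones, "zone_assignment"))
  if (inherits(geo, "geo_clusters")) geo <- geo$cluster
  stats::setNames(zones$cluster_zone[as.character(geo)], names(geo))
}

# best one-to-one label matching between two partitions (maximizes total
# overlap); exhaustive over permutations of the smaller label set
align_labels <- function(ref, alt) {
  lr <- sort(unique(ref)); la <- sort(unique(alt))
  swap <- length(la) > length(lr)
  a <- if (swap) ref else alt
  b <- if (swap) alt else ref
  ct <- table(factor(a, sort(unique(a))), factor(b, sort(unique(b))))
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  cols <- colnames(ct)
  best <- NULL; best_score <- -1
  for (p in perms(seq_len(ncol(ct)))) {
    sc <- sum(ct[cbind(seq_len(min(nrow(ct), ncol(ct))),
                       p[seq_len(min(nrow(ct), ncol(ct)))])])
    if (sc > best_score) { best_score <- sc; best <- p }
  }
  map <- stats::setNames(cols[best[seq_len(min(nrow(ct), ncol(ct)))]],
                         rownames(ct))
  if (swap) {
    inv <- stats::setNames(names(map), map)
    stats::setNames(as.vector(inv[as.character(alt)]), names(alt))
  } else {
    stats::setNames(as.vector(map[as.character(alt)]), names(alt))
  }
}

#' Per-zone balanced accuracy between two zone assignments
#'
#' For each reference zone, with A = trials in the zone under both
#' assignments, B = in the reference zone only, C = in the alternative zone
#' only and D = in neither, the balanced accuracy is
#' (A/(A+C) + D/(B+D)) / 2.  Because zone labels are arbitrary across SOM
#' runs, the alternative labels are first aligned to the reference by the
#' one-to-one matching that maximizes total overlap.
#'
#' @param zones_ref,zones_alt named vectors trial -> zone (same trial set).
#' @param align align labels before scoring (default TRUE).
#' @return named numeric vector: balanced accuracy per reference zone (NA
#'   for a zone empty after alignment).
#' @export
balanced_accuracy <- function(zones_ref, zones_alt, align = TRUE) {
  common <- intersect(names(zones_ref), names(zones_alt))
  stop_if(length(common) == 0, "no shared trials")
  ref <- zones_ref[common]; alt <- zones_alt[common]
  if (align) alt <- align_labels(ref, alt)
  out <- sapply(sort(unique(as.character(ref))), function(z) {
    in_ref <- as.character(ref) == z
    in_alt <- !is.na(alt) & as.character(alt) == z
    A <- sum(in_ref & in_alt); B <- sum(in_ref & !in_alt)
    C <- sum(!in_ref & in_alt); D <- sum(!in_ref & !in_alt)
    if ((A + C) == 0 || (B + D) == 0) return(NA_real_)
    (A / (A + C) + D / (B + D)) / 2
  })
  out
}
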