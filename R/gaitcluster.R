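# Unsupervised grouping of gait points: pairwise gait distances, Ward
# linkage, dendrogram cut, circular centroids, model naming, per-cluster
# summaries and circular histograms.

#' Pairwise normalized gait distances
#'
#' Normalized hypertorus distance ([gait_distance()]) for every unordered
#' pair of gait points, as a `stats::dist` object suitable for
#' [ward_linkage()].
#'
#' @param points Matrix of gait points (rows, cycles); rows with `NA` are
#'   not allowed here (drop them first).
#' @param metric A [metric_tensor()] of matching dimension.
#' @return A `dist` object of normalized distances in `[0, 1]`.
#' @export
pairwise_gait_distances <- function(points, metric) {
  stopifnot(inherits(metric, "gait_metric"))
  X <- as.matrix(points)
  if (nrow(X) < 2L) stop("need at least 2 gait points", call. = FALSE)
  if (ncol(X) != nrow(metric$g))
    stop("gait point dimension does not match the metric", call. = FALSE)
  if (anyNA(X)) stop("gait points contain NA; drop undefined frames first",
                     call. = FALSE)
  g <- metric$g
  k <- ncol(X)
  n <- nrow(X)
  D2 <- matrix(0, n, n)
  V <- vector("list", k)
  for (i in seq_len(k)) {
    d <- outer(X[, i], X[, i], "-") %% 1
    V[[i]] <- ifelse(d > 0.5, d - 1, d)
  }
  for (i in seq_len(k)) for (j in i:k) {
    w <- if (i == j) g[i, j] else 2 * g[i, j]
    D2 <- D2 + w * V[[i]] * V[[j]]
  }
  stats::as.dist(sqrt(pmax(D2, 0)) / metric$d_max)
}

#' Ward-linkage hierarchical clustering on gait distances
#'
#' Agglomerative clustering with Ward's criterion applied directly to the
#' precomputed (non-Euclidean) gait-distance matrix via the Lance-Williams
#' update (`stats::hclust`, method `"ward.D2"`). Merge heights are
#' monotone non-decreasing. Ward's criterion formally assumes Euclidean
#' distances; applying it to gait distances follows the field's practice
#' and is validated on simulations rather than by theory.
#'
#' @param distances A `dist` object from [pairwise_gait_distances()].
#' @return An `hclust` tree.
#' @export
ward_linkage <- function(distances) {
  if (!inherits(distances, "dist"))
    stop("`distances` must be a dist object", call. = FALSE)
  if (attr(distances, "Size") < 2L)
    stop("need at least 2 points", call. = FALSE)
  stats::hclust(distances, method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' Cuts below the `k - 1` highest merges, i.e. keeps the `k` most dissimilar
#' branches. The field's convention is `k = 3` for empirical datasets and
#' `k = 2` for two-model simulations.
#'
#' @param tree An `hclust` tree from [ward_linkage()].
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
cut_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1L || k > n) stop("`k` out of range", call. = FALSE)
  stats::cutree(tree, k = k)
}

#' Circular centroid of a set of gait points
#'
#' Per-coordinate circular mean, mapped back to `[0, 1)` cycles.
#'
#' @param points Matrix of gait points (rows, cycles).
#' @return Numeric vector, one circular mean per coordinate.
#' @export
cluster_centroid <- function(points) {
  X <- as.matrix(points)
  if (nrow(X) < 1L) stop("empty cluster", call. = FALSE)
  apply(X, 2, circular_mean)
}

#' Name clusters by their nearest model gait
#'
#' Each cluster is named after the model gait nearest to its centroid;
#' clusters sharing a nearest model are numbered by increasing centroid
#' distance (`MT1` closer than `MT2`). Ties between models are broken by
#' their order in `models` (canonical: ALT, ABT, MT) with a message.
#'
#' @param centroids Matrix of cluster centroids (rows, cycles).
#' @param models Named list of [gait_model()]s valid for the leg count.
#' @param metric A [metric_tensor()].
#' @return Data frame with `cluster`, `name`, `model`, `distance`
#'   (normalized centroid-to-model distance).
#' @export
name_clusters <- function(centroids, models, metric) {
  centroids <- as.matrix(centroids)
  stopifnot(length(models) >= 1L)
  D <- vapply(models, function(m) model_distances(centroids, m, metric),
              numeric(nrow(centroids)))
  D <- matrix(D, nrow = nrow(centroids),
              dimnames = list(NULL, names(models)))
  nearest <- apply(D, 1, function(r) {
    w <- which(r == min(r))
    if (length(w) > 1L)
      message("tie in nearest-model naming broken by canonical order")
    w[1]
  })
  dist_near <- D[cbind(seq_len(nrow(D)), nearest)]
  model_name <- names(models)[nearest]
  name <- character(nrow(D))
  for (m in unique(model_name)) {
    idx <- which(model_name == m)
    rk <- rank(dist_near[idx], ties.method = "first")
    name[idx] <- paste0(m, rk)
  }
  data.frame(cluster = seq_len(nrow(D)), name = name, model = model_name,
             distance = dist_near)
}

#' Assign each gait point to its nearest model gait
#'
#' The per-point baseline classifier: every gait point is labeled with the
#' model gait at the smallest normalized distance. Ties go to the first
#' model in `models` order (canonical: ALT, ABT, MT) and are counted in the
#' `ties` attribute.
#'
#' @param points Matrix of gait points (rows, cycles).
#' @param models Named list of [gait_model()]s.
#' @param metric A [metric_tensor()].
#' @return Character vector of model names per point, with attribute
#'   `ties` (number of exact ties).
#' @export
nearest_model_assignment <- function(points, models, metric) {
  points <- as.matrix(points)
  stopifnot(length(models) >= 1L)
  D <- vapply(models, function(m) model_distances(points, m, metric),
              numeric(nrow(points)))
  D <- matrix(D, nrow = nrow(points), dimnames = list(NULL, names(models)))
  ties <- 0L
  lab <- apply(D, 1, function(r) {
    w <- which(r == min(r))
    if (length(w) > 1L) ties <<- ties + 1L
    names(models)[w[1]]
  })
  if (ties > 0L)
    message(sprintf("%d nearest-model ties broken by canonical order", ties))
  structure(lab, ties = ties)
}

#' Full clustering pipeline for a set of gait points
#'
#' Pairwise distances, Ward linkage, dendrogram cut, circular centroids,
#' model naming, and bootstrap model proximities per cluster.
#'
#' @param points Matrix of gait points (rows, cycles); `NA` rows dropped.
#' @param metric A [metric_tensor()].
#' @param k Number of clusters (default 3, the empirical convention; use 2
#'   for two-model simulations).
#' @param models Named list of [gait_model()]s; defaults to
#'   [model_gaits()] for the metric's leg count.
#' @param n_boot Bootstrap resamples for centroid-model proximities.
#' @param seed Optional seed for the bootstrap.
#' @param treatment Optional per-point treatment codes; cluster fractions
#'   per treatment are then reported.
#' @return An object of class `cluster_result`: list with `labels`, `k`,
#'   `tree`, `centroids` (matrix), `names` (data frame from
#'   [name_clusters()]), `proximity` (data frame cluster x model: mean and
#'   CI), `fractions` (per-treatment cluster fractions or `NULL`) and
#'   `kept` (logical: which input rows were used).
#' @export
cluster_gaits <- function(points, metric, k = 3L, models = NULL,
                          n_boot = 1000L, seed = NULL, treatment = NULL) {
  X <- as.matrix(points)
  kept <- !apply(X, 1, anyNA)
  X <- X[kept, , drop = FALSE]
  if (is.null(models)) models <- model_gaits(metric$n_legs)
  d <- pairwise_gait_distances(X, metric)
  tree <- ward_linkage(d)
  labels <- cut_clusters(tree, k)
  centroids <- t(vapply(seq_len(k), function(cl)
    cluster_centroid(X[labels == cl, , drop = FALSE]),
    numeric(ncol(X))))
  nm <- name_clusters(centroids, models, metric)
  prox <- do.call(rbind, lapply(seq_len(k), function(cl) {
    do.call(rbind, lapply(names(models), function(mn) {
      b <- dataset_to_model(X[labels == cl, , drop = FALSE], models[[mn]],
                            metric, n_boot = n_boot, seed = seed)
      data.frame(cluster = cl, name = nm$name[cl], model = mn,
                 mean = b$mean, ci_lo = b$ci[1], ci_hi = b$ci[2])
    }))
  }))
  fractions <- NULL
  if (!is.null(treatment)) {
    tr <- treatment[kept]
    tab <- table(tr, nm$name[labels])
    fractions <- prop.table(tab, margin = 1)
  }
  structure(list(labels = labels, k = as.integer(k), tree = tree,
                 centroids = centroids, names = nm, proximity = prox,
                 fractions = fractions, kept = kept),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d points in %d clusters\n",
              length(x$labels), x$k))
  info <- x$names
  sizes <- table(x$labels)
  for (i in seq_len(nrow(info)))
    cat(sprintf("  %s: n = %d, centroid %.3f from %s\n", info$name[i],
                sizes[[as.character(info$cluster[i])]], info$distance[i],
                info$model[i]))
  invisible(x)
}

#' Per-cluster kinematic and stability summaries
#'
#' Frame-aligned summaries of speed, static stability margin and support
#' count by gait cluster: speed mean and s.d., SSM median and MAD, and the
#' distribution of the number of tarsi in stance.
#'
#' @param labels Cluster label per frame (integer or character).
#' @param speed Speed per frame (mm/s).
#' @param ssm Static stability margin per frame (mm).
#' @param n_support Number of tarsi in stance per frame.
#' @return List with `stats` (data frame: cluster, n, speed_mean, speed_sd,
#'   ssm_median, ssm_mad) and `n_support` (table of counts per cluster).
#' @export
cluster_summaries <- function(labels, speed, ssm, n_support) {
  n <- length(labels)
  if (length(speed) != n || length(ssm) != n || length(n_support) != n)
    stop("inputs must be frame-aligned (equal lengths)", call. = FALSE)
  cls <- sort(unique(labels))
  stats_df <- do.call(rbind, lapply(cls, function(cl) {
    i <- labels == cl
    data.frame(cluster = cl, n = sum(i),
               speed_mean = mean(speed[i], na.rm = TRUE),
               speed_sd = stats::sd(speed[i]),
               ssm_median = stats::median(ssm[i], na.rm = TRUE),
               ssm_mad = stats::mad(ssm[i], na.rm = TRUE))
  }))
  hist_tab <- table(cluster = labels, n_support = n_support)
  list(stats = stats_df, n_support = hist_tab)
}

#' Circular histogram of phase differences
#'
#' Bins circular samples on `[0, 1)` and reports the circular mean
#' direction and mean resultant length `R` (1 = fully concentrated,
#' 0 = uniform); the polar-plot analogue of a leg-pair phase-difference
#' histogram.
#'
#' @param samples Numeric vector of phase differences in cycles; `NA`
#'   dropped.
#' @param n_bins Number of equal bins on `[0, 1)`, default 24.
#' @return An object of class `circular_histogram`: list with `breaks`,
#'   `counts`, `mid` (bin midpoints), `mean_direction` (cycles) and `R`.
#' @export
circular_histogram <- function(samples, n_bins = 24L) {
  x <- wrap_cycle(samples[!is.na(samples)])
  if (length(x) < 1L) stop("need at least 1 sample", call. = FALSE)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = FALSE,
                                  left.open = FALSE), nbins = n_bins)
  structure(list(breaks = breaks, counts = counts,
                 mid = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2,
                 mean_direction = circular_mean(x),
                 R = resultant_length(x), n = length(x)),
            class = "circular_histogram")
}

#' @export
print.circular_histogram <- function(x, ...) {
  cat(sprintf("<circular_histogram> n = %d in %d bins; mean direction %.3f cycles, R = %.3f\n",
              x$n, length(x$counts), x$mean_direction, x$R))
  invisible(x)
}
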