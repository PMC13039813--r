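#' PCA with varimax rotation of the leading loadings
#'
#' Columns are standardized to zero mean and unit variance (constant columns
#' are dropped with a warning), the covariance of the standardized features
#' is eigen-decomposed via [stats::prcomp()], and a varimax rotation is
#' applied to the first `rotate` loading vectors to make each rotated
#' component load on few features.  The rotation is orthogonal, so the total
#' variance explained by the rotated block is unchanged.
#'
#' @param features numeric matrix or data frame (rows = snapshots).
#' @param rotate number of leading components to varimax-rotate.
#' @return list with `scores`, `loadings`, `rotated_loadings`, `rotation`,
#'   `variance_explained` (sums to 1), and `dropped` (names of constant
#'   columns removed).
#' @export
pca_varimax <- function(features, rotate = 3) {
  X <- as.matrix(features)
  stopifnot(nrow(X) >= 2)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping constant columns: ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  rotate <- min(rotate, ncol(p$rotation))
  vm <- stats::varimax(p$rotation[, seq_len(rotate), drop = FALSE])
  list(scores = p$x, loadings = p$rotation,
       rotated_loadings = unclass(vm$loadings), rotation = vm$rotmat,
       variance_explained = ve, dropped = dropped)
}

#' K-means with silhouette-based choice of k
#'
#' Runs k-means++ style clustering ([stats::kmeans()] with `nstart`
#' restarts) for each k in `k_range`, scores each solution by the mean
#' silhouette width ([cluster::silhouette()]) and returns the k with the
#' largest value.  Deterministic for a fixed seed.
#'
#' @param scores numeric matrix (typically the first three PC scores).
#' @param k_range candidate cluster counts (default 2:8); values exceeding
#'   the number of rows are skipped.
#' @param seed RNG seed.
#' @param nstart random restarts per k.
#' @return list with `best_k`, `labels` (for best k), `silhouettes` (named
#'   mean widths per k) and `fits` (kmeans objects).
#' @export
kmeans_silhouette <- function(scores, k_range = 2:8, seed = 1, nstart = 50) {
  scores <- as.matrix(scores)
  set.seed(seed)
  k_range <- k_range[k_range >= 2 & k_range <= nrow(scores) - 1]
  if (length(k_range) == 0) stop("no feasible k in range")
  d <- stats::dist(scores)
  fits <- list(); sil <- stats::setNames(numeric(0), character(0))
  for (k in k_range) {
    km <- stats::kmeans(scores, centers = k, nstart = nstart, iter.max = 100)
    sw <- cluster::silhouette(km$cluster, d)
    sil[as.character(k)] <- mean(sw[, "sil_width"])
    fits[[as.character(k)]] <- km
  }
  best <- as.integer(names(sil)[which.max(sil)])
  list(best_k = best, labels = fits[[as.character(best)]]$cluster,
       silhouettes = sil, fits = fits)
}

#' Morphology classification pipeline
#'
#' Standardized features -> PCA -> varimax diagnostics -> K-means on the
#' first three principal components with silhouette model selection.  When
#' four clusters emerge they are named by ordering the cluster-mean
#' `span_c`: the lowest-span_c cluster is the ring class (near-2D bundles),
#' then discs, then loose shells, then tight shells.
#'
#' @param features data frame containing the feature columns and a `span_c`
#'   column used only for naming.
#' @param feature_cols character vector of clustering feature columns
#'   (default: `surface_fraction` plus any `f*` state-fraction columns).
#' @param k_range,seed,nstart passed to [kmeans_silhouette()].
#' @return list with `assignments` (data frame: PC1..PC3, cluster,
#'   morphology), `pca`, `clustering`, `cluster_order` (clusters sorted by
#'   mean span_c).
#' @export
classify_morphologies <- function(features, feature_cols = NULL,
                                  k_range = 2:8, seed = 1, nstart = 50) {
  if (is.null(feature_cols))
    feature_cols <- intersect(c("surface_fraction", "f0", "f1", "f2", "f3",
                                "f4", "0F", "0B", "1F", "1B", "2F", "2B",
                                "span_a", "span_b", "span_c",
                                "alignment_angle"),
                              names(features))
  pca <- pca_varimax(features[, feature_cols, drop = FALSE])
  npc <- min(3, ncol(pca$scores))
  cl <- kmeans_silhouette(pca$scores[, seq_len(npc), drop = FALSE],
                          k_range = k_range, seed = seed, nstart = nstart)
  ord <- order(tapply(features$span_c, cl$labels, mean))
  morph_names <- if (cl$best_k == 4) {
    nm <- c("ring", "disc", "tight shell", "loose shell")
    # the two highest-span_c clusters are the shells; a tight shell
    # concentrates points at the surface, so when surface fractions are
    # available the higher-coverage one of the two is named "tight"
    if ("surface_fraction" %in% names(features)) {
      sf <- tapply(features$surface_fraction, cl$labels, mean)
      shells <- ord[3:4]
      nm[3:4] <- if (sf[as.character(shells[1])] >=
                     sf[as.character(shells[2])])
        c("tight shell", "loose shell") else c("loose shell", "tight shell")
    }
    nm
  } else paste0("class-", seq_len(cl$best_k))
  name_of <- stats::setNames(morph_names, ord)
  assignments <- data.frame(pca$scores[, seq_len(npc), drop = FALSE],
                            cluster = cl$labels,
                            morphology = unname(name_of[as.character(cl$labels)]))
  list(assignments = assignments, pca = pca, clustering = cl,
       cluster_order = ord)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to renaming), ~0 for random agreement.
#' @param a,b label vectors of equal length.
#' @return numeric in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  exp_idx <- si * sj / n2
  max_idx <- (si + sj) / 2
  if (max_idx == exp_idx) return(1)
  (sij - exp_idx) / (max_idx - exp_idx)
}
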