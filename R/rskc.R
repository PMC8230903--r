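#' Robust sparse k-means (trimmed sparse k-means)
#'
#' Sparse k-means learns a non-negative feature-weight vector `w` with
#' `||w||_2 <= 1` and `||w||_1 <= l1_bound` that maximizes the weighted
#' between-cluster sum of squares; the robust variant additionally trims a
#' fixed proportion `alpha` of observations in every iteration so that gross
#' outliers influence neither the partition nor the weights. Observations are
#' flagged both by their *weighted* distances (during the trimmed k-means
#' step) and by their *unweighted* distances to the cluster centres; the union
#' is excluded from centre and weight updates.
#'
#' The algorithm alternates (a) trimmed k-means on the weight-scaled data and
#' (b) a soft-thresholding weight update with bisection on the threshold to
#' satisfy the L1 bound, over `nstart` k-means++ restarts, keeping the
#' restart with the largest weighted between-cluster sum of squares.
#'
#' @param data numeric matrix, observations x features.
#' @param ncl number of clusters (`< nrow(data)`).
#' @param alpha proportion of observations to trim, in `[0, 0.5)`.
#' @param l1_bound L1 bound on the weight vector (`>= 1`).
#' @param nstart number of random restarts.
#' @param seed integer seed for the restart initialization stream.
#' @param max_iter maximum alternations per restart.
#' @param tol relative objective-change convergence tolerance.
#' @return an object of class `rskc`: `labels` (every observation, including
#'   trimmed ones, mapped to its nearest centre at convergence), `weights`,
#'   `centers` (ncl x p, on the original feature scale), `outliers` (indices
#'   flagged by either criterion), `objective`, and the call parameters.
#' @references Kondo, Salibian-Barrera & Zamar (2016), J. Stat. Software.
#' @export
rskc <- function(data, ncl, alpha = 0.1, l1_bound, nstart = 20, seed = NULL,
                 max_iter = 100, tol = 1e-6) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (!is.numeric(ncl) || ncl < 1 || ncl >= n) {
    stopf("'ncl' must satisfy 1 <= ncl < n observations")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 0.5) {
    stopf("'alpha' must lie in [0, 0.5)")
  }
  if (!is.numeric(l1_bound) || l1_bound < 1) stopf("'l1_bound' must be >= 1")
  if (all(apply(data, 2, stats::var) < .Machine$double.eps)) {
    stopf("degenerate input: the data matrix is constant")
  }
  ncl <- as.integer(ncl)
  n_trim <- ceiling(alpha * n)
  best <- NULL
  for (r in seq_len(nstart)) {
    res <- with_seed(child_seed(seed, r),
                     rskc_once(data, ncl, n_trim, l1_bound, max_iter, tol))
    if (is.null(best) || res$objective > best$objective) best <- res
  }
  best$call_params <- list(ncl = ncl, alpha = alpha, l1_bound = l1_bound,
                           nstart = nstart, seed = seed)
  class(best) <- "rskc"
  best
}

rskc_once <- function(data, ncl, n_trim, l1_bound, max_iter, tol) {
  n <- nrow(data); p <- ncol(data)
  w <- rep(1 / sqrt(p), p)
  obj_old <- -Inf
  centers <- NULL; labels <- NULL; out_w <- integer(0); out_e <- integer(0)
  for (it in seq_len(max_iter)) {
    sw <- sqrt(w)
    xw <- sweep(data, 2, sw, "*")
    km <- trimmed_kmeans(xw, ncl, n_trim, init = if (it == 1L)
      random_init(xw, ncl) else sweep(centers, 2, sw, "*"))
    labels <- km$labels
    out_w <- km$trimmed
    # centres in the unweighted space from observations not trimmed (weighted)
    centers <- matrix(0, ncl, p)
    for (k in seq_len(ncl)) {
      mem <- setdiff(which(labels == k), out_w)
      if (!length(mem)) mem <- which(labels == k)
      centers[k, ] <- colMeans(data[mem, , drop = FALSE])
    }
    # flag by unweighted distances too
    d_unw <- rowSums((data - centers[labels, , drop = FALSE])^2)
    out_e <- if (n_trim > 0) order(d_unw, decreasing = TRUE)[seq_len(n_trim)] else integer(0)
    excl <- union(out_w, out_e)
    w <- update_weights(data, labels, excl, l1_bound)
    obj <- weighted_bcss(data, labels, excl, w)
    if (is.finite(obj_old) && abs(obj - obj_old) <= tol * max(1, abs(obj_old))) {
      obj_old <- obj
      break
    }
    obj_old <- obj
  }
  # final labels: every observation mapped to nearest centre in weighted space
  sw <- sqrt(w)
  xw <- sweep(data, 2, sw, "*")
  cw <- sweep(centers, 2, sw, "*")
  d2 <- outer(rowSums(xw^2), rep(1, ncl)) - 2 * xw %*% t(cw) +
    outer(rep(1, n), rowSums(cw^2))
  labels <- max.col(-d2, ties.method = "first")
  list(labels = labels, weights = w, centers = centers,
       outliers = sort(union(out_w, out_e)),
       outliers_weighted = sort(out_w), outliers_unweighted = sort(out_e),
       objective = obj_old, iterations = it)
}

# Uniform random initial centres (distinct observations), as in classic
# (robust sparse) k-means. Distance-weighted seeding such as k-means++ is
# deliberately avoided: with gross outliers present it preferentially seeds
# centres *on* the outliers, which defeats the trimming.
random_init <- function(x, k) {
  x[sample.int(nrow(x), k), , drop = FALSE]
}

# Lloyd iterations with trimming: assign, drop the n_trim largest distances,
# recompute centres from the rest.
trimmed_kmeans <- function(x, k, n_trim, init, max_iter = 100) {
  n <- nrow(x)
  centers <- init
  labels_old <- rep(0L, n)
  trimmed <- integer(0)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    labels <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(n), labels)]
    trimmed <- if (n_trim > 0) order(dmin, decreasing = TRUE)[seq_len(n_trim)] else integer(0)
    for (kk in seq_len(k)) {
      mem <- setdiff(which(labels == kk), trimmed)
      if (!length(mem)) {
        # empty cluster: re-seed at the farthest untrimmed observation
        cand <- setdiff(order(dmin, decreasing = TRUE), trimmed)
        mem <- cand[1]
      }
      centers[kk, ] <- colMeans(x[mem, , drop = FALSE])
    }
    if (identical(labels, labels_old)) break
    labels_old <- labels
  }
  list(labels = labels, centers = centers, trimmed = trimmed)
}

# Per-feature between-cluster sum of squares on the non-excluded observations.
feature_bcss <- function(data, labels, excl) {
  use <- setdiff(seq_len(nrow(data)), excl)
  x <- data[use, , drop = FALSE]
  lab <- labels[use]
  grand <- colMeans(x)
  tot <- colSums(sweep(x, 2, grand)^2)
  wss <- numeric(ncol(data))
  for (k in unique(lab)) {
    xk <- x[lab == k, , drop = FALSE]
    wss <- wss + colSums(sweep(xk, 2, colMeans(xk))^2)
  }
  pmax(tot - wss, 0)
}

weighted_bcss <- function(data, labels, excl, w) {
  sum(w * feature_bcss(data, labels, excl))
}

# w = soft(b, delta) / ||soft(b, delta)||_2 with the smallest delta >= 0 such
# that ||w||_1 <= l1_bound (bisection).
update_weights <- function(data, labels, excl, l1_bound) {
  b <- feature_bcss(data, labels, excl)
  if (all(b <= 0)) return(rep(1 / sqrt(length(b)), length(b)))
  wfun <- function(delta) {
    s <- pmax(b - delta, 0)
    nrm <- sqrt(sum(s^2))
    if (nrm == 0) rep(0, length(b)) else s / nrm
  }
  w <- wfun(0)
  if (sum(w) <= l1_bound) return(w)
  lo <- 0; hi <- max(b)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(wfun(mid)) > l1_bound) lo <- mid else hi <- mid
  }
  wfun(hi)
}

#' @export
print.rskc <- function(x, ...) {
  cp <- x$call_params
  cat(sprintf("Robust sparse k-means: %d clusters, alpha = %g, L1 bound = %g\n",
              cp$ncl, cp$alpha, cp$l1_bound))
  cat(sprintf("Objective (weighted BCSS): %.4f; %d outlier(s); %d active feature weight(s)\n",
              x$objective, length(x$outliers), sum(x$weights > 1e-8)))
  invisible(x)
}

#' Select all genes sharing a cluster with seed genes
#'
#' Returns the union of the members of every cluster that contains at least
#' one seed gene (the seeds themselves included). Trimmed observations keep
#' the label of their nearest centre, so a seed flagged as an outlier still
#' maps to a cluster.
#'
#' @param result an [rskc()] result.
#' @param gene_ids identifiers, one per clustered observation.
#' @param seeds identifiers of the seed genes (e.g. NAM transcription
#'   factors).
#' @return character vector of gene ids.
#' @export
select_seed_clusters <- function(result, gene_ids, seeds) {
  if (length(gene_ids) != length(result$labels)) {
    stopf("'gene_ids' must have one id per clustered observation")
  }
  missing <- setdiff(seeds, gene_ids)
  if (length(missing)) stopf("seed '%s' is absent from gene_ids", missing[1])
  seed_clusters <- unique(result$labels[match(seeds, gene_ids)])
  gene_ids[result$labels %in% seed_clusters]
}
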