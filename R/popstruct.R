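#' Modified Rogers distance between accessions
#'
#' Pairwise Euclidean allele-frequency distance
#' \eqn{d(i,j) = \sqrt{\frac{1}{2m}\sum_{loci}\sum_{alleles}(p_a(i)-p_a(j))^2}}
#' over the \eqn{m} loci non-missing in both accessions (pairwise-complete).
#' For homozygous-only data this reduces to the square root of the fraction
#' of discordant loci, so identical accessions are at 0, accessions with
#' opposite homozygotes everywhere at 1, and half-discordant pairs at
#' \eqn{\sqrt{0.5}}.
#'
#' @param gt A genotype tibble.
#' @return Symmetric numeric matrix of distances with accession dimnames;
#'   pairs sharing no non-missing locus are `NA` (with a warning).
#' @export
modified_rogers_distance <- function(gt) {
  assert_genotype_tibble(gt)
  m <- genotype_matrix(gt)
  A <- m == 0L
  B <- m == 2L
  A[is.na(A)] <- FALSE
  B[is.na(B)] <- FALSE
  obs <- !is.na(m)
  storage.mode(A) <- storage.mode(B) <- storage.mode(obs) <- "double"

  shared <- crossprod(obs)
  disc <- crossprod(A, B) + crossprod(B, A)
  if (any(shared == 0)) {
    warn("some accession pairs share no non-missing locus; distance set NA")
  }
  d <- sqrt(disc / shared) # 0/0 -> NaN
  d[shared == 0] <- NA_real_
  diag(d) <- 0
  d
}

#' Principal coordinate analysis of a genetic distance matrix
#'
#' Classical metric scaling (PCoA) of the modified Rogers distance matrix.
#' Variance-explained fractions come from the eigenvalues; negative
#' eigenvalues are truncated to zero and excluded from the denominator.
#'
#' @param dist Symmetric distance matrix (e.g. from
#'   [modified_rogers_distance()]).
#' @param n_components Number of components to keep (default 4).
#' @return An object of class `msp_ordination` with elements `coordinates`
#'   (tibble: accession + one column per component), `var_explained`
#'   (fractions, nonincreasing) and `eig` (all eigenvalues).
#' @export
ordinate <- function(dist, n_components = 4) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) {
    abort("distance matrix must be symmetric")
  }
  n <- nrow(dist)
  n_components <- min(n_components, n - 1)
  sc <- stats::cmdscale(stats::as.dist(dist), k = n_components, eig = TRUE)
  pts <- sc$points
  if (is.null(pts) || ncol(pts) == 0) { # degenerate: all-zero distances
    pts <- matrix(0, n, n_components,
                  dimnames = list(rownames(dist), NULL))
  } else if (ncol(pts) < n_components) {
    pts <- cbind(pts, matrix(0, n, n_components - ncol(pts)))
  }
  colnames(pts) <- paste0("PC", seq_len(ncol(pts)))
  pos <- pmax(sc$eig, 0)
  ve <- if (sum(pos) > 0) pos[seq_len(n_components)] / sum(pos) else
    rep(0, n_components)

  structure(list(
    coordinates = dplyr::bind_cols(
      tibble::tibble(accession = rownames(dist) %||%
                       paste0("acc", seq_len(n))),
      tibble::as_tibble(as.data.frame(pts))),
    var_explained = ve,
    eig = sc$eig
  ), class = "msp_ordination")
}

#' @export
print.msp_ordination <- function(x, ...) {
  cat(sprintf("PCoA of %d accessions; variance explained: %s\n",
              nrow(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$var_explained),
                    collapse = ", ")))
  invisible(x)
}

#' K-means clustering over a range of k with an elbow diagnostic
#'
#' Runs k-means (squared Euclidean, best of `n_restarts` random starts) on
#' the ordination coordinates for each k in `k_range`, recording the total
#' within-cluster sum of squares (WSS). The number of clusters is taken from
#' `k` when supplied (the intended workflow is to inspect the WSS-vs-k curve
#' and choose); otherwise the automatic fallback picks the k with the
#' largest relative WSS drop. WSS is made nonincreasing in k by warm-starting
#' a refit from the previous solution whenever random restarts fail to
#' improve on it.
#'
#' @param x An `msp_ordination`, a coordinates tibble (first column
#'   `accession`) or a numeric matrix.
#' @param k_range Candidate cluster counts (default 1:15).
#' @param n_restarts Random restarts per k (default 25).
#' @param k Chosen number of clusters; `NULL` for automatic elbow choice.
#' @param seed Optional integer fixing the clustering randomness.
#' @return An object of class `msp_clustering`: `wss` tibble (k, wss),
#'   `k` chosen, `clusters` tibble (accession, cluster) and the chosen
#'   `stats::kmeans` fit.
#' @export
elbow_kmeans <- function(x, k_range = 1:15, n_restarts = 25, k = NULL,
                         seed = NULL) {
  if (inherits(x, "msp_ordination")) x <- x$coordinates
  if (is.data.frame(x)) {
    acc <- if ("accession" %in% names(x)) x$accession else
      paste0("acc", seq_len(nrow(x)))
    X <- as.matrix(dplyr::select(x, dplyr::where(is.numeric)))
  } else {
    X <- as.matrix(x)
    acc <- rownames(X) %||% paste0("acc", seq_len(nrow(X)))
  }
  if (max(k_range) > nrow(X)) {
    abort("k_range exceeds the number of accessions")
  }

  run <- function() {
    fits <- vector("list", length(k_range))
    wss <- numeric(length(k_range))
    for (i in seq_along(k_range)) {
      kk <- k_range[i]
      fit <- if (kk == 1) {
        ctr <- matrix(colMeans(X), 1)
        list(cluster = rep(1L, nrow(X)),
             tot.withinss = sum(sweep(X, 2, ctr)^2), centers = ctr)
      } else {
        suppressWarnings(stats::kmeans(X, centers = kk, nstart = n_restarts,
                                       iter.max = 50))
      }
      # enforce WSS(k) <= WSS(k-1): seed a refit with the previous centers
      # plus the point worst-fit by them
      if (i > 1 && fit$tot.withinss > wss[i - 1]) {
        prev <- fits[[i - 1]]$centers
        d2 <- apply(X, 1, function(r) min(colSums((t(prev) - r)^2)))
        init <- unique(rbind(prev, X[which.max(d2), , drop = FALSE]))
        if (nrow(init) == kk) {
          fit2 <- suppressWarnings(stats::kmeans(X, centers = init,
                                                 iter.max = 50))
          if (fit2$tot.withinss < fit$tot.withinss) fit <- fit2
        }
      }
      fits[[i]] <- fit
      wss[i] <- fit$tot.withinss
    }
    list(fits = fits, wss = wss)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  if (is.null(k)) {
    if (length(k_range) == 1) {
      k <- k_range
    } else {
      drop_rel <- (utils::head(res$wss, -1) - utils::tail(res$wss, -1)) /
        ifelse(utils::head(res$wss, -1) > 0, utils::head(res$wss, -1), 1)
      k <- k_range[which.max(drop_rel) + 1]
    }
  }
  k <- as.integer(k)
  if (!k %in% k_range) abort("`k` must lie in `k_range`")
  fit <- res$fits[[match(k, k_range)]]

  structure(list(
    wss = tibble::tibble(k = k_range, wss = res$wss),
    k = k,
    clusters = tibble::tibble(accession = acc,
                              cluster = as.integer(fit$cluster)),
    fit = fit
  ), class = "msp_clustering")
}

#' @export
print.msp_clustering <- function(x, ...) {
  cat(sprintf("k-means over k = %d..%d; chosen k = %d (sizes: %s)\n",
              min(x$wss$k), max(x$wss$k), x$k,
              paste(table(x$clusters$cluster), collapse = ", ")))
  invisible(x)
}

#' Population structure in one call
#'
#' Convenience wrapper: modified Rogers distance, PCoA, then k-means with
#' the elbow diagnostic.
#'
#' @inheritParams modified_rogers_distance
#' @inheritParams elbow_kmeans
#' @param n_components Components kept for clustering (default 4).
#' @return List with `dist`, `ordination` and `clustering`, class
#'   `msp_structure`.
#' @export
population_structure <- function(gt, n_components = 4, k_range = 1:15,
                                 n_restarts = 25, k = NULL, seed = NULL) {
  d <- modified_rogers_distance(gt)
  ord <- ordinate(d, n_components = n_components)
  cl <- elbow_kmeans(ord, k_range = k_range, n_restarts = n_restarts,
                     k = k, seed = seed)
  structure(list(dist = d, ordination = ord, clustering = cl),
            class = "msp_structure")
}

#' @export
print.msp_structure <- function(x, ...) {
  print(x$ordination)
  print(x$clustering)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy msp_ordination
#' @export
tidy.msp_ordination <- function(x, ...) x$coordinates

#' @method glance msp_ordination
#' @export
glance.msp_ordination <- function(x, ...) {
  tibble::tibble(n_accessions = nrow(x$coordinates),
                 n_components = length(x$var_explained),
                 pc1_var = x$var_explained[1],
                 pc2_var = x$var_explained[2])
}

#' @method tidy msp_clustering
#' @export
tidy.msp_clustering <- function(x, ...) x$clusters

#' @method glance msp_clustering
#' @export
glance.msp_clustering <- function(x, ...) {
  tibble::tibble(k = x$k, wss = x$wss$wss[match(x$k, x$wss$k)],
                 n_accessions = nrow(x$clusters))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ordination
#'
#' @param object An `msp_ordination`.
#' @param panel Optional panel tibble (`accession`, `morphotype`) used to
#'   colour points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot msp_ordination
#' @export
autoplot.msp_ordination <- function(object, panel = NULL, ...) {
  df <- object$coordinates
  if (!is.null(panel)) {
    df <- dplyr::left_join(df, panel, by = "accession")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$morphotype),
                            alpha = 0.8)
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
}

#' Plot the WSS-vs-k elbow curve
#'
#' @param object An `msp_clustering`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot msp_clustering
#' @export
autoplot.msp_clustering <- function(object, ...) {
  ggplot2::ggplot(object$wss, ggplot2::aes(.data$k, .data$wss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares") +
    ggplot2::theme_minimal()
}
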