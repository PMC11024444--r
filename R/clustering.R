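kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 <= 0)) {
      i <- sample.int(n, 1)
    } else {
      i <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    centers[j + 1, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' k-means clustering of full thermogram profiles
#'
#' Lloyd iterations on the raw 451-dimensional heat-capacity curves
#' (Euclidean distance, no per-feature standardization — profiles share one
#' physical unit), with k-means++ initialization and the best of `restarts`
#' runs kept by total within-cluster sum of squares. Clusters are relabeled
#' in decreasing size order for stable reporting. Deterministic given
#' `seed`.
#'
#' @param x A `tlb_cohort`, tibble with a `thermogram` list-column, list of
#'   thermograms, or an n x 451 profile matrix.
#' @param k Number of clusters (2 <= k <= n).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts; best run kept.
#' @param timepoint Optional timepoint filter applied when `x` is a cohort
#'   (clustering is typically run on baseline profiles).
#' @return A `tlb_kmeans` object: list with `k`, `assignments` (named
#'   integer vector), `centers` (k x 451 matrix), `wss`, `silhouette_mean`,
#'   `sizes`, `seed`, `restarts`.
#' @export
kmeans_profiles <- function(x, k, seed = 1, restarts = 50, timepoint = NULL) {
  m <- if (is.data.frame(x) && "thermogram" %in% names(x)) {
    profile_matrix(x, timepoint)
  } else {
    as_profile_matrix(x)
  }
  n <- nrow(m)
  if (k < 2 || k > n) abort("k must be between 2 and the number of samples")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- NULL
    for (attempt in 1:5) {
      init <- kmeanspp_init(m, k)
      fit <- tryCatch(
        suppressWarnings(kmeans(m, centers = init, iter.max = 100,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && !any(fit$size == 0)) break
      fit <- NULL
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("k-means failed on every restart")
  ord <- order(best$size, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  assignments <- relabel[best$cluster]
  names(assignments) <- rownames(m)
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  sil <- mean(cluster::silhouette(assignments, dist(m))[, "sil_width"])
  structure(list(k = k, assignments = assignments, centers = centers,
                 wss = best$tot.withinss, silhouette_mean = sil,
                 sizes = as.integer(best$size[ord]), seed = seed,
                 restarts = restarts),
            class = "tlb_kmeans")
}

#' @export
print.tlb_kmeans <- function(x, ...) {
  cat("Thermogram k-means: k =", x$k, "\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("  within-SS: %.4f  mean silhouette: %.3f\n",
              x$wss, x$silhouette_mean))
  invisible(x)
}

#' @method tidy tlb_kmeans
#' @export
tidy.tlb_kmeans <- function(x, ...) {
  tibble(sample_id = names(x$assignments),
         cluster = unname(x$assignments))
}

#' @method glance tlb_kmeans
#' @export
glance.tlb_kmeans <- function(x, ...) {
  tibble(k = x$k, wss = x$wss, silhouette_mean = x$silhouette_mean,
         n = length(x$assignments))
}

#' Scan cluster counts by within-SS and silhouette
#'
#' Runs [kmeans_profiles()] for each candidate k and reports the
#' within-cluster sum of squares (elbow inspection) and mean silhouette
#' coefficient (Euclidean distance on the curve vectors); the
#' silhouette-maximizing k is recorded in the `best_k` attribute.
#'
#' @inheritParams kmeans_profiles
#' @param k_range Candidate cluster counts, each in `[2, n - 1]`.
#' @return Tibble with `k`, `wss`, `silhouette_mean`; attribute `best_k`.
#' @export
select_k <- function(x, k_range = 2:8, seed = 1, restarts = 50,
                     timepoint = NULL) {
  m <- if (is.data.frame(x) && "thermogram" %in% names(x)) {
    profile_matrix(x, timepoint)
  } else {
    as_profile_matrix(x)
  }
  if (nrow(m) < 3) abort("need at least 3 samples to scan k")
  if (any(k_range < 2 | k_range > nrow(m) - 1)) {
    abort("k_range must lie within [2, n - 1]")
  }
  res <- purrr::map_dfr(k_range, function(k) {
    fit <- kmeans_profiles(m, k, seed = seed, restarts = restarts)
    tibble(k = k, wss = fit$wss, silhouette_mean = fit$silhouette_mean)
  })
  attr(res, "best_k") <- res$k[[which.max(res$silhouette_mean)]]
  res
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Phenotype-by-cluster purity table
#'
#' Cross-tabulates true phenotype labels against cluster assignments and
#' expresses each cluster's composition as column percentages (share of the
#' cluster per phenotype, one decimal, half away from zero).
#'
#' @param result A `tlb_kmeans` fit, or a vector of cluster labels.
#' @param phenotypes Phenotype label per clustered sample: a vector in
#'   sample order, or a named vector / data frame with `sample_id` +
#'   `phenotype` matched against the assignment names.
#' @return A `tlb_purity` tibble with `phenotype`, `cluster`, `n`, `pct`;
#'   attributes `counts` (phenotype x cluster matrix) and `totals`
#'   (per-cluster sizes).
#' @export
purity_table <- function(result, phenotypes) {
  assignments <- if (inherits(result, "tlb_kmeans")) {
    result$assignments
  } else result
  if (is.data.frame(phenotypes)) {
    phenotypes <- setNames(phenotypes$phenotype, phenotypes$sample_id)
  }
  if (!is.null(names(phenotypes)) && !is.null(names(assignments))) {
    miss <- setdiff(names(assignments), names(phenotypes))
    if (length(miss) > 0) {
      abort(paste0("missing phenotype label for ", length(miss), " sample(s)"))
    }
    phenotypes <- phenotypes[names(assignments)]
  }
  if (length(phenotypes) != length(assignments) || anyNA(phenotypes)) {
    abort("need one phenotype label per clustered sample")
  }
  counts <- table(phenotype = phenotypes, cluster = assignments)
  totals <- colSums(counts)
  pct <- sweep(counts, 2, totals, "/") * 100
  out <- as_tibble(as.data.frame(counts, stringsAsFactors = FALSE))
  names(out) <- c("phenotype", "cluster", "n")
  out$cluster <- as.integer(out$cluster)
  out$pct <- round_half_up(as.vector(pct), 1)
  out <- dplyr::arrange(out, .data$cluster, .data$phenotype)
  attr(out, "counts") <- unclass(counts)
  attr(out, "totals") <- totals
  class(out) <- c("tlb_purity", class(out))
  out
}
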