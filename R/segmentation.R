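# Statistical screening of a scan's profiles: representative extraction,
# clustering into a few subsets, spatial abundance maps and outlier-sample
# flagging. Simplified re-implementation of the signal-classification
# workflow: intensity normalisation -> PCA (3 components) -> seeded
# k-means -> medoid representatives.

#' Segment a scan grid into profile subsets
#'
#' Each pixel's profile is normalised to unit total intensity (and, for
#' SAXS, log-transformed first, since the dynamic range spans decades),
#' projected on the first `n_pc` principal components, and clustered by
#' k-means (20 restarts, seeded, hence deterministic). Each subset is
#' represented by its medoid profile -- the member closest to the subset
#' centre in score space, which makes the representatives maximally
#' decorrelated members of the data themselves. Duplicate profiles are
#' allowed (a perfectly homogeneous scan yields identical representatives
#' and abundance concentrated in one subset).
#'
#' @param grid A [scan_grid].
#' @param k Number of subsets (default 4).
#' @param seed Seed for the k-means restarts.
#' @param log_transform Log-transform intensities before normalisation;
#'   default TRUE for SAXS, FALSE for WAXS.
#' @param n_pc Number of principal components used for clustering and
#'   reported as scores (default 3).
#' @return An object of class `segmentation_result`: `k`, `labels`
#'   (per-pixel subset index, 1..k), `scores` (pixels x `n_pc` PC
#'   coordinates), `representatives` (list of [qprofile]s),
#'   `representative_pixels`, `abundance` (fractions summing to 1),
#'   `explained_variance` (per retained component) and the pixel `index`.
#' @examples
#' g <- generate_scan(scan_spec(n_rows = 6, n_cols = 6))
#' seg <- segment_scan(g, k = 2)
#' seg$abundance
#' @export
segment_scan <- function(grid, k = 4L, seed = 1L,
                         log_transform = NULL, n_pc = 3L) {
  stopifnot(inherits(grid, "scan_grid"))
  npx <- nrow(grid$intensity)
  if (k < 1) stop("k must be >= 1")
  if (k > npx) stop("k exceeds the number of pixels")
  if (is.null(log_transform)) log_transform <- grid$modality == "saxs"

  X <- grid$intensity / pmax(rowSums(grid$intensity), .Machine$double.eps)
  if (log_transform) X <- log(X + 1e-12)

  n_pc <- min(n_pc, npx - 1L, ncol(X))
  constant <- all(abs(sweep(X, 2, X[1, ])) < 1e-12)
  if (constant || n_pc < 1) {
    # degenerate homogeneous scan: single effective subset
    labels <- rep(1L, npx)
    scores <- matrix(0, npx, max(n_pc, 1L))
    evar <- rep(0, max(n_pc, 1L))
  } else {
    pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    scores <- pca$x[, seq_len(n_pc), drop = FALSE]
    evar <- (pca$sdev^2 / sum(pca$sdev^2))[seq_len(n_pc)]
    n_distinct <- nrow(unique(round(scores, 12)))
    k_eff <- min(k, n_distinct)
    labels <- .with_seed(seed, {
      stats::kmeans(scores, centers = k_eff, nstart = 20,
                    iter.max = 100)$cluster
    })
  }
  # medoid representative per subset: member nearest the subset mean in
  # score space
  rep_px <- integer(0)
  for (g in sort(unique(labels))) {
    members <- which(labels == g)
    ctr <- colMeans(scores[members, , drop = FALSE])
    d2 <- rowSums(sweep(scores[members, , drop = FALSE], 2, ctr)^2)
    rep_px[g] <- members[which.min(d2)]
  }
  # empty subsets (duplicate-profile degeneracy) reuse the first medoid
  length(rep_px) <- k
  rep_px[is.na(rep_px)] <- rep_px[which(!is.na(rep_px))[1]]
  abundance <- as.numeric(table(factor(labels, levels = seq_len(k))) / npx)
  reps <- lapply(rep_px, function(i) get_profile(grid, i))
  structure(list(k = as.integer(k), labels = labels, scores = scores,
                 representatives = reps, representative_pixels = rep_px,
                 abundance = abundance, explained_variance = evar,
                 index = grid$index, seed = as.integer(seed),
                 log_transform = log_transform),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> k = %d, abundance: %s; PC var: %s\n",
              x$k,
              paste(sprintf("%.2f", x$abundance), collapse = " "),
              paste(sprintf("%.3f", x$explained_variance), collapse = " ")))
  invisible(x)
}

#' Flag anomalous samples against a reference profile
#'
#' Computes each sample's correlation distance `1 - cor(I, I_ref)` to a
#' reference (control) profile and flags samples whose distance exceeds a
#' threshold, mirroring the exclusion of anomalous profiles (e.g. dried or
#' badly prepared tissue) from downstream analysis. The default threshold
#' is `median + 5 * MAD` of the distances across samples.
#'
#' @param summaries List of per-sample representative [qprofile]s (or a
#'   numeric matrix, samples in rows).
#' @param reference The control [qprofile] (or numeric vector), on the
#'   same q grid.
#' @param threshold Absolute distance threshold; `NULL` (default) uses the
#'   median + 5 MAD rule; `Inf` flags nothing.
#' @return A data frame with one row per sample: `sample`, `distance`,
#'   `flagged`.
#' @export
flag_outlier_samples <- function(summaries, reference, threshold = NULL) {
  if (is.matrix(summaries)) {
    M <- summaries
  } else {
    if (length(summaries) < 2) stop("need at least 2 samples")
    M <- do.call(rbind, lapply(summaries, function(p) {
      if (inherits(p, "qprofile")) p$intensity else as.numeric(p)
    }))
  }
  if (nrow(M) < 2) stop("need at least 2 samples")
  ref <- if (inherits(reference, "qprofile")) reference$intensity else {
    as.numeric(reference)
  }
  if (length(ref) != ncol(M)) stop("reference length mismatch")
  d <- apply(M, 1, function(x) {
    if (stats::sd(x) < 1e-15 || stats::sd(ref) < 1e-15) {
      if (max(abs(x - ref)) < 1e-12) 0 else 2
    } else {
      1 - stats::cor(x, ref)
    }
  })
  if (is.null(threshold)) {
    threshold <- stats::median(d) + 5 * stats::mad(d)
  }
  data.frame(sample = if (!is.null(names(summaries))) names(summaries) else {
    seq_len(nrow(M))
  }, distance = d, flagged = d > threshold, row.names = NULL)
}

#' Rand index between two partitions
#'
#' Label-permutation-invariant agreement between two clusterings: the
#' fraction of pixel pairs on which the partitions agree (same subset in
#' both, or different subsets in both). 1 means identical partitions.
#'
#' @param a,b Integer label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 2) return(1)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}
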