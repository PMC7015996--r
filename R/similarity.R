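#' Principal component analysis of a feature matrix
#'
#' Mean-centres the columns (no variance scaling: fingerprint features are
#' already max-normalized to a common scale) and extracts the leading
#' principal components. Loadings follow the sign convention that each
#' column's largest-magnitude entry is positive, so scores and plots are
#' reproducible across platforms.
#'
#' @param x Numeric matrix or data frame, recordings in rows (row names are
#'   carried into the scores), features in columns.
#' @param n_components Number of components to keep (default 4).
#' @return A `pca_model`: `mean_vector`, `loadings` (p x k, orthonormal),
#'   `scores` (n x k), `explained_variance_fraction` (length k),
#'   `explained_all` (all computable components), `n_components`.
#' @export
fit_pca <- function(x, n_components = 4L) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !all(is.finite(x)))
    stop_("feature matrix must be numeric and finite", class = "validation_error")
  n <- nrow(x); p <- ncol(x)
  n_components <- check_count(n_components, "n_components")
  if (n_components > min(n - 1L, p))
    stop_("n_components = %d exceeds min(n - 1, p) = %d", n_components,
          min(n - 1L, p), class = "validation_error")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- seq_len(n_components)
  loadings <- pc$rotation[, k, drop = FALSE]
  scores <- pc$x[, k, drop = FALSE]
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    sign(loadings[which.max(abs(loadings[, j])), j])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  rownames(scores) <- rownames(x)
  structure(list(mean_vector = colMeans(x), loadings = loadings,
                 scores = scores, explained_variance_fraction = frac[k],
                 explained_all = frac, n_components = n_components),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d samples, %d components; explained %s\n",
              nrow(x$scores), x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

#' Venetian-blinds cross-validated PRESS for component selection
#'
#' Interleaved row hold-out: split `s` holds out rows `s, s + n_splits,
#' s + 2 n_splits, ...`; a PCA is fitted on the remaining rows and each
#' held-out row is reconstructed from its `k` leading loadings with
#' variable-wise deletion: each variable is predicted from the row's other
#' variables via the training loadings, so the prediction never sees the
#' value it predicts. (Plain projection of complete held-out rows shrinks
#' monotonically with `k` and cannot reveal the model rank.) Squared
#' prediction residuals are accumulated into PRESS(k) for
#' `k = 1..max_components`.
#'
#' @param x Feature matrix, rows = recordings.
#' @param max_components Largest component count to evaluate.
#' @param n_splits Number of interleaved folds (default 10).
#' @return Numeric vector `press` of length `max_components`, named by k.
#' @export
venetian_blinds_press <- function(x, max_components, n_splits = 10L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  n_splits <- check_count(n_splits, "n_splits", lower = 2L)
  max_components <- check_count(max_components, "max_components")
  if (n < n_splits)
    stop_("need at least n_splits = %d rows, got %d", n_splits, n,
          class = "validation_error")
  min_train <- n - ceiling(n / n_splits)
  if (max_components > min(min_train - 1L, p - 1L))
    stop_("max_components = %d infeasible: needs <= min(%d, %d) for the smallest training fold",
          max_components, min_train - 1L, p - 1L, class = "validation_error")
  press <- numeric(max_components)
  for (s in seq_len(n_splits)) {
    held <- seq(s, n, by = n_splits)
    train <- x[-held, , drop = FALSE]
    centre <- colMeans(train)
    pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
    xc <- sweep(x[held, , drop = FALSE], 2, centre)
    for (k in seq_len(max_components)) {
      L <- pc$rotation[, seq_len(k), drop = FALSE]
      for (j in seq_len(p)) {
        Lj <- L[-j, , drop = FALSE]
        # minimum-norm least-squares score from the other variables,
        # then predict variable j (pseudo-inverse handles rank-deficient
        # loadings of noiseless low-rank data)
        sv <- svd(Lj)
        pos <- sv$d > max(sv$d, 1e-300) * 1e-10
        pinv <- sv$v[, pos, drop = FALSE] %*%
          ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
        scores_hat <- xc[, -j, drop = FALSE] %*% t(pinv)
        pred_j <- scores_hat %*% L[j, ]
        press[k] <- press[k] + sum((xc[, j] - pred_j)^2)
      }
    }
  }
  names(press) <- seq_len(max_components)
  press
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Euclidean distances between PCA scores
#'
#' Distance between every unordered pair of recordings in the leading
#' `n_pcs_for_distance` score dimensions (default 2, the dimensions shown on
#' a scores plot).
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param n_pcs_for_distance Number of leading score dimensions to use.
#' @return Data frame with columns `id1`, `id2`, `distance`, one row per
#'   unordered pair; the full symmetric matrix is attached as attribute
#'   `"matrix"`.
#' @export
score_distances <- function(model, n_pcs_for_distance = 2L) {
  stopifnot(inherits(model, "pca_model"))
  n_pcs_for_distance <- check_count(n_pcs_for_distance, "n_pcs_for_distance")
  if (n_pcs_for_distance > model$n_components)
    stop_("n_pcs_for_distance = %d exceeds the %d fitted components",
          n_pcs_for_distance, model$n_components, class = "validation_error")
  s <- model$scores[, seq_len(n_pcs_for_distance), drop = FALSE]
  ids <- rownames(s) %||% as.character(seq_len(nrow(s)))
  d <- as.matrix(stats::dist(s))
  dimnames(d) <- list(ids, ids)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                    distance = d[ut], stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$id1, out$id2), ]
  rownames(out) <- NULL
  attr(out, "matrix") <- d
  out
}

#' Select similar and dissimilar cross-subject recording pairs
#'
#' Greedy selection without replacement: repeatedly take the
#' smallest-distance pair whose recordings come from different subjects and
#' are not yet used (`n_each` similar pairs), then the largest-distance such
#' pair (`n_each` dissimilar pairs). All `4 * n_each` recordings are
#' distinct, and no pair joins two recordings of the same subject. Distance
#' ties are broken by recording id, so the selection is deterministic and
#' independent of input row order.
#'
#' @param distances Pair table from [score_distances()].
#' @param subjects Named character vector mapping recording id to subject id.
#' @param n_each Number of similar and of dissimilar pairs (default 5).
#' @return A `pair_selection`: `similar` and `dissimilar` data frames
#'   (`id1`, `id2`, `distance`; similar sorted ascending, dissimilar
#'   descending) and `n_each`.
#' @export
select_pairs <- function(distances, subjects, n_each = 5L) {
  n_each <- check_count(n_each, "n_each")
  need <- c("id1", "id2", "distance")
  if (!is.data.frame(distances) || !all(need %in% names(distances)))
    stop_("'distances' must have columns id1, id2, distance",
          class = "validation_error")
  ids <- union(distances$id1, distances$id2)
  if (!all(ids %in% names(subjects)))
    stop_("subject map missing some recording ids", class = "selection_error")
  cross <- distances[subjects[distances$id1] != subjects[distances$id2], , drop = FALSE]
  take <- function(tbl, k, used) {
    out <- tbl[0, need]
    for (r in seq_len(nrow(tbl))) {
      if (nrow(out) == k) break
      row <- tbl[r, ]
      if (!(row$id1 %in% used) && !(row$id2 %in% used)) {
        out <- rbind(out, row[, need])
        used <- c(used, row$id1, row$id2)
      }
    }
    if (nrow(out) < k)
      stop_("could not find %d disjoint cross-subject pairs", k,
            class = "selection_error")
    list(pairs = out, used = used)
  }
  asc <- cross[order(cross$distance, cross$id1, cross$id2), ]
  sim <- take(asc, n_each, character(0))
  desc <- cross[order(-cross$distance, cross$id1, cross$id2), ]
  dis <- take(desc, n_each, sim$used)
  rownames(sim$pairs) <- rownames(dis$pairs) <- NULL
  structure(list(similar = sim$pairs, dissimilar = dis$pairs,
                 n_each = n_each),
            class = "pair_selection")
}

#' @export
print.pair_selection <- function(x, ...) {
  cat(sprintf("pair_selection: %d similar + %d dissimilar pairs\n",
              nrow(x$similar), nrow(x$dissimilar)))
  invisible(x)
}

#' Rank selected pairs under two distance tables
#'
#' Ranks the selected pairs by their distance in each of two tables (for
#' instance frequency-domain fingerprint distances versus time-domain
#' hemodynamic distances) and reports the Spearman rank correlation between
#' the two orders. A low correlation indicates the two feature spaces order
#' the pairs differently, i.e. carry different information.
#'
#' @param pairs A `pair_selection`.
#' @param table_a,table_b Pair tables from [score_distances()]; every
#'   selected pair must appear in both.
#' @return List with `ranking` (data frame: `id1`, `id2`, `kind`,
#'   `distance_a`, `distance_b`, `rank_a`, `rank_b`) and
#'   `spearman` (rank correlation of the two orders).
#' @export
rank_pairs <- function(pairs, table_a, table_b) {
  stopifnot(inherits(pairs, "pair_selection"))
  sel <- rbind(cbind(pairs$similar, kind = "similar"),
               cbind(pairs$dissimilar, kind = "dissimilar"))
  lookup <- function(tbl, label) {
    key <- pair_key(tbl$id1, tbl$id2)
    hit <- match(pair_key(sel$id1, sel$id2), key)
    if (anyNA(hit))
      stop_("pair %s-%s missing from distance table %s",
            sel$id1[which(is.na(hit))[1]], sel$id2[which(is.na(hit))[1]],
            label, class = "validation_error")
    tbl$distance[hit]
  }
  da <- lookup(table_a, "A")
  db <- lookup(table_b, "B")
  out <- data.frame(id1 = sel$id1, id2 = sel$id2, kind = sel$kind,
                    distance_a = da, distance_b = db,
                    rank_a = rank(da), rank_b = rank(db))
  list(ranking = out,
       spearman = stats::cor(da, db, method = "spearman"))
}
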