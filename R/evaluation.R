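#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{BC(u, v) = \sum |u_i - v_i| / \sum (u_i + v_i)}, bounded in
#' [0, 1] for non-negative input. Two all-zero vectors are defined to be
#' at distance 0.
#'
#' @param u,v Non-negative numeric vectors over the same ordered
#'   function list.
#' @return Dissimilarity in [0, 1].
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v))
    stopf("length mismatch: %d vs %d", length(u), length(v))
  tot <- sum(u) + sum(v)
  if (tot == 0) return(0)
  sum(abs(u - v)) / tot
}

#' All pairwise Bray-Curtis dissimilarities of a profile table
#'
#' @param table Samples x functions abundance matrix with >= 2 samples.
#' @return A symmetric matrix with zero diagonal and sample IDs as
#'   dimnames.
#' @export
distance_matrix <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L) stop("need at least 2 samples", call. = FALSE)
  n <- nrow(table)
  rs <- rowSums(table)
  d <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1L)) {
    ui <- table[i, ]
    for (j in (i + 1L):n) {
      tot <- rs[i] + rs[j]
      d[i, j] <- d[j, i] <- if (tot == 0) 0 else sum(abs(ui - table[j, ])) / tot
    }
  }
  d
}

#' Mean and spread of paired WGS:amplicon distances
#'
#' Computes the Bray-Curtis distance between the two members of each
#' pair (e.g. the WGS-derived and amplicon-predicted profiles of the
#' same specimen) and summarizes them. This is the headline quantity for
#' judging calibration: a good calibration pulls the paired distance
#' below the within-group distance of WGS samples.
#'
#' @param pairs A \code{"paired_profiles"} object.
#' @param sd_divisor \code{"n-1"} (sample standard deviation, default)
#'   or \code{"n"} (population-style).
#' @return A list with \code{mean}, \code{sd}, \code{n} and
#'   \code{distances} (the raw per-pair values, for downstream tests).
#' @export
paired_distance_summary <- function(pairs, sd_divisor = c("n-1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  n <- length(pairs$sample_ids)
  if (n < 1L) stop("zero pairs", call. = FALSE)
  d <- vapply(seq_len(n),
              function(i) bray_curtis(pairs$wgs[i, ], pairs$amplicon[i, ]),
              numeric(1))
  names(d) <- pairs$sample_ids
  s <- if (n == 1L) 0 else stats::sd(d)
  if (sd_divisor == "n") s <- sqrt(sum((d - mean(d))^2) / n)
  list(mean = mean(d), sd = s, n = n, distances = d)
}

#' Within-group distance summaries
#'
#' For each group label, summarizes the dissimilarities between distinct
#' same-group samples (e.g. distances among WGS samples of the same body
#' site). Groups with a single sample have no within-group pairs and are
#' reported as \code{NA}.
#'
#' @param dm Symmetric distance matrix with sample IDs as dimnames.
#' @param metadata Named character vector (sample ID -> label) covering
#'   every sample in \code{dm}.
#' @param sd_divisor See \code{\link{paired_distance_summary}}.
#' @return A data frame with columns group, n_samples, n_pairs, mean, sd.
#' @export
within_group_distance_summary <- function(dm, metadata,
                                          sd_divisor = c("n-1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  ids <- rownames(dm)
  missing <- setdiff(ids, names(metadata))
  if (length(missing) > 0L)
    stopf("unlabeled sample(s): %s", paste(missing, collapse = ", "))
  labels <- metadata[ids]
  groups <- sort(unique(labels))
  rows <- lapply(groups, function(g) {
    members <- ids[labels == g]
    k <- length(members)
    if (k < 2L)
      return(data.frame(group = g, n_samples = k, n_pairs = 0L,
                        mean = NA_real_, sd = NA_real_))
    sub <- dm[members, members]
    d <- sub[upper.tri(sub)]
    s <- if (length(d) == 1L) 0 else stats::sd(d)
    if (sd_divisor == "n") s <- sqrt(sum((d - mean(d))^2) / length(d))
    data.frame(group = g, n_samples = k, n_pairs = length(d),
               mean = mean(d), sd = s)
  })
  do.call(rbind, rows)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers \eqn{-\tfrac12 D^2}, eigendecomposes, and returns
#' coordinates scaled by the square roots of the largest non-negative
#' eigenvalues. Explained fractions are relative to the sum of positive
#' eigenvalues. The sign of each axis is fixed so that its
#' largest-magnitude loading is positive, making ordinations
#' deterministic.
#'
#' @param dm Symmetric distance matrix with zero diagonal.
#' @param n_axes Number of axes to keep (capped at the number of
#'   positive eigenvalues).
#' @return A list with \code{coordinates} (samples x axes matrix, axes
#'   named Axis1..k), \code{explained} (fraction per kept axis) and
#'   \code{eigenvalues} (all of them).
#' @export
pcoa <- function(dm, n_axes = 2L) {
  dm <- as.matrix(dm)
  if (n_axes < 1L) stop("n_axes must be >= 1", call. = FALSE)
  n <- nrow(dm)
  a <- -0.5 * dm^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- j %*% a %*% j
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- eig$values > max(eig$values, 0) * 1e-12 & eig$values > 0
  if (!any(pos))
    stop("no positive eigenvalues: distance matrix has no metric structure",
         call. = FALSE)
  k <- min(n_axes, sum(pos))
  vals <- eig$values[pos][seq_len(k)]
  vecs <- eig$vectors[, pos, drop = FALSE][, seq_len(k), drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(vals), `*`)
  for (ax in seq_len(k)) {  # deterministic axis orientation
    if (coords[which.max(abs(coords[, ax])), ax] < 0)
      coords[, ax] <- -coords[, ax]
  }
  dimnames(coords) <- list(rownames(dm), paste0("Axis", seq_len(k)))
  list(coordinates = coords,
       explained = vals / sum(eig$values[pos]),
       eigenvalues = eig$values)
}

#' PERMANOVA effect size of a grouping factor
#'
#' Partitions the distance-based sum of squares by group:
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / N} over all samples,
#' \eqn{SS_{within}} summed per group with group-size divisors, and
#' \eqn{R^2 = (SS_{total} - SS_{within}) / SS_{total}} — the fraction of
#' beta-diversity explained by the factor (as reported by an Adonis
#' test). A permutation p-value is computed by shuffling labels.
#'
#' @param dm Symmetric distance matrix with sample IDs as dimnames.
#' @param metadata Named character vector (sample ID -> label).
#' @param permutations Number of label permutations for the p-value
#'   (default 999); 0 skips the test.
#' @param seed Seed for the permutations (required when
#'   \code{permutations > 0}).
#' @return A list with \code{r2}, \code{p_value} (NA when
#'   \code{permutations = 0}), \code{ss_total}, \code{ss_within} and
#'   \code{n_groups}.
#' @export
permanova_r2 <- function(dm, metadata, permutations = 999, seed = NULL) {
  dm <- as.matrix(dm)
  ids <- rownames(dm)
  missing <- setdiff(ids, names(metadata))
  if (length(missing) > 0L)
    stopf("unlabeled sample(s): %s", paste(missing, collapse = ", "))
  labels <- as.character(metadata[ids])
  if (length(unique(labels)) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  d2 <- dm^2
  n <- length(ids)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_for <- function(lab) {
    sum(vapply(unique(lab), function(g) {
      idx <- which(lab == g)
      if (length(idx) < 2L) return(0)
      sub <- d2[idx, idx]
      sum(sub[upper.tri(sub)]) / length(idx)
    }, numeric(1)))
  }
  ss_within <- ss_within_for(labels)
  r2 <- (ss_total - ss_within) / ss_total
  p <- NA_real_
  if (permutations > 0) {
    if (is.null(seed))
      stop("a seed is required for the permutation test", call. = FALSE)
    perm_r2 <- with_seed(seed, vapply(seq_len(permutations), function(i) {
      lab <- sample(labels)
      (ss_total - ss_within_for(lab)) / ss_total
    }, numeric(1)))
    p <- (1 + sum(perm_r2 >= r2)) / (permutations + 1)
  }
  list(r2 = r2, p_value = p, ss_total = ss_total, ss_within = ss_within,
       n_groups = length(unique(labels)))
}

#' Nearest-profile classification against a labelled database
#'
#' Assigns each query profile the label of its closest database profile
#' under Bray-Curtis dissimilarity (database search semantics: top-1
#' match wins). Queries listed in \code{exclude_ids} — e.g. amplicon
#' samples from the same hosts as the database WGS samples — are
#' skipped. Ties are broken by the lexicographically smallest database
#' sample ID.
#'
#' @param database Samples x functions abundance matrix of reference
#'   profiles (e.g. WGS).
#' @param database_labels Named character vector covering the database.
#' @param queries Samples x functions abundance matrix to classify.
#' @param exclude_ids Query sample IDs to skip.
#' @return Named character vector of predicted labels for the retained
#'   queries.
#' @export
nearest_profile_classify <- function(database, database_labels, queries,
                                     exclude_ids = character(0)) {
  database <- as.matrix(database); queries <- as.matrix(queries)
  if (nrow(database) < 1L) stop("empty database", call. = FALSE)
  missing <- setdiff(rownames(database), names(database_labels))
  if (length(missing) > 0L)
    stopf("database sample(s) without a label: %s",
          paste(missing, collapse = ", "))
  if (length(intersect(colnames(database), colnames(queries))) == 0L)
    stop("query and database function universes are disjoint", call. = FALSE)
  keep <- setdiff(rownames(queries), exclude_ids)
  queries <- queries[keep, , drop = FALSE]
  funs <- union(colnames(database), colnames(queries))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(funs),
                  dimnames = list(rownames(m), funs))
    out[, colnames(m)] <- m
    out
  }
  db <- pad(database); qu <- pad(queries)
  db <- db[order(rownames(db)), , drop = FALSE]  # lexicographic tie-break
  db_sums <- rowSums(db)
  preds <- vapply(seq_len(nrow(qu)), function(i) {
    q <- qu[i, ]
    tot <- sum(q) + db_sums
    num <- colSums(abs(t(db) - q))
    d <- ifelse(tot == 0, 0, num / tot)
    unname(database_labels[rownames(db)[which.min(d)]])
  }, character(1))
  stats::setNames(preds, rownames(qu))
}

#' Confusion counts and classification metrics
#'
#' Computes the confusion matrix of a binary status classification and
#' the standard derived metrics: accuracy = (TP + TN) / all samples,
#' recall = TP / (TP + FN), precision = TP / (TP + FP),
#' F1 = 2 * recall * precision / (recall + precision). Metrics whose
#' denominator is zero are reported as \code{NA} (undefined) rather than
#' coerced to 0.
#'
#' @param predicted,truth Aligned label vectors; if both are named, they
#'   are matched by name.
#' @param positive_label The label counted as positive (e.g. the disease
#'   status).
#' @return A list of class \code{"classification_report"} with counts
#'   \code{tp}, \code{tn}, \code{fp}, \code{fn} and metrics
#'   \code{accuracy}, \code{precision}, \code{recall}, \code{f1}.
#' @export
classification_metrics <- function(predicted, truth, positive_label) {
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    common <- intersect(names(predicted), names(truth))
    predicted <- predicted[common]; truth <- truth[common]
  }
  if (length(predicted) != length(truth))
    stopf("length mismatch: %d predictions vs %d truths",
          length(predicted), length(truth))
  pp <- predicted == positive_label
  tp_ <- truth == positive_label
  tp <- sum(pp & tp_); fp <- sum(pp & !tp_)
  fn <- sum(!pp & tp_); tn <- sum(!pp & !tp_)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / length(truth),
                 precision = precision, recall = recall, f1 = f1,
                 n = length(truth)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification of %d samples: TP=%d TN=%d FP=%d FN=%d\n",
              x$n, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  accuracy=%.4f precision=%.4f recall=%.4f F1=%.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Seeded random selection of training pairs
#'
#' Draws \code{n} pairs uniformly without replacement. When metadata is
#' supplied, the draw is rejected and resampled until every group (e.g.
#' every body site) is represented at least once, mirroring the usual
#' protocol of covering all habitats in the training set.
#'
#' @param pairs A \code{"paired_profiles"} object.
#' @param n Number of pairs to select.
#' @param metadata Optional named character vector of group labels.
#' @param seed Seed making the selection deterministic.
#' @return A \code{"paired_profiles"} object with the selected pairs.
#' @export
select_training_pairs <- function(pairs, n, metadata = NULL, seed) {
  ids <- pairs$sample_ids
  if (n > length(ids))
    stopf("requested %d pairs but only %d available", n, length(ids))
  if (!is.null(metadata)) {
    missing <- setdiff(ids, names(metadata))
    if (length(missing) > 0L)
      stopf("unlabeled pair(s): %s", paste(missing, collapse = ", "))
    groups <- unique(metadata[ids])
    if (n < length(groups))
      stopf("n = %d cannot cover all %d groups", n, length(groups))
  }
  sel <- with_seed(seed, {
    cand <- NULL
    for (attempt in seq_len(100000L)) {
      cand <- sort(sample(ids, n))
      if (is.null(metadata) ||
          length(unique(metadata[cand])) == length(unique(metadata[ids])))
        break
      cand <- NULL
    }
    if (is.null(cand))
      stop("could not cover all groups after 100000 resampling attempts",
           call. = FALSE)
    cand
  })
  subset_pairs(pairs, sel)
}
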