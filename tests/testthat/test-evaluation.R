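test_that("Bray-Curtis matches its closed form and stays within bounds", {
  expect_equal(bray_curtis(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(bray_curtis(c(0, 0), c(0, 0)), 0)  # defined degenerate case
  expect_error(bray_curtis(c(1, 0), c(1, 0, 0)), "length mismatch")

  set.seed(2)
  for (i in 1:25) {
    u <- runif(10); v <- runif(10)
    d <- bray_curtis(u, v)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(v, u))                       # symmetry
    expect_equal(d, vegan::vegdist(rbind(u, v))[1])          # oracle
  }
})

test_that("the distance matrix is symmetric, zero-diagonal and consistent", {
  set.seed(3)
  m <- matrix(runif(15), 3, 5,
              dimnames = list(c("A", "B", "C"), paste0("F", 1:5)))
  dm <- distance_matrix(m)
  expect_identical(dm, t(dm))
  expect_equal(unname(diag(dm)), c(0, 0, 0))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(dm[i, j], bray_curtis(m[i, ], m[j, ]))

  dup <- m[c(1, 1), ]
  rownames(dup) <- c("A", "A2")
  expect_equal(unname(distance_matrix(dup)), matrix(0, 2, 2))
  expect_error(distance_matrix(m[1, , drop = FALSE]), "at least 2")
})

test_that("paired and within-group distance summaries are correct", {
  m <- profile_mat(c(0.5, 0.5), "A", c("F1", "F2"))
  expect_equal(paired_distance_summary(as_pairs(m, m))[c("mean", "sd")],
               list(mean = 0, sd = 0))

  # two pairs at known distances 0.5 and 0
  wgs <- profile_mat(c(0.5, 0.5, 1, 0), c("A", "B"), c("F1", "F2"))
  amp <- profile_mat(c(1, 0, 1, 0), c("A", "B"), c("F1", "F2"))
  s <- paired_distance_summary(as_pairs(wgs, amp))
  expect_equal(s$mean, 0.25)
  expect_equal(s$sd, stats::sd(c(0.5, 0)))
  s_pop <- paired_distance_summary(as_pairs(wgs, amp), sd_divisor = "n")
  expect_equal(s_pop$sd, 0.25)

  four <- rbind(wgs, amp * 0 + c(0.25, 0.75))
  rownames(four) <- c("A", "B", "C", "D")
  dm <- distance_matrix(four)
  meta <- c(A = "g1", B = "g1", C = "g2", D = "g2")
  wg <- within_group_distance_summary(dm, meta)
  expect_equal(wg$mean[wg$group == "g1"], dm["A", "B"])
  expect_equal(wg$mean[wg$group == "g2"], dm["C", "D"])
  # singleton groups have no within pairs: undefined, not zero
  wg1 <- within_group_distance_summary(dm, c(A = "x", B = "y", C = "y",
                                             D = "y"))
  expect_true(is.na(wg1$mean[wg1$group == "x"]))
  expect_error(within_group_distance_summary(dm, meta[-1]),
               "unlabeled sample.*A")
})

test_that("PCoA recovers Euclidean-embeddable configurations", {
  # known planar points; their distance matrix must be reproduced
  pts <- matrix(c(0, 0, 3, 0, 0, 4, 3, 4, 1, 2), ncol = 2, byrow = TRUE)
  rownames(pts) <- paste0("P", 1:5)
  dm <- as.matrix(stats::dist(pts))
  ord <- pcoa(dm, n_axes = 2)
  rec <- as.matrix(stats::dist(ord$coordinates))
  expect_lt(max(abs(rec - dm)), 1e-9)
  expect_equal(sum(ord$explained), 1, tolerance = 1e-9)
  # cross-check coordinates against classical scaling up to sign
  cs <- stats::cmdscale(dm, k = 2)
  expect_lt(max(abs(abs(ord$coordinates) - abs(cs))), 1e-9)

  # two samples at distance d sit at +/- d/2 on the single axis
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  ord2 <- pcoa(d2, n_axes = 1)
  expect_equal(sort(unname(ord2$coordinates[, 1])), c(-0.3, 0.3),
               tolerance = 1e-12)

  # duplicated sample gets identical coordinates
  dm3 <- as.matrix(stats::dist(pts[c(1, 1, 2, 3), ]))
  ord3 <- pcoa(dm3, n_axes = 2)
  expect_lt(max(abs(ord3$coordinates[1, ] - ord3$coordinates[2, ])), 1e-9)

  # deterministic axis orientation: largest-magnitude loading positive
  for (ax in seq_len(ncol(ord$coordinates)))
    expect_gt(ord$coordinates[which.max(abs(ord$coordinates[, ax])), ax], 0)

  expect_error(pcoa(matrix(0, 3, 3), 2), "no positive eigenvalues")
})

test_that("PERMANOVA R2 matches the direct partition and vegan::adonis2", {
  set.seed(8)
  # two tight, well-separated clusters of profiles
  base1 <- c(rep(0.18, 5), rep(0.02, 5))
  base2 <- c(rep(0.02, 5), rep(0.18, 5))
  prof <- rbind(
    t(replicate(5, abs(base1 + rnorm(10, 0, 0.002)))),
    t(replicate(5, abs(base2 + rnorm(10, 0, 0.002)))))
  prof <- prof / rowSums(prof)
  dimnames(prof) <- list(paste0("S", 1:10), paste0("F", 1:10))
  meta <- setNames(rep(c("c1", "c2"), each = 5), rownames(prof))
  dm <- distance_matrix(prof)
  res <- permanova_r2(dm, meta, permutations = 199, seed = 4)
  expect_gt(res$r2, 0.9)
  expect_lt(res$p_value, 0.05)

  # direct sum-of-squares computation as an independent oracle
  n <- 10; d2 <- dm^2
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- sum(d2[1:5, 1:5][upper.tri(d2[1:5, 1:5])]) / 5 +
    sum(d2[6:10, 6:10][upper.tri(d2[6:10, 6:10])]) / 5
  expect_equal(res$r2, (ss_tot - ss_w) / ss_tot, tolerance = 1e-12)

  # vegan cross-check
  adon <- vegan::adonis2(stats::as.dist(dm) ~ grp,
                         data = data.frame(grp = meta), permutations = 0)
  expect_equal(res$r2, adon$R2[1], tolerance = 1e-10)

  # invariance to group renaming and to sample reordering
  meta2 <- setNames(ifelse(meta == "c1", "zzz", "aaa"), names(meta))
  expect_equal(permanova_r2(dm, meta2, permutations = 0)$r2, res$r2)
  ix <- sample(10)
  expect_equal(permanova_r2(dm[ix, ix], meta, permutations = 0)$r2, res$r2)

  # random labels on one homogeneous cloud: small R2, p above 0.05
  set.seed(12)
  cloud <- matrix(abs(rnorm(200, 0.1, 0.01)), 20, 10)
  cloud <- cloud / rowSums(cloud)
  dimnames(cloud) <- list(paste0("S", 1:20), paste0("F", 1:10))
  lab <- setNames(sample(rep(c("a", "b"), 10)), rownames(cloud))
  null_res <- permanova_r2(distance_matrix(cloud), lab,
                           permutations = 199, seed = 5)
  expect_lt(null_res$r2, 0.2)
  expect_gt(null_res$p_value, 0.05)

  expect_error(permanova_r2(dm, setNames(rep("g", 10), names(meta)),
                            permutations = 0), "at least 2 groups")
  expect_error(permanova_r2(dm, meta, permutations = 99), "seed")
})

test_that("nearest-profile classification follows 1-NN with stated tie rule", {
  db <- profile_mat(c(0.8, 0.2, 0,
                      0, 0.2, 0.8,
                      0.5, 0.5, 0), c("D1", "D2", "D3"),
                    c("F1", "F2", "F3"))
  labels <- c(D1 = "healthy", D2 = "gingivitis", D3 = "healthy")
  # identical query wins at distance 0
  q <- profile_mat(c(0, 0.2, 0.8), "Q1", c("F1", "F2", "F3"))
  expect_equal(unname(nearest_profile_classify(db, labels, q)), "gingivitis")

  # equidistant query takes the lexicographically smallest database ID
  db2 <- profile_mat(c(1, 0, 0, 1), c("B", "A"), c("F1", "F2"))
  lab2 <- c(A = "right", B = "left")
  qeq <- profile_mat(c(0.5, 0.5), "Q", c("F1", "F2"))
  expect_equal(unname(nearest_profile_classify(db2, lab2, qeq)), "right")

  # excluded queries are skipped
  q2 <- rbind(q, profile_mat(c(0.8, 0.2, 0), "Q2", c("F1", "F2", "F3")))
  preds <- nearest_profile_classify(db, labels, q2, exclude_ids = "Q1")
  expect_identical(names(preds), "Q2")

  # consistent column permutation leaves predictions unchanged
  perm <- c(3, 1, 2)
  expect_identical(
    nearest_profile_classify(db[, perm], labels, q2[, perm]),
    nearest_profile_classify(db, labels, q2))

  qdisj <- profile_mat(c(1, 0), "Q", c("G1", "G2"))
  expect_error(nearest_profile_classify(db, labels, qdisj), "disjoint")
})

test_that("classification metrics reproduce the confusion-count formulas", {
  # TP=3 FN=1 FP=1 TN=5
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  rep_ <- classification_metrics(pred, truth, "pos")
  expect_equal(rep_[c("tp", "fn", "fp", "tn")],
               list(tp = 3L, fn = 1L, fp = 1L, tn = 5L))
  expect_equal(rep_$recall, 0.75)
  expect_equal(rep_$precision, 0.75)
  expect_equal(rep_$f1, 0.75)
  expect_equal(rep_$accuracy, 0.8)
  expect_equal(rep_$tp + rep_$tn + rep_$fp + rep_$fn, length(truth))

  perfect <- classification_metrics(truth, truth, "pos")
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$f1, 1)

  # no positives anywhere: precision and recall undefined, not zero
  none <- classification_metrics(rep("neg", 4), rep("neg", 4), "pos")
  expect_true(is.na(none$precision)); expect_true(is.na(none$recall))
  expect_equal(none$accuracy, 1)

  expect_error(classification_metrics(c("a", "b"), c("a"), "a"),
               "length mismatch")
})

test_that("training-pair selection is seeded, covering, and exhaustive at n = all", {
  set.seed(77)
  m <- matrix(runif(80), 8, 10,
              dimnames = list(paste0("S", 1:8), paste0("F", 1:10)))
  pairs <- align_pairs(m, m)
  all_sel <- select_training_pairs(pairs, 8, seed = 1)
  expect_setequal(all_sel$sample_ids, pairs$sample_ids)

  s1 <- select_training_pairs(pairs, 3, seed = 42)
  s2 <- select_training_pairs(pairs, 3, seed = 42)
  expect_identical(s1$sample_ids, s2$sample_ids)

  meta <- setNames(rep(c("g1", "g2", "g3", "g4"), each = 2),
                   paste0("S", 1:8))
  cov <- select_training_pairs(pairs, 4, metadata = meta, seed = 3)
  expect_setequal(unname(meta[cov$sample_ids]), c("g1", "g2", "g3", "g4"))

  expect_error(select_training_pairs(pairs, 9, seed = 1), "only 8 available")
  expect_error(select_training_pairs(pairs, 3, metadata = meta, seed = 1),
               "cannot cover")
})
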