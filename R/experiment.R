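#' Training-set-size experiment for calibration performance
#'
#' Reproduces the standard protocol for assessing how many paired
#' training samples a calibration needs: for each training-set size N
#' and each repeat, randomly select N pairs (covering every group when
#' metadata is given), train a model, calibrate the held-out amplicon
#' profiles, and record the mean and standard deviation of the paired
#' WGS:amplicon Bray-Curtis distances before and after calibration.
#' Per-N means over the repeats give the machine-readable analogue of a
#' distance-versus-N curve, which typically plateaus at N around 15.
#'
#' @param wgs,amplicon Paired samples x functions abundance matrices
#'   (matched by sample ID).
#' @param n_list Integer vector of training-set sizes.
#' @param repeats Number of random selections per N (default 10).
#' @param seed Master seed; every selection derives its own sub-seed.
#' @param metadata Optional named group labels; when given, every
#'   selection covers all groups.
#' @param clip_negative,renormalize Passed to
#'   \code{\link{calibrate_profiles}}.
#' @return An object of class \code{"calibration_experiment"}: a list
#'   with \code{per_repeat} (one row per (N, repeat): mean/sd before
#'   and after calibration over the held-out pairs) and \code{per_n}
#'   (per-N means over repeats).
#' @export
run_experiment <- function(wgs, amplicon, n_list, repeats = 10, seed,
                           metadata = NULL, clip_negative = TRUE,
                           renormalize = TRUE) {
  pairs <- align_pairs(wgs, amplicon)
  n_avail <- length(pairs$sample_ids)
  n_list <- as.integer(n_list)
  if (any(n_list >= n_avail))
    stopf("every N must leave held-out pairs: %d pairs available", n_avail)
  if (any(n_list < 1L)) stop("N must be >= 1", call. = FALSE)
  seeds <- matrix(derive_seeds(seed, length(n_list) * repeats),
                  nrow = length(n_list))
  rows <- list()
  for (i in seq_along(n_list)) {
    for (r in seq_len(repeats)) {
      train <- select_training_pairs(pairs, n_list[i], metadata,
                                     seed = seeds[i, r])
      held <- subset_pairs(pairs,
                           setdiff(pairs$sample_ids, train$sample_ids))
      model <- train_model(train)
      calibrated <- calibrate_profiles(model, held$amplicon,
                                       clip_negative = clip_negative,
                                       renormalize = renormalize)
      before <- paired_distance_summary(held)
      after <- paired_distance_summary(
        structure(list(wgs = held$wgs, amplicon = calibrated,
                       sample_ids = held$sample_ids),
                  class = "paired_profiles"))
      rows[[length(rows) + 1L]] <- data.frame(
        n_train = n_list[i], repeat_id = r, n_held_out = before$n,
        mean_before = before$mean, sd_before = before$sd,
        mean_after = after$mean, sd_after = after$sd)
    }
  }
  per_repeat <- do.call(rbind, rows)
  per_n <- do.call(rbind, lapply(split(per_repeat, per_repeat$n_train),
    function(df) data.frame(
      n_train = df$n_train[1L], repeats = nrow(df),
      mean_before = mean(df$mean_before),
      mean_after = mean(df$mean_after))))
  per_n <- per_n[order(per_n$n_train), ]
  rownames(per_n) <- NULL
  structure(list(per_repeat = per_repeat, per_n = per_n, seed = seed),
            class = "calibration_experiment")
}

#' @export
print.calibration_experiment <- function(x, ...) {
  cat("Calibration training-set-size experiment\n")
  cat(sprintf("  %d repeats per N, seed %d\n",
              max(x$per_repeat$repeat_id), x$seed))
  print(x$per_n, row.names = FALSE)
  invisible(x)
}

#' Plot the distance-versus-training-size curve of an experiment
#'
#' @param x A \code{"calibration_experiment"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.calibration_experiment <- function(x, ...) {
  pn <- x$per_n
  ylim <- range(pn$mean_before, pn$mean_after)
  graphics::plot(pn$n_train, pn$mean_after, type = "b", pch = 19,
                 ylim = ylim, xlab = "training pairs (N)",
                 ylab = "mean paired Bray-Curtis distance", ...)
  graphics::lines(pn$n_train, pn$mean_before, type = "b", pch = 1,
                  lty = 2)
  graphics::legend("topright", legend = c("calibrated", "uncalibrated"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
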