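#' Least-squares fit of one function's amplicon-to-WGS mapping
#'
#' For a single molecular function, estimates the affine map
#' \eqn{k_{WGS} = slope \cdot k_{16S} + intercept} that minimizes the
#' total squared error over N paired training abundances, using the
#' closed-form least-squares solution. When the amplicon abundances have
#' zero variance the slope is undefined; the fit then falls back to the
#' least-squares-optimal constant predictor (slope 0, intercept mean(y))
#' and is flagged degenerate.
#'
#' @param x Numeric vector of amplicon-predicted abundances.
#' @param y Numeric vector of WGS-derived abundances, same length.
#' @param function_id Optional identifier carried in the result.
#' @return A list with elements \code{function_id}, \code{slope},
#'   \code{intercept}, \code{n_train} and \code{degenerate}.
#' @export
fit_function_regression <- function(x, y, function_id = NA_character_) {
  if (length(x) != length(y))
    stopf("length mismatch: %d amplicon vs %d WGS values",
          length(x), length(y))
  n <- length(x)
  if (n < 1L) stop("at least one training pair is required", call. = FALSE)
  # centered form of the closed-form least-squares solution (numerically
  # stable for abundance-scale values); degenerate iff x has exactly
  # zero sample variance
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) {
    return(list(function_id = function_id, slope = 0,
                intercept = ybar, n_train = n, degenerate = TRUE))
  }
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  list(function_id = function_id, slope = slope,
       intercept = ybar - slope * xbar, n_train = n, degenerate = FALSE)
}

#' Train a per-function calibration model from paired profiles
#'
#' Fits, for every molecular function in the paired tables, the affine
#' map from 16S-amplicon-predicted relative abundance to shotgun-WGS
#' relative abundance by ordinary least squares (the WGS profile is
#' treated as the gold standard). One regression is fitted per function;
#' a function absent from a sample contributes abundance 0.
#'
#' @param pairs A \code{"paired_profiles"} object from
#'   \code{\link{align_pairs}}, or a list with aligned \code{wgs} and
#'   \code{amplicon} matrices sharing dimnames.
#' @param created_from Free-text provenance stored with the model.
#' @return An object of class \code{"calibration_model"}: a list with
#'   \code{regressions} (data frame with columns function_id, slope,
#'   intercept, n_train, degenerate), \code{training_sample_ids} and
#'   \code{created_from}.
#' @seealso \code{\link{calibrate_profiles}}, \code{\link{save_model}}
#' @examples
#' sim <- simulate_paired_dataset(generator_config(
#'   n_functions = 50, groups = list(gut = 6, oral = 6), seed = 1))
#' fit <- train_model(align_pairs(sim$wgs, sim$amplicon))
#' fit
#' head(coef(fit))
#' @export
train_model <- function(pairs, created_from = "train_model") {
  x <- as.matrix(pairs$amplicon); y <- as.matrix(pairs$wgs)
  if (!identical(dim(x), dim(y)) || !identical(colnames(x), colnames(y)))
    stop("`pairs` must hold aligned wgs/amplicon matrices (see align_pairs)",
         call. = FALSE)
  n <- nrow(x)
  if (n < 1L) stop("zero training pairs", call. = FALSE)
  # vectorized closed-form least squares (centered form), one fit per
  # column; degenerate iff a column's abscissae have zero variance
  xbar <- colMeans(x); ybar <- colMeans(y)
  xc <- sweep(x, 2, xbar); yc <- sweep(y, 2, ybar)
  sxx <- colSums(xc^2); sxy <- colSums(xc * yc)
  degen <- sxx == 0
  slope <- ifelse(degen, 0, sxy / ifelse(degen, 1, sxx))
  intercept <- ifelse(degen, ybar, ybar - slope * xbar)
  structure(list(
    regressions = data.frame(
      function_id = colnames(x), slope = unname(slope),
      intercept = unname(intercept), n_train = n,
      degenerate = unname(degen), stringsAsFactors = FALSE),
    training_sample_ids = rownames(x),
    created_from = created_from),
    class = "calibration_model")
}

#' Calibrate amplicon profiles with a trained model
#'
#' Applies the per-function affine map to every sample of an
#' amplicon-predicted profile table, producing WGS-equivalent expected
#' abundances. Functions in the table without a model regression are
#' passed through unchanged (their count is reported via a message);
#' functions known to the model but absent from the table are never
#' created. Negative calibrated abundances are clipped to 0 by default
#' (relative abundances are non-negative), and each sample is
#' renormalized to sum 1 so the output remains compositional.
#'
#' @param model A \code{"calibration_model"}.
#' @param amplicon Samples x functions abundance matrix to calibrate.
#' @param clip_negative Clip negative outputs to 0 (default \code{TRUE}).
#' @param renormalize Rescale each sample to sum 1 (default \code{TRUE}).
#' @return The calibrated samples x functions matrix.
#' @export
calibrate_profiles <- function(model, amplicon, clip_negative = TRUE,
                               renormalize = TRUE) {
  stopifnot(inherits(model, "calibration_model"))
  reg <- model$regressions
  if (nrow(reg) == 0L) stop("model has no regressions", call. = FALSE)
  amplicon <- as.matrix(amplicon)
  validate_profile_table(amplicon, "amplicon table")
  hit <- colnames(amplicon) %in% reg$function_id
  n_pass <- sum(!hit)
  if (n_pass > 0L)
    message(n_pass, " function(s) absent from the model passed through unchanged")
  idx <- match(colnames(amplicon)[hit], reg$function_id)
  out <- amplicon
  out[, hit] <- sweep(sweep(amplicon[, hit, drop = FALSE], 2,
                            reg$slope[idx], `*`),
                      2, reg$intercept[idx], `+`)
  if (clip_negative) out[out < 0] <- 0
  if (renormalize) {
    sums <- rowSums(out)
    sums[sums == 0] <- 1
    out <- out / sums
  }
  out
}

#' @export
print.calibration_model <- function(x, ...) {
  r <- x$regressions
  cat(sprintf(
    "Per-function amplicon-to-WGS calibration model\n  %d functions (%d degenerate), trained on %d paired samples\n",
    nrow(r), sum(r$degenerate), length(x$training_sample_ids)))
  invisible(x)
}

#' @export
summary.calibration_model <- function(object, ...) {
  r <- object$regressions
  nd <- r[!r$degenerate, , drop = FALSE]
  out <- list(
    n_functions = nrow(r),
    n_degenerate = sum(r$degenerate),
    n_train = length(object$training_sample_ids),
    slope_summary = if (nrow(nd)) summary(nd$slope) else NULL,
    intercept_summary = if (nrow(nd)) summary(nd$intercept) else NULL,
    created_from = object$created_from)
  class(out) <- "summary.calibration_model"
  out
}

#' @export
print.summary.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration model: %d functions, %d degenerate, %d training pairs\n",
              x$n_functions, x$n_degenerate, x$n_train))
  if (!is.null(x$slope_summary)) {
    cat("Slopes (non-degenerate):\n"); print(x$slope_summary)
    cat("Intercepts (non-degenerate):\n"); print(x$intercept_summary)
  }
  cat("Provenance:", x$created_from, "\n")
  invisible(x)
}

#' @export
coef.calibration_model <- function(object, ...) {
  r <- object$regressions
  m <- cbind(slope = r$slope, intercept = r$intercept)
  rownames(m) <- r$function_id
  m
}

#' Predict (calibrate) amplicon profiles from a fitted model
#'
#' @param object A \code{"calibration_model"}.
#' @param newdata Samples x functions amplicon abundance matrix.
#' @param ... Passed to \code{\link{calibrate_profiles}}
#'   (\code{clip_negative}, \code{renormalize}).
#' @return Calibrated abundance matrix.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  calibrate_profiles(object, newdata, ...)
}

#' Training residuals of a calibration model
#'
#' @param object A \code{"calibration_model"}.
#' @param pairs The \code{"paired_profiles"} the model was trained on.
#' @param ... Unused.
#' @return Matrix of residuals (observed WGS minus fitted) per training
#'   sample and function.
#' @export
residuals.calibration_model <- function(object, pairs, ...) {
  fitted <- calibrate_profiles(object, pairs$amplicon,
                               clip_negative = FALSE, renormalize = FALSE)
  pairs$wgs[, colnames(fitted), drop = FALSE] - fitted
}

#' Plot the fitted per-function calibration parameters
#'
#' Draws a slope-versus-intercept scatter of the non-degenerate
#' per-function regressions, with reference lines at the identity
#' mapping (slope 1, intercept 0).
#'
#' @param x A \code{"calibration_model"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.calibration_model <- function(x, ...) {
  r <- x$regressions[!x$regressions$degenerate, , drop = FALSE]
  graphics::plot(r$slope, r$intercept, xlab = "slope", ylab = "intercept",
                 main = "Per-function calibration parameters", ...)
  graphics::abline(v = 1, h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Save / load a calibration model as versioned TSV
#'
#' The model file is plain TSV (columns function_id, slope, intercept,
#' n_train, degenerate) preceded by \code{#}-comment lines carrying a
#' format version and the training sample IDs, so models diff cleanly
#' and port across languages. \code{load_model(save_model(m))}
#' reproduces slopes and intercepts to within 1e-12.
#'
#' @param model A \code{"calibration_model"} with at least one regression.
#' @param path File path.
#' @return \code{save_model} returns the path invisibly;
#'   \code{load_model} returns a \code{"calibration_model"}.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  if (nrow(model$regressions) == 0L)
    stop("refusing to save a model with no regressions", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ampcal calibration model v1",
               paste0("# training_samples: ",
                      paste(model$training_sample_ids, collapse = ",")),
               paste0("# created_from: ", model$created_from)), con)
  utils::write.table(
    format(model$regressions, digits = 17, scientific = FALSE, trim = TRUE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  train_ids <- character(0)
  created <- "load_model"
  for (cl in lines[is_comment]) {
    if (startsWith(cl, "# training_samples: "))
      train_ids <- strsplit(sub("^# training_samples: ", "", cl), ",")[[1L]]
    if (startsWith(cl, "# created_from: "))
      created <- sub("^# created_from: ", "", cl)
  }
  body_start <- which(!is_comment)[1L]
  if (is.na(body_start)) stopf("no model table found in %s", path)
  df <- utils::read.delim(text = paste(lines[!is_comment], collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("function_id", "slope", "intercept", "n_train", "degenerate")
  if (!all(need %in% colnames(df)))
    stopf("malformed model file %s: missing column(s) %s", path,
          paste(setdiff(need, colnames(df)), collapse = ", "))
  for (col in c("slope", "intercept", "n_train")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad_row <- which(is.na(v))[1L]
      stopf("non-numeric %s at line %d of %s", col,
            body_start + bad_row, path)
    }
    df[[col]] <- v
  }
  df$degenerate <- as.logical(df$degenerate)
  structure(list(regressions = df, training_sample_ids = train_ids,
                 created_from = created),
            class = "calibration_model")
}
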