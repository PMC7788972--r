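# Synthetic paired WGS/16S-amplicon profile generator.
#
# The generative model mirrors the assumption under which the calibration
# is identifiable: per function, the WGS relative abundance is an affine
# function of the amplicon-predicted one plus observation noise. Group
# means share a sparse Dirichlet backbone so function universes overlap
# across groups, as they do in real KO tables.

# Fixed sparsity of the shared Dirichlet backbone group means are drawn
# around (KO tables are sparse; most functions are rare or absent).
.BACKBONE_ALPHA <- 0.4

#' Configuration for the synthetic paired-profile generator
#'
#' @param n_functions Number of molecular functions (>= 2).
#' @param groups Named list or vector mapping group label (e.g. body
#'   site or disease status) to its number of paired samples (>= 1).
#' @param concentration Dirichlet concentration of samples around their
#'   group mean; larger values give tighter clusters.
#' @param group_mean_concentration Dirichlet concentration of the group
#'   means around the shared sparse backbone; small values give very
#'   distinct communities (body-site-like), large values give subtly
#'   different ones (disease-status-like).
#' @param slope_range Length-2 range the ground-truth per-function
#'   slopes are drawn from uniformly; the lower bound must be > 0.
#' @param intercept_scale Upper bound of the uniform ground-truth
#'   intercepts (0 disables intercepts).
#' @param noise_sd Standard deviation of additive Gaussian observation
#'   noise on WGS abundances (clipped at 0).
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @return A validated list of class \code{"generator_config"}.
#' @export
generator_config <- function(n_functions = 300,
                             groups = list(gut = 40, oral = 40,
                                           skin = 25, vaginal = 20),
                             concentration = 1000,
                             group_mean_concentration = 50,
                             slope_range = c(0.5, 2),
                             intercept_scale = 0.001,
                             noise_sd = 5e-4,
                             seed) {
  groups <- unlist(groups)
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("`groups` must be named by group label", call. = FALSE)
  if (n_functions < 2L) stop("n_functions must be >= 2", call. = FALSE)
  if (any(groups < 1)) stop("every group needs >= 1 sample", call. = FALSE)
  if (length(slope_range) != 2L || slope_range[1L] <= 0 ||
      slope_range[2L] < slope_range[1L])
    stop("slope_range must be (low, high) with low > 0", call. = FALSE)
  if (concentration <= 0 || group_mean_concentration <= 0)
    stop("concentrations must be positive", call. = FALSE)
  if (intercept_scale < 0 || noise_sd < 0)
    stop("intercept_scale and noise_sd must be non-negative", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  structure(list(n_functions = as.integer(n_functions), groups = groups,
                 concentration = concentration,
                 group_mean_concentration = group_mean_concentration,
                 slope_range = slope_range,
                 intercept_scale = intercept_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Backbone and group means are a deterministic function of the seed so
# that paired datasets and unpaired cohorts built from the same config
# share the same community structure.
group_means <- function(config) {
  seed_means <- derive_seeds(config$seed, 3L)[1L]
  with_seed(seed_means, {
    backbone <- rdirichlet1(rep(.BACKBONE_ALPHA, config$n_functions))
    means <- t(vapply(names(config$groups), function(g)
      rdirichlet1(backbone * config$group_mean_concentration),
      numeric(config$n_functions)))
    rownames(means) <- names(config$groups)
    means
  })
}

#' Simulate a paired WGS/16S-amplicon dataset with known distortion
#'
#' Draws, per group, a mean composition from a shared sparse backbone;
#' per sample, an amplicon profile around its group mean; and one
#' ground-truth (slope, intercept) per function. The WGS profile is the
#' affine distortion of the amplicon profile plus Gaussian noise,
#' clipped at 0 and (by default) renormalized. With
#' \code{renormalize_wgs = FALSE} and \code{noise_sd = 0} the WGS table
#' is exactly affine in the amplicon table, so training on all pairs
#' recovers the ground-truth parameters to machine precision.
#'
#' @param config A \code{\link{generator_config}}.
#' @param renormalize_wgs Renormalize WGS profiles to sum 1 after
#'   distortion (realistic, but breaks exact affinity; default
#'   \code{TRUE}).
#' @return A list with \code{wgs} and \code{amplicon} (samples x
#'   functions matrices with identical sample IDs), \code{truth} (the
#'   generating \code{"calibration_model"}), \code{metadata} (sample ID
#'   -> group label) and \code{config}.
#' @export
simulate_paired_dataset <- function(config, renormalize_wgs = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  nf <- config$n_functions
  fun_ids <- sprintf("F%04d", seq_len(nf))
  means <- group_means(config)
  seed_body <- derive_seeds(config$seed, 3L)[2L]
  out <- with_seed(seed_body, {
    slopes <- stats::runif(nf, config$slope_range[1L], config$slope_range[2L])
    intercepts <- stats::runif(nf, 0, config$intercept_scale)
    ids <- unlist(lapply(names(config$groups), function(g)
      sprintf("%s_%03d", g, seq_len(config$groups[[g]]))))
    labels <- rep(names(config$groups), times = config$groups)
    amp <- t(vapply(seq_along(ids), function(i)
      rdirichlet1(config$concentration * means[labels[i], ]),
      numeric(nf)))
    noise <- matrix(stats::rnorm(length(ids) * nf, 0, config$noise_sd),
                    nrow = length(ids))
    wgs <- sweep(amp, 2, slopes, `*`)
    wgs <- sweep(wgs, 2, intercepts, `+`) + noise
    wgs[wgs < 0] <- 0
    list(slopes = slopes, intercepts = intercepts, ids = ids,
         labels = labels, amp = amp, wgs = wgs)
  })
  dimnames(out$amp) <- list(out$ids, fun_ids)
  dimnames(out$wgs) <- list(out$ids, fun_ids)
  if (renormalize_wgs) {
    sums <- rowSums(out$wgs); sums[sums == 0] <- 1
    out$wgs <- out$wgs / sums
  }
  truth <- structure(list(
    regressions = data.frame(
      function_id = fun_ids, slope = out$slopes,
      intercept = out$intercepts, n_train = NA_integer_,
      degenerate = FALSE, stringsAsFactors = FALSE),
    training_sample_ids = character(0),
    created_from = "synthetic ground truth"),
    class = "calibration_model")
  list(wgs = out$wgs, amplicon = out$amp, truth = truth,
       metadata = stats::setNames(out$labels, out$ids), config = config)
}

#' Simulate an amplicon-only cohort consistent with a ground truth
#'
#' Draws new amplicon-regime samples from the same group means as
#' \code{\link{simulate_paired_dataset}} (the config's seed pins the
#' community structure), without paired WGS counterparts. Relative to
#' the WGS regime — the image of the ground-truth affine maps — these
#' samples carry the inverse distortion, so calibrating the cohort with
#' \code{truth} (or a model trained on a small paired set from the same
#' config) moves it toward the WGS regime. This is the unpaired-cohort
#' scenario where one small paired training set calibrates a much
#' larger amplicon-only collection.
#'
#' @param config A \code{\link{generator_config}}.
#' @param truth A \code{"calibration_model"} covering the config's
#'   functions (e.g. the \code{truth} of \code{simulate_paired_dataset});
#'   checked for coverage so that calibration is well-defined.
#' @param n_per_group Optional named vector overriding the config's
#'   per-group sample counts; groups set to 0 are absent from the output.
#' @return A list with \code{amplicon} (samples x functions matrix) and
#'   \code{metadata}.
#' @export
simulate_unpaired_cohort <- function(config, truth, n_per_group = NULL) {
  stopifnot(inherits(config, "generator_config"),
            inherits(truth, "calibration_model"))
  nf <- config$n_functions
  fun_ids <- sprintf("F%04d", seq_len(nf))
  if (!all(fun_ids %in% truth$regressions$function_id))
    stop("truth model does not cover the config's functions", call. = FALSE)
  counts <- config$groups
  if (!is.null(n_per_group)) {
    counts[names(n_per_group)] <- n_per_group
    counts <- counts[counts > 0]
  }
  if (length(counts) == 0L) stop("no samples requested", call. = FALSE)
  means <- group_means(config)
  seed_cohort <- derive_seeds(config$seed, 3L)[3L]
  out <- with_seed(seed_cohort, {
    ids <- unlist(lapply(names(counts), function(g)
      sprintf("%s_cohort_%03d", g, seq_len(counts[[g]]))))
    labels <- rep(names(counts), times = counts)
    amp <- t(vapply(seq_along(ids), function(i)
      rdirichlet1(config$concentration * means[labels[i], ]),
      numeric(nf)))
    list(ids = ids, labels = labels, amp = amp)
  })
  dimnames(out$amp) <- list(out$ids, fun_ids)
  list(amplicon = out$amp, metadata = stats::setNames(out$labels, out$ids))
}
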