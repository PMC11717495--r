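#' @title Synthetic cohorts for the purity/copy-number chain
#' @description Generates tumour/normal mixtures with known ground
#'   truth: integer arm-level copy number profiles, true purities,
#'   noisy observed log2 segments (one simulated probe per
#'   `bin_spacing`, averaged per arm), method-specific biased purity
#'   observers calibrated to published marginals, paired serial-section
#'   replicates, and labelled cell point patterns. Everything is
#'   deterministic under the config seed, with an independent RNG
#'   stream per component.
#' @name synthetic-data
NULL

#' Biased purity-observer model
#'
#' An affine-plus-noise observer of true purity: the reported value is
#' `target_mean + attenuation * (true - truth_mean) * (target_sd /
#' truth_sd)` plus Gaussian noise sized so the marginal SD equals
#' `target_sd`, clamped to \[1, 100\] and rounded to `granularity`
#' (e.g. 5 for pathologist scores, 0 for continuous).
#'
#' @param method Method name.
#' @param target_mean,target_sd Marginal mean and SD (percent) the
#'   observer should reproduce.
#' @param attenuation Fraction in (0, 1] governing correlation with
#'   true purity (1 = fully informative).
#' @param granularity Reporting step in percent (0 = continuous).
#' @return A `bias_model` list.
#' @export
bias_model <- function(method, target_mean, target_sd, attenuation = 1,
                       granularity = 0) {
  stopifnot(target_sd > 0, attenuation > 0, attenuation <= 1,
            granularity >= 0)
  structure(list(method = method, target_mean = target_mean,
                 target_sd = target_sd, attenuation = attenuation,
                 granularity = granularity), class = "bias_model")
}

#' Default observer models
#'
#' Calibrated to the published cohort marginals: expression-based
#' deconvolution (estimate) mean 79.2 SD 10.5, methylation-based
#' (infiniumpurify) 62.7 SD 11.8, pathologist scores (cp) 35.9 SD 13.1
#' at 5% granularity; attenuation 0.6 for all three, matching the
#' mid-range correlations such methods show against cell-count purity.
#'
#' @return Named list of `bias_model`s.
#' @export
default_bias_models <- function() {
  list(
    estimate = bias_model("estimate", 79.2, 10.5, attenuation = 0.6),
    infiniumpurify = bias_model("infiniumpurify", 62.7, 11.8,
                                attenuation = 0.6),
    cp = bias_model("cp", 35.9, 13.1, attenuation = 0.6, granularity = 5)
  )
}

#' Simulation configuration
#'
#' @param seed RNG seed (mandatory).
#' @param n_samples Number of samples.
#' @param arms An `arm_table`.
#' @param cna_rate Per-arm probability of aberration.
#' @param aberrant_cn_weights Named weights over integer copy numbers
#'   for aberrant arms (default favours single-copy events,
#'   colorectal-like).
#' @param purity_mean,purity_sd Truth purity distribution (percent),
#'   Gaussian truncated to `purity_range`.
#' @param purity_range Truncation bounds for true purity (percent).
#' @param noise_sd SD of Gaussian noise on each simulated probe's log2
#'   ratio.
#' @param bin_spacing Base pairs between simulated probes; each arm
#'   carries `max(1, round(length / bin_spacing))` probes whose noisy
#'   log2 ratios are averaged into one segment.
#' @param replicate_sd SD (percentage points) of the slide-to-slide
#'   noise between paired serial sections.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed,
                              n_samples = 300,
                              arms = default_karyotype(),
                              cna_rate = 0.3,
                              aberrant_cn_weights = c("0" = 0.05,
                                                      "1" = 0.45,
                                                      "3" = 0.40,
                                                      "4" = 0.10),
                              purity_mean = 58.9, purity_sd = 16.3,
                              purity_range = c(5, 95),
                              noise_sd = 0.15, bin_spacing = 3e6,
                              replicate_sd = 5) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(arms, "arm_table"), n_samples >= 1,
            cna_rate >= 0, cna_rate <= 1, noise_sd >= 0,
            bin_spacing > 0, replicate_sd >= 0, purity_sd > 0,
            all(aberrant_cn_weights >= 0))
  structure(list(seed = as.integer(seed), n_samples = n_samples,
                 arms = arms, cna_rate = cna_rate,
                 aberrant_cn_weights = aberrant_cn_weights /
                   sum(aberrant_cn_weights),
                 purity_mean = purity_mean, purity_sd = purity_sd,
                 purity_range = purity_range, noise_sd = noise_sd,
                 bin_spacing = bin_spacing, replicate_sd = replicate_sd),
            class = "sim_config")
}

#' Load a simulation config from YAML
#'
#' Any field of [simulation_config()] may appear; `seed` is mandatory.
#' `arms` may name a BED file path.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$arms)) y$arms <- read_arm_bed(y$arms)
  if (!is.null(y$aberrant_cn_weights))
    y$aberrant_cn_weights <- unlist(y$aberrant_cn_weights)
  if (!is.null(y$purity_range)) y$purity_range <- unlist(y$purity_range)
  do.call(simulation_config, y)
}

# independent, reproducible per-component seeds derived from the master
.component_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 6L),
                  c("truth_purity", "profile", "segments", "observers",
                    "slides", "cells"))
}

#' Draw true tumour purities
#'
#' Gaussian truncated to `purity_range` by inverse-CDF sampling.
#'
#' @param config A `sim_config`.
#' @param n Number of draws (default `config$n_samples`).
#' @return Purities in percent.
#' @export
simulate_true_purity <- function(config, n = config$n_samples) {
  lo <- stats::pnorm(config$purity_range[1L], config$purity_mean,
                     config$purity_sd)
  hi <- stats::pnorm(config$purity_range[2L], config$purity_mean,
                     config$purity_sd)
  stats::qnorm(stats::runif(n, lo, hi), config$purity_mean,
               config$purity_sd)
}

#' Simulate true arm-level copy number profiles
#'
#' Each arm is aberrant with probability `cna_rate`; aberrant copy
#' numbers are drawn from `aberrant_cn_weights`, otherwise 2.
#'
#' @param config A `sim_config`.
#' @return Integer matrix, samples x arms (dimnames set).
#' @export
simulate_true_profile <- function(config) {
  n <- config$n_samples; arms <- config$arms
  cn <- matrix(2L, n, nrow(arms),
               dimnames = list(sprintf("S%04d", seq_len(n)), arms$name))
  aberrant <- matrix(stats::runif(n * nrow(arms)) < config$cna_rate,
                     n, nrow(arms))
  k <- sum(aberrant)
  if (k > 0) {
    vals <- as.integer(names(config$aberrant_cn_weights))
    cn[aberrant] <- vals[sample.int(length(vals), k, replace = TRUE,
                                    prob = config$aberrant_cn_weights)]
  }
  cn
}

#' Simulate an observed segment profile for one sample
#'
#' Forward mixture model: each arm's expected log2 ratio is
#' `log2((p * cn + 2 * (1 - p)) / 2)`; probe-level Gaussian noise
#' (`noise_sd`) is added at one probe per `bin_spacing` and averaged
#' into a single segment spanning the arm.
#'
#' @param true_cn Named integer vector of true copy number per arm
#'   (names = arm names of `config$arms`).
#' @param purity_percent True purity in percent, in (0, 100].
#' @param config A `sim_config`.
#' @param sample_id Sample identifier.
#' @return Segment data frame (one segment per arm).
#' @export
simulate_observed_segments <- function(true_cn, purity_percent, config,
                                       sample_id = "sample") {
  stopifnot(purity_percent > 0, purity_percent <= 100)
  arms <- config$arms
  stopifnot(all(arms$name %in% names(true_cn)))
  p <- purity_percent / 100
  cn <- true_cn[arms$name]
  mu <- log2((p * cn + 2 * (1 - p)) / 2)
  n_bins <- pmax(1L, as.integer(round(arms$length / config$bin_spacing)))
  noise <- vapply(n_bins, function(nb)
    mean(stats::rnorm(nb, 0, config$noise_sd)), 0)
  data.frame(sample_id = sample_id, chrom = arms$chrom,
             start = arms$start, end = arms$end,
             log2_ratio = as.numeric(mu + noise),
             stringsAsFactors = FALSE)
}

#' Simulate purity estimates from a biased observer
#'
#' @param true_purity Vector of true purities (percent).
#' @param model A `bias_model`.
#' @param truth_mean,truth_sd Parameters of the truth distribution the
#'   observer is calibrated against (percent).
#' @return Observed purities (percent), clamped to \[1, 100\] and
#'   rounded to the model's granularity.
#' @export
simulate_purity_estimates <- function(true_purity, model,
                                      truth_mean = 58.9,
                                      truth_sd = 16.3) {
  stopifnot(inherits(model, "bias_model"))
  scale <- model$target_sd / truth_sd
  resid_sd <- model$target_sd * sqrt(1 - model$attenuation^2)
  v <- model$target_mean +
    model$attenuation * (true_purity - truth_mean) * scale +
    stats::rnorm(length(true_purity), 0, resid_sd)
  v <- pmin(pmax(v, 1), 100)
  if (model$granularity > 0)
    v <- round(v / model$granularity) * model$granularity
  v
}

#' Simulate paired serial-section purity measurements
#'
#' Two measurements share the true value and receive independent
#' Gaussian perturbations of SD `replicate_sd`, clamped to \[0, 100\].
#'
#' @param true_purity Vector of true purities (percent).
#' @param replicate_sd Slide-to-slide SD in percentage points.
#' @return Matrix with columns `he1`, `he2`.
#' @export
simulate_paired_slides <- function(true_purity, replicate_sd) {
  stopifnot(replicate_sd >= 0)
  n <- length(true_purity)
  m <- cbind(he1 = true_purity + stats::rnorm(n, 0, replicate_sd),
             he2 = true_purity + stats::rnorm(n, 0, replicate_sd))
  m[] <- pmin(100, pmax(0, m))
  m
}

#' Simulate a labelled cell point pattern in a square ROI
#'
#' Poisson(density x area) cells placed uniformly in a square ROI;
#' each is tumour with probability purity/100. Coordinates in microns.
#'
#' @param purity_percent True purity in percent.
#' @param density_per_mm2 Cell density (default 19000, resection-like;
#'   biopsies run nearer 26000).
#' @param area_mm2 ROI area in mm^2.
#' @return List: `detections` (data frame `x`, `y`, `cls`,
#'   `confidence`) and `rois` (a `roi_set` holding the square).
#' @export
simulate_cell_detections <- function(purity_percent,
                                     density_per_mm2 = 19000,
                                     area_mm2 = 1) {
  stopifnot(density_per_mm2 > 0, area_mm2 > 0,
            purity_percent >= 0, purity_percent <= 100)
  side <- sqrt(area_mm2) * 1000            # microns
  n <- stats::rpois(1L, density_per_mm2 * area_mm2)
  cls <- ifelse(stats::runif(n) < purity_percent / 100,
                "tumour", "background")
  det <- data.frame(x = stats::runif(n, 0, side),
                    y = stats::runif(n, 0, side),
                    cls = factor(cls, levels = c("tumour", "background")),
                    confidence = stats::runif(n, 0.5, 1))
  square <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  list(detections = det, rois = roi_set(list(square)))
}

#' Simulate a full cohort bundle
#'
#' Draws true purities and copy number profiles, observed segments,
#' paired-slide cell-count purities (`softctm_he1`, `softctm_he2`) and
#' each biased observer's estimates. Each component consumes its own
#' seeded RNG stream derived from `config$seed`, so the bundle is
#' bit-reproducible and components are independent.
#'
#' @param config A `sim_config`.
#' @param bias_models Named list of `bias_model`s
#'   (default [default_bias_models()]).
#' @return List of class `sim_cohort`: `truth_cn` (matrix samples x
#'   arms), `truth_purity` (named vector, percent), `segments` (all
#'   samples), `purity` (data frame `sample_id`, `method`, `value`
#'   including truth and paired slides), `config`.
#' @export
simulate_cohort <- function(config, bias_models = default_bias_models()) {
  stopifnot(inherits(config, "sim_config"))
  cs <- .component_seeds(config$seed)
  ids <- sprintf("S%04d", seq_len(config$n_samples))

  set.seed(cs[["truth_purity"]])
  truth <- stats::setNames(simulate_true_purity(config), ids)

  set.seed(cs[["profile"]])
  truth_cn <- simulate_true_profile(config)

  set.seed(cs[["segments"]])
  segs <- do.call(rbind, lapply(seq_along(ids), function(i)
    simulate_observed_segments(truth_cn[i, ], truth[[i]], config,
                               sample_id = ids[i])))

  set.seed(cs[["slides"]])
  slides <- simulate_paired_slides(truth, config$replicate_sd)

  set.seed(cs[["observers"]])
  obs <- lapply(bias_models, function(m)
    simulate_purity_estimates(truth, m, truth_mean = config$purity_mean,
                              truth_sd = config$purity_sd))

  purity <- rbind(
    data.frame(sample_id = ids, method = "truth", value = unname(truth)),
    data.frame(sample_id = ids, method = "softctm_he1",
               value = unname(slides[, "he1"])),
    data.frame(sample_id = ids, method = "softctm_he2",
               value = unname(slides[, "he2"])),
    do.call(rbind, lapply(names(obs), function(m)
      data.frame(sample_id = ids, method = m, value = unname(obs[[m]]))))
  )
  structure(list(truth_cn = truth_cn, truth_purity = truth,
                 segments = segs, purity = purity, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d samples x %d arms, methods: %s (seed %d)\n",
    x$config$n_samples, nrow(x$config$arms),
    paste(unique(x$purity$method), collapse = ", "), x$config$seed))
  invisible(x)
}

#' Extract one method's purity vector from a cohort bundle
#'
#' @param cohort A `sim_cohort`.
#' @param method Method name present in `cohort$purity`.
#' @return Named numeric vector (percent) over sample IDs.
#' @export
cohort_purity <- function(cohort, method) {
  sub <- cohort$purity[cohort$purity$method == method, ]
  if (nrow(sub) == 0L)
    stop("method '", method, "' not in cohort", call. = FALSE)
  stats::setNames(sub$value, sub$sample_id)
}
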