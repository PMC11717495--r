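#' @title End-to-end orchestration
#' @description Runs the full chain on a synthetic cohort or on files
#'   in the package dialects: purity tables, purity-adjusted arm-call
#'   matrices per method, WGII, and the concordance report against a
#'   reference method, with a machine-readable manifest.
#' @name pipeline
NULL

#' Read / write a purity table
#'
#' TSV with header `sample_id`, `method`, `value` (percent).
#'
#' @param path File path.
#' @return `read_purity_table`: data frame with those columns.
#' @export
read_purity_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "method", "value")
  if (!all(need %in% names(df)))
    stop("purity table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$value <- as.numeric(df$value)
  df[need]
}

#' @rdname read_purity_table
#' @param purity Purity data frame.
#' @export
write_purity_table <- function(purity, path) {
  utils::write.table(purity[, c("sample_id", "method", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Reports (never raises) dialect violations: out-of-range purities,
#' samples present in segments but missing from the purity table and
#' vice versa, and non-finite log2 ratios.
#'
#' @param segments Segment data frame (or `NULL`).
#' @param purity Purity data frame (or `NULL`).
#' @param arms An `arm_table`.
#' @return Data frame with columns `type`, `message`; zero rows when
#'   clean.
#' @export
validate_inputs <- function(segments = NULL, purity = NULL,
                            arms = default_karyotype()) {
  issues <- list()
  add <- function(type, msg)
    issues[[length(issues) + 1L]] <<- data.frame(type = type,
                                                 message = msg)
  if (!is.null(purity)) {
    bad <- purity$value < 0 | purity$value > 100 | !is.finite(purity$value)
    if (any(bad))
      add("purity_out_of_range",
          sprintf("%d purity value(s) outside [0, 100] (e.g. %s: %g)",
                  sum(bad), purity$sample_id[bad][1L],
                  purity$value[bad][1L]))
  }
  if (!is.null(segments)) {
    if (any(!is.finite(segments$log2_ratio)))
      add("log2_not_finite", "non-finite log2_ratio in segments")
    off <- setdiff(unique(segments$chrom), unique(arms$chrom))
    if (length(off))
      add("unknown_chromosome",
          paste("segment chromosome(s) absent from arm table:",
                paste(off, collapse = ", ")))
  }
  if (!is.null(segments) && !is.null(purity)) {
    for (m in setdiff(unique(purity$method), "truth")) {
      have <- purity$sample_id[purity$method == m]
      miss <- setdiff(unique(segments$sample_id), have)
      if (length(miss))
        add("missing_purity",
            sprintf("method %s lacks purity for sample(s): %s", m,
                    paste(miss, collapse = ", ")))
    }
    orphan <- setdiff(unique(purity$sample_id),
                      unique(segments$sample_id))
    if (length(orphan))
      add("missing_segments",
          paste("purity given for sample(s) without segments:",
                paste(orphan, collapse = ", ")))
  }
  if (length(issues) == 0L)
    return(data.frame(type = character(), message = character()))
  do.call(rbind, issues)
}

#' Run the full analysis chain
#'
#' Either simulates a cohort (`config` given) or loads segment and
#' purity files, then: adjusts every sample's profile with every
#' method's purity, writes per-method arm-call matrices, the WGII
#' table, the concordance report against `reference_method`, the
#' pairwise purity correlation matrix, and a JSON manifest (package
#' version, seed, input digests, warnings).
#'
#' @param output_dir Output directory (created if absent).
#' @param config A `sim_config` or path to its YAML for simulate mode;
#'   `NULL` to read files instead.
#' @param segments_file,purity_file Input paths (file mode).
#' @param arms An `arm_table`.
#' @param reference_method Reference purity method for the concordance
#'   report.
#' @param purity_floor Clamp floor for [mixture_adjust()].
#' @param wgii_level `"arm"` or `"segment"`.
#' @return Invisibly, a list with `arm_calls` (per method), `wgii`,
#'   `concordance`, `purity`, `validation`, `manifest`.
#' @export
run_full <- function(output_dir, config = NULL, segments_file = NULL,
                     purity_file = NULL, arms = default_karyotype(),
                     reference_method = "softctm_he1",
                     purity_floor = 0.05,
                     wgii_level = c("arm", "segment")) {
  wgii_level <- match.arg(wgii_level)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()
  if (!is.null(config)) {
    if (is.character(config)) config <- read_sim_config(config)
    cohort <- simulate_cohort(config)
    segments <- cohort$segments
    purity <- cohort$purity
    arms <- config$arms
    seed <- config$seed
    write_seg(segments, file.path(output_dir, "segments.seg"))
    write_purity_table(purity, file.path(output_dir, "purity.tsv"))
  } else {
    if (is.null(segments_file) || is.null(purity_file))
      stop("need config (simulate mode) or segments_file + purity_file",
           call. = FALSE)
    segments <- read_seg(segments_file)
    purity <- read_purity_table(purity_file)
    inputs <- c(segments_file, purity_file)
    seed <- NA_integer_
  }
  validation <- validate_inputs(segments, purity, arms)
  methods <- setdiff(unique(purity$method), "truth")
  if (!reference_method %in% methods)
    stop("reference method '", reference_method,
         "' has no purity estimates", call. = FALSE)

  warnings_seen <- character()
  runs <- list()
  for (m in methods) {
    pv <- purity[purity$method == m, ]
    # adjustment needs strictly positive purity; the clamp floor governs
    pvec <- stats::setNames(pmax(pv$value, 100 * purity_floor),
                            pv$sample_id)
    runs[[m]] <- withCallingHandlers(
      adjust_cohort(segments, pvec, arms, purity_floor),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    write_arm_calls(runs[[m]],
                    file.path(output_dir, paste0("arm_calls_", m, ".tsv")))
  }

  wg <- do.call(rbind, lapply(methods, function(m) {
    w <- wgii(runs[[m]], arms, level = wgii_level)
    w$method <- m
    w
  }))
  utils::write.table(wg[, c("sample_id", "method", "wgii",
                            "aberrant_length", "total_length")],
                     file.path(output_dir, "wgii.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- concordance_report(runs, reference_method)
  utils::write.table(concordance_table(report),
                     file.path(output_dir, "concordance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(report, function(r)
      list(matrix = r$matrix, n_total = r$n_total, n_diff = r$n_diff,
           n_under = r$n_under, n_over = r$n_over,
           frac_diff = r$frac_diff, frac_under = r$frac_under,
           frac_over = r$frac_over)),
    file.path(output_dir, "concordance.json"),
    auto_unbox = TRUE, digits = NA)

  # pairwise purity correlation matrix across methods
  wide <- Reduce(function(a, b) merge(a, b, by = "sample_id"),
                 lapply(methods, function(m) {
                   d <- purity[purity$method == m, c("sample_id", "value")]
                   names(d)[2L] <- m
                   d
                 }))
  cors <- stats::cor(as.matrix(wide[, methods, drop = FALSE]))
  utils::write.table(round(cors, 4),
                     file.path(output_dir, "purity_correlations.tsv"),
                     sep = "\t", quote = FALSE)

  manifest <- list(
    package = "cnpurity",
    version = as.character(utils::packageVersion("cnpurity")),
    r_version = as.character(getRversion()),
    seed = seed, reference_method = reference_method,
    purity_floor = purity_floor, wgii_level = wgii_level,
    methods = methods,
    n_samples = length(unique(segments$sample_id)),
    n_arms = nrow(arms),
    input_digests = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    warnings = as.list(table(warnings_seen)),
    validation_issues = nrow(validation))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(arm_calls = runs, wgii = wg, concordance = report,
                 purity = purity, validation = validation,
                 manifest = manifest))
}
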