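#' @title Arm-level call concordance between purity methods
#' @description Cross-tabulates {loss, neutral, gain} arm calls from a
#'   reference adjustment run against a comparator run.
#'   *Undercalling*: the comparator calls neutral where the reference
#'   called a CNA (the aberration is missed). *Overcalling*: every
#'   other disagreement, i.e. the comparator calls a CNA the reference
#'   did not make — including the rare loss/gain switches.
#' @name concordance
NULL

#' Round half away from zero
#'
#' The display convention for reported percentages (one decimal by
#' default); differs from [round()], which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Cross-tabulate arm calls of two runs
#'
#' @param reference,comparator Arm-call matrices (samples x arms, same
#'   dimnames) as produced by [adjust_cohort()].
#' @return 3x3 integer matrix, rows = reference call, columns =
#'   comparator call, in loss/neutral/gain order.
#' @export
cross_tabulate <- function(reference, comparator) {
  if (!identical(dim(reference), dim(comparator)))
    stop("call matrices differ in shape", call. = FALSE)
  if (!is.null(rownames(reference)) && !is.null(rownames(comparator))) {
    miss <- c(setdiff(rownames(reference), rownames(comparator)),
              setdiff(rownames(comparator), rownames(reference)))
    if (length(miss))
      stop("sample mismatch between runs: ",
           paste(unique(miss), collapse = ", "), call. = FALSE)
    comparator <- comparator[rownames(reference), colnames(reference),
                             drop = FALSE]
  }
  m <- table(factor(reference, levels = CALL_LEVELS),
             factor(comparator, levels = CALL_LEVELS))
  matrix(as.integer(m), 3, 3, dimnames = list(CALL_LEVELS, CALL_LEVELS))
}

#' Concordance statistics from a 3x3 cross-tabulation
#'
#' @param matrix 3x3 non-negative integer matrix, rows = reference
#'   call, columns = comparator call, loss/neutral/gain order.
#' @return A `cna_concordance` list: `matrix`, `n_total`, `n_diff`,
#'   `n_under`, `n_over`, and percentages `frac_diff` (of `n_total`),
#'   `frac_under`, `frac_over` (of `n_diff`; 0 when `n_diff` is 0).
#'   Percentages carry full precision; printing rounds to 1 decimal,
#'   half away from zero.
#' @export
#' @examples
#' m <- matrix(c(1340, 0, 0, 749, 6808, 675, 1, 0, 1659), 3, 3,
#'             dimnames = list(c("loss","neutral","gain"),
#'                             c("loss","neutral","gain")))
#' concordance_stats(m)  # 1425 differing calls, 99.9% undercalling
concordance_stats <- function(matrix) {
  if (!is.matrix(matrix) || !identical(dim(matrix), c(3L, 3L)))
    stop("expected a 3x3 matrix", call. = FALSE)
  if (any(matrix < 0)) stop("negative counts", call. = FALSE)
  storage.mode(matrix) <- "double"
  dimnames(matrix) <- list(CALL_LEVELS, CALL_LEVELS)
  off <- row(matrix) != col(matrix)
  n_total <- sum(matrix)
  n_diff <- sum(matrix[off])
  # undercalling: reference CNA, comparator neutral
  n_under <- matrix["loss", "neutral"] + matrix["gain", "neutral"]
  n_over <- n_diff - n_under
  structure(list(
    matrix = matrix, n_total = n_total, n_diff = n_diff,
    n_under = n_under, n_over = n_over,
    frac_diff = 100 * n_diff / n_total,
    frac_under = if (n_diff > 0) 100 * n_under / n_diff else 0,
    frac_over = if (n_diff > 0) 100 * n_over / n_diff else 0
  ), class = "cna_concordance")
}

#' @export
print.cna_concordance <- function(x, ...) {
  print(x$matrix)
  cat(sprintf("Different calls  %d/%d (%.1f%%)\n", x$n_diff, x$n_total,
              round_half_away(x$frac_diff)))
  cat(sprintf("Undercalling     %d/%d (%.1f%%)\n", x$n_under, x$n_diff,
              round_half_away(x$frac_under)))
  cat(sprintf("Overcalling      %d/%d (%.1f%%)\n", x$n_over, x$n_diff,
              round_half_away(x$frac_over)))
  invisible(x)
}

#' Concordance report across purity methods
#'
#' Cross-tabulates the reference method's arm calls against every other
#' method's.
#'
#' @param runs Named list of arm-call matrices, one per purity method.
#' @param reference_method Name of the reference entry in `runs`.
#' @return Named list of `cna_concordance` results, one per comparator.
#' @export
concordance_report <- function(runs, reference_method) {
  if (length(runs) < 2L) stop("need at least two methods", call. = FALSE)
  if (!reference_method %in% names(runs))
    stop("reference method '", reference_method, "' not among runs",
         call. = FALSE)
  ref <- runs[[reference_method]]
  comps <- setdiff(names(runs), reference_method)
  stats::setNames(lapply(comps, function(m)
    concordance_stats(cross_tabulate(ref, runs[[m]]))), comps)
}

#' Serialise a concordance report
#'
#' @param report Named list from [concordance_report()].
#' @return Data frame mirroring the tabular report layout (one row per
#'   comparator).
#' @export
concordance_table <- function(report) {
  do.call(rbind, lapply(names(report), function(m) {
    r <- report[[m]]
    data.frame(comparator = m, n_total = r$n_total, n_diff = r$n_diff,
               n_under = r$n_under, n_over = r$n_over,
               frac_diff = round_half_away(r$frac_diff),
               frac_under = round_half_away(r$frac_under),
               frac_over = round_half_away(r$frac_over),
               stringsAsFactors = FALSE)
  }))
}

#' Published reference cross-tabulations
#'
#' The packaged arm-level CNA cross-tabulations from a two-cohort
#' colorectal-cancer comparison of purity-estimation methods (resection
#' cohort FOCUS, N = 288 samples; biopsy cohort GRAMPIAN, N = 74), with
#' cell-detection-based purity on the first H&E section as the
#' reference and the serial-section replicate (softctm_he2),
#' expression-based (estimate), methylation-based (infiniumpurify) and
#' pathologist (cp) adjustments as comparators, over 39 autosomal arms.
#'
#' @return Named list (`"<cohort>.<comparator>"`) of 3x3 count
#'   matrices, each with attributes `cohort`, `comparator`,
#'   `n_samples`.
#' @export
reference_crosstabs <- function() {
  path <- system.file("extdata", "cna_concordance_reference.tsv",
                      package = "cnpurity", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- list()
  for (co in unique(df$cohort)) for (cm in unique(df$comparator)) {
    sub <- df[df$cohort == co & df$comparator == cm, ]
    sub <- sub[match(CALL_LEVELS, sub$ref_call), ]
    m <- as.matrix(sub[, c("loss", "neutral", "gain")])
    dimnames(m) <- list(CALL_LEVELS, CALL_LEVELS)
    attr(m, "cohort") <- co
    attr(m, "comparator") <- cm
    attr(m, "n_samples") <- sub$n_samples[1L]
    out[[paste(co, cm, sep = ".")]] <- m
  }
  out
}
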