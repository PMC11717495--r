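#' @title Purity adjustment of copy number by mixture inversion
#' @description A bulk sample is modelled as a two-component mixture of
#'   tumour cells at copy number `cn_tumour` and normal diploid cells:
#'   `cn_observed = p * cn_tumour + 2 * (1 - p)` at tumour purity `p`.
#'   Adjustment inverts this for `cn_tumour` given an estimated purity.
#' @name cn-adjust
NULL

CALL_LEVELS <- c("loss", "neutral", "gain")

#' Observed copies from a log2 copy ratio
#'
#' The standard transform for SEG-style input: `2 * 2^log2_ratio`,
#' i.e. a ratio of 0 is diploid.
#'
#' @param log2_ratio Finite numeric vector.
#' @return Observed copy number (> 0).
#' @export
observed_cn_from_log2 <- function(log2_ratio) {
  if (any(!is.finite(log2_ratio)))
    stop("log2_ratio must be finite", call. = FALSE)
  2 * 2^log2_ratio
}

#' Invert the tumour/normal mixture for tumour copy number
#'
#' Solves `cn_observed = p * cn_tumour + 2 * (1 - p)` for `cn_tumour`,
#' clipping negative solutions at 0. Purities below `floor` are clamped
#' up to it with a warning: dividing by a near-zero purity explodes the
#' adjusted copy number, so very low estimates are treated as
#' quality-control failures rather than taken literally.
#'
#' @param cn_observed Observed copies (>= 0). Vectorised.
#' @param purity Tumour purity as a fraction in (0, 1]. Recycled.
#' @param floor Clamp floor for purity (default 0.05).
#' @return Adjusted tumour copy number (>= 0).
#' @export
#' @examples
#' mixture_adjust(2.5, 0.5)  # 3
mixture_adjust <- function(cn_observed, purity, floor = 0.05) {
  if (any(purity <= 0) || any(purity > 1))
    stop("purity must be a fraction in (0, 1]", call. = FALSE)
  if (any(cn_observed < 0))
    stop("cn_observed must be >= 0", call. = FALSE)
  if (any(purity < floor)) {
    warning(sprintf("%d purity value(s) below clamp floor %.2f; clamped",
                    sum(purity < floor), floor), call. = FALSE)
    purity <- pmax(purity, floor)
  }
  pmax(0, (cn_observed - 2 * (1 - purity)) / purity)
}

#' Classify a tumour copy number as loss, neutral, or gain
#'
#' The copy number is rounded half-away-from-zero to the nearest
#' integer; rounded values >= 3 are gains, <= 1 losses, 2 neutral
#' (equivalently, cut points at 1.5 and 2.5 with 2.5 rounding up to
#' gain and 1.5 to neutral).
#'
#' @param cn_tumour Adjusted copy number (>= 0). Vectorised.
#' @return Character vector over `c("loss", "neutral", "gain")`.
#' @export
#' @examples
#' classify_cn(c(1, 2.4, 2.6))  # loss neutral gain
classify_cn <- function(cn_tumour) {
  if (any(cn_tumour < 0)) stop("cn_tumour must be >= 0", call. = FALSE)
  rounded <- floor(cn_tumour + 0.5)   # half away from zero for cn >= 0
  ifelse(rounded >= 3, "gain", ifelse(rounded <= 1, "loss", "neutral"))
}

#' Aggregate segment calls over one arm
#'
#' Length-weighted plurality of the segment calls covering the arm;
#' ties are broken toward neutral, and an arm with no coverage is
#' neutral.
#'
#' @param calls Character vector of segment calls.
#' @param weights Overlap lengths (bp), same length as `calls`.
#' @return A single call.
#' @export
arm_call <- function(calls, weights) {
  if (length(calls) == 0L) return("neutral")
  stopifnot(length(calls) == length(weights))
  w <- vapply(CALL_LEVELS, function(lv) sum(weights[calls == lv]), 0)
  top <- which(w == max(w))
  if (length(top) > 1L) "neutral" else CALL_LEVELS[top]
}

#' Purity-adjust a segment profile and call chromosome arms
#'
#' For one sample: converts each segment's log2 ratio to observed
#' copies, inverts the tumour/normal mixture at the supplied purity,
#' classifies each segment, and aggregates calls per chromosome arm by
#' length-weighted plurality. Arms without segment coverage are called
#' neutral, so every arm of the table receives exactly one call.
#'
#' @param segments Segment data frame for a single sample (`chrom`,
#'   `start`, `end`, `log2_ratio`; a `sample_id` column, if present,
#'   must be constant).
#' @param purity_percent Tumour purity in percent, in (0, 100].
#' @param arms An `arm_table` (default [default_karyotype()]).
#' @param purity_floor Clamp floor passed to [mixture_adjust()].
#' @return A list of class `adjusted_profile`: `segments` (the input
#'   plus `cn_observed`, `cn_tumour`, `call`), `arm_calls` (named
#'   character vector over all arms), `purity_used` (fraction after
#'   clamping), `sample_id`.
#' @export
adjust_profile <- function(segments, purity_percent,
                           arms = default_karyotype(),
                           purity_floor = 0.05) {
  if (length(purity_percent) != 1L || purity_percent <= 0 ||
      purity_percent > 100)
    stop("purity_percent must be a single value in (0, 100]", call. = FALSE)
  if (is.null(segments$sample_id)) segments$sample_id <- "sample"
  sid <- unique(segments$sample_id)
  if (length(sid) > 1L)
    stop("adjust_profile expects a single sample; got: ",
         paste(sid, collapse = ", "), call. = FALSE)
  p <- purity_percent / 100
  p_used <- max(p, purity_floor)
  segments$cn_observed <- observed_cn_from_log2(segments$log2_ratio)
  segments$cn_tumour <- mixture_adjust(segments$cn_observed, p,
                                       floor = purity_floor)
  segments$call <- classify_cn(segments$cn_tumour)
  ov <- intersect_segments_with_arms(segments, arms)
  arm_calls <- stats::setNames(rep("neutral", nrow(arms)), arms$name)
  if (nrow(ov) > 0L) {
    for (a in unique(ov$arm_name)) {
      sub <- ov[ov$arm_name == a, , drop = FALSE]
      arm_calls[[a]] <- arm_call(sub$call, sub$overlap_length)
    }
  }
  structure(list(segments = segments, arm_calls = arm_calls,
                 purity_used = p_used, sample_id = sid),
            class = "adjusted_profile")
}

#' @export
print.adjusted_profile <- function(x, ...) {
  tab <- table(factor(x$arm_calls, levels = CALL_LEVELS))
  cat(sprintf(
    "adjusted_profile %s: %d segments, purity %.1f%%; arms: %d loss / %d neutral / %d gain\n",
    x$sample_id, nrow(x$segments), 100 * x$purity_used,
    tab[["loss"]], tab[["neutral"]], tab[["gain"]]))
  invisible(x)
}

#' Purity-adjust a cohort of segment profiles
#'
#' @param segments Segment data frame for all samples (with
#'   `sample_id`).
#' @param purity Named numeric vector of purities in percent (names =
#'   sample IDs), or a data frame with `sample_id` and `value`.
#' @param arms An `arm_table`.
#' @param purity_floor Clamp floor passed to [mixture_adjust()].
#' @return Arm-call matrix: samples x arms, values in
#'   loss/neutral/gain.
#' @export
adjust_cohort <- function(segments, purity, arms = default_karyotype(),
                          purity_floor = 0.05) {
  if (is.data.frame(purity))
    purity <- stats::setNames(purity$value, purity$sample_id)
  ids <- unique(segments$sample_id)
  missing <- setdiff(ids, names(purity))
  if (length(missing))
    stop("no purity estimate for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(purity[ids] <= 0 | purity[ids] > 100))
    stop("purity must be in (0, 100]", call. = FALSE)
  p_row <- unname(purity[segments$sample_id]) / 100
  segments$cn_observed <- observed_cn_from_log2(segments$log2_ratio)
  segments$cn_tumour <- mixture_adjust(segments$cn_observed, p_row,
                                       floor = purity_floor)
  segments$call <- classify_cn(segments$cn_tumour)
  calls <- matrix("neutral", nrow = length(ids), ncol = nrow(arms),
                  dimnames = list(ids, arms$name))
  ov <- intersect_segments_with_arms(segments, arms)
  if (nrow(ov) == 0L) return(calls)
  # length-weighted plurality per (sample, arm); ties -> neutral
  tab <- stats::xtabs(overlap_length ~ sample_id + arm_name +
                        factor(call, levels = CALL_LEVELS), data = ov)
  L <- tab[, , "loss", drop = FALSE][, , 1L]
  N <- tab[, , "neutral", drop = FALSE][, , 1L]
  G <- tab[, , "gain", drop = FALSE][, , 1L]
  top <- pmax(L, N, G)
  res <- ifelse((L == top) + (N == top) + (G == top) > 1L, "neutral",
                ifelse(G == top, "gain",
                       ifelse(L == top, "loss", "neutral")))
  res[top == 0] <- "neutral"        # no coverage
  calls[rownames(tab), colnames(tab)] <- res
  calls[ids, , drop = FALSE]
}

#' Read / write an arm-call matrix
#'
#' TSV with sample IDs in the first column (`sample_id`) and one column
#' per arm, values loss/neutral/gain.
#'
#' @param path File path.
#' @return `read_arm_calls`: a character matrix samples x arms.
#' @export
read_arm_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  bad <- setdiff(unique(as.vector(m)), CALL_LEVELS)
  if (length(bad))
    stop("invalid call value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  m
}

#' @rdname read_arm_calls
#' @param calls Character matrix samples x arms.
#' @export
write_arm_calls <- function(calls, path) {
  df <- data.frame(sample_id = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
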