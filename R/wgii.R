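#' Whole Genome Instability Index
#'
#' WGII is the proportion of the genome (by length) with an aberrant
#' copy number: the summed lengths of loss or gain calls divided by the
#' total length considered. By default it is computed at arm
#' resolution over the autosomal arm table (denominator =
#' [arm_total_length()]); `level = "segment"` instead computes it over
#' classified segments against the total segment-covered length.
#'
#' @param calls For `level = "arm"`: an arm-call matrix (samples x
#'   arms) or a named call vector for one sample. For
#'   `level = "segment"`: an `adjusted_profile` or its `segments` data
#'   frame (needs `sample_id`, `start`, `end`, `call`).
#' @param arms An `arm_table`; required for arm level.
#' @param level `"arm"` (default) or `"segment"`.
#' @return Data frame: `sample_id`, `wgii`, `aberrant_length`,
#'   `total_length`.
#' @export
#' @examples
#' arms <- default_karyotype()
#' calls <- setNames(rep("neutral", nrow(arms)), arms$name)
#' wgii(calls, arms)$wgii  # 0
wgii <- function(calls, arms = default_karyotype(),
                 level = c("arm", "segment")) {
  level <- match.arg(level)
  if (level == "segment") {
    if (inherits(calls, "adjusted_profile")) calls <- calls$segments
    if (is.null(calls$sample_id)) calls$sample_id <- "sample"
    res <- lapply(split(calls, calls$sample_id), function(s) {
      len <- s$end - s$start
      data.frame(sample_id = s$sample_id[1L],
                 aberrant_length = sum(len[s$call != "neutral"]),
                 total_length = sum(len))
    })
    out <- do.call(rbind, res)
  } else {
    stopifnot(inherits(arms, "arm_table"))
    if (nrow(arms) == 0L) stop("empty arm table", call. = FALSE)
    if (!is.matrix(calls))
      calls <- matrix(calls, nrow = 1, dimnames = list("sample", names(calls)))
    if (!all(colnames(calls) %in% arms$name))
      stop("call matrix has arms absent from the arm table", call. = FALSE)
    lens <- stats::setNames(arms$length, arms$name)[colnames(calls)]
    total <- arm_total_length(arms)
    aberr <- apply(calls, 1L, function(cc) sum(lens[cc != "neutral"]))
    out <- data.frame(sample_id = rownames(calls),
                      aberrant_length = as.numeric(aberr),
                      total_length = total)
  }
  out$wgii <- out$aberrant_length / out$total_length
  rownames(out) <- NULL
  out[, c("sample_id", "wgii", "aberrant_length", "total_length")]
}

#' Compare WGII between two purity-adjustment runs
#'
#' Pearson correlation with 95% CI plus a Bland-Altman agreement
#' summary. Differences follow the first-minus-second convention.
#'
#' @param results_a,results_b Matched WGII data frames from [wgii()]
#'   (aligned by `sample_id`) or plain numeric vectors.
#' @return List with elements `pearson` ([pearson_ci()]) and
#'   `bland_altman` ([bland_altman()]).
#' @export
wgii_compare <- function(results_a, results_b) {
  if (is.data.frame(results_a)) {
    if (!is.data.frame(results_b))
      stop("both inputs must be WGII data frames or both vectors",
           call. = FALSE)
    miss <- c(setdiff(results_a$sample_id, results_b$sample_id),
              setdiff(results_b$sample_id, results_a$sample_id))
    if (length(miss))
      stop("unmatched sample IDs: ", paste(unique(miss), collapse = ", "),
           call. = FALSE)
    results_b <- results_b[match(results_a$sample_id, results_b$sample_id), ]
    a <- results_a$wgii; b <- results_b$wgii
  } else {
    a <- results_a; b <- results_b
    if (length(a) != length(b))
      stop("WGII vectors must have equal length", call. = FALSE)
  }
  list(pearson = pearson_ci(a, b), bland_altman = bland_altman(a, b))
}
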