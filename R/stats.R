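#' Pearson correlation with a Fisher-z 95% confidence interval
#'
#' Product-moment correlation; the CI uses the Fisher z-transform with
#' standard error 1/sqrt(n - 3) (as `stats::cor.test` computes it).
#'
#' @param x,y Matched numeric vectors, n >= 4, each with nonzero
#'   variance.
#' @return A `pearson_ci` list: `r`, `ci_low`, `ci_high`, `n`,
#'   `p_value`.
#' @export
#' @examples
#' pearson_ci(1:10, 2 * (1:10) + 1)$r  # 1
pearson_ci <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need n >= 4", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  structure(list(r = unname(ct$estimate),
                 ci_low = ct$conf.int[1L], ci_high = ct$conf.int[2L],
                 n = length(x), p_value = ct$p.value),
            class = "pearson_ci")
}

#' @export
print.pearson_ci <- function(x, ...) {
  cat(sprintf("r = %.3f, CI = (%.3f, %.3f), n = %d, p = %.3g\n",
              x$r, x$ci_low, x$ci_high, x$n, x$p_value))
  invisible(x)
}

#' Paired-samples t-test
#'
#' Classical paired t on the differences `x - y` (first minus second),
#' two-sided.
#'
#' @param x,y Matched numeric vectors, n >= 2.
#' @return List: `t`, `p_value`, `mean_difference` (x minus y), `n`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  d <- x - y
  if (length(d) < 2L) stop("need n >= 2", call. = FALSE)
  if (stats::var(d) == 0)
    stop("zero difference variance: paired t undefined", call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = unname(tt$estimate), n = length(d))
}

#' Bland-Altman agreement summary
#'
#' Differences are `x - y` (first minus second); the bias is their
#' mean and the limits of agreement are bias +/- 1.96 SD of the
#' differences.
#'
#' @param x,y Matched numeric vectors, n >= 2.
#' @return A `bland_altman` list: `bias`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need n >= 2", call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  structure(list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
                 loa_high = mean(d) + 1.96 * s, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("bias = %.4g (x - y), LoA = (%.4g, %.4g), n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}
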