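# Shared fixtures and independent oracles.

# toy two-arm genome: chr1p [0, 50), chr1q [50, 100)
toy_arms <- function() {
  path <- tempfile(fileext = ".bed")
  writeLines(c("1\t0\t50\t1p", "1\t50\t100\t1q"), path)
  read_arm_bed(path)
}

# arbitrary toy arm table from a data frame spec
make_arms <- function(chrom, start, end, name) {
  path <- tempfile(fileext = ".bed")
  writeLines(paste(chrom, start, end, name, sep = "\t"), path)
  read_arm_bed(path)
}

make_segments <- function(chrom, start, end, log2_ratio,
                          sample_id = "S1") {
  data.frame(sample_id = sample_id, chrom = as.character(chrom),
             start = start, end = end, log2_ratio = log2_ratio,
             stringsAsFactors = FALSE)
}

# brute-force O(n*m) interval intersection oracle
brute_force_overlaps <- function(segments, arms) {
  out <- NULL
  for (i in seq_len(nrow(segments))) for (j in seq_len(nrow(arms))) {
    if (segments$chrom[i] != arms$chrom[j]) next
    s <- max(segments$start[i], arms$start[j])
    e <- min(segments$end[i], arms$end[j])
    if (e > s)
      out <- rbind(out, data.frame(seg = i, arm = arms$name[j],
                                   overlap_length = e - s))
  }
  out
}

# independent point-in-polygon oracle: winding-free crossing count with
# explicit boundary test, written scalar-wise (deliberately different
# construction from the package's vectorised version)
oracle_point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- ring[j, 1]; y1 <- ring[j, 2]
    x2 <- ring[i, 1]; y2 <- ring[i, 2]
    # on-segment check
    d <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(d) < 1e-9 &&
        px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
        py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9)
      return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# base-pair-resolution majority-vote oracle for arm aggregation
oracle_arm_call_bp <- function(starts, ends, calls, arm_len) {
  bp <- rep("uncovered", arm_len)
  for (i in seq_along(calls))
    bp[(starts[i] + 1):ends[i]] <- calls[i]
  w <- table(factor(bp, levels = c("loss", "neutral", "gain")))
  if (max(w) == 0) return("neutral")
  top <- names(w)[w == max(w)]
  if (length(top) > 1) "neutral" else top
}

quiet_adjust <- function(...) suppressWarnings(adjust_cohort(...))
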