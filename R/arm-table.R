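#' @title Chromosome-arm coordinate frame
#' @description Internal coordinates are 0-based half-open (BED convention).
#'   SEG-dialect files on disk are 1-based inclusive and converted on read.
#' @name arm-table
NULL

# canonical chromosome ordering key: numeric autosomes first, then lexical
.chrom_key <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom)
}

.normalise_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

.validate_arm_table <- function(df) {
  if (nrow(df) == 0L) stop("no arms", call. = FALSE)
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1L]
    stop(sprintf("arm %s: start (%d) must be < end (%d)",
                 df$name[bad], df$start[bad], df$end[bad]), call. = FALSE)
  }
  if (!all(df$arm %in% c("p", "q")))
    stop("arm suffix must be 'p' or 'q'", call. = FALSE)
  # arms of one chromosome must not overlap
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop(sprintf("overlapping arms on chromosome %s", ch), call. = FALSE)
  }
  invisible(df)
}

.new_arm_table <- function(df) {
  df <- df[.chrom_key(df$chrom), , drop = FALSE]
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), , drop = FALSE]
  rownames(df) <- NULL
  df$length <- df$end - df$start
  .validate_arm_table(df)
  structure(df, class = c("arm_table", "data.frame"))
}

#' Read a chromosome-arm table from a BED4 file
#'
#' Expects at least four tab-separated columns: chromosome, start, end
#' (0-based half-open) and an arm name ending in `p` or `q` (e.g. `1p`,
#' `17q`). No header. A leading `chr` prefix on chromosome names is
#' stripped.
#'
#' @param path Path to the BED file.
#' @return An `arm_table`: a data frame with columns `chrom`, `arm`,
#'   `start`, `end`, `name`, `length`, ordered by chromosome and start,
#'   with total genome length available via [arm_total_length()].
#' @export
#' @examples
#' arms <- default_karyotype()
#' nrow(arms)           # 39 autosomal arms
#' arm_total_length(arms)
read_arm_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no arms", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("malformed BED line %d: expected >= 4 tab-separated fields",
                 which(nf < 4L)[1L]), call. = FALSE)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("malformed BED line %d: non-numeric coordinate",
                 which(is.na(start) | is.na(end))[1L]), call. = FALSE)
  name <- vapply(fields, `[`, "", 4L)
  df <- data.frame(
    chrom = .normalise_chrom(vapply(fields, `[`, "", 1L)),
    arm   = substr(name, nchar(name), nchar(name)),
    start = start, end = end, name = name,
    stringsAsFactors = FALSE
  )
  .new_arm_table(df)
}

#' Default 39-arm autosomal karyotype (hg19)
#'
#' The packaged coordinate frame: the p and q arms of autosomes 1-22 with
#' the acrocentric p-arms (13p, 14p, 15p, 21p, 22p) absent, giving the 39
#' arms over which arm-level calls are made. Boundaries follow the
#' GRCh37/hg19 centromere gap annotation; centromeric gaps belong to
#' neither arm.
#'
#' @return An `arm_table` of 39 arms.
#' @export
default_karyotype <- function() {
  read_arm_bed(system.file("extdata", "hg19_arms.bed", package = "cnpurity",
                           mustWork = TRUE))
}

#' Total genome length of an arm table
#'
#' @param arms An `arm_table`.
#' @return Total length in base pairs (sum of arm lengths).
#' @export
arm_total_length <- function(arms) {
  stopifnot(inherits(arms, "arm_table"))
  sum(arms$length)
}

#' Write an arm table back to BED4
#'
#' @param arms An `arm_table`.
#' @param path Output path.
#' @export
write_arm_bed <- function(arms, path) {
  stopifnot(inherits(arms, "arm_table"))
  utils::write.table(
    data.frame(arms$chrom, format(arms$start, scientific = FALSE, trim = TRUE),
               format(arms$end, scientific = FALSE, trim = TRUE), arms$name),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.arm_table <- function(x, ...) {
  cat(sprintf("arm_table: %d arms, %s bp total\n", nrow(x),
              format(sum(x$length), big.mark = ",")))
  NextMethod()
}

#' Read a SEG-like segment file
#'
#' Tab-separated with header `sample`, `chrom`, `start`, `end`,
#' `log2_ratio`; coordinates 1-based inclusive on disk, converted to
#' 0-based half-open in memory.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `log2_ratio`.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  if (!all(need %in% names(df)))
    stop("segment file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    sample_id = as.character(df$sample),
    chrom = .normalise_chrom(df$chrom),
    start = as.numeric(df$start) - 1,   # to 0-based half-open
    end = as.numeric(df$end),
    log2_ratio = as.numeric(df$log2_ratio),
    stringsAsFactors = FALSE
  )
  .validate_segments(out)
  out
}

#' Write segments in the SEG-like dialect
#'
#' @param segments Segment data frame (`sample_id`, `chrom`, `start`,
#'   `end`, `log2_ratio`; 0-based half-open).
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  .validate_segments(segments)
  out <- data.frame(
    sample = segments$sample_id, chrom = segments$chrom,
    start = format(segments$start + 1, scientific = FALSE, trim = TRUE),
    end = format(segments$end, scientific = FALSE, trim = TRUE),
    log2_ratio = segments$log2_ratio
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_segments <- function(segments) {
  need <- c("sample_id", "chrom", "start", "end", "log2_ratio")
  stopifnot(all(need %in% names(segments)))
  if (any(segments$start >= segments$end))
    stop("segment start must be < end", call. = FALSE)
  if (any(!is.finite(segments$log2_ratio)))
    stop("log2_ratio must be finite", call. = FALSE)
  # non-overlap within a sample/chromosome
  key <- paste(segments$sample_id, segments$chrom)
  for (k in unique(key)) {
    sub <- segments[key == k, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping segments within ", k, call. = FALSE)
  }
  invisible(segments)
}

.arms_granges <- function(arms, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(arms$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = arms$start + 1, end = arms$end))
}

#' Intersect segments with chromosome arms
#'
#' Computes, for every (segment, arm) pair with positive overlap, the
#' overlapping interval. Segments on chromosomes absent from the arm
#' table are skipped with a warning; segment portions outside all arms
#' (e.g. centromeric gaps) are dropped.
#'
#' @param segments Segment data frame (`sample_id`, `chrom`, `start`,
#'   `end`, `log2_ratio`; 0-based half-open).
#' @param arms An `arm_table`.
#' @return Data frame with one row per overlap: the segment columns plus
#'   `arm_name`, `overlap_start`, `overlap_end`, `overlap_length`.
#' @export
intersect_segments_with_arms <- function(segments, arms) {
  stopifnot(inherits(arms, "arm_table"))
  .validate_segments(segments)
  segments$chrom <- .normalise_chrom(segments$chrom)
  unknown <- setdiff(unique(segments$chrom), unique(arms$chrom))
  if (length(unknown) > 0L) {
    warning("skipping segments on chromosome(s) absent from arm table: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    segments <- segments[!segments$chrom %in% unknown, , drop = FALSE]
  }
  empty <- data.frame(
    sample_id = character(), chrom = character(), start = numeric(),
    end = numeric(), log2_ratio = numeric(), arm_name = character(),
    overlap_start = numeric(), overlap_end = numeric(),
    overlap_length = numeric(), stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(empty)
  seqlv <- unique(c(arms$chrom, segments$chrom))
  seg_gr <- GenomicRanges::GRanges(
    seqnames = factor(segments$chrom, levels = seqlv),
    ranges = IRanges::IRanges(start = segments$start + 1, end = segments$end))
  arm_gr <- .arms_granges(arms, seqlv)
  hits <- GenomicRanges::findOverlaps(seg_gr, arm_gr)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  inter <- IRanges::pintersect(IRanges::ranges(seg_gr)[qi],
                               IRanges::ranges(arm_gr)[si])
  out <- segments[qi, , drop = FALSE]
  out$arm_name <- arms$name[si]
  out$overlap_start <- IRanges::start(inter) - 1
  out$overlap_end <- IRanges::end(inter)
  out$overlap_length <- IRanges::width(inter)
  rownames(out) <- NULL
  out
}
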