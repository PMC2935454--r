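# Platform-exclusive coverage analysis: partition contig positions by which
# sequencing platform covers them, characterize coverage gaps, and compute
# the Poisson expectation for uncovered genome fraction under uniform
# coverage.

#' Construct a two-platform coverage track
#'
#' @param contig contig id.
#' @param depths named list of two non-negative integer vectors of equal
#'   length (per-position depth, one vector per platform tag).
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(contig, depths) {
  if (!is.list(depths) || is.null(names(depths)))
    abort("depths must be a named list of per-platform depth vectors")
  lens <- vapply(depths, length, integer(1))
  if (length(unique(lens)) != 1) abort("depth vectors must share a length")
  if (any(vapply(depths, function(d) any(d < 0), logical(1))))
    abort("depths must be non-negative")
  structure(list(contig = contig, length = unname(lens[1]),
                 depths = depths), class = "coverage_track")
}

# Convert a logical per-position mask to a canonical interval set
# (0-based half-open, sorted, maximal, disjoint).
mask_to_intervals <- function(mask) {
  if (!length(mask) || !any(mask))
    return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Partition a contig by platform coverage
#'
#' Splits `[0, length)` into the four classes: covered by both platforms,
#' exclusively by the first, exclusively by the second, or by neither. A
#' position counts as covered at depth >= 1.
#'
#' @param track a `coverage_track` with exactly two platforms.
#' @return named list of four interval data frames (`both`, `only_A`,
#'   `only_B`, `neither`, where A/B follow the order of platforms in the
#'   track) plus a `platforms` character vector.
#' @export
coverage_partition <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (length(track$depths) != 2)
    abort("coverage_partition requires exactly two platforms")
  a <- track$depths[[1]] >= 1
  b <- track$depths[[2]] >= 1
  list(both = mask_to_intervals(a & b),
       only_A = mask_to_intervals(a & !b),
       only_B = mask_to_intervals(!a & b),
       neither = mask_to_intervals(!a & !b),
       platforms = names(track$depths))
}

#' Summary statistics of an interval set of coverage gaps
#'
#' @param gaps interval data frame (`start`, `end`, 0-based half-open).
#' @param short_cutoff optional length below which gaps are counted into the
#'   `n_short` bucket (mirrors the "short gap" framing of exclusive-coverage
#'   length distributions); default 20.
#' @return list of class `gap_stats`: `count`, `mean_length` (`NA` with
#'   `mean_defined = FALSE` when empty), `n_short`, `histogram` (table of
#'   lengths, bin width one base).
#' @export
gap_stats <- function(gaps, short_cutoff = 20L) {
  len <- gaps$end - gaps$start
  structure(list(count = length(len),
                 mean_length = if (length(len)) mean(len) else NA_real_,
                 mean_defined = length(len) > 0,
                 n_short = sum(len < short_cutoff),
                 histogram = table(len)), class = "gap_stats")
}

#' Expected uncovered genome fraction under uniform coverage
#'
#' Under uniform (Poisson) coverage at mean fold-coverage c, the zero class
#' exp(-c) is the fraction of the genome expected to receive no read.
#'
#' @param c fold-coverage (>= 0); vectorized.
#' @return fraction in [0, 1].
#' @export
expected_uncovered_fraction <- function(c) {
  if (any(c < 0)) abort("fold-coverage must be non-negative")
  exp(-c)
}

#' Genome fraction covered exclusively by each platform
#'
#' @param tracks list of `coverage_track` objects sharing the same platform
#'   pair.
#' @return list with per-platform exclusive fractions (named by platform
#'   tag), their `sum`, and `total_bases`.
#' @export
exclusive_fraction <- function(tracks) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  plats <- names(tracks[[1]]$depths)
  only <- c(0, 0); total <- 0
  for (tr in tracks) {
    if (!identical(names(tr$depths), plats))
      abort("inconsistent platforms across tracks")
    part <- coverage_partition(tr)
    only <- only + c(sum(part$only_A$end - part$only_A$start),
                     sum(part$only_B$end - part$only_B$start))
    total <- total + tr$length
  }
  res <- stats::setNames(as.list(only / total), plats)
  res$sum <- sum(only) / total
  res$total_bases <- total
  res
}

#' Write / read interval sets as BED
#'
#' Three-column BED (chrom, start, end), 0-based half-open, matching the
#' package's internal interval convention directly.
#'
#' @param intervals interval data frame (`start`, `end`).
#' @param contig contig name for the first BED column.
#' @param path file path.
#' @return `read_bed()` returns a data frame `contig`, `start`, `end`.
#' @export
write_bed <- function(intervals, contig, path) {
  df <- data.frame(contig = contig, start = intervals$start,
                   end = intervals$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("contig", "start", "end"))
  df
}
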