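#' Read a BED file into a region set
#'
#' Reads BED3+ intervals (0-based, half-open), validates them, and returns a
#' merged, sorted region set. Overlapping or bookended intervals on the same
#' chromosome are unioned, so the total span of the result equals the span of
#' the union of the input intervals.
#'
#' @param path Path to a BED file (at least three tab- or space-separated
#'   columns: chrom, start, end; further columns are ignored).
#' @param label Character label attached to the set (e.g. `"neutral"`,
#'   `"target"`).
#' @return A `region_set`: a data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and attribute `label`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t0\t10", "chr1\t5\t15"), bed)
#' r <- read_regions(bed)
#' region_span(r) # 15
#' @export
read_regions <- function(path, label = "regions") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(region_set(data.frame(chrom = character(), start = integer(),
                                 end = integer()), label))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", idx[which(nf < 3L)[1]],
         ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1]], ": non-numeric coordinates")
  }
  if (any(start < 0)) {
    stop("invalid BED line ", idx[which(start < 0)[1]], ": negative start")
  }
  if (any(start >= end)) {
    stop("invalid BED line ", idx[which(start >= end)[1]],
         ": start >= end (empty or inverted interval)")
  }
  region_set(data.frame(chrom = chrom, start = as.integer(start),
                        end = as.integer(end), stringsAsFactors = FALSE),
             label)
}

#' Construct a region set from chrom/start/end records
#'
#' Intervals are interpreted as 0-based half-open; records are merged
#' (unioned) per chromosome and sorted.
#'
#' @param x Data frame with columns `chrom`, `start`, `end`.
#' @param label Character label for the set.
#' @return A `region_set` data frame.
#' @export
region_set <- function(x, label = "regions") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
  } else {
    if (any(x$start < 0)) stop("negative coordinates in region set")
    if (any(x$start >= x$end)) stop("start >= end in region set")
    gr <- GenomicRanges::reduce(as_granges_0based(x))
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("region_set", "data.frame")
  attr(out, "label") <- label
  out
}

# 0-based half-open data.frame -> 1-based closed GRanges
as_granges_0based <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Total span of a region set
#'
#' @param x A `region_set`.
#' @return Total number of bases covered (regions are merged, so this is the
#'   size of the union).
#' @export
region_span <- function(x) {
  stopifnot(inherits(x, "region_set"))
  if (nrow(x) == 0L) return(0L)
  sum(x$end - x$start)
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("Region set '%s': %d region(s), %d bp on %d chromosome(s)\n",
              attr(x, "label") %||% "regions", nrow(x), region_span(x),
              length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Write a region set as BED
#'
#' @param x A `region_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(x, path) {
  stopifnot(inherits(x, "region_set"))
  utils::write.table(as.data.frame(x)[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
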