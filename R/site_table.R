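SITE_TABLE_COLS <- c("chrom", "pos0", "ref", "alt", "context7", "Y", "common",
                     "coverage", "gc_frac", "cpg_island", "excluded",
                     "reason", "P")

#' Read a variant table (VCF or TSV)
#'
#' Variants must be biallelic single-nucleotide records; indels and
#' multi-allelic records are rejected (multi-allelic VCF records must be
#' pre-split). Positions are converted to 0-based internally.
#'
#' @param path Path to a VCF 4.x file or a headered TSV with columns
#'   `chrom`, `pos0`, `ref`, `alt`, `af`, `coverage`.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param af_field Name of the INFO field carrying the alternative-allele
#'   frequency (VCF only).
#' @param coverage_field Name of the INFO field carrying mean sequencing
#'   coverage (VCF only); missing values become `NA`.
#' @return Data frame with columns `chrom`, `pos0` (0-based), `ref`, `alt`,
#'   `af`, `coverage`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          af_field = "AF", coverage_field = "mean_dp") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    alt <- fix[, "ALT"]
    if (any(grepl(",", alt))) {
      stop("multi-allelic VCF records found; pre-split them (one ALT per record)")
    }
    af <- suppressWarnings(as.numeric(vcfR::extract.info(v, af_field)))
    cov <- suppressWarnings(as.numeric(vcfR::extract.info(v, coverage_field)))
    if (all(is.na(af))) stop("INFO field '", af_field, "' absent or non-numeric")
    out <- data.frame(chrom = fix[, "CHROM"],
                      pos0 = as.integer(fix[, "POS"]) - 1L,
                      ref = fix[, "REF"], alt = alt,
                      af = af,
                      coverage = if (length(cov)) cov else NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("chrom", "pos0", "ref", "alt", "af")
    if (!all(need %in% names(out))) {
      stop("variant TSV must have columns: ", paste(need, collapse = ", "))
    }
    if (!"coverage" %in% names(out)) out$coverage <- NA_real_
    out <- out[, c("chrom", "pos0", "ref", "alt", "af", "coverage")]
  }
  validate_variants(out)
  out
}

validate_variants <- function(v) {
  bases <- c("A", "C", "G", "T")
  bad <- !(v$ref %in% bases) | !(v$alt %in% bases)
  if (any(bad)) {
    stop("non-SNV variant records (indels or ambiguous alleles) at rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (any(v$ref == v$alt)) stop("variant with alt equal to ref")
  if (any(v$af < 0 | v$af > 1, na.rm = TRUE)) {
    stop("allele frequency outside [0,1]")
  }
  invisible(v)
}

read_fasta_seqs <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    seqs <- reference
  } else {
    seqs <- Biostrings::readDNAStringSet(reference)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

read_coverage_track <- function(coverage) {
  if (is.character(coverage) && length(coverage) == 1L) {
    cov <- utils::read.table(coverage, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos0", "coverage") %in% names(cov))) {
      stop("coverage TSV must have columns chrom, pos0, coverage")
    }
    return(cov)
  }
  coverage
}

#' Assemble a per-site, per-allele site table
#'
#' Enumerates every site in `regions`, records its heptamer context,
#' covariates and rare/common variant status for each of the three possible
#' alternative alleles, and applies the standard filters: sites with a
#' non-ACGT base in the 7-mer context, CpG sites (either strand of a CpG
#' dinucleotide), sites with mean coverage below `min_coverage`, and sites
#' carrying any common variant (frequency at or above `rare_max_af`) are
#' excluded with a reason code. For retained sites the rare-variant
#' indicator `Y` is 1 for allele `j` when a variant with
#' `0 < AF < rare_max_af` is present.
#'
#' @param reference FASTA path or a [Biostrings::DNAStringSet].
#' @param regions A `region_set` of sites to tabulate.
#' @param variants Variant data frame as returned by [read_variants()], or
#'   `NULL` for none.
#' @param cpg_islands Optional `region_set` of CpG islands (covariate track,
#'   not a filter).
#' @param coverage Per-site mean coverage: a single number, a data frame
#'   with columns `chrom`, `pos0`, `coverage`, or a path to such a TSV.
#'   Sites absent from the track get the coverage recorded on a variant at
#'   the site, else `NA` (which excludes them as low-coverage).
#' @param min_coverage Sites with coverage below this are excluded
#'   (default 20).
#' @param rare_max_af Variants with frequency at or above this are common and
#'   exclude the whole site (default 0.001). Frequencies above
#'   `1 - rare_max_af` (reference allele is the minor one) count as common
#'   too.
#' @param gc_window Window size (bp) for the fractional G+C covariate
#'   (default 200).
#' @return A `site_table`: data frame with one row per (site, alternative
#'   allele), columns `r SITE_TABLE_COLS`. Alternative alleles appear in
#'   alphabetical order among the non-reference bases; `P` is `NA` until
#'   filled by [predict_rates()].
#' @export
build_site_table <- function(reference, regions, variants = NULL,
                             cpg_islands = NULL, coverage = NA_real_,
                             min_coverage = 20, rare_max_af = 0.001,
                             gc_window = 200) {
  stopifnot(inherits(regions, "region_set"))
  seqs <- read_fasta_seqs(reference)
  coverage <- read_coverage_track(coverage)

  missing_chrom <- setdiff(unique(regions$chrom), names(seqs))
  if (length(missing_chrom)) {
    stop("regions reference chromosomes absent from FASTA: ",
         paste(missing_chrom, collapse = ", "))
  }

  per_chrom <- lapply(split(regions, regions$chrom), function(rr) {
    chrom <- rr$chrom[1]
    len <- Biostrings::width(seqs[chrom])
    if (any(rr$end > len)) {
      stop("region ", chrom, ":", rr$start[which(rr$end > len)[1]], "-",
           rr$end[which(rr$end > len)[1]], " extends beyond contig length ",
           len)
    }
    pos0 <- unlist(lapply(seq_len(nrow(rr)),
                          function(i) seq.int(rr$start[i], rr$end[i] - 1L)))
    chr_seq <- as.character(seqs[[chrom]])
    site_frame(chrom, pos0, chr_seq, gc_window)
  })
  tab <- do.call(rbind, per_chrom)
  rownames(tab) <- NULL

  # covariates ---------------------------------------------------------
  key <- paste(tab$chrom, tab$pos0)
  if (is.data.frame(coverage)) {
    m <- match(key, paste(coverage$chrom, coverage$pos0))
    tab$coverage <- coverage$coverage[m]
  } else {
    tab$coverage <- as.numeric(coverage)
  }
  tab$cpg_island <- FALSE
  if (!is.null(cpg_islands) && nrow(cpg_islands)) {
    isl <- cpg_islands[cpg_islands$chrom %in% unique(tab$chrom), , drop = FALSE]
    for (i in seq_len(nrow(isl))) {
      hit <- tab$chrom == isl$chrom[i] & tab$pos0 >= isl$start[i] &
        tab$pos0 < isl$end[i]
      tab$cpg_island[hit] <- TRUE
    }
  }

  # variants ------------------------------------------------------------
  tab$Y <- 0L
  tab$common <- 0L
  if (!is.null(variants) && nrow(variants)) {
    validate_variants(variants)
    vkey <- paste(variants$chrom, variants$pos0)
    vsite <- match(vkey, key)
    here <- !is.na(vsite)
    if (any(here)) {
      v <- variants[here, , drop = FALSE]
      site_ref <- tab$ref[vsite[here]]
      mism <- v$ref != site_ref
      if (any(mism)) {
        bad <- which(mism)[1]
        stop("variant reference allele mismatch with FASTA at ",
             v$chrom[bad], ":", v$pos0[bad], " (variant ref ", v$ref[bad],
             ", FASTA ", site_ref[bad], ")")
      }
      rkey <- paste(v$chrom, v$pos0, v$alt)
      m <- match(paste(tab$chrom, tab$pos0, tab$alt), rkey)
      hit <- !is.na(m)
      af <- v$af[m[hit]]
      common <- af >= rare_max_af | af > 1 - rare_max_af
      tab$Y[hit] <- as.integer(!common & af > 0)
      tab$common[hit] <- as.integer(common)
      # carry variant-borne coverage onto sites missing a track value
      vcov <- v$coverage[m[hit]]
      fill <- hit
      fill[hit] <- is.na(tab$coverage[hit]) & !is.na(vcov)
      site_of <- paste(tab$chrom[fill], tab$pos0[fill])
      if (any(fill)) {
        cov_by_site <- stats::setNames(vcov[is.na(tab$coverage[hit]) &
                                              !is.na(vcov)], site_of)
        miss <- is.na(tab$coverage)
        tab$coverage[miss] <- cov_by_site[paste(tab$chrom[miss],
                                                tab$pos0[miss])]
      }
    }
  }
  tab$P <- NA_real_
  tab <- apply_site_filters(tab, min_coverage = min_coverage)
  as_site_table(tab)
}

# per-site frame with ref, context, cpg flag and gc fraction
site_frame <- function(chrom, pos0, chr_seq, gc_window) {
  len <- nchar(chr_seq)
  base_at <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- p >= 0L & p < len
    out[ok] <- substring(chr_seq, p[ok] + 1L, p[ok] + 1L)
    out
  }
  ref <- base_at(pos0)
  lo <- pos0 - 3L
  hi <- pos0 + 3L
  ctx <- substring(chr_seq, lo + 1L, hi + 1L)
  ctx[lo < 0L | hi >= len] <- NA_character_
  ctx <- toupper(ctx)
  ref <- toupper(ref)
  nxt <- toupper(base_at(pos0 + 1L))
  prv <- toupper(base_at(pos0 - 1L))
  cpg <- (ref == "C" & !is.na(nxt) & nxt == "G") |
    (ref == "G" & !is.na(prv) & prv == "C")
  cpg[is.na(cpg)] <- FALSE

  gc <- gc_fraction(chr_seq, pos0, gc_window)

  bases <- c("A", "C", "G", "T")
  alt_list <- lapply(ref, function(b) {
    if (is.na(b) || !(b %in% bases)) bases[1:3] else setdiff(bases, b)
  })
  n <- length(pos0)
  data.frame(chrom = rep(chrom, n * 3L),
             pos0 = rep(pos0, each = 3L),
             ref = rep(ref, each = 3L),
             alt = unlist(alt_list),
             context7 = rep(ctx, each = 3L),
             Y = 0L, common = 0L,
             coverage = NA_real_,
             gc_frac = rep(gc, each = 3L),
             cpg_island = FALSE,
             excluded = FALSE, reason = "",
             P = NA_real_,
             stringsAsFactors = FALSE)
}

gc_fraction <- function(chr_seq, pos0, window) {
  half <- window %/% 2L
  len <- nchar(chr_seq)
  is_gc <- as.integer(strsplit(toupper(chr_seq), "")[[1]] %in% c("G", "C"))
  cum <- c(0L, cumsum(is_gc))
  lo <- pmax(pos0 - half, 0L)
  hi <- pmin(pos0 + half + 1L, len) # half-open [lo, hi)
  (cum[hi + 1L] - cum[lo + 1L]) / pmax(hi - lo, 1L)
}

#' Apply (or re-apply) site-level exclusion filters
#'
#' Marks sites as excluded with a reason code: `"context"` (non-ACGT base in
#' the 7-mer), `"CpG"`, `"low_coverage"`, or `"common"` (any common variant
#' at the site). Idempotent: re-applying to an already filtered table leaves
#' it unchanged.
#'
#' @param tab A site table (or compatible data frame).
#' @param min_coverage Coverage threshold.
#' @return The table with `excluded`/`reason` recomputed.
#' @export
apply_site_filters <- function(tab, min_coverage = 20) {
  ctx_ok <- !is.na(tab$context7) & grepl("^[ACGT]{7}$", tab$context7)
  nxt <- substring(tab$context7, 5L, 5L)
  prv <- substring(tab$context7, 3L, 3L)
  cpg_site <- (tab$ref == "C" & nxt == "G") | (tab$ref == "G" & prv == "C")
  cpg_site[is.na(cpg_site)] <- FALSE
  low_cov <- is.na(tab$coverage) | tab$coverage < min_coverage

  site_key <- paste(tab$chrom, tab$pos0)
  common_site <- stats::ave(tab$common, site_key, FUN = max) > 0

  reason <- rep("", nrow(tab))
  reason[common_site] <- "common"
  reason[low_cov] <- "low_coverage"
  reason[cpg_site] <- "CpG"
  reason[!ctx_ok] <- "context"
  tab$excluded <- nzchar(reason)
  tab$reason <- reason
  tab
}

#' Coerce a data frame to a site table
#'
#' Validates the site-table invariants: required columns, exactly three
#' alternative alleles per site in alphabetical order among non-reference
#' bases, `Y` and `common` never both 1 for the same allele, and (where `P`
#' is filled) `P` in (0,1) with the per-site sum below 1.
#'
#' @param x Data frame with the site-table columns (see
#'   [build_site_table()]).
#' @return A `site_table`.
#' @export
as_site_table <- function(x) {
  miss <- setdiff(SITE_TABLE_COLS, names(x))
  if (length(miss)) stop("site table is missing columns: ",
                         paste(miss, collapse = ", "))
  x <- as.data.frame(x)[, SITE_TABLE_COLS]
  key <- paste(x$chrom, x$pos0, x$alt)
  if (anyDuplicated(key)) {
    stop("duplicated (chrom, pos, alt) rows: ",
         key[which(duplicated(key))[1]])
  }
  cnt <- table(paste(x$chrom, x$pos0))
  if (length(cnt) && any(cnt != 3L)) {
    stop("every site must have exactly 3 alternative-allele rows")
  }
  if (any(x$Y == 1L & x$common == 1L)) {
    stop("a variant cannot be both rare and common at the same allele")
  }
  filled <- !is.na(x$P) & !x$excluded
  if (any(filled)) {
    if (any(x$P[filled] <= 0 | x$P[filled] >= 1)) {
      stop("filled P values must lie in (0,1)")
    }
    psum <- tapply(x$P[filled], paste(x$chrom, x$pos0)[filled], sum)
    if (any(psum >= 1)) stop("per-site sum of P must be < 1")
  }
  class(x) <- c("site_table", "data.frame")
  x
}

#' Number of retained sites in a site table
#'
#' @param tab A `site_table`.
#' @return Number of distinct non-excluded sites (the `M` of the estimator).
#' @export
n_retained_sites <- function(tab) {
  keep <- !tab$excluded
  length(unique(paste(tab$chrom, tab$pos0)[keep]))
}

#' @export
print.site_table <- function(x, ...) {
  n_sites <- length(unique(paste(x$chrom, x$pos0)))
  cat(sprintf(paste0("Site table: %d sites (%d retained), %d rare variants",
                     " among retained sites\n"),
              n_sites, n_retained_sites(x), sum(x$Y[!x$excluded])))
  excl <- table(x$reason[x$excluded & !duplicated(paste(x$chrom, x$pos0))])
  if (length(excl)) {
    cat("Exclusions:",
        paste(names(excl), excl, sep = "=", collapse = ", "), "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Write / read a site table as headered TSV
#'
#' One row per (site, alternative allele); round-trips every field exactly
#' for integer and logical columns and to full printed precision for reals.
#'
#' @param tab A `site_table`.
#' @param path Output (input) path.
#' @return `write_site_table` returns `path` invisibly; `read_site_table`
#'   returns a `site_table`.
#' @export
write_site_table <- function(tab, path) {
  stopifnot(inherits(tab, "site_table"))
  out <- as.data.frame(tab)
  for (cc in c("coverage", "gc_frac", "P")) {
    out[[cc]] <- trimws(formatC(out[[cc]], digits = 17, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character",
                                        ref = "character",
                                        alt = "character",
                                        context7 = "character",
                                        reason = "character"),
                         na.strings = "NA", fill = FALSE)
  extra <- setdiff(names(x), SITE_TABLE_COLS)
  if (length(extra)) stop("unknown site-table columns: ",
                          paste(extra, collapse = ", "))
  if (nrow(x) == 0L) {
    x <- stats::setNames(
      data.frame(character(), integer(), character(), character(),
                 character(), integer(), integer(), numeric(), numeric(),
                 logical(), logical(), character(), numeric(),
                 stringsAsFactors = FALSE),
      SITE_TABLE_COLS)
    class(x) <- c("site_table", "data.frame")
    return(x)
  }
  x$reason[is.na(x$reason)] <- ""
  as_site_table(x)
}
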