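# In-code fixtures shared across test files.

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  path
}

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  path
}

write_vcf <- function(df, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           "##INFO=<ID=mean_dp,Number=1,Type=Float,Description=\"Mean depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s;mean_dp=%s",
                  df$chrom, df$pos0 + 1L, df$ref, df$alt,
                  format(df$af, scientific = FALSE), df$coverage)
  writeLines(c(hdr, body), path)
  path
}

# A CpG-free toy chromosome: alternating A/T core with defined bases so
# heptamer contexts are valid for positions 3..(n-4).
toy_chrom_seq <- function(n = 20L) {
  paste(rep(c("A", "T"), length.out = n), collapse = "")
}

# Toy 10-site region (positions 3..12 of a 16 bp A/T chromosome) with
# variants supplied by the caller.
toy_region_inputs <- function(variants = NULL, coverage = 30) {
  chr <- toy_chrom_seq(16L)
  fa <- write_fasta(c(chrT = chr))
  reg <- region_set(data.frame(chrom = "chrT", start = 3L, end = 13L))
  list(fasta = fa, regions = reg, variants = variants, coverage = coverage,
       seq = chr)
}

# Full-pipeline fixture: synthetic genome, a neutral and a target segment,
# rare variants simulated from a hidden 3-mer truth, mutation model fit on
# the neutral segment, depletion estimated on the target. Returns one
# lambda_fit per requested true lambda (the model is fit once).
run_e2e_pipeline <- function(lambdas, n_bp = 230000L, genome_seed = 11L,
                             truth_seed = 7L, sim_seed = 99L) {
  g <- synthetic_genome(n_bp, seed = genome_seed, gc = 0.41,
                        dir = tempfile("e2e"))
  tgt_lo <- 100000L
  tgt_hi <- 130000L
  neutral_r <- region_set(data.frame(chrom = g$chrom,
                                     start = c(0L, tgt_hi),
                                     end = c(tgt_lo, n_bp)), "neutral")
  target_r <- region_set(data.frame(chrom = g$chrom, start = tgt_lo,
                                    end = tgt_hi), "target")
  cpg <- read_regions(g$cpg_bed, "cpg")
  cov <- utils::read.table(g$coverage, header = TRUE, sep = "\t")

  # hidden truth: per-(3-mer, alt) logits
  bases <- c("A", "C", "G", "T")
  k3 <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases,
                        paste0))
  set.seed(truth_seed)
  truth <- stats::setNames(runif(length(k3) * 4L, -3.4, -2.6),
                           paste(rep(k3, each = 4L), bases))
  true_p <- function(tab) {
    stats::plogis(unname(truth[paste(substring(tab$context7, 3L, 5L),
                                     tab$alt)]))
  }

  set.seed(sim_seed)
  neutral <- build_site_table(g$fasta, neutral_r, coverage = cov,
                              cpg_islands = cpg)
  keep <- !neutral$excluded
  neutral$Y[keep] <- rbinom(sum(keep), 1L, true_p(neutral[keep, ]))
  model <- fit_mutation_model(neutral, sample_fraction = 1, seed = 5,
                              min_sites = 50)

  target0 <- build_site_table(g$fasta, target_r, coverage = cov,
                              cpg_islands = cpg)
  target0 <- suppressWarnings(predict(model, target0))
  tkeep <- !target0$excluded
  tp <- true_p(target0[tkeep, ])
  lapply(lambdas, function(lam) {
    tgt <- target0
    tgt$Y[tkeep] <- rbinom(sum(tkeep), 1L, (1 - lam) * tp)
    estimate_lambda(tgt)
  })
}

# Site table drawn from a handful of heptamer contexts with known
# per-(context, alt) rare-variant probabilities; Y simulated from them.
sim_context_table <- function(n_sites_per_ctx, ctx_rates, lambda_s = 0,
                              coverage = 30, gc_frac = 0.5,
                              cpg_island = FALSE) {
  ctxs <- names(ctx_rates)
  rows <- lapply(seq_along(ctxs), function(k) {
    m <- n_sites_per_ctx
    ref <- substring(ctxs[k], 4L, 4L)
    alts <- setdiff(c("A", "C", "G", "T"), ref)
    data.frame(chrom = "sim", pos0 = 0L, ref = ref,
               alt = rep(alts, m),
               context7 = ctxs[k],
               Y = 0L, common = 0L, coverage = coverage, gc_frac = gc_frac,
               cpg_island = cpg_island, excluded = FALSE, reason = "",
               rate = rep(as.numeric(ctx_rates[[k]]), m),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$pos0 <- rep(seq_len(nrow(tab) / 3L) - 1L, each = 3L)
  tab$Y <- stats::rbinom(nrow(tab), 1L, (1 - lambda_s) * tab$rate)
  tab$P <- NA_real_
  tab$rate <- NULL
  as_site_table(tab)
}
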