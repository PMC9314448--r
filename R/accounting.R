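# Genome-wide accounting: combine per-category depletion estimates and site
# counts into background-adjusted expected numbers of ultraselected sites,
# fold enrichments, and expected strongly deleterious mutations per
# potential zygote.

#' Bundled genome-wide partition estimates
#'
#' Depletion estimates (`lambda_s` with standard errors) and site counts
#' for a mutually exclusive and exhaustive partition of the autosomal human
#' genome -- coding sequence, UTRs, splice sites, and conserved/nonconserved
#' lncRNA, intronic and intergenic fractions -- obtained from 71,702 deeply
#' sequenced genomes (gnomAD v3). Shipped as the worked input for
#' [build_accounting()].
#'
#' @return Data frame with columns `name`, `lambda_s`, `stderr`, `n_sites`.
#' @export
genome_partition <- function() {
  data.frame(
    name = c("CDS", "5' UTR", "3' UTR", "splice",
             "nonconserved lncRNA", "conserved lncRNA",
             "nonconserved intron", "conserved intron",
             "nonconserved intergenic", "conserved intergenic"),
    lambda_s = c(0.148, -0.161, 0.028, 0.464, 0.009, 0.055, 0.009, 0.058,
                 0.003, 0.048),
    stderr = c(4e-04, 6e-04, 2e-04, 1.2e-03, 1e-04, 3e-04, 9e-05, 2e-04,
               1e-05, 2e-04),
    n_sites = c(33.8, 8.2, 36.1, 0.8, 453.6, 23.3, 972.6, 44.3, 1255.5,
                46.9) * 1e6,
    stringsAsFactors = FALSE)
}

#' Genome-wide ultraselection accounting
#'
#' For each category, subtracts the background category's `lambda_s`
#' (flooring at zero: a conservative correction for residual
#' mutation-model misspecification), multiplies by the category's site
#' count to get the expected number of ultraselected sites, and derives the
#' expected proportion of ultraselected sites, the fold enrichment
#' (expected proportion over proportion of all analysed sites), and --
#' at twice the per-generation mutation rate, allowing for either
#' homologous copy to mutate -- the expected number of de novo strongly
#' deleterious mutations per potential zygote. When standard errors are
#' present, [propagate_errors()] results are attached.
#'
#' @param rows Data frame with columns `name`, `lambda_s`, `n_sites` and
#'   optionally `stderr`.
#' @param background_name Name of the putatively neutral background
#'   category whose `lambda_s` is subtracted from every row.
#' @param mu Per-site, per-generation mutation rate (default 1.2e-8).
#' @return A `partition_accounting` with a per-category `table` and a
#'   `totals` list; totals are computed from unrounded values.
#' @examples
#' acct <- build_accounting(genome_partition(), "nonconserved intron")
#' acct$totals$exp_sdel # ~0.26 per potential zygote
#' @export
build_accounting <- function(rows, background_name, mu = 1.2e-8) {
  need <- c("name", "lambda_s", "n_sites")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(rows$name)) stop("duplicate category names")
  if (!background_name %in% rows$name) {
    stop("background category '", background_name, "' not found")
  }
  if (any(rows$n_sites <= 0)) stop("site counts must be positive")

  lam_bg <- rows$lambda_s[rows$name == background_name]
  tab <- data.frame(name = rows$name, lambda_s = rows$lambda_s,
                    n_sites = rows$n_sites, stringsAsFactors = FALSE)
  tab$adj_lambda <- pmax(tab$lambda_s - lam_bg, 0)
  tab$exp_sites <- tab$adj_lambda * tab$n_sites
  tab$prop_sites <- tab$n_sites / sum(tab$n_sites)
  total_exp <- sum(tab$exp_sites)
  tab$exp_prop <- if (total_exp > 0) tab$exp_sites / total_exp else 0
  tab$fold_enrich <- tab$exp_prop / tab$prop_sites
  tab$exp_sdel <- tab$exp_sites * 2 * mu

  out <- list(table = tab,
              totals = list(n_sites = sum(tab$n_sites),
                            exp_sites = total_exp,
                            exp_prop_genome = total_exp / sum(tab$n_sites),
                            exp_sdel = total_exp * 2 * mu),
              background = background_name, mu = mu)
  if ("stderr" %in% names(rows)) {
    out$errors <- propagate_errors(rows, background_name, mu = mu)
  }
  structure(out, class = "partition_accounting")
}

#' Error propagation for the accounting
#'
#' Standard errors of the background-adjusted `lambda_s` combine the
#' category and background errors in quadrature; errors on expected site
#' counts scale by the category size; totals combine per-category errors
#' in quadrature assuming independence. Categories floored at zero
#' (including the background itself) are pinned by construction and carry
#' zero error.
#'
#' @param rows Data frame with `name`, `lambda_s`, `stderr`, `n_sites`.
#' @param background_name Background category name.
#' @param mu Mutation rate used for the deleterious-mutation error.
#' @return List with per-category `se_adj_lambda`, `se_exp_sites`, and
#'   totals `se_total_exp_sites`, `se_total_exp_sdel`.
#' @export
propagate_errors <- function(rows, background_name, mu = 1.2e-8) {
  if (!"stderr" %in% names(rows)) stop("rows lack a stderr column")
  if (any(rows$stderr < 0)) stop("negative standard errors")
  if (!background_name %in% rows$name) {
    stop("background category '", background_name, "' not found")
  }
  bg <- rows$name == background_name
  se_bg <- rows$stderr[bg]
  lam_bg <- rows$lambda_s[bg]
  floored <- (rows$lambda_s - lam_bg) <= 0
  se_adj <- sqrt(rows$stderr^2 + se_bg^2)
  se_adj[floored] <- 0
  se_exp <- rows$n_sites * se_adj
  list(name = rows$name,
       se_adj_lambda = se_adj,
       se_exp_sites = se_exp,
       se_total_exp_sites = sqrt(sum(se_exp^2)),
       se_total_exp_sdel = 2 * mu * sqrt(sum(se_exp^2)))
}

#' @export
print.partition_accounting <- function(x, digits = 3, ...) {
  tab <- x$table
  disp <- data.frame(category = tab$name,
                     lambda_s = tab$lambda_s,
                     `sites (M)` = round(tab$n_sites / 1e6, 1),
                     `adj lambda` = round(tab$adj_lambda, 3),
                     `exp. sites (M)` = round(tab$exp_sites / 1e6, 1),
                     `exp. prop` = sprintf("%.1f%%", 100 * tab$exp_prop),
                     `fold enr.` = round(tab$fold_enrich, 1),
                     `exp. s-del` = round(tab$exp_sdel, 2),
                     check.names = FALSE)
  print.data.frame(disp, row.names = FALSE)
  cat(sprintf(paste0("Total: %.1f M expected ultraselected sites ",
                     "(%.3f%% of %.1f M analysed); %.2f expected strongly ",
                     "deleterious mutations per potential zygote ",
                     "(mu = %.3g, background = %s)\n"),
              x$totals$exp_sites / 1e6, 100 * x$totals$exp_prop_genome,
              x$totals$n_sites / 1e6, x$totals$exp_sdel, x$mu,
              x$background))
  if (!is.null(x$errors)) {
    cat(sprintf("Total s-del SE (quadrature): %.2g\n",
                x$errors$se_total_exp_sdel))
  }
  invisible(x)
}
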