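# Serialization of a fitted mutation model as a plain-text bundle
# directory: context_rates.tsv, covariates.json, regional.tsv, manifest.json.

#' Save / load a mutation model bundle
#'
#' The bundle is a directory of plain-text files: `context_rates.tsv`
#' (per-level context counts), `covariates.json` (coefficients and fit
#' metadata), `regional.tsv` (window intercepts), and `manifest.json`.
#'
#' @param model A `mutation_model`.
#' @param dir Bundle directory (created if needed).
#' @return `save_mutation_model` returns `dir` invisibly;
#'   `load_mutation_model` returns a `mutation_model`.
#' @export
save_mutation_model <- function(model, dir) {
  stopifnot(inherits(model, "mutation_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  level_df <- function(level, k) {
    ny <- level$y
    ctx_alt <- strsplit(names(ny), " ", fixed = TRUE)
    data.frame(level = k,
               context = vapply(ctx_alt, `[[`, "", 1L),
               alt = vapply(ctx_alt, `[[`, "", 2L),
               y = as.numeric(ny),
               n_sites = as.numeric(level$n_sites[
                 vapply(ctx_alt, `[[`, "", 1L)]),
               stringsAsFactors = FALSE)
  }
  rates <- model$rates
  ctx <- rbind(level_df(rates$k7, 7L), level_df(rates$k3, 3L),
               level_df(rates$k1, 1L))
  utils::write.table(ctx, file.path(dir, "context_rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cov <- model$covariates
  jsonlite::write_json(
    list(intercept = cov$intercept,
         coefficients = as.list(cov$coefficients),
         loglik = cov$loglik, n_obs = cov$n_obs, seed = cov$seed,
         sample_fraction = cov$sample_fraction),
    file.path(dir, "covariates.json"), auto_unbox = TRUE, digits = NA)

  if (!is.null(model$scaler)) {
    utils::write.table(model$scaler$windows,
                       file.path(dir, "regional.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(model$scaler$chrom_intercepts),
                         file.path(dir, "regional_chrom.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    c(model$meta, list(pseudocount_ctx = rates$pseudocount,
                       has_regional = !is.null(model$scaler),
                       window = model$scaler$window %||% NA,
                       step = model$scaler$step %||% NA,
                       min_sites = model$scaler$min_sites %||% NA)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_mutation_model
#' @export
load_mutation_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ctx <- utils::read.table(file.path(dir, "context_rates.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(context = "character",
                                          alt = "character"))
  mk_level <- function(k) {
    sub <- ctx[ctx$level == k, , drop = FALSE]
    n <- sub[!duplicated(sub$context), c("context", "n_sites")]
    list(n_sites = stats::setNames(n$n_sites, n$context),
         y = stats::setNames(sub$y, paste(sub$context, sub$alt)))
  }
  rates <- structure(list(k7 = mk_level(7L), k3 = mk_level(3L),
                          k1 = mk_level(1L),
                          pseudocount = manifest$pseudocount_ctx),
                     class = "context_rates")

  cj <- jsonlite::read_json(file.path(dir, "covariates.json"),
                            simplifyVector = TRUE)
  cov <- structure(list(intercept = cj$intercept,
                        coefficients = unlist(cj$coefficients),
                        loglik = cj$loglik, n_obs = cj$n_obs,
                        seed = cj$seed,
                        sample_fraction = cj$sample_fraction),
                   class = "covariate_model")

  scaler <- NULL
  if (isTRUE(manifest$has_regional)) {
    wins <- utils::read.table(file.path(dir, "regional.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE,
                              colClasses = c(chrom = "character"))
    ci <- unlist(jsonlite::read_json(file.path(dir, "regional_chrom.json"),
                                     simplifyVector = TRUE))
    scaler <- structure(list(windows = wins, chrom_intercepts = ci,
                             window = manifest$window, step = manifest$step,
                             min_sites = manifest$min_sites),
                        class = "regional_scaler")
  }
  meta <- manifest[setdiff(names(manifest),
                           c("pseudocount_ctx", "has_regional", "window",
                             "step", "min_sites"))]
  structure(list(rates = rates, covariates = cov, scaler = scaler,
                 meta = meta),
            class = "mutation_model")
}
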