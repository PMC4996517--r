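# Replicated-study harnesses: hit ratios of the top-ranked model against the
# known causal pair, and empirical type-I error of the max-statistic
# permutation test on null data.

#' Did a top-ranked combination identify the causal pair?
#'
#' Modes follow the three locus classifiers of the power study:
#' `"two"` — the top pair equals the causal pair as a set; `"single"` — the
#' top single SNP is a member of the causal pair; `"three"` — the top triple
#' contains both causal SNPs.
#'
#' @param top integer vector, the top-ranked SNP combination for the mode's
#'   order (length 1, 2 or 3).
#' @param causal_pair integer vector of the two causal SNP indices.
#' @param mode `"single"`, `"two"` or `"three"`.
#' @return `TRUE`/`FALSE`.
#' @export
hit_indicator <- function(top, causal_pair, mode = c("two", "single", "three")) {
  mode <- match.arg(mode)
  if (length(causal_pair) != 2L) stop("'causal_pair' must name two SNPs")
  need <- c(single = 1L, two = 2L, three = 3L)[mode]
  if (length(top) != need) {
    stop(sprintf("mode '%s' needs a top combination of length %d, got %d",
                 mode, need, length(top)))
  }
  switch(mode,
         single = top %in% causal_pair,
         two = setequal(top, causal_pair),
         three = all(causal_pair %in% top))
}

#' Hit ratio over replicated scans
#'
#' Fraction of replicates whose top-ranked combination identifies the causal
#' pair under the given locus mode (see [hit_indicator()]).
#'
#' @param tops list with one top combination (integer vector) per replicate.
#' @param causal_pair integer vector of the two causal SNP indices.
#' @inheritParams hit_indicator
#' @return Number in `[0, 1]`.
#' @export
hit_ratio <- function(tops, causal_pair, mode = c("two", "single", "three")) {
  mode <- match.arg(mode)
  if (length(tops) == 0L) stop("'tops' must be non-empty")
  mean(vapply(tops, hit_indicator, logical(1),
              causal_pair = causal_pair, mode = mode))
}

#' Empirical type-I error from null-data p-values
#'
#' @param pvalues permutation p-values, one per null-dataset replicate.
#' @param alpha significance level.
#' @return Fraction of p-values `<= alpha`.
#' @export
estimate_type1_error <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) stop("'pvalues' must be non-empty")
  mean(pvalues <= alpha)
}

#' Type-I-error study on null datasets
#'
#' Generates `replicates` independent null datasets (quantitative trait
#' independent of every SNP, mixture law with a flat mean table; see
#' [simulate_null_dataset()]), categorizes each trait into `J` classes,
#' computes the dataset's maximum pairwise GIDS and its max-statistic
#' permutation p-value with `B` permutations, and reports the fraction of
#' p-values at or below `alpha`. Replicates alternate through the `mafs`
#' grid so the estimate averages over allele frequencies.
#'
#' @param J number of phenotype classes (2, 3 or 4).
#' @param replicates number of null datasets.
#' @param B permutations per dataset.
#' @param n,p samples and SNPs per dataset.
#' @param mafs minor allele frequencies cycled across replicates.
#' @param alpha significance level.
#' @param sigma_H,alpha_mix mixture parameters of the null trait law.
#' @param seed integer seed for the whole study.
#' @return Object of class `type1_study`: list with `pvalues`, `rate`,
#'   `percent`, and the study configuration.
#' @export
type1_study <- function(J, replicates = 200L, B = 200L, n = 400L, p = 20L,
                        mafs = c(0.2, 0.4), alpha = 0.05,
                        sigma_H = 1, alpha_mix = 0.4, seed = NULL) {
  if (replicates < 1L) stop("'replicates' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  data_seeds <- sample.int(.Machine$integer.max, replicates)
  perm_seeds <- sample.int(.Machine$integer.max, replicates)
  pvalues <- vapply(seq_len(replicates), function(r) {
    maf <- mafs[(r - 1L) %% length(mafs) + 1L]
    ds <- simulate_null_dataset(n, p, maf, trait = "quantitative",
                                sigma_H = sigma_H, alpha = alpha_mix,
                                seed = data_seeds[r])
    classes <- categorize_trait(ds$phenotype, J)
    scan <- scan_order(ds$genotypes, classes, k = 2L)
    null <- permutation_null(ds$genotypes, classes, k = 2L, B = B,
                             seed = perm_seeds[r])
    permutation_pvalue(scan$gids[1L], null)
  }, numeric(1))
  rate <- estimate_type1_error(pvalues, alpha)
  structure(list(J = J, replicates = replicates, B = B, n = n, p = p,
                 mafs = mafs, alpha = alpha, pvalues = pvalues,
                 rate = rate, percent = 100 * rate,
                 se_percent = 100 * sqrt(rate * (1 - rate) / replicates)),
            class = "type1_study")
}

#' @export
print.type1_study <- function(x, ...) {
  cat(sprintf(
    "Type-I error at alpha = %.2f (J = %d, %d null datasets, B = %d): %.1f%% (SE %.1f%%)\n",
    x$alpha, x$J, x$replicates, x$B, x$percent, x$se_percent))
  invisible(x)
}

#' Replicated power study for one simulation scenario
#'
#' Simulates `replicates` datasets from a scenario (see
#' [scenario_categorical()] / [scenario_quantitative()]), scans each at
#' orders 1, 2 and 3, and reports the single-, two- and three-locus hit
#' ratios of the top-ranked combinations against the scenario's causal pair,
#' with binomial standard errors. Optionally appends one JSON line per
#' replicate to `log_path`.
#'
#' @param scenario a scenario object.
#' @param replicates number of simulated datasets.
#' @param orders interaction orders to scan; hit ratios are reported for the
#'   modes whose order is included (1 = single, 2 = two, 3 = three).
#' @param seed integer seed for the whole study.
#' @param log_path optional path for a JSON-lines per-replicate log.
#' @return Object of class `gids_study`: list with `summary` (data frame:
#'   `mode`, `hits`, `replicates`, `ratio`, `se`) and `tops` (per-replicate
#'   top combinations by order).
#' @export
run_study <- function(scenario, replicates = 100L, orders = c(1L, 2L, 3L),
                      seed = NULL, log_path = NULL) {
  if (!inherits(scenario, "gids_scenario")) stop("'scenario' must be a scenario object")
  if (replicates < 1L) stop("'replicates' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  modes <- c("single", "two", "three")[match(orders, 1:3, nomatch = 0L)]
  modes <- modes[!is.na(modes) & nzchar(modes)]
  tops <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    ds <- simulate_scenario(scenario, seed = rep_seeds[r])
    classes <- scenario_classes(scenario, ds)
    top_r <- lapply(orders, function(k) {
      scan <- scan_order(ds$genotypes, classes, k)
      unlist(scan[1L, seq_len(k)], use.names = FALSE)
    })
    names(top_r) <- paste0("order", orders)
    tops[[r]] <- top_r
    if (!is.null(log_path)) {
      rec <- list(replicate = r, seed = rep_seeds[r],
                  tops = lapply(top_r, as.integer),
                  causal_pair = as.integer(scenario$causal))
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
          file = log_path, append = TRUE, sep = "")
    }
  }
  rows <- lapply(seq_along(orders), function(m) {
    k <- orders[m]
    if (!k %in% 1:3) return(NULL)
    mode <- c("single", "two", "three")[k]
    tk <- lapply(tops, `[[`, paste0("order", k))
    ratio <- hit_ratio(tk, scenario$causal, mode)
    data.frame(mode = mode, hits = as.integer(round(ratio * replicates)),
               replicates = replicates, ratio = ratio,
               se = sqrt(ratio * (1 - ratio) / replicates))
  })
  structure(list(summary = do.call(rbind, rows), tops = tops,
                 scenario = scenario, replicates = replicates),
            class = "gids_study")
}

#' @export
print.gids_study <- function(x, ...) {
  cat(sprintf("Power study: %d replicates of scenario '%s'\n",
              x$replicates, x$scenario$name))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
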