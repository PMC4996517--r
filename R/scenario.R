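# Simulation scenarios: self-contained descriptions of a data-generating
# condition (sample size, SNP panel, causal pair, phenotype law) that the
# study harness and the command line can replicate from a seed.

#' Categorical-phenotype simulation scenario
#'
#' @param n,p samples and SNPs per dataset.
#' @param maf minor allele frequency (scalar or length-p).
#' @param causal causal SNP column indices (length matching the penetrance
#'   order).
#' @param penetrance a [penetrance_from_odds()] object or row-stochastic
#'   `3^k x J` matrix.
#' @param name scenario label used in reports.
#' @return Object of class `gids_scenario`.
#' @export
scenario_categorical <- function(n = 400L, p = 20L, maf = 0.5,
                                 causal = c(1L, 2L), penetrance,
                                 name = "categorical") {
  structure(list(type = "categorical", n = n, p = p, maf = maf,
                 causal = causal, penetrance = penetrance, name = name),
            class = "gids_scenario")
}

#' Quantitative-phenotype simulation scenario
#'
#' The simulated trait is categorized into `J` classes with
#' [categorize_trait()] before scanning.
#'
#' @inheritParams scenario_categorical
#' @param model a [quant_penetrance_model()].
#' @param J number of phenotype classes the trait is cut into (2, 3 or 4).
#' @export
scenario_quantitative <- function(n = 400L, p = 20L, maf = 0.2,
                                  causal = c(1L, 2L), model, J = 3L,
                                  name = "quantitative") {
  structure(list(type = "quantitative", n = n, p = p, maf = maf,
                 causal = causal, model = model, J = J, name = name),
            class = "gids_scenario")
}

#' Shipped strong-effect three-class scenario
#'
#' The default power-study condition: n = 400 samples, 20 SNPs at MAF 0.5,
#' causal pair (1, 2), three phenotype classes with prevalences 0.3/0.4/0.3,
#' and the cyclic odds-ratio pattern of [odds_pattern_cyclic()].
#'
#' @param theta odds ratio of the favored class per genotype cell.
#' @export
scenario_strong_categorical <- function(theta = 4) {
  pen <- penetrance_from_odds(c(0.3, 0.4, 0.3), odds_pattern_cyclic(theta),
                              mafs = c(0.5, 0.5))
  scenario_categorical(n = 400L, p = 20L, maf = 0.5, causal = c(1L, 2L),
                       penetrance = pen, name = "strong-categorical")
}

#' Simulate one dataset from a scenario
#'
#' @param scenario a `gids_scenario`.
#' @param seed optional integer seed.
#' @return A [gids_dataset()] (quantitative scenarios keep the raw trait;
#'   categorization happens at scan time).
#' @export
simulate_scenario <- function(scenario, seed = NULL) {
  if (!inherits(scenario, "gids_scenario")) stop("not a scenario object")
  if (!is.null(seed)) set.seed(seed)
  g <- simulate_genotypes(scenario$n, scenario$p, scenario$maf)
  y <- if (scenario$type == "categorical") {
    simulate_categorical_phenotype(g, scenario$causal, scenario$penetrance)
  } else {
    simulate_quantitative_phenotype(g, scenario$causal, scenario$model)
  }
  gids_dataset(g, y)
}

scenario_classes <- function(scenario, dataset) {
  if (scenario$type == "categorical") {
    dataset$phenotype
  } else {
    categorize_trait(dataset$phenotype, scenario$J)
  }
}

#' Read a simulation scenario from a YAML config file
#'
#' Recognized fields: `name`, `type` ("categorical"/"quantitative"), `n`,
#' `p`, `maf`, `causal`, and either `prevalence` + `odds_ratios` (row-major
#' `3^k x J`) for the categorical type, or `heritability` (or an explicit
#' 3 x 3 `f` table) + `sigma_L`, `sigma_H`, `alpha`, `J` for the
#' quantitative type.
#'
#' @param path YAML file path.
#' @return A `gids_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  field <- function(key, default = NULL) cfg[[key]] %||% default
  type <- match.arg(field("type"), c("categorical", "quantitative"))
  causal <- as.integer(field("causal", c(1L, 2L)))
  name <- field("name", type)
  if (type == "categorical") {
    prevalence <- unlist(field("prevalence"))
    or <- matrix(unlist(field("odds_ratios")), ncol = length(prevalence),
                 byrow = TRUE)
    pen <- penetrance_from_odds(prevalence, or,
                                mafs = rep_len(field("maf", 0.5), length(causal)))
    scenario_categorical(field("n", 400L), field("p", 20L), field("maf", 0.5),
                         causal, pen, name)
  } else {
    mafs <- rep_len(field("maf", 0.2), 2L)
    model <- if (!is.null(field("f"))) {
      quant_penetrance_model(matrix(unlist(field("f")), 3L, byrow = TRUE),
                             field("sigma_L", 1), field("sigma_H", 1),
                             field("alpha", 0.4), mafs)
    } else {
      quant_model_from_heritability(field("heritability"),
                                    sigma_L = field("sigma_L", 1),
                                    sigma_H = field("sigma_H", 1),
                                    alpha = field("alpha", 0.4), mafs = mafs)
    }
    scenario_quantitative(field("n", 400L), field("p", 20L), field("maf", 0.2),
                          causal, model, field("J", 3L), name)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
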