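# Data-generating models for the power and type-I-error studies: independent
# Hardy-Weinberg genotypes, a penetrance-driven categorical phenotype, and a
# Gaussian-mixture quantitative phenotype keyed to a 3 x 3 mean table.

#' Simulate independent SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP's minor-allele count is drawn as `Binomial(2, maf)` independently
#' across samples and SNPs (no linkage disequilibrium).
#'
#' @param n number of samples.
#' @param p number of SNPs.
#' @param maf minor allele frequency in `(0, 0.5]`; scalar or length-p vector.
#' @param seed optional integer seed.
#' @return n x p integer matrix with columns `SNP1..SNPp`.
#' @export
simulate_genotypes <- function(n, p, maf, seed = NULL) {
  if (n < 1L || p < 1L) stop("'n' and 'p' must be at least 1")
  maf <- rep_len(maf, p)
  if (any(maf <= 0 | maf > 0.5)) stop("'maf' must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  colnames(g) <- paste0("SNP", seq_len(p))
  g
}

hwe_cell_probs <- function(mafs) {
  # joint probabilities of the 3^k multi-locus genotype cells, mixed-radix
  # order matching build_contingency_table()
  per_snp <- lapply(mafs, function(q) c((1 - q)^2, 2 * q * (1 - q), q^2))
  probs <- 1
  for (pr in per_snp) probs <- as.vector(outer(pr, probs))  # first SNP most significant
  probs
}

#' Penetrance table from prevalences and odds ratios
#'
#' Converts a `3^k x J` odds-ratio table `OR_ij` plus marginal class
#' prevalences `v_j` into per-genotype-cell class probabilities: each cell's
#' unnormalized class weight is `OR_ij * v_j`, renormalized to sum to one
#' within the cell (a multinomial-logit tilt of the prevalence vector). This
#' construction reproduces `p_{j|i} = v` exactly when all odds ratios are 1,
#' and concentrates a cell on a class as that class's odds ratio grows. The
#' conversion is this package's own device: the study design only requires
#' that penetrances be "determined" by prevalences and odds ratios, and any
#' row-stochastic table can also be passed directly to the phenotype
#' simulator. When `mafs` are supplied the achieved marginal
#' prevalence under Hardy-Weinberg genotype frequencies is reported, and
#' `match_prevalence = TRUE` runs an iterative proportional fitting pass that
#' rescales class weights until the achieved marginals hit `v_j`.
#'
#' @param prevalence length-J vector summing to 1.
#' @param odds_ratios `3^k x J` matrix of positive odds ratios.
#' @param mafs optional length-k minor allele frequencies of the causal SNPs.
#' @param match_prevalence rescale so genotype-averaged class frequencies
#'   match `prevalence` (requires `mafs`).
#' @param tol,max_iter convergence control for the fitting pass.
#' @return Object of class `categorical_penetrance`: list with `k`, `table`
#'   (`3^k x J`, rows sum to 1), `prevalence`, `mafs`,
#'   `achieved_prevalence` (NULL without `mafs`).
#' @export
penetrance_from_odds <- function(prevalence, odds_ratios, mafs = NULL,
                                 match_prevalence = FALSE,
                                 tol = 1e-6, max_iter = 200L) {
  odds_ratios <- as.matrix(odds_ratios)
  J <- ncol(odds_ratios)
  if (length(prevalence) != J) stop("'prevalence' must match ncol(odds_ratios)")
  if (abs(sum(prevalence) - 1) > 1e-8) stop("'prevalence' must sum to 1")
  if (any(odds_ratios <= 0)) stop("odds ratios must be positive")
  k <- round(log(nrow(odds_ratios), 3))
  if (3^k != nrow(odds_ratios)) stop("odds-ratio table must have 3^k rows")
  w <- sweep(odds_ratios, 2L, prevalence, `*`)
  if (any(!is.finite(w))) stop("non-finite class weights")
  tab <- w / rowSums(w)
  achieved <- NULL
  if (!is.null(mafs)) {
    if (length(mafs) != k) stop("'mafs' must have one entry per causal SNP")
    cell_p <- hwe_cell_probs(mafs)
    achieved <- as.vector(cell_p %*% tab)
    if (match_prevalence) {
      scale <- rep(1, J)
      for (it in seq_len(max_iter)) {
        tab <- sweep(w, 2L, scale, `*`)
        tab <- tab / rowSums(tab)
        achieved <- as.vector(cell_p %*% tab)
        if (max(abs(achieved - prevalence)) < tol) break
        scale <- scale * prevalence / achieved
      }
    }
  }
  structure(list(k = k, table = tab, prevalence = prevalence, mafs = mafs,
                 achieved_prevalence = achieved),
            class = "categorical_penetrance")
}

#' Shipped strong-effect three-class interaction pattern
#'
#' A representative two-locus odds-ratio pattern for a 3-class phenotype in
#' which one class per genotype cell carries an elevated odds ratio, the
#' favored class cycling over the nine cells as `(i + j) mod 3`. With the
#' default `theta = 4` and prevalences 0.3/0.4/0.3 this gives a strong
#' two-way interaction signal at the study scale (n = 400, MAF 0.5).
#'
#' @param theta odds ratio of each cell's favored class (others are 1).
#' @return 9 x 3 odds-ratio matrix in mixed-radix cell order.
#' @export
odds_pattern_cyclic <- function(theta = 4) {
  stopifnot(theta > 0)
  or <- matrix(1, 9, 3)
  g <- expand.grid(j = 0:2, i = 0:2)  # mixed-radix: first SNP most significant
  favored <- (g$i + g$j) %% 3 + 1
  or[cbind(seq_len(9), favored)] <- theta
  or
}

#' Simulate a categorical phenotype from a penetrance model
#'
#' Each sample's class is drawn from the multinomial row of its causal-pair
#' genotype cell; SNPs outside `causal` never influence the phenotype.
#'
#' @param genotypes n x p genotype matrix (no missing values at the causal
#'   SNPs).
#' @param causal ordered vector of causal SNP column indices (length
#'   `penetrance$k`).
#' @param penetrance a [penetrance_from_odds()] object, or a `3^k x J` row-
#'   stochastic matrix.
#' @param seed optional integer seed.
#' @return Integer class vector in `1..J`.
#' @export
simulate_categorical_phenotype <- function(genotypes, causal, penetrance,
                                           seed = NULL) {
  tab <- if (inherits(penetrance, "categorical_penetrance")) {
    penetrance$table
  } else {
    as.matrix(penetrance)
  }
  k <- round(log(nrow(tab), 3))
  if (length(causal) != k) stop("'causal' length must match the penetrance order")
  if (any(abs(rowSums(tab) - 1) > 1e-8)) stop("penetrance rows must sum to 1")
  g <- as.matrix(genotypes)[, causal, drop = FALSE]
  if (anyNA(g)) stop("missing genotypes at causal SNPs are not supported")
  if (!is.null(seed)) set.seed(seed)
  cell <- as.vector(g %*% 3^((k - 1):0)) + 1L
  cum <- t(apply(tab, 1L, cumsum))
  u <- runif(nrow(g))
  J <- ncol(tab)
  as.integer(1L + rowSums(u > cum[cell, -J, drop = FALSE]))
}

#' Gaussian-mixture quantitative penetrance model
#'
#' Defines the trait-generating law for a two-locus quantitative phenotype.
#' Cell `(i, j)` of the 3 x 3 mean table `f` is compared with the reference
#' mean `fbar`; a sample in a below-average cell draws
#' `y ~ N(f_ij, sigma_L^2)`, while a sample in a cell at or above average
#' draws from the symmetric two-component mixture
#' `0.5 N(f_ij - alpha, sigma_H^2) + 0.5 N(f_ij + alpha, sigma_H^2)`
#' (mean `f_ij`, variance `sigma_H^2 + alpha^2`). `fbar` is the genotype-
#' frequency-weighted mean of `f` under Hardy-Weinberg frequencies at `mafs`
#' by default; `fbar = "unweighted"` uses the plain 9-cell average.
#'
#' @param f 3 x 3 numeric mean table (rows: first causal SNP's genotype
#'   0/1/2; columns: second SNP's).
#' @param sigma_L,sigma_H standard deviations of the low and high branches.
#' @param alpha mixture offset (>= 0); 0.4 overlaps the components adequately.
#' @param mafs length-2 minor allele frequencies of the causal pair.
#' @param fbar `"weighted"` (default) or `"unweighted"`.
#' @return Object of class `quant_penetrance`: list with `f`, `fbar` (number),
#'   `sigma_L`, `sigma_H`, `alpha`, `mafs`, `heritability`.
#' @export
quant_penetrance_model <- function(f, sigma_L = 1, sigma_H = 1, alpha = 0.4,
                                   mafs = c(0.2, 0.2),
                                   fbar = c("weighted", "unweighted")) {
  f <- as.matrix(f)
  if (!all(dim(f) == c(3L, 3L))) stop("'f' must be a 3 x 3 mean table")
  if (sigma_L <= 0 || sigma_H <= 0) stop("standard deviations must be positive")
  if (alpha < 0) stop("'alpha' must be non-negative")
  if (length(mafs) != 2L) stop("'mafs' must have length 2")
  fbar <- match.arg(fbar)
  w <- matrix(hwe_cell_probs(mafs), 3L, 3L, byrow = TRUE)  # rows: SNP1 genotype
  fb <- if (fbar == "weighted") sum(w * f) else mean(f)
  cell_var <- ifelse(f < fb, sigma_L^2, sigma_H^2 + alpha^2)
  var_g <- sum(w * (f - fb)^2)
  var_e <- sum(w * cell_var)
  structure(list(f = f, fbar = fb, sigma_L = sigma_L, sigma_H = sigma_H,
                 alpha = alpha, mafs = mafs, weights = w,
                 heritability = var_g / (var_g + var_e)),
            class = "quant_penetrance")
}

#' Scale a mean pattern to a target heritability
#'
#' Builds a [quant_penetrance_model()] whose genotype-explained variance
#' fraction `VarG / (VarG + VarE)` equals `h2`, by scaling the centered
#' pattern `f0 - mean(f0)` (scaling preserves which cells lie below the
#' weighted mean, so the branch variances are fixed and the scale has a
#' closed form). `VarG` is the Hardy-Weinberg-weighted variance of the cell
#' means and `VarE` the weighted within-cell variance (`sigma_L^2` below the
#' mean, `sigma_H^2 + alpha^2` at or above).
#'
#' @param h2 target heritability in `(0, 1)`.
#' @param pattern 3 x 3 shape of the cell means; default is the checkerboard
#'   `(i + j) mod 2`, a pure-interaction pattern.
#' @inheritParams quant_penetrance_model
#' @export
quant_model_from_heritability <- function(h2, pattern = NULL,
                                          sigma_L = 1, sigma_H = 1,
                                          alpha = 0.4, mafs = c(0.2, 0.2),
                                          fbar = c("weighted", "unweighted")) {
  if (h2 <= 0 || h2 >= 1) stop("'h2' must lie in (0, 1)")
  if (is.null(pattern)) pattern <- outer(0:2, 0:2, function(i, j) (i + j) %% 2)
  fbar <- match.arg(fbar)
  base <- quant_penetrance_model(pattern, sigma_L, sigma_H, alpha, mafs, fbar)
  f0 <- pattern - base$fbar
  var_g0 <- sum(base$weights * f0^2)
  if (var_g0 <= 1e-12) stop("'pattern' has no genotype variance to scale")
  cell_var <- ifelse(f0 < 0, sigma_L^2, sigma_H^2 + alpha^2)
  var_e <- sum(base$weights * cell_var)
  scale <- sqrt(h2 / (1 - h2) * var_e / var_g0)
  quant_penetrance_model(scale * f0, sigma_L, sigma_H, alpha, mafs, fbar)
}

#' Simulate a quantitative trait from the mixture model
#'
#' @inheritParams simulate_categorical_phenotype
#' @param causal length-2 vector of causal SNP column indices.
#' @param model a [quant_penetrance_model()].
#' @return Numeric trait vector of length n.
#' @export
simulate_quantitative_phenotype <- function(genotypes, causal, model,
                                            seed = NULL) {
  if (!inherits(model, "quant_penetrance")) {
    stop("'model' must be a quant_penetrance_model()")
  }
  if (length(causal) != 2L) stop("'causal' must name two SNPs")
  g <- as.matrix(genotypes)[, causal, drop = FALSE]
  if (anyNA(g)) stop("missing genotypes at causal SNPs are not supported")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(g)
  f_cell <- model$f[cbind(g[, 1L] + 1L, g[, 2L] + 1L)]
  low <- f_cell < model$fbar
  y <- numeric(n)
  y[low] <- rnorm(sum(low), f_cell[low], model$sigma_L)
  n_hi <- sum(!low)
  if (n_hi > 0L) {
    shift <- model$alpha * (2 * rbinom(n_hi, 1L, 0.5) - 1)
    y[!low] <- rnorm(n_hi, f_cell[!low] + shift, model$sigma_H)
  }
  y
}

#' Categorize a quantitative trait into J near-equal-probability classes
#'
#' Thresholds are placed relative to the sample mean and standard deviation
#' of the trait: `(mu)` for `J = 2`, `(mu - z*s, mu + z*s)` with `z = 0.43`
#' for `J = 3`, and `(mu - z*s, mu, mu + z*s)` with `z = 0.67` for `J = 4` —
#' the standard-normal cut points that give partitions of similar area. A
#' value exactly at a threshold joins the upper class.
#'
#' @param y numeric trait vector with positive standard deviation.
#' @param J number of classes, 2, 3 or 4.
#' @param z optional threshold multiplier overriding the default for `J`.
#' @return Integer class vector in `1..J`.
#' @export
categorize_trait <- function(y, J, z = NULL) {
  if (!J %in% 2:4) stop("'J' must be 2, 3 or 4")
  mu <- mean(y)
  s <- sd(y)
  if (!is.finite(s) || s == 0) stop("trait is degenerate (zero variance)")
  if (is.null(z)) z <- c(NA, NA, 0.43, 0.67)[J]
  thr <- switch(as.character(J),
                "2" = mu,
                "3" = c(mu - z * s, mu + z * s),
                "4" = c(mu - z * s, mu, mu + z * s))
  as.integer(1L + findInterval(y, thr))
}

#' Simulate a null dataset (phenotype independent of every SNP)
#'
#' Genotypes come from [simulate_genotypes()]; the phenotype is generated
#' with a constant penetrance table — no genotype cell differs — so it is
#' statistically independent of all SNPs. The quantitative form follows the
#' mixture law with a flat mean table (every cell on the at-or-above-average
#' branch: `0.5 N(-alpha, sigma_H^2) + 0.5 N(alpha, sigma_H^2)`); the
#' categorical form draws classes i.i.d. from `prevalence`.
#'
#' @inheritParams simulate_genotypes
#' @param trait `"quantitative"` or `"categorical"`.
#' @param prevalence class probabilities for the categorical form (its length
#'   sets J); default `c(0.3, 0.4, 0.3)`.
#' @param sigma_H,alpha mixture parameters for the quantitative form.
#' @return List of class `gids_dataset` with elements `genotypes`,
#'   `phenotype`, `trait`.
#' @export
simulate_null_dataset <- function(n, p, maf,
                                  trait = c("quantitative", "categorical"),
                                  prevalence = c(0.3, 0.4, 0.3),
                                  sigma_H = 1, alpha = 0.4, seed = NULL) {
  trait <- match.arg(trait)
  if (!is.null(seed)) set.seed(seed)
  genotypes <- simulate_genotypes(n, p, maf)
  phenotype <- if (trait == "quantitative") {
    shift <- alpha * (2 * rbinom(n, 1L, 0.5) - 1)
    rnorm(n, shift, sigma_H)
  } else {
    sample.int(length(prevalence), n, replace = TRUE, prob = prevalence)
  }
  gids_dataset(genotypes, phenotype)
}
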