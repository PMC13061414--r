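#' Construct a genome
#'
#' A genome is a named numeric vector of seven unbounded allelic values.
#' Bounds are applied at phenotype expression, never at the gene, so
#' mutation needs no reflection or truncation rules.
#'
#' @param alpha Helping-propensity allele; expressed help is
#'   `max(0, alpha)`.
#' @param beta Dispersal allele; the scalar dispersal phenotype is `beta`
#'   clamped to `[0, 1]`.
#' @param beta_0,beta_R Intercept and dominance slope of the optional
#'   logistic dispersal reaction norm.
#' @param gamma_0,gamma_R Intercept and dominance slope of the task-choice
#'   reaction norm.
#' @param neutral Drift-only marker locus used for relatedness estimation.
#' @return Named numeric vector.
#' @export
#' @examples
#' g <- genome(alpha = 0.5)
#' express_help(g)
genome <- function(alpha = 0, beta = 1, beta_0 = 1, beta_R = 0,
                   gamma_0 = 0, gamma_R = 0, neutral = 0) {
  c(alpha = alpha, beta = beta, beta_0 = beta_0, beta_R = beta_R,
    gamma_0 = gamma_0, gamma_R = gamma_R, neutral = neutral)
}

#' Expressed level of help
#'
#' The amount of alloparental care an individual provides each cycle; it
#' equals the allelic value of the helping gene with a boundary of 0 for
#' negative values, and is fixed for the individual's life.
#'
#' @param genome A genome (named vector or one-row data frame).
#' @return Non-negative help level `H`.
#' @export
express_help <- function(genome) {
  max(0, genome[["alpha"]])
}

#' Dispersal propensity
#'
#' Probability that a subordinate leaves its group (and that a floater
#' declines to join one).  The scalar variant is the dispersal allele
#' clamped to `[0, 1]` (0 = certain philopatry, 1 = absolute dispersal).
#' The rank-norm variant is a logistic reaction norm of dominance,
#' `D = 1 / (1 + exp(beta_R * R - beta_0))`, mirroring the task-choice
#' norm.
#'
#' @param genome A genome.
#' @param R Dominance value (>= 0); only used by the rank-norm variant.
#' @param variant `"SCALAR"` (default, base model) or `"RANK_NORM"`.
#' @return Dispersal probability in `[0, 1]`.
#' @export
dispersal_propensity <- function(genome, R = 0,
                                 variant = c("SCALAR", "RANK_NORM")) {
  variant <- match.arg(variant)
  if (variant == "SCALAR") {
    min(1, max(0, genome[["beta"]]))
  } else {
    1 / (1 + exp(genome[["beta_R"]] * R - genome[["beta_0"]]))
  }
}

#' Task-choice probability
#'
#' Probability of choosing the defensive task (versus the work task) this
#' cycle, a logistic reaction norm of the individual's dominance value:
#' `T = 1 / (1 + exp(gamma_R * R - gamma_0))`.  With `gamma_R = 0` the
#' probability is constant in dominance (no age polyethism); `gamma_R > 0`
#' shifts individuals from defense towards work as dominance rises, and
#' `gamma_R < 0` the reverse.
#'
#' @param genome A genome.
#' @param R Dominance value (>= 0).
#' @return Defense probability in `[0, 1]`.
#' @export
task_probability <- function(genome, R) {
  1 / (1 + exp(genome[["gamma_R"]] * R - genome[["gamma_0"]]))
}

#' Dominance value
#'
#' Competitiveness for a breeding vacancy: age (a proxy for resource
#' holding potential) minus the current cycle's work cost, bounded below
#' at 0.  The work cost is not cumulative over time; individuals not
#' performing work this cycle pay none.
#'
#' @param t Age in cycles (>= 1).
#' @param y_h Work-cost scaling on dominance.
#' @param H_work Help expressed in the work task this cycle (0 otherwise).
#' @return `max(0, t - y_h * H_work)`, vectorized.
#' @export
dominance_value <- function(t, y_h, H_work = 0) {
  pmax(0, t - y_h * H_work)
}

#' Mutate a genome
#'
#' Transmission with mutation: independently at each locus (including the
#' neutral locus), with probability `mu` a deviate from
#' `Normal(0, sigma_mu)` is added to the inherited allelic value.  The
#' dispersal allele, whose phenotype is the identity map onto the closed
#' probability interval, is truncated into `[0, 1]` at the gene so that
#' standing variation stays adjacent to both boundaries instead of
#' drifting irreversibly beyond them; every other locus (including the
#' helping allele, whose 0 boundary is one-sided) is unbounded, with
#' bounds applied at phenotype expression only.  The draw order is the
#' engine contract: loci in genome order, one uniform per locus and one
#' normal when it mutates.
#'
#' @param genome Parent genome.
#' @param mu Per-locus mutation rate.
#' @param sigma_mu Mutation step standard deviation.
#' @return Offspring genome.
#' @export
mutate_genome <- function(genome, mu, sigma_mu) {
  for (l in seq_along(genome)) {
    if (stats::runif(1) < mu) {
      v <- genome[[l]] + stats::rnorm(1) * sigma_mu
      if (identical(names(genome)[l], "beta")) v <- min(1, max(0, v))
      genome[[l]] <- v
    }
  }
  genome
}

#' Within-group relatedness from the neutral locus
#'
#' Ordinary-least-squares slope of the helpers' neutral allelic values
#' regressed on their breeders' (one observation per helper over all
#' current breeder-helper pairs).  The slope is the standard
#' marker-regression estimate of relatedness; under cross-fostering it is
#' statistically indistinguishable from 0, and for clonal philopatric
#' groups it approaches 1.
#'
#' @param pairs Two-column matrix or data frame: breeder neutral value,
#'   helper neutral value; one row per helper.
#' @return The regression slope, or `NA` when fewer than 2 pairs exist or
#'   the breeder-side variance is zero (degenerate design, not an error).
#' @export
#' @examples
#' estimate_relatedness(cbind(c(0, 1, 2), c(0, 1, 2)))  # clones: slope 1
estimate_relatedness <- function(pairs) {
  pairs <- as.matrix(pairs)
  n <- nrow(pairs)
  if (is.null(n) || n < 2) return(NA_real_)
  x <- as.numeric(pairs[, 1])
  y <- as.numeric(pairs[, 2])
  den <- n * sum(x * x) - sum(x)^2
  if (den <= 0) return(NA_real_)
  (n * sum(x * y) - sum(x) * sum(y)) / den
}
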