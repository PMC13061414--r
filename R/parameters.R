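#' Default model parameters
#'
#' Returns the scaling parameters of the cooperative-breeding
#' division-of-labour model with their standard values.  All costs and
#' benefits are dimensionless scalings inside logistic survival and
#' saturating fecundity functions.
#'
#' @param y_h Cost of help on dominance value when performing work tasks.
#' @param x_h Cost of help on survival when performing defensive tasks.
#' @param x_n Survival benefit of group size (direct, group-augmentation
#'   benefit).  Forced to 0 in the kin-selection-only scenario.
#' @param x_0 Intercept of the logistic survival function.
#' @param m Baseline mortality in `[0, 1]`; higher values describe harsher
#'   environments.
#' @param f Mean number of groups a floater samples when bidding for a
#'   breeding vacancy.
#' @param k_m Slack on the balanced-task requirement of the
#'   division-of-labour fecundity mode.
#' @param k_h Effect of cumulative help on breeder fecundity.
#' @param k_0 Breeder fecundity in the absence of help.
#' @param mu Per-locus mutation rate in `[0, 1]`.
#' @param sigma_mu Standard deviation of the Gaussian mutation step.
#' @param N_b Number of breeding territories (positive integer).
#' @param n_cycles Default run length in breeding cycles.
#' @param n_replicates Default replicate count for grid runs.
#'
#' @return A named list of parameters.
#' @seealso [scenario_config()], [validate_parameters()]
#' @export
#' @examples
#' p <- default_parameters(m = 0.3, N_b = 100)
#' p$m
default_parameters <- function(y_h = 0.1, x_h = 5, x_n = 3, x_0 = 1.5,
                               m = 0.1, f = 2, k_m = 0.1, k_h = 1, k_0 = 1,
                               mu = 0.05, sigma_mu = 0.04, N_b = 5000,
                               n_cycles = 200000, n_replicates = 20) {
  list(y_h = y_h, x_h = x_h, x_n = x_n, x_0 = x_0, m = m, f = f,
       k_m = k_m, k_h = k_h, k_0 = k_0, mu = mu, sigma_mu = sigma_mu,
       N_b = as.integer(N_b), n_cycles = as.integer(n_cycles),
       n_replicates = as.integer(n_replicates))
}

#' Scenario configuration
#'
#' Switches selecting which fitness benefits operate and how fecundity
#' responds to the task mix:
#' * `benefit_mode`: `"KS_GA"` (both kin selection and group augmentation,
#'   the default model), `"KS_ONLY"` (group-size survival benefit removed,
#'   `x_n = 0`), or `"GA_ONLY"` (kin structure destroyed by cross-fostering
#'   philopatric newborns into random groups).
#' * `fecundity_mode`: `"DOL"` caps each task's effective cumulative help at
#'   the balanced split plus slack `k_m` (division of labour required for
#'   full productivity); `"NO_DOL"` leaves the sums unconstrained.
#' * `dispersal_norm`: `"SCALAR"` uses the clamped allelic value of the
#'   dispersal gene; `"RANK_NORM"` uses a logistic reaction norm of
#'   dispersal to dominance.
#'
#' @param benefit_mode One of `"KS_GA"`, `"KS_ONLY"`, `"GA_ONLY"`.
#' @param fecundity_mode One of `"DOL"`, `"NO_DOL"`.
#' @param dispersal_norm One of `"SCALAR"`, `"RANK_NORM"`.
#' @param seed Integer seed recorded with the scenario.
#' @return A named list with class-checked fields.
#' @export
scenario_config <- function(benefit_mode = c("KS_GA", "KS_ONLY", "GA_ONLY"),
                            fecundity_mode = c("DOL", "NO_DOL"),
                            dispersal_norm = c("SCALAR", "RANK_NORM"),
                            seed = 1L) {
  list(benefit_mode = match.arg(benefit_mode),
       fecundity_mode = match.arg(fecundity_mode),
       dispersal_norm = match.arg(dispersal_norm),
       seed = as.integer(seed))
}

config_error <- function(field, message) {
  stop(errorCondition(sprintf("invalid configuration: %s (%s)", field,
                              message),
                      field = field,
                      class = c("dolsim_config_error", "error",
                                "condition")))
}

#' Validate a parameter set and scenario
#'
#' Checks all parameter invariants and applies scenario-driven overrides:
#' in the kin-selection-only scenario the group-size survival benefit is
#' removed by forcing `x_n = 0`.
#'
#' @param params Parameter list as from [default_parameters()].
#' @param scenario Scenario list as from [scenario_config()].
#' @return A list with elements `params` and `scenario`, with overrides
#'   applied; errors of class `dolsim_config_error` name the offending
#'   field.
#' @export
#' @examples
#' cfg <- validate_parameters(default_parameters(),
#'                            scenario_config("KS_ONLY"))
#' cfg$params$x_n  # forced to 0
validate_parameters <- function(params = default_parameters(),
                                scenario = scenario_config()) {
  required <- names(default_parameters())
  missing <- setdiff(required, names(params))
  if (length(missing) > 0)
    config_error(missing[1], "missing parameter")
  for (nm in required) {
    v <- params[[nm]]
    if (length(v) != 1 || !is.numeric(v) || !is.finite(v))
      config_error(nm, "must be a single finite number")
  }
  if (params$m < 0 || params$m > 1)
    config_error("m", "baseline mortality must lie in [0, 1]")
  if (params$mu < 0 || params$mu > 1)
    config_error("mu", "mutation rate must lie in [0, 1]")
  if (params$sigma_mu < 0)
    config_error("sigma_mu", "mutation step SD must be >= 0")
  if (params$N_b < 1)
    config_error("N_b", "need at least one breeding territory")
  if (params$k_m < 0)
    config_error("k_m", "task-balance slack must be >= 0")
  if (params$f < 0)
    config_error("f", "floater sampling rate must be >= 0")
  if (params$k_0 < 0)
    config_error("k_0", "baseline fecundity must be >= 0")
  if (params$n_cycles < 1)
    config_error("n_cycles", "run length must be >= 1")
  if (params$n_replicates < 1)
    config_error("n_replicates", "replicate count must be >= 1")
  if (!scenario$benefit_mode %in% c("KS_GA", "KS_ONLY", "GA_ONLY"))
    config_error("benefit_mode", "unknown benefit mode")
  if (!scenario$fecundity_mode %in% c("DOL", "NO_DOL"))
    config_error("fecundity_mode", "unknown fecundity mode")
  if (!scenario$dispersal_norm %in% c("SCALAR", "RANK_NORM"))
    config_error("dispersal_norm", "unknown dispersal norm variant")
  if (scenario$benefit_mode == "KS_ONLY")
    params$x_n <- 0
  structure(list(params = params, scenario = scenario),
            class = "dolsim_config")
}

# Integer codes shared with the compiled engine.
benefit_mode_code <- function(x)
  c(KS_ONLY = 1L, GA_ONLY = 2L, KS_GA = 3L)[[x]]
fecundity_mode_code <- function(x) c(DOL = 1L, NO_DOL = 2L)[[x]]
dispersal_norm_code <- function(x) c(SCALAR = 1L, RANK_NORM = 2L)[[x]]

engine_params <- function(params, scenario) {
  c(params,
    list(benefit_mode_code = benefit_mode_code(scenario$benefit_mode),
         fecundity_mode_code = fecundity_mode_code(scenario$fecundity_mode),
         dispersal_norm_code = dispersal_norm_code(scenario$dispersal_norm)))
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment.  Keys are the
#' parameter names of [default_parameters()] plus the scenario switches
#' `benefit_mode`, `fecundity_mode`, `dispersal_norm` and `seed`.  Unknown
#' keys are rejected.  The parsed configuration is validated before being
#' returned.
#'
#' @param path Path to the configuration file.
#' @return A validated configuration (see [validate_parameters()]).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  params <- default_parameters()
  scen_keys <- c("benefit_mode", "fecundity_mode", "dispersal_norm", "seed")
  scen <- scenario_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      config_error(ln, "expected 'key = value'")
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (key %in% names(params)) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) config_error(key, "expected a numeric value")
      params[[key]] <- if (key %in% c("N_b", "n_cycles", "n_replicates"))
        as.integer(num) else num
    } else if (key %in% scen_keys) {
      scen[[key]] <- if (key == "seed") as.integer(val) else val
    } else {
      config_error(key, "unknown configuration key")
    }
  }
  validate_parameters(params, scen)
}

# Key-value echo of a configuration, used as '#'-prefixed output headers.
config_lines <- function(params, scenario) {
  keys <- c(names(default_parameters()),
            "benefit_mode", "fecundity_mode", "dispersal_norm", "seed")
  vals <- c(unlist(params[names(default_parameters())]),
            scenario$benefit_mode, scenario$fecundity_mode,
            scenario$dispersal_norm, scenario$seed)
  paste0(keys, " = ", vals)
}

#' Initial allelic values of the evolving genes
#'
#' The ancestral state: no helping (`alpha = 0`), absolute dispersal
#' (`beta = 1`), dispersal-norm intercept 1 and slope 0, and a flat task
#' reaction norm (`gamma_0 = gamma_R = 0`, i.e. either task with
#' probability one half).
#'
#' @return Named numeric vector of the six selected loci.
#' @export
initial_alleles <- function() {
  c(alpha = 0, beta = 1, beta_0 = 1, beta_R = 0, gamma_0 = 0, gamma_R = 0)
}
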