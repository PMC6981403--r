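#' Synthetic categorical survey configuration
#'
#' Describes a survey population with known dependency structure: a few
#' "confounder" variables drawn uniformly over their levels, a block of
#' dependent variables whose conditional level probabilities shift with the
#' confounders, and independent noise variables. The defaults are the
#' package's reference recovery condition: 3 strata of 2,000 subjects, one
#' binary confounder driving 12 dependent binary variables at a log-odds
#' effect of beta = 2, plus 12 binary noise variables and no missingness.
#'
#' Dependent variable level probabilities follow a multinomial logit: for a
#' dependent variable with levels `0..L-1`, level `l` gets utility
#' `beta * z * l / (L - 1)` where `z` is the mean of the confounders' level
#' indices rescaled to \[0, 1\]; for binary variables this is
#' `P(X = 1 | C = c) = plogis(beta * c)`, so `beta = 0` makes everything
#' independent. Conditional tables are shared across strata; `divergence`
#' flips the sign of each dependent variable's effect independently per
#' stratum with the given probability, creating heterogeneous strata for
#' robustness experiments.
#'
#' @param n_subjects subjects per stratum.
#' @param n_strata number of strata.
#' @param n_confounders number of planted confounder variables.
#' @param n_dependent number of confounder-driven variables.
#' @param n_noise number of independent noise variables.
#' @param levels_confounder,levels_dependent,levels_noise levels per variable
#'   class (single integer, or a vector of candidate level counts sampled
#'   per variable).
#' @param beta log-odds effect size (>= 0) linking confounder level to
#'   dependent-variable level probabilities.
#' @param missing_rate per-cell probability of replacing the answer with the
#'   reserved `MISSING` label, in \[0, 1).
#' @param divergence per-stratum probability of flipping a dependent
#'   variable's effect sign (0 = identical conditional tables everywhere).
#' @param seed integer master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 2000L, n_strata = 3L,
                       n_confounders = 1L, n_dependent = 12L, n_noise = 12L,
                       levels_confounder = 2L, levels_dependent = 2L,
                       levels_noise = 2L, beta = 2, missing_rate = 0,
                       divergence = 0, seed = 1L) {
  stopifnot(n_subjects >= 2L, n_strata >= 1L, n_confounders >= 0L,
            n_dependent >= 0L, n_noise >= 0L, beta >= 0,
            missing_rate >= 0, missing_rate < 1,
            divergence >= 0, divergence <= 1,
            all(levels_confounder >= 2L), all(levels_dependent >= 2L),
            all(levels_noise >= 2L))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_strata = as.integer(n_strata),
                 n_confounders = as.integer(n_confounders),
                 n_dependent = as.integer(n_dependent),
                 n_noise = as.integer(n_noise),
                 levels_confounder = as.integer(levels_confounder),
                 levels_dependent = as.integer(levels_dependent),
                 levels_noise = as.integer(levels_noise),
                 beta = as.numeric(beta),
                 missing_rate = as.numeric(missing_rate),
                 divergence = as.numeric(divergence),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Names of the planted confounder variables
#'
#' @param config a [sim_config()].
#' @return character vector (`conf_1`, `conf_2`, ...; empty if none).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_confounders == 0L) character(0)
  else sprintf("conf_%d", seq_len(config$n_confounders))
}

#' Simulate a categorical survey table with planted structure
#'
#' Generates `n_strata` independent strata from the conditional tables
#' described in [sim_config()]. Variables are named `conf_*`, `dep_*`,
#' `noise_*`; levels are the strings `"0", "1", ...`; strata are labelled
#' `stratum_1, ...`. The draw is fully determined by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [categorical_table()] with a stratum vector.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_survey_impl(config))
}

simulate_survey_impl <- function(cfg) {
  pick_levels <- function(pool, n) {
    if (n == 0L) return(integer(0))
    if (length(pool) == 1L) rep(pool, n) else sample(pool, n, replace = TRUE)
  }
  L_conf <- pick_levels(cfg$levels_confounder, cfg$n_confounders)
  L_dep <- pick_levels(cfg$levels_dependent, cfg$n_dependent)
  L_noise <- pick_levels(cfg$levels_noise, cfg$n_noise)
  vars <- c(sprintf("conf_%d", seq_len(cfg$n_confounders)),
            sprintf("dep_%d", seq_len(cfg$n_dependent)),
            sprintf("noise_%d", seq_len(cfg$n_noise)))
  if (length(vars) == 0L) stop("no variables configured")

  strata_tables <- vector("list", cfg$n_strata)
  for (s in seq_len(cfg$n_strata)) {
    n <- cfg$n_subjects
    # per-stratum effect orientation: shared (+1) unless divergence flips it
    sign_dep <- if (cfg$n_dependent > 0L) {
      ifelse(runif(cfg$n_dependent) < cfg$divergence, -1, 1)
    } else numeric(0)
    conf <- matrix(0L, n, cfg$n_confounders)
    for (j in seq_len(cfg$n_confounders))
      conf[, j] <- sample.int(L_conf[j], n, replace = TRUE) - 1L
    # confounder drive in [0, 1]: mean of rescaled level indices
    z <- if (cfg$n_confounders > 0L) {
      rowMeans(sweep(conf, 2, pmax(L_conf - 1L, 1L), "/"))
    } else rep(0, n)
    dep <- matrix(0L, n, cfg$n_dependent)
    for (j in seq_len(cfg$n_dependent)) {
      L <- L_dep[j]
      # multinomial logit over levels 0..L-1, utility beta * z * l/(L-1)
      u <- outer(cfg$beta * sign_dep[j] * z, (0:(L - 1)) / (L - 1))
      pr <- exp(u)
      pr <- pr / rowSums(pr)
      cum <- t(apply(pr, 1, cumsum))
      r <- runif(n)
      dep[, j] <- rowSums(r > cum[, -L, drop = FALSE])
    }
    noise <- matrix(0L, n, cfg$n_noise)
    for (j in seq_len(cfg$n_noise))
      noise[, j] <- sample.int(L_noise[j], n, replace = TRUE) - 1L
    values <- cbind(conf, dep, noise)
    storage.mode(values) <- "character"
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(length(values)) < cfg$missing_rate, nrow = n)
      values[miss] <- "MISSING"
    }
    colnames(values) <- vars
    strata_tables[[s]] <- values
  }
  values <- do.call(rbind, strata_tables)
  stratum <- rep(sprintf("stratum_%d", seq_len(cfg$n_strata)),
                 each = cfg$n_subjects)
  df <- as.data.frame(values, stringsAsFactors = FALSE)
  df$stratum <- stratum
  categorical_table(df, stratum_col = "stratum")
}

#' Recovery score of a ranking against the planted truth
#'
#' Fraction of the top-k ranked dummy nodes whose source variable is a
#' planted confounder: `|top-k nodes from truth variables| / min(k, number of
#' truth dummies present)`.
#'
#' @param top_k a [rank_hubs()] data.frame (or any with a `node` column).
#' @param truth character vector of confounder variable names
#'   ([ground_truth()]).
#' @param n_truth_dummies total number of dummy columns generated by the
#'   truth variables (defaults to two per confounder, the all-binary case).
#' @return recovery fraction in \[0, 1\] (`NA` if the truth set is empty).
#' @export
recovery_score <- function(top_k, truth, n_truth_dummies = 2L * length(truth)) {
  if (length(truth) == 0L) return(NA_real_)
  src <- sub("=[^=]*$", "", top_k$node)
  sum(src %in% truth) / min(nrow(top_k), n_truth_dummies)
}
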