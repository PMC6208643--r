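#' Parameters of the individual-based microbiota assembly model
#'
#' Bundles and validates the parameters of the colonization model. Each host
#' community holds exactly `capacity` microbial individuals; at each of
#' `years` time steps the whole community is redrawn multinomially with
#' recruitment probabilities mixing three normalized components weighted by
#' the `beta_*` strengths: the Gaussian environmental fitness of each microbe
#' given the host trait (`beta_env`), the current relative abundances
#' (`beta_abun`, the reproduction/drift component), and a trait-similarity
#' competition penalty (`beta_comp`).
#'
#' Defaults are the filtering scenario: `niche_breadth = 0.5`, `beta_env = 1`,
#' `beta_abun = 0`, `beta_comp = 0`, `years = 20`, `capacity = 150`.
#'
#' @param niche_breadth Standard deviation (trait units) of the Gaussian
#'   niches, > 0.
#' @param beta_env,beta_abun,beta_comp Nonnegative filter strengths.
#' @param years Number of time steps, positive integer.
#' @param capacity Carrying capacity: individuals per host community,
#'   positive integer.
#' @return An object of class `assembly_params`.
#' @examples
#' assembly_params()                          # filtering preset
#' assembly_params(beta_env = 0, beta_abun = 1) # neutral drift
#' @export
assembly_params <- function(niche_breadth = 0.5, beta_env = 1, beta_abun = 0,
                            beta_comp = 0, years = 20L, capacity = 150L) {
  if (!is.numeric(niche_breadth) || niche_breadth <= 0) {
    stop("`niche_breadth` must be > 0")
  }
  for (b in list(beta_env = beta_env, beta_abun = beta_abun,
                 beta_comp = beta_comp)) {
    if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0) {
      stop("beta strengths must be single nonnegative numbers")
    }
  }
  if (years < 1 || years != round(years)) stop("`years` must be a positive integer")
  if (capacity < 1 || capacity != round(capacity)) {
    stop("`capacity` must be a positive integer")
  }
  structure(
    list(niche_breadth = niche_breadth, beta_env = beta_env,
         beta_abun = beta_abun, beta_comp = beta_comp,
         years = as.integer(years), capacity = as.integer(capacity)),
    class = "assembly_params"
  )
}

#' @export
print.assembly_params <- function(x, ...) {
  cat("Microbiota assembly parameters\n")
  cat(sprintf("  niche breadth (sd): %g\n", x$niche_breadth))
  cat(sprintf("  beta_env %g | beta_abun %g | beta_comp %g\n",
              x$beta_env, x$beta_abun, x$beta_comp))
  cat(sprintf("  %d time steps, carrying capacity %d\n", x$years, x$capacity))
  invisible(x)
}

#' Gaussian environmental fitness of microbes on a host
#'
#' Fitness of microbe i is the product over trait dimensions of Gaussian
#' kernels of the mismatch between the host trait value and the microbial
#' preference: `prod_t exp(-(h_t - m_it)^2 / (2 sigma^2))`. Lies in (0, 1];
#' equals 1 iff the microbe matches the host perfectly on every trait.
#'
#' @param host_trait Numeric vector, one value per trait dimension.
#' @param microbe_prefs Microbes x traits matrix of preferences.
#' @param niche_breadth Gaussian niche SD, > 0.
#' @return Numeric vector of fitness values over microbes.
#' @export
environmental_fitness <- function(host_trait, microbe_prefs, niche_breadth) {
  if (niche_breadth <= 0) stop("`niche_breadth` must be > 0")
  microbe_prefs <- as.matrix(microbe_prefs)
  if (length(host_trait) != ncol(microbe_prefs)) {
    stop("host trait dimension must match microbe preference columns")
  }
  d2 <- sweep(microbe_prefs, 2L, host_trait)^2
  exp(-rowSums(d2) / (2 * niche_breadth^2))
}

#' Competition penalty from niche overlap with residents
#'
#' Penalty on microbe i given resident abundances a:
#' `C_i = 1 - sum_j a_j k(m_i, m_j) / sum_j a_j`, with k the Gaussian
#' similarity kernel of the trait preferences. For an empty community all
#' penalties are 1 (no competition). A microbe identical to the entire
#' resident community has penalty 0.
#'
#' @param abundances Nonnegative integer vector over the microbe pool.
#' @param microbe_prefs Microbes x traits preference matrix.
#' @param niche_breadth Gaussian niche SD, > 0.
#' @param kernel Optional precomputed microbes x microbes similarity kernel
#'   (used internally to avoid recomputation across steps and hosts).
#' @return Numeric vector of penalties in \[0, 1\].
#' @export
competition_penalty <- function(abundances, microbe_prefs, niche_breadth,
                                kernel = NULL) {
  microbe_prefs <- as.matrix(microbe_prefs)
  m <- nrow(microbe_prefs)
  if (length(abundances) != m) stop("abundance vector length must match pool size")
  if (any(abundances < 0)) stop("abundances must be nonnegative")
  tot <- sum(abundances)
  if (tot == 0) return(rep(1, m))
  if (is.null(kernel)) kernel <- niche_kernel(microbe_prefs, niche_breadth)
  pmin(pmax(1 - drop(kernel %*% abundances) / tot, 0), 1)
}

# Gaussian niche-overlap kernel between all pairs of microbes
niche_kernel <- function(microbe_prefs, niche_breadth) {
  if (niche_breadth <= 0) stop("`niche_breadth` must be > 0")
  d2 <- as.matrix(stats::dist(as.matrix(microbe_prefs)))^2
  exp(-d2 / (2 * niche_breadth^2))
}

#' Recruitment probabilities for one colonization step
#'
#' Combines the three filter components as a convex additive mixture:
#' `p` is proportional to `beta_env * E + beta_abun * A + beta_comp * C`,
#' where each component vector is first normalized to sum to 1 (a component
#' whose total mass is zero contributes nothing). If all betas are zero, or
#' every weighted component has vanished, recruitment is uniform over the
#' pool.
#'
#' @param env_fit Environmental fitness vector (see
#'   [environmental_fitness()]).
#' @param abundances Current abundance vector (the reproduction component;
#'   uniform when the community is empty).
#' @param comp_pen Competition penalty vector (see [competition_penalty()]).
#' @param params An [assembly_params()] object.
#' @return Probability vector summing to 1.
#' @export
recruitment_probabilities <- function(env_fit, abundances, comp_pen, params) {
  m <- length(env_fit)
  if (length(abundances) != m || length(comp_pen) != m) {
    stop("component vectors must have equal length")
  }
  if (any(env_fit < 0) || any(abundances < 0) || any(comp_pen < 0)) {
    stop("component vectors must be nonnegative")
  }
  norm1 <- function(v) {
    s <- sum(v)
    if (s > 0) v / s else rep(0, length(v))
  }
  abun_hat <- if (sum(abundances) > 0) norm1(abundances) else rep(1 / m, m)
  p <- params$beta_env * norm1(env_fit) +
    params$beta_abun * abun_hat +
    params$beta_comp * norm1(comp_pen)
  s <- sum(p)
  if (s == 0) rep(1 / m, m) else p / s
}

#' Assemble one host's microbial community
#'
#' Individual-based assembly: starting from an empty community, at each of
#' `params$years` steps all `params$capacity` individuals are redrawn from a
#' multinomial distribution with the recruitment probabilities computed from
#' the previous step's abundances (full-replacement dynamics). The source
#' pool is infinite and unbiased: every microbe is always available as a
#' colonist.
#'
#' @param host_trait Numeric vector of the host's trait value(s).
#' @param microbe_prefs Microbes x traits preference matrix (rownames are the
#'   microbe labels).
#' @param params An [assembly_params()] object.
#' @param seed Optional integer seed.
#' @param kernel Optional precomputed niche kernel (internal optimization).
#' @return Named integer abundance vector summing to `params$capacity`.
#' @export
assemble_community <- function(host_trait, microbe_prefs, params, seed = NULL,
                               kernel = NULL) {
  stopifnot(inherits(params, "assembly_params"))
  microbe_prefs <- as.matrix(microbe_prefs)
  m <- nrow(microbe_prefs)
  if (!is.null(seed)) set.seed(seed)
  efit <- environmental_fitness(host_trait, microbe_prefs, params$niche_breadth)
  if (params$beta_comp > 0 && is.null(kernel)) {
    kernel <- niche_kernel(microbe_prefs, params$niche_breadth)
  }
  abund <- integer(m)
  for (step in seq_len(params$years)) {
    cpen <- if (params$beta_comp > 0) {
      competition_penalty(abund, microbe_prefs, params$niche_breadth, kernel)
    } else {
      rep(1, m)
    }
    p <- recruitment_probabilities(efit, abund, cpen, params)
    abund <- drop(stats::rmultinom(1L, params$capacity, p))
  }
  names(abund) <- rownames(microbe_prefs)
  abund
}

#' Assemble one community per host
#'
#' Runs [assemble_community()] independently for every host, with per-host
#' seeds derived from the master seed so hosts can be reproduced in
#' isolation.
#'
#' @param host_traits Hosts x traits matrix (rownames are host labels).
#' @param microbe_prefs Microbes x traits preference matrix.
#' @param params An [assembly_params()] object.
#' @param seed Optional master integer seed.
#' @return Hosts x microbes integer matrix; every row sums to
#'   `params$capacity`.
#' @export
assemble_system <- function(host_traits, microbe_prefs, params, seed = NULL) {
  stopifnot(inherits(params, "assembly_params"))
  host_traits <- as.matrix(host_traits)
  microbe_prefs <- as.matrix(microbe_prefs)
  n <- nrow(host_traits)
  if (!is.null(seed)) set.seed(seed)
  host_seeds <- sample.int(.Machine$integer.max, n)
  kernel <- if (params$beta_comp > 0) {
    niche_kernel(microbe_prefs, params$niche_breadth)
  } else {
    NULL
  }
  tab <- t(vapply(
    seq_len(n),
    function(i) {
      assemble_community(host_traits[i, ], microbe_prefs, params,
                         seed = host_seeds[i], kernel = kernel)
    },
    integer(nrow(microbe_prefs))
  ))
  rownames(tab) <- rownames(host_traits)
  colnames(tab) <- rownames(microbe_prefs)
  tab
}
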