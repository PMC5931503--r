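#' Specify a Bayesian isotopic mixing model run
#'
#' Bundles the data and MCMC settings for a mixing-model fit.  Each
#' consumer observation (nest-year) is fitted independently; the defaults
#' mirror the field-standard setup of four Markov chains of 10000 steps
#' with a 1000-step burn-in.
#'
#' @param sources a [source_spec()] table with `K >= 2` rows.
#' @param tef a [tef_spec()].
#' @param consumers data frame from [average_siblings()] (columns
#'   `territory_id`, `year`, `mean_delta13C`, `mean_delta15N`).
#' @param n_chains number of Markov chains (default 4).
#' @param n_iter steps per chain, including burn-in (default 10000).
#' @param n_burnin burn-in steps discarded per chain (default 1000).
#' @param seed master seed; per-(consumer, chain) substreams are derived
#'   deterministically from it.
#' @param rhat_threshold convergence flag threshold (default 1.1).
#' @param residual_sd `NULL` (default) to estimate the per-isotope
#'   residual SD under a half-Cauchy(0, 1) prior, or a length-2 positive
#'   numeric to fix it (e.g. for noiseless oracle checks or prior-only
#'   runs with a huge value).
#' @return list of class `mixing_model_spec`.
#' @export
mixing_model_spec <- function(sources, tef, consumers,
                              n_chains = 4L, n_iter = 10000L,
                              n_burnin = 1000L, seed = 1L,
                              rhat_threshold = 1.1, residual_sd = NULL) {
  if (!inherits(sources, "source_spec")) stop_input("sources must be a source_spec table")
  if (!inherits(tef, "tef_spec")) stop_input("tef must be a tef_spec")
  if (nrow(sources) < 2) stop_input("need at least two sources (K >= 2)")
  check_columns(consumers,
                c("territory_id", "year", "mean_delta13C", "mean_delta15N"),
                "consumer observations")
  if (nrow(consumers) < 1) stop_input("need at least one consumer observation")
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  n_burnin <- as.integer(n_burnin)
  if (n_chains < 1 || n_iter <= n_burnin || n_burnin < 0)
    stop_input("require n_chains >= 1 and n_iter > n_burnin >= 0")
  if (!is.null(residual_sd)) {
    if (length(residual_sd) != 2 || any(residual_sd <= 0))
      stop_input("fixed residual_sd must be two positive values")
  }
  structure(list(sources = sources, tef = tef, consumers = consumers,
                 n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 seed = as.integer(seed), rhat_threshold = rhat_threshold,
                 residual_sd = residual_sd),
            class = "mixing_model_spec")
}

#' Mixing-model joint log posterior (reference implementation)
#'
#' Pure-R reference for the density the sampler targets; the compiled
#' sampler core is cross-checked against it in the test suite.
#' Proportions are `p = softmax(f)` with independent standard-normal
#' priors on `f`; residual SDs get half-Cauchy(0, 1) priors (sampled on
#' the log scale, Jacobian included).  For isotope `j` the observation
#' likelihood is
#' \deqn{x_j \sim N\!\Big(\sum_k p_k(\mu_{kj} + \mu_{TEF,j}),\;
#'   \sum_k p_k^2(\sigma_{kj}^2 + \sigma_{TEF,j}^2) + \sigma_j^2\Big).}
#'
#' @param f numeric vector of K unconstrained reals.
#' @param log_sigma numeric length-2 vector, log residual SD per isotope.
#' @param x numeric length-2 consumer observation (delta13C, delta15N).
#' @param sources a [source_spec()] table.
#' @param tef a [tef_spec()].
#' @return scalar log posterior density (finite for finite inputs).
#' @export
mixing_log_posterior <- function(f, log_sigma, x, sources, tef) {
  stopifnot(length(f) == nrow(sources), length(log_sigma) == 2, length(x) == 2)
  p <- softmax(f)
  mu <- cbind(sources$mu13C + tef$mu13C, sources$mu15N + tef$mu15N)
  sd2 <- cbind(sources$sd13C^2 + tef$sd13C^2, sources$sd15N^2 + tef$sd15N^2)
  sigma <- exp(log_sigma)
  lp <- sum(stats::dnorm(f, 0, 1, log = TRUE))
  lp <- lp + sum(log(2 / pi) - log1p(sigma^2) + log_sigma)
  for (j in 1:2) {
    m <- sum(p * mu[, j])
    v <- sum(p^2 * sd2[, j]) + sigma[j]^2
    lp <- lp + stats::dnorm(x[j], m, sqrt(v), log = TRUE)
  }
  lp
}

#' Draw from the diet posterior for every consumer observation
#'
#' Runs the adaptive random-walk Metropolis sampler (compiled core) for
#' each consumer observation and chain.  Chains are initialised
#' overdispersed (f from N(0,1)), adapt their step size towards an
#' acceptance rate of ~0.3 during burn-in, and are frozen thereafter.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [mixing_model_spec()].
#' @return object of class `diet_posterior`: a list with `draws` (list,
#'   one `chains x iterations x K` array per consumer), `sigma` (list of
#'   `chains x iterations x 2` arrays), `consumers`, `source_names`,
#'   `accept_rates` and the spec settings.
#' @export
sample_posterior <- function(spec) {
  stopifnot(inherits(spec, "mixing_model_spec"))
  K <- nrow(spec$sources)
  mu <- cbind(spec$sources$mu13C, spec$sources$mu15N)
  sd2 <- cbind(spec$sources$sd13C^2 + spec$tef$sd13C^2,
               spec$sources$sd15N^2 + spec$tef$sd15N^2)
  tef_mu <- c(spec$tef$mu13C, spec$tef$mu15N)
  n_keep <- spec$n_iter - spec$n_burnin
  n_obs <- nrow(spec$consumers)
  draws <- vector("list", n_obs)
  sig_draws <- vector("list", n_obs)
  acc <- matrix(NA_real_, n_obs, spec$n_chains)
  for (i in seq_len(n_obs)) {
    x <- c(spec$consumers$mean_delta13C[i], spec$consumers$mean_delta15N[i])
    arr <- array(NA_real_, c(spec$n_chains, n_keep, K))
    sarr <- array(NA_real_, c(spec$n_chains, n_keep, 2L))
    sigma_fixed <- !is.null(spec$residual_sd)
    for (ch in seq_len(spec$n_chains)) {
      set.seed(derive_seed(spec$seed, i, ch))
      f0 <- rnorm(K)
      ls0 <- if (sigma_fixed) log(spec$residual_sd) else rnorm(2, 0, 0.5)
      res <- .cpp_sample_chain(x, mu, sd2, tef_mu, spec$n_iter,
                               spec$n_burnin, f0, ls0, 0.3, sigma_fixed)
      arr[ch, , ] <- res$p
      sarr[ch, , ] <- res$sigma
      acc[i, ch] <- res$accept_rate
    }
    draws[[i]] <- arr
    sig_draws[[i]] <- sarr
  }
  structure(list(draws = draws, sigma = sig_draws,
                 consumers = spec$consumers,
                 source_names = spec$sources$name,
                 accept_rates = acc,
                 n_chains = spec$n_chains, n_iter = spec$n_iter,
                 n_burnin = spec$n_burnin, seed = spec$seed,
                 rhat_threshold = spec$rhat_threshold),
            class = "diet_posterior")
}

#' @rdname sample_posterior
#' @export
fit_mixing_model <- sample_posterior

#' @export
print.diet_posterior <- function(x, ...) {
  cat(sprintf("Diet posterior: %d consumer(s), %d source(s), %d chain(s) x %d kept draws\n",
              length(x$draws), length(x$source_names), x$n_chains,
              x$n_iter - x$n_burnin))
  invisible(x)
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor R-hat computed on split chains (each
#' chain halved, doubling the chain count), the standard guard against
#' within-chain trends.  Values near 1 indicate convergence; the
#' conventional flag threshold is 1.1.  Constant identical chains return
#' 1 by convention.
#'
#' @param draws matrix of posterior draws, iterations x chains
#'   (`>= 2` chains, `>= 10` iterations).
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop_input("gelman_rubin needs at least 2 chains")
  if (nrow(draws) < 10) stop_input("gelman_rubin needs at least 10 draws per chain")
  n2 <- floor(nrow(draws) / 2)
  split <- cbind(draws[seq_len(n2), , drop = FALSE],
                 draws[seq.int(nrow(draws) - n2 + 1, nrow(draws)), , drop = FALSE])
  m <- ncol(split); n <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# Effective sample size across chains (Geyer initial monotone sequence on
# the chain-averaged autocorrelation, as in standard MCMC practice).
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  W <- mean(apply(draws, 2, var))
  if (W == 0) return(m * n)
  B <- if (m > 1) n * var(colMeans(draws)) else 0
  var_plus <- (n - 1) / n * W + B / n
  # chain-averaged autocovariances
  max_lag <- min(n - 1, 1000L)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(draws[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho <- rho[-1] # drop lag 0
  # Geyer: sum consecutive pairs while positive and monotone
  tau <- 1
  prev <- Inf
  for (t in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
  }
  max(m * n / tau, 1)
}

#' Summarize a diet posterior
#'
#' Per consumer and source: posterior mean, SD, median, central 50% and
#' 95% credible intervals, split R-hat and effective sample size.  A
#' `converged` flag compares the largest R-hat per consumer against the
#' spec threshold (default 1.1); non-convergence is reported, never
#' fatal.
#'
#' @param post a `diet_posterior` from [sample_posterior()].
#' @return data frame of class `fit_summary`, one row per
#'   consumer x source, with columns `territory_id`, `year`, `source`,
#'   `mean`, `sd`, `q2.5`, `q25`, `q50`, `q75`, `q97.5`, `rhat`, `ess`,
#'   `converged`.
#' @export
summarize_posterior <- function(post) {
  stopifnot(inherits(post, "diet_posterior"))
  if (length(post$draws) == 0) stop_input("empty posterior")
  K <- length(post$source_names)
  rows <- vector("list", length(post$draws) * K)
  idx <- 1
  for (i in seq_along(post$draws)) {
    arr <- post$draws[[i]] # chains x iters x K
    rhats <- numeric(K)
    for (k in seq_len(K)) {
      mat <- t(arr[, , k, drop = FALSE][, , 1]) # iters x chains
      v <- as.vector(arr[, , k])
      q <- quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
      rhats[k] <- if (post$n_chains >= 2) gelman_rubin(mat) else NA_real_
      rows[[idx]] <- data.frame(
        territory_id = as.character(post$consumers$territory_id[i]),
        year = post$consumers$year[i],
        source = post$source_names[k],
        mean = mean(v), sd = sd(v),
        q2.5 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q97.5 = q[5],
        rhat = rhats[k], ess = ess_basic(mat),
        stringsAsFactors = FALSE)
      idx <- idx + 1
    }
    conv <- all(is.na(rhats)) || max(rhats, na.rm = TRUE) <= post$rhat_threshold
    for (k in seq_len(K)) rows[[idx - K - 1 + k]]$converged <- conv
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fit_summary", "data.frame")
  out
}

#' Population-level diet summary from a mixing-model fit
#'
#' Arithmetic mean and SD, across nest-year observations, of the
#' per-observation posterior mean contribution of each source, reported
#' as percentages.  This is the standard population diet composition
#' summary (mean percent, with the SD measuring between-nest spread).
#'
#' @param summary a `fit_summary` from [summarize_posterior()].
#' @return data frame with columns `source`, `mean_pct`, `sd_pct`.
#' @export
population_diet_summary <- function(summary) {
  check_columns(summary, c("source", "mean"), "fit summary")
  sources <- unique(summary$source)
  rows <- lapply(sources, function(s) {
    v <- summary$mean[summary$source == s]
    data.frame(source = s, mean_pct = 100 * mean(v),
               sd_pct = if (length(v) > 1) 100 * sd(v) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
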