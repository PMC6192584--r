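#' Log unnormalized posterior of a mixing problem
#'
#' Reference (pure R) evaluation of the model the sampler targets:
#' log Dirichlet(p | alpha) plus, for every consumer i and isotope j,
#' log Normal(X_ij | m_ij, s_ij^2) with
#' m_ij = sum_k w_k (mu_jk + Delta_jk) and
#' s_ij^2 = sum_k w_k^2 (omega_jk^2 + tau_jk^2), where w_k = p_k or the
#' concentration-weighted p_k q_jk / sum_k p_k q_jk. Used by the grid
#' oracle and by tests cross-checking the MCMC sampler.
#'
#' @param p Diet-proportion vector on the K-simplex.
#' @param problem A [mixing_problem()].
#' @param simplex_tol Tolerance for `sum(p) == 1`.
#' @return A single log-density value (unnormalized in the evidence only).
#' @export
log_unnormalized_posterior <- function(p, problem, simplex_tol = 1e-8) {
  stopifnot(inherits(problem, "mixing_problem"))
  K <- nrow(problem$sources)
  if (length(p) != K || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > simplex_tol) {
    stop_input("`p` must be a length-K vector on the simplex (sum 1, all >= 0).")
  }
  p <- p / sum(p)
  alpha <- problem$prior
  lp <- lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum(ifelse(alpha == 1, 0, (alpha - 1) * log(p)))
  for (i in seq_len(nrow(problem$consumers))) {
    cons <- problem$consumers[i, ]
    mats <- problem_matrices(problem, cons$guild)
    x <- c(cons$d13c, cons$d15n)
    for (j in 1:2) {
      w <- mix_weights(p, mats$q[j, ], problem$concentration_dependent)
      m <- sum(w * mats$a[j, ])
      s2 <- sum(w^2 * mats$v[j, ])
      if (s2 <= 0) {
        stop_input(
          "Degenerate model: total mixture variance is zero for an isotope.",
          class = "ventmix_degenerate_error"
        )
      }
      lp <- lp + dnorm(x[j], m, sqrt(s2), log = TRUE)
    }
  }
  lp
}

mix_weights <- function(p, q, conc_dep) {
  if (!conc_dep) return(p)
  p * q / sum(p * q)
}

#' Fit the Bayesian mixing model by MCMC
#'
#' Samples diet proportions with an adaptive random-walk Metropolis sampler
#' on the isometric log-ratio transform of the simplex (Jacobian-corrected),
#' running several independent chains. By default each consumer is fitted
#' individually; `per_individual = FALSE` pools all consumers under a single
#' proportion vector (they must then share one guild).
#'
#' `iterations` is the total across chains; `burn_in` and `thin` apply per
#' chain. Identical seed and inputs give identical draws. Convergence is
#' checked with the split-chain R-hat statistic; values above 1.05 raise a
#' warning and are recorded in the result, never silently dropped.
#'
#' @param problem A [mixing_problem()].
#' @param iterations Total MCMC iterations across all chains (default
#'   500,000).
#' @param burn_in Burn-in iterations per chain (default 50,000), during
#'   which the proposal scale adapts.
#' @param thin Keep every `thin`-th post-burn-in draw per chain.
#' @param chains Number of independent chains.
#' @param seed Integer seed; per-chain streams are derived from it.
#' @param per_individual Fit each consumer separately (default) or pool.
#' @return A `mixing_fit` object; see [tidy.mixing_fit()],
#'   [glance.mixing_fit()], [autoplot.mixing_fit()].
#' @examples
#' pr <- kst_preset()$ep_crustacean_venting
#' fit <- fit_mixing(pr, iterations = 20000, burn_in = 2000, thin = 5,
#'                   seed = 1)
#' tidy(fit)
#' @export
fit_mixing <- function(problem, iterations = 500000, burn_in = 50000,
                       thin = 15, chains = 4, seed = 1L,
                       per_individual = TRUE) {
  stopifnot(inherits(problem, "mixing_problem"))
  n_iter <- as.integer(iterations %/% chains)
  if (n_iter <= burn_in) {
    stop_input("`iterations`/`chains` must exceed `burn_in` (per chain).")
  }
  seed <- as.integer(seed)

  src_names <- problem$sources$name
  K <- length(src_names)
  V <- ilr_basis(K)

  groups <- if (per_individual) {
    lapply(seq_len(nrow(problem$consumers)), function(i) problem$consumers[i, ])
  } else {
    if (length(unique(problem$consumers$guild)) > 1 &&
        is.null(problem$source_guilds)) {
      stop_input("Pooled fitting requires all consumers to share one guild.")
    }
    list(problem$consumers)
  }

  draws_list <- list()
  diag_list <- list()
  acc_list <- list()
  oop_list <- list()
  warn_msgs <- character()

  for (g in seq_along(groups)) {
    cons <- groups[[g]]
    gid <- if (per_individual) as.character(cons$id) else "pooled"
    mats <- problem_matrices(problem, cons$guild[1])
    x <- cbind(cons$d13c, cons$d15n) # n_obs x J
    if (any(rowSums(mats$v) == 0)) {
      stop_input(
        "Degenerate model: all sources have zero total variance for an isotope.",
        class = "ventmix_degenerate_error"
      )
    }

    chain_draws <- vector("list", chains)
    acc <- numeric(chains)
    for (ch in seq_len(chains)) {
      set.seed(chain_seed(seed, g, ch))
      res <- mix_mcmc_cpp(
        x, mats$a, mats$v, mats$q, problem$prior, V,
        n_iter, as.integer(burn_in), as.integer(thin),
        problem$concentration_dependent, 0.5
      )
      chain_draws[[ch]] <- res$draws
      acc[ch] <- res$acceptance_rate
    }

    n_keep <- nrow(chain_draws[[1]])
    rhat <- vapply(seq_len(K), function(k) {
      split_rhat(vapply(chain_draws, function(d) d[, k], numeric(n_keep)))
    }, numeric(1))
    bad <- is.finite(rhat) & rhat > 1.05
    if (any(bad)) {
      msg <- paste0(
        "Chains for consumer \"", gid, "\" may not have converged: ",
        "split R-hat ", paste0(sprintf("%.3f", rhat[bad]), collapse = ", "),
        " for source(s) ", paste(src_names[bad], collapse = ", "), "."
      )
      warn_msgs <- c(warn_msgs, msg)
      warn(msg, class = "ventmix_convergence_warning")
    }

    all_draws <- do.call(rbind, chain_draws)
    draws_list[[g]] <- tibble(
      id = gid,
      .chain = rep(seq_len(chains), each = n_keep),
      .draw = rep(seq_len(n_keep), chains)
    ) |>
      dplyr::bind_cols(as_tibble(`colnames<-`(all_draws, src_names))) |>
      tidyr::pivot_longer(dplyr::all_of(src_names),
                          names_to = "source", values_to = "proportion")

    diag_list[[g]] <- tibble(id = gid, source = src_names, rhat = rhat)
    acc_list[[g]] <- tibble(id = gid, chain = seq_len(chains),
                            acceptance_rate = acc)
    # mixing-polygon check: TDF-corrected sources must bracket the consumer
    # per isotope (bounding-box test; a 2-source hull is a degenerate segment)
    oop <- any(vapply(1:2, function(j) {
      xs <- x[, j]
      any(xs < min(mats$a[j, ]) - 1e-12 | xs > max(mats$a[j, ]) + 1e-12)
    }, logical(1)))
    oop_list[[g]] <- tibble(id = gid, out_of_polygon = oop)
  }

  structure(
    list(
      draws = dplyr::bind_rows(draws_list),
      diagnostics = dplyr::bind_rows(diag_list),
      acceptance = dplyr::bind_rows(acc_list),
      out_of_polygon = dplyr::bind_rows(oop_list),
      convergence_warnings = warn_msgs,
      problem = problem,
      iterations = iterations, burn_in = burn_in, thin = thin,
      chains = chains, seed = seed, per_individual = per_individual
    ),
    class = "mixing_fit"
  )
}

chain_seed <- function(seed, group, chain) {
  as.integer((abs(as.double(seed)) * 7919 + group * 104729 + chain * 1299709) %%
               2147483647)
}

# Orthonormal basis of the simplex's log-ratio subspace (columns orthogonal
# to 1), via normalized Helmert contrasts.
ilr_basis <- function(K) {
  H <- stats::contr.helmert(K)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

# Split-chain R-hat (Gelman-Rubin with halved chains) on an iter x chain
# matrix of draws.
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- n %/% 2
  if (half < 2) return(NA_real_)
  chains <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Exhaustive simplex-grid posterior oracle
#'
#' Enumerates the lattice of proportion vectors with step `resolution` on
#' the K-simplex, weights each node by the exponentiated
#' [log_unnormalized_posterior()], and returns the normalized posterior
#' expectation of each source's proportion. Deterministic, so it serves as
#' an independent check on the MCMC sampler; feasible for K <= 4.
#'
#' @inheritParams fit_mixing
#' @param resolution Simplex lattice step (must divide 1; <= 0.02 not
#'   required but K^lattice size must stay enumerable).
#' @param per_individual Fit each consumer separately (default) or pool.
#' @return A tibble with columns `id`, `source`, `mean`.
#' @export
grid_posterior_mean <- function(problem, resolution = 0.01,
                                per_individual = TRUE) {
  stopifnot(inherits(problem, "mixing_problem"))
  K <- nrow(problem$sources)
  if (K > 4) {
    stop_input("Grid enumeration supports K <= 4 sources.",
               class = "ventmix_capability_error")
  }
  N <- round(1 / resolution)
  P <- simplex_lattice(K, N)

  groups <- if (per_individual) {
    lapply(seq_len(nrow(problem$consumers)), function(i) problem$consumers[i, ])
  } else {
    list(problem$consumers)
  }

  out <- purrr::map_dfr(seq_along(groups), function(g) {
    cons <- groups[[g]]
    gid <- if (per_individual) as.character(cons$id) else "pooled"
    sub <- problem
    sub$consumers <- cons
    ll <- grid_log_posterior(P, sub)
    w <- exp(ll - max(ll))
    w <- w / sum(w)
    tibble(
      id = gid,
      source = problem$sources$name,
      mean = as.numeric(crossprod(P, w))
    )
  })
  out
}

# vectorized log posterior over the rows of a lattice matrix P (nodes x K)
grid_log_posterior <- function(P, problem) {
  alpha <- problem$prior
  ll <- numeric(nrow(P))
  for (k in seq_along(alpha)) {
    # flat components contribute 0 even at the lattice boundary (0 * log 0)
    if (alpha[k] != 1) ll <- ll + (alpha[k] - 1) * log(P[, k])
  }
  for (i in seq_len(nrow(problem$consumers))) {
    cons <- problem$consumers[i, ]
    mats <- problem_matrices(problem, cons$guild)
    x <- c(cons$d13c, cons$d15n)
    for (j in 1:2) {
      if (problem$concentration_dependent) {
        W <- sweep(P, 2, mats$q[j, ], "*")
        W <- W / rowSums(W)
      } else {
        W <- P
      }
      m <- as.numeric(W %*% mats$a[j, ])
      s2 <- as.numeric(W^2 %*% mats$v[j, ])
      ll <- ll + dnorm(x[j], m, sqrt(s2), log = TRUE)
    }
  }
  ll
}

# all length-K compositions of N, as proportions (rows sum to 1)
simplex_lattice <- function(K, N) {
  if (K == 1) return(matrix(1, 1, 1))
  counts <- utils::combn(N + K - 1, K - 1)
  # stars and bars: positions of K-1 bars among N + K - 1 slots
  lower <- rbind(0, counts)
  upper <- rbind(counts, N + K)
  P <- t(upper - lower - 1)
  stopifnot(all(rowSums(P) == N))
  P / N
}

#' Deterministic two-source single-isotope mixing fraction
#'
#' The closed-form mass balance for one isotope and two sources:
#' \eqn{f_1 = (X - \Delta - \mu_2) / (\mu_1 - \mu_2)}. The result is not
#' clipped to \[0, 1\]; values outside it flag a consumer lying outside the
#' two-source mixing interval.
#'
#' @param consumer One-row data frame with `d13c`, `d15n` (and anything
#'   else), or a named vector/list with those elements.
#' @param sources Two-row source table (see [mixing_problem()]); the
#'   returned fraction is the first row's contribution.
#' @param tdf Two-row TDF tibble from [tdf_for_guild()].
#' @param isotope `"C13"` or `"N15"`.
#' @return The source-1 fraction (numeric scalar, unclipped).
#' @examples
#' f <- analytic_two_source_point(
#'   tibble::tibble(d13c = -21.0, d15n = 6.0),
#'   kst_sources(c("vent_pom", "seawater_pom")),
#'   tdf_for_guild(kst_tdf(), "herbivore"), "C13"
#' )
#' @export
analytic_two_source_point <- function(consumer, sources, tdf, isotope) {
  check_isotope(isotope)
  sources <- check_sources(sources)
  if (nrow(sources) != 2) {
    stop_input("`sources` must contain exactly two sources.")
  }
  x <- if (isotope == "C13") consumer$d13c else consumer$d15n
  delta <- tdf$mean[match(isotope, tdf$isotope)]
  mu <- if (isotope == "C13") sources$d13c_mean else sources$d15n_mean
  if (mu[1] == mu[2]) {
    stop_input(paste0(
      "Source means are equal for ", isotope,
      " (", mu[1], " per mil); the two-source mass balance is undefined."
    ))
  }
  (x - delta - mu[2]) / (mu[1] - mu[2])
}

#' @describeIn fit_mixing Posterior summaries: one row per consumer-source
#'   pair with posterior mean, SD, median and a central credible interval.
#' @param x,object A `mixing_fit`.
#' @param conf.level Width of the central credible interval.
#' @param ... Unused.
#' @method tidy mixing_fit
#' @export
tidy.mixing_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  x$draws |>
    dplyr::group_by(.data$id, .data$source) |>
    dplyr::summarise(
      mean = mean(.data$proportion),
      sd = stats::sd(.data$proportion),
      median = stats::median(.data$proportion),
      conf.low = stats::quantile(.data$proportion, a, names = FALSE),
      conf.high = stats::quantile(.data$proportion, 1 - a, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(source = factor(.data$source,
                                  levels = x$problem$sources$name)) |>
    dplyr::arrange(.data$id, .data$source) |>
    dplyr::mutate(source = as.character(.data$source))
}

#' @describeIn fit_mixing One-row fit overview: sizes, seed, worst R-hat,
#'   acceptance-rate range, out-of-polygon count.
#' @method glance mixing_fit
#' @export
glance.mixing_fit <- function(x, ...) {
  tibble(
    n_consumers = dplyr::n_distinct(x$draws$id),
    n_sources = nrow(x$problem$sources),
    iterations = x$iterations, chains = x$chains,
    burn_in = x$burn_in, thin = x$thin, seed = x$seed,
    n_draws = nrow(x$draws) / nrow(x$problem$sources),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_acceptance = min(x$acceptance$acceptance_rate),
    max_acceptance = max(x$acceptance$acceptance_rate),
    n_out_of_polygon = sum(x$out_of_polygon$out_of_polygon),
    converged = length(x$convergence_warnings) == 0
  )
}

#' @export
print.mixing_fit <- function(x, ...) {
  g <- glance(x)
  cat("<mixing_fit> ", g$n_consumers, " consumer(s) x ", g$n_sources,
      " sources; ", g$iterations, " iterations (", g$chains, " chains), seed ",
      g$seed, "\n", sep = "")
  cat("max split R-hat ", sprintf("%.3f", g$max_rhat),
      "; acceptance ", sprintf("%.2f-%.2f", g$min_acceptance,
                               g$max_acceptance), "\n", sep = "")
  if (g$n_out_of_polygon > 0) {
    cat(g$n_out_of_polygon, "consumer(s) outside the mixing polygon\n")
  }
  print(tidy(x), n = 20)
  invisible(x)
}
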