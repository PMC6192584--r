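#' Assemble a Bayesian mixing problem
#'
#' Bundles consumers, candidate food sources, a TDF registry and a Dirichlet
#' prior into the unit of inference for the diet-proportion model. Tissue
#' values of a consumer are modelled as a mixture of TDF-shifted source
#' distributions:
#' \deqn{X_{ij} \sim N\left(\sum_k p_k(\mu_{jk} + \Delta_{jk}),\;
#'       \sum_k p_k^2(\omega_{jk}^2 + \tau_{jk}^2)\right)}
#' with \eqn{p} on the simplex and a Dirichlet(\eqn{\alpha}) prior.
#'
#' @param consumers Data frame of consumer observations: columns `id`,
#'   `guild`, `d13c`, `d15n`; optionally `taxon`, `site`, `distance_m`.
#' @param sources Data frame of food sources: columns `name`, `d13c_mean`,
#'   `d13c_sd`, `d15n_mean`, `d15n_sd`; optionally `conc_c`, `conc_n`
#'   (elemental fractions in (0, 1]; equal concentrations assumed when
#'   absent). Single-replicate sources must be given an explicit SD -- an
#'   `NA` SD is rejected here rather than silently treated as zero.
#' @param tdf TDF registry (columns `guild`, `isotope`, `mean`, `sd`);
#'   defaults to the KST guild registry [kst_tdf()].
#' @param prior Dirichlet concentration vector, length K. Default: flat,
#'   `rep(1, K)`.
#' @param concentration_dependent If `TRUE`, mixture weights for isotope j
#'   become \eqn{p_k q_{jk} / \sum_k p_k q_{jk}} using the sources'
#'   elemental concentrations.
#' @param source_guilds Optional named character vector mapping source names
#'   to guilds, for per-source TDFs. Default `NULL`: the consumer's own
#'   guild TDF is applied to every source.
#' @return An object of class `mixing_problem`.
#' @examples
#' kst_preset()$ep_crustacean_venting
#' @export
mixing_problem <- function(consumers, sources, tdf = kst_tdf(), prior = NULL,
                           concentration_dependent = FALSE,
                           source_guilds = NULL) {
  sources <- check_sources(sources)
  consumers <- check_consumers(consumers)
  check_tdf(tdf)

  K <- nrow(sources)
  if (K < 2) {
    stop_input("A mixing problem needs at least K = 2 sources.")
  }
  if (is.null(prior)) prior <- rep(1, K)
  if (length(prior) != K || any(!is.finite(prior)) || any(prior <= 0)) {
    stop_input("`prior` must be a length-K vector of positive Dirichlet concentrations.")
  }
  if (isTRUE(concentration_dependent) &&
      (!all(c("conc_c", "conc_n") %in% names(sources)) ||
       any(is.na(sources$conc_c)) || any(is.na(sources$conc_n)))) {
    stop_input("Concentration-dependent mixing needs `conc_c` and `conc_n` for every source.")
  }
  if (!is.null(source_guilds)) {
    if (is.null(names(source_guilds)) ||
        !setequal(names(source_guilds), sources$name)) {
      stop_input("`source_guilds` must be named by exactly the source names.")
    }
    for (g in unique(source_guilds)) tdf_for_guild(tdf, g)
  }
  # every consumer guild must resolve now, not at fit time
  for (g in unique(consumers$guild)) tdf_for_guild(tdf, g)

  structure(
    list(
      consumers = consumers, sources = sources, tdf = tdf,
      prior = as.numeric(prior),
      concentration_dependent = isTRUE(concentration_dependent),
      source_guilds = source_guilds
    ),
    class = "mixing_problem"
  )
}

#' @export
print.mixing_problem <- function(x, ...) {
  cat("<mixing_problem> ", nrow(x$sources), " sources, ",
      nrow(x$consumers), " consumer(s)",
      if (x$concentration_dependent) ", concentration-dependent" else "",
      "\n", sep = "")
  cat("sources: ", paste(x$sources$name, collapse = ", "), "\n", sep = "")
  cat("prior:   Dirichlet(", paste(format(x$prior), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

check_sources <- function(sources) {
  req <- c("name", "d13c_mean", "d13c_sd", "d15n_mean", "d15n_sd")
  if (!is.data.frame(sources) || !all(req %in% names(sources))) {
    stop_input(paste0(
      "`sources` must be a data frame with columns ",
      paste(req, collapse = ", "), "."
    ))
  }
  if (anyDuplicated(sources$name)) {
    stop_input("Source names must be unique.")
  }
  num <- c("d13c_mean", "d13c_sd", "d15n_mean", "d15n_sd")
  for (col in num) {
    if (any(!is.finite(sources[[col]]))) {
      stop_input(paste0(
        "`sources$", col, "` must be finite for every source; a ",
        "single-replicate source needs an explicitly supplied SD."
      ))
    }
  }
  if (any(sources$d13c_sd < 0) || any(sources$d15n_sd < 0)) {
    stop_input("Source SDs must be >= 0.")
  }
  for (col in intersect(c("conc_c", "conc_n"), names(sources))) {
    bad <- !is.na(sources[[col]]) &
      (sources[[col]] <= 0 | sources[[col]] > 1)
    if (any(bad)) {
      stop_input("Elemental concentrations must lie in (0, 1].")
    }
  }
  as_tibble(sources)
}

check_consumers <- function(consumers) {
  req <- c("id", "guild", "d13c", "d15n")
  if (!is.data.frame(consumers) || !all(req %in% names(consumers))) {
    stop_input(paste0(
      "`consumers` must be a data frame with columns ",
      paste(req, collapse = ", "), "."
    ))
  }
  if (any(!is.finite(consumers$d13c)) || any(!is.finite(consumers$d15n))) {
    stop_input("Consumer d13c and d15n must be finite for mixing.")
  }
  if (anyDuplicated(consumers$id)) {
    stop_input("Consumer ids must be unique.")
  }
  as_tibble(consumers)
}

# J x K matrices for one consumer: TDF-adjusted source means `a`, total
# variances `v` (source + TDF), and concentrations `q`. Row order: C13, N15.
problem_matrices <- function(problem, guild) {
  src <- problem$sources
  K <- nrow(src)
  mu <- rbind(src$d13c_mean, src$d15n_mean)
  om2 <- rbind(src$d13c_sd^2, src$d15n_sd^2)
  if (is.null(problem$source_guilds)) {
    tdf <- tdf_for_guild(problem$tdf, guild)
    delta <- matrix(tdf$mean, nrow = 2, ncol = K)
    tau2 <- matrix(tdf$sd^2, nrow = 2, ncol = K)
  } else {
    per <- lapply(problem$source_guilds[src$name],
                  function(g) tdf_for_guild(problem$tdf, g))
    delta <- vapply(per, function(t) t$mean, numeric(2))
    tau2 <- vapply(per, function(t) t$sd^2, numeric(2))
  }
  q <- matrix(1, nrow = 2, ncol = K)
  if (problem$concentration_dependent) {
    q <- rbind(src$conc_c, src$conc_n)
  }
  list(a = mu + delta, v = om2 + tau2, q = q, mu = mu)
}
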