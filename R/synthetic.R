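#' KST food-source isotope table
#'
#' Measured source pools of the Kueishan Tao (KST) shallow hydrothermal
#' vent system, as mean +/- 1 sigma of d13C and d15N (per mil). The vent
#' fluid POM summary derives from two replicate samplings; seawater POM
#' pools surface and bottom transect samples.
#'
#' @param names Optional character vector selecting (and ordering) sources.
#' @return A source tibble (see [mixing_problem()]).
#' @export
kst_sources <- function(names = NULL) {
  src <- tibble(
    name = c("seawater_pom", "vent_pom", "zooplankton",
             "ep_crustaceans", "green_macroalgae"),
    d13c_mean = c(-23.4, -18.2, -21.0, -19.9, -20.1),
    d13c_sd = c(0.7, 1.1, 0.2, 0.1, 2.2),
    d15n_mean = c(5.0, -1.7, 6.1, 6.0, 4.6),
    d15n_sd = c(1.1, 0.4, 1.0, 0.6, 0.6)
  )
  if (is.null(names)) return(src)
  miss <- setdiff(names, src$name)
  if (length(miss) > 0) {
    stop_input(paste0("Unknown KST source(s): ", paste(miss, collapse = ", ")))
  }
  src[match(names, src$name), ]
}

#' KST mixing-problem catalogue
#'
#' The study system's mixing problems, assembled from the printed source
#' and consumer tables: pelagic/epibenthic primary consumers (zooplankton
#' size classes and pooled epibenthic crustaceans, venting vs non-venting
#' areas) partitioned between seawater POM and vent POM under the herbivore
#' TDF; suspension feeders (sea anemone, coral) partitioned between
#' zooplankton and epibenthic crustaceans under the carnivore TDF; and
#' qualitative crab and sea-snail problems (taxon means, three sources).
#'
#' Zooplankton/epibenthic consumers are the pooled per-row values of the
#' venting-gradient table; higher-order consumers are taxon means.
#'
#' @return A named list of [mixing_problem()] objects.
#' @examples
#' names(kst_preset())
#' @export
kst_preset <- function() {
  pom <- kst_sources(c("seawater_pom", "vent_pom"))
  prey <- kst_sources(c("zooplankton", "ep_crustaceans"))
  crab_src <- kst_sources(c("zooplankton", "ep_crustaceans", "vent_pom"))
  snail_src <- kst_sources(c("green_macroalgae", "ep_crustaceans",
                             "zooplankton"))

  herb <- function(id, taxon, d13c, d15n) {
    tibble(id = id, taxon = taxon, guild = "herbivore",
           d13c = d13c, d15n = d15n)
  }
  carn <- function(id, taxon, d13c, d15n) {
    tibble(id = id, taxon = taxon, guild = "carnivore",
           d13c = d13c, d15n = d15n)
  }

  zoo <- list(
    zooplankton_venting = c(
      ">2000" = -20.7, "1000-2000" = -20.7, "500-1000" = -20.9,
      "363-500" = -21.0, "200-363" = -21.2
    ),
    zooplankton_nonventing = c(
      ">2000" = -21.0, "1000-2000" = -21.2, "500-1000" = -21.1,
      "363-500" = -21.2, "200-363" = -21.3
    )
  )
  zoo_n <- list(
    zooplankton_venting = c(6.9, 6.7, 6.0, 5.5, 5.3),
    zooplankton_nonventing = c(7.5, 6.5, 5.9, 5.1, 5.3)
  )

  out <- list()
  for (area in names(zoo)) {
    cons <- herb(
      id = paste0(area, "_", names(zoo[[area]]), "um"),
      taxon = "zooplankton", d13c = unname(zoo[[area]]), d15n = zoo_n[[area]]
    )
    out[[area]] <- mixing_problem(cons, pom)
  }
  out$ep_crustacean_venting <- mixing_problem(
    herb("ep_crustacean_venting", "ep_crustaceans", -19.8, 6.5), pom
  )
  out$ep_crustacean_nonventing <- mixing_problem(
    herb("ep_crustacean_nonventing", "ep_crustaceans", -20.0, 5.6), pom
  )
  out$anemone <- mixing_problem(
    carn("anemone", "Anthopleura sp.", -19.9, 9.2), prey
  )
  out$coral <- mixing_problem(
    carn("coral", "Tubastraea sp.", -20.3, 8.8), prey
  )
  out$crab_mean <- mixing_problem(
    carn("crab_mean", "Xenograpsus testudinatus", -17.2, 8.2), crab_src
  )
  out$snails <- mixing_problem(
    carn(c("anachis_misera", "ergalatax_contractus"),
         c("Anachis misera", "Ergalatax contractus"),
         c(-18.0, -17.1), c(8.8, 8.7)),
    snail_src
  )
  out
}

#' Define a simulation scenario with known ground truth
#'
#' Fixes true source distributions, true diet proportions, a TDF and a
#' consumer count, so simulated data can be refitted and the inference
#' checked against truth.
#'
#' @param sources Source table (see [mixing_problem()]): the true means and
#'   SDs.
#' @param true_proportions Numeric vector on the K-simplex (shared by all
#'   consumers) or an `n_consumers` x K matrix of per-consumer truths.
#' @param tdf TDF registry; `guild` selects the row set applied.
#' @param guild Guild whose TDF shifts the simulated consumers.
#' @param n_consumers Number of consumers to draw.
#' @param seed Scenario seed. Consumer draws use counter-based substreams,
#'   so increasing `n_consumers` never changes earlier consumers.
#' @return A `simulation_scenario` object.
#' @export
simulation_scenario <- function(sources, true_proportions, tdf = kst_tdf(),
                                guild = "herbivore", n_consumers = 50,
                                seed = 1L) {
  sources <- check_sources(sources)
  check_tdf(tdf)
  tdf_for_guild(tdf, guild)
  K <- nrow(sources)
  P <- true_proportions
  if (is.numeric(P) && is.null(dim(P))) {
    P <- matrix(P, nrow = n_consumers, ncol = K, byrow = TRUE)
  }
  if (!is.matrix(P) || nrow(P) != n_consumers || ncol(P) != K ||
      any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop_input("`true_proportions` must be (a matrix of) simplex vectors of length K.")
  }
  if (n_consumers < 1) stop_input("`n_consumers` must be >= 1.")
  structure(
    list(sources = sources, true_proportions = P, tdf = tdf, guild = guild,
         n_consumers = as.integer(n_consumers), seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' Simulate consumers from a scenario
#'
#' Draws each consumer's tissue values from the mixing model's own
#' likelihood: \eqn{X_{ij} \sim N(\sum_k p_k(\mu_{jk}+\Delta_j),\;
#' \sum_k p_k^2(\omega_{jk}^2+\tau_j^2))}. This tests internal consistency
#' of the inference; it does not emulate per-prey tissue sampling.
#'
#' @param scenario A [simulation_scenario()].
#' @return A consumer tibble (columns `id`, `taxon`, `guild`, `d13c`,
#'   `d15n`) plus the true proportions as `true_<source>` columns.
#' @export
simulate_consumers <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  src <- scenario$sources
  tdf <- tdf_for_guild(scenario$tdf, scenario$guild)
  a <- rbind(src$d13c_mean, src$d15n_mean) + matrix(tdf$mean, 2, nrow(src))
  v <- rbind(src$d13c_sd^2, src$d15n_sd^2) + matrix(tdf$sd^2, 2, nrow(src))

  rows <- purrr::map_dfr(seq_len(scenario$n_consumers), function(i) {
    p <- scenario$true_proportions[i, ]
    m <- as.numeric(a %*% p)
    s <- sqrt(as.numeric(v %*% p^2))
    set.seed(substream_seed(scenario$seed, i))
    x <- rnorm(2, m, s)
    tibble(
      id = sprintf("sim_%04d", i), taxon = "simulated",
      guild = scenario$guild, d13c = x[1], d15n = x[2]
    )
  })
  truth <- as_tibble(`colnames<-`(scenario$true_proportions,
                                  paste0("true_", src$name)))
  dplyr::bind_cols(rows, truth)
}

substream_seed <- function(seed, counter) {
  as.integer((abs(as.double(seed)) * 48271 + counter * 16807) %% 2147483647)
}

#' Parameter-recovery experiment
#'
#' Simulates consumers under a scenario, refits each with the mixing model,
#' and reports how well the posterior recovers the known truth: per-source
#' bias and RMSE of the posterior mean, and coverage of the central 95%
#' credible intervals.
#'
#' @param scenario A [simulation_scenario()].
#' @param iterations,burn_in,thin,chains Sampler settings per consumer fit
#'   (see [fit_mixing()]); defaults are sized for many repeated fits.
#' @param seed Fitting seed (distinct from the scenario's simulation seed).
#' @return A `recovery_report`: list with `per_consumer` (truth vs
#'   posterior summaries, CI coverage indicator) and `summary` (per-source
#'   bias, RMSE, coverage).
#' @examples
#' sc <- simulation_scenario(
#'   kst_sources(c("seawater_pom", "vent_pom")), c(0.7, 0.3),
#'   n_consumers = 5, seed = 42
#' )
#' rep <- recovery_experiment(sc, iterations = 8000, burn_in = 1000,
#'                            thin = 5, chains = 2, seed = 1)
#' rep$summary
#' @export
recovery_experiment <- function(scenario, iterations = 20000,
                                burn_in = 2000, thin = 5, chains = 2,
                                seed = 1L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  cons <- simulate_consumers(scenario)
  src_names <- scenario$sources$name
  truth <- cons |>
    dplyr::select("id", dplyr::starts_with("true_")) |>
    tidyr::pivot_longer(-"id", names_to = "source", values_to = "true",
                        names_prefix = "true_")
  problem <- mixing_problem(
    dplyr::select(cons, -dplyr::starts_with("true_")),
    scenario$sources, scenario$tdf
  )
  fit <- fit_mixing(problem, iterations = iterations, burn_in = burn_in,
                    thin = thin, chains = chains, seed = seed)
  per <- tidy(fit) |>
    dplyr::inner_join(truth, by = c("id", "source")) |>
    dplyr::mutate(
      error = .data$mean - .data$true,
      covered = .data$true >= .data$conf.low & .data$true <= .data$conf.high
    )
  summary <- per |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(
      bias = mean(.data$error),
      rmse = sqrt(mean(.data$error^2)),
      coverage = mean(.data$covered),
      .groups = "drop"
    )
  structure(
    list(per_consumer = per, summary = summary, fit_glance = glance(fit),
         scenario = scenario),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$scenario$n_consumers, " simulated consumer(s), ",
      nrow(x$scenario$sources), " sources\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @describeIn recovery_experiment Per-source recovery summary as a tibble.
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$summary
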