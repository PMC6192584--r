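#' Read and write the package's CSV schemas
#'
#' Plain-text interchange for the tabular inputs. `sources.csv` is long
#' (one row per source-isotope): `name, isotope, mean, sd, n, concentration`
#' (the last two optional); it is widened into the source-table layout used
#' by [mixing_problem()]. `consumers.csv`: `id, taxon, guild, d13c, d15n,
#' site, distance_m` (last three optional). `tdf.csv`: `guild, isotope,
#' mean, sd`. `aa_replicates.csv`: `organism, amino_acid, d15n`. Writers
#' emit full-precision decimals so a write/read round trip is lossless.
#'
#' @param path File path.
#' @return The validated tibble in the package's working layout.
#' @name ventmix_io
NULL

read_schema <- function(path, required) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      stop_input(paste0("Failed to parse \"", path, "\": ",
                        conditionMessage(e)),
                 class = "ventmix_parse_error")
    }
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_input(paste0(
      "Malformed CSV \"", path, "\": ", probs$expected[1], " expected but got ",
      probs$actual[1], " at line ", probs$row[1], "."
    ), class = "ventmix_parse_error")
  }
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop_input(paste0("\"", path, "\" is missing column(s): ",
                      paste(miss, collapse = ", "), "."),
               class = "ventmix_parse_error")
  }
  df
}

#' @rdname ventmix_io
#' @export
read_sources <- function(path) {
  long <- read_schema(path, c("name", "isotope", "mean", "sd"))
  if (any(!long$isotope %in% ISOTOPES)) {
    stop_input("sources.csv isotope labels must be \"C13\" or \"N15\".",
               class = "ventmix_parse_error")
  }
  vals <- c("mean", "sd")
  if ("concentration" %in% names(long)) vals <- c(vals, "concentration")
  wide <- long |>
    tidyr::pivot_wider(id_cols = "name", names_from = "isotope",
                       values_from = dplyr::all_of(vals))
  out <- tibble(
    name = wide$name,
    d13c_mean = wide$mean_C13, d13c_sd = wide$sd_C13,
    d15n_mean = wide$mean_N15, d15n_sd = wide$sd_N15
  )
  if ("concentration" %in% names(long)) {
    out$conc_c <- wide$concentration_C13
    out$conc_n <- wide$concentration_N15
  }
  check_sources(out)
}

#' @rdname ventmix_io
#' @param sources Source table in the wide working layout.
#' @export
write_sources <- function(sources, path) {
  sources <- check_sources(sources)
  long <- tibble(
    name = rep(sources$name, each = 2),
    isotope = rep(ISOTOPES, nrow(sources)),
    mean = as.numeric(rbind(sources$d13c_mean, sources$d15n_mean)),
    sd = as.numeric(rbind(sources$d13c_sd, sources$d15n_sd))
  )
  if (all(c("conc_c", "conc_n") %in% names(sources))) {
    long$concentration <- as.numeric(rbind(sources$conc_c, sources$conc_n))
  }
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname ventmix_io
#' @export
read_consumers <- function(path) {
  check_consumers(read_schema(path, c("id", "guild", "d13c", "d15n")))
}

#' @rdname ventmix_io
#' @param consumers Consumer table.
#' @export
write_consumers <- function(consumers, path) {
  readr::write_csv(check_consumers(consumers), path)
  invisible(path)
}

#' @rdname ventmix_io
#' @export
read_tdf <- function(path) {
  as_tibble(check_tdf(read_schema(path, c("guild", "isotope", "mean", "sd"))))
}

#' @rdname ventmix_io
#' @param tdf TDF registry table.
#' @export
write_tdf <- function(tdf, path) {
  readr::write_csv(check_tdf(tdf), path)
  invisible(path)
}

#' @rdname ventmix_io
#' @export
read_aa_replicates <- function(path) {
  read_schema(path, c("organism", "amino_acid", "d15n"))
}

#' Configure an end-to-end analysis run
#'
#' Bundles input paths and sampler settings for [run_pipeline()]. All paths
#' must exist at configuration time. The configuration's numeric settings
#' are hashed into `config_hash` (recorded in the run manifest), so two
#' runs share a hash exactly when their settings agree.
#'
#' @param sources,consumers Paths to `sources.csv` / `consumers.csv`.
#' @param tdf Path to `tdf.csv`, or `NULL` to use the KST guild registry.
#' @param aa_replicates Optional path to `aa_replicates.csv`; when given,
#'   the pipeline also writes a trophic-level table.
#' @param beta,delta_diff Trophic-position parameters (see
#'   [trophic_position()]).
#' @param iterations,burn_in,thin,chains,seed Sampler settings (see
#'   [fit_mixing()]).
#' @param per_individual Fit each consumer separately (default) or pooled.
#' @param out_dir Output directory (created if absent).
#' @return A `run_config` object.
#' @export
run_config <- function(sources, consumers, tdf = NULL, aa_replicates = NULL,
                       beta = 3.4, delta_diff = 7.6,
                       iterations = 500000, burn_in = 50000, thin = 15,
                       chains = 4, seed = 1L, per_individual = TRUE,
                       out_dir = "ventmix-results") {
  for (p in c(sources, consumers, tdf, aa_replicates)) {
    if (!file.exists(p)) {
      stop_input(paste0("Input path does not exist: \"", p, "\"."))
    }
  }
  if (iterations / chains <= burn_in) {
    stop_input("`iterations`/`chains` must exceed `burn_in`.")
  }
  settings <- list(
    beta = beta, delta_diff = delta_diff, iterations = iterations,
    burn_in = burn_in, thin = thin, chains = chains, seed = as.integer(seed),
    per_individual = isTRUE(per_individual)
  )
  structure(
    c(list(sources = sources, consumers = consumers, tdf = tdf,
           aa_replicates = aa_replicates, out_dir = out_dir,
           config_hash = settings_hash(settings)),
      settings),
    class = "run_config"
  )
}

# short deterministic hash of the numeric settings (order-stable)
settings_hash <- function(settings) {
  s <- paste(names(settings),
             vapply(settings, function(x) format(x, digits = 17), ""),
             sep = "=", collapse = ";")
  raw <- charToRaw(s)
  h <- c(5381, 52711)
  for (b in as.integer(raw)) {
    h[1] <- (h[1] * 33 + b) %% 2147483629
    h[2] <- (h[2] * 31 + b) %% 2147483587
  }
  sprintf("%08x%08x", as.integer(h[1]), as.integer(h[2]))
}

#' Run the full analysis pipeline
#'
#' Reads the configured CSV inputs, fits the mixing model to every
#' consumer, optionally computes amino-acid trophic positions, and writes
#' the results plus a manifest to the output directory:
#' `mixing_summary.csv` (one row per consumer-source pair: posterior mean,
#' SD, median, 2.5% and 97.5% quantiles), `diagnostics.csv`,
#' `trophic_levels.csv` (when amino-acid replicates are configured) and
#' `manifest.json` (package version, seed, settings, config hash,
#' convergence and mixing-polygon flags). Identical configuration and seed
#' give byte-identical numeric outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the result tibbles and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sources <- read_sources(config$sources)
  consumers <- read_consumers(config$consumers)
  tdf <- if (is.null(config$tdf)) kst_tdf() else read_tdf(config$tdf)

  bad <- setdiff(unique(consumers$guild), unique(tdf$guild))
  if (length(bad) > 0) {
    ids <- consumers$id[consumers$guild %in% bad]
    stop_input(paste0(
      "Unknown guild \"", bad[1], "\" for consumer(s): ",
      paste(ids, collapse = ", "), "."
    ), class = "ventmix_lookup_error")
  }

  problem <- mixing_problem(consumers, sources, tdf)
  fit <- fit_mixing(
    problem, iterations = config$iterations, burn_in = config$burn_in,
    thin = config$thin, chains = config$chains, seed = config$seed,
    per_individual = config$per_individual
  )

  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  summary <- tidy(fit)
  readr::write_csv(summary, file.path(config$out_dir, "mixing_summary.csv"))
  readr::write_csv(fit$diagnostics,
                   file.path(config$out_dir, "diagnostics.csv"))

  tl <- NULL
  if (!is.null(config$aa_replicates)) {
    tl <- trophic_position(read_aa_replicates(config$aa_replicates),
                           beta = config$beta,
                           delta_diff = config$delta_diff)
    readr::write_csv(tl, file.path(config$out_dir, "trophic_levels.csv"))
  }

  manifest <- list(
    package = "ventmix",
    version = as.character(utils::packageVersion("ventmix")),
    config_hash = config$config_hash,
    seed = config$seed,
    iterations = config$iterations, burn_in = config$burn_in,
    thin = config$thin, chains = config$chains,
    per_individual = config$per_individual,
    n_consumers = nrow(consumers), n_sources = nrow(sources),
    max_rhat = max(fit$diagnostics$rhat, na.rm = TRUE),
    convergence_warnings = fit$convergence_warnings,
    out_of_polygon = fit$out_of_polygon$id[fit$out_of_polygon$out_of_polygon]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(mixing_summary = summary, trophic_levels = tl,
                 fit = fit, manifest = manifest))
}
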