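#' Convert isotope-ratio measurements to delta notation
#'
#' Stable isotope compositions are reported in per-mil delta notation
#' relative to an international standard (VPDB for carbon, atmospheric N2
#' for nitrogen):
#' \deqn{\delta X = (R_{sample}/R_{standard} - 1) \times 1000}
#' where \eqn{R} is the heavy/light isotope ratio.
#'
#' @param r_sample Isotope ratio(s) of the sample; non-negative.
#' @param r_standard Isotope ratio of the standard; strictly positive.
#' @return Delta value(s) in per mil (numeric, vectorized over `r_sample`).
#' @seealso [ratio_from_delta()] for the inverse transform.
#' @examples
#' delta_from_ratios(1.01 * 0.0112372, 0.0112372) # +10 per mil
#' @export
delta_from_ratios <- function(r_sample, r_standard) {
  if (!is.numeric(r_sample) || !is.numeric(r_standard)) {
    stop_input("`r_sample` and `r_standard` must be numeric isotope ratios.")
  }
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop_input("`r_standard` must be a positive, finite isotope ratio.")
  }
  if (any(!is.finite(r_sample)) || any(r_sample < 0)) {
    stop_input("`r_sample` must be a non-negative, finite isotope ratio.")
  }
  (r_sample / r_standard - 1) * 1000
}

#' @rdname delta_from_ratios
#' @param delta Delta value(s) in per mil.
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop_input("`r_standard` must be a positive, finite isotope ratio.")
  }
  (delta / 1000 + 1) * r_standard
}

#' Summarize replicate delta measurements
#'
#' Computes the arithmetic mean and sample standard deviation (n - 1
#' denominator) of replicate per-mil measurements, the convention behind
#' "mean +/- 1 sigma" columns in isotope data tables. With a single
#' replicate the SD is undefined and returned as `NA` -- never silently 0 --
#' so that a zero-variance source cannot slip into a mixing model unnoticed.
#'
#' When `data` is a data frame, replicates are summarized per group after
#' `dplyr::group_by()`-style grouping on the columns named in `...`.
#'
#' @param data A numeric vector of replicate values, or a data frame
#'   containing them.
#' @param value For the data-frame method, the column holding replicate
#'   values (tidy-eval).
#' @param ... For the data-frame method, columns to group by (tidy-eval).
#' @return A tibble with columns `mean`, `sd`, `n` (plus grouping columns
#'   for the data-frame method).
#' @examples
#' summarize_replicates(c(-17.4, -19.0)) # -18.2 +/- 1.1
#' @export
summarize_replicates <- function(data, value, ...) {
  if (is.numeric(data)) {
    return(summarize_vec(data))
  }
  if (!is.data.frame(data)) {
    stop_input("`data` must be a numeric vector or a data frame.")
  }
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(summarize_vec({{ value }}), .groups = "drop")
}

summarize_vec <- function(x) {
  if (length(x) == 0 || any(!is.finite(x))) {
    stop_input("Replicate values must be a non-empty vector of finite numbers.")
  }
  n <- length(x)
  tibble(
    mean = mean(x),
    sd = if (n >= 2) stats::sd(x) else NA_real_,
    n = n
  )
}

#' Guild-dependent trophic discrimination factors
#'
#' The per-trophic-step isotopic shift between diet and consumer tissue
#' (TDF) differs between feeding guilds. `kst_tdf()` returns the guild TDF
#' registry used for the Kueishan Tao (KST) shallow-vent analyses:
#' delta13C / delta15N shifts of -0.41 +/- 1.14 and +2.52 +/- 2.50 per mil
#' for herbivores, and +0.91 +/- 1.04 and +3.23 +/- 0.41 per mil for
#' carnivores.
#'
#' @return A tibble with columns `guild`, `isotope` (`"C13"` or `"N15"`),
#'   `mean`, `sd` (per mil).
#' @examples
#' kst_tdf()
#' tdf_for_guild(kst_tdf(), "herbivore")
#' @export
kst_tdf <- function() {
  tibble(
    guild = rep(c("herbivore", "carnivore"), each = 2),
    isotope = rep(ISOTOPES, 2),
    mean = c(-0.41, 2.52, 0.91, 3.23),
    sd = c(1.14, 2.50, 1.04, 0.41)
  )
}

#' Look up the TDF pair for a feeding guild
#'
#' An unregistered guild is an error, never a silent default: picking a TDF
#' is a scientific decision the model must not make on the user's behalf.
#'
#' @param registry A TDF table as returned by [kst_tdf()] (columns `guild`,
#'   `isotope`, `mean`, `sd`).
#' @param guild Guild label to look up.
#' @return A two-row tibble (one row per isotope) with `isotope`, `mean`,
#'   `sd`.
#' @export
tdf_for_guild <- function(registry, guild) {
  check_tdf(registry)
  if (length(guild) != 1 || !is.character(guild)) {
    stop_input("`guild` must be a single guild label.")
  }
  hit <- registry[registry$guild == guild, c("isotope", "mean", "sd")]
  if (nrow(hit) == 0) {
    stop_input(
      paste0(
        "Guild \"", guild, "\" is not registered in the TDF table ",
        "(available: ", paste(unique(registry$guild), collapse = ", "), ")."
      ),
      class = "ventmix_lookup_error"
    )
  }
  if (!setequal(hit$isotope, ISOTOPES)) {
    stop_input(paste0(
      "TDF registry for guild \"", guild,
      "\" must supply both C13 and N15 entries."
    ))
  }
  as_tibble(hit[match(ISOTOPES, hit$isotope), ])
}

check_tdf <- function(registry) {
  if (!is.data.frame(registry) ||
      !all(c("guild", "isotope", "mean", "sd") %in% names(registry))) {
    stop_input(
      "TDF registry must be a data frame with columns guild, isotope, mean, sd."
    )
  }
  if (any(!registry$isotope %in% ISOTOPES)) {
    stop_input("TDF isotope labels must be \"C13\" or \"N15\".")
  }
  if (any(!is.finite(registry$mean)) || any(!is.finite(registry$sd)) ||
      any(registry$sd < 0)) {
    stop_input("TDF means must be finite and SDs finite and >= 0.")
  }
  invisible(registry)
}

check_isotope <- function(isotope) {
  if (length(isotope) != 1 || !isotope %in% ISOTOPES) {
    stop_input("`isotope` must be \"C13\" or \"N15\".")
  }
  isotope
}
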