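#' Invert the mass balance for a pure-diet hypothetical source
#'
#' If a consumer feeds exclusively on one (unmeasured) source, the source's
#' isotope values follow directly from subtracting the TDF from the
#' consumer's tissue values: \eqn{h_j = X_j - \Delta_j}. This is the
#' "trophic position 2" scenario for reconstructing a hypothetical vent POM
#' end member from the most 13C-enriched crab.
#'
#' @param consumer Data frame with columns `d13c`, `d15n` (vectorized over
#'   rows; an `id` column is carried through if present).
#' @param tdf Two-row TDF tibble from [tdf_for_guild()].
#' @return A tibble with inferred `d13c`, `d15n` per consumer row.
#' @examples
#' invert_pure_diet(tibble::tibble(d13c = -13.9, d15n = 1.1),
#'                  tdf_for_guild(kst_tdf(), "herbivore"))
#' @export
invert_pure_diet <- function(consumer, tdf) {
  cons <- check_inversion_consumer(consumer)
  d <- tdf_means(tdf)
  out <- tibble(d13c = as.numeric(cons$d13c - d["C13"]),
               d15n = as.numeric(cons$d15n - d["N15"]))
  if ("id" %in% names(consumer)) out <- dplyr::bind_cols(
    tibble(id = consumer$id), out
  )
  out
}

#' Invert the mass balance for a partially known diet
#'
#' Reconstructs an unmeasured end member that makes up a fraction `f` of a
#' consumer's diet when the remaining diet is known:
#' \deqn{h_j = \frac{X_j - \Delta_j - \sum_d w_d m_{jd}}{f}}
#' with known-diet weights \eqn{w_d \ge 0} summing to \eqn{1 - f}. With
#' `fraction = 1` this reduces to [invert_pure_diet()]. TDF uncertainty is
#' not propagated: this is deliberate point algebra, the "simple mass
#' balance" of end-member reconstruction.
#'
#' @inheritParams invert_pure_diet
#' @param fraction The hypothetical source's diet fraction, in (0, 1].
#' @param known_diet Data frame of the known diet items with columns
#'   `d13c`, `d15n`, `weight` (weights sum to `1 - fraction`); required
#'   whenever `fraction < 1`.
#' @param reference_sources Optional source table (see [mixing_problem()]);
#'   when given, logical flag columns mark an inferred value falling
#'   outside the measured sources' range of means.
#' @return A tibble with `d13c`, `d15n` and, when `reference_sources` is
#'   supplied, `d13c_outside_sources`, `d15n_outside_sources`.
#' @examples
#' invert_mixed_diet(
#'   tibble::tibble(d13c = -13.9, d15n = 1.1),
#'   tdf_for_guild(kst_tdf(), "carnivore"),
#'   fraction = 0.5,
#'   known_diet = tibble::tibble(
#'     d13c = c(-21.0, -19.9), d15n = c(6.1, 6.0), weight = c(0.25, 0.25)
#'   )
#' )
#' @export
invert_mixed_diet <- function(consumer, tdf, fraction, known_diet = NULL,
                              reference_sources = NULL) {
  cons <- check_inversion_consumer(consumer)
  d <- tdf_means(tdf)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop_input("`fraction` must lie in (0, 1]; with fraction = 0 there is nothing to invert.")
  }
  if (fraction < 1) {
    if (is.null(known_diet)) {
      stop_input("`known_diet` is required when `fraction` < 1.")
    }
    if (!is.data.frame(known_diet) ||
        !all(c("d13c", "d15n", "weight") %in% names(known_diet))) {
      stop_input("`known_diet` needs columns d13c, d15n, weight.")
    }
    if (any(known_diet$weight < 0) ||
        abs(sum(known_diet$weight) - (1 - fraction)) > 1e-9) {
      stop_input(paste0(
        "Known-diet weights must be >= 0 and sum to 1 - fraction = ",
        format(1 - fraction), " (got ", format(sum(known_diet$weight)), ")."
      ))
    }
    kc <- sum(known_diet$weight * known_diet$d13c)
    kn <- sum(known_diet$weight * known_diet$d15n)
  } else {
    kc <- 0
    kn <- 0
  }
  out <- tibble(
    d13c = as.numeric(cons$d13c - d["C13"] - kc) / fraction,
    d15n = as.numeric(cons$d15n - d["N15"] - kn) / fraction
  )
  if (!is.null(reference_sources)) {
    src <- check_sources(reference_sources)
    out$d13c_outside_sources <- out$d13c < min(src$d13c_mean) |
      out$d13c > max(src$d13c_mean)
    out$d15n_outside_sources <- out$d15n < min(src$d15n_mean) |
      out$d15n > max(src$d15n_mean)
  }
  out
}

#' Forward two-pool mixing of a consumer from its diet
#'
#' The forward counterpart of the inversions: given the hypothetical end
#' member, its fraction, the known diet and the TDF, returns the consumer
#' tissue values implied by the mass balance. Composing it with
#' [invert_mixed_diet()] reproduces the consumer exactly.
#'
#' @param endmember Data frame/list with `d13c`, `d15n` of the hypothetical
#'   source.
#' @inheritParams invert_mixed_diet
#' @return A tibble with the implied consumer `d13c`, `d15n`.
#' @export
forward_mix <- function(endmember, tdf, fraction, known_diet = NULL) {
  d <- tdf_means(tdf)
  kc <- if (is.null(known_diet)) 0 else sum(known_diet$weight * known_diet$d13c)
  kn <- if (is.null(known_diet)) 0 else sum(known_diet$weight * known_diet$d15n)
  tibble(
    d13c = as.numeric(fraction * endmember$d13c + kc + d["C13"]),
    d15n = as.numeric(fraction * endmember$d15n + kn + d["N15"])
  )
}

check_inversion_consumer <- function(consumer) {
  if (!all(c("d13c", "d15n") %in% names(consumer))) {
    stop_input("`consumer` needs `d13c` and `d15n` values.")
  }
  if (any(!is.finite(consumer$d13c)) || any(!is.finite(consumer$d15n))) {
    stop_input("Consumer d13c and d15n must be finite.")
  }
  consumer
}

tdf_means <- function(tdf) {
  if (!is.data.frame(tdf) || !all(c("isotope", "mean") %in% names(tdf)) ||
      !setequal(tdf$isotope, ISOTOPES)) {
    stop_input("`tdf` must be a two-row tibble from tdf_for_guild().")
  }
  stats::setNames(tdf$mean[match(ISOTOPES, tdf$isotope)], ISOTOPES)
}
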