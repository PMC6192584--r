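#' Trophic position from amino-acid d15N (Glu/Phe)
#'
#' Compound-specific nitrogen isotopes separate trophic enrichment from
#' baseline variation: "trophic" amino acids (glutamic acid) enrich in 15N
#' with each trophic transfer while "source" amino acids (phenylalanine)
#' barely change. The trophic level follows
#' \deqn{TL = \frac{\delta^{15}N_{tro} - \delta^{15}N_{src} - \beta}
#'            {\Delta_{tro} - \Delta_{src}} + 1}
#' where \eqn{\beta} is the producer-level offset between the two amino
#' acids and the denominator is the per-trophic-level enrichment
#' difference. Replicate measurements are averaged at full precision before
#' the formula is applied; the propagated SD is
#' \eqn{\sqrt{sd_{tro}^2/n_{tro} + sd_{src}^2/n_{src}}/|\Delta_{diff}|}.
#'
#' The defaults `beta = 3.4` and `delta_diff = 7.6` per mil are the
#' standard aquatic-food-web calibration for the Glu/Phe pair; both are
#' explicit, overridable parameters, never hidden constants.
#'
#' @param data Data frame of replicate measurements with columns
#'   `organism`, `amino_acid`, `d15n`.
#' @param beta Producer-level offset (per mil) between trophic and source
#'   amino acid.
#' @param delta_diff Per-trophic-level enrichment difference (per mil);
#'   must be nonzero.
#' @param trophic_aa,source_aa Labels of the trophic and source amino acid
#'   in `data` (defaults `"Glu"`, `"Phe"`).
#' @return A tibble with one row per organism: replicate means/SDs/counts
#'   for each amino acid, `tl`, and `tl_sd` (`NA` when either amino acid
#'   has a single replicate).
#' @examples
#' trophic_position(kst_aa_replicates())
#' @export
trophic_position <- function(data, beta = 3.4, delta_diff = 7.6,
                             trophic_aa = "Glu", source_aa = "Phe") {
  if (!is.data.frame(data) ||
      !all(c("organism", "amino_acid", "d15n") %in% names(data))) {
    stop_input("`data` needs columns organism, amino_acid, d15n.")
  }
  if (!is.numeric(delta_diff) || length(delta_diff) != 1 || delta_diff == 0 ||
      !is.finite(delta_diff)) {
    stop_input("`delta_diff` must be a single nonzero enrichment difference.")
  }
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta)) {
    stop_input("`beta` must be a single finite offset in per mil.")
  }

  keep <- data$amino_acid %in% c(trophic_aa, source_aa)
  data <- data[keep, ]
  summ <- data |>
    summarize_replicates(.data$d15n, .data$organism, .data$amino_acid)

  wide <- summ |>
    dplyr::mutate(role = ifelse(.data$amino_acid == trophic_aa,
                                "trophic", "source")) |>
    tidyr::pivot_wider(
      id_cols = "organism", names_from = "role",
      values_from = c("mean", "sd", "n")
    )
  need <- c("mean_trophic", "mean_source")
  if (!all(need %in% names(wide)) ||
      any(is.na(wide$mean_trophic)) || any(is.na(wide$mean_source))) {
    stop_input(paste0(
      "Every organism needs at least one replicate of both \"", trophic_aa,
      "\" and \"", source_aa, "\"."
    ))
  }

  wide |>
    dplyr::mutate(
      tl = (.data$mean_trophic - .data$mean_source - beta) / delta_diff + 1,
      tl_sd = sqrt(.data$sd_trophic^2 / .data$n_trophic +
                     .data$sd_source^2 / .data$n_source) / abs(delta_diff)
    )
}

#' Amino-acid d15N replicates for the two KST vent crabs
#'
#' Triplicate glutamic-acid and phenylalanine d15N measurements for two
#' vent crab (*Xenograpsus testudinatus*) individuals, ready for
#' [trophic_position()].
#'
#' @return A tibble with columns `organism`, `amino_acid`, `d15n`.
#' @export
kst_aa_replicates <- function() {
  tibble(
    organism = rep(c("crab_1", "crab_2"), each = 6),
    amino_acid = rep(rep(c("Glu", "Phe"), each = 3), 2),
    d15n = c(
      14.5, 14.0, 14.0, -1.3, -0.5, -1.0,
      8.6, 8.7, 9.2, -6.1, -5.4, -6.2
    )
  )
}
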