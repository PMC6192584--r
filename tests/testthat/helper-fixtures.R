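# shared fixtures: built in code, no stored data

# half-up rounding to the printed number of decimals (base round() is
# banker's rounding and disagrees on exact .5 cases)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# a TDF registry with no trophic shift and no TDF variance
zero_tdf <- function(guild = "consumer") {
  tibble::tibble(
    guild = guild, isotope = c("C13", "N15"), mean = 0, sd = 0
  )
}

two_sources <- function(mu1 = c(-20, 5), mu2 = c(-10, 15),
                        sd1 = c(1, 1), sd2 = c(1, 1),
                        names = c("s1", "s2")) {
  tibble::tibble(
    name = names,
    d13c_mean = c(mu1[1], mu2[1]), d13c_sd = c(sd1[1], sd2[1]),
    d15n_mean = c(mu1[2], mu2[2]), d15n_sd = c(sd1[2], sd2[2])
  )
}

consumer_at <- function(d13c, d15n, guild = "consumer", id = "c1") {
  tibble::tibble(id = id, taxon = "test", guild = guild,
                 d13c = d13c, d15n = d15n)
}

# consumer exactly midway between two mirrored sources, zero TDF: the
# posterior must be symmetric under source swap
symmetric_problem <- function() {
  mixing_problem(consumer_at(-15, 10), two_sources(), zero_tdf())
}

posterior_mean_of <- function(fit, source, id = NULL) {
  td <- generics::tidy(fit)
  if (!is.null(id)) td <- td[td$id == id, ]
  td$mean[td$source == source]
}
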