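write_kst_inputs <- function(dir) {
  src <- kst_sources(c("seawater_pom", "vent_pom"))
  cons <- dplyr::bind_rows(
    kst_preset()$ep_crustacean_venting$consumers,
    kst_preset()$ep_crustacean_nonventing$consumers
  )
  write_sources(src, file.path(dir, "sources.csv"))
  write_consumers(cons, file.path(dir, "consumers.csv"))
  write_tdf(kst_tdf(), file.path(dir, "tdf.csv"))
  readr::write_csv(kst_aa_replicates(), file.path(dir, "aa.csv"))
  dir
}

test_that("every CSV schema round-trips at full precision", {
  d <- withr::local_tempdir()
  src <- kst_sources()
  src$d13c_mean[1] <- -23.4 + 1e-12 # sub-printing precision must survive
  src$conc_c <- c(0.4, 0.5, 0.45, 0.42, 0.38)
  src$conc_n <- c(0.08, 0.1, 0.09, 0.11, 0.05)
  p <- file.path(d, "sources.csv")
  write_sources(src, p)
  expect_equal(read_sources(p), src)

  cons <- kst_preset()$snails$consumers
  pc <- file.path(d, "consumers.csv")
  write_consumers(cons, pc)
  expect_equal(read_consumers(pc), cons)

  pt <- file.path(d, "tdf.csv")
  write_tdf(kst_tdf(), pt)
  expect_equal(read_tdf(pt), kst_tdf())
})

test_that("readers reject malformed or incomplete tables", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.csv")
  writeLines(c("name,isotope,mean", "a,C13,1"), p)
  expect_error(read_sources(p), class = "ventmix_parse_error")
  writeLines(c("name,isotope,mean,sd", "a,B11,1,1"), p)
  expect_error(read_sources(p), class = "ventmix_parse_error")
  # a source missing one isotope fails validation after widening
  writeLines(c("name,isotope,mean,sd", "a,C13,-20,1", "a,N15,5,1",
               "b,C13,-15,1"), p)
  expect_error(read_sources(p), class = "ventmix_input_error")
})

test_that("the pipeline writes summaries, trophic levels and a manifest", {
  d <- withr::local_tempdir()
  write_kst_inputs(d)
  cfg <- run_config(
    sources = file.path(d, "sources.csv"),
    consumers = file.path(d, "consumers.csv"),
    tdf = file.path(d, "tdf.csv"),
    aa_replicates = file.path(d, "aa.csv"),
    iterations = 20000, burn_in = 2000, thin = 5, chains = 2, seed = 101,
    out_dir = file.path(d, "out")
  )
  res <- run_pipeline(cfg)

  # one row per consumer-source pair
  expect_equal(nrow(res$mixing_summary), 2 * 2)
  expect_setequal(unique(res$mixing_summary$source),
                  c("seawater_pom", "vent_pom"))
  expect_true(file.exists(file.path(d, "out", "mixing_summary.csv")))
  expect_true(file.exists(file.path(d, "out", "trophic_levels.csv")))

  manifest <- jsonlite::read_json(file.path(d, "out", "manifest.json"))
  expect_equal(manifest$seed, 101)
  expect_equal(manifest$config_hash, cfg$config_hash)
  expect_equal(manifest$n_consumers, 2)

  tl <- readr::read_csv(file.path(d, "out", "trophic_levels.csv"),
                        show_col_types = FALSE)
  expect_equal(round_half_up(tl$tl[tl$organism == "crab_1"], 2), 2.54)
})

test_that("identical config and seed reproduce byte-identical outputs", {
  d <- withr::local_tempdir()
  write_kst_inputs(d)
  mk <- function(out) {
    run_config(
      sources = file.path(d, "sources.csv"),
      consumers = file.path(d, "consumers.csv"),
      iterations = 12000, burn_in = 1000, thin = 5, chains = 2, seed = 7,
      out_dir = file.path(d, out)
    )
  }
  run_pipeline(mk("out1"))
  run_pipeline(mk("out2"))
  f1 <- readLines(file.path(d, "out1", "mixing_summary.csv"))
  f2 <- readLines(file.path(d, "out2", "mixing_summary.csv"))
  expect_identical(f1, f2)
})

test_that("the config hash tracks numeric settings and nothing else", {
  d <- withr::local_tempdir()
  write_kst_inputs(d)
  base <- function(...) {
    args <- utils::modifyList(
      list(
        sources = file.path(d, "sources.csv"),
        consumers = file.path(d, "consumers.csv"),
        iterations = 12000, burn_in = 1000, thin = 5, chains = 2, seed = 7,
        out_dir = file.path(d, "o")
      ),
      list(...)
    )
    do.call(run_config, args)
  }
  expect_identical(base()$config_hash, base()$config_hash)
  expect_false(identical(base()$config_hash, base(thin = 6)$config_hash))
  expect_false(identical(base()$config_hash, base(seed = 8)$config_hash))
  expect_false(identical(base()$config_hash, base(beta = 3.5)$config_hash))
})

test_that("an unknown guild fails naming the offending consumer", {
  d <- withr::local_tempdir()
  write_kst_inputs(d)
  cons <- read_consumers(file.path(d, "consumers.csv"))
  cons$guild[2] <- "mystery"
  write_consumers(cons, file.path(d, "consumers.csv"))
  cfg <- run_config(
    sources = file.path(d, "sources.csv"),
    consumers = file.path(d, "consumers.csv"),
    iterations = 12000, burn_in = 1000, thin = 5, chains = 2, seed = 7,
    out_dir = file.path(d, "o")
  )
  err <- expect_error(run_pipeline(cfg), class = "ventmix_lookup_error")
  expect_match(conditionMessage(err), "mystery")
  expect_match(conditionMessage(err), cons$id[2])
})

test_that("configs demand existing inputs and coherent sampler settings", {
  d <- withr::local_tempdir()
  write_kst_inputs(d)
  expect_error(
    run_config(sources = file.path(d, "nope.csv"),
               consumers = file.path(d, "consumers.csv")),
    class = "ventmix_input_error"
  )
  expect_error(
    run_config(sources = file.path(d, "sources.csv"),
               consumers = file.path(d, "consumers.csv"),
               iterations = 1000, burn_in = 5000),
    class = "ventmix_input_error"
  )
})
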