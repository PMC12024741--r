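# generator determinism, truth consistency, fragment-length law

test_that("simulated references hit the target GC and are deterministic", {
  ref <- simulate_reference(10000, 0.5, seed = 3)
  gc <- sum(strsplit(ref[[1]], "")[[1]] %in% c("G", "C")) / 10000
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 10000))
  expect_identical(ref, simulate_reference(10000, 0.5, seed = 3))

  hi <- simulate_reference(10000, 0.99, seed = 3)
  gc_hi <- sum(strsplit(hi[[1]], "")[[1]] %in% c("G", "C")) / 10000
  expect_gt(gc_hi, 0.95)
  expect_error(simulate_reference(10000, 1.2), "gc")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(endogenous_fraction = 1.2), "probabilities")
  expect_error(simulation_config(decay = 0), "decay")
  expect_error(simulation_config(len_min = 10), "len_min")
  expect_error(simulation_config(ref_length = 500, len_max = 600),
               "len_max")
})

test_that("noiseless endogenous-only run emits perfect mapped records", {
  ref <- simulate_reference(20000, 0.42, seed = 4)
  cfg <- simulation_config(seed = 10, ref_length = 20000L, n_reads = 500L,
                           endogenous_fraction = 1, d0_5p = 0, d0_3p = 0,
                           seq_error = 0, len_max = 150L)
  sim <- simulate_reads(cfg, ref)
  expect_true(all(sim$records$is_mapped))
  expect_true(all(sim$records$md == as.character(sim$records$length)))
  expect_true(all(sim$truth$events_5p == 0 & sim$truth$events_3p == 0))
})

test_that("truth rows correspond one-to-one with emitted reads", {
  sm <- small_sim()
  sim <- sm$sim
  expect_identical(sim$truth$read_id, sim$records$read_id)
  expect_identical(sim$truth$true_length, sim$records$length)
  expect_identical(sim$truth$origin == "endogenous", sim$records$is_mapped)
  expect_identical(sim$truth$multi_flag,
                   sim$records$is_mapped & sim$records$mapq == 0L)
})

test_that("MD-derived mismatches equal truth events when seq_error = 0", {
  ref <- simulate_reference(20000, 0.42, seed = 6)
  cfg <- simulation_config(seed = 13, ref_length = 20000L, n_reads = 400L,
                           endogenous_fraction = 0.9, seq_error = 0,
                           d0_5p = 0.2, d0_3p = 0.1, decay = 0.6,
                           len_max = 150L)
  sim <- simulate_reads(cfg, ref, emit_sam = FALSE)
  mapped <- which(sim$records$is_mapped)
  for (i in mapped) {
    pw <- reconstruct_pairwise(sim$records[i, ])
    expect_equal(sum(pw$read != pw$ref),
                 sim$truth$events_5p[i] + sim$truth$events_3p[i])
  }
})

test_that("emitted SAM parses cleanly and deterministically", {
  sm <- small_sim()
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(sm$sim$sam, f)
  expect_no_error(rec <- read_alignments(f))
  expect_equal(nrow(rec), 1500L)
  # same config, same bytes
  cfg <- sm$sim$config
  again <- simulate_reads(cfg, sm$ref)
  expect_identical(again$sam, sm$sim$sam)
})

test_that("fragment lengths match the truncated law's discrete mean", {
  ref <- simulate_reference(20000, 0.42, seed = 9)
  law <- list(law = "lognormal", meanlog = log(50) - 0.25^2 / 2,
              sdlog = 0.25)
  cfg <- simulation_config(seed = 17, ref_length = 20000L,
                           n_reads = 50000L, endogenous_fraction = 0,
                           fragment_law = law, len_min = 25L,
                           len_max = 150L)
  sim <- simulate_reads(cfg, ref, emit_sam = FALSE)
  k <- 25:150
  pk <- plnorm(k + 0.5, law$meanlog, law$sdlog) -
    plnorm(k - 0.5, law$meanlog, law$sdlog)
  mu <- sum(k * pk) / sum(pk)
  sig2 <- sum(k^2 * pk) / sum(pk) - mu^2
  se <- sqrt(sig2 / cfg$n_reads)
  expect_lt(abs(mean(sim$records$length) - mu), 3 * se)
})

test_that("study fixtures are deterministic and ordered as designed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fx1 <- make_study_fixture("tanning_gradient", seed = 5, dir = d1,
                            n_reads = 400L, ref_length = 20000L)
  fx2 <- make_study_fixture("tanning_gradient", seed = 5, dir = d2,
                            n_reads = 400L, ref_length = 20000L)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  # the designed per-level endogenous means decline with tanning depth;
  # realised sample means carry the configured between-sample spread, so
  # only the wide none-vs-deep contrast is forced at n = 5 per level
  p <- fx1$sample_params
  lv <- c("none", "slight", "deep")
  means <- vapply(lv, function(g)
    mean(p$endogenous_fraction[p$group == g]), 0)
  expect_gt(means["none"], means["deep"])
  expect_gt(means["slight"], means["deep"])
  expect_error(make_study_fixture("unknown_scenario"), "arg")
})

test_that("paired fixture produces complete pairs and dispersion contrast", {
  d <- withr::local_tempdir()
  fx <- make_study_fixture("paired_hair_skin", seed = 8, dir = d,
                           n_reads = 300L, ref_length = 20000L)
  p <- fx$sample_params
  expect_equal(sum(p$group == "hair"), 8L)
  expect_equal(sum(p$group == "skin"), 8L)
  expect_setequal(p$pair_id[p$group == "hair"],
                  p$pair_id[p$group == "skin"])
  cfg <- jsonlite::read_json(fx$config_path)
  expect_equal(cfg$schema, "shaftqc-study/1")
  expect_true(all(vapply(cfg$comparisons, function(x) isTRUE(x$paired),
                         TRUE)))
})
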