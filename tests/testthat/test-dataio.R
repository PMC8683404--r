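test_that("constructors validate their invariants", {
  expect_error(spike_train("c", 1, 0, c(1, 0.5)), "strictly increasing")
  expect_error(spike_train("c", 1, 0, c(-1, 0.5)), "negative spike time")
  expect_error(spike_train("c", 1, 0, c(0.5, NaN)), "non-finite")
  expect_error(stimulus_protocol("p", "electrical", c(1, 1.5),
                                 amplitude = 10, phase_duration = 1),
               "1 s apart")
  expect_error(stimulus_protocol("p", "electrical", c(1, 3), amplitude = -2,
                                 phase_duration = 1), "positive")
  expect_error(recording_session("s", list(spike_train("c", 99999L, 0L, 1)),
                                 list()), "not in channel map")
  # reference electrode is represented but carries no units
  cmap <- default_channel_map()
  expect_equal(nrow(cmap), 60L)
  expect_equal(sum(!cmap$is_reference), 59L)
  expect_error(recording_session("s", list(spike_train("c", 15L, 0L, 1)),
                                 list()), "reference channel")
})

make_roundtrip_session <- function(seed, n_cells = 3) {
  with_seed_local <- function(s, f) { set.seed(s); f() }
  with_seed_local(seed, function() {
    trains <- lapply(seq_len(n_cells), function(i)
      spike_train(sprintf("u%02d", i), sample(setdiff(1:60, 15), 1),
                  sample(0:2, 1), sort(runif(sample(1:40, 1), 0, 900))))
    protos <- list(
      stimulus_protocol("light", "light", seq(5, 81, by = 4)),
      stimulus_protocol("e1", "electrical", 90 + 0:9, amplitude = 10,
                        phase_duration = 0.5),
      stimulus_protocol("e2", "electrical", 110 + 0:9, amplitude = 30,
                        phase_duration = 2))
    recording_session(sprintf("rt_%d", seed), trains, protos,
                      group_label = sample(c("normal", "mnu_treated"), 1))
  })
}

expect_session_equal <- function(a, b) {
  expect_equal(a$session_id, b$session_id)
  expect_equal(a$sampling_rate, b$sampling_rate)
  expect_equal(a$group_label, b$group_label)
  expect_setequal(names(a$spike_trains), names(b$spike_trains))
  for (nm in names(a$spike_trains)) {
    expect_equal(a$spike_trains[[nm]]$channel_id, b$spike_trains[[nm]]$channel_id)
    expect_equal(a$spike_trains[[nm]]$unit_index, b$spike_trains[[nm]]$unit_index)
    expect_equal(a$spike_trains[[nm]]$times, b$spike_trains[[nm]]$times,
                 tolerance = 1e-9)
  }
  expect_setequal(names(a$protocols), names(b$protocols))
  for (nm in names(a$protocols)) {
    pa <- a$protocols[[nm]]; pb <- b$protocols[[nm]]
    expect_equal(pa$kind, pb$kind)
    expect_equal(pa$onsets, pb$onsets, tolerance = 1e-9)
    if (pa$kind == "electrical") {
      expect_equal(pa$amplitude, pb$amplitude)
      expect_equal(pa$phase_duration, pb$phase_duration)
    }
  }
}

test_that("csv round-trip preserves sessions and is byte-deterministic", {
  for (seed in 1:5) {
    s <- make_roundtrip_session(seed)
    d <- file.path(tempdir(), sprintf("rt_csv_%d", seed))
    write_session(s, d, "csv_dir")
    expect_session_equal(read_session(d, "csv_dir"), s)
  }
  s <- make_roundtrip_session(9)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_session(s, d1, "csv_dir"); write_session(s, d2, "csv_dir")
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("hdf5 round-trip preserves sessions including empty ones", {
  for (seed in 6:8) {
    s <- make_roundtrip_session(seed)
    f <- file.path(tempdir(), sprintf("rt_%d.h5", seed))
    write_session(s, f, "hdf5")
    expect_session_equal(read_session(f, "hdf5"), s)
  }
  empty <- recording_session("empty", list(), list())
  f <- file.path(tempdir(), "empty.h5")
  write_session(empty, f, "hdf5")
  back <- read_session(f, "hdf5")
  expect_equal(length(back$spike_trains), 0L)
  expect_equal(length(back$protocols), 0L)
  d <- file.path(tempdir(), "empty_csv")
  write_session(empty, d, "csv_dir")
  expect_equal(length(read_session(d, "csv_dir")$spike_trains), 0L)
})

test_that("readers reject malformed inputs with informative errors", {
  s <- make_roundtrip_session(10)
  d <- file.path(tempdir(), "bad_csv")
  write_session(s, d, "csv_dir")
  sp <- utils::read.csv(file.path(d, "spikes.csv"))
  sp$time_s[1] <- -1
  utils::write.csv(sp[order(sp$cell_id, as.numeric(sp$time_s)), ],
                   file.path(d, "spikes.csv"), row.names = FALSE, quote = FALSE)
  expect_error(read_session(d, "csv_dir"), "negative spike time")
  unlink(file.path(d, "protocols.csv"))
  expect_error(read_session(d, "csv_dir"), "protocols.csv")
  expect_error(read_session(file.path(tempdir(), "nope_dir"), "csv_dir"),
               "does not exist")
  # non-finite spike times are refused at write time
  st <- spike_train("c", 1, 0, c(1, 2))
  st$times[2] <- Inf
  bad <- recording_session("s", list(), list())
  bad$spike_trains <- list(c = st)
  expect_error(write_session(bad, file.path(tempdir(), "x.h5"), "hdf5"),
               "non-finite")
})

test_that("unknown optional blocks are ignored with a warning", {
  s <- make_roundtrip_session(11)
  d <- file.path(tempdir(), "extra_csv")
  write_session(s, d, "csv_dir")
  utils::write.csv(data.frame(x = 1), file.path(d, "mystery.csv"),
                   row.names = FALSE)
  expect_warning(back <- read_session(d, "csv_dir"), "mystery")
  expect_session_equal(back, s)
})

test_that("run_pipeline orchestrates deterministically and handles edge cases", {
  patch <- make_patch(patch_spec("normal", n_cells = 4, seed = 5),
                      n_pulses = 8, light_repeats = 5)
  b1 <- suppressWarnings(suppressMessages(run_pipeline(patch$session, seed = 2)))
  b2 <- suppressWarnings(suppressMessages(run_pipeline(patch$session, seed = 2)))
  expect_identical(b1$thresholds, b2$thresholds)
  expect_identical(b1$sd_fits, b2$sd_fits)
  expect_identical(b1$cells, b2$cells)

  # no electrical protocols -> configuration error
  light_only <- recording_session("lo", patch$session$spike_trains,
                                  patch$session$protocols["light"])
  expect_error(run_pipeline(light_only), "no electrical protocols")

  # zero spikes everywhere -> all cells unresponsive, empty threshold table
  silent <- patch$session
  silent$spike_trains <- lapply(silent$spike_trains, function(st)
    spike_train(st$cell_id, st$channel_id, st$unit_index, numeric()))
  bs <- suppressWarnings(run_pipeline(silent))
  expect_true(all(!bs$cells$es_responsive))
  expect_true(all(bs$cells$modulation == "unmodulated"))
  expect_equal(nrow(bs$thresholds), 0L)
  expect_equal(nrow(bs$sd_fits), 0L)
})
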