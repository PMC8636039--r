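test_that("EDF round trip preserves data to quantization, labels, channels", {
  ts <- fix_recordings(sessions = 2, trials = 2)
  f <- tempfile(fileext = ".edf")
  write_edf(subset_trials(ts, ts$session == 1), f, countdown_s = 1, rest_s = 1)
  back <- read_edf(f, montage_labels = ts$channels)
  orig <- subset_trials(ts, ts$session == 1)
  q <- max(abs(orig$data)) / 32767
  expect_lt(max(abs(back$data - orig$data)), 2 * q)
  expect_identical(back$labels, orig$labels)
  expect_identical(back$channels, orig$channels)
  expect_equal(back$fs, ts$fs)
  # annotations carry the class set
  expect_true(all(back$labels %in% me_classes()))
  # missing montage channel is a named error
  expect_error(read_edf(f, montage_labels = c(ts$channels, "Oz")),
               "missing montage channels: Oz")
  expect_error(suppressWarnings(read_edf(tempfile())),
               "cannot open|malformed")
})

test_that("config round-trips through YAML and rejects unknown keys", {
  cfg <- default_config(seed = 7)
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$nmm$bands$low$A, 2.7)
  expect_equal(cfg2$seed, 7L)
  expect_equal(cfg2$gan$iterations, 200)
  writeLines("nmm:\n  nonsense: 1\n", f)
  expect_error(read_config(f), "unknown config key 'nmm.nonsense'")
  writeLines("synthetic:\n  snr_db: -3\n", f)
  cfg3 <- read_config(f)
  expect_equal(cfg3$synthetic$snr_db, -3)
  expect_equal(cfg3$synthetic$sessions, 4L)  # untouched defaults
})

test_that("CLI: usage errors exit 2, simulate is byte-deterministic", {
  expect_equal(run_cli(character(0)), 2L)
  expect_equal(run_cli("frobnicate"), 2L)
  expect_equal(suppressMessages(run_cli(c("augment-eval", "--out",
                                          tempfile()))), 1L)
  d1 <- tempfile(); d2 <- tempfile()
  cfgf <- tempfile(fileext = ".yaml")
  cfg <- default_config(seed = 5)
  cfg$nmm$t_total <- 5
  write_config(cfg, cfgf)
  expect_equal(run_cli(c("simulate", "--config", cfgf, "--out", d1)), 0L)
  expect_equal(run_cli(c("simulate", "--config", cfgf, "--out", d2)), 0L)
  for (band in c("low", "medium", "high")) {
    f1 <- file.path(d1, paste0("source_", band, ".txt"))
    expect_true(file.exists(f1))
    expect_identical(readLines(f1),
                     readLines(file.path(d2, paste0("source_", band, ".txt"))))
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
  mf <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(mf$seed, 5L)
  expect_equal(mf$package, "simbci")
})

test_that("CLI make-synthetic writes per-subject per-session EDFs", {
  d <- tempfile()
  cfgf <- tempfile(fileext = ".yaml")
  cfg <- default_config(seed = 3)
  cfg$synthetic$task_s <- 1
  cfg$synthetic$sessions <- 2
  cfg$synthetic$trials <- 2
  write_config(cfg, cfgf)
  expect_equal(run_cli(c("make-synthetic", "--config", cfgf, "--subjects", "2",
                         "--out", d)), 0L)
  subs <- list.dirs(d, recursive = FALSE)
  expect_equal(length(subs), 2L)
  for (s in subs)
    expect_equal(sort(basename(list.files(s))),
                 c("session1.edf", "session2.edf"))
  ts <- read_edf(file.path(subs[1], "session1.edf"))
  expect_equal(length(ts$labels), 8L)   # 4 classes x 2 trials
  expect_equal(sort(unique(ts$labels)), sort(me_classes()))
})

test_that("lead-field export and manifest flow through the forward command", {
  d <- tempfile()
  cfgf <- tempfile(fileext = ".yaml")
  write_config(default_config(seed = 2), cfgf)
  expect_equal(run_cli(c("forward", "--config", cfgf, "--out", d)), 0L)
  lf <- read.table(file.path(d, "leadfield.txt"), row.names = 1)
  expect_equal(nrow(lf), 30L)
  expect_equal(ncol(lf), 12L)   # 4 dipoles x 3 moment components
  side <- jsonlite::read_json(file.path(d, "leadfield.json"))
  expect_equal(side$method, "analytic")
  expect_equal(side$reference, "CPz")
})
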