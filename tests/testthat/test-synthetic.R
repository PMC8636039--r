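test_that("generated recordings have the protocol geometry and are seeded", {
  prot <- recording_protocol(n_subjects = 1, sessions = 2, trials = 2,
                             task_s = 1)
  scen <- scenario_config(snr_db = 10, seed = 9, montage = montage8())
  ts <- generate_subject_recordings(prot, scen, 1)
  expect_equal(dim(ts$data), c(16L, 1000L, 8L))   # 4 classes x 2 x 2 trials
  expect_equal(sort(unique(ts$labels)), sort(me_classes()))
  expect_equal(as.integer(table(ts$labels)), rep(4L, 4))
  ts2 <- generate_subject_recordings(prot, scen, 1)
  expect_identical(ts$data, ts2$data)             # seed determinism
  # a different subject differs (jitter + noise streams)
  ts3 <- generate_subject_recordings(prot, scen, 2)
  expect_gt(max(abs(ts3$data - ts$data)), 0)
  expect_error(generate_subject_recordings(
    prot, scenario_config(class_weights = list(mRB = population_weights(1, 1, 1)),
                          montage = montage8()), 1),
    "no class weights")
})

test_that("default protocol arithmetic: trials, samples, split, windows", {
  prot <- recording_protocol()
  expect_equal(prot$sessions * prot$trials, 24L)  # per subject per class
  expect_equal(round(prot$task_s * prot$fs), 4000L)
  # windowing: 4 s at 1000 Hz in 100-ms windows
  ts <- random_trial_set(n = 2, nsmp = 4000, nch = 2)
  expect_equal(dim(slice_windows(ts, 100)$windows)[1] / 2, 40)
})

test_that("session split is disjoint with a 1:3 template:test ratio", {
  ts <- fix_recordings()
  spl <- split_sessions(ts)
  expect_equal(unique(spl$template$session), 1L)
  expect_false(1L %in% spl$test$session)
  expect_equal(length(spl$template$labels) * 3, length(spl$test$labels))
  single <- subset_trials(ts, ts$session == 1)
  expect_error(split_sessions(single), "at least 2 sessions")
})

test_that("class separability is monotone in SNR", {
  accs <- vapply(c(-40, 0, 40), function(snr) {
    ts <- fix_recordings(snr_db = snr)
    spl <- split_sessions(ts)
    rep_ <- run_classification(spl$template, spl$test,
                               classifier_set("knn_fine"), validate = FALSE,
                               seed = 2)
    unname(rep_$test["knn_fine"])
  }, 1.0)
  expect_true(all(diff(accs) > 0))
  expect_lt(accs[1], 35)    # chance-ish at -40 dB
  expect_gt(accs[3], 90)    # recoverable at +40 dB
})

test_that("configured band-energy weights are recovered at high SNR", {
  prot <- recording_protocol(n_subjects = 1, sessions = 1, trials = 4,
                             task_s = 4)
  w_cfg <- population_weights(0.2, 0.5, 0.3)
  scen <- scenario_config(snr_db = 40, seed = 21, jitter = 0,
                          montage = montage8(),
                          class_weights = list(mRB = w_cfg, mFB = w_cfg,
                                               mLS = w_cfg, mRS = w_cfg))
  ts <- generate_subject_recordings(prot, scen, 1)
  w <- band_weights_from_reference(subset_trials(ts, ts$labels == "mRB"))
  tot <- w$w_low + w$w_medium + w$w_high
  expect_equal(w$w_low / tot, 0.2, tolerance = 0.15 * 5)
  expect_equal(w$w_medium / tot, 0.5, tolerance = 0.15)
  expect_equal(w$w_high / tot, 0.3, tolerance = 0.15)
})

test_that("theoretical simulation shares geometry with the recordings", {
  prot <- recording_protocol(n_subjects = 1, sessions = 2, trials = 2,
                             task_s = 1)
  scen <- scenario_config(seed = 4, montage = montage8())
  sim <- simulate_scalp_trials(prot, scen, trials_per_class = 2)
  expect_equal(dim(sim$data), c(8L, 1000L, 8L))
  expect_identical(sim$data,
                   simulate_scalp_trials(prot, scen, trials_per_class = 2)$data)
  # noiseless: CPz (the reference) carries no signal
  expect_lt(max(abs(sim$data[, , which(sim$channels == "CPz")])), 1e-12)
})
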