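# Shared fixtures, built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small 8-electrode montage used by the desk-scale scenarios
montage8 <- function() {
  montage_subset(standard_montage(),
                 c("Fp1", "Fp2", "Fz", "C3", "Cz", "C4", "CPz", "Pz"))
}

# reduced-protocol recordings (1 s task, 8 channels) shared across tests
fix_recordings <- function(snr_db = 10, seed = 3, sessions = 4, trials = 3) {
  key <- sprintf("rec_%g_%d_%d_%d", snr_db, seed, sessions, trials)
  fixture(key, function() {
    prot <- recording_protocol(n_subjects = 1, sessions = sessions,
                               trials = trials, task_s = 1)
    scen <- scenario_config(snr_db = snr_db, seed = seed, montage = montage8())
    generate_subject_recordings(prot, scen, 1)
  })
}

random_trial_set <- function(n = 8, nsmp = 300, nch = 4, fs = 1000, sd = 1,
                             seed = 1) {
  set.seed(seed)
  trial_set(array(rnorm(n * nsmp * nch, 0, sd), c(n, nsmp, nch)),
            rep(me_classes(), length.out = n), fs)
}
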