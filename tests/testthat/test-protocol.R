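test_that("default schedule is 15 acquisition / 10 rest / 35 extinction", {
  sched <- build_schedule(session_config())
  expect_equal(nrow(sched), 60)
  expect_equal(sum(sched$phase == "acquisition"), 15)
  expect_equal(sum(sched$phase == "rest"), 10)
  expect_equal(sum(sched$phase == "extinction"), 35)
  expect_equal(sched$phase[16], "rest")
  expect_equal(sched$phase[26], "extinction")
  expect_true(all(sched$us[sched$phase == "acquisition"] == 1))
  expect_true(all(sched$us[sched$phase != "acquisition"] == 0))
  expect_true(all(!sched$plasticity_on[sched$phase == "rest"]))
})

test_that("phase-input contract holds for arbitrary trial counts", {
  set.seed(5)
  for (i in 1:10) {
    cfg <- session_config(n_acq = sample(0:20, 1), n_rest = sample(0:10, 1),
                          n_ext = sample(0:40, 1))
    s <- build_schedule(cfg)
    expect_equal(nrow(s), cfg$n_acq + cfg$n_rest + cfg$n_ext)
    expect_true(all(s$i_hip[s$phase != "acquisition"] == 0))
    expect_true(all(s$i_pfc[s$phase != "extinction"] == 0))
    expect_true(all(s$i_thal[s$phase == "rest"] == 0))
    expect_true(all(s$i_thal[s$phase != "rest"] > 0))
    expect_true(all(s$us == (s$phase == "acquisition")))
  }
  # no rest: extinction begins right after acquisition
  s0 <- build_schedule(session_config(n_rest = 0))
  expect_equal(s0$phase[16], "extinction")
})

test_that("condition overlays replace exactly the printed modulations", {
  base <- circuit_params()
  naive <- apply_condition(base, condition_overlay("naive"))
  expect_identical(unclass(naive), unclass(base))

  acute <- apply_condition(base, condition_overlay("acute"))
  expect_equal(acute$w_ba_inhib, 0.25)
  expect_equal(acute$w_la_inhib, 1.5)
  expect_equal(acute$w_baf_cea, 0.4)
  expect_equal(acute$w_bae_cea, 0.6)
  expect_equal(acute$w_cea_inhib, 2.5)
  expect_equal(acute$w_la_cea, 0.65)   # not listed -> unchanged
  expect_equal(acute$w_la_baf, 0.49)

  chronic <- apply_condition(base, condition_overlay("chronic"))
  expect_equal(chronic$w_cea_inhib, 2.5)
  expect_equal(chronic$dr_cea, -0.5)
  expect_equal(chronic$w_la_baf, 0.6)
  expect_equal(chronic$w_bae_cea, 0.98)

  expect_error(apply_condition(base, list(w_nonsense = 1)), "unknown")
})

test_that("rest trials and alpha = 0 leave weights untouched", {
  cfg <- fast_config("naive", seed = 21)
  res <- run_session(cfg)
  rest <- res$records[res$records$phase == "rest", ]
  w_end_acq <- res$records[res$records$phase == "acquisition", ][cfg$n_acq, ]
  for (col in c("w_thal_la", "w_hip_baf", "w_pfc_bae"))
    expect_true(all(rest[[col]] == w_end_acq[[col]]))

  cfg0 <- fast_config("naive", seed = 21,
                      learning = learning_params(alpha = 0))
  res0 <- run_session(cfg0)
  for (col in c("w_thal_la", "w_hip_baf", "w_pfc_bae"))
    expect_true(all(res0$records[[col]] == cfg0$init_weights[[col]]))
  expect_true(is.na(res0$trials_to_acquisition))
})

test_that("fear weights are frozen during extinction; mPFC weight never decreases", {
  res <- run_session(fast_config("naive", seed = 31))
  ext <- res$records[res$records$phase == "extinction", ]
  expect_equal(length(unique(ext$w_thal_la)), 1L)
  expect_equal(length(unique(ext$w_hip_baf)), 1L)
  expect_true(all(diff(ext$w_pfc_bae) >= 0))
  # acquisition weights never decrease either
  acq <- res$records[res$records$phase == "acquisition", ]
  expect_true(all(diff(acq$w_thal_la) >= 0))
  expect_true(all(diff(acq$w_hip_baf) >= 0))
})

test_that("criteria counting follows the stated conventions", {
  fake <- function(u_on_acq, u_on_ext) {
    rec <- data.frame(
      trial = seq_len(length(u_on_acq) + 2 + length(u_on_ext)) - 1,
      phase = rep(c("acquisition", "rest", "extinction"),
                  c(length(u_on_acq), 2, length(u_on_ext))),
      u_on = c(u_on_acq, 0, 0, u_on_ext))
    structure(list(records = rec,
                   config = list(crit_acq = 0.5, crit_ext = 0.1)),
              class = "session_result")
  }
  r <- fake(c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7), c(0.8, 0.7, 0.05, 0.9))
  expect_equal(trials_to_acquisition(r), 5)  # first crossing, 1-based
  expect_equal(trials_to_extinction(r), 3)   # counted from the recall trial
  r2 <- fake(rep(0.2, 6), rep(0.5, 4))
  expect_true(is.na(trials_to_acquisition(r2)))
  expect_true(is.na(trials_to_extinction(r2)))
  # no extinction phase at all
  r3 <- fake(c(0.9), numeric(0))
  expect_true(is.na(trials_to_extinction(r3)))
})

test_that("noise-free criteria are deterministic and independent of rest length", {
  off <- noise_spec(enabled = FALSE)
  a <- run_session(fast_config("naive", noise = off))
  b <- run_session(fast_config("naive", noise = off))
  expect_identical(a$records, b$records)
  expect_false(is.na(a$trials_to_acquisition))
  expect_false(is.na(a$trials_to_extinction))
  c0 <- run_session(fast_config("naive", noise = off, n_rest = 0))
  expect_equal(c0$trials_to_extinction, a$trials_to_extinction)
})

test_that("an untrained acquisition trial yields near-maximal prediction error", {
  cfg <- fast_config("naive", noise = noise_spec(enabled = FALSE),
                     init_weights = plastic_weights(0, 0, 0))
  sched <- build_schedule(cfg)
  out <- run_trial(circuit_state(), cfg$init_weights, sched[1, ], cfg)
  expect_gt(out$record$err, 0.9)
  expect_lt(out$record$readout, 0.1)
})
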