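test_that("nullclines match closed-form evaluation", {
  spec <- reduced_system_spec()  # naive extinction rates 0.15 / 0.9 / 0.8
  # dU_Off/dt = 0 at u_on = 0: F(0.98 * 0.9)
  expect_equal(off_nullcline(0, spec),
               1 / (1 + exp(-10 * (0.882 - 0.5))), tolerance = 1e-12)
  expect_equal(off_nullcline(0, spec), 0.979, tolerance = 1e-3)
  # dU_On/dt = 0 at u_off = 0: F(0.65*0.15 + 0.65*0.8) = F(0.6175)
  expect_equal(on_nullcline(0, spec),
               1 / (1 + exp(-10 * (0.6175 - 0.5))), tolerance = 1e-12)
  # saturation limit under strong inhibition
  strong <- reduced_system_spec(params = circuit_params(w_cea_inhib = 10))
  expect_lt(off_nullcline(1, strong), 1e-6)
})

test_that("nullclines are strictly decreasing in the opposing variable", {
  u <- seq(0, 1, length.out = 101)
  for (cond in c("naive", "acute", "chronic")) {
    p <- apply_condition(circuit_params(), condition_overlay(cond))
    spec <- reduced_system_spec(params = p)
    expect_true(all(diff(off_nullcline(u, spec)) < 0))
    expect_true(all(diff(on_nullcline(u, spec)) < 0))
  }
  # no coupling -> constant nullcline
  dec <- reduced_system_spec(params = circuit_params(w_cea_inhib = 0))
  expect_equal(length(unique(off_nullcline(u, dec))), 1L)
})

test_that("a decoupled system has a unique equilibrium at the nullcline constants", {
  spec <- reduced_system_spec(params = circuit_params(w_cea_inhib = 0))
  eq <- find_equilibria(spec)
  expect_equal(nrow(eq), 1L)
  expect_equal(eq$u_on, on_nullcline(0, spec), tolerance = 1e-8)
  expect_equal(eq$u_off, off_nullcline(0, spec), tolerance = 1e-8)
  expect_true(eq$stable)
})

test_that("equilibria agree with exhaustive 2-D grid search", {
  for (cond in c("naive", "chronic")) {
    p <- apply_condition(circuit_params(), condition_overlay(cond))
    spec <- reduced_system_spec(params = p)
    eq <- find_equilibria(spec)
    brute <- grid_equilibria(spec, res = 1e-3)
    expect_equal(nrow(eq), nrow(brute))
    for (i in seq_len(nrow(eq))) {
      d <- sqrt((brute$u_on - eq$u_on[i])^2 + (brute$u_off - eq$u_off[i])^2)
      expect_lt(min(d), 5e-3)
    }
    # fixed-point residuals below 1e-6 in both coordinates
    for (i in seq_len(nrow(eq))) {
      expect_lt(abs(on_nullcline(eq$u_off[i], spec) - eq$u_on[i]), 1e-6)
      expect_lt(abs(off_nullcline(eq$u_on[i], spec) - eq$u_off[i]), 1e-6)
    }
  }
})

test_that("the naive extinction state has a stable high-Off low-On equilibrium", {
  eq <- find_equilibria(reduced_system_spec())
  hi <- eq[eq$u_off > 0.8 & eq$u_on < 0.2, ]
  expect_gte(nrow(hi), 1L)
  expect_true(any(hi$stable))
})

test_that("noise-free reduced trajectories settle on a stable equilibrium", {
  spec <- reduced_system_spec()
  tr <- simulate_reduced(spec, n_steps = 1000,
                         noise = noise_spec(enabled = FALSE))
  end <- tr[1000, c("u_on", "u_off")]
  eq <- find_equilibria(spec)
  stable <- eq[eq$stable, ]
  d <- sqrt((stable$u_on - end$u_on)^2 + (stable$u_off - end$u_off)^2)
  expect_lt(min(d), 1e-4)
  # noisy trajectory stays in the unit square
  tn <- simulate_reduced(spec, n_steps = 2000, seed = 12)
  expect_true(all(tn$u_on >= 0 & tn$u_on <= 1))
  expect_true(all(tn$u_off >= 0 & tn$u_off <= 1))
})

test_that("late-extinction CeAOff equilibrium is graded naive > acute > chronic", {
  # frozen BLA rates harvested from each condition's own full simulation
  eq_off <- sapply(setNames(nm = c("naive", "acute", "chronic")),
                   function(cond) {
    p <- apply_condition(circuit_params(), condition_overlay(cond))
    res <- run_session(session_config(cond, seed = 61))
    fr <- harvest_frozen_rates(res)
    spec <- reduced_system_spec(u_baf = fr$u_baf, u_bae = fr$u_bae,
                                u_la = fr$u_la, params = p)
    eq <- find_equilibria(spec)
    stable <- eq[eq$stable, ]
    max(stable$u_off)  # the extinction-side equilibrium
  })
  expect_gt(eq_off[["naive"]], eq_off[["acute"]])
  expect_gt(eq_off[["acute"]], eq_off[["chronic"]])
})

test_that("noise perturbs the reduced trajectory more under chronic alcohol", {
  # same noise seed in both conditions; spread around the extinction state
  spread <- sapply(setNames(nm = c("naive", "chronic")), function(cond) {
    p <- apply_condition(circuit_params(), condition_overlay(cond))
    res <- run_session(session_config(cond, seed = 61))
    fr <- harvest_frozen_rates(res)
    spec <- reduced_system_spec(u_baf = fr$u_baf, u_bae = fr$u_bae,
                                u_la = fr$u_la, params = p)
    tr <- simulate_reduced(spec, n_steps = 3000, seed = 77, init = c(0, 1))
    sd(tr$u_off[1000:3000])
  })
  expect_gt(spread[["chronic"]], spread[["naive"]])
})

test_that("robustness right-hand side matches closed forms", {
  naive <- reduced_system_spec()
  expect_identical(robustness_rhs(naive, 1, 1, 1), 0.8)
  # margin positive in the naive extinction regime
  expect_gt(naive$w_cea_inhib - robustness_rhs(naive, 1, 1, 1), 0)
  chronic <- reduced_system_spec(
    params = apply_condition(circuit_params(), condition_overlay("chronic")))
  expect_equal(robustness_rhs(chronic, 1, 1, 1), 0.3, tolerance = 1e-12)
  expect_warning(inf_rhs <- robustness_rhs(naive, 1, 1, 0), "unreachable")
  expect_identical(inf_rhs, Inf)
  # divergence as u_off -> 0+
  expect_gt(robustness_rhs(naive, 1, 1, 1e-9), 1e8)
})

test_that("frozen-rate relaxation reproduces the full model's CeA averages", {
  res <- run_session(session_config("naive", seed = 71))
  fr <- harvest_frozen_rates(res)
  spec <- reduced_system_spec(u_baf = fr$u_baf, u_bae = fr$u_bae,
                              u_la = fr$u_la)
  # start on the extinction side of the bistable CeA switch, as the full
  # model does after the extinction transition
  tr <- simulate_reduced(spec, n_steps = 4000, seed = 72, init = c(0, 1))
  ext <- res$records[res$records$phase == "extinction", ]
  k <- res$trials_to_extinction
  post <- ext[(k + 2):nrow(ext), ]
  # compare within the extinction attractor; occasional whole-trial flips
  # back to the fear state are a full-circuit phenomenon the frozen-BLA
  # reduction cannot express
  post <- post[post$u_on <= 0.5, ]
  expect_true(abs(mean(tr$u_off[2000:4000]) - mean(post$u_off)) < 0.05)
  expect_true(abs(mean(tr$u_on[2000:4000]) - mean(post$u_on)) < 0.05)
})
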