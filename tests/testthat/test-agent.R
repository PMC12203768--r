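test_that("interference scale is 1 with no exposure and decreases hyperbolically", {
  expect_equal(interference_scale(0, 0.5), 1)
  expect_equal(interference_scale(1000, 0), 1)
  expect_equal(interference_scale(100, 0.01), 0.5)
  P <- 0:50
  expect_true(all(diff(interference_scale(P, 0.2)) < 0))
})

test_that("state updates have the right fixed points and exposure accounting", {
  prot <- quick_protocol()
  par <- agent_params(kappa = 0)
  st <- agent_state(prot, par)

  # no feedback: zero is a fixed point of pure decay
  st2 <- agent_update(st, list(context = "main", target_deg = 45,
                               kind = "none", cursor_deg = NA,
                               clamp_sign = -1), par)
  expect_equal(unname(st2$x["main"]), 0)

  # constant CW clamp converges to u / (1 - a_f) in the CCW direction
  tr <- list(context = "main", target_deg = 45, cursor_deg = 45 - 15,
             kind = "clamped", clamp_sign = -1)
  for (i in 1:3000) st <- agent_update(st, tr, par)
  expect_equal(unname(st$x["main"]), par$u / (1 - par$a_f), tolerance = 1e-4)
  expect_equal(unname(st$P["main"]), 0)  # learning clamp is not discrepant

  # reversed clamp and veridical/rotated cursors count as discrepant
  st <- agent_state(prot, par)
  st <- agent_update(st, list(context = "main", target_deg = 45,
                              cursor_deg = 60, kind = "clamped",
                              clamp_sign = -1), par)
  st <- agent_update(st, list(context = "main", target_deg = 45,
                              cursor_deg = 47, kind = "veridical",
                              clamp_sign = -1), par)
  st <- agent_update(st, list(context = "main", target_deg = 45,
                              cursor_deg = 44, kind = "rotated",
                              clamp_sign = -1), par)
  expect_equal(unname(st$P["main"]), 3)
  expect_error(agent_update(st, list(context = "main", target_deg = 45,
                                     cursor_deg = 45, kind = "weird",
                                     clamp_sign = -1), par),
               "unknown feedback kind")
})

test_that("adaptation barely generalizes between distant contexts", {
  prot <- clamp_protocol("E5")
  par <- agent_params()
  st <- agent_state(prot, par)
  tr <- list(context = "ctx1", target_deg = 10, cursor_deg = 10 - 15,
             kind = "clamped", clamp_sign = -1)
  for (i in 1:500) st <- agent_update(st, tr, par)
  leak <- max(abs(st$x[c("ctx2", "ctx3")])) / abs(st$x["ctx1"])
  expect_lt(leak, 0.01)
})

test_that("simulated participants are reproducible and close the feedback loop", {
  prot <- quick_protocol()
  t1 <- simulate_participant(prot, seed = 42)
  t2 <- simulate_participant(prot, seed = 42)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 1200)
  expect_true(all(diff(t1$trial) > 0))

  # cursor column must equal the policy mapping applied to the recorded hand
  clamped <- t1[t1$feedback == "clamped" & t1$block == "learning1", ]
  expect_equal(clamped$cursor_deg, clamped$target_deg - 15)
  ver <- t1[t1$feedback == "veridical", ]
  expect_equal(ver$cursor_deg, ver$hand_deg)
  none <- t1[t1$feedback == "none", ]
  expect_true(all(is.na(none$cursor_deg)))
  rev <- t1[t1$block == "washout_reversed_clamp", ]
  expect_equal(rev$cursor_deg, rev$target_deg + 15)

  # learning rises toward a 15-25 degree asymptote; aftereffect well above 5
  rel <- t1$hand_deg - t1$target_deg
  late <- mean(rel[t1$block == "learning1" & t1$cycle > 80])
  expect_gt(late, 15); expect_lt(late, 25)
  expect_gt(mean(rel[t1$block == "aftereffect1"]), 5)
})

test_that("no-feedback washout decays slowly and incompletely", {
  prot <- clamp_protocol("E2")
  tr <- simulate_participant(prot, seed = 5)
  rel <- tr$hand_deg - tr$target_deg
  ae1 <- mean(rel[tr$block == "aftereffect1"])
  wash_end <- mean(rel[tr$block == "washout_no_feedback" & tr$cycle > 200])
  expect_lt(wash_end, ae1)
  expect_gt(wash_end, 1)  # incomplete decay by the end of the washout block
})

test_that("gradual washout tracks the individual aftereffect down to veridical", {
  tr <- simulate_participant(clamp_protocol("E3"), seed = 8)
  w <- tr[tr$block == "washout_gradual", ]
  first_rot <- w$rotation_deg[1]
  ae1 <- mean(tr$hand_deg[tr$block == "aftereffect1"] -
              tr$target_deg[tr$block == "aftereffect1"])
  expect_equal(first_rot, -ae1, tolerance = 1e-10)
  mags <- as.numeric(tapply(abs(w$rotation_deg), w$cycle, unique))
  expect_equal(diff(mags[1:10]), rep(-1, 9))
  expect_true(any(w$feedback == "veridical"))  # ramp reached zero
})

test_that("cohorts are counterbalanced exactly and error on impossible sizes", {
  co <- simulate_cohort("E1", 8, seed = 11)
  signs <- tapply(co$clamp_sign, co$participant, unique)
  expect_equal(sum(signs == -1), 4)
  expect_equal(sum(signs == 1), 4)

  co5 <- simulate_cohort("E5", 6, seed = 11)
  expo <- unique(co5[, c("participant", "context", "veridical_cycles")])
  tab <- table(expo$context, expo$veridical_cycles)
  expect_true(all(tab == 2))  # each context sees each exposure in 1/3 of cohort

  co4 <- simulate_cohort("E4", 4, seed = 11)
  roles <- unique(co4[, c("participant", "context", "context_role")])
  expect_equal(sum(roles$context == "ctxA" & roles$context_role == "relearn"), 2)

  expect_error(simulate_cohort("E1", 43, seed = 11), "divisible")
  expect_error(simulate_cohort("E5", 44, seed = 11), "divisible")
})

test_that("refitting the learner to cohort learning curves recovers its parameters", {
  par <- agent_params()
  co <- simulate_cohort("E1", 12, params = par, seed = 21)
  # exposure entering learning 1: 5 veridical cycles x 4 targets
  s <- interference_scale(20, par$kappa)
  fit <- fit_state_space(co, "learning1", scale = s)
  expect_equal(fit$a_f, par$a_f, tolerance = 0.05)
  expect_equal(fit$u, par$u, tolerance = 0.1)
  expect_equal(fit$sigma_m, par$sigma_m, tolerance = 0.1)
  # the fitted deterministic curve matches the independent loop oracle
  expect_equal(fit$fitted_cycle_means,
               unname(oracle_learning_curve(fit$a_f, fit$u, s, 80, 4)),
               tolerance = 1e-8)
})
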