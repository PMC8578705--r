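test_that("rate constraints and the forbidden edge are enforced", {
  r <- gating_rates()
  q <- rate_matrix(r)
  expect_equal(q["C4", "I4"], 0)        # irreversible step
  expect_equal(q["O4", "C4"], 0.4 / 100)
  expect_equal(q["I4", "O4"], 0.2 / 100)
  expect_equal(unname(rowSums(q)), rep(0, 3))
  expect_error(gating_rates(k1 = 10, dt = 0.0125), "dt")
  expect_error(gating_rates(k1 = -1), "k1")
  # Inf reverse factor disables the reverse edges
  ri <- gating_rates(reverse_factor = Inf)
  expect_equal(rate_matrix(ri)["I4", "O4"], 0)
})

test_that("null dynamics leave the ensemble unchanged", {
  r0 <- gating_rates(0, 0, 0)
  e <- receptor_ensemble(100, 20, 3)
  set.seed(1)
  s <- step_ensemble(e, r0)
  expect_equal(c(s$C4, s$O4, s$I4), c(100, 20, 3))
  expect_equal(meanfield_occupancies(c(0.2, 0.5, 0.3), r0, 500),
               c(C4 = 0.2, O4 = 0.5, I4 = 0.3))
})

test_that("per-step transition probability equals k1 * dt", {
  # 2e6 closed receptors for one step: the opening fraction estimates the
  # per-step probability 0.4 * 0.0125 = 0.005
  n <- 2e6
  e <- receptor_ensemble(n, 0, 0)
  set.seed(42)
  for (engine in c("multinomial", "per_receptor")) {
    s <- step_ensemble(e, gating_rates(), engine = engine)
    p_hat <- s$O4 / n
    se <- sqrt(0.005 * 0.995 / n)
    expect_lt(abs(p_hat - 0.005), 3 * se)
    expect_equal(s$C4 + s$O4 + s$I4, n)
  }
})

test_that("injection raises C4 by the occupancy-model increment", {
  e <- receptor_ensemble(10, 5, 2)
  expect_equal(inject_tetraliganded(e, 17)$C4, 10)  # increment 0
  e2 <- inject_tetraliganded(e, 100)
  expect_equal(c(e2$C4, e2$O4, e2$I4), c(93, 5, 2))
  expect_error(inject_tetraliganded(e, 10), "unsupported")
  # population well at 60 nM: the expected tetra-liganded count
  n60 <- round(tetra_count(60, occupancy_model(794, 2e10)))
  e3 <- inject_tetraliganded(receptor_ensemble(), n60)
  expect_equal(e3$C4, round(2e10 * (60 / (60 + 794))^4))
  expect_equal(e3$O4 + e3$I4, 0)
  # sequential 60 -> 90 nM injections scale the total by the 4.41 fold-change
  n90 <- round(tetra_count(90, occupancy_model(794, 2e10)))
  expect_equal(n90 / n60, 4.41, tolerance = 1e-3)
})

test_that("counts are conserved between injections for every step", {
  pr <- addition_protocol(c(0, 5), c(100, 300), kd = 794,
                          receptors_total = 1e7)
  tr <- simulate_protocol(pr, gating_rates(), seed = 11, duration = 10)
  m <- occupancy_model(794, 1e7)
  tot <- tr$C4 + tr$O4 + tr$I4
  expect_equal(unique(tot[tr$time_s < 5]), round(tetra_count(100, m)))
  expect_equal(unique(tot[tr$time_s >= 5]), round(tetra_count(300, m)))
  expect_true(all(tr$C4 >= 0 & tr$O4 >= 0 & tr$I4 >= 0))
  expect_true(all(tr[c("C4", "O4", "I4")] == round(tr[c("C4", "O4", "I4")])))
})

test_that("identical (protocol, rates, seed) give identical trajectories", {
  pr <- addition_protocol(0, 143, kd = 794, receptors_total = 9101)
  a <- simulate_protocol(pr, gating_rates(), seed = 7, duration = 50)
  b <- simulate_protocol(pr, gating_rates(), seed = 7, duration = 50)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_protocol(pr, gating_rates(), seed = 8, duration = 50)
  expect_false(identical(a$O4, c_$O4))
})

test_that("protocol validation rejects malformed schedules", {
  expect_error(addition_protocol(c(0, 0), c(10, 20), 794, 1e4),
               "strictly increasing")
  expect_error(addition_protocol(c(0, 10), c(20, 10), 794, 1e4),
               "non-decreasing")
  pr <- addition_protocol(0, 0, kd = 794, receptors_total = 1e6)
  tr <- simulate_protocol(pr, gating_rates(), seed = 1, duration = 5)
  expect_true(all(tr$C4 + tr$O4 + tr$I4 == 0))
  expect_error(simulate_protocol(pr, gating_rates()), "seed")
})

test_that("ensemble means track the master-equation oracle within 3 SE", {
  # 1e5 receptors injected at t = 0, compared state-by-state against the
  # matrix exponential at every recorded time
  n0 <- 1e5
  m <- occupancy_model(794, round(n0 / tetra_fraction(
    fractional_occupancy(5000, 794))))
  pr <- addition_protocol(0, 5000, kd = 794,
                          receptors_total = m$receptors_per_cell)
  expect_equal(round(tetra_count(5000, m)), n0)
  tr <- simulate_protocol(pr, gating_rates(), seed = 3, duration = 120,
                          record_every = 160)
  mf <- meanfield_occupancies(c(1, 0, 0), gating_rates(), tr$time_s)
  for (st in c("C4", "O4", "I4")) {
    se <- pmax(sqrt(n0 * mf[, st] * (1 - mf[, st])), 1)
    expect_lt(max(abs(tr[[st]] - n0 * mf[, st]) / se), 3)
  }
})

test_that("the simulator mean is exact against the discrete-chain oracle", {
  # at well-scale counts the O(k dt) discretisation bias exceeds binomial
  # noise, so the exact fixed-step chain mean is the sharper oracle
  pr <- addition_protocol(0, 300, kd = 794, receptors_total = 2e10)
  n0 <- round(tetra_count(300, occupancy_model(794, 2e10)))
  tr <- simulate_protocol(pr, gating_rates(), seed = 2, duration = 60,
                          record_every = 480)
  mfd <- meanfield_occupancies(c(1, 0, 0), gating_rates(), tr$time_s,
                               method = "discrete")
  se <- pmax(sqrt(n0 * mfd[, "O4"] * (1 - mfd[, "O4"])), 1)
  expect_lt(max(abs(tr$O4 - n0 * mfd[, "O4"]) / se), 3)
})

test_that("matrix-exponential and fine-step ODE oracles agree to 1e-6", {
  r <- gating_rates()
  p_expm <- meanfield_occupancies(c(1, 0, 0), r, 2)
  p_ode <- ode_occupancies(c(1, 0, 0), r, 2)
  expect_equal(unname(p_expm), p_ode, tolerance = 1e-6)
  # probabilities stay normalised far out in time
  p_far <- meanfield_occupancies(c(1, 0, 0), r, 5000)
  expect_equal(sum(p_far), 1, tolerance = 1e-10)
  expect_equal(meanfield_occupancies(c(0, 1, 0), r, 0),
               c(C4 = 0, O4 = 1, I4 = 0))
  expect_error(meanfield_occupancies(c(0.5, 0.6, 0.2), r, 1), "sum")
})

test_that("halving dt shifts the chain mean by less than one MC SE at 1e5", {
  r1 <- gating_rates(dt = 0.0125)
  r2 <- gating_rates(dt = 0.00625)
  n <- 1e5
  for (tt in c(5, 20, 60)) {
    p1 <- meanfield_occupancies(c(1, 0, 0), r1, tt, method = "discrete")
    p2 <- meanfield_occupancies(c(1, 0, 0), r2, tt, method = "discrete")
    se <- sqrt(p1 * (1 - p1) / n)
    expect_true(all(abs(p1 - p2) < se))
  }
})

test_that("long-run state distribution matches the null-space oracle", {
  pi_ <- stationary_distribution(gating_rates())
  # stationarity by linear algebra: pi Q = 0
  expect_equal(as.numeric(pi_ %*% rate_matrix(gating_rates())),
               rep(0, 3), tolerance = 1e-12)
  # with all exits open, pi_O / pi_I = (k_-2 + k_3) / k_2
  expect_equal(pi_[["O4"]] / pi_[["I4"]], (0.002 + 0.004) / 0.2,
               tolerance = 1e-10)
  n0 <- 2e4
  m <- occupancy_model(794, round(n0 / tetra_fraction(
    fractional_occupancy(5000, 794))))
  pr <- addition_protocol(0, 5000, kd = 794,
                          receptors_total = m$receptors_per_cell)
  tr <- simulate_protocol(pr, gating_rates(), seed = 5, duration = 150,
                          record_every = 8000)
  last <- tr[nrow(tr), ]
  ntot <- last$C4 + last$O4 + last$I4
  for (st in c("C4", "O4", "I4")) {
    se <- sqrt(ntot * pi_[[st]] * (1 - pi_[[st]]))
    expect_lt(abs(last[[st]] - ntot * pi_[[st]]), 3 * se)
  }
})

test_that("dwell times converge to the reciprocal total exit rate", {
  r <- gating_rates()
  for (case in list(list("C4", 1 / 0.4), list("O4", 1 / 0.204),
                    list("I4", 1 / 0.006))) {
    d <- dwell_time_sample(case[[1]], r, n = 2e4, seed = 9)
    expect_lt(abs(mean(d) - case[[2]]), 3 * stats::sd(d) / sqrt(length(d)))
  }
  # mean closed dwell ~2.5 s, open dwell ~5 s
  expect_equal(mean(dwell_time_sample("C4", r, 2e4, seed = 1)), 2.5,
               tolerance = 0.03)
  expect_equal(mean(dwell_time_sample("O4", r, 2e4, seed = 1)), 4.9,
               tolerance = 0.03)
  # single-exit I4 when reverse transitions are disabled: 1/k3 = 250 s
  ri <- gating_rates(reverse_factor = Inf)
  expect_equal(mean(dwell_time_sample("I4", ri, 2e4, seed = 2)), 250,
               tolerance = 0.05)
  # no exit at all: infinite dwell reported as such
  expect_true(all(is.infinite(
    dwell_time_sample("I4", gating_rates(k3 = 0, reverse_factor = Inf),
                      n = 5, seed = 1))))
})

test_that("per-receptor and multinomial engines agree in distribution", {
  pr <- addition_protocol(0, 1000, kd = 794, receptors_total = 1e6)
  n0 <- round(tetra_count(1000, occupancy_model(794, 1e6)))
  a <- simulate_protocol(pr, gating_rates(), seed = 21, duration = 15,
                         record_every = 400, engine = "per_receptor")
  mfd <- meanfield_occupancies(c(1, 0, 0), gating_rates(), a$time_s,
                               method = "discrete")
  se <- pmax(sqrt(n0 * mfd[, "O4"] * (1 - mfd[, "O4"])), 1)
  expect_lt(max(abs(a$O4 - n0 * mfd[, "O4"]) / se), 3)
})

test_that("gating trajectories round-trip through delimited text", {
  pr <- addition_protocol(0, 300, kd = 794, receptors_total = 1e6)
  tr <- simulate_protocol(pr, gating_rates(), seed = 4, duration = 10,
                          record_every = 80)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  expect_error(write_trajectory(tr, path), "overwrite")
  back <- utils::read.table(path, header = TRUE, sep = ",",
                            comment.char = "#")
  expect_equal(back$O4, tr$O4)
  meta <- readLines(path, n = 4)
  expect_true(any(grepl("seed: 4", meta)))
})
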