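cfg_small <- function(...) pheromone_config(max_steps = 500L, ...)

test_that("configuration derives kappa from the fade-out time and validates", {
  cfg <- pheromone_config()
  expect_equal(cfg$L, 20L)
  expect_equal(cfg$exit_width_loci, 3L)
  expect_equal(cfg$exit_rows, c(8L, 9L, 10L))
  expect_equal(cfg$kappa, (8 / 20 / 0.94) / 60)
  expect_error(pheromone_config(eta = 1.5), "must not exceed")
  expect_error(pheromone_config(eta = 0), "positive")
  expect_error(pheromone_config(L = 4), ">= 5")
  expect_error(tau_to_kappa(0), "positive")
  expect_error(tau_to_kappa(-5), "positive")
  # one-step fade-out limit: tau equal to the step time gives kappa = T
  dt <- (8 / 20) / 0.94
  expect_equal(tau_to_kappa(dt), 1)
})

test_that("world initialisation is deterministic, in bounds, with a clean field", {
  cfg <- pheromone_config()
  w1 <- init_world(cfg, 400, seed = 3)
  w2 <- init_world(cfg, 400, seed = 3)
  expect_identical(w1, w2)
  expect_true(all(w1$pos >= 0 & w1$pos <= 19))
  expect_equal(sum(w1$field), 0)
  expect_true(all(abs(w1$vel) <= 1))
  expect_true(all(rowSums(abs(w1$vel)) >= 1))
  expect_error(init_world(cfg, 0), "positive integer")
})

test_that("deposit and evaporate follow the bookkeeping rules", {
  cfg <- pheromone_config()
  w <- init_world(cfg, 1, seed = 4)
  w <- deposit(w, eta = 0.5)
  locus <- w$pos[1, ] + 1L
  expect_equal(w$field[locus[1], locus[2]], 0.5)
  expect_equal(sum(w$field), 0.5)

  # evaporation clamps at zero
  w$field[1, 1] <- 0.003
  w <- evaporate(w, kappa = 0.0071)
  expect_equal(w$field[1, 1], 0)
  expect_true(all(w$field >= 0))
  expect_equal(w$field[locus[1], locus[2]], 0.5 - 0.0071)

  # deposit then evaporate with eta = kappa over an empty field cancels
  w0 <- init_world(cfg, 1, seed = 4)
  w0 <- evaporate(deposit(w0, eta = 0.01), kappa = 0.01)
  expect_equal(sum(w0$field), 0)

  # k co-located ants deposit k * eta
  w3 <- init_world(cfg, 3, seed = 5)
  w3$pos[1, ] <- w3$pos[2, ] <- w3$pos[3, ] <- c(7L, 7L)
  w3 <- deposit(w3)
  expect_equal(w3$field[8, 8], 3 * cfg$eta)
})

test_that("gradient sensing clips at the threshold and breaks ties at random", {
  cfg <- pheromone_config()
  w <- init_world(cfg, 1, seed = 6)
  w$pos[1, ] <- c(10L, 10L)

  expect_null(sense_gradient(w, 1))  # nothing to sense

  # unique sub-threshold maximum at the NE neighbour
  w$field[12, 12] <- 0.4
  expect_equal(unname(sense_gradient(w, 1)), c(1L, 1L))

  # a value of 6 is clipped to the threshold and ties with an exact 1
  w$field[12, 12] <- 6
  w$field[10, 10] <- 1  # SW neighbour (9, 9) in 0-based coordinates
  picks <- replicate(400, paste(sense_gradient(w, 1), collapse = ","))
  expect_setequal(unique(picks), c("1,1", "-1,-1"))
  frac <- mean(picks == "1,1")
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.6)

  # the ant's own locus is not in its detection range
  w2 <- init_world(cfg, 1, seed = 6)
  w2$pos[1, ] <- c(10L, 10L)
  w2$field[11, 11] <- 5
  expect_null(sense_gradient(w2, 1))

  # off-lattice neighbours are excluded: corner ant sees only 3 loci
  w3 <- init_world(cfg, 1, seed = 6)
  w3$pos[1, ] <- c(0L, 0L)
  w3$field[2, 2] <- 0.2
  expect_equal(unname(sense_gradient(w3, 1)), c(1L, 1L))
})

test_that("bracket is the sign quantiser", {
  expect_equal(bracket(0), 0L)
  expect_equal(bracket(1.7), 1L)
  expect_equal(bracket(-0.2), -1L)
  expect_equal(bracket(c(-2, 0, 2)), c(-1L, 0L, 1L))
  expect_error(bracket(NaN), "finite")
  expect_error(bracket(Inf), "finite")
})

test_that("movement combines persistence with the sensed gradient", {
  cfg <- pheromone_config()
  w <- init_world(cfg, 1, seed = 7)
  w$pos[1, ] <- c(10L, 10L)
  w$vel[1, ] <- c(1L, 0L)

  # no gradient: pure persistence
  w1 <- move_ant(w, 1, NULL)
  expect_equal(unname(w1$pos[1, ]), c(11L, 10L))
  expect_equal(unname(w1$vel[1, ]), c(1L, 0L))

  # opposing gradient cancels to (0,0): repaired to the previous velocity
  w2 <- move_ant(w, 1, c(-1L, 0L))
  expect_equal(unname(w2$vel[1, ]), c(1L, 0L))
  expect_equal(unname(w2$pos[1, ]), c(11L, 10L))

  # oblique gradient turns the heading
  w3 <- move_ant(w, 1, c(0L, 1L))
  expect_equal(unname(w3$vel[1, ]), c(1L, 1L))
  expect_equal(unname(w3$pos[1, ]), c(11L, 11L))

  # reflection at the right edge
  w4 <- init_world(cfg, 1, seed = 7)
  w4$pos[1, ] <- c(19L, 5L)
  w4$vel[1, ] <- c(1L, 0L)
  w4 <- move_ant(w4, 1, NULL)
  expect_equal(unname(w4$pos[1, ]), c(18L, 5L))
  expect_equal(unname(w4$vel[1, ]), c(-1L, 0L))

  # corner hit reflects both components
  w5 <- init_world(cfg, 1, seed = 7)
  w5$pos[1, ] <- c(0L, 0L)
  w5$vel[1, ] <- c(-1L, -1L)
  w5 <- move_ant(w5, 1, NULL)
  expect_equal(unname(w5$pos[1, ]), c(1L, 1L))
  expect_equal(unname(w5$vel[1, ]), c(1L, 1L))
})

test_that("escape triggers on Moore-adjacency to an exit locus", {
  cfg <- pheromone_config()
  w <- init_world(cfg, 2, seed = 8)

  # adjacent to a left-exit locus
  w$pos[1, ] <- c(1L, 9L)
  esc <- check_escape(w, 1)
  expect_equal(esc$side, "left")
  expect_false(esc$world$active[1])
  expect_equal(esc$world$escaped_left, 1L)

  # centre of the lattice: no escape
  w$pos[2, ] <- c(10L, 10L)
  expect_equal(check_escape(w, 2)$side, "none")

  # left edge but away from the exit rows: no escape
  w$pos[2, ] <- c(0L, 3L)
  expect_equal(check_escape(w, 2)$side, "none")

  # right side, underfoot on an exit locus
  w$pos[2, ] <- c(19L, 10L)
  expect_equal(check_escape(w, 2)$side, "right")

  # two ants adjacent to opposite exits escape independently in one step
  w2 <- init_world(cfg, 2, seed = 8)
  w2$pos[1, ] <- c(2L, 9L); w2$vel[1, ] <- c(-1L, 0L)
  w2$pos[2, ] <- c(17L, 9L); w2$vel[2, ] <- c(1L, 0L)
  w2$field[10, 10] <- 0  # keep field clean so both just persist
  w2 <- step_world(w2)
  expect_equal(w2$escaped_left, 1L)
  expect_equal(w2$escaped_right, 1L)
})

test_that("step conserves ants and evolves the field within its bounds", {
  cfg <- cfg_small()
  w <- init_world(cfg, 10, seed = 9)
  for (s in 1:50) {
    w <- step_world(w)
    expect_true(all(w$field >= 0))
    expect_equal(sum(w$active) + w$escaped_left + w$escaped_right, 10L)
    # total pheromone is bounded by deposits minus (clamped) evaporation
    expect_lte(sum(w$field), 50 * 10 * cfg$eta)
  }
  expect_equal(w$step_count, 50L)

  # a world with no active ants only evaporates
  w0 <- init_world(cfg, 1, seed = 10)
  w0$active[1] <- FALSE
  w0$field[5, 5] <- 0.02
  w0 <- step_world(w0)
  expect_equal(w0$field[5, 5], 0.02 - cfg$kappa)
  expect_equal(w0$step_count, 1L)
  # with no ants the field drains to zero within max(field)/kappa steps
  for (s in seq_len(ceiling(0.02 / cfg$kappa))) w0 <- step_world(w0)
  expect_equal(sum(w0$field), 0)
})

test_that("the compiled runner reproduces the R-level trajectory exactly", {
  cfg <- pheromone_config()
  for (seed in c(7, 21)) {
    w <- init_world(cfg, 12, seed = seed)
    for (s in 1:80) w <- step_world(w)
    st <- run_pheromone_state(cfg, 12, 80, seed = seed)
    expect_identical(w$field, st$field)
    expect_identical(unname(w$pos), unname(as.matrix(st$pos)))
    expect_identical(unname(w$vel), unname(as.matrix(st$vel)))
    expect_identical(unname(w$active), as.vector(st$active))
    expect_identical(w$escaped_left, st$n_left)
    expect_identical(w$escaped_right, st$n_right)
  }
})

test_that("full runs are deterministic per seed and respect the step cap", {
  cfg <- cfg_small()
  r1 <- run_pheromone_escape(10, cfg, seed = 12)
  r2 <- run_pheromone_escape(10, cfg, seed = 12)
  expect_identical(r1, r2)
  expect_lte(r1$steps, 500)
  expect_equal(r1$n_escaped, r1$n_left + r1$n_right)

  # a lone ant that escapes has N = 1 and collective asymmetry exactly 0
  one <- run_pheromone_escape(1, pheromone_config(), seed = 4)
  expect_false(one$truncated)
  expect_equal(one$n_escaped, 1)
  expect_equal(collective_asymmetry(one$n_left, one$n_right), 0)
  # a lone ant can also trap itself on its own saturated trail; such runs
  # hit the step cap and are flagged
  stuck <- run_pheromone_escape(1, pheromone_config(), seed = 1)
  expect_true(stuck$truncated)
  expect_equal(stuck$n_escaped, 0)

  sims <- simulate_pheromone(5, 20, cfg, seed = 14)
  expect_equal(nrow(sims), 20)
  expect_true(all(sims$n_escaped == sims$n_left + sims$n_right))
  expect_true(all(sims$n_escaped <= 5))
})

test_that("an insensate ensemble (tiny eta) centres collective asymmetry on zero", {
  # eta must be positive by contract; an ant-scale deposit far below what
  # evaporation removes leaves the field permanently empty, so ants reduce
  # to persistent random walkers (the fair-coin null)
  # Without a field the walk is deterministic after initialisation, so some
  # orbits never meet an exit and whole runs truncate; the escaped subsets
  # are still left/right exchangeable, so include truncated runs.
  cfg <- pheromone_config(eta = 1e-9, tau_s = 6, max_steps = 4000L)
  sim <- simulate_pheromone(10, 200, cfg, seed = 15)
  s <- summarise_runs(sim, exclude_truncated = FALSE)
  expect_lt(abs(s$mean_delta_c), 3 * s$se)
})

test_that("run summaries exclude truncated runs by default", {
  runs <- data.frame(run_id = 1:3, n_requested = 10L,
                     n_escaped = c(10L, 10L, 4L),
                     n_left = c(7L, 5L, 4L), n_right = c(3L, 5L, 0L),
                     steps = c(100L, 120L, 500L),
                     truncated = c(FALSE, FALSE, TRUE))
  s <- summarise_runs(runs)
  expect_equal(s$runs_used, 2)
  expect_equal(s$mean_delta_c,
               mean(collective_asymmetry(c(7, 5), c(3, 5))))
  s_all <- summarise_runs(runs, exclude_truncated = FALSE)
  expect_equal(s_all$runs_used, 3)
  tt <- runs_to_trial_table(runs)
  expect_equal(nrow(tt), 2)
})
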