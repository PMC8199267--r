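test_that("preset resolver reproduces the full defaults table", {
  # (scoring, speed) -> (ants, rho, sigma), explicit settings override
  expect_tab <- function(sf, sp, ants, rho, sigma, ov = NULL) {
    p <- resolve_defaults(sf, sp, overrides = ov)
    expect_equal(p$n_ants, ants)
    expect_equal(p$rho, rho)
    expect_equal(p$sigma, sigma)
  }
  expect_tab("chemplp", 4, 20L, 0.15, 0.25)
  expect_tab("chemplp", 2, 20L, 0.20, 0.5)
  expect_tab("chemplp", 1, 20L, 0.20, 1.25)
  expect_tab("chemplp", 4, 10L, 0.15, 0.25, ov = list(n_ants = 10L))
  expect_tab("chemplp", 4, 50L, 0.15, 0.25, ov = list(n_ants = 50L))
  expect_tab("chemplp", 4, 20L, 0.10, 0.25, ov = list(rho = 0.10))
  expect_tab("chemplp", 4, 20L, 0.25, 0.25, ov = list(rho = 0.25))
  expect_tab("chemplp", 4, 20L, 0.15, 1, ov = list(sigma = 1))
  expect_tab("plp", 4, 20L, 0.20, 0.5)
  expect_tab("plp95", 4, 20L, 0.20, 1.25)
  expect_error(resolve_defaults("plp", 2), "preset")
  expect_error(resolve_defaults("nonsense", 4), "preset")
  # iteration budget is divided by the speed setting
  expect_equal(resolve_defaults("chemplp", 4)$iterations, 25L)
  expect_equal(resolve_defaults("chemplp", 2)$iterations, 50L)
  expect_equal(resolve_defaults("chemplp", 1)$iterations, 100L)
})

test_that("pheromone initialization is uniform and within bounds", {
  spec <- make_box_spec(rbind(c(0, 0), c(360, 10)), c(12L, 5L),
                        c(TRUE, FALSE))
  ph <- init_pheromones(spec)
  for (i in 1:2) {
    pr <- selection_probabilities(ph$tau[[i]])
    expect_equal(pr, rep(1 / length(pr), length(pr)), tolerance = 1e-12)
    expect_true(all(ph$tau[[i]] >= ph$tau_min[i] - 1e-12))
    expect_true(all(ph$tau[[i]] <= ph$tau_max[i] + 1e-12))
  }
  single <- make_box_spec(rbind(0, 360), 1L, TRUE)
  expect_equal(selection_probabilities(init_pheromones(single)$tau[[1]]), 1)
})

test_that("interval selection follows trail-proportional probabilities", {
  expect_equal(select_interval(c(5, 0, 0, 0)), 1L)
  expect_error(select_interval(c(0, 0)), "degenerate")
  expect_equal(sum(selection_probabilities(runif(17))), 1, tolerance = 1e-12)

  # tau = (1, 3): frequencies within 3 binomial standard errors
  set.seed(21)
  n <- 1e5
  draws <- vapply(seq_len(n), function(i) select_interval(c(1, 3)), 1L)
  p_hat <- mean(draws == 2L)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(p_hat - 0.75), 3 * se)

  # uniform tau over 6: chi-square goodness of fit at alpha = 0.01
  draws6 <- vapply(seq_len(n), function(i) select_interval(rep(2, 6)), 1L)
  cs <- chisq.test(tabulate(draws6, 6))
  expect_gt(cs$p.value, 0.01)
})

test_that("ant sampling respects bounds and the trail distribution", {
  spec <- make_box_spec(rbind(c(0, -5), c(360, 5)), c(8L, 4L), c(TRUE, FALSE))
  ph <- init_pheromones(spec)
  ph$tau[[1]] <- c(8, 4, 2, 1, 1, 1, 1, 2)  # skewed trails
  ph$tau[[2]] <- c(1, 1, 6, 2)
  set.seed(31)
  n <- 5000
  ints <- matrix(0L, n, 2)
  in_bounds <- TRUE; in_cell <- TRUE
  for (k in seq_len(n)) {
    a <- sample_ant(ph, spec)
    in_bounds <- in_bounds &&
      all(a$x >= spec$bounds[1, ] & a$x <= spec$bounds[2, ])
    # the sampled value must lie inside the chosen interval
    in_cell <- in_cell &&
      assign_interval(a$x[1], spec$partitions[[1]]) == a$intervals[1]
    ints[k, ] <- a$intervals
  }
  expect_true(in_bounds)
  expect_true(in_cell)
  for (i in 1:2) {
    p <- selection_probabilities(ph$tau[[i]])
    emp <- tabulate(ints[, i], length(p)) / n
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(emp - p) < 4 * se + 1e-3))
  }
  # deterministic matrix: a single positive interval pins the sample
  ph$tau[[1]] <- c(0, 0, 0, 0, 0, 0, 1, 0) * 5
  ph$tau[[2]] <- c(0, 1, 0, 0)
  for (k in 1:50) {
    a <- sample_ant(ph, spec)
    expect_identical(a$intervals, c(7L, 2L))
  }
  # midpoint mode lands exactly on cell centers
  a <- sample_ant(ph, spec, sample_within = "midpoint")
  expect_equal(a$x[2], interval_midpoint(spec$partitions[[2]], 2L))
})

test_that("simplex refinement minimizes quadratics and never worsens", {
  spec <- make_box_spec(rbind(c(-5, -5), c(5, 5)), c(10L, 10L),
                        c(FALSE, FALSE))
  f <- function(x) sum((x - c(1.2, -2.3))^2)
  ls <- local_search(c(0.8, -2), f, spec, sigma = 1, budget = 300)
  expect_lt(max(abs(ls$s - c(1.2, -2.3))), 1e-3)
  expect_lte(ls$f_s, f(c(0.8, -2)))

  # constant objective: no false improvement
  lc <- local_search(c(1, 1), function(x) 7, spec, sigma = 1, budget = 50)
  expect_equal(lc$f_s, 7)

  # 20 random quadratics: at least as good as a reference simplex optimizer
  set.seed(41)
  for (k in 1:20) {
    ctr <- runif(2, -4, 4)
    w <- runif(2, 0.5, 3)
    fq <- function(x) sum(w * (x - ctr)^2)
    mine <- local_search(runif(2, -4, 4), fq, spec, sigma = 2, budget = 400)
    ref <- optim(mine$s * 0, fq, method = "Nelder-Mead")
    expect_lt(mine$f_s, ref$value + 1e-3)
    expect_lt(max(abs(mine$s - ctr)), 1e-2)
  }
  # rotational wrap: solution is reported inside [0, 360)
  rspec <- make_box_spec(rbind(0, 360), 12L, TRUE)
  fr <- function(x) 1 - cos((x - 350) * pi / 180)
  lr <- local_search(340, fr, rspec, sigma = 2, budget = 200)
  expect_true(lr$s >= 0 && lr$s < 360)
  expect_lt(fr(lr$s), 1e-4)
  expect_error(local_search(c(0, 0), f, spec, sigma = 1, budget = 2),
               "budget")
})

test_that("deposit neighborhoods match an exhaustive window table", {
  n <- 12L
  prot <- build_partition(0, 360, 360 / n)
  ptrn <- build_partition(-6, 6, 1)
  # hand-coded membership: interval j of the solution entitles interval l
  # iff j is within 2 (rotational, wrapped) or 1 (translational, clipped)
  for (l in 1:n) {
    for (j in 1:n) {
      s <- interval_midpoint(prot, j)
      want <- as.numeric(min((j - l) %% n, (l - j) %% n) <= 2)
      expect_identical(deposit_indicator(l, s, prot, TRUE), want)
    }
  }
  for (l in 1:12) {
    for (j in 1:12) {
      s <- interval_midpoint(ptrn, j)
      want <- as.numeric(abs(j - l) <= 1)
      expect_identical(deposit_indicator(l, s, ptrn, FALSE), want)
    }
  }
})

test_that("pheromone update reproduces hand-computed trail values", {
  # 2 dofs x 4 intervals; rho = 0.15, f(s) = -5, s in interval 2 (rot) and
  # interval 3 (translational)
  spec <- make_box_spec(rbind(c(0, 0), c(360, 4)), c(4L, 4L), c(TRUE, FALSE))
  ph <- init_pheromones(spec)  # tau0 = 1 everywhere
  params <- resolve_defaults("chemplp", 4)  # rho = 0.15
  s <- c(interval_midpoint(spec$partitions[[1]], 2L),
         interval_midpoint(spec$partitions[[2]], 3L))
  got <- update_pheromones(ph, list(s = s, f_s = -5), spec, params)
  # by hand: evaporation 1 * 0.85 = 0.85; deposit +5 on the window
  # (rotational dof, 4 intervals: window of +/-2 around interval 2 wraps to
  # all four; translational: intervals 2,3,4); then bounds tau_max = 5/0.15
  # = 33.33, tau_min = 33.33/8 = 4.1667, and 0.85 clamps up to tau_min
  tmax <- 5 / 0.15
  tmin <- tmax / 8
  expect_equal(got$tau[[1]], rep(5.85, 4), tolerance = 1e-12)
  expect_equal(got$tau[[2]], c(tmin, 5.85, 5.85, 5.85), tolerance = 1e-9)
  expect_equal(got$tau_max, rep(tmax, 2), tolerance = 1e-12)
  expect_equal(got$tau_min, rep(tmin, 2), tolerance = 1e-12)
  expect_equal(got$t, 1L)

  # rho = 0, non-negative score: nothing changes
  p0 <- resolve_defaults("chemplp", 4, overrides = list(rho = 0))
  same <- update_pheromones(init_pheromones(spec), list(s = s, f_s = 2),
                            spec, p0)
  expect_equal(same$tau, init_pheromones(spec)$tau)

  # rho = 1, no deposit: everything lands on tau_min
  p1 <- resolve_defaults("chemplp", 4, overrides = list(rho = 1))
  ph1 <- init_pheromones(spec)
  ph1$dtau_best <- 5  # bounds already established by an earlier deposit
  drained <- update_pheromones(ph1, list(s = s, f_s = 0), spec, p1)
  expect_equal(drained$tau[[1]], rep(drained$tau_min[1], 4))
})

test_that("MAX-MIN clamping bounds hold over many random updates", {
  spec <- make_box_spec(rbind(c(0, -3), c(360, 3)), c(6L, 6L), c(TRUE, FALSE))
  params <- resolve_defaults("chemplp", 4)
  ph <- init_pheromones(spec)
  set.seed(51)
  violations <- 0L
  norm_err <- 0
  for (k in 1:10000) {
    s <- c(runif(1, 0, 360), runif(1, -3, 3))
    f_s <- runif(1, -30, 5)
    ph <- update_pheromones(ph, list(s = s, f_s = f_s), spec, params)
    for (i in 1:2) {
      if (any(ph$tau[[i]] < ph$tau_min[i] - 1e-9) ||
          any(ph$tau[[i]] > ph$tau_max[i] + 1e-9)) violations <- violations + 1L
    }
    norm_err <- max(norm_err,
                    abs(sum(selection_probabilities(ph$tau[[1]])) - 1))
  }
  expect_equal(violations, 0L)
  expect_lt(norm_err, 1e-12)
  expect_equal(ph$t, 10000L)
})

test_that("the optimizer is seed-reproducible with a monotone best trace", {
  spec <- make_box_spec(rbind(c(-4, 0), c(4, 360)), c(8L, 12L),
                        c(FALSE, TRUE))
  f <- function(x) (x[1] - 1.3)^2 + (1 - cos((x[2] - 200) * pi / 180)) - 2
  params <- resolve_defaults("chemplp", 4,
                             overrides = list(iterations = 15L,
                                              ls_budget = 10L))
  r1 <- aco_optimize(f, spec, params, seed = 7)
  r2 <- aco_optimize(f, spec, params, seed = 7)
  expect_identical(r1$best, r2$best)
  expect_identical(r1$trace, r2$trace)
  for (s in 1:5) {
    r <- aco_optimize(f, spec, params, seed = s, use_local_search = FALSE)
    expect_true(all(diff(r$best_trace) <= 0))
  }
})

test_that("trail mass concentrates on a strongly negative separable basin", {
  # sign test over seeds: the basin interval's selection probability after
  # the run exceeds its uniform starting level in most runs
  spec <- make_box_spec(rbind(c(-4, -4), c(4, 4)), c(8L, 8L), c(FALSE, FALSE))
  f <- function(x) 5 * sum((x - c(1.5, -2.5))^2) - 10
  params <- resolve_defaults("chemplp", 4,
                             overrides = list(iterations = 20L,
                                              stagnation = Inf))
  basin <- c(assign_interval(1.5, spec$partitions[[1]]),
             assign_interval(-2.5, spec$partitions[[2]]))
  wins <- 0
  for (s in 1:50) {
    r <- aco_optimize(f, spec, params, seed = s, use_local_search = FALSE)
    p1 <- selection_probabilities(r$pheromones$tau[[1]])[basin[1]]
    p2 <- selection_probabilities(r$pheromones$tau[[2]])[basin[2]]
    wins <- wins + (p1 > 1 / 8 && p2 > 1 / 8)
  }
  # two-sided binomial sign test against chance at alpha = 0.05
  expect_lt(binom.test(wins, 50, 0.5)$p.value, 0.05)
  expect_gt(wins, 25)
})

test_that("search speed divides the evaluation budget proportionally", {
  setup <- probe_grid_setup(seed = 3)
  counts <- sapply(c(1, 2, 4), function(sp) {
    params <- resolve_defaults("chemplp", sp,
                               overrides = list(ls_budget = 10L,
                                                stagnation = Inf))
    aco_optimize(setup$obj, setup$spec, params, seed = 5)$n_evaluations
  })
  # one iteration block of slack (ants * (1 + ls budget evaluations))
  block <- 20 * 11
  expect_lt(abs(counts[1] - 2 * counts[2]), 2 * block)
  expect_lt(abs(counts[2] - 2 * counts[3]), 2 * block)
  expect_lt(abs(counts[1] - 4 * counts[3]), 3 * block)
})
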