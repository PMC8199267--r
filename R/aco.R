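#' ACO search parameters and the preset defaults resolver
#'
#' The resolver encodes the shipped defaults of the docking engine: the
#' number of ants is 20 for every preset, while evaporation rate
#' \code{rho} (\code{aco_evap}) and simplex scale \code{sigma}
#' (\code{aco_sigma}) depend on the scoring function and the
#' \code{search_speed} setting (1, 2 or 4; higher is faster because the
#' iteration budget is \code{ceiling(base_iterations / search_speed)}):
#' \tabular{llll}{
#'   scoring \tab speed \tab rho \tab sigma \cr
#'   chemplp \tab 4 \tab 0.15 \tab 0.25 \cr
#'   chemplp \tab 2 \tab 0.20 \tab 0.5 \cr
#'   chemplp \tab 1 \tab 0.20 \tab 1.25 \cr
#'   plp     \tab 4 \tab 0.20 \tab 0.5 \cr
#'   plp95   \tab 4 \tab 0.20 \tab 1.25 \cr
#' }
#' \code{plp}/\code{plp95} presets are defined for speed 4 only; other
#' combinations raise a configuration error.  Explicit user settings
#' (\code{overrides}) replace the preset values.
#'
#' @param scoring_function one of \code{"chemplp"}, \code{"plp"},
#'   \code{"plp95"}.
#' @param search_speed 1, 2 or 4.
#' @param overrides named list of explicit settings (\code{n_ants},
#'   \code{rho}, \code{sigma}, \code{iterations}, \code{stagnation}, ...).
#' @return object of class \code{aco_params}.
#' @export
resolve_defaults <- function(scoring_function, search_speed = 4,
                             overrides = NULL) {
  key <- paste(scoring_function, search_speed, sep = "/")
  preset <- switch(key,
    "chemplp/4" = list(rho = 0.15, sigma = 0.25),
    "chemplp/2" = list(rho = 0.20, sigma = 0.5),
    "chemplp/1" = list(rho = 0.20, sigma = 1.25),
    "plp/4"     = list(rho = 0.20, sigma = 0.5),
    "plp95/4"   = list(rho = 0.20, sigma = 1.25),
    stop(sprintf("no default preset for scoring_function '%s' with search_speed %s",
                 scoring_function, search_speed), call. = FALSE))
  p <- list(n_ants = 20L, rho = preset$rho, sigma = preset$sigma,
            search_speed = as.integer(search_speed),
            base_iterations = 100L,
            iterations = as.integer(ceiling(100L / search_speed)),
            stagnation = 15L,
            ls_budget = 60L,
            seed = NULL,
            scoring_function = scoring_function)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
    if (!is.null(overrides$base_iterations) || !is.null(overrides$search_speed)) {
      if (is.null(overrides$iterations)) {
        p$iterations <- as.integer(ceiling(p$base_iterations / p$search_speed))
      }
    }
  }
  stopifnot(p$rho >= 0, p$rho <= 1, p$n_ants >= 1, p$iterations >= 1)
  structure(p, class = "aco_params")
}

#' Initialize a pheromone matrix
#'
#' One pheromone vector per degree of freedom, uniform at \code{tau0} over
#' the intervals, so the first iteration's selection probabilities are
#' uniform.  Trail bounds follow a MAX-MIN scheme: the upper bound is the
#' fixed point deposit/rho of the update recursion, estimated at run time
#' from the best deposit seen so far, and the lower bound is
#' \code{tau_max / (2 * n_intervals)}; before any deposit the bounds bracket
#' \code{tau0} itself.
#'
#' @param spec a \code{\link{build_dof_spec}} result (or any list with
#'   \code{partitions} and \code{rotational}).
#' @param tau0 initial trail level (default 1).
#' @return object of class \code{pheromone_matrix}: \code{tau} (list of
#'   numeric vectors), \code{tau_min}, \code{tau_max}, iteration counter
#'   \code{t}, running best deposit \code{dtau_best}.
#' @export
init_pheromones <- function(spec, tau0 = 1) {
  ni <- vapply(spec$partitions, function(p) p$n_intervals, 1L)
  structure(list(
    tau = lapply(ni, function(n) rep(tau0, n)),
    tau_min = tau0 / (2 * ni),
    tau_max = rep(tau0, length(ni)),
    t = 0L, dtau_best = 0, tau0 = tau0),
    class = "pheromone_matrix")
}

#' Pheromone-proportional interval selection
#'
#' Draws interval l with probability tau_l / sum(tau): the trail-following
#' rule of the ant system.
#'
#' @param tau_row non-negative pheromone vector for one dof.
#' @return integer interval index.
#' @export
select_interval <- function(tau_row) {
  s <- sum(tau_row)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate pheromone row (all zero)", call. = FALSE)
  }
  sample.int(length(tau_row), 1L, prob = tau_row)
}

#' Selection probabilities of one pheromone row
#' @param tau_row non-negative pheromone vector.
#' @return normalized probability vector (sums to 1).
#' @export
selection_probabilities <- function(tau_row) tau_row / sum(tau_row)

#' Sample one ant's pose vector
#'
#' Per dof: select an interval with \code{\link{select_interval}}, then draw
#' the continuous value uniformly within it (or take the midpoint when
#' \code{sample_within = "midpoint"}, used by grid-comparison oracles).
#'
#' @param ph a \code{\link{init_pheromones}} matrix.
#' @param spec the dof specification.
#' @param sample_within \code{"uniform"} or \code{"midpoint"}.
#' @return list with \code{x} (numeric dof vector) and \code{intervals}
#'   (chosen interval indices).
#' @export
sample_ant <- function(ph, spec, sample_within = c("uniform", "midpoint")) {
  sample_within <- match.arg(sample_within)
  n <- length(ph$tau)
  if (n != spec$n) stop("pheromone/spec dimension mismatch", call. = FALSE)
  l <- integer(n); x <- numeric(n)
  for (i in seq_len(n)) {
    l[i] <- select_interval(ph$tau[[i]])
    z <- spec$partitions[[i]]$boundaries
    x[i] <- if (sample_within == "uniform") {
      stats::runif(1, z[l[i]], z[l[i] + 1L])
    } else {
      (z[l[i]] + z[l[i] + 1L]) / 2
    }
  }
  list(x = x, intervals = l)
}

#' Deposit-neighborhood indicator
#'
#' Decides whether the refined solution component \code{s_component}
#' entitles interval \code{l} to a pheromone deposit.  The neighborhood
#' window around the solution is wider for rotational dofs (boundaries
#' z_{l-3}..z_{l+2}, i.e. the solution's interval plus two on either side,
#' wrapping at 0/360) than for translational dofs (z_{l-2}..z_{l+1}, one on
#' either side, clipped at the box edge).
#'
#' @param l candidate interval index.
#' @param s_component refined solution value for this dof.
#' @param p the dof's \code{\link{build_partition}}.
#' @param rotational logical.
#' @return 0 or 1.
#' @export
deposit_indicator <- function(l, s_component, p, rotational) {
  n <- p$n_intervals
  j <- assign_interval(s_component, p)
  off <- if (rotational) (j - l) %% n else j - l
  if (rotational) {
    # offsets -2..2 modulo n
    as.numeric(off <= 2 || off >= n - 2)
  } else {
    as.numeric(abs(off) <= 1)
  }
}

#' Evaporate, deposit, clamp
#'
#' The trail update: every entry decays by (1 - rho); intervals inside the
#' deposit neighborhood of the iteration-best refined solution receive
#' \code{abs(f(s))} when \code{f(s) < 0} (no deposit otherwise); finally all
#' entries are clamped into the MAX-MIN bounds, which are re-estimated from
#' the best deposit seen so far (\code{tau_max = dtau_best / rho} when
#' \code{rho > 0}).
#'
#' @param ph a \code{pheromone_matrix}.
#' @param best list with \code{s} (refined dof vector) and \code{f_s}
#'   (its score), the iteration-best ant.
#' @param spec the dof specification.
#' @param params an \code{\link{resolve_defaults}} parameter set (uses
#'   \code{rho}).
#' @return the updated \code{pheromone_matrix} (iteration counter advanced).
#' @export
update_pheromones <- function(ph, best, spec, params) {
  rho <- params$rho
  dtau <- if (best$f_s < 0) abs(best$f_s) else 0
  for (i in seq_along(ph$tau)) {
    tau <- ph$tau[[i]] * (1 - rho)
    if (dtau > 0) {
      p <- spec$partitions[[i]]
      dep <- vapply(seq_len(p$n_intervals), function(l) {
        deposit_indicator(l, best$s[i], p, spec$rotational[i])
      }, 1)
      tau <- tau + dep * dtau
    }
    ph$tau[[i]] <- tau
  }
  if (dtau > ph$dtau_best) ph$dtau_best <- dtau
  if (ph$dtau_best > 0 && rho > 0) {
    ni <- vapply(spec$partitions, function(p) p$n_intervals, 1L)
    ph$tau_max <- rep(ph$dtau_best / rho, length(ph$tau))
    ph$tau_min <- ph$tau_max / (2 * ni)
  }
  for (i in seq_along(ph$tau)) {
    ph$tau[[i]] <- pmin(pmax(ph$tau[[i]], ph$tau_min[i]), ph$tau_max[i])
  }
  ph$t <- ph$t + 1L
  ph
}

# canonicalize a dof vector: wrap rotational components modulo 360, clip
# translational components to their bounds
canonicalize_dof <- function(x, spec) {
  for (i in seq_len(spec$n)) {
    if (spec$rotational[i]) {
      x[i] <- x[i] %% 360
      if (x[i] == 360) x[i] <- 0
    } else {
      x[i] <- min(max(x[i], spec$bounds[1, i]), spec$bounds[2, i])
    }
  }
  x
}

#' Nelder-Mead simplex refinement of a sampled pose
#'
#' Derivative-free local minimization with an explicit evaluation budget.
#' The initial simplex is the start point plus one vertex per dof displaced
#' by \code{sigma} interval widths (\code{sigma * (b_i - a_i) / n_i});
#' rotational components are wrapped modulo 360 and translations clipped to
#' the box before every evaluation.  Standard coefficients (reflection 1,
#' expansion 2, contraction 0.5, shrink 0.5).  The returned solution never
#' scores worse than the start point.
#'
#' @param x start dof vector.
#' @param f objective (lower is better).
#' @param spec the dof specification.
#' @param sigma simplex scale in interval widths.
#' @param budget maximum number of objective evaluations (>= n + 1).
#' @return list with \code{s} (refined vector, canonicalized), \code{f_s},
#'   \code{evaluations}.
#' @export
local_search <- function(x, f, spec, sigma, budget = 60L) {
  n <- spec$n
  if (budget < n + 1L) stop("local search budget must be >= n + 1", call. = FALSE)
  evals <- 0L
  best_x <- canonicalize_dof(x, spec)
  fx <- f(best_x); evals <- evals + 1L
  best_f <- fx
  eval_f <- function(v) {
    cv <- canonicalize_dof(v, spec)
    val <- f(cv)
    evals <<- evals + 1L
    if (val < best_f) { best_f <<- val; best_x <<- cv }
    val
  }
  step <- sigma * (spec$bounds[2, ] - spec$bounds[1, ]) /
    vapply(spec$partitions, function(p) p$n_intervals, 1)
  simplex <- matrix(rep(x, n + 1L), nrow = n + 1L, byrow = TRUE)
  fv <- numeric(n + 1L)
  fv[1] <- fx
  for (i in seq_len(n)) {
    simplex[i + 1L, i] <- simplex[i + 1L, i] + step[i]
    if (evals >= budget) return(list(s = best_x, f_s = best_f, evaluations = evals))
    fv[i + 1L] <- eval_f(simplex[i + 1L, ])
  }
  while (evals < budget) {
    o <- order(fv)
    simplex <- simplex[o, , drop = FALSE]; fv <- fv[o]
    centroid <- colMeans(simplex[1:n, , drop = FALSE])
    xr <- centroid + 1 * (centroid - simplex[n + 1L, ])
    fr <- eval_f(xr)
    if (fr < fv[1]) {
      if (evals >= budget) break
      xe <- centroid + 2 * (centroid - simplex[n + 1L, ])
      fe <- eval_f(xe)
      if (fe < fr) { simplex[n + 1L, ] <- xe; fv[n + 1L] <- fe }
      else { simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr
    } else {
      if (evals >= budget) break
      xc <- centroid + 0.5 * (simplex[n + 1L, ] - centroid)
      fc <- eval_f(xc)
      if (fc < fv[n + 1L]) { simplex[n + 1L, ] <- xc; fv[n + 1L] <- fc }
      else {
        # shrink toward the best vertex
        for (i in 2:(n + 1L)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          if (evals >= budget) break
          fv[i] <- eval_f(simplex[i, ])
        }
      }
    }
    if (max(abs(fv - fv[1])) < 1e-10) break
  }
  list(s = best_x, f_s = best_f, evaluations = evals)
}

#' Core ant-colony optimization loop over a discretized box
#'
#' The engine behind \code{\link{run_aco}}, usable with any objective.
#' Each iteration samples \code{n_ants} poses from the pheromone
#' distribution, optionally refines each by simplex local search, updates
#' the trails with the iteration-best refined solution and tracks the global
#' best.  Fully reproducible from \code{seed}: per-(iteration, ant) RNG
#' substreams are derived arithmetically from it, so results do not depend
#' on ant evaluation order.
#'
#' @param f objective taking a dof vector, lower is better.
#' @param spec a dof specification (\code{\link{build_dof_spec}} or
#'   \code{\link{make_box_spec}}).
#' @param params an \code{\link{resolve_defaults}} parameter set.
#' @param seed integer seed.
#' @param use_local_search logical; when FALSE ants are scored as sampled
#'   (used by grid-oracle comparisons).
#' @param sample_within passed to \code{\link{sample_ant}}.
#' @return list: \code{best} (\code{x}, \code{intervals}, \code{s},
#'   \code{f_s}), per-iteration \code{trace} and non-increasing
#'   \code{best_trace}, \code{n_evaluations}, \code{iterations_run},
#'   final \code{pheromones}.
#' @export
aco_optimize <- function(f, spec, params, seed = 1L,
                         use_local_search = TRUE,
                         sample_within = "uniform") {
  ph <- init_pheromones(spec)
  n_eval <- 0L
  fcount <- function(x) { n_eval <<- n_eval + 1L; f(x) }
  global_best <- NULL
  trace <- numeric(0)
  best_trace <- numeric(0)
  stagnant <- 0L
  iters_run <- 0L
  for (t in seq_len(params$iterations)) {
    iter_best <- NULL
    for (a in seq_len(params$n_ants)) {
      set.seed((as.numeric(seed) + 1000003 * t + 7919 * a) %% 2147483647)
      ant <- sample_ant(ph, spec, sample_within = sample_within)
      if (use_local_search) {
        ls <- local_search(ant$x, fcount, spec, params$sigma,
                           budget = params$ls_budget)
        sol <- list(x = ant$x, intervals = ant$intervals,
                    s = ls$s, f_s = ls$f_s)
      } else {
        fs <- fcount(ant$x)
        sol <- list(x = ant$x, intervals = ant$intervals, s = ant$x, f_s = fs)
      }
      if (is.null(iter_best) || sol$f_s < iter_best$f_s) iter_best <- sol
    }
    ph <- update_pheromones(ph, iter_best, spec, params)
    improved <- is.null(global_best) || iter_best$f_s < global_best$f_s
    if (improved) { global_best <- iter_best; stagnant <- 0L }
    else stagnant <- stagnant + 1L
    trace <- c(trace, iter_best$f_s)
    best_trace <- c(best_trace, global_best$f_s)
    iters_run <- t
    if (!is.null(params$stagnation) && is.finite(params$stagnation) &&
        stagnant >= params$stagnation) break
  }
  list(best = global_best, trace = trace, best_trace = best_trace,
       n_evaluations = n_eval, iterations_run = iters_run,
       pheromones = ph)
}

#' Box-and-partition specification for generic objectives
#'
#' Builds the same structure as \code{\link{build_dof_spec}} for an
#' arbitrary box, so the ACO engine and its oracles can run on toy
#' objectives without a molecule.
#'
#' @param bounds 2 x n matrix of lower/upper bounds.
#' @param n_intervals integer vector of interval counts per dof.
#' @param rotational logical vector per dof.
#' @return a \code{dof_spec}-shaped list.
#' @export
make_box_spec <- function(bounds, n_intervals, rotational) {
  n <- ncol(bounds)
  stopifnot(length(n_intervals) == n, length(rotational) == n)
  partitions <- lapply(seq_len(n), function(i) {
    build_partition(bounds[1, i], bounds[2, i],
                    (bounds[2, i] - bounds[1, i]) / n_intervals[i])
  })
  structure(list(bounds = bounds, rotational = rotational,
                 partitions = partitions, n = n,
                 rot_bonds = integer(), branches = list(), sphere = NULL),
            class = "dof_spec")
}

#' Dock one ligand with the ant-colony engine
#'
#' Builds the ligand's degree-of-freedom space inside the scenario's
#' docking sphere, then runs \code{\link{aco_optimize}} with the scenario's
#' scoring function as the objective.
#'
#' @param receptor receptor \code{\link{molecule}}.
#' @param ligand ligand \code{\link{molecule}}.
#' @param scenario a \code{\link{docking_scenario}}.
#' @param seed integer seed (overrides the scenario's).
#' @return the \code{\link{aco_optimize}} result plus \code{score}
#'   (best total), \code{breakdown} (full \code{score_breakdown} of the
#'   best pose), \code{pose_xyz} (its coordinates) and \code{spec}.
#' @export
run_aco <- function(receptor, ligand, scenario, seed = NULL) {
  if (is.null(seed)) seed <- if (!is.null(scenario$aco$seed)) scenario$aco$seed else 1L
  spec <- build_dof_spec(ligand, scenario$sphere,
                         angular_step = scenario$angular_step,
                         linear_step = scenario$linear_step)
  if (scenario$sphere$radius <= 0) stop("zero-volume search box", call. = FALSE)
  cache <- score_cache(receptor, ligand, scenario$params)
  obj <- function(x) {
    score_pose(receptor, ligand, x, scenario$params, spec, cache)$total
  }
  res <- aco_optimize(obj, spec, scenario$aco, seed = seed,
                      use_local_search = isTRUE(scenario$use_local_search),
                      sample_within = scenario$sample_within %||% "uniform")
  res$score <- res$best$f_s
  res$breakdown <- score_pose(receptor, ligand, res$best$s, scenario$params,
                              spec, cache)
  res$pose_xyz <- apply_pose(ligand, res$best$s, spec)
  res$spec <- spec
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
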