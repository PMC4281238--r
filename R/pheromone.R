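# Lattice alarm-pheromone escape model.
#
# Square lattice of L x L loci, two exits (runs of boundary loci) centred on
# the left and right edges. Each time step: every active ant deposits a
# constant amount of pheromone on its locus, every locus evaporates a
# constant amount (clamped at zero), then each ant senses the clipped
# pheromone maximum over its Moore-8 neighbourhood, turns toward it, moves
# exactly one locus (reflecting at the boundary), and escapes if an exit
# locus is within its detection range.
#
# Coordinates are 0-based (x = column, y = row). A single RNG stream drives
# everything in a documented order: initialisation (per ant: x, y, heading),
# then per step, per active ant in index order, one draw per sensing event
# with two or more tied maxima. The compiled runner in src/ consumes the
# stream identically, so an R-stepped world and a compiled run agree
# locus-for-locus under the same seed.

# the 8 Moore directions in fixed scan order (shared with the compiled code)
MOORE_DIRS <- matrix(as.integer(c(-1, -1, -1, 0, -1, 1,
                                  0, -1, 0, 1,
                                  1, -1, 1, 0, 1, 1)),
                     ncol = 2, byrow = TRUE,
                     dimnames = list(NULL, c("dx", "dy")))

#' Configuration of the lattice alarm-pheromone model
#'
#' Physical scale: the lattice side `L` is fixed so one locus matches one ant
#' body length (cell 8.0 cm across, body 0.39 cm, hence L = 20), and one time
#' step is the time to cross one locus at the measured walking speed
#' (0.94 cm/s), about 0.43 s. Pheromone amounts are relative: the perception
#' threshold `threshold` is the reference value 1, and the per-step deposit
#' `eta` and evaporation `kappa` must not exceed it. `kappa` is usually given
#' indirectly through the fade-out time `tau_s` (seconds for a locus at
#' threshold to evaporate to zero) via [tau_to_kappa()].
#'
#' @param L Lattice side in loci (default 20).
#' @param eta Pheromone deposited per ant per step (default 0.5).
#' @param tau_s Pheromone fade-out time in seconds (default 60); ignored if
#'   `kappa` is given directly.
#' @param kappa Pheromone evaporated per locus per step; default derived
#'   from `tau_s`.
#' @param threshold Perception saturation level (default 1): neighbouring
#'   loci holding more than this are indistinguishable and tie.
#' @param exit_width_cm Physical exit width (default 1.0 cm), mapped to
#'   `ceiling(exit_width_cm / locus_cm)` contiguous boundary loci centred on
#'   each of the left and right edges.
#' @param max_steps Step cap per run (default 20000).
#' @param cell_cm,body_length_cm,speed_cm_s Physical constants of the
#'   experimental cell and ants.
#' @return A list of class `pheromone_config`.
#' @export
pheromone_config <- function(L = 20L, eta = 0.5, tau_s = 60, kappa = NULL,
                             threshold = 1, exit_width_cm = 1.0,
                             max_steps = 20000L, cell_cm = 8.0,
                             body_length_cm = 0.39, speed_cm_s = 0.94) {
  if (L < 5 || L != round(L)) stop("`L` must be an integer >= 5", call. = FALSE)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  if (is.null(kappa))
    kappa <- tau_to_kappa(tau_s, threshold = threshold, L = L,
                          cell_cm = cell_cm, speed_cm_s = speed_cm_s)
  if (eta <= 0 || kappa <= 0)
    stop("`eta` and `kappa` must be positive", call. = FALSE)
  if (eta > threshold || kappa > threshold)
    stop("`eta` and `kappa` must not exceed `threshold`", call. = FALSE)
  if (max_steps < 1) stop("`max_steps` must be positive", call. = FALSE)
  locus_cm <- cell_cm / L
  exit_w <- as.integer(ceiling(exit_width_cm / locus_cm))
  structure(list(L = as.integer(L), eta = eta, kappa = kappa,
                 threshold = threshold, exit_width_loci = exit_w,
                 exit_rows = exit_row_indices(as.integer(L), exit_w),
                 max_steps = as.integer(max_steps), tau_s = tau_s,
                 cell_cm = cell_cm, body_length_cm = body_length_cm,
                 speed_cm_s = speed_cm_s),
            class = "pheromone_config")
}

# 0-based row indices of the exit loci, centred on the edge
exit_row_indices <- function(L, width) {
  centre <- (L - 1L) %/% 2L
  start <- centre - (width - 1L) %/% 2L
  rows <- start + 0:(width - 1L)
  if (any(rows < 0L | rows >= L))
    stop("exit wider than the lattice edge", call. = FALSE)
  rows
}

#' Convert a pheromone fade-out time to a per-step evaporation amount
#'
#' One simulation step lasts `locus_cm / speed` seconds (the time for an ant
#' to cross one locus), so a locus holding the threshold amount fades to zero
#' in `threshold / kappa` steps. Requiring that fade-out to span `tau_s`
#' seconds gives `kappa = threshold * dt / tau_s`. With the default physical
#' constants (8 cm cell, L = 20, 0.94 cm/s) one step is about 0.4255 s and
#' `tau_s = 60` gives `kappa` of about 0.00709.
#'
#' @param tau_s Fade-out time in seconds (> 0).
#' @param threshold Perception threshold (default 1).
#' @param L Lattice side (default 20).
#' @param cell_cm Physical cell side (default 8.0).
#' @param speed_cm_s Ant walking speed (default 0.94).
#' @return The evaporation amount per locus per step.
#' @export
tau_to_kappa <- function(tau_s, threshold = 1, L = 20L, cell_cm = 8.0,
                         speed_cm_s = 0.94) {
  if (length(tau_s) != 1L || !is.finite(tau_s) || tau_s <= 0)
    stop("`tau_s` must be a positive number of seconds", call. = FALSE)
  dt <- (cell_cm / L) / speed_cm_s
  threshold * dt / tau_s
}

#' Initialise a pheromone world
#'
#' Places `n_ants` ants on uniformly random loci (multiple occupancy is
#' allowed) with headings uniform over the 8 lattice directions, over an
#' all-zero pheromone field.
#'
#' @param config A [pheromone_config()].
#' @param n_ants Number of ants (>= 1).
#' @param seed Optional integer seed.
#' @return A list of class `pheromone_world` with elements `field` (L x L
#'   matrix, `field[x+1, y+1]`), `pos` and `vel` (n x 2 integer matrices,
#'   0-based positions), `active` (logical), `escaped_left`, `escaped_right`,
#'   `step_count`, `config`.
#' @export
init_world <- function(config = pheromone_config(), n_ants, seed = NULL) {
  stopifnot(inherits(config, "pheromone_config"))
  if (length(n_ants) != 1L || n_ants < 1 || n_ants != round(n_ants))
    stop("`n_ants` must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- config$L
  n_ants <- as.integer(n_ants)
  pos <- matrix(0L, n_ants, 2)
  vel <- matrix(0L, n_ants, 2)
  for (i in seq_len(n_ants)) {
    pos[i, 1] <- as.integer(min(floor(runif(1) * L), L - 1L))
    pos[i, 2] <- as.integer(min(floor(runif(1) * L), L - 1L))
    d <- min(floor(runif(1) * 8), 7) + 1L
    vel[i, ] <- MOORE_DIRS[d, ]
  }
  structure(list(field = matrix(0, L, L), pos = pos, vel = vel,
                 active = rep(TRUE, n_ants),
                 escaped_left = 0L, escaped_right = 0L,
                 step_count = 0L, config = config),
            class = "pheromone_world")
}

#' Elementary world updates
#'
#' `deposit()` adds the per-ant deposit to every active ant's locus (k
#' co-located ants add k deposits); `evaporate()` removes the evaporation
#' amount from every locus, clamping at zero. Exposed mainly for testing and
#' for building custom update schemes; [step_world()] composes them.
#'
#' @param world A `pheromone_world`.
#' @param eta,kappa Override the config amounts (defaults from the world's
#'   config).
#' @return The updated world.
#' @export
deposit <- function(world, eta = world$config$eta) {
  for (i in which(world$active)) {
    x <- world$pos[i, 1] + 1L
    y <- world$pos[i, 2] + 1L
    world$field[x, y] <- world$field[x, y] + eta
  }
  world
}

#' @rdname deposit
#' @export
evaporate <- function(world, kappa = world$config$kappa) {
  world$field <- pmax(world$field - kappa, 0)
  world
}

#' Sense the pheromone gradient around one ant
#'
#' Examines the up-to-8 Moore neighbours of the ant's locus (loci outside
#' the lattice are ignored; the ant's own locus is not in its detection
#' range). Each neighbouring amount is first clipped at the perception
#' threshold — amounts above it are indistinguishable. If every clipped
#' value is zero there is nothing to sense and `NULL` is returned; otherwise
#' the unit-step vector toward a locus attaining the clipped maximum is
#' returned, with ties broken uniformly at random from the run's RNG stream.
#'
#' @param world A `pheromone_world`.
#' @param i Ant index.
#' @return Integer `c(gx, gy)` with components in `{-1, 0, 1}`, or `NULL`.
#' @export
sense_gradient <- function(world, i) {
  L <- world$config$L
  Tthr <- world$config$threshold
  x <- world$pos[i, 1]; y <- world$pos[i, 2]
  best <- 0
  tied <- integer(0)
  for (d in seq_len(8)) {
    nx <- x + MOORE_DIRS[d, 1]; ny <- y + MOORE_DIRS[d, 2]
    if (nx < 0 || nx >= L || ny < 0 || ny >= L) next
    v <- min(world$field[nx + 1L, ny + 1L], Tthr)
    if (v > best) {
      best <- v
      tied <- d
    } else if (v == best && v > 0) {
      tied <- c(tied, d)
    }
  }
  if (best <= 0) return(NULL)
  d <- if (length(tied) == 1L) tied else
    tied[min(floor(runif(1) * length(tied)), length(tied) - 1) + 1L]
  MOORE_DIRS[d, ]
}

#' Sign quantiser for lattice velocities
#'
#' Maps a real to `{-1, 0, 1}` by sign, keeping every move exactly one locus
#' per step when applied componentwise to the velocity update.
#'
#' @param x Finite numeric vector.
#' @return Integer vector of signs.
#' @export
bracket <- function(x) {
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  as.integer(sign(x))
}

#' Move one ant for one step
#'
#' If no gradient was sensed the ant keeps its heading (pure persistence);
#' otherwise the new velocity is `bracket(vel + g)` componentwise, and a
#' `(0, 0)` result (gradient exactly opposing the heading) is repaired by
#' keeping the previous heading, since a stationary velocity is not allowed.
#' The ant then advances one locus; a component that would leave the lattice
#' is reflected (velocity component negated, position mirrored inside).
#'
#' @param world A `pheromone_world`.
#' @param i Ant index.
#' @param g Sensed direction from [sense_gradient()], or `NULL`.
#' @return The updated world.
#' @export
move_ant <- function(world, i, g = NULL) {
  L <- world$config$L
  v <- world$vel[i, ]
  if (!is.null(g)) {
    v_new <- bracket(v + g)
    if (all(v_new == 0L)) v_new <- v
    v <- v_new
  }
  p <- world$pos[i, ] + v
  for (k in 1:2) {
    if (p[k] < 0L) {
      p[k] <- -p[k]
      v[k] <- -v[k]
    } else if (p[k] > L - 1L) {
      p[k] <- 2L * (L - 1L) - p[k]
      v[k] <- -v[k]
    }
  }
  world$pos[i, ] <- p
  world$vel[i, ] <- v
  world
}

#' Check whether an ant has reached an exit
#'
#' An ant escapes as soon as any exit locus lies within its detection range:
#' its Moore-8 neighbourhood or the locus it stands on. Returns the exit
#' side and deactivates the ant in the returned world.
#'
#' @param world A `pheromone_world`.
#' @param i Ant index.
#' @return A list with `side` (`"none"`, `"left"` or `"right"`) and `world`.
#' @export
check_escape <- function(world, i) {
  L <- world$config$L
  x <- world$pos[i, 1]; y <- world$pos[i, 2]
  near_rows <- any(abs(y - world$config$exit_rows) <= 1L)
  side <- "none"
  if (near_rows && x <= 1L) side <- "left"
  else if (near_rows && x >= L - 2L) side <- "right"
  if (side == "left") {
    world$escaped_left <- world$escaped_left + 1L
    world$active[i] <- FALSE
  } else if (side == "right") {
    world$escaped_right <- world$escaped_right + 1L
    world$active[i] <- FALSE
  }
  list(side = side, world = world)
}

#' Advance a pheromone world by one step
#'
#' One synchronous update: deposit by all active ants, evaporation on every
#' locus, then each active ant in index order senses, moves and is checked
#' for escape. The field is fixed during the ant sweep (deposits take effect
#' the following step).
#'
#' @param world A `pheromone_world`.
#' @return The updated world, `step_count` incremented.
#' @export
step_world <- function(world) {
  world <- deposit(world)
  world <- evaporate(world)
  for (i in which(world$active)) {
    g <- sense_gradient(world, i)
    world <- move_ant(world, i, g)
    esc <- check_escape(world, i)
    world <- esc$world
  }
  world$step_count <- world$step_count + 1L
  world
}

#' Run one pheromone-model escape
#'
#' Initialises a world and steps it (in compiled code) until every ant has
#' escaped or `max_steps` is reached. Runs that hit the cap are flagged
#' `truncated`; their counts cover escaped ants only.
#'
#' @param n_ants Number of ants.
#' @param config A [pheromone_config()].
#' @param seed Optional integer seed.
#' @return A list with `n_left`, `n_right`, `n_escaped`, `steps`,
#'   `truncated`.
#' @examples
#' run_pheromone_escape(10, seed = 1)
#' @export
run_pheromone_escape <- function(n_ants, config = pheromone_config(),
                                 seed = NULL) {
  stopifnot(inherits(config, "pheromone_config"))
  if (length(n_ants) != 1L || n_ants < 1 || n_ants != round(n_ants))
    stop("`n_ants` must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- run_pheromone_cpp(config$L, config$eta, config$kappa,
                           config$threshold, config$exit_rows,
                           as.integer(n_ants), config$max_steps)
  list(n_left = res$n_left, n_right = res$n_right,
       n_escaped = res$n_left + res$n_right,
       steps = res$steps, truncated = res$truncated)
}

#' Monte-Carlo ensemble of pheromone-model escapes
#'
#' @param n_ants Number of ants per run.
#' @param runs Number of independent runs.
#' @param config A [pheromone_config()].
#' @param seed Optional integer seed (one stream across all runs).
#' @return A data.frame with one row per run: `run_id`, `n_requested`,
#'   `n_escaped`, `n_left`, `n_right`, `steps`, `truncated`.
#' @seealso [summarise_runs()] for mean collective asymmetry with its SE.
#' @export
simulate_pheromone <- function(n_ants, runs, config = pheromone_config(),
                               seed = NULL) {
  stopifnot(inherits(config, "pheromone_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", runs)
  for (r in seq_len(runs)) {
    res <- run_pheromone_cpp(config$L, config$eta, config$kappa,
                             config$threshold, config$exit_rows,
                             as.integer(n_ants), config$max_steps)
    out[[r]] <- data.frame(run_id = r, n_requested = as.integer(n_ants),
                           n_escaped = res$n_left + res$n_right,
                           n_left = res$n_left, n_right = res$n_right,
                           steps = res$steps, truncated = res$truncated)
  }
  do.call(rbind, out)
}

#' Step a world in compiled code (for cross-validation)
#'
#' Runs the compiled simulator for at most `max_steps` steps and returns the
#' full final state, consuming the RNG stream exactly as the R-level
#' [step_world()] loop does. Used to verify that the compiled and R
#' implementations produce identical trajectories.
#'
#' @param config A [pheromone_config()].
#' @param n_ants Number of ants.
#' @param max_steps Steps to run.
#' @param seed Optional integer seed.
#' @return A list with `field`, `pos`, `vel`, `active`, `n_left`, `n_right`,
#'   `steps`, `truncated`.
#' @keywords internal
#' @export
run_pheromone_state <- function(config, n_ants, max_steps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_pheromone_cpp(config$L, config$eta, config$kappa, config$threshold,
                    config$exit_rows, as.integer(n_ants),
                    as.integer(max_steps))
}
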