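# Vicsek-like alignment escape model in a circular two-exit arena.
#
# Point particles move at constant speed inside a disc. Each step every
# particle blends its own heading with the mean heading of neighbours within
# an interaction radius (weight beta), advances, reflects specularly off the
# wall, and escapes on coming within a capture radius of either of two exit
# points on the boundary (left at angle pi, right at angle 0). The update is
# noise-free and synchronous; stochasticity enters only through the random
# initial positions and headings.

#' Configuration of the Vicsek-like arena model
#'
#' @param radius_cm Arena radius (default 4.0, an 8 cm cell).
#' @param beta Alignment weight in `[0, 1]`; 0 gives independent particles.
#' @param interact_radius_cm Neighbourhood radius for alignment.
#' @param capture_radius_cm Escape distance from an exit point (default 0.5,
#'   half a 1 cm exit).
#' @param speed_cm_per_step Distance travelled per step (default 0.4, one
#'   body-scale hop, commensurate with the lattice model's step).
#' @param exit_angles Two boundary angles in radians, left then right
#'   (default `c(pi, 0)`).
#' @param max_steps Step cap per run.
#' @return A list of class `vicsek_config`.
#' @export
vicsek_config <- function(radius_cm = 4.0, beta = 0.8,
                          interact_radius_cm = 3.75,
                          capture_radius_cm = 0.5,
                          speed_cm_per_step = 0.4,
                          exit_angles = c(pi, 0),
                          max_steps = 10000L) {
  if (beta < 0 || beta > 1) stop("`beta` must lie in [0, 1]", call. = FALSE)
  if (radius_cm <= 0 || interact_radius_cm < 0 || capture_radius_cm <= 0 ||
      speed_cm_per_step <= 0)
    stop("radii and speed must be positive", call. = FALSE)
  if (capture_radius_cm >= radius_cm)
    stop("`capture_radius_cm` must be smaller than the arena radius",
         call. = FALSE)
  if (length(exit_angles) != 2L)
    stop("`exit_angles` must give exactly two exits", call. = FALSE)
  structure(list(radius = radius_cm, beta = beta,
                 interact_radius = interact_radius_cm,
                 capture_radius = capture_radius_cm,
                 speed = speed_cm_per_step,
                 exit_angles = exit_angles,
                 max_steps = as.integer(max_steps)),
            class = "vicsek_config")
}

#' Alignment heading update
#'
#' New heading = normalise(`(1 - beta) * own + beta * mean of neighbour
#' headings`). A particle with no neighbours keeps its heading, as does one
#' whose combination cancels to the zero vector.
#'
#' @param heading Unit 2-vector, the particle's current heading.
#' @param neighbour_headings Matrix with one unit heading per row (possibly
#'   zero rows), the neighbours within the interaction radius.
#' @param beta Alignment weight in `[0, 1]`.
#' @return A unit 2-vector.
#' @export
alignment_update <- function(heading, neighbour_headings, beta) {
  if (is.null(neighbour_headings) || NROW(neighbour_headings) == 0L)
    return(heading)
  nb <- matrix(neighbour_headings, ncol = 2)
  v <- (1 - beta) * heading + beta * colMeans(nb)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(heading)
  v / nv
}

#' Advance one particle inside the disc with specular wall reflection
#'
#' Moves a particle by `speed` along its heading; if the move crosses the
#' arena boundary the trajectory is reflected specularly about the boundary
#' normal at the crossing point (repeatedly, for grazing multi-bounce
#' steps), preserving speed. The returned position is strictly inside the
#' disc.
#'
#' @param pos Numeric 2-vector, current position with `|pos| <= radius`.
#' @param heading Unit 2-vector.
#' @param speed Step length.
#' @param radius Arena radius.
#' @return A list with the new `pos` and `heading`.
#' @export
reflect_disc <- function(pos, heading, speed, radius) {
  d <- speed * heading
  inner <- radius * (1 - 1e-12)
  for (iter in 1:16) {
    pn <- pos + d
    if (sqrt(sum(pn^2)) <= inner) {
      pos <- pn
      break
    }
    a <- sum(d^2)
    b <- 2 * sum(pos * d)
    cc <- sum(pos^2) - radius^2
    disc <- max(b^2 - 4 * a * cc, 0)
    t <- (-b + sqrt(disc)) / (2 * a)
    t <- min(max(t, 0), 1)
    q <- pos + t * d
    nrm <- q / sqrt(sum(q^2))
    rem <- (1 - t) * d
    rem <- rem - 2 * sum(rem * nrm) * nrm
    pos <- q
    qn <- sqrt(sum(pos^2))
    if (qn >= inner) pos <- pos * (inner / qn)
    d <- rem
    if (sqrt(sum(d^2)) < 1e-15) break
  }
  nd <- sqrt(sum(d^2))
  if (nd > 1e-15) heading <- d / nd
  pn2 <- sqrt(sum(pos^2))
  if (pn2 > inner) pos <- pos * (inner / pn2)
  list(pos = pos, heading = heading)
}

exit_points <- function(config) {
  rbind(left = config$radius * c(cos(config$exit_angles[1]),
                                 sin(config$exit_angles[1])),
        right = config$radius * c(cos(config$exit_angles[2]),
                                  sin(config$exit_angles[2])))
}

#' Run one Vicsek-model escape
#'
#' Initialises `n_ants` particles uniformly in the disc with uniform random
#' headings and steps the compiled simulator until all have escaped or
#' `max_steps` is reached.
#'
#' @param n_ants Number of particles.
#' @param config A [vicsek_config()].
#' @param seed Optional integer seed.
#' @return A list with `n_left`, `n_right`, `n_escaped`, `steps`,
#'   `truncated`.
#' @export
run_vicsek_escape <- function(n_ants, config = vicsek_config(), seed = NULL) {
  stopifnot(inherits(config, "vicsek_config"))
  if (length(n_ants) != 1L || n_ants < 1 || n_ants != round(n_ants))
    stop("`n_ants` must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ex <- exit_points(config)
  res <- run_vicsek_cpp(config$radius, config$beta, config$interact_radius,
                        config$capture_radius, config$speed,
                        ex[1, ], ex[2, ], as.integer(n_ants),
                        config$max_steps)
  list(n_left = res$n_left, n_right = res$n_right,
       n_escaped = res$n_left + res$n_right,
       steps = res$steps, truncated = res$truncated)
}

#' Monte-Carlo ensemble of Vicsek-model escapes
#'
#' @inheritParams run_vicsek_escape
#' @param runs Number of independent runs.
#' @return A data.frame with the same per-run schema as
#'   [simulate_pheromone()].
#' @export
simulate_vicsek <- function(n_ants, runs, config = vicsek_config(),
                            seed = NULL) {
  stopifnot(inherits(config, "vicsek_config"))
  if (!is.null(seed)) set.seed(seed)
  ex <- exit_points(config)
  out <- vector("list", runs)
  for (r in seq_len(runs)) {
    res <- run_vicsek_cpp(config$radius, config$beta, config$interact_radius,
                          config$capture_radius, config$speed,
                          ex[1, ], ex[2, ], as.integer(n_ants),
                          config$max_steps)
    out[[r]] <- data.frame(run_id = r, n_requested = as.integer(n_ants),
                           n_escaped = res$n_left + res$n_right,
                           n_left = res$n_left, n_right = res$n_right,
                           steps = res$steps, truncated = res$truncated)
  }
  do.call(rbind, out)
}

#' Parameter sweep over alignment strength and interaction radius
#'
#' Runs a full factorial grid of alignment weights, interaction radii and
#' group sizes, summarising each cell by the mean collective asymmetry over
#' the requested replicate runs.
#'
#' @param betas,radii,n_values Non-empty numeric grids.
#' @param runs Replicate runs per grid cell.
#' @param config Base [vicsek_config()]; `beta` and `interact_radius` are
#'   overridden per cell.
#' @param seed Optional integer seed (one stream over the whole sweep).
#' @return A data.frame with columns `beta`, `r`, `n`, `runs`,
#'   `mean_delta_c`, `se`.
#' @export
vicsek_grid_sweep <- function(betas = c(0.2, 0.5, 0.8),
                              radii = c(0.6, 2.0, 3.75),
                              n_values = c(10L, 40L, 160L),
                              runs = 200L, config = vicsek_config(),
                              seed = NULL) {
  if (!length(betas) || !length(radii) || !length(n_values))
    stop("grids must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(beta = betas, r = radii, n = n_values,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$beta <- grid$beta[g]
    cfg$interact_radius <- grid$r[g]
    sim <- simulate_vicsek(grid$n[g], runs, cfg)
    s <- summarise_runs(sim)
    out[[g]] <- data.frame(beta = grid$beta[g], r = grid$r[g],
                           n = grid$n[g], runs = s$runs_used,
                           mean_delta_c = s$mean_delta_c, se = s$se)
  }
  do.call(rbind, out)
}

#' Initialise arena particles (for cross-validation)
#'
#' Draws positions uniformly over the disc (radius via the square-root
#' transform) and headings uniformly over angle, consuming the RNG stream in
#' the same order as the compiled runner (per particle: radial draw, angular
#' draw, heading draw).
#'
#' @param config A [vicsek_config()].
#' @param n_ants Number of particles.
#' @param seed Optional integer seed.
#' @return A list with `pos` and `heading` (n x 2 matrices).
#' @keywords internal
#' @export
init_arena <- function(config, n_ants, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(0, n_ants, 2)
  heading <- matrix(0, n_ants, 2)
  for (i in seq_len(n_ants)) {
    rr <- config$radius * sqrt(runif(1))
    th <- 2 * pi * runif(1)
    pos[i, ] <- rr * c(cos(th), sin(th))
    ha <- 2 * pi * runif(1)
    heading[i, ] <- c(cos(ha), sin(ha))
  }
  list(pos = pos, heading = heading)
}

#' Run the compiled Vicsek simulator and return full state
#'
#' @inheritParams run_vicsek_escape
#' @param max_steps Steps to run.
#' @return A list with `pos`, `heading`, `active`, `n_left`, `n_right`,
#'   `steps`, `truncated`.
#' @keywords internal
#' @export
run_vicsek_state <- function(config, n_ants, max_steps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ex <- exit_points(config)
  run_vicsek_cpp(config$radius, config$beta, config$interact_radius,
                 config$capture_radius, config$speed,
                 ex[1, ], ex[2, ], as.integer(n_ants),
                 as.integer(max_steps))
}
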