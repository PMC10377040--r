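#' Rate constants for the single-antibody model
#'
#' Bundles the six mass-action rate constants. In the pathogen variant the
#' antigen replicates at net rate `k1 - k5`; in the self-antigen variant
#' the antigen is held constant (replenished by the host) and `k1`, `k5`
#' are unused. `k4` is the regeneration coefficient: the rate at which
#' antigen-antibody complexes stimulate production of new antibody,
#' standing in for the strength of T-helper stimulation (small for
#' self-antigens, large for foreign antigens).
#'
#' @param k2 Association rate (> 0), per concentration per time.
#' @param k_minus2 Dissociation rate (>= 0), per time.
#' @param k3 Clearance rate of antigen-antibody complexes, per time.
#' @param k4 Complex-stimulated antibody regeneration rate, per time.
#' @param k6 Natural antibody decay rate, per time.
#' @param k1 Antigen replication rate (pathogen variant only), per time.
#' @param k5 Antigen degradation rate (pathogen variant only), per time.
#' @return A `model1_params` list.
#' @details Complex clearance should be markedly faster than natural
#'   antibody decay; a warning (not an error) is raised when `k3 <= k6`.
#' @export
model1_params <- function(k2, k_minus2 = 1e-18, k3 = 0.5, k4 = 0.1,
                          k6 = 0.02, k1 = 0, k5 = 0) {
  p <- list(k1 = k1, k2 = k2, k_minus2 = k_minus2, k3 = k3, k4 = k4,
            k5 = k5, k6 = k6)
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0, logical(1))]
  if (length(bad)) {
    stop("rate constants must be single finite nonnegative numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$k2 <= 0) stop("`k2` must be > 0", call. = FALSE)
  if (p$k3 <= p$k6) {
    warning("complex clearance k3 should significantly exceed antibody ",
            "decay k6", call. = FALSE)
  }
  class(p) <- "model1_params"
  p
}

check_state3 <- function(state) {
  if (!is.numeric(state) || length(state) != 3L || !all(is.finite(state))) {
    stop("state must be a finite numeric triple (x, y, z)", call. = FALSE)
  }
  unname(state)
}

#' Derivatives of the single-antibody pathogen system
#'
#' Mass-action kinetics of complex `x`, free antibody `y` and replicating
#' antigen `z`:
#' dx/dt = k2*y*z - k_minus2*x - k3*x,
#' dy/dt = k_minus2*x - k2*y*z + k4*x - k6*y,
#' dz/dt = k_minus2*x - k2*y*z - k5*z + k1*z.
#'
#' @param state Numeric triple `c(x, y, z)`.
#' @param params A [model1_params()] bundle.
#' @return Named derivative triple `c(dx, dy, dz)`.
#' @export
rhs_pathogen <- function(state, params) {
  s <- check_state3(state)
  x <- s[1]; y <- s[2]; z <- s[3]
  bind <- params$k2 * y * z
  diss <- params$k_minus2 * x
  c(dx = bind - diss - params$k3 * x,
    dy = diss - bind + params$k4 * x - params$k6 * y,
    dz = diss - bind - params$k5 * z + params$k1 * z)
}

#' Derivatives of the single-antibody self-antigen system
#'
#' Identical to [rhs_pathogen()] for the complex and antibody, but the
#' self-antigen is held exactly constant (consumption by binding is
#' balanced by host replenishment): dz/dt = 0.
#'
#' @inheritParams rhs_pathogen
#' @return Named derivative triple `c(dx, dy, dz)` with `dz = 0`.
#' @export
rhs_self <- function(state, params) {
  d <- rhs_pathogen(state, params)
  d["dz"] <- 0
  d
}

#' Rate constants for multi-antibody competition
#'
#' Several antibodies with distinct binding kinetics compete for one
#' replicating antigen. All antibodies share `k1`, `k3`, `k4`, `k5`,
#' `k6`; each has its own `k2`, `k_minus2`.
#'
#' @param k2,k_minus2 Numeric vectors, one entry per antibody.
#' @inheritParams model1_params
#' @return A `competition_params` list with `m` antibodies.
#' @export
competition_params <- function(k2, k_minus2, k1 = 0.1, k3 = 1, k4 = 2,
                               k5 = 0.02, k6 = 0.02) {
  if (length(k2) != length(k_minus2)) {
    stop("`k2` and `k_minus2` must have the same length", call. = FALSE)
  }
  stopifnot(all(k2 > 0), all(k_minus2 >= 0),
            k1 >= 0, k3 >= 0, k4 >= 0, k5 >= 0, k6 >= 0)
  p <- list(m = length(k2), k1 = k1, k2 = k2, k_minus2 = k_minus2,
            k3 = k3, k4 = k4, k5 = k5, k6 = k6)
  class(p) <- "competition_params"
  p
}

#' Derivatives of the multi-antibody competition system
#'
#' Natural mass-action generalization of the pathogen system: each
#' antibody j binds the shared antigen with its own `k2_j`, `k_minus2_j`,
#' and the antigen balance sums the binding and dissociation fluxes over
#' all antibodies. With a single antibody this reduces exactly to
#' [rhs_pathogen()].
#'
#' @param state List with numeric vectors `x`, `y` (length m) and scalar
#'   `z`.
#' @param params A [competition_params()] bundle.
#' @return List with `dx`, `dy` (length m) and `dz`.
#' @export
rhs_competition <- function(state, params) {
  x <- state$x; y <- state$y; z <- state$z
  if (length(x) != params$m || length(y) != params$m || length(z) != 1L) {
    stop("state dimensions do not match the number of antibodies",
         call. = FALSE)
  }
  bind <- params$k2 * y * z
  diss <- params$k_minus2 * x
  list(dx = bind - diss - params$k3 * x,
       dy = diss - bind + params$k4 * x - params$k6 * y,
       dz = (params$k1 - params$k5) * z + sum(diss - bind))
}

## Shared adaptive integration on a uniform output grid. The solver is
## lsoda (switches between stiff and non-stiff methods); a negative
## undershoot beyond -10*atol aborts rather than being clipped, so
## stiffness failures are not masked.
integrate_core <- function(state0, derivs, t_end, n_points, rtol, atol,
                           labels, model, n_classes = NA_integer_) {
  stopifnot(t_end > 0, n_points >= 2, rtol > 0, atol > 0)
  times <- seq(0, t_end, length.out = n_points)
  out <- deSolve::ode(y = state0, times = times, func = derivs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1]
  if (is.null(istate) || istate < 0 || nrow(out) < n_points) {
    last_t <- out[nrow(out), 1]
    stop(sprintf("integration failed at t = %.6g (istate = %s)",
                 last_t, istate), call. = FALSE)
  }
  states <- out[, -1, drop = FALSE]
  if (!all(is.finite(states))) {
    stop("integration produced non-finite states", call. = FALSE)
  }
  if (min(states) < -10 * atol) {
    stop(sprintf("integration undershot below -10*atol (min = %.3g)",
                 min(states)), call. = FALSE)
  }
  colnames(states) <- labels
  traj <- list(times = times, states = states, labels = labels,
               model = model, n_classes = n_classes)
  class(traj) <- "ab_trajectory"
  traj
}

#' Integrate the single-antibody model
#'
#' Solves the pathogen or self-antigen system with an adaptive,
#' stiffness-capable solver and samples the solution on a uniform grid.
#'
#' @param state0 Initial state `c(x, y, z)`, all components >= 0.
#' @param params A [model1_params()] bundle.
#' @param t_end Time horizon (> 0); time is dimensionless.
#' @param model `"self"` (constant antigen) or `"pathogen"` (replicating
#'   antigen).
#' @param n_points Number of uniformly spaced sample times (including 0).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return An `ab_trajectory`: list with `times`, a states matrix with
#'   columns `x`, `y`, `z`, and metadata.
#' @export
integrate_model1 <- function(state0, params, t_end,
                             model = c("self", "pathogen"),
                             n_points = 201, rtol = 1e-8, atol = 1e-6) {
  model <- match.arg(model)
  s0 <- check_state3(state0)
  if (any(s0 < 0)) stop("initial state must be nonnegative", call. = FALSE)
  rhs <- if (model == "self") rhs_self else rhs_pathogen
  derivs <- function(t, s, parms) list(unname(rhs(s, params)))
  integrate_core(s0, derivs, t_end, n_points, rtol, atol,
                 labels = c("x", "y", "z"),
                 model = paste0("model1_", model))
}

#' Integrate the multi-antibody competition model
#'
#' @param state0 List with vectors `x`, `y` (length m, >= 0) and scalar
#'   `z` (>= 0).
#' @param params A [competition_params()] bundle.
#' @inheritParams integrate_model1
#' @return An `ab_trajectory` with columns `x_1..x_m`, `y_1..y_m`, `z`.
#' @export
integrate_competition <- function(state0, params, t_end, n_points = 201,
                                  rtol = 1e-8, atol = 1e-6) {
  m <- params$m
  s0 <- c(state0$x, state0$y, state0$z)
  if (length(s0) != 2 * m + 1 || any(s0 < 0) || !all(is.finite(s0))) {
    stop("initial state must be nonnegative with x, y of length m and ",
         "scalar z", call. = FALSE)
  }
  derivs <- function(t, s, parms) {
    d <- rhs_competition(list(x = s[1:m], y = s[m + 1:m], z = s[2 * m + 1]),
                         params)
    list(c(d$dx, d$dy, d$dz))
  }
  integrate_core(s0, derivs, t_end, n_points, rtol, atol,
                 labels = c(paste0("x_", 1:m), paste0("y_", 1:m), "z"),
                 model = "model1_competition", n_classes = m)
}
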