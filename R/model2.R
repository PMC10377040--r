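#' Parameters for the nine-class repertoire model
#'
#' Couples an [affinity_grid()] and its [mutation_kernel()] with the
#' shared kinetic constants. Somatic hypermutation affects only the
#' production term `k4 * x_i`: a fraction `p` of newly produced antibody
#' is redistributed across the adjacent affinity classes according to the
#' kernel; existing antibodies never convert.
#'
#' @param grid An [affinity_grid()].
#' @param k3 Complex clearance rate, per time.
#' @param k4 Complex-stimulated regeneration rate, per time.
#' @param k6 Antibody decay rate, per time.
#' @param p Somatic hypermutation rate, in `[0, 1]`.
#' @param kernel Optional pre-built [mutation_kernel()]; rebuilt from the
#'   grid when omitted.
#' @param replicating If `TRUE`, the antigen replicates (foreign-antigen
#'   exploration variant): dz/dt gains `(k1 - k5) * z` plus the binding
#'   and dissociation fluxes. Default `FALSE`: the antigen is constant.
#' @param k1,k5 Antigen replication and degradation rates, used only when
#'   `replicating = TRUE`.
#' @return A `model2_params` list.
#' @export
model2_params <- function(grid, k3 = 0.5, k4 = 0.6, k6 = 0.02, p = 0,
                          kernel = NULL, replicating = FALSE,
                          k1 = 0, k5 = 0) {
  stopifnot(inherits(grid, "affinity_grid"))
  if (is.null(kernel)) kernel <- mutation_kernel(grid)
  stopifnot(inherits(kernel, "mutation_kernel"))
  if (kernel$n != grid$n) {
    stop("kernel and grid have different numbers of classes", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("somatic hypermutation rate `p` must be in [0, 1]", call. = FALSE)
  }
  stopifnot(k3 >= 0, k4 >= 0, k6 >= 0, k1 >= 0, k5 >= 0)
  out <- list(grid = grid, kernel = kernel, k3 = k3, k4 = k4, k6 = k6,
              p = p, replicating = isTRUE(replicating), k1 = k1, k5 = k5)
  class(out) <- "model2_params"
  out
}

check_state2 <- function(state, n) {
  if (!is.list(state) || is.null(state$x) || is.null(state$y) ||
      is.null(state$z)) {
    stop("state must be a list with `x`, `y` (length n) and scalar `z`",
         call. = FALSE)
  }
  if (length(state$x) != n || length(state$y) != n || length(state$z) != 1L) {
    stop(sprintf("state dimensions do not match the grid (n = %d)", n),
         call. = FALSE)
  }
  if (!all(is.finite(c(state$x, state$y, state$z)))) {
    stop("state must be finite", call. = FALSE)
  }
  state
}

#' Derivatives of the repertoire model with somatic hypermutation
#'
#' Per-class complex kinetics plus redistribution of newly produced
#' antibody across adjacent affinity classes:
#' dx_i/dt = k2_i*y_i*z - k_minus2_i*x_i - k3*x_i;
#' dy_i/dt = k_minus2_i*x_i - k2_i*y_i*z
#'   + ((1-p) + p*stay_i)*k4*x_i
#'   + p*inflow_{i+1->i}*k4*x_{i+1} + p*inflow_{i-1->i}*k4*x_{i-1}
#'   - k6*y_i;
#' dz/dt = 0 (constant antigen). The inflow probabilities are the kernel
#' entries of the neighbouring classes directed at class i; because each
#' kernel row sums to 1, redistribution conserves the total production
#' flux `k4 * sum(x)` exactly.
#'
#' @param state List with vectors `x`, `y` (length n) and scalar `z`.
#' @param params A [model2_params()] bundle.
#' @return List with `dx`, `dy` (length n) and `dz`.
#' @export
rhs_shm <- function(state, params) {
  n <- params$grid$n
  state <- check_state2(state, n)
  x <- state$x; y <- state$y; z <- state$z
  k2 <- params$grid$classes$k2
  km2 <- params$grid$classes$k_minus2
  S <- params$kernel$split
  p <- params$p; k4 <- params$k4

  bind <- k2 * y * z
  diss <- km2 * x
  dx <- bind - diss - params$k3 * x

  prod_flux <- k4 * x
  production <- ((1 - p) + p * S[, "p_stay"]) * prod_flux
  if (n > 1) {
    ## from the stronger neighbour i+1 moving weaker, and from the weaker
    ## neighbour i-1 moving stronger
    idx <- seq_len(n - 1)
    production[idx] <- production[idx] +
      p * S[idx + 1, "p_weaker"] * prod_flux[idx + 1]
    production[idx + 1] <- production[idx + 1] +
      p * S[idx, "p_stronger"] * prod_flux[idx]
  }
  dy <- diss - bind + production - params$k6 * y

  dz <- 0
  if (params$replicating) {
    dz <- (params$k1 - params$k5) * z + sum(diss - bind)
  }
  list(dx = dx, dy = dy, dz = dz)
}

#' Repertoire derivatives in a foreign-antigen environment
#'
#' Identical dynamics to [rhs_shm()]; intended for foreign-antigen
#' parameter sets, where the self/foreign distinction is carried entirely
#' by the elevated regeneration rate `k4`. The antigen stays constant
#' unless `params` was built with `replicating = TRUE`.
#'
#' @inheritParams rhs_shm
#' @return List with `dx`, `dy` and `dz`.
#' @export
rhs_shm_foreign <- function(state, params) {
  rhs_shm(state, params)
}

#' Integrate the repertoire model
#'
#' @param state0 List with nonnegative vectors `x`, `y` (length n) and
#'   scalar `z`.
#' @param params A [model2_params()] bundle.
#' @inheritParams integrate_model1
#' @return An `ab_trajectory` with columns `x_1..x_n`, `y_1..y_n`, `z`.
#' @export
integrate_shm <- function(state0, params, t_end, n_points = 201,
                          rtol = 1e-8, atol = 1e-6) {
  n <- params$grid$n
  state0 <- check_state2(state0, n)
  s0 <- c(state0$x, state0$y, state0$z)
  if (any(s0 < 0)) stop("initial state must be nonnegative", call. = FALSE)
  derivs <- function(t, s, parms) {
    d <- rhs_shm(list(x = s[1:n], y = s[n + 1:n], z = s[2 * n + 1]), params)
    list(c(d$dx, d$dy, d$dz))
  }
  integrate_core(s0, derivs, t_end, n_points, rtol, atol,
                 labels = c(paste0("x_", 1:n), paste0("y_", 1:n), "z"),
                 model = "model2", n_classes = n)
}
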