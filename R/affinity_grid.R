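#' Construct a discrete ladder of antibody affinity classes
#'
#' Binding affinity is discretized into `n` classes of equilibrium
#' dissociation constant Kd = k_minus2 / k2, spaced one decade apart in
#' log10(Kd). Classes are numbered in ascending binding strength: class 1
#' has the smallest association rate `k2` (weakest binder, largest Kd) and
#' class `n` the largest. All classes share the dissociation rate
#' `k_minus2`, so the log10(Kd) ladder descends by exactly one bin width
#' per class.
#'
#' The defaults reproduce the nine-class ladder used throughout the
#' shipped scenarios: k2 from 1e-13 to 1e-5 with k_minus2 = 1e-18, giving
#' log10(Kd) = -5, -6, ..., -13 with the class at -9 sitting on the mean
#' of the underlying Normal(`mu`, `sigma`^2) distribution of observed
#' antibody log10(Kd) values.
#'
#' @param n Number of affinity classes (>= 1).
#' @param k2_weakest,k2_strongest Association rates of the weakest and
#'   strongest classes. Must satisfy `k2_strongest / k2_weakest ==
#'   10^(n-1)` so classes are decade-spaced.
#' @param k_minus2 Shared dissociation rate (> 0).
#' @param mu,sigma Mean and standard deviation of the log10(Kd)
#'   distribution the repertoire is drawn from.
#' @return An object of class `affinity_grid`: a list with `classes` (a
#'   data frame with columns `index`, `log10_kd`, `k2`, `k_minus2`), `n`,
#'   `mu`, `sigma` and `bin_width`.
#' @examples
#' g <- affinity_grid()
#' g$classes$log10_kd      # -5, -6, ..., -13
#' @export
affinity_grid <- function(n = 9, k2_weakest = 1e-13, k2_strongest = 1e-5,
                          k_minus2 = 1e-18, mu = -9, sigma = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  stopifnot(k2_weakest > 0, k2_strongest > 0, k_minus2 > 0, sigma > 0)
  decades <- log10(k2_strongest / k2_weakest)
  if (abs(decades - (n - 1)) > 1e-8) {
    stop(sprintf(paste0(
      "classes must be decade-spaced: k2_strongest/k2_weakest must equal ",
      "10^(n-1) = 10^%d, got 10^%.6g"), n - 1L, decades), call. = FALSE)
  }
  k2 <- 10^seq(log10(k2_weakest), log10(k2_strongest), length.out = n)
  if (n == 1L) k2 <- k2_weakest
  log10_kd <- log10(k_minus2 / k2)
  grid <- list(
    classes = data.frame(index = seq_len(n), log10_kd = log10_kd,
                         k2 = k2, k_minus2 = rep(k_minus2, n)),
    n = n, mu = mu, sigma = sigma, bin_width = 1
  )
  class(grid) <- "affinity_grid"
  grid
}

#' @export
print.affinity_grid <- function(x, ...) {
  cat(sprintf("Affinity grid: %d classes, log10(Kd) ~ Normal(%g, %g^2)\n",
              x$n, x$mu, x$sigma))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

check_class_index <- function(grid, i) {
  if (!is.numeric(i) || any(i < 1) || any(i > grid$n) || any(i != round(i))) {
    stop(sprintf("class index out of range 1..%d", grid$n), call. = FALSE)
  }
  as.integer(i)
}

#' Probability mass of an affinity-class bin
#'
#' Mass of the Normal(`mu`, `sigma`^2) log10(Kd) distribution on the bin
#' `[log10_kd_i - w/2, log10_kd_i + w/2)` of class `i`, where `w` is the
#' grid's bin width. Masses over all bins sum to slightly less than 1;
#' the tails beyond the outermost bins are excluded.
#'
#' @param grid An [affinity_grid()].
#' @param i Class index (vectorized).
#' @return Probability mass (or masses) in `[0, 1]`.
#' @examples
#' bin_mass(affinity_grid(), 5)   # 0.3829, the central class
#' @export
bin_mass <- function(grid, i) {
  i <- check_class_index(grid, i)
  centre <- grid$classes$log10_kd[i]
  h <- grid$bin_width / 2
  stats::pnorm(centre + h, grid$mu, grid$sigma) -
    stats::pnorm(centre - h, grid$mu, grid$sigma)
}

#' Somatic-hypermutation transition probabilities for one class
#'
#' A mutated offspring of class `i` draws a new log10(Kd) from the grid's
#' Normal(`mu`, `sigma`^2) distribution. Mass falling inside class `i`'s
#' own bin is "stay"; all mass on the weaker-binding side (larger
#' log10(Kd)) is lumped into the single adjacent weaker class, and all
#' mass on the stronger-binding side into the single adjacent stronger
#' class. Mass that would leave the grid at either end is absorbed into
#' "stay", so the triple sums to 1 exactly.
#'
#' @inheritParams bin_mass
#' @return Named numeric vector `c(p_weaker, p_stay, p_stronger)`.
#' @examples
#' mutation_split(affinity_grid(), 6)  # 0.6915, 0.2417, 0.0668
#' @export
mutation_split <- function(grid, i) {
  i <- check_class_index(grid, i)
  stopifnot(length(i) == 1L)
  centre <- grid$classes$log10_kd[i]
  h <- grid$bin_width / 2
  ## weaker binding = larger log10(Kd); classes ascend in binding strength,
  ## so the weaker neighbour is i - 1 and the stronger neighbour is i + 1
  p_weaker <- stats::pnorm(centre + h, grid$mu, grid$sigma,
                           lower.tail = FALSE)
  p_stronger <- stats::pnorm(centre - h, grid$mu, grid$sigma)
  p_stay <- 1 - p_weaker - p_stronger
  if (i == 1L) {             # no weaker class on the grid
    p_stay <- p_stay + p_weaker
    p_weaker <- 0
  }
  if (i == grid$n) {         # no stronger class on the grid
    p_stay <- p_stay + p_stronger
    p_stronger <- 0
  }
  c(p_weaker = p_weaker, p_stay = p_stay, p_stronger = p_stronger)
}

#' Build the full mutation kernel for a grid
#'
#' Applies [mutation_split()] to every class. Row `i` of the kernel gives
#' the probabilities that a mutated offspring of class `i` moves one class
#' weaker, stays, or moves one class stronger.
#'
#' @param grid An [affinity_grid()].
#' @return An object of class `mutation_kernel`: a list with `n` and
#'   `split`, an `n` x 3 matrix with columns `p_weaker`, `p_stay`,
#'   `p_stronger`. Every row sums to 1.
#' @examples
#' mutation_kernel(affinity_grid())$split[6, ]
#' @export
mutation_kernel <- function(grid) {
  stopifnot(inherits(grid, "affinity_grid"))
  split <- t(vapply(seq_len(grid$n), function(i) mutation_split(grid, i),
                    numeric(3)))
  dimnames(split) <- list(NULL, c("p_weaker", "p_stay", "p_stronger"))
  kern <- list(n = grid$n, split = split)
  class(kern) <- "mutation_kernel"
  kern
}

#' @export
print.mutation_kernel <- function(x, ...) {
  cat(sprintf("Somatic-hypermutation kernel over %d affinity classes\n", x$n))
  print(round(x$split, 5))
  invisible(x)
}

#' Initial repertoire composition over the grid
#'
#' Distributes a total antibody concentration across the affinity classes
#' in proportion to their bin masses, emulating a naive repertoire whose
#' log10(Kd) values follow the grid's normal distribution. The fractions
#' sum to slightly less than 1 (tail mass outside the grid is dropped).
#'
#' @param grid An [affinity_grid()].
#' @param total Total antibody concentration (>= 0).
#' @return Numeric vector of length `grid$n`.
#' @examples
#' initial_composition(affinity_grid(), 1e6)  # 0.3829e6 in class 5
#' @export
initial_composition <- function(grid, total) {
  stopifnot(inherits(grid, "affinity_grid"))
  if (!is.numeric(total) || length(total) != 1L || total < 0) {
    stop("`total` must be a single nonnegative number", call. = FALSE)
  }
  total * bin_mass(grid, seq_len(grid$n))
}

#' Write the mutation kernel as CSV
#'
#' One row per affinity class with its kinetic constants and transition
#' probabilities, at full double precision.
#'
#' @param grid An [affinity_grid()].
#' @param file Path or connection passed to [utils::write.csv()]; `""`
#'   writes to standard output.
#' @param kernel Optional pre-built [mutation_kernel()]; rebuilt from the
#'   grid when omitted.
#' @return The exported data frame, invisibly.
#' @export
write_kernel_csv <- function(grid, file = "", kernel = NULL) {
  stopifnot(inherits(grid, "affinity_grid"))
  if (is.null(kernel)) kernel <- mutation_kernel(grid)
  stopifnot(inherits(kernel, "mutation_kernel"), kernel$n == grid$n)
  out <- data.frame(
    class_index = grid$classes$index,
    log10_kd = grid$classes$log10_kd,
    k2 = grid$classes$k2,
    k_minus2 = grid$classes$k_minus2,
    kernel$split
  )
  utils::write.csv(format(out, digits = 17, trim = TRUE), file = file,
                   row.names = FALSE, quote = FALSE)
  invisible(out)
}
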