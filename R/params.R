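#' Simulation parameters in reduced Lennard-Jones units
#'
#' Collects every model constant of the coarse-grained bead-spring force field
#' and the Langevin integrator.  Lengths are in \eqn{\sigma}, energies in
#' \eqn{\epsilon}, masses in \eqn{m}, and time in
#' \eqn{\tau = \sigma\sqrt{m/\epsilon}}.
#'
#' The WCA cutoff is fixed at \eqn{r_c = 2^{1/6}\sigma} so that the pair
#' potential is purely repulsive; it is derived from `sigma` and is not a free
#' parameter.  The friction coefficient and temperature default to the
#' standard Kremer-Grest choices \eqn{\gamma = 1\,m/\tau} and
#' \eqn{k_BT = 1\,\epsilon}.
#'
#' @param epsilon Energy scale \eqn{\epsilon}.
#' @param sigma Length scale \eqn{\sigma} (bead diameter).
#' @param mass Bead mass \eqn{m}.
#' @param kT Thermal energy \eqn{k_BT} in \eqn{\epsilon}.
#' @param gamma Langevin friction coefficient in \eqn{m/\tau}.
#' @param dt Integration time step in \eqn{\tau}.
#' @param f_ext Magnitude of the driving force, in \eqn{\epsilon\sigma^{-1}},
#'   applied along +x to every bead whose axial coordinate lies inside the
#'   pore.
#' @param k_fene FENE spring constant \eqn{k_b} in \eqn{\epsilon\sigma^{-2}}.
#' @param R0 Maximum FENE bond extension in \eqn{\sigma}.
#' @param skin Neighbour-list skin distance in \eqn{\sigma}.
#' @return An object of class `sim_params`: a named list of the above plus the
#'   derived WCA cutoff `r_c`.
#' @examples
#' p <- sim_params()
#' p$r_c  # 2^(1/6)
#' @export
sim_params <- function(epsilon = 1, sigma = 1, mass = 1, kT = 1, gamma = 1,
                       dt = 0.0025, f_ext = 1, k_fene = 30, R0 = 1.5,
                       skin = 0.4) {
  stopifnot(epsilon > 0, sigma > 0, mass > 0, kT >= 0, gamma >= 0,
            dt > 0, k_fene > 0, R0 > sigma, skin > 0)
  p <- list(epsilon = epsilon, sigma = sigma, mass = mass, kT = kT,
            gamma = gamma, dt = dt, f_ext = f_ext, k_fene = k_fene, R0 = R0,
            skin = skin, r_c = 2^(1 / 6) * sigma)
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Bead-spring simulation parameters (reduced LJ units)\n")
  cat(sprintf("  epsilon=%g sigma=%g mass=%g kT=%g gamma=%g\n",
              x$epsilon, x$sigma, x$mass, x$kT, x$gamma))
  cat(sprintf("  dt=%g tau   f_ext=%g eps/sigma   FENE: k=%g, R0=%g   r_c=%.6f\n",
              x$dt, x$f_ext, x$k_fene, x$R0, x$r_c))
  invisible(x)
}

# flat parameter list for the C++ engine
.engine_params <- function(params, pore = NULL) {
  list(dt = params$dt, gamma = params$gamma, kT = params$kT,
       mass = params$mass, epsilon = params$epsilon, sigma = params$sigma,
       k_fene = params$k_fene, R0 = params$R0, f_ext = params$f_ext,
       x_p = if (is.null(pore)) 0 else pore$x_p,
       pore_length = if (is.null(pore)) 4 else pore$pore_length,
       box_y = if (is.null(pore)) -1 else pore$box[1],
       box_z = if (is.null(pore)) -1 else pore$box[2],
       skin = params$skin)
}

#' FENE bond restoring force
#'
#' Magnitude of the finitely extensible nonlinear elastic (FENE) restoring
#' force \eqn{k_b r / (1 - (r/R_0)^2)} at bond length `r`.  This is the
#' attractive FENE term alone; in the force field it is combined with the WCA
#' repulsion acting on the same pair (Kremer-Grest convention), which supplies
#' the excluded-volume part.
#'
#' @param r Bond length(s) in \eqn{\sigma}; must satisfy \eqn{0 < r < R_0}.
#' @param params A [sim_params()] object.
#' @return Force magnitude(s) in \eqn{\epsilon\sigma^{-1}}.
#' @examples
#' fene_force(1.0)  # 54 at the default k = 30, R0 = 1.5
#' @export
fene_force <- function(r, params = sim_params()) {
  if (any(r <= 0)) stop("bond length must be positive")
  if (any(r >= params$R0))
    stop(sprintf("bond length >= R0 = %g: FENE force diverges (integration blow-up)",
                 params$R0))
  params$k_fene * r / (1 - (r / params$R0)^2)
}

#' WCA pair energy
#'
#' Purely repulsive truncated-and-shifted Lennard-Jones energy
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < r_c = 2^{1/6}\sigma}, and exactly zero beyond the cutoff.
#'
#' @param r Pair distance(s) in \eqn{\sigma}; must be positive.
#' @param params A [sim_params()] object.
#' @return Energy value(s) in \eqn{\epsilon}.
#' @examples
#' wca_energy(1)         # epsilon
#' wca_energy(2^(1/6))   # 0 at the cutoff
#' @export
wca_energy <- function(r, params = sim_params()) {
  if (any(r <= 0)) stop("pair distance must be positive")
  sr6 <- (params$sigma / r)^6
  e <- 4 * params$epsilon * (sr6^2 - sr6) + params$epsilon
  ifelse(r < params$r_c, e, 0)
}

# run `code` under a local, restored RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
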