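#' Carreau-Yasuda blood rheology parameters
#'
#' Shear-thinning viscosity model for whole blood,
#' \deqn{\mu(\dot\gamma) = (\mu_0-\mu_\infty)\,
#'   \bigl(1+(\lambda\dot\gamma)^a\bigr)^{(m-1)/a} + \mu_\infty,}
#' interpolating between the zero-shear plateau \eqn{\mu_0} and the
#' infinite-shear plateau \eqn{\mu_\infty}.  Defaults are the standard
#' literature values for blood used throughout the package
#' (\eqn{\mu_0=0.056} Pa s, \eqn{\mu_\infty=0.0035} Pa s,
#' \eqn{\lambda=1.902} s, \eqn{a=1.25}, \eqn{m=0.22}) with a density of
#' 1056 kg/m3.
#'
#' Setting `mu0 == mu_inf` gives a constant (Newtonian) viscosity; the solver
#' oracles use this degenerate mode.
#'
#' @param mu0 zero-shear viscosity (Pa s)
#' @param mu_inf infinite-shear viscosity (Pa s)
#' @param lambda_cy time constant (s)
#' @param a Yasuda exponent (dimensionless)
#' @param m power-law index (dimensionless, `m < 1` for shear thinning)
#' @param rho blood density (kg/m3)
#' @return an object of class `rheology_params`
#' @export
#' @examples
#' viscosity(0)                   # 0.056, the zero-shear plateau
#' viscosity(1e9) - 0.0035        # ~0, the infinite-shear plateau
rheology_params <- function(mu0 = 0.056, mu_inf = 0.0035, lambda_cy = 1.902,
                            a = 1.25, m = 0.22, rho = 1056) {
  stopifnot(is.numeric(mu0), is.numeric(mu_inf), is.numeric(lambda_cy))
  if (!(mu0 >= mu_inf && mu_inf > 0))
    stop("rheology: need mu0 >= mu_inf > 0")
  if (lambda_cy <= 0) stop("rheology: lambda_cy must be positive")
  if (rho <= 0) stop("rheology: density must be positive")
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda_cy = lambda_cy,
                 a = a, m = m, rho = rho),
            class = "rheology_params")
}

#' @export
print.rheology_params <- function(x, ...) {
  cat("Carreau-Yasuda rheology: mu0 =", x$mu0, "Pa.s, mu_inf =", x$mu_inf,
      "Pa.s, lambda =", x$lambda_cy, "s, a =", x$a, ", m =", x$m,
      ", rho =", x$rho, "kg/m3\n")
  invisible(x)
}

#' Carreau-Yasuda dynamic viscosity
#'
#' @param gamma_dot shear rate magnitude (1/s), vectorised, must be >= 0
#' @param params a [rheology_params()] object
#' @return dynamic viscosity (Pa s), same length as `gamma_dot`
#' @export
viscosity <- function(gamma_dot, params = rheology_params()) {
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop("viscosity: shear rate must be finite and non-negative")
  with(params,
       (mu0 - mu_inf) * (1 + (lambda_cy * gamma_dot)^a)^((m - 1) / a) + mu_inf)
}

#' Shear-rate magnitude of an axisymmetric flow field
#'
#' Computes \eqn{\dot\gamma = \sqrt{2\,D\!:\!D}} from the axisymmetric
#' strain-rate tensor with components
#' \eqn{D_{zz}, D_{rr}, D_{\theta\theta}=u_r/r,
#' D_{rz}=\tfrac12(\partial u_z/\partial r + \partial u_r/\partial z)}.
#' Gradients are taken on the body-fitted structured grid via the local
#' coordinate-transform Jacobian.
#'
#' @param field a `flow_field` (see [solve_steady()])
#' @return matrix (n_axial x n_radial cells) of shear rate (1/s)
#' @export
shear_rate <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  g <- field_gradients(field, c("uz", "ur"))
  rr <- field$rc
  dtt <- field$ur / pmax(rr, 1e-12)
  sqrt(2 * (g$uz$dz^2 + g$ur$dr^2 + dtt^2) + (g$uz$dr + g$ur$dz)^2)
}

# Gradients of cell-centred matrices on a curvilinear structured grid.
# field must carry zc, rc (cell centres, metres).  Returns per-variable
# lists with dz and dr matrices.
field_gradients <- function(field, vars) {
  X <- field$zc; Y <- field$rc
  didx <- function(M) {            # d/di along axial index (rows)
    n <- nrow(M)
    rbind(M[2, ] - M[1, ],
          (M[3:n, , drop = FALSE] - M[1:(n - 2), , drop = FALSE]) / 2,
          M[n, ] - M[n - 1, ])
  }
  djdx <- function(M) {            # d/dj along radial index (cols)
    n <- ncol(M)
    cbind(M[, 2] - M[, 1],
          (M[, 3:n, drop = FALSE] - M[, 1:(n - 2), drop = FALSE]) / 2,
          M[, n] - M[, n - 1])
  }
  xi <- didx(X); yi <- didx(Y); xj <- djdx(X); yj <- djdx(Y)
  det <- xi * yj - xj * yi
  det[abs(det) < 1e-300] <- 1e-300
  out <- lapply(vars, function(v) {
    M <- field[[v]]
    fi <- didx(M); fj <- djdx(M)
    list(dz = (fi * yj - fj * yi) / det,
         dr = (fj * xi - fi * xj) / det)
  })
  names(out) <- vars
  out
}
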