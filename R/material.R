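#' Hyperelastic material parameters
#'
#' Defines one tissue of the second-order polynomial (Mooney-Rivlin
#' family) strain-energy model
#' \deqn{U = \sum_{i+j=1}^{2} C_{ij}(\bar I_1-3)^i(\bar I_2-3)^j
#'       + \sum_{i=1}^{2} \frac{1}{D_i}(J_{el}-1)^{2i}.}
#' The initial (zero-strain) shear modulus is \eqn{\mu_0 = 2(C_{10}+C_{01})}
#' and the initial bulk modulus \eqn{K_0 = 2/D_1}.  When `d1`/`d2` are not
#' supplied they are derived from the Poisson ratio through
#' \eqn{K_0 = 2\mu_0(1+\nu)/(3(1-2\nu))} with `d2 = d1`, which reproduces
#' near-incompressibility at \eqn{\nu = 0.495}.
#'
#' Published parameter tables for breast tissue are commonly quoted as
#' bare numbers; here they are interpreted on the MPa scale by default
#' (`unit = "MPa"`), which places the malignant-tumor initial shear
#' modulus at 5.64 kPa, consistent with shear moduli reconstructed by
#' elastography.  Set `unit` to taste if your coefficients are already in
#' Pa or kPa.
#'
#' @param c10,c01,c11,c20,c02 polynomial coefficients, in `unit`.
#' @param d1,d2 compressibility coefficients (1/`unit`); derived from
#'   `poisson_ratio` when `NULL`.
#' @param poisson_ratio dimensionless, in (0, 0.5).
#' @param density mass density in kg/m^3.
#' @param label tissue name.
#' @param unit unit of the supplied coefficients.
#' @param isochoric logical; if `TRUE` (default) the polynomial part is
#'   evaluated on the deviatoric invariants \eqn{\bar I_k} so that all
#'   volumetric response is carried by the `d` terms (the convention of
#'   standard FE implementations of this model).
#' @return object of class `material_params` (coefficients stored in Pa).
#' @examples
#' tumor <- material_params(1.41e-3, 1.41e-3, 17.1e-2, 1.66e-2, 1.66e-2,
#'                          label = "tumor")
#' mu0(tumor)  # 5640 Pa
#' @export
material_params <- function(c10, c01, c11 = 0, c20 = 0, c02 = 0,
                            d1 = NULL, d2 = NULL, poisson_ratio = 0.495,
                            density = 1000, label = "tissue",
                            unit = c("MPa", "kPa", "Pa"),
                            isochoric = TRUE) {
  unit <- match.arg(unit)
  scale <- c(MPa = 1e6, kPa = 1e3, Pa = 1)[[unit]]
  co <- c(c10 = c10, c01 = c01, c11 = c11, c20 = c20, c02 = c02) * scale
  check_finite(co, "hyperelastic coefficients")
  if (co[["c10"]] + co[["c01"]] <= 0)
    nlswei_abort("c10 + c01 must be positive (mu0 = 2(c10+c01) > 0)",
                 "nlswei_invalid_input")
  if (!is.finite(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5)
    nlswei_abort("poisson_ratio must lie in (0, 0.5)", "nlswei_invalid_input")
  if (!is.finite(density) || density <= 0)
    nlswei_abort("density must be positive", "nlswei_invalid_input")
  mu <- 2 * (co[["c10"]] + co[["c01"]])
  if (is.null(d1)) {
    k0 <- 2 * mu * (1 + poisson_ratio) / (3 * (1 - 2 * poisson_ratio))
    d1 <- 2 / k0
  } else {
    d1 <- d1 / scale
  }
  if (is.null(d2)) d2 <- d1 else d2 <- d2 / scale
  if (d1 <= 0 || d2 <= 0)
    nlswei_abort("compressibility coefficients d1, d2 must be positive",
                 "nlswei_invalid_input")
  structure(list(c10 = co[["c10"]], c01 = co[["c01"]], c11 = co[["c11"]],
                 c20 = co[["c20"]], c02 = co[["c02"]], d1 = d1, d2 = d2,
                 poisson_ratio = poisson_ratio, density = density,
                 label = label, isochoric = isochoric),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params> %s\n", x$label))
  cat(sprintf("  mu0 = %.4g kPa, K0 = %.4g kPa, nu = %.3f, rho = %g kg/m3\n",
              mu0(x) / 1e3, 2 / x$d1 / 1e3, x$poisson_ratio, x$density))
  cat(sprintf("  C10 %.3g  C01 %.3g  C11 %.3g  C20 %.3g  C02 %.3g  (Pa)\n",
              x$c10, x$c01, x$c11, x$c20, x$c02))
  invisible(x)
}

#' Initial shear modulus 2(C10 + C01)
#' @param params a [material_params()] object.
#' @return scalar, Pa.
#' @export
mu0 <- function(params) 2 * (params$c10 + params$c01)

#' @noRd
mat_vec <- function(p) {
  c(c10 = p$c10, c01 = p$c01, c11 = p$c11, c20 = p$c20, c02 = p$c02,
    d1 = p$d1, d2 = p$d2, iso = as.numeric(isTRUE(p$isochoric)))
}

# one row per material for the compiled kernels
#' @noRd
mat_matrix <- function(materials) {
  do.call(rbind, lapply(materials, mat_vec))
}

#' Load material parameter sets from a key-value text file
#'
#' Reads a YAML file with a `tissues:` block of polynomial coefficients
#' (see `system.file("extdata", "materials.yaml", package = "nlswei")`
#' for the packaged breast-tissue sets) and validates each entry.
#'
#' @param path YAML file; default: the packaged breast tissue table.
#' @return named list of [material_params()].
#' @export
load_materials <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.yaml", package = "nlswei")
  cfg <- yaml::read_yaml(path)
  unit <- cfg$unit %||% "MPa"
  nu <- cfg$poisson_ratio %||% 0.495
  rho <- cfg$density %||% 1000
  out <- lapply(names(cfg$tissues), function(nm) {
    ti <- cfg$tissues[[nm]]
    material_params(c10 = ti$c10, c01 = ti$c01, c11 = ti$c11 %||% 0,
                    c20 = ti$c20 %||% 0, c02 = ti$c02 %||% 0,
                    d1 = ti$d1, d2 = ti$d2,
                    poisson_ratio = ti$poisson_ratio %||% nu,
                    density = ti$density %||% rho, label = nm, unit = unit)
  })
  names(out) <- names(cfg$tissues)
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Finite-strain state (plane strain)
#'
#' Either supply the in-plane deformation gradient `F` (2x2; the
#' out-of-plane stretch is 1) or the invariants directly.  With `F`, the
#' invariants of the 3D left Cauchy-Green tensor are computed; when
#' `isochoric = TRUE` the deviatoric invariants
#' \eqn{\bar I_1 = J^{-2/3} I_1}, \eqn{\bar I_2 = J^{-4/3} I_2} are
#' stored, with `jel = det(F)`.
#'
#' @param F 2x2 in-plane deformation gradient.
#' @param i1,i2,jel invariants (used when `F` is `NULL`).
#' @param isochoric use deviatoric invariants when deriving from `F`.
#' @return object of class `strain_state`.
#' @examples
#' strain_state(diag(2))            # identity: i1 = i2 = 3, jel = 1
#' strain_state(i1 = 3.01, i2 = 3.01, jel = 1)
#' @export
strain_state <- function(F = NULL, i1 = NULL, i2 = NULL, jel = NULL,
                         isochoric = TRUE) {
  if (!is.null(F)) {
    F <- matrix(as.numeric(F), 2, 2)
    check_finite(F, "deformation gradient")
    J <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
    if (J <= 0)
      nlswei_abort("deformation gradient has non-positive determinant",
                   "nlswei_degenerate_deformation")
    B11 <- F[1, 1]^2 + F[1, 2]^2
    B22 <- F[2, 1]^2 + F[2, 2]^2
    B12 <- F[1, 1] * F[2, 1] + F[1, 2] * F[2, 2]
    i1 <- B11 + B22 + 1
    i2 <- (B11 * B22 - B12^2) + B11 + B22
    if (isochoric) {
      i1 <- i1 * J^(-2 / 3)
      i2 <- i2 * J^(-4 / 3)
    }
    jel <- J
  } else {
    F <- NULL
  }
  check_finite(c(i1, i2, jel), "strain invariants")
  if (jel <= 0)
    nlswei_abort("elastic volume ratio jel must be positive",
                 "nlswei_degenerate_deformation")
  structure(list(F = F, i1 = i1, i2 = i2, jel = jel, isochoric = isochoric),
            class = "strain_state")
}

#' @export
print.strain_state <- function(x, ...) {
  cat(sprintf("<strain_state> i1 = %.6g, i2 = %.6g, jel = %.6g\n",
              x$i1, x$i2, x$jel))
  invisible(x)
}

#' Strain-energy density
#'
#' Evaluates the polynomial strain-energy function at a finite-strain
#' state.  Vanishes at the identity deformation.
#'
#' @param params a [material_params()] object.
#' @param state a [strain_state()] object.
#' @return energy density in Pa (J/m^3).
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "material_params"), inherits(state, "strain_state"))
  a <- state$i1 - 3
  b <- state$i2 - 3
  v <- state$jel - 1
  check_finite(c(a, b, v), "strain state")
  params$c10 * a + params$c01 * b + params$c11 * a * b +
    params$c20 * a^2 + params$c02 * b^2 + v^2 / params$d1 + v^4 / params$d2
}

#' Cauchy stress at a finite-strain state
#'
#' Differentiates the strain energy with respect to the deformation
#' gradient (first Piola-Kirchhoff stress) and pushes the result to the
#' current configuration, \eqn{\sigma = J^{-1} P F^T}.  Requires a state
#' constructed from a deformation gradient.
#'
#' @inheritParams strain_energy
#' @return list with `sigma` (2x2 in-plane Cauchy stress, Pa) and `s33`
#'   (out-of-plane normal stress, Pa).
#' @export
cauchy_stress <- function(params, state) {
  stopifnot(inherits(params, "material_params"), inherits(state, "strain_state"))
  if (is.null(state$F))
    nlswei_abort("cauchy_stress needs a state built from a deformation gradient",
                 "nlswei_invalid_input")
  pv <- mat_vec(params)
  pv["iso"] <- as.numeric(isTRUE(state$isochoric))
  cpp_cauchy_F(pv, state$F)
}

#' Tangent (incremental) shear modulus at finite pre-strain
#'
#' The wave-carrying shear stiffness for a small shear superposed on the
#' pre-strain `F`: a perturbation \eqn{F' = (I + \gamma e_2\otimes e_1)F}
#' (vertical motion varying laterally, the polarization/propagation pair
#' of the wave stage).  Two definitions are available:
#' \describe{
#'   \item{`"acoustoelastic"` (default)}{\eqn{J^{-1}\,\partial^2 U/
#'     \partial\gamma^2}, the acoustic-tensor component governing the
#'     speed of that wave in the pre-stressed medium.}
#'   \item{`"cauchy"`}{slope of the Cauchy shear stress,
#'     \eqn{\partial\sigma_{21}/\partial\gamma}.}
#' }
#' For the (nearly diagonal) pre-strains produced by platen compression
#' the two agree to a fraction of a percent.  Both reduce to
#' \eqn{\mu_0 = 2(C_{10}+C_{01})} at the identity.
#'
#' @inheritParams strain_energy
#' @param gamma perturbation magnitude for the central difference.
#' @param mode which incremental modulus definition to use.
#' @return scalar modulus, Pa.
#' @export
tangent_shear_modulus <- function(params, state, gamma = 1e-6,
                                  mode = c("acoustoelastic", "cauchy")) {
  stopifnot(inherits(params, "material_params"), inherits(state, "strain_state"))
  mode <- match.arg(mode)
  if (is.null(state$F))
    nlswei_abort("tangent_shear_modulus needs a state built from a deformation gradient",
                 "nlswei_invalid_input")
  pv <- mat_vec(params)
  pv["iso"] <- as.numeric(isTRUE(state$isochoric))
  cpp_tangent_shear(pv, state$F, gamma, if (mode == "acoustoelastic") 0L else 1L)
}

#' Uniaxial plane-strain compression response
#'
#' Compresses the material vertically under plane strain with a free
#' (traction-less) lateral face, and reports the nominal vertical stress
#' and the tangent shear modulus along the loading path.  The lateral
#' stretch at each level is found by minimizing the strain energy.
#'
#' @param params a [material_params()] object.
#' @param strain_grid compression fractions in `[0, 0.5)`.
#' @param mode passed to [tangent_shear_modulus()].
#' @return data.frame with columns `strain`, `lateral_stretch`,
#'   `nominal_stress` (Pa, negative in compression), `cauchy_stress_yy`
#'   (Pa) and `tangent_modulus` (Pa).
#' @export
uniaxial_response <- function(params, strain_grid,
                              mode = c("acoustoelastic", "cauchy")) {
  stopifnot(inherits(params, "material_params"))
  mode <- match.arg(mode)
  check_finite(strain_grid, "strain grid")
  if (any(strain_grid < 0 | strain_grid >= 0.5))
    nlswei_abort("strains must lie in [0, 0.5)", "nlswei_invalid_input")
  pv <- mat_vec(params)
  Fc <- function(l2, l1) matrix(c(l1, 0, 0, l2), 2, 2)
  rows <- lapply(strain_grid, function(eps) {
    l2 <- 1 - eps
    l1 <- if (eps == 0) 1 else
      optimize(function(l1) cpp_strain_energy_F(pv, Fc(l2, l1)),
               c(0.8, 1 / l2 * 1.5), tol = 1e-12)$minimum
    F <- Fc(l2, l1)
    st <- strain_state(F = F, isochoric = params$isochoric)
    # nominal stress P22 = dU/d(lambda2) at the relaxed lateral stretch
    h <- 1e-7
    p22 <- (cpp_strain_energy_F(pv, Fc(l2 + h, l1)) -
            cpp_strain_energy_F(pv, Fc(l2 - h, l1))) / (2 * h)
    sig <- cauchy_stress(params, st)
    data.frame(strain = eps, lateral_stretch = l1, nominal_stress = p22,
               cauchy_stress_yy = sig$sigma[2, 2],
               tangent_modulus = tangent_shear_modulus(params, st, mode = mode))
  })
  do.call(rbind, rows)
}
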