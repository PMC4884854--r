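#' Quasi-static platen compression of the phantom
#'
#' Solves static equilibrium of the hyperelastic phantom under a rigid
#' flat platen descending by `level x height`, with a fixed (or roller)
#' base, frictionless contact (vertical displacement prescribed on
#' contacting nodes, horizontal motion free, nodes released when the
#' contact reaction turns tensile) and free lateral surfaces.  A
#' total-Lagrangian Newton iteration with load substepping and an
#' active-set treatment of the contact is used.
#'
#' @param phantom a [build_phantom()] or [make_test_fixture()] model.
#' @param level compression fraction of the model height, in `[0, 0.35]`.
#' @param control solver options, see [compression_control()].
#' @return object of class `deformed_state`: nodal displacements (m),
#'   per-element deformation gradient, Cauchy stress (Pa), tangent shear
#'   modulus field (Pa), convergence info.
#' @seealso [staged_compression()] for several levels along one loading
#'   path, [roi_statistics()] for per-tissue summaries.
#' @export
solve_compression <- function(phantom, level, control = compression_control()) {
  staged_compression(phantom, level, control)[[1]]
}

#' Solver options for the compression stage
#'
#' @param step initial load increment (fraction of model height).
#' @param min_step smallest increment before giving up.
#' @param max_newton Newton iterations per increment.
#' @param rtol relative residual tolerance (against the largest internal
#'   force magnitude).
#' @param atol absolute residual floor (N per metre of thickness).
#' @param tangent_gamma perturbation for the tangent-modulus field.
#' @param tangent_mode `"acoustoelastic"` or `"cauchy"`, see
#'   [tangent_shear_modulus()].
#' @param verbose print per-increment convergence lines.
#' @return list of options.
#' @export
compression_control <- function(step = 0.01, min_step = 1e-5,
                                max_newton = 40, rtol = 1e-7, atol = 1e-8,
                                tangent_gamma = 1e-6,
                                tangent_mode = "acoustoelastic",
                                verbose = FALSE) {
  list(step = step, min_step = min_step, max_newton = max_newton,
       rtol = rtol, atol = atol, tangent_gamma = tangent_gamma,
       tangent_mode = tangent_mode, verbose = verbose)
}

#' Compression at a sequence of levels along one loading path
#'
#' Lowers the platen incrementally, warm-starting each level from the
#' previous one, and snapshots the deformed state at each requested
#' level.
#'
#' @inheritParams solve_compression
#' @param levels ascending compression fractions in `[0, 0.35]`.
#' @return list of `deformed_state`, one per level.
#' @export
staged_compression <- function(phantom, levels,
                               control = compression_control()) {
  stopifnot(inherits(phantom, "phantom_model"))
  check_finite(levels, "levels")
  if (any(levels < 0 | levels > 0.35))
    nlswei_abort("levels must lie in [0, 0.35]", "nlswei_invalid_input")
  if (is.unsorted(levels, strictly = FALSE))
    nlswei_abort("levels must be ascending", "nlswei_invalid_input")

  n <- nrow(phantom$node_xy)
  u <- numeric(2 * n)
  mats <- mat_matrix(phantom$materials)
  X <- phantom$node_xy
  elems <- phantom$elems
  emat <- phantom$elem_mat

  # fixed dofs from the base support
  base <- phantom$base_nodes
  fix_dofs_base <- if (phantom$base_bc == "fixed")
    c(2 * base - 1, 2 * base) else 2 * base
  if (phantom$base_bc == "roller") {
    # pin the lateral dof of the base node nearest the midline to remove
    # the rigid horizontal mode
    pin <- base[which.min(abs(X[base, 1] - phantom$platen_center))]
    fix_dofs_base <- c(fix_dofs_base, 2 * pin - 1)
  }

  fscale_ref <- max(mu0(phantom$materials[[1]]) * phantom$spacing, 1e-6)
  states <- vector("list", length(levels))
  cur <- 0
  active <- integer(0)
  for (li in seq_along(levels)) {
    target <- levels[li]
    step <- min(control$step, max(target - cur, control$step))
    while (cur < target - 1e-12) {
      nxt <- min(cur + step, target)
      res <- try(solve_increment(phantom, X, elems, emat, mats, u, nxt,
                                 fix_dofs_base, active, control, fscale_ref),
                 silent = TRUE)
      if (inherits(res, "try-error") || !res$converged) {
        step <- step / 2
        if (step < control$min_step) {
          msg <- if (inherits(res, "try-error")) attr(res, "condition")$message
                 else sprintf("residual %.3g", res$residual)
          nlswei_abort(sprintf(
            paste0("compression solve failed at level %.4f (%s); ",
                   "consider smaller load substeps via compression_control()"),
            nxt, msg), "nlswei_solver_error")
        }
        next
      }
      u <- res$u
      active <- res$active
      cur <- nxt
      if (res$newton_iters <= 4) step <- min(step * 1.5, control$step)
      if (control$verbose)
        message(sprintf("level %.3f: %d newton, %d contact nodes, r = %.2e",
                        cur, res$newton_iters, length(active), res$residual))
    }
    states[[li]] <- make_state(phantom, X, elems, emat, mats, u, cur, active,
                               control, if (cur > 0) res$residual else 0)
  }
  states
}

# one load increment: active-set contact loop around Newton
#' @noRd
solve_increment <- function(phantom, X, elems, emat, mats, u, level,
                            fix_dofs_base, active, control, fscale_ref) {
  H <- phantom$height
  hp <- H - level * H   # platen height above the base
  cand <- phantom$top_nodes
  half <- phantom$platen_width / 2
  marg <- phantom$spacing    # footprint hysteresis for sliding edge nodes
  newton_total <- 0L
  # each node may change contact state once per increment (ping-pong guard)
  released_once <- integer(0)
  added_once <- integer(0)
  in_footprint <- function(nodes, extra = 0) {
    abs(X[nodes, 1] + u[2 * nodes - 1] - phantom$platen_center) <=
      half + extra
  }
  # initial activation: candidates penetrating the platen plane
  pen <- X[cand, 2] + u[2 * cand] - hp
  active <- union(intersect(active, cand[in_footprint(cand, marg)]),
                  cand[in_footprint(cand) & pen > 0])
  for (as_it in 1:30) {
    u[2 * active] <- hp - X[active, 2]
    fix <- unique(c(fix_dofs_base, 2 * active))
    nr <- newton_solve(X, elems, emat, mats, u, fix, control, fscale_ref)
    if (!nr$converged) return(list(converged = FALSE, residual = nr$residual))
    u <- nr$u
    newton_total <- newton_total + nr$iters
    # release nodes whose vertical reaction is tensile (platen pulling)
    f <- cpp_fem_force(X, elems, emat, mats, u)
    ry <- f[2 * active]
    rel_tol <- 1e-3 * max(c(-ry, fscale_ref * 1e-3))
    release <- setdiff(active[ry > rel_tol | !in_footprint(active, marg)],
                       added_once)
    # activate nodes that penetrate
    pen <- X[cand, 2] + u[2 * cand] - hp
    addn <- setdiff(setdiff(cand[in_footprint(cand) & pen > 1e-9 * H], active),
                    released_once)
    if (!length(release) && !length(addn))
      return(list(converged = TRUE, u = u, active = active,
                  residual = nr$residual, newton_iters = newton_total))
    released_once <- union(released_once, release)
    added_once <- union(added_once, addn)
    active <- setdiff(union(active, addn), release)
  }
  list(converged = FALSE, residual = NA_real_)
}

#' @noRd
newton_solve <- function(X, elems, emat, mats, u, fix, control, fscale_ref) {
  nd <- 2 * nrow(X)
  free <- setdiff(seq_len(nd), fix)
  for (it in 1:control$max_newton) {
    f <- try(cpp_fem_force(X, elems, emat, mats, u), silent = TRUE)
    if (inherits(f, "try-error")) return(list(converged = FALSE, residual = Inf))
    r <- -f[free]
    fscale <- max(max(abs(f)), fscale_ref)
    rnorm <- max(abs(r))
    if (rnorm < control$rtol * fscale + control$atol)
      return(list(converged = TRUE, u = u, iters = it, residual = rnorm))
    K <- cpp_fem_stiffness(X, elems, emat, mats, u, 1e-9)
    Ks <- Matrix::sparseMatrix(i = K$i + 1L, j = K$j + 1L, x = K$v,
                               dims = c(nd, nd))
    Kff <- Ks[free, free, drop = FALSE]
    Kff <- (Kff + Matrix::t(Kff)) / 2
    du <- try(as.numeric(Matrix::solve(Kff, r)), silent = TRUE)
    if (inherits(du, "try-error")) return(list(converged = FALSE, residual = rnorm))
    # backtracking line search on the residual norm
    alpha <- 1
    for (ls in 1:10) {
      u_try <- u
      u_try[free] <- u[free] + alpha * du
      f_try <- try(cpp_fem_force(X, elems, emat, mats, u_try), silent = TRUE)
      ok <- !inherits(f_try, "try-error") && all(is.finite(f_try))
      if (ok && (max(abs(f_try[free])) < rnorm || alpha < 0.01)) break
      alpha <- alpha / 2
    }
    if (!ok) return(list(converged = FALSE, residual = rnorm))
    u <- u_try
  }
  list(converged = FALSE, residual = rnorm)
}

#' @noRd
make_state <- function(phantom, X, elems, emat, mats, u, level, active,
                       control, residual) {
  fl <- cpp_fem_fields(X, elems, emat, mats, u, control$tangent_gamma,
                       if (control$tangent_mode == "acoustoelastic") 0L else 1L)
  f <- cpp_fem_force(X, elems, emat, mats, u)
  base_dofs <- 2 * phantom$base_nodes
  structure(list(
    compression_level = level,
    u = matrix(u, ncol = 2, byrow = TRUE),
    F = fl$F,                  # per element: F11, F21, F12, F22
    stress = fl$stress,        # per element: s11, s21, s12, s22 (Pa)
    s33 = fl$s33,
    tangent_modulus = fl$tangent,
    energy_density = fl$energy,
    total_energy = cpp_fem_energy(X, elems, emat, mats, u),
    contact_nodes = active,
    platen_force = -sum(f[2 * active]),
    base_force = sum(f[base_dofs]),
    converged = TRUE, residual = residual,
    tangent_mode = control$tangent_mode), class = "deformed_state")
}

#' @export
print.deformed_state <- function(x, ...) {
  cat(sprintf("<deformed_state> level %.2f, %d contact nodes, residual %.2e\n",
              x$compression_level, length(x$contact_nodes), x$residual))
  cat(sprintf("  platen force %.4g N/m, stored energy %.4g J/m\n",
              x$platen_force, x$total_energy))
  invisible(x)
}

#' Per-tissue summaries of a deformed state
#'
#' Means and standard deviations of the compressive vertical strain, the
#' vertical Cauchy stress magnitude and the tangent shear modulus over
#' the tumor disc and over a same-size disc placed in the surrounding
#' tissue (by default at the same depth, one tumor diameter lateral of
#' the tumor center, on the far side from the push).
#'
#' @param state a `deformed_state`.
#' @param phantom the phantom it was computed on.
#' @param surr_center center `c(x, y)` (mm) of the surrounding-tissue
#'   disc; default `tumor_center + c(tumor_diameter, 0)`.
#' @param surr_diameter diameter (mm) of the surrounding disc; default:
#'   the tumor diameter.
#' @return data.frame with one row per tissue (`tumor`, `surrounding`):
#'   means and sds of strain (fraction), vertical stress (Pa) and tangent
#'   modulus (Pa).
#' @export
roi_statistics <- function(state, phantom, surr_center = NULL,
                           surr_diameter = NULL) {
  stopifnot(inherits(state, "deformed_state"), inherits(phantom, "phantom_model"))
  if (!isTRUE(state$converged))
    nlswei_abort("state is not converged", "nlswei_invalid_input")
  rois <- roi_elements(phantom, surr_center, surr_diameter)
  summarize <- function(sel) {
    if (!any(sel)) nlswei_abort("empty ROI", "nlswei_invalid_input")
    eyy <- abs(state$F[sel, 4] - 1)          # nominal vertical strain
    syy <- abs(state$stress[sel, 4])
    gt <- state$tangent_modulus[sel]
    data.frame(n = sum(sel),
               strain = mean(eyy), strain_sd = sd(eyy),
               stress = mean(syy), stress_sd = sd(syy),
               modulus = mean(gt), modulus_sd = sd(gt))
  }
  out <- rbind(summarize(rois$tumor), summarize(rois$surr))
  out <- cbind(tissue = c("tumor", "surrounding"), out)
  rownames(out) <- NULL
  out
}

# element selections for the two ROIs (reference configuration)
#' @noRd
roi_elements <- function(phantom, surr_center = NULL, surr_diameter = NULL) {
  ec <- element_centers(phantom)
  lab <- phantom$label[phantom$elem_cell]
  if (is.null(surr_center))
    surr_center <- (phantom$tumor_center +
                      c(phantom$tumor_diameter, 0)) * 1e3
  if (is.null(surr_diameter)) surr_diameter <- phantom$tumor_diameter * 1e3
  sc <- mm(surr_center); sr <- mm(surr_diameter) / 2
  tumor <- lab == 2L
  surr <- (ec[, 1] - sc[1])^2 + (ec[, 2] - sc[2])^2 <= sr^2 & lab == 1L
  if (!any(tumor)) {
    # pure-background fixtures: use a tumor-size disc at the tumor position
    tc <- phantom$tumor_center
    tr <- if (phantom$tumor_diameter > 0) phantom$tumor_diameter / 2 else sr
    tumor <- (ec[, 1] - tc[1])^2 + (ec[, 2] - tc[2])^2 <= tr^2
  }
  list(tumor = tumor, surr = surr, surr_center = sc,
       surr_diameter = 2 * sr)
}
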