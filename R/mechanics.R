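#' Material parameters of the intact tendon and the mechanics engine
#'
#' The constitutive families used for intact tendon carry several stiffness
#' parameters (collagen and ground-substance moduli); because the tissue
#' mixture rule scales *all* of them by one common multiplier, this engine
#' collapses them into a single effective axial modulus. The default places
#' the initial 10%-density callus core at about 15% axial strain under the
#' 2 N load (the peak of the strain-dependent tendon production law, i.e.
#' the start of the tendon production phase) and the intact stump at about
#' 6% strain.
#'
#' @param axial_modulus Effective axial Young's modulus of intact, aligned
#'   tendon (MPa).
#' @param poisson Poisson-type ground coupling ratio (dimensionless).
#' @param permeability Darcy permeability (mm^4 / (N s), i.e. mm^2/(MPa s)).
#' @param skempton Undrained pore-pressure coefficient (dimensionless);
#'   instantaneous pore pressure is `skempton * K * (-volumetric strain)`
#'   with `K` the drained bulk modulus.
#' @param alignment_weight Fraction of the axial stiffness that is
#'   fibril-orientation independent; the remaining `1 - alignment_weight`
#'   scales with the mean squared cosine between the element's fibrils and
#'   the load axis (randomly oriented fibrils give mean 1/3, fully aligned
#'   fibrils give 1, recovering the intact modulus).
#' @param stiffness_floor Lower bound on the mixture-times-alignment factor,
#'   keeping the stiffness matrix nonsingular in acellular early-callus
#'   elements.
#' @return An object of class `material_parameters`.
#' @export
material_parameters <- function(axial_modulus = 10, poisson = 0.3,
                                permeability = 1e-3, skempton = 1,
                                alignment_weight = 0.5,
                                stiffness_floor = 0.01) {
  stopifnot(axial_modulus > 0, poisson > 0, poisson < 0.5,
            permeability > 0, skempton >= 0,
            alignment_weight >= 0, alignment_weight <= 1,
            stiffness_floor > 0)
  structure(list(axial_modulus = axial_modulus, poisson = poisson,
                 permeability = permeability, skempton = skempton,
                 alignment_weight = alignment_weight,
                 stiffness_floor = stiffness_floor),
            class = "material_parameters")
}

#' Tensile load protocol
#'
#' Defaults follow the rodent gait load used throughout: a 2.0 N tensile
#' load applied as a linear ramp at 1.1 N/s along the tendon axis.
#'
#' @param peak Peak force (N).
#' @param rate Ramp rate (N/s); the ramp duration `peak / rate` is the time
#'   window over which pore pressure is allowed to drain.
#' @param axis Load axis (unit 3-vector).
#' @return An object of class `load_protocol`.
#' @export
load_protocol <- function(peak = 2.0, rate = 1.1, axis = c(0, 0, 1)) {
  stopifnot(peak > 0, rate > 0, length(axis) == 3, sum(axis^2) > 0)
  structure(list(peak = peak, rate = rate, axis = axis / sqrt(sum(axis^2))),
            class = "load_protocol")
}

#' Octahedral shear strain from principal strains
#'
#' `eps_os = (1/3) * sqrt((e1 - e3)^2 + (e1 - e2)^2 + (e2 - e3)^2)`.
#' Symmetric under permutation of its arguments and zero for a pure
#' hydrostatic strain state.
#'
#' @param e1,e2,e3 Principal strains (any consistent unit; vectorized).
#' @return Non-negative octahedral shear strain in the same unit.
#' @export
octahedral_shear_strain <- function(e1, e2, e3) {
  sqrt((e1 - e3)^2 + (e1 - e2)^2 + (e2 - e3)^2) / 3
}

#' Hydrostatic stress of a stress tensor
#'
#' One third of the trace of the (symmetric) stress tensor.
#'
#' @param sigma Symmetric 3 x 3 stress tensor (MPa).
#' @return Scalar hydrostatic stress (MPa).
#' @export
hydrostatic_stress <- function(sigma) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == c(3, 3)))
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("stress tensor must be symmetric", call. = FALSE)
  sum(diag(sigma)) / 3
}

#' Tissue-mixture stiffness multiplier
#'
#' Composite scaling of every intact-tendon stiffness parameter by the local
#' tissue content: `0.5 * rhoF + rhoT + 2.62 * rhoC + 40.40 * rhoB`.
#' Cartilage- and bone-like tissue stiffen the element (about 50 and 500
#' times stiffer than tendon at the 2 N working point in the source
#' framework), fat softens it.
#'
#' @param fat,tendon,cartilage,bone Tissue density fractions in `[0, 1]`
#'   (vectorized), or pass a matrix with those four columns as `fat`.
#' @return Numeric multiplier(s).
#' @export
mixture_multiplier <- function(fat, tendon = NULL, cartilage = NULL,
                               bone = NULL) {
  if (is.matrix(fat)) {
    m <- fat
    fat <- m[, "fat"]; tendon <- m[, "tendon"]
    cartilage <- m[, "cartilage"]; bone <- m[, "bone"]
  }
  if (any(c(fat, tendon, cartilage, bone) < 0))
    stop("negative tissue density", call. = FALSE)
  unname(0.5 * fat + tendon + 2.62 * cartilage + 40.40 * bone)
}

#' Assemble per-element effective material state
#'
#' Applies the tissue [mixture_multiplier()] and the fibril-alignment factor
#' to the intact axial modulus. Stump elements are intact tendon
#' (multiplier 1, aligned fibrils) by construction. The combined factor is
#' floored at `stiffness_floor` to keep early acellular elements solvable.
#'
#' @param state An `element_state` (see [element_state_init()]).
#' @param params A [material_parameters()] object.
#' @param axis Load axis for the alignment factor (unit 3-vector).
#' @return List with `multiplier` (mixture rule), `alignment` (factor in
#'   `[alignment_weight, 1]`), `modulus` (effective axial modulus, MPa) and
#'   `floored` (logical, where the floor was active).
#' @export
assemble_material <- function(state, params = material_parameters(),
                              axis = c(0, 0, 1)) {
  mult <- mixture_multiplier(state$densities)
  mult[state$region == "stump"] <- 1
  g <- fibril_alignment(state$fibrils, axis)
  align <- params$alignment_weight + (1 - params$alignment_weight) * g
  raw <- mult * align
  floored <- raw < params$stiffness_floor
  eff <- pmax(raw, params$stiffness_floor)
  list(multiplier = mult, alignment = align,
       modulus = eff * params$axial_modulus, floored = floored)
}

# Mean squared cosine between each element's fibrils and the given axis.
fibril_alignment <- function(fibrils, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  proj <- fibrils[, , 1] * axis[1] + fibrils[, , 2] * axis[2] +
    fibrils[, , 3] * axis[3]
  if (is.null(dim(proj))) proj <- matrix(proj, nrow = dim(fibrils)[1])
  rowMeans(proj^2)
}

#' Solve one quasi-static load ramp and extract biophysical stimuli
#'
#' Small-strain linear elastic solve under the peak load, followed by a
#' staggered one-step backward-difference Darcy pressure relaxation over the
#' ramp duration to obtain pore pressure and fluid flow. Stimuli are
#' evaluated per element at the centroid: principal strains (reported in %),
#' octahedral shear strain (%), hydrostatic stress (MPa), pore pressure
#' (MPa, compression positive), fluid-flow speed (um/s) and the maximum
#' principal strain direction.
#'
#' @param mesh A `healing_mesh`.
#' @param moduli Per-element effective axial moduli (MPa), or the result of
#'   [assemble_material()].
#' @param protocol A [load_protocol()].
#' @param params A [material_parameters()] (Poisson ratio, permeability,
#'   Skempton coefficient).
#' @param ops Optional precomputed [mesh_operators()] (must match
#'   `params$poisson`).
#' @return An object of class `stimulus_field`: list with per-element
#'   `e1`, `e2`, `e3`, `oss` (percent), `hydro`, `pp` (MPa), `ff` (um/s),
#'   `dir` (E x 3 max-principal-strain directions), plus `end_disp` (mm),
#'   `stiffness` (N/mm) and `reaction` (N).
#' @export
solve_ramp <- function(mesh, moduli, protocol = load_protocol(),
                       params = material_parameters(), ops = NULL) {
  if (is.list(moduli)) moduli <- moduli$modulus
  if (is.null(ops)) ops <- mesh_operators(mesh, params$poisson)
  ne <- ops$ne
  if (length(moduli) != ne)
    stop("need one modulus per element", call. = FALSE)
  if (any(!is.finite(moduli)) || any(moduli <= 0))
    stop("zero-stiffness element(s): ",
         paste(utils::head(which(moduli <= 0), 5), collapse = ", "),
         call. = FALSE)

  nn <- ops$nn
  vals <- as.vector(ops$Kvals * rep(moduli, each = 576L))
  nf <- length(ops$free_dofs)
  Kff <- Matrix::sparseMatrix(i = ops$kif, j = ops$kjf,
                              x = vals[ops$ksel], dims = c(nf, nf))
  f <- numeric(3L * nn)
  aw <- ops$load_weights
  loaded <- mesh$sets$loaded
  f[3L * loaded] <- protocol$peak * aw[loaded] / sum(aw)

  u <- numeric(3L * nn)
  sol <- tryCatch({
    Ks <- Matrix::forceSymmetric(Kff)
    ch <- ops$cache$chol
    ch <- if (is.null(ch)) Matrix::Cholesky(Ks, LDL = FALSE, super = TRUE)
          else Matrix::update(ch, Ks)
    ops$cache$chol <- ch
    Matrix::solve(ch, f[ops$free_dofs], system = "A")
  }, error = function(e) stop("mechanics solver failed: ",
                              conditionMessage(e), call. = FALSE))
  u[ops$free_dofs] <- as.numeric(sol)

  end_disp <- sum(f[3L * loaded] * u[3L * loaded]) / protocol$peak
  # axial reaction on the fixed face, from the constrained stiffness rows
  reaction <- -sum(vals[ops$rsel] * u[ops$rj])

  e1 <- e2 <- e3 <- hydro <- epsv <- numeric(ne)
  dir <- matrix(0, ne, 3L)
  p0e <- numeric(ne)
  kbulk_fac <- 1 / (3 * (1 - 2 * params$poisson))
  for (e in seq_len(ne)) {
    eps <- as.numeric(ops$Bc[, , e] %*% u[ops$dofmat[, e]])
    tens <- matrix(c(eps[1], eps[4] / 2, eps[6] / 2,
                     eps[4] / 2, eps[2], eps[5] / 2,
                     eps[6] / 2, eps[5] / 2, eps[3]), 3, 3)
    ev <- eigen(tens, symmetric = TRUE)
    e1[e] <- ev$values[1]; e2[e] <- ev$values[2]; e3[e] <- ev$values[3]
    dir[e, ] <- ev$vectors[, 1]
    sig <- moduli[e] * as.numeric(ops$D1 %*% eps)
    hydro[e] <- sum(sig[1:3]) / 3
    epsv[e] <- sum(eps[1:3])
    p0e[e] <- -params$skempton * moduli[e] * kbulk_fac * epsv[e]
  }

  # Staggered pore-fluid stage: undrained pressure projected to nodes, one
  # implicit Darcy step over the ramp duration, drained external surface.
  tau <- protocol$peak / protocol$rate
  p0n <- elem_to_node(ops, p0e)
  A <- Matrix::Diagonal(x = ops$lumped) +
    tau * params$permeability * ops$Lmat
  drained <- mesh$sets$surface
  p <- numeric(nn)
  pf <- setdiff(seq_len(nn), drained)
  p[pf] <- as.numeric(Matrix::solve(A[pf, pf],
                                    (ops$lumped * p0n)[pf]))
  pp <- node_to_elem(ops, p)
  ff <- numeric(ne)
  for (e in seq_len(ne)) {
    g <- as.numeric(ops$Gc[, , e] %*% p[mesh$elems[e, ]])
    ff[e] <- params$permeability * sqrt(sum(g^2)) * 1000
  }

  structure(list(e1 = 100 * e1, e2 = 100 * e2, e3 = 100 * e3,
                 oss = 100 * octahedral_shear_strain(e1, e2, e3),
                 hydro = hydro, pp = pp, ff = ff, dir = dir,
                 end_disp = end_disp,
                 stiffness = protocol$peak / end_disp,
                 reaction = reaction),
            class = "stimulus_field")
}

#' Secant stiffness of the construct at peak load
#'
#' Peak force divided by the (work-conjugate) end displacement of the
#' loaded face; with the linear engine the secant equals the tangent.
#'
#' @inheritParams solve_ramp
#' @return Scalar stiffness (N/mm).
#' @export
stiffness_at_load <- function(mesh, moduli, protocol = load_protocol(),
                              params = material_parameters(), ops = NULL) {
  sol <- solve_ramp(mesh, moduli, protocol, params, ops)
  if (!is.finite(sol$stiffness) || sol$end_disp <= 0)
    stop("degenerate model: zero end displacement", call. = FALSE)
  sol$stiffness
}
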