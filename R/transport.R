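#' Angiogenesis gate parameters
#'
#' @param a_oss Octahedral-shear-strain threshold (percent) below which
#'   vessel ingrowth can cross an element; default 6, the middle of the
#'   3-6-12 sensitivity grid.
#' @param maturation Angiogenesis fraction above which (strictly) a node is
#'   a matured blood vessel; default 0.90.
#' @return An object of class `angio_gate`.
#' @export
angio_gate <- function(a_oss = 6, maturation = 0.90) {
  stopifnot(a_oss > 0, maturation > 0)
  structure(list(a_oss = a_oss, maturation = maturation),
            class = "angio_gate")
}

# Shared implicit diffusion core. `elements = NULL` uses the full mesh
# Laplacian; otherwise only the listed elements conduct.
implicit_diffusion <- function(mesh, rho, D, dt, sources, ops,
                               elements = NULL) {
  nn <- ops$nn
  L <- if (is.null(elements)) {
    ops$Lmat
  } else {
    Matrix::sparseMatrix(i = as.vector(ops$li[, elements, drop = FALSE]),
                         j = as.vector(ops$lj[, elements, drop = FALSE]),
                         x = as.vector(ops$Lvals[, elements, drop = FALSE]),
                         dims = c(nn, nn))
  }
  A <- Matrix::Diagonal(x = ops$lumped) + dt * D * L
  out <- rho
  if (length(sources)) {
    out[sources] <- 1
    free <- setdiff(seq_len(nn), sources)
    rhs <- (ops$lumped * rho)[free] -
      as.numeric(A[free, sources, drop = FALSE] %*% rep(1, length(sources)))
    out[free] <- as.numeric(Matrix::solve(A[free, free], rhs))
  } else {
    out <- as.numeric(Matrix::solve(A, ops$lumped * rho))
  }
  out
}

#' One implicit diffusion step of a nodal field
#'
#' Backward-Euler step of `d rho / dt = D lap(rho)` on the mesh's finite
#' element Laplacian with lumped mass: Dirichlet value 1 at source nodes,
#' zero flux elsewhere. Without sources the scheme conserves the lumped
#' nodal mass exactly. The result is clamped to `[0, 1]`.
#'
#' @param mesh A `healing_mesh`.
#' @param rho Nodal field, fractions in `[0, 1]`.
#' @param D Diffusion constant (mm^2/day).
#' @param dt Time step (days).
#' @param sources Integer node indices held at density 1.
#' @param ops Optional precomputed [mesh_operators()].
#' @return Updated nodal field.
#' @export
diffuse_step <- function(mesh, rho, D, dt = 1, sources = integer(0),
                         ops = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.numeric(D) || D <= 0) stop("D must be > 0", call. = FALSE)
  if (is.null(ops)) ops <- mesh_operators(mesh)
  out <- implicit_diffusion(mesh, rho, D, dt, sources, ops)
  out <- pmin(pmax(out, 0), 1)
  out[sources] <- 1
  out
}

#' One oxygen step: diffusion plus cellular consumption
#'
#' Operator splitting of `d rho / dt = O lap(rho) - C * rho_cells * rho`:
#' an implicit diffusion step from the source nodes followed by exact
#' integration of the linear consumption sink,
#' `rho <- rho * exp(-C * rho_cells * dt)`, so that an isolated fully
#' cellularized node decays exactly as `exp(-C t)`. Source nodes (external
#' surface and matured vessels) are held at 1.
#'
#' @param mesh A `healing_mesh`.
#' @param rho Nodal oxygen field, fractions.
#' @param O Oxygen diffusion constant (mm^2/day).
#' @param C Consumption coefficient (1/day at full cell density).
#' @param cells Nodal cell density field.
#' @param dt Time step (days).
#' @param sources Integer node indices held at oxygen 1.
#' @param ops Optional precomputed [mesh_operators()].
#' @return Updated nodal oxygen field.
#' @export
oxygen_step <- function(mesh, rho, O, C, cells, dt = 1,
                        sources = integer(0), ops = NULL) {
  if (!is.numeric(C) || C < 0) stop("C must be >= 0", call. = FALSE)
  if (is.null(ops)) ops <- mesh_operators(mesh)
  out <- diffuse_step(mesh, rho, O, dt, sources, ops)
  decay <- exp(-C * cells * dt)
  if (length(sources)) {
    free <- setdiff(seq_len(ops$nn), sources)
    out[free] <- out[free] * decay[free]
  } else {
    out <- out * decay
  }
  pmin(pmax(out, 0), 1)
}

#' One strain-gated angiogenesis step
#'
#' Vessel ingrowth diffuses only across elements whose octahedral shear
#' strain is below the gate threshold (`A-OSS`); gated elements contribute
#' zero conductance, so nodes behind a fully gated region receive nothing.
#' The field is made explicitly non-decreasing (vessels do not regress).
#'
#' @param mesh A `healing_mesh`.
#' @param rho Nodal angiogenesis field, fractions.
#' @param A Angiogenesis diffusion constant (mm^2/day).
#' @param dt Time step (days).
#' @param stimuli A `stimulus_field` from [solve_ramp()] (per-element `oss`
#'   in percent), or a numeric vector of per-element octahedral shear
#'   strains in percent.
#' @param gate An [angio_gate()].
#' @param sources Integer node indices held at angiogenesis 1.
#' @param ops Optional precomputed [mesh_operators()].
#' @return Updated nodal angiogenesis field.
#' @export
angiogenesis_step <- function(mesh, rho, A, dt = 1, stimuli, gate = angio_gate(),
                              sources = integer(0), ops = NULL) {
  oss <- if (inherits(stimuli, "stimulus_field")) stimuli$oss else stimuli
  if (is.null(oss) || length(oss) != nrow(mesh$elems))
    stop("missing per-element octahedral shear strain", call. = FALSE)
  if (is.null(ops)) ops <- mesh_operators(mesh)
  open <- which(oss < gate$a_oss)
  out <- rho
  if (length(open)) {
    out <- implicit_diffusion(mesh, rho, A, dt, sources, ops,
                              elements = open)
  }
  out[sources] <- 1
  out <- pmin(pmax(out, 0), 1)
  pmax(out, rho)
}

#' Flag matured blood vessels
#'
#' A node whose angiogenesis level strictly exceeds the maturation
#' threshold becomes a matured vessel providing blood supply (and an
#' oxygen source). Flags are monotone: once set, never revoked.
#'
#' @param rho Nodal angiogenesis field, fractions.
#' @param vessels Current logical vessel flags (recycled if scalar).
#' @param gate An [angio_gate()] (or a numeric maturation threshold).
#' @return Logical vector of vessel flags.
#' @export
mature_vessels <- function(rho, vessels = FALSE, gate = angio_gate()) {
  thr <- if (inherits(gate, "angio_gate")) gate$maturation else gate
  as.logical(vessels | (rho > thr))
}

#' Calibrate the cell-infiltration diffusivity
#'
#' Finds, by bisection, the smallest diffusion constant `D` (within the
#' bracket, to relative tolerance `tol`) such that `target_day` daily
#' implicit diffusion steps from the external callus surface yield a
#' volume-weighted mean callus cell density of at least `target_mean`
#' (the infiltration rate is set to reach 95% cell density after 2 weeks).
#'
#' @param mesh A `healing_mesh` with a non-empty external surface set.
#' @param dt Time step (days).
#' @param target_day Day at which the target must be met.
#' @param target_mean Required mean callus cell density (fraction).
#' @param bracket Initial `c(low, high)` bracket for `D` (mm^2/day).
#' @param tol Relative bracket tolerance.
#' @param ops Optional precomputed [mesh_operators()].
#' @return Calibrated `D` (mm^2/day) with attributes `mean_at_target`,
#'   `bracket` and `iterations`.
#' @export
calibrate_cell_infiltration <- function(mesh, dt = 1, target_day = 14,
                                        target_mean = 0.95,
                                        bracket = c(1e-4, 50), tol = 1e-3,
                                        ops = NULL) {
  if (is.null(ops)) ops <- mesh_operators(mesh)
  sources <- mesh$sets$surface
  if (!length(sources)) stop("mesh has no external surface set",
                             call. = FALSE)
  replay <- function(D) {
    rho <- numeric(ops$nn)
    for (d in seq_len(target_day))
      rho <- diffuse_step(mesh, rho, D, dt, sources, ops)
    callus_mean(mesh, rho, ops)
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- replay(lo); fhi <- replay(hi)
  if (flo >= target_mean || fhi < target_mean)
    stop(sprintf(paste0("cell infiltration target %.3f unreachable in ",
                        "bracket [%g, %g] (means %.4f, %.4f)"),
                 target_mean, lo, hi, flo, fhi), call. = FALSE)
  it <- 0L
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (replay(mid) >= target_mean) hi <- mid else lo <- mid
    it <- it + 1L
  }
  structure(hi, mean_at_target = replay(hi), bracket = c(lo, hi),
            iterations = it)
}
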