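# Low-level finite element machinery shared by the mechanics and transport
# modules. Everything that depends only on mesh geometry is precomputed once
# in mesh_operators(); the daily simulation loop then only rescales element
# stiffness values and refactorizes the sparse systems.

hex_corners <- function() {
  matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
           -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
         ncol = 3L, byrow = TRUE)
}

# Shape function values and natural derivatives at one natural point.
hex_shape <- function(xi, eta, ze) {
  cc <- hex_corners()
  N <- (1 + xi * cc[, 1]) * (1 + eta * cc[, 2]) * (1 + ze * cc[, 3]) / 8
  dN <- cbind(cc[, 1] * (1 + eta * cc[, 2]) * (1 + ze * cc[, 3]),
              cc[, 2] * (1 + xi * cc[, 1]) * (1 + ze * cc[, 3]),
              cc[, 3] * (1 + xi * cc[, 1]) * (1 + eta * cc[, 2])) / 8
  list(N = N, dN = dN)
}

# 2x2x2 Gauss rule (weights are all 1), cached.
hex_gauss <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- 1 / sqrt(3)
    pts <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g),
                                 ze = c(-g, g)))
    sh <- lapply(seq_len(8L), function(i)
      hex_shape(pts[i, 1], pts[i, 2], pts[i, 3]))
    cache <<- list(pts = pts,
                   N = lapply(sh, `[[`, "N"),
                   dN = lapply(sh, `[[`, "dN"))
    cache
  }
})

# Isotropic elasticity matrix for unit Young's modulus (engineering shears).
elastic_D <- function(poisson) {
  nu <- poisson
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

strain_B <- function(dNdx) {
  B <- matrix(0, 6, 24)
  ix <- 3 * (seq_len(8) - 1)
  B[1, ix + 1] <- dNdx[, 1]
  B[2, ix + 2] <- dNdx[, 2]
  B[3, ix + 3] <- dNdx[, 3]
  B[4, ix + 1] <- dNdx[, 2]; B[4, ix + 2] <- dNdx[, 1]
  B[5, ix + 2] <- dNdx[, 3]; B[5, ix + 3] <- dNdx[, 2]
  B[6, ix + 1] <- dNdx[, 3]; B[6, ix + 3] <- dNdx[, 1]
  B
}

hex_faces <- function() {
  list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
       c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
}

# Consistent nodal weights (integral of shape functions) over a bilinear
# quadrilateral face in 3D; returns 4 weights summing to the face area.
quad_face_weights <- function(x4) {
  g <- 1 / sqrt(3)
  w <- numeric(4)
  cs <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), ncol = 2, byrow = TRUE)
  for (a in c(-g, g)) for (b in c(-g, g)) {
    N <- (1 + a * cs[, 1]) * (1 + b * cs[, 2]) / 4
    dNa <- cs[, 1] * (1 + b * cs[, 2]) / 4
    dNb <- cs[, 2] * (1 + a * cs[, 1]) / 4
    ta <- crossprod(x4, dNa)
    tb <- crossprod(x4, dNb)
    nrm <- c(ta[2] * tb[3] - ta[3] * tb[2],
             ta[3] * tb[1] - ta[1] * tb[3],
             ta[1] * tb[2] - ta[2] * tb[1])
    w <- w + N * sqrt(sum(nrm^2))
  }
  w
}

#' Precompute finite element operators for a mesh
#'
#' Assembles, once per mesh, everything the daily iteration reuses: element
#' stiffness matrices for unit Young's modulus, the nodal diffusion
#' (Laplacian) matrix and lumped mass, centroid strain-displacement and
#' gradient operators, the node-element volume-weighted transfer matrix,
#' consistent load weights on the loaded face, and the displacement boundary
#' conditions (axial fixity on the fixed face plus two in-plane pins that
#' remove rigid-body modes without constraining lateral contraction).
#'
#' @param mesh A `healing_mesh` of 8-node hexahedra.
#' @param poisson Poisson's ratio used for the unit-modulus element
#'   stiffness matrices (the elastic stimuli scale linearly with the
#'   effective modulus at fixed Poisson's ratio).
#' @return An object of class `mesh_ops` (opaque; pass to the mechanics and
#'   transport functions to avoid re-assembly).
#' @export
mesh_operators <- function(mesh, poisson = 0.3) {
  nodes <- mesh$nodes
  elems <- mesh$elems
  nn <- nrow(nodes)
  ne <- nrow(elems)
  gp <- hex_gauss()
  D1 <- elastic_D(poisson)
  csh <- hex_shape(0, 0, 0)

  Kvals <- matrix(0, 576, ne)
  Lvals <- matrix(0, 64, ne)
  emass <- matrix(0, 8, ne)
  Bc <- array(0, c(6, 24, ne))
  Gc <- array(0, c(3, 8, ne))
  V <- numeric(ne)
  dofmat <- matrix(0L, 24, ne)

  for (e in seq_len(ne)) {
    en <- elems[e, ]
    x <- nodes[en, ]
    Ke <- matrix(0, 24, 24)
    Le <- matrix(0, 8, 8)
    me <- numeric(8)
    vol <- 0
    for (g in seq_len(8L)) {
      J <- crossprod(gp$dN[[g]], x)
      dJ <- det(J)
      if (dJ <= 0) stop("inverted element ", e, call. = FALSE)
      dNdx <- gp$dN[[g]] %*% t(solve(J))
      B <- strain_B(dNdx)
      Ke <- Ke + crossprod(B, D1 %*% B) * dJ
      Le <- Le + tcrossprod(dNdx) * dJ
      me <- me + gp$N[[g]] * dJ
      vol <- vol + dJ
    }
    # Monotone (M-matrix) repair of the element diffusion matrix: the
    # consistent hex Laplacian has positive off-diagonals on skewed
    # elements, which makes steep reaction-diffusion profiles oscillate.
    # Clip positive off-diagonal conductances and restore zero row sums;
    # the operator stays symmetric and mass-conservative and the implicit
    # step then satisfies a discrete maximum principle.
    off <- Le; diag(off) <- 0
    off[off > 0] <- 0
    diag(off) <- -rowSums(off)
    Le <- off
    Jc <- crossprod(csh$dN, x)
    dNdxc <- csh$dN %*% t(solve(Jc))
    Bc[, , e] <- strain_B(dNdxc)
    Gc[, , e] <- t(dNdxc)
    Kvals[, e] <- as.vector(Ke)
    Lvals[, e] <- as.vector(Le)
    emass[, e] <- me
    V[e] <- vol
    dofmat[, e] <- as.vector(rbind(3L * en - 2L, 3L * en - 1L, 3L * en))
  }

  ki <- as.vector(apply(dofmat, 2L, function(d) rep(d, times = 24L)))
  kj <- as.vector(apply(dofmat, 2L, function(d) rep(d, each = 24L)))
  li_mat <- apply(elems, 1L, function(en) rep(en, times = 8L))   # 64 x ne
  lj_mat <- apply(elems, 1L, function(en) rep(en, each = 8L))

  Lmat <- Matrix::sparseMatrix(i = as.vector(li_mat), j = as.vector(lj_mat),
                               x = as.vector(Lvals), dims = c(nn, nn))
  transfer <- Matrix::sparseMatrix(i = as.vector(t(elems)),
                                   j = rep(seq_len(ne), each = 8L),
                                   x = as.vector(emass), dims = c(nn, ne))
  lumped <- as.numeric(transfer %*% rep(1, ne))
  callus <- mesh$region == "callus"
  callus_lumped <- if (any(callus)) {
    as.numeric(transfer[, callus, drop = FALSE] %*% rep(1, sum(callus)))
  } else numeric(nn)

  # Consistent load weights on the loaded face.
  loaded <- mesh$sets$loaded
  aw <- numeric(nn)
  for (e in seq_len(ne)) {
    en <- elems[e, ]
    for (f in hex_faces()) {
      fn <- en[f]
      if (all(fn %in% loaded))
        aw[fn] <- aw[fn] + quad_face_weights(nodes[fn, ])
    }
  }

  # Displacement boundary conditions: u_z = 0 on the fixed face, plus pins.
  fixed <- mesh$sets$fixed
  fixed_dofs <- 3L * fixed
  r2 <- nodes[fixed, 1]^2 + nodes[fixed, 2]^2
  pinA <- fixed[which.min(r2)]
  same_y <- fixed[abs(nodes[fixed, 2] - nodes[pinA, 2]) < 1e-9 &
                  fixed != pinA]
  pin_dofs <- c(3L * pinA - 2L, 3L * pinA - 1L)
  if (length(same_y)) {
    pinB <- same_y[which.max(abs(nodes[same_y, 1] - nodes[pinA, 1]))]
    pin_dofs <- c(pin_dofs, 3L * pinB - 1L)
  }
  cons <- sort(unique(c(fixed_dofs, pin_dofs)))
  free <- setdiff(seq_len(3L * nn), cons)

  # Reduced-system triplet bookkeeping: assemble K_ff directly each day and
  # compute the fixed-face axial reaction from the few constrained rows.
  fmap <- integer(3L * nn)
  fmap[free] <- seq_along(free)
  in_free <- fmap[ki] > 0L & fmap[kj] > 0L
  ksel <- which(in_free)
  rsel <- which(ki %in% fixed_dofs)

  structure(list(nn = nn, ne = ne, poisson = poisson, D1 = D1,
                 Kvals = Kvals, ki = ki, kj = kj, dofmat = dofmat,
                 ksel = ksel, kif = fmap[ki[ksel]], kjf = fmap[kj[ksel]],
                 rsel = rsel, rj = kj[rsel], cache = new.env(),
                 Lvals = Lvals, li = li_mat, lj = lj_mat, Lmat = Lmat,
                 emass = emass, transfer = transfer, lumped = lumped,
                 callus_lumped = callus_lumped,
                 Bc = Bc, Gc = Gc, V = V,
                 load_weights = aw, constrained_dofs = cons,
                 free_dofs = free),
            class = "mesh_ops")
}

# Average a nodal field onto elements (volume-weighted shape integrals).
node_to_elem <- function(ops, x) as.numeric(Matrix::crossprod(ops$transfer, x)) / ops$V

# Project an element field onto nodes (volume-weighted).
elem_to_node <- function(ops, x) as.numeric(ops$transfer %*% x) / ops$lumped

#' Volume-weighted mean of a nodal field over the callus
#'
#' @param mesh A `healing_mesh`.
#' @param rho Nodal field (length = number of nodes), fraction in `[0, 1]`.
#' @param ops Optional precomputed [mesh_operators()].
#' @return Scalar mean, weighted by the lumped nodal volume contributed by
#'   callus elements.
#' @export
callus_mean <- function(mesh, rho, ops = NULL) {
  if (is.null(ops)) ops <- mesh_operators(mesh)
  w <- ops$callus_lumped
  sum(w * rho) / sum(w)
}
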