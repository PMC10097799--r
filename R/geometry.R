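#' Geometry parameters for the idealized stump-callus construct
#'
#' The healing tendon is modelled as an axisymmetric solid of revolution:
#' two cylindrical tendon stumps joined by a bulging callus whose radius
#' follows a cosine (sine-squared) profile, rising from the stump radius at
#' both stump-callus interfaces to `callus_radius` at the callus midpoint.
#' Dimensions are in millimetres and are order-of-magnitude plausible for a
#' healing rat Achilles tendon; all of them are configurable.
#'
#' @param stump_radius Radius of the intact tendon stumps (mm).
#' @param stump_length Length of each stump segment (mm).
#' @param callus_radius Maximum radius of the bulging callus (mm); must be at
#'   least `stump_radius`.
#' @param callus_length Axial length of the callus (mm).
#' @param n_axial_stump Number of element layers along each stump.
#' @param n_axial_callus Number of element layers along the callus.
#' @param n_cross Number of element divisions across the square parameter grid
#'   that is mapped onto the circular cross-section; must be a positive even
#'   number so that a node sits exactly on the tendon axis.
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(stump_radius = 1.0, stump_length = 3.0,
                            callus_radius = 2.5, callus_length = 5.0,
                            n_axial_stump = 3L, n_axial_callus = 8L,
                            n_cross = 8L) {
  p <- list(stump_radius = stump_radius, stump_length = stump_length,
            callus_radius = callus_radius, callus_length = callus_length,
            n_axial_stump = as.integer(n_axial_stump),
            n_axial_callus = as.integer(n_axial_callus),
            n_cross = as.integer(n_cross))
  problems <- character()
  dims <- c(stump_radius = stump_radius, stump_length = stump_length,
            callus_radius = callus_radius, callus_length = callus_length)
  bad <- names(dims)[!is.finite(dims) | dims <= 0]
  if (length(bad))
    problems <- c(problems, paste0("dimension must be > 0: ",
                                   paste(bad, collapse = ", ")))
  if (is.finite(callus_radius) && is.finite(stump_radius) &&
      callus_radius < stump_radius)
    problems <- c(problems, "callus_radius must be >= stump_radius")
  if (p$n_axial_stump < 1L || p$n_axial_callus < 1L)
    problems <- c(problems, "axial element counts must be >= 1")
  if (p$n_cross < 2L || p$n_cross %% 2L != 0L)
    problems <- c(problems, "n_cross must be a positive even number")
  if (length(problems))
    stop("invalid geometry configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  class(p) <- "geometry_params"
  p
}

#' Radius of the construct profile at axial position z
#'
#' @param z Axial coordinate(s), mm.
#' @param params A [geometry_params()] object.
#' @return Profile radius (mm) at each `z`.
#' @export
profile_radius <- function(z, params) {
  rs <- params$stump_radius
  z0 <- params$stump_length
  lc <- params$callus_length
  dr <- params$callus_radius - rs
  r <- rep(rs, length(z))
  in_callus <- z > z0 & z < z0 + lc
  xi <- (z[in_callus] - z0) / lc
  r[in_callus] <- rs + dr * sin(pi * xi)^2
  r
}

#' Closed-form volume of the parameterized profile
#'
#' Volume of the solid of revolution of [profile_radius()]:
#' `pi * (2 * Ls * rs^2 + Lc * (rs^2 + rs * dr + 3 * dr^2 / 8))`,
#' using `int sin^2 = Lc/2` and `int sin^4 = 3 Lc/8` over one bulge.
#'
#' @param params A [geometry_params()] object.
#' @param region `"total"`, `"callus"` or `"stump"`.
#' @return Volume in mm^3.
#' @export
profile_volume <- function(params, region = c("total", "callus", "stump")) {
  region <- match.arg(region)
  rs <- params$stump_radius
  dr <- params$callus_radius - rs
  v_stump <- pi * rs^2 * 2 * params$stump_length
  v_callus <- pi * params$callus_length * (rs^2 + rs * dr + 3 * dr^2 / 8)
  switch(region, total = v_stump + v_callus, callus = v_callus,
         stump = v_stump)
}

# Map the square [-1,1]^2 onto the unit disc (elliptical mapping); boundary
# grid nodes land exactly on the unit circle, interior quads stay convex.
square_to_disc <- function(u, v) {
  cbind(u * sqrt(pmax(0, 1 - v^2 / 2)), v * sqrt(pmax(0, 1 - u^2 / 2)))
}

#' Build the idealized stump-callus healing mesh
#'
#' Structured 8-node hexahedral mesh: a square grid is mapped onto the
#' circular cross-section and extruded along the tendon axis (z), with the
#' cross-section scaled by the axial radius profile. Element data live at
#' element centroids; transport fields live at nodes.
#'
#' @param params A [geometry_params()] object.
#' @return An object of class `healing_mesh` with fields
#'   `nodes` (N x 3 matrix, mm), `elems` (E x 8 integer matrix, VTK
#'   hexahedron corner ordering), `region` (character, `"stump"`/`"callus"`),
#'   `volumes` (mm^3) and `sets`, a list of node-index sets: `fixed` (z = 0
#'   face), `loaded` (z = max face), `surface` (external callus surface) and
#'   `stump_nodes` (nodes on or beyond the stump-callus interfaces).
#' @export
build_mesh <- function(params = geometry_params()) {
  if (!inherits(params, "geometry_params"))
    params <- do.call(geometry_params, params)
  n <- params$n_cross
  uv <- seq(-1, 1, length.out = n + 1L)
  grid <- expand.grid(u = uv, v = uv)          # u fastest
  disc <- square_to_disc(grid$u, grid$v)

  z0 <- params$stump_length
  lc <- params$callus_length
  z_st1 <- seq(0, z0, length.out = params$n_axial_stump + 1L)
  z_cal <- seq(z0, z0 + lc, length.out = params$n_axial_callus + 1L)
  z_st2 <- seq(z0 + lc, 2 * z0 + lc, length.out = params$n_axial_stump + 1L)
  z_stations <- c(z_st1, z_cal[-1L], z_st2[-1L])
  n_layers <- length(z_stations) - 1L
  npl <- (n + 1L)^2                            # nodes per layer

  nodes <- matrix(0, npl * length(z_stations), 3L)
  for (k in seq_along(z_stations)) {
    r <- profile_radius(z_stations[k], params)
    idx <- (k - 1L) * npl + seq_len(npl)
    nodes[idx, 1L:2L] <- disc * r
    nodes[idx, 3L] <- z_stations[k]
  }

  nid <- function(i, j, k) (k - 1L) * npl + (j - 1L) * (n + 1L) + i
  elems <- matrix(0L, n * n * n_layers, 8L)
  e <- 0L
  for (k in seq_len(n_layers)) {
    for (j in seq_len(n)) {
      for (i in seq_len(n)) {
        e <- e + 1L
        elems[e, ] <- c(nid(i, j, k), nid(i + 1L, j, k),
                        nid(i + 1L, j + 1L, k), nid(i, j + 1L, k),
                        nid(i, j, k + 1L), nid(i + 1L, j, k + 1L),
                        nid(i + 1L, j + 1L, k + 1L), nid(i, j + 1L, k + 1L))
      }
    }
  }

  layer_of_elem <- rep(seq_len(n_layers), each = n * n)
  callus_layers <- seq(params$n_axial_stump + 1L,
                       params$n_axial_stump + params$n_axial_callus)
  region <- ifelse(layer_of_elem %in% callus_layers, "callus", "stump")

  zmax <- max(z_stations)
  tol <- 1e-9
  fixed <- which(abs(nodes[, 3L]) < tol)
  loaded <- which(abs(nodes[, 3L] - zmax) < tol)
  on_rim <- abs(abs(grid$u) - 1) < tol | abs(abs(grid$v) - 1) < tol
  rim_idx <- which(rep(on_rim, length(z_stations)))
  zr <- nodes[rim_idx, 3L]
  surface <- rim_idx[zr >= z0 - tol & zr <= z0 + lc + tol]
  stump_nodes <- which(nodes[, 3L] <= z0 + tol | nodes[, 3L] >= z0 + lc - tol)

  mesh <- structure(list(nodes = nodes, elems = elems, region = region,
                         params = params,
                         sets = list(fixed = fixed, loaded = loaded,
                                     surface = surface,
                                     stump_nodes = stump_nodes)),
                    class = "healing_mesh")
  mesh$volumes <- element_volumes(mesh)
  mesh
}

#' Element volumes
#'
#' Volumes of all elements of a mesh; 8-node hexahedra are integrated with
#' 2 x 2 x 2 Gauss quadrature of the Jacobian determinant, 4-node tetrahedra
#' use the closed form `|det| / 6`.
#'
#' @param mesh A `healing_mesh` (or any list with `nodes` and `elems`).
#' @return Numeric vector of element volumes (mm^3).
#' @export
element_volumes <- function(mesh) {
  nodes <- mesh$nodes
  elems <- mesh$elems
  ne <- nrow(elems)
  vols <- numeric(ne)
  if (ncol(elems) == 4L) {
    for (e in seq_len(ne)) {
      x <- nodes[elems[e, ], ]
      vols[e] <- det(cbind(x[2, ] - x[1, ], x[3, ] - x[1, ],
                           x[4, ] - x[1, ])) / 6
    }
    if (any(vols <= 0))
      stop("inverted element (non-positive volume): ",
           paste(which(vols <= 0), collapse = ", "), call. = FALSE)
    return(vols)
  }
  gp <- hex_gauss()
  for (e in seq_len(ne)) {
    x <- nodes[elems[e, ], ]
    v <- 0
    for (g in seq_len(8L)) {
      J <- crossprod(gp$dN[[g]], x)   # 3x3, J[a,b] = dx_b/dxi_a
      dJ <- det(J)
      if (dJ <= 0)
        stop("inverted element (negative Jacobian) in element ", e,
             call. = FALSE)
      v <- v + dJ
    }
    vols[e] <- v
  }
  vols
}

#' Single unit-cube element fixture
#'
#' One 8-node hexahedron spanning the unit cube, with the z = 0 face fixed
#' and the z = 1 face loaded. On fixtures the "external surface" set is the
#' fixed face, giving a transparent one-dimensional infiltration direction.
#'
#' @return A `healing_mesh` with one element, labelled `"callus"`.
#' @export
fixture_single_element <- function() fixture_bar(1L)

#' Straight bar fixture of n unit-cube elements
#'
#' @param n Number of elements stacked along z (>= 1).
#' @return A `healing_mesh` with `n` elements in series, fixed face at z = 0,
#'   loaded face at z = n, surface set equal to the fixed face.
#' @export
fixture_bar <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  xy <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  nodes <- do.call(rbind, lapply(0:n, function(k) cbind(xy, k)))
  colnames(nodes) <- NULL
  elems <- t(vapply(seq_len(n), function(k) {
    b <- (k - 1L) * 4L
    c(b + 1L, b + 2L, b + 3L, b + 4L, b + 5L, b + 6L, b + 7L, b + 8L)
  }, integer(8L)))
  mesh <- structure(list(nodes = nodes, elems = elems,
                         region = rep("callus", n), params = NULL,
                         sets = list(fixed = 1:4,
                                     loaded = (4L * n + 1L):(4L * n + 4L),
                                     surface = 1:4,
                                     stump_nodes = integer(0))),
                    class = "healing_mesh")
  mesh$volumes <- element_volumes(mesh)
  mesh
}

#' @export
print.healing_mesh <- function(x, ...) {
  cat("<healing_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elems),
      " elements (", sum(x$region == "callus"), " callus / ",
      sum(x$region == "stump"), " stump), volume ",
      format(sum(x$volumes), digits = 6), " mm^3\n", sep = "")
  invisible(x)
}
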