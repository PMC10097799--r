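TISSUES <- c("fat", "tendon", "cartilage", "bone")

#' Initialize the per-element tissue state
#'
#' Callus elements start with 10% tendon-like density (collagen and ground
#' matrix at 10% of the stump value) and randomly oriented fibrils; stump
#' elements are intact tendon (density 1) with all fibrils along the tendon
#' axis and are immutable thereafter. Fibril initialization is the only
#' consumer of the RNG stream.
#'
#' @param mesh A `healing_mesh`.
#' @param callus_tendon Initial tendon-like density fraction in the callus.
#' @param n_fibrils Number of collagen fibril directions per element.
#' @return An object of class `element_state`: list with `densities`
#'   (E x 4 matrix, columns fat/tendon/cartilage/bone), `fibrils`
#'   (E x n_fibrils x 3 unit vectors), `ref_angle` (E x n_fibrils, set on
#'   the first reorientation call), `region` and `integrals` (E x 4 matrix
#'   of time-integrated densities, filled by [run_healing()]).
#' @export
element_state_init <- function(mesh, callus_tendon = 0.10,
                               n_fibrils = 13L) {
  ne <- nrow(mesh$elems)
  dens <- matrix(0, ne, 4L, dimnames = list(NULL, TISSUES))
  stump <- mesh$region == "stump"
  dens[stump, "tendon"] <- 1
  dens[!stump, "tendon"] <- callus_tendon
  fib <- array(0, c(ne, n_fibrils, 3L))
  fib[, , 3L] <- 1                      # stumps: aligned with tendon axis
  nc <- sum(!stump)
  if (nc) {
    # uniform directions on the sphere
    z <- stats::runif(nc * n_fibrils, -1, 1)
    phi <- stats::runif(nc * n_fibrils, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    fib[!stump, , 1L] <- r * cos(phi)
    fib[!stump, , 2L] <- r * sin(phi)
    fib[!stump, , 3L] <- z
  }
  structure(list(densities = dens,
                 fibrils = fib,
                 ref_angle = matrix(NA_real_, ne, n_fibrils),
                 region = mesh$region,
                 integrals = matrix(0, ne, 4L,
                                    dimnames = list(NULL, TISSUES))),
            class = "element_state")
}

#' Produce the selected tissue and degrade the others
#'
#' Daily density bookkeeping for every callus element. The produced amount
#' is `delta = rate * cell_density * dt` (production is linear in the local
#' cell density: no cells, no production). The other three tissues jointly
#' lose `min(delta, their total)`, apportioned proportionally to their
#' current densities, and the target gain is clamped so that no density
#' leaves `[0, 1]` and the total stays at most 1. During the first
#' `inflammatory$days` days a mechanics-independent baseline applies:
#' tendon is produced at `inflammatory$fraction` of the default rate
#' regardless of the proposed tissue. Stump elements are immutable.
#'
#' @param state An `element_state`.
#' @param tissue Character vector (or scalar) of tissues to produce per
#'   element: `"fat"`, `"tendon"`, `"cartilage"`, `"bone"` or `"none"`.
#' @param rate Production rate(s), fraction/day.
#' @param cells Per-element cell density fraction(s).
#' @param dt Time step (days).
#' @param day Current healing day (used for the inflammatory phase).
#' @param inflammatory List with `days`, `fraction` and `rate` (the default
#'   daily rate the baseline is a fraction of).
#' @return The updated `element_state`.
#' @export
produce_and_degrade <- function(state, tissue, rate, cells, dt = 1, day,
                                inflammatory = list(days = 5,
                                                    fraction = 0.5,
                                                    rate = 0.02)) {
  ne <- nrow(state$densities)
  tissue <- rep_len(as.character(tissue), ne)
  rate <- rep_len(rate, ne)
  cells <- rep_len(cells, ne)
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  bad <- setdiff(unique(tissue), c(TISSUES, "none"))
  if (length(bad))
    stop("unknown tissue label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (day <= inflammatory$days) {
    tissue[] <- "tendon"
    rate[] <- inflammatory$fraction * inflammatory$rate
  }
  act <- which(state$region == "callus" & tissue != "none")
  if (!length(act)) return(state)

  dens <- state$densities
  tcol <- match(tissue[act], TISSUES)
  delta <- rate[act] * cells[act] * dt
  target <- dens[cbind(act, tcol)]
  total <- rowSums(dens[act, , drop = FALSE])
  others <- total - target
  loss <- pmin(delta, others)
  gain <- pmin(delta, 1 - target, 1 - total + loss)
  scale <- ifelse(others > 0, 1 - loss / others, 1)
  dens[act, ] <- dens[act, , drop = FALSE] * scale
  dens[cbind(act, tcol)] <- target + gain
  dens[dens < 0] <- 0
  state$densities <- dens
  state
}

#' Recompute per-element material state from current densities
#'
#' Thin wrapper over [assemble_material()]: the mixture multiplier and
#' effective modulus are recomputed from the current tissue densities each
#' iteration (monotone non-decreasing in bone density at fixed others).
#'
#' @inheritParams assemble_material
#' @return See [assemble_material()].
#' @export
update_material_state <- function(state, params = material_parameters(),
                                  axis = c(0, 0, 1)) {
  assemble_material(state, params, axis)
}

#' Save or restore an element-state snapshot
#'
#' Serializes the full per-element state (densities, fibrils, reference
#' angles, running integrals) to a structured binary container (RDS), so a
#' healing run can be restarted or post-processed later.
#'
#' @param state An `element_state`.
#' @param path File path.
#' @return `write_state()` returns the path invisibly; `read_state()`
#'   returns the restored `element_state`.
#' @export
write_state <- function(state, path) {
  stopifnot(inherits(state, "element_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "element_state"))
    stop("file does not contain an element state", call. = FALSE)
  state
}

#' Rotate collagen fibrils toward the maximum principal strain direction
#'
#' Each callus fibril rotates in the plane it spans with the target
#' direction, by a fixed daily angle equal to its day-0 angle to the target
#' divided by `total_days` (so alignment from random to longitudinal takes
#' `total_days` days, four weeks by default), never overshooting. The
#' day-0 reference angle is recorded on the first call. Directions are
#' sign-symmetric (`v` and `-v` are the same fibril).
#'
#' @param state An `element_state`.
#' @param target Target direction(s): a unit 3-vector or an E x 3 matrix of
#'   per-element maximum principal strain directions.
#' @param dt Time step (days).
#' @param total_days Days for full alignment (default 28).
#' @return The updated `element_state`.
#' @export
reorient_fibrils <- function(state, target, dt = 1, total_days = 28) {
  ne <- nrow(state$densities)
  if (is.null(dim(target))) {
    if (length(target) != 3 || sum(target^2) == 0)
      stop("target must be a nonzero 3-vector", call. = FALSE)
    target <- matrix(target, ne, 3, byrow = TRUE)
  }
  nrm <- sqrt(rowSums(target^2))
  if (any(nrm == 0)) stop("zero-length target direction", call. = FALSE)
  target <- target / nrm
  callus <- state$region == "callus"
  nf <- dim(state$fibrils)[2]
  for (j in seq_len(nf)) {
    v <- state$fibrils[, j, ]
    if (is.null(dim(v))) v <- matrix(v, nrow = ne)
    dot <- rowSums(v * target)
    sgn <- ifelse(dot < 0, -1, 1)
    tt <- target * sgn
    cosang <- pmin(1, pmax(-1, abs(dot)))
    theta <- acos(cosang)
    ref <- state$ref_angle[, j]
    ref[is.na(ref)] <- theta[is.na(ref)]
    state$ref_angle[, j] <- ref
    step <- pmin(ref * dt / total_days, theta)
    s <- sin(theta)
    w1 <- ifelse(s > 1e-12, sin(theta - step) / s, 1)
    w2 <- ifelse(s > 1e-12, sin(step) / s, 0)
    vn <- v * w1 + tt * w2
    vn <- vn / sqrt(rowSums(vn^2))
    keep <- !callus
    vn[keep, ] <- v[keep, ]
    state$fibrils[, j, ] <- vn
  }
  state
}
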