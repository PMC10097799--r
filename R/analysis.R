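#' Callus bone volume
#'
#' Integrates bone density times element volume: `sum(rho_b * V)` (mm^3).
#'
#' @param rho_b Per-element bone density fractions, or an `element_state`
#'   (its bone column is used).
#' @param volumes Per-element volumes (mm^3).
#' @param region Optional per-element region labels; when given, only
#'   `"callus"` elements are integrated.
#' @return Bone volume in mm^3.
#' @export
bone_volume <- function(rho_b, volumes, region = NULL) {
  if (inherits(rho_b, "element_state")) {
    if (is.null(region)) region <- rho_b$region
    rho_b <- rho_b$densities[, "bone"]
  }
  if (length(rho_b) != length(volumes))
    stop("mismatched lengths: ", length(rho_b), " densities vs ",
         length(volumes), " volumes", call. = FALSE)
  if (!is.null(region)) {
    keep <- region == "callus"
    rho_b <- rho_b[keep]
    volumes <- volumes[keep]
  }
  sum(rho_b * volumes)
}

#' Temporal evolution curves in long format
#'
#' @param history A `healing_history`.
#' @return Tidy long data frame with columns `day`, `quantity`, `value`;
#'   densities in percent, stiffness in N/mm, bone volume in mm^3.
#' @export
temporal_curves <- function(history) {
  tab <- history$table
  if (is.null(tab) || !nrow(tab)) stop("empty history", call. = FALSE)
  dens <- c("fat", "tendon", "cartilage", "bone")
  pieces <- lapply(dens, function(q)
    data.frame(day = tab$day, quantity = q, value = 100 * tab[[q]]))
  pieces <- c(pieces, list(
    data.frame(day = tab$day, quantity = "stiffness",
               value = tab$stiffness),
    data.frame(day = tab$day, quantity = "bone_volume",
               value = tab$bone_volume)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' First day a tissue appears in the callus
#'
#' First day the mean callus density of the tissue exceeds the threshold
#' (0.1 percentage points by default, a tolerance against float dust).
#'
#' @param history A `healing_history`.
#' @param tissue One of `"fat"`, `"tendon"`, `"cartilage"`, `"bone"`.
#' @param threshold Threshold in percent.
#' @return The day (integer) or `NA` if the tissue never appears.
#' @export
first_appearance <- function(history, tissue, threshold = 0.1) {
  tab <- history$table
  hit <- which(100 * tab[[tissue]] > threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(tab$day[hit[1]])
}

#' Cross-run summary report
#'
#' One row per healing run: first-appearance days, final mean densities,
#' final stiffness and final bone volume.
#'
#' @param histories A `healing_history` or a list of them.
#' @param labels Run labels (defaults to list names).
#' @return A data frame with class `summary_report`.
#' @export
summary_report <- function(histories, labels = NULL) {
  if (inherits(histories, "healing_history")) histories <- list(histories)
  if (!length(histories)) stop("empty input", call. = FALSE)
  if (is.null(labels))
    labels <- names(histories) %||% paste0("run", seq_along(histories))
  rows <- Map(function(h, lab) {
    last <- h$table[nrow(h$table), ]
    data.frame(label = lab,
               first_tendon = first_appearance(h, "tendon"),
               first_cartilage = first_appearance(h, "cartilage"),
               first_bone = first_appearance(h, "bone"),
               final_fat = 100 * last$fat,
               final_tendon = 100 * last$tendon,
               final_cartilage = 100 * last$cartilage,
               final_bone = 100 * last$bone,
               final_stiffness = last$stiffness,
               final_bone_volume = last$bone_volume,
               stringsAsFactors = FALSE)
  }, histories, labels)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary_report", "data.frame")
  out
}

#' Density-weighted mean radial position of a tissue
#'
#' Radial (distance-from-axis) centroid of a tissue distribution over the
#' callus, weighted by element volume times the given per-element weight
#' (e.g. a density or its time integral). Used to locate where a tissue
#' concentrates: values below the volume-weighted mean callus radius
#' indicate the callus core, values above the periphery.
#'
#' @param mesh A `healing_mesh`.
#' @param weight Per-element non-negative weights (e.g.
#'   `state$integrals[, "cartilage"]`).
#' @return List with `radius` (weighted mean radius, mm) and
#'   `callus_radius_mean` (volume-weighted mean radius of all callus
#'   elements, mm).
#' @export
radial_centroid <- function(mesh, weight) {
  cent <- elem_centroids(mesh)
  r <- sqrt(cent[, 1]^2 + cent[, 2]^2)
  callus <- mesh$region == "callus"
  w <- weight[callus] * mesh$volumes[callus]
  if (sum(w) <= 0) stop("weights sum to zero over the callus",
                        call. = FALSE)
  list(radius = sum(r[callus] * w) / sum(w),
       callus_radius_mean = sum(r[callus] * mesh$volumes[callus]) /
         sum(mesh$volumes[callus]))
}

elem_centroids <- function(mesh) {
  t(apply(mesh$elems, 1L, function(en) colMeans(mesh$nodes[en, ])))
}
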