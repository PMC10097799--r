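# Legacy ASCII VTK unstructured-grid I/O. Kept deliberately minimal: scalar
# cell/point data only, which is all the healing fields need; files open in
# ParaView/VisIt and round-trip through read_vtk().

#' Export mesh and fields to a legacy VTK file
#'
#' Writes the mesh with tissue densities (percent), region labels and
#' stimuli as cell data, and transport fields as point data, to a legacy
#' ASCII VTK unstructured grid.
#'
#' @param mesh A `healing_mesh`.
#' @param path Output file path (conventionally `.vtk`).
#' @param state Optional `element_state` (densities exported in percent).
#' @param transport Optional transport list with nodal `cells`, `angio`,
#'   `oxygen` and logical `vessels`.
#' @param stimuli Optional `stimulus_field` (e1, oss in percent; hydro, pp
#'   in MPa; ff in um/s).
#' @return The path, invisibly.
#' @export
export_fields <- function(mesh, path, state = NULL, transport = NULL,
                          stimuli = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  num <- function(x) format(x, digits = 17, scientific = TRUE)

  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elems)
  npe <- ncol(mesh$elems)
  wl("# vtk DataFile Version 3.0", "tendon healing fields", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(paste("POINTS", nn, "double"))
  wl(apply(mesh$nodes, 1L, function(p) paste(num(p), collapse = " ")))
  wl(paste("CELLS", ne, ne * (npe + 1L)))
  wl(apply(mesh$elems, 1L, function(en)
    paste(c(npe, en - 1L), collapse = " ")))
  wl(paste("CELL_TYPES", ne))
  wl(as.character(rep(if (npe == 8L) 12L else 10L, ne)))

  scalar <- function(name, x, type = "double") {
    wl(paste("SCALARS", name, type, 1), "LOOKUP_TABLE default",
       if (type == "int") as.character(as.integer(x)) else num(x))
  }
  wl(paste("CELL_DATA", ne))
  scalar("region", as.integer(mesh$region == "callus"), "int")
  if (!is.null(state)) {
    for (tis in colnames(state$densities))
      scalar(paste0("rho_", tis), 100 * state$densities[, tis])
  }
  if (!is.null(stimuli)) {
    for (nm in c("e1", "oss", "hydro", "pp", "ff"))
      scalar(nm, stimuli[[nm]])
  }
  if (!is.null(transport)) {
    wl(paste("POINT_DATA", nn))
    scalar("cells", transport$cells)
    scalar("angiogenesis", transport$angio)
    scalar("oxygen", transport$oxygen)
    scalar("vessel", as.integer(transport$vessels), "int")
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [export_fields()]
#'
#' @param path Path to a legacy ASCII VTK file with scalar data arrays.
#' @return List with `nodes`, `elems` (1-based), `cell_data` and
#'   `point_data` (named lists of numeric vectors).
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  i <- grep("^POINTS", lines)[1]
  nn <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  nodes <- matrix(as.numeric(unlist(
    strsplit(trimws(lines[(i + 1):(i + nn)]), "\\s+"))), nn, 3, byrow = TRUE)
  i <- grep("^CELLS", lines)[1]
  ne <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
  cell_rows <- strsplit(trimws(lines[(i + 1):(i + ne)]), "\\s+")
  npe <- as.integer(cell_rows[[1]][1])
  elems <- matrix(as.integer(unlist(lapply(cell_rows, `[`, -1L))) + 1L,
                  ne, npe, byrow = TRUE)

  parse_scalars <- function(start, end, n) {
    out <- list()
    j <- start
    while (j <= end) {
      if (grepl("^SCALARS", lines[j])) {
        nm <- strsplit(lines[j], "\\s+")[[1]][2]
        vals <- as.numeric(lines[(j + 2):(j + 1 + n)])
        out[[nm]] <- vals
        j <- j + 2 + n
      } else j <- j + 1
    }
    out
  }
  icd <- grep("^CELL_DATA", lines)
  ipd <- grep("^POINT_DATA", lines)
  cell_data <- if (length(icd))
    parse_scalars(icd[1] + 1,
                  if (length(ipd) && ipd[1] > icd[1]) ipd[1] - 1
                  else length(lines), ne) else list()
  point_data <- if (length(ipd))
    parse_scalars(ipd[1] + 1, length(lines), nn) else list()
  list(nodes = nodes, elems = elems, cell_data = cell_data,
       point_data = point_data)
}
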