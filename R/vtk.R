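#' Write a structured-grid soil field as legacy ASCII VTK
#'
#' Writes cell data (water content and/or pressure head) of a
#' \code{box3d} grid as a \code{STRUCTURED_POINTS} legacy VTK file.
#'
#' @param grid a \code{soil_grid} of kind \code{box3d}
#' @param fields named list of per-cell numeric vectors
#' @param path output path
#' @param title dataset title line
#' @return \code{path}, invisibly
#' @export
write_vtk_soil <- function(grid, fields, path, title = "soil") {
  stopifnot(grid$kind == "box3d")
  for (f in fields) if (length(f) != grid$n)
    stop("field length does not match the number of cells")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d",
                       grid$nx + 1, grid$ny + 1, grid$nz + 1),
               sprintf("ORIGIN %g %g %g",
                       -grid$lx / 2, -grid$ly / 2, -grid$lz),
               sprintf("SPACING %g %g %g", grid$dx, grid$dy, grid$dz),
               sprintf("CELL_DATA %d", grid$n)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    # vtk expects x fastest, then y, then z ascending; our cells are
    # ordered x, y, then z downward from the surface -> reverse z layers
    v <- fields[[nm]]
    m <- matrix(v, nrow = grid$nx * grid$ny)
    v_out <- as.vector(m[, rev(seq_len(grid$nz))])
    writeLines(format(v_out, scientific = TRUE, digits = 7), con)
  }
  invisible(path)
}

#' Read back a structured soil VTK file
#'
#' Minimal reader for the files produced by \code{\link{write_vtk_soil}}
#' (round-trip checks and downstream analysis).
#'
#' @param path VTK file path
#' @return a list with \code{dims}, \code{origin}, \code{spacing} and a
#'   named list \code{fields} of per-cell vectors in grid order
#' @export
read_vtk_soil <- function(path) {
  ln <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
                                         grep("^DIMENSIONS", ln,
                                              value = TRUE))), "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(sub("ORIGIN", "",
                                           grep("^ORIGIN", ln,
                                                value = TRUE))),
                                "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "",
                                            grep("^SPACING", ln,
                                                 value = TRUE))),
                                 "\\s+")[[1]])
  ncell <- prod(dims - 1L)
  fields <- list()
  i <- 1
  nx <- dims[1] - 1L; ny <- dims[2] - 1L; nz <- dims[3] - 1L
  while (i <= length(ln)) {
    if (grepl("^SCALARS", ln[i])) {
      nm <- strsplit(ln[i], "\\s+")[[1]][2]
      vals <- as.numeric(ln[(i + 2):(i + 1 + ncell)])
      m <- matrix(vals, nrow = nx * ny)
      fields[[nm]] <- as.vector(m[, rev(seq_len(nz))])
      i <- i + 2 + ncell
    } else i <- i + 1
  }
  list(dims = dims, origin = origin, spacing = spacing, fields = fields)
}

#' Write a root system as legacy ASCII VTK polylines
#'
#' One polyline per root axis, points in root-system node order, with
#' optional per-node point data (e.g., xylem pressure head).
#'
#' @param rs a \code{root_system}
#' @param path output path
#' @param point_data named list of per-node vectors (node order of
#'   \code{rs$nodes})
#' @return \code{path}, invisibly
#' @export
write_vtk_root <- function(rs, path, point_data = list()) {
  nd <- rs$nodes
  for (f in point_data) if (length(f) != nrow(nd))
    stop("point data length does not match the number of nodes")
  chains <- rsml_chains(rs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "root", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(nd))), con)
  writeLines(sprintf("%g %g %g", nd$x, nd$y, nd$z), con)
  sizes <- vapply(chains, length, integer(1))
  writeLines(sprintf("LINES %d %d", length(chains),
                     sum(sizes) + length(chains)), con)
  for (ch in chains) {
    ix <- match(ch, nd$id) - 1L
    writeLines(paste(c(length(ix), ix), collapse = " "), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nd)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], scientific = TRUE, digits = 7),
                 con)
    }
  }
  invisible(path)
}

#' Read back a polyline root VTK file
#' @param path VTK file path
#' @return a list with \code{points} (matrix), \code{lines} (list of
#'   0-based index vectors) and \code{point_data}
#' @export
read_vtk_root <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)
  np <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(ln[(ip + 1):(ip + np)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  il <- grep("^LINES", ln)
  nl <- as.integer(strsplit(ln[il], "\\s+")[[1]][2])
  lines <- lapply(ln[(il + 1):(il + nl)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    v[-1]
  })
  pd <- list()
  ipd <- grep("^POINT_DATA", ln)
  if (length(ipd)) {
    i <- ipd + 1
    while (i <= length(ln)) {
      if (grepl("^SCALARS", ln[i])) {
        nm <- strsplit(ln[i], "\\s+")[[1]][2]
        pd[[nm]] <- as.numeric(ln[(i + 2):(i + 1 + np)])
        i <- i + 2 + np
      } else i <- i + 1
    }
  }
  list(points = pts, lines = lines, point_data = pd)
}
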