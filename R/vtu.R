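# Minimal VTK XML unstructured-grid (.vtu) writer for mesh snapshots.
# ASCII appended-free format; one VTK_QUAD (type 9) per element.

#' Export a mesh snapshot as a VTK unstructured grid
#'
#' Writes the mesh, with optional per-element (cell) and per-node (point)
#' scalar fields, as an ASCII XML `.vtu` file readable by ParaView and
#' meshio.  Integer fields are written as `Int32`, everything else as
#' `Float64`.  Output is byte-deterministic for a given mesh and data.
#'
#' @param mesh A `gp_mesh`.
#' @param path Output file path (conventionally ending in `.vtu`).
#' @param cell_data Named list of per-element vectors.
#' @param point_data Named list of per-node vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, cell_data = list(), point_data = list()) {
  stopifnot(inherits(mesh, "gp_mesh"))
  np <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  for (v in cell_data) stopifnot(length(v) == ne)
  for (v in point_data) stopifnot(length(v) == ne || length(v) == np)

  num <- function(x) paste(sprintf("%.9g", as.numeric(x)), collapse = " ")
  darray <- function(name, x, comps = 1) {
    type <- if (is.integer(x)) "Int32" else "Float64"
    val <- if (is.integer(x)) paste(x, collapse = " ") else num(x)
    sprintf(paste0('        <DataArray type="%s" Name="%s" ',
                   'NumberOfComponents="%d" format="ascii">\n',
                   '          %s\n        </DataArray>'),
            type, name, comps, val)
  }

  pts <- t(cbind(mesh$nodes, 0))  # x y z interleaved
  conn <- as.integer(t(mesh$elems) - 1L)
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', np, ne),
    '      <Points>',
    darray("Points", as.numeric(pts), comps = 3),
    '      </Points>',
    '      <Cells>',
    darray("connectivity", conn),
    darray("offsets", as.integer(seq_len(ne) * 4L)),
    darray("types", rep(9L, ne)),
    '      </Cells>')
  if (length(cell_data)) {
    lines <- c(lines, '      <CellData>',
               vapply(names(cell_data),
                      function(nm) darray(nm, cell_data[[nm]]), ""),
               '      </CellData>')
  }
  if (length(point_data)) {
    lines <- c(lines, '      <PointData>',
               vapply(names(point_data),
                      function(nm) darray(nm, point_data[[nm]]), ""),
               '      </PointData>')
  }
  lines <- c(lines, '    </Piece>', '  </UnstructuredGrid>', '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}
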