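#' Convert a labeled voxel volume to a conforming tetrahedral mesh
#'
#' Each labeled voxel is split into 6 tetrahedra using the Kuhn (Freudenthal)
#' subdivision around the main diagonal. The split is translation-invariant,
#' so face diagonals of neighbouring voxels coincide and the resulting mesh is
#' conforming. Each tet inherits its voxel's label; background voxels are
#' dropped. Per-label volume is preserved exactly (each tet has volume
#' \eqn{h_x h_y h_z / 6}).
#'
#' @param labels 3-D array of region labels (character, factor or integer).
#' @param voxel_size voxel edge length in meters: a scalar for isotropic
#'   voxels, or a length-3 vector of per-axis spacings. An anisotropic voxel
#'   shape must be stated explicitly via the length-3 form.
#' @param origin position of the grid corner (meters), default \code{c(0,0,0)}.
#' @param background label treated as empty space and dropped
#'   (default \code{NA}; \code{""} and \code{"background"} are always dropped).
#' @return a validated \code{\link{tet_mesh}}.
#' @export
voxel_to_tetmesh <- function(labels, voxel_size, origin = c(0, 0, 0),
                             background = NA) {
  if (length(dim(labels)) != 3) stop("labels must be a 3-D array")
  if (!length(voxel_size) %in% c(1, 3))
    stop("voxel_size must be a scalar or an explicit per-axis length-3 vector")
  h <- rep(as.numeric(voxel_size), length.out = 3)
  lab <- as.vector(labels)
  if (is.factor(lab)) lab <- as.character(lab)
  keep <- !is.na(lab) & !(lab %in% c("", "background"))
  if (!is.na(background)) keep <- keep & lab != background
  if (!any(keep)) stop("no labeled voxels")
  dims <- dim(labels)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  vox <- which(keep) - 1L
  ix <- vox %% nx
  iy <- (vox %/% nx) %% ny
  iz <- vox %/% (nx * ny)

  # grid-point id (1-based) for 0-based point coordinates
  px <- nx + 1L; py <- ny + 1L
  vid <- function(x, y, z) 1 + x + px * (y + py * z)

  # corner ids c000..c111
  c000 <- vid(ix, iy, iz);     c100 <- vid(ix + 1L, iy, iz)
  c010 <- vid(ix, iy + 1L, iz); c110 <- vid(ix + 1L, iy + 1L, iz)
  c001 <- vid(ix, iy, iz + 1L); c101 <- vid(ix + 1L, iy, iz + 1L)
  c011 <- vid(ix, iy + 1L, iz + 1L); c111 <- vid(ix + 1L, iy + 1L, iz + 1L)

  # Kuhn subdivision: 6 tets along vertex-permutation paths from c000 to c111
  tets <- rbind(
    cbind(c000, c100, c110, c111),
    cbind(c000, c100, c101, c111),
    cbind(c000, c010, c110, c111),
    cbind(c000, c010, c011, c111),
    cbind(c000, c001, c101, c111),
    cbind(c000, c001, c011, c111))
  region <- rep(lab[keep], 6L)

  used <- sort(unique(as.vector(tets)))
  remap <- integer(px * py * (nz + 1L))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)

  u0 <- used - 1L
  gx <- u0 %% px
  gy <- (u0 %/% px) %% py
  gz <- u0 %/% (px * py)
  vertices <- cbind(origin[1] + gx * h[1],
                    origin[2] + gy * h[2],
                    origin[3] + gz * h[3])
  tet_mesh(vertices, tets, region)
}

#' Write a labeled mesh as VTK legacy ASCII
#'
#' Writes an unstructured-grid VTK legacy file with a \code{region} integer
#' cell-data array plus a sidecar region-name table
#' (\code{<path>.regions.tsv}, columns \code{id} and \code{name}).
#'
#' @param mesh a \code{tet_mesh}.
#' @param path output file path (conventionally \code{.vtk}).
#' @param unit length unit of the written coordinates in meters
#'   (default 1: write meters).
#' @param point_data named list of per-vertex numeric fields to export
#'   (e.g. a solved potential); \code{NA}s written as 0.
#' @return invisibly \code{path}.
#' @export
write_mesh <- function(mesh, path, unit = 1, point_data = list()) {
  lev <- sort(unique(mesh$region))
  id <- match(mesh$region, lev) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$vertices); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0",
               "labeled tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$vertices / unit, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(id), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- as.numeric(point_data[[nm]])
      v[!is.finite(v)] <- 0
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(format(v, digits = 17, trim = TRUE), con)
    }
  }
  utils::write.table(data.frame(id = seq_along(lev) - 1L, name = lev),
                     paste0(path, ".regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled mesh from VTK legacy ASCII
#'
#' Reads an unstructured-grid VTK legacy file written by
#' \code{\link{write_mesh}} (or any ASCII legacy file with tetrahedral cells
#' and a \code{region} integer cell-data array). Region ids are mapped to
#' names through the sidecar \code{<path>.regions.tsv} if present, otherwise
#' the integer ids are used as labels.
#'
#' @param path input file path.
#' @param format mesh format id; only \code{"vtk"} (legacy ASCII) is supported.
#' @param unit length unit of the stored coordinates in meters (default 1).
#' @return a validated \code{\link{tet_mesh}}.
#' @export
read_mesh <- function(path, format = "vtk", unit = 1) {
  format <- match.arg(format, "vtk")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks_at <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1]]
  find_kw <- function(kw) {
    hit <- grep(paste0("^\\s*", kw, "\\b"), lines)
    if (!length(hit)) NA_integer_ else hit[1]
  }
  ip <- find_kw("POINTS")
  if (is.na(ip)) stop("format error: no POINTS section")
  n <- as.integer(toks_at(ip)[2])
  pts <- scan(text = lines[(ip + 1):length(lines)], n = 3 * n, quiet = TRUE)
  vertices <- matrix(pts, ncol = 3, byrow = TRUE) * unit

  ic <- find_kw("CELLS")
  if (is.na(ic)) stop("format error: no CELLS section")
  m <- as.integer(toks_at(ic)[2])
  sz <- as.integer(toks_at(ic)[3])
  cells <- scan(text = lines[(ic + 1):length(lines)], n = sz, quiet = TRUE)
  it <- find_kw("CELL_TYPES")
  if (is.na(it)) stop("format error: no CELL_TYPES section")
  types <- scan(text = lines[(it + 1):length(lines)], n = m, quiet = TRUE)
  if (any(types != 10))
    stop("unsupported cell type(s): ", paste(unique(types[types != 10]), collapse = ", "),
         " (only tetrahedra, VTK type 10, are supported)")
  if (sz != 5L * m) stop("unsupported cell layout (expected 4-vertex cells)")
  cm <- matrix(cells, ncol = 5, byrow = TRUE)
  if (any(cm[, 1] != 4)) stop("unsupported cell with != 4 vertices")
  tets <- cm[, 2:5, drop = FALSE] + 1L

  ir <- grep("^\\s*SCALARS\\s+region\\b", lines)
  if (!length(ir)) stop("format error: missing 'region' cell label array")
  id <- as.integer(scan(text = lines[(ir[1] + 2):length(lines)], n = m, quiet = TRUE))
  side <- paste0(path, ".regions.tsv")
  if (file.exists(side)) {
    tab <- utils::read.table(side, header = TRUE, sep = "\t",
                             colClasses = c("integer", "character"))
    region <- tab$name[match(id, tab$id)]
    if (anyNA(region)) stop("format error: region id missing from region table")
  } else {
    region <- as.character(id)
  }
  tet_mesh(vertices, tets, region)
}
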