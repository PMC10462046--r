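#' Read a structure file (GRO or PDB)
#'
#' Parses a Gromacs GRO or a PDB file into a topology and a single
#' coordinate frame. Coordinates are returned in nm (PDB Angstrom values are
#' converted). Only orthorhombic boxes are supported; a GRO box line with
#' off-diagonal components, or a PDB CRYST1 record with non-90-degree
#' angles, is rejected.
#'
#' @param path path to a .gro or .pdb file
#' @return list with elements `topology` (sk_topology) and `frame` (sk_frame)
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gro = read_gro(path),
    pdb = read_pdb_structure(path),
    stop("unsupported structure format '.", ext, "'; expected .gro or .pdb")
  )
}

# GRO fixed-width format: title line, atom count, one fixed-width line per
# atom (resid %5d, resname %-5s, atom name %5s, atom number %5d, x y z %8.3f),
# final box line. No installed R package parses GRO, hence the hand parser.
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GRO parse error: file too short (", path, ")")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1L) stop("GRO parse error at line 2: invalid atom count")
  if (length(lines) < 2L + n + 1L) {
    stop("GRO parse error: expected ", n, " atom lines plus a box line, got ",
         length(lines) - 2L, " lines after the header")
  }
  atom_lines <- lines[3:(2L + n)]
  bad <- which(nchar(atom_lines) < 44L)
  if (length(bad)) {
    stop("GRO parse error at line ", 2L + bad[1], ": atom record too short")
  }
  resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  resname <- trimws(substr(atom_lines, 6, 10))
  name <- trimws(substr(atom_lines, 11, 15))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop("GRO parse error at line ", 2L + bad[1], ": malformed atom record")
  }
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + n + 1L]),
                                               "\\s+")[[1]]))
  if (length(boxv) == 0L || anyNA(boxv)) {
    stop("GRO parse error: missing or malformed box line")
  }
  if (length(boxv) > 3L && any(abs(boxv[4:length(boxv)]) > 1e-9)) {
    stop("triclinic boxes are not supported; only orthorhombic boxes")
  }
  top <- system_topology(name, resname, resid)
  fr <- frame(cbind(x, y, z), time = 0, box = boxv[1:3])
  list(topology = top, frame = fr)
}

# PDB via bio3d (established reader); the CRYST1 box record is scanned
# separately because bio3d does not expose it. Coordinates Angstrom -> nm.
read_pdb_structure <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("PDB parse error: no ATOM/HETATM records")
  cryst <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cryst) == 0L) {
    stop("PDB file has no CRYST1 box record; a box is required")
  }
  fields <- suppressWarnings(as.numeric(c(
    substr(cryst[1], 7, 15), substr(cryst[1], 16, 24), substr(cryst[1], 25, 33),
    substr(cryst[1], 34, 40), substr(cryst[1], 41, 47), substr(cryst[1], 48, 54)
  )))
  if (anyNA(fields[1:3])) stop("PDB parse error: malformed CRYST1 record")
  angles <- fields[4:6]
  angles[is.na(angles)] <- 90
  if (any(abs(angles - 90) > 1e-6)) {
    stop("triclinic boxes are not supported; only orthorhombic boxes")
  }
  top <- system_topology(at$elety, at$resid, at$resno)
  fr <- frame(cbind(at$x, at$y, at$z) / 10, time = 0, box = fields[1:3] / 10)
  list(topology = top, frame = fr)
}
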