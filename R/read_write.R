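#' Read a molecular structure from PDB or GRO
#'
#' PDB files are parsed with bio3d; GRO files with a fixed-column reader
#' (GROMACS stores nm, converted to Angstrom on read). Author residue
#' numbering is preserved exactly.
#'
#' @param path path to the file.
#' @param format `"pdb"` or `"gro"`; default guessed from the extension.
#' @return an [md_structure].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gro") "gro" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, pdb = read_pdb_structure(path), gro = read_gro_structure(path))
}

read_pdb_structure <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom
  elem <- trimws(a$elesy)
  bad <- is.na(elem) | elem == ""
  if (any(bad)) {
    warning("element column missing for ", sum(bad),
            " atom(s); inferred from atom names")
    elem[bad] <- guess_element(a$elety[bad])
  }
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  atoms <- data.frame(name = trimws(a$elety), elem = elem,
                      resname = trimws(a$resid), resno = a$resno,
                      chain = chain, occ = a$o, stringsAsFactors = FALSE)
  xyz <- cbind(a$x, a$y, a$z)
  md_structure(atoms, xyz)
}

read_gro_structure <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("GRO file too short: ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("GRO format error at line 2: expected atom count")
  if (length(lines) < 2L + nat + 1L) {
    stop("GRO format error: file declares ", nat, " atoms but has only ",
         length(lines) - 3L, " atom lines")
  }
  al <- lines[3:(2L + nat)]
  num <- function(s, from, to) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    if (anyNA(v)) {
      stop("GRO format error at line ", which(is.na(v))[1] + 2L,
           ": bad numeric field")
    }
    v
  }
  resno <- as.integer(num(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  xyz <- cbind(num(al, 21, 28), num(al, 29, 36), num(al, 37, 44)) * 10  # nm -> A
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + nat + 1L]),
                                              "\\s+")[[1]][1:3])) * 10
  if (anyNA(box)) box <- NULL
  atoms <- data.frame(name = name, elem = guess_element(name),
                      resname = resname, resno = resno, chain = "A",
                      occ = NA_real_, stringsAsFactors = FALSE)
  md_structure(atoms, xyz, box = box)
}

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

pdb_atom_line <- function(rec, serial, name, resname, chain, resno, x, y, z,
                          occ, elem) {
  name_fmt <- ifelse(nchar(name) <= 3L, sprintf(" %-3s", name),
                     sprintf("%-4s", name))
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name_fmt, resname, substr(chain, 1, 1), resno,
          x, y, z, ifelse(is.na(occ), 1, occ), 0, elem)
}

structure_pdb_lines <- function(st) {
  a <- st$atoms
  rec <- ifelse(a$resname %in% STANDARD_AA, "ATOM", "HETATM")
  pdb_atom_line(rec, seq_len(nrow(a)), a$name, a$resname, a$chain, a$resno,
                st$xyz[, 1], st$xyz[, 2], st$xyz[, 3], a$occ, a$elem)
}

#' Write a structure to a PDB or GRO file
#'
#' @param st an [md_structure].
#' @param path output path.
#' @param format `"pdb"` or `"gro"` (guessed from the extension by default).
#' @return `path`, invisibly.
#' @export
write_structure <- function(st, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "gro") "gro" else "pdb"
  }
  stopifnot(inherits(st, "md_structure"))
  if (format == "pdb") {
    writeLines(c(structure_pdb_lines(st), "END"), path)
  } else {
    a <- st$atoms
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$resno %% 100000L, a$resname, a$name,
                     seq_len(nrow(a)) %% 100000L,
                     st$xyz[, 1] / 10, st$xyz[, 2] / 10, st$xyz[, 3] / 10)
    box <- if (is.null(st$box)) c(0, 0, 0) else st$box / 10
    writeLines(c("written by bindmodes", sprintf("%5d", nrow(a)), lines,
                 sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])), path)
  }
  invisible(path)
}

#' Read an MD trajectory
#'
#' Supported containers: DCD (CHARMM/NAMD binary, via bio3d) and multi-model
#' PDB. XTC is not readable here; convert upstream (e.g.
#' `gmx trjconv -f in.xtc -o out.dcd`) before loading. Coordinates are
#' Angstrom throughout.
#'
#' @param topology an [md_structure] giving the atom table; the trajectory
#'   must have exactly the same atom count.
#' @param path trajectory file.
#' @param format `"dcd"`, `"multipdb"` or `"auto"`.
#' @param source_id label for the originating simulation copy.
#' @return an [md_trajectory].
#' @export
read_trajectory <- function(topology, path,
                            format = c("auto", "dcd", "multipdb", "xtc"),
                            source_id = basename(path)) {
  format <- match.arg(format)
  stopifnot(inherits(topology, "md_structure"))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, dcd = "dcd", xtc = "xtc", "multipdb")
  }
  if (format == "xtc") {
    stop("XTC reading is not supported; convert to DCD ",
         "(e.g. 'gmx trjconv -f in.xtc -o out.dcd') or multi-model PDB")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  nat <- nrow(topology$atoms)
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    tn <- nrow(xyz)
    if (ncol(xyz) != 3L * nat) {
      stop("atom-count mismatch: topology has ", nat,
           " atoms but trajectory frames have ", ncol(xyz) / 3)
    }
    coords <- array(NA_real_, dim = c(tn, nat, 3L))
    for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3L * nat, by = 3L), drop = FALSE]
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
    tn <- nrow(xyz)
    if (ncol(xyz) != 3L * nat) {
      stop("atom-count mismatch: topology has ", nat,
           " atoms but trajectory frames have ", ncol(xyz) / 3)
    }
    coords <- array(NA_real_, dim = c(tn, nat, 3L))
    for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3L * nat, by = 3L), drop = FALSE]
  }
  if (tn < 1L) stop("trajectory contains zero frames")
  md_trajectory(topology, coords, source_id = source_id)
}

#' Write a trajectory
#'
#' Multi-model PDB (text) or DCD (binary, CHARMM layout readable by common
#' MD toolkits).
#'
#' @param traj an [md_trajectory].
#' @param path output path.
#' @param format `"multipdb"` or `"dcd"` (guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "multipdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "dcd") "dcd" else "multipdb"
  }
  stopifnot(inherits(traj, "md_trajectory"))
  tn <- n_frames(traj)
  if (format == "multipdb") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(tn)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(structure_pdb_lines(frame_structure(traj, i)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    write_dcd(traj, path)
  }
  invisible(path)
}

# Minimal CHARMM-format DCD writer (Fortran unformatted records,
# little-endian, single precision).  Enough for round-trips through
# standard readers; no unit cell, no fixed atoms.
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  endian <- "little"
  rec <- function(writer) {
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4L, endian = endian)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L, endian = endian)
  }
  tn <- n_frames(traj)
  nat <- n_atoms(traj)
  rec(function(cc) {
    writeChar("CORD", cc, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- tn      # NSET
    icntrl[2] <- 1L      # ISTART
    icntrl[3] <- 1L      # NSAVC
    icntrl[4] <- tn      # NSTEP
    icntrl[20] <- 24L    # CHARMM version stamp
    writeBin(icntrl, cc, size = 4L, endian = endian)
  })
  rec(function(cc) {
    writeBin(1L, cc, size = 4L, endian = endian)
    title <- sprintf("%-80s", "written by bindmodes")
    writeChar(title, cc, nchars = 80, eos = NULL)
  })
  rec(function(cc) writeBin(nat, cc, size = 4L, endian = endian))
  for (i in seq_len(tn)) {
    for (k in 1:3) {
      rec(function(cc) writeBin(as.numeric(traj$coords[i, , k]), cc,
                                size = 4L, endian = endian))
    }
  }
  invisible(path)
}
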