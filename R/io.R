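#' Read a structure file into a topology and a coordinate frame
#'
#' PDB files are parsed with bio3d; GRO files with a fixed-width parser
#' (coordinates converted nm -> Angstrom). Atom roles are assigned from a
#' residue-name dictionary; unknown residue names get the ligand role with
#' a warning.
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"gro"`.
#' @param role_map Residue-name to role dictionary; see
#'   [default_role_map()].
#' @param region_map Optional region map data.frame passed through to
#'   [topology()].
#' @return List with elements `topology`, `coords` (n x 3, Angstrom),
#'   `box` (length-3, Angstrom) and `time` (0 ns).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           role_map = default_role_map(),
                           region_map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro",
                     stop("cannot infer structure format from extension '",
                          ext, "'; pass format explicitly"))
  }
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "pdb") read_pdb_structure(path, role_map, region_map)
  else read_gro_structure(path, role_map, region_map)
}

read_pdb_structure <- function(path, role_map, region_map) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  chain <- at$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  fix <- is.na(elem) | !nzchar(trimws(elem))
  elem[fix] <- vapply(at$elety[fix], guess_element, "")
  elem <- trimws(elem)
  atoms <- data.frame(
    name = trimws(at$elety), element = elem,
    resid = as.integer(at$resno), resname = trimws(at$resid),
    chain = chain, role = assign_roles(at$resid, role_map),
    stringsAsFactors = FALSE)
  box <- c(1e6, 1e6, 1e6)
  cr <- grep("^CRYST1", readLines(path, n = 200), value = TRUE)
  ok <- FALSE
  if (length(cr) >= 1) {
    fields <- suppressWarnings(as.numeric(c(
      substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33),
      substr(cr[1], 34, 40), substr(cr[1], 41, 47),
      substr(cr[1], 48, 54))))
    if (all(is.finite(fields[1:3])) && all(fields[1:3] > 0)) {
      if (any(abs(fields[4:6] - 90) > 1e-3))
        stop("triclinic boxes are not supported (CRYST1 angles != 90)")
      box <- fields[1:3]
      ok <- TRUE
    }
  }
  if (!ok) {
    message("no usable CRYST1 record in ", basename(path),
            "; treating the system as non-periodic (box 1e6 A)")
  }
  coords <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  list(topology = topology(atoms, region_map), coords = coords,
       box = box, time = 0)
}

read_gro_structure <- function(path, role_map, region_map) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("malformed GRO file (fewer than 3 lines): ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat))
    stop("malformed GRO file at line 2 (atom count): ", path)
  if (length(lines) < 2 + nat + 1)
    stop("GRO file truncated: expected ", nat, " atom lines")
  al <- lines[3:(2 + nat)]
  num <- function(s, i) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v)))
      stop("malformed GRO coordinate at line ", 2 + which(is.na(v))[1])
    v
  }
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  if (any(is.na(resid)))
    stop("malformed GRO residue number at line ", 2 + which(is.na(resid))[1])
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- num(substr(al, 21, 28)) * 10
  y <- num(substr(al, 29, 36)) * 10
  z <- num(substr(al, 37, 44)) * 10
  boxline <- strsplit(trimws(lines[3 + nat]), "\\s+")[[1]]
  bv <- suppressWarnings(as.numeric(boxline))
  if (any(is.na(bv)) || !length(bv) %in% c(3, 9))
    stop("malformed GRO box line ", 3 + nat)
  if (length(bv) == 9 && any(abs(bv[4:9]) > 1e-9))
    stop("triclinic boxes are not supported (GRO off-diagonal box terms)")
  box <- bv[1:3] * 10
  atoms <- data.frame(
    name = name, element = vapply(name, guess_element, ""),
    resid = resid, resname = resname, chain = "A",
    role = assign_roles(resname, role_map), stringsAsFactors = FALSE)
  coords <- unname(cbind(x, y, z))
  dimnames(coords) <- NULL
  list(topology = topology(atoms, region_map),
       coords = coords, box = box, time = 0)
}

#' Write a topology + coordinates as PDB
#'
#' @param top A [topology()].
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param path Output file path.
#' @param box Length-3 box edges (Angstrom) written as CRYST1, or NULL.
#' @return Invisibly, the path.
#' @export
write_structure <- function(top, coords, path, box = NULL) {
  a <- top$atoms
  coords <- as_coord_matrix(coords)
  if (nrow(coords) != nrow(a))
    stop("coordinate count does not match topology")
  lines <- character(0)
  if (!is.null(box)) {
    b <- check_box(box)
    lines <- sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      b[1], b[2], b[3], 90, 90, 90)
  }
  # PDB v3 name justification: 4-char field starting in column 14 unless
  # the name itself is 4 characters
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  lines <- c(lines, sprintf(
    "ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    (seq_len(nrow(a)) - 1L) %% 99999 + 1L, nm,
    substr(a$resname, 1, 4), substr(a$chain, 1, 1), a$resid %% 10000,
    coords[, 1], coords[, 2], coords[, 3], 1, 0,
    toupper(a$element)), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory in the plaintext dialect
#'
#' One header line per frame, `t=<ns> box=<a> <b> <c>`, followed by one
#' `x y z` line per atom (Angstrom, 6 decimal places). This is the
#' package's text interchange format for small, reviewable fixtures.
#'
#' @param traj A [trajectory()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (i in seq_len(nf)) {
    cat(sprintf("t=%.6f box=%.6f %.6f %.6f\n", traj$times[i],
                traj$box[i, 1], traj$box[i, 2], traj$box[i, 3]),
        file = con)
    xyz <- traj$coords[, , i]
    writeLines(sprintf("%.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Supported formats: the plaintext dialect written by
#' [write_trajectory()], and DCD (read via bio3d; DCD stores no frame
#' times, so times are `(0:(n-1)) * dt_ns`). XTC and TRR are not
#' supported; convert to DCD or plaintext first.
#'
#' @param path Trajectory file path.
#' @param top The matching [topology()].
#' @param format `"auto"` (by extension), `"plaintext"` or `"dcd"`.
#' @param dt_ns Frame spacing in ns for formats that store no times.
#' @param box Fallback box (length 3, Angstrom) for DCD files without a
#'   unit cell.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, top, format = c("auto", "plaintext",
                                                  "dcd", "xtc", "trr"),
                            dt_ns = 1, box = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, dcd = "dcd", xtc = "xtc", trr = "trr",
                     "plaintext")
  }
  if (format %in% c("xtc", "trr"))
    stop(toupper(format), " reading is not supported; convert the ",
         "trajectory to DCD or to the plaintext dialect ",
         "(see ?write_trajectory)")
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (format == "dcd") read_dcd_trajectory(path, top, dt_ns, box)
  else read_plaintext_trajectory(path, top)
}

read_plaintext_trajectory <- function(path, top) {
  lines <- readLines(path)
  nat <- n_atoms(top)
  per <- nat + 1
  if (length(lines) == 0 || length(lines) %% per != 0)
    stop("plaintext trajectory length (", length(lines), " lines) is not ",
         "a multiple of atoms+1 (", per, "): atom-count mismatch with ",
         "the topology")
  nf <- length(lines) %/% per
  heads <- lines[(0:(nf - 1)) * per + 1]
  hm <- regmatches(heads, regexec(
    "^t=([-0-9.eE+]+) box=([-0-9.eE+]+) ([-0-9.eE+]+) ([-0-9.eE+]+)$",
    heads))
  bad <- which(vapply(hm, length, 0L) != 5)
  if (length(bad) > 0)
    stop("malformed frame header at line ", (bad[1] - 1) * per + 1)
  times <- vapply(hm, function(m) as.numeric(m[2]), 0)
  box <- t(vapply(hm, function(m) as.numeric(m[3:5]), numeric(3)))
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times are not strictly increasing")
  body <- lines[-((0:(nf - 1)) * per + 1)]
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) != 3 * nat * nf)
    stop("malformed coordinate line in plaintext trajectory")
  coords <- array(0, c(nat, 3, nf))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  for (i in seq_len(nf))
    coords[, , i] <- m[((i - 1) * nat + 1):(i * nat), ]
  trajectory(top, coords, times, box)
}

read_dcd_trajectory <- function(path, top, dt_ns, box) {
  xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
  nat <- n_atoms(top)
  if (ncol(xyz) != 3 * nat)
    stop("DCD atom count (", ncol(xyz) / 3,
         ") does not match topology (", nat, ")")
  nf <- nrow(xyz)
  cell <- tryCatch(
    suppressWarnings(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE)),
    error = function(e) NULL)
  if (!is.null(cell) && ncol(cell) >= 3 && all(is.finite(cell[, 1:3])) &&
      all(cell[, 1:3] > 0)) {
    if (ncol(cell) >= 6 && any(abs(cell[, 4:6] - 90) > 1e-3))
      stop("triclinic boxes are not supported (DCD unit-cell angles)")
    boxm <- as.matrix(cell[, 1:3, drop = FALSE])
  } else {
    if (is.null(box))
      stop("DCD carries no usable unit cell; pass box= explicitly")
    boxm <- matrix(check_box(box), nf, 3, byrow = TRUE)
  }
  coords <- array(0, c(nat, 3, nf))
  for (i in seq_len(nf))
    coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  trajectory(top, coords, (seq_len(nf) - 1) * dt_ns, boxm)
}
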