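ROLE_LEVELS <- c("protein", "lipid", "ligand", "ion", "solvent")

# Three-way residue chemical classes (Kyte-Doolittle-style partition).
AA_CLASS <- c(
  ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
  ILE = "hydrophobic", PHE = "hydrophobic", MET = "hydrophobic",
  TRP = "hydrophobic", PRO = "hydrophobic", GLY = "hydrophobic",
  CYS = "hydrophobic",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
  TYR = "polar", HIS = "polar",
  ASP = "charged", GLU = "charged", LYS = "charged", ARG = "charged"
)

#' Default residue-name to role dictionary
#'
#' Maps residue names to the roles used throughout the package (protein,
#' lipid, ligand, ion, solvent). Standard amino acids map to protein,
#' common phospholipids to lipid, fatty acids (DHA, DA) to ligand, simple
#' monatomic species to ion, and water models to solvent. Residue names
#' absent from the dictionary are assigned the ligand role with a warning
#' (never silently dropped). Override or extend by passing a modified copy
#' to [read_structure()].
#'
#' @return Named character vector: residue name -> role.
#' @export
default_role_map <- function() {
  aa <- names(AA_CLASS)
  c(
    stats::setNames(rep("protein", length(aa)), aa),
    POPC = "lipid", POPE = "lipid", POPS = "lipid", DPPC = "lipid",
    DOPC = "lipid", DMPC = "lipid", CHL1 = "lipid",
    DHA = "ligand", DA = "ligand", LIG = "ligand", MTS = "ligand",
    `NA` = "ion", CL = "ion", K = "ion", SOD = "ion", CLA = "ion",
    POT = "ion", CA2 = "ion", MG = "ion",
    SOL = "solvent", HOH = "solvent", TIP3 = "solvent", WAT = "solvent",
    SPC = "solvent"
  )
}

#' Construct a molecular topology
#'
#' The topology is the static atom table every analysis consumes: atom
#' names, residue identity, chain (subunit) membership, and a coarse role
#' label. An optional region map attributes residues to named protein
#' regions (helices S1-S4, the S3-S4 linker, the pore, ...) with an
#' extracellular-half flag, in the residue numbering of the input file.
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`
#'   (integer), `resname`, `chain`, `role` (one of protein, lipid, ligand,
#'   ion, solvent). A 0-based `index` column is added if absent.
#' @param region_map Optional data.frame with columns `region`, `chain`,
#'   `resid` and logical `extracellular`. Every (chain, resid) must exist
#'   in `atoms`; regions within one chain must be disjoint.
#' @return Object of class `topology`.
#' @export
topology <- function(atoms, region_map = NULL) {
  req <- c("name", "element", "resid", "resname", "chain", "role")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$index)) atoms$index <- seq_len(nrow(atoms)) - 1L
  if (anyDuplicated(atoms$index))
    stop("atom indices must be unique within a topology")
  if (any(!nzchar(atoms$element)))
    stop("every atom must carry a non-empty element symbol")
  bad <- setdiff(unique(atoms$role), ROLE_LEVELS)
  if (length(bad) > 0)
    stop("unknown atom roles: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(ROLE_LEVELS, collapse = ", "), ")")
  atoms$resid <- as.integer(atoms$resid)
  if (!is.null(region_map)) {
    region_map <- as.data.frame(region_map, stringsAsFactors = FALSE)
    rreq <- c("region", "chain", "resid")
    if (!all(rreq %in% names(region_map)))
      stop("region_map needs columns: ", paste(rreq, collapse = ", "))
    if (is.null(region_map$extracellular))
      region_map$extracellular <- FALSE
    key_top <- paste(atoms$chain, atoms$resid)
    key_reg <- paste(region_map$chain, region_map$resid)
    if (!all(key_reg %in% key_top))
      stop("region_map refers to residues absent from the topology: ",
           paste(utils::head(setdiff(key_reg, key_top), 5), collapse = "; "))
    if (anyDuplicated(key_reg))
      stop("regions within one chain must be disjoint (duplicated ",
           "chain/resid in region_map)")
  }
  structure(list(atoms = atoms, region_map = region_map),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat("topology:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resid))), "residues,",
      length(unique(a$chain)), "chains\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(a$role)),
                                table(a$role)), collapse = " "), "\n")
  if (!is.null(x$region_map))
    cat("  regions:", paste(unique(x$region_map$region), collapse = " "),
        "\n")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Subunit (chain) to residue mapping
#'
#' @param top A [topology()].
#' @return Named list: chain id -> ordered integer vector of residue ids.
#' @export
subunits <- function(top) {
  a <- top$atoms
  lapply(split(a$resid, a$chain), function(r) unique(r))
}

#' Construct a trajectory
#'
#' Time-ordered Cartesian frames over a fixed topology. Internal units are
#' Angstrom and nanoseconds throughout; unit conversion happens only in the
#' file readers.
#'
#' @param top A [topology()].
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param times Numeric vector of frame times (ns), strictly increasing.
#' @param box Length-3 orthorhombic box edges (Angstrom), or an
#'   `n_frames x 3` matrix for a fluctuating box.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(top, coords, times, box) {
  stopifnot(inherits(top, "topology"))
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != n_atoms(top))
    stop("coordinate count (", dim(coords)[1],
         ") does not match topology atom count (", n_atoms(top), ")")
  nf <- dim(coords)[3]
  times <- as.numeric(times)
  if (length(times) != nf)
    stop("length(times) must equal the number of frames")
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (any(times < 0)) stop("frame times must be >= 0")
  if (is.matrix(box)) {
    if (nrow(box) != nf || ncol(box) != 3)
      stop("per-frame box must be an n_frames x 3 matrix")
    for (i in seq_len(nf)) check_box(box[i, ])
  } else {
    box <- matrix(check_box(box), nf, 3, byrow = TRUE)
  }
  structure(list(topology = top, coords = coords, times = times,
                 box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  nf <- n_frames(x)
  cat("trajectory:", n_atoms(x$topology), "atoms,", nf, "frames, t = [",
      x$times[1], ",", x$times[nf], "] ns, box =",
      paste(signif(x$box[1, ], 4), collapse = " x "), "A\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Per-frame durations (ns)
#'
#' Frame i carries the duration of the interval to frame i+1; the last
#' frame carries the preceding interval's duration. For a single frame the
#' nominal spacing falls back to 1 ns.
#'
#' @param traj A [trajectory()].
#' @return Numeric vector of frame durations (ns).
#' @export
frame_durations <- function(traj) {
  nf <- n_frames(traj)
  if (nf == 1) return(1)
  d <- diff(traj$times)
  c(d, d[nf - 1])
}

frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Heavy-atom (non-hydrogen) filter
#'
#' @param top A [topology()].
#' @param idx 1-based atom positions to filter.
#' @return The subset of `idx` whose element is not hydrogen.
#' @export
heavy_atoms <- function(top, idx) {
  idx[toupper(top$atoms$element[idx]) != "H"]
}

guess_element <- function(name) {
  s <- sub("^[0-9'\"]+", "", toupper(name))
  s <- sub("[^A-Z].*$", "", s)
  if (!nzchar(s)) return("X")
  substr(s, 1, 1)
}

assign_roles <- function(resnames, role_map = default_role_map()) {
  rn <- toupper(trimws(resnames))
  roles <- unname(role_map[rn])
  unknown <- unique(rn[is.na(roles)])
  if (length(unknown) > 0) {
    warning("unknown residue name(s) assigned role 'ligand': ",
            paste(unknown, collapse = ", "), call. = FALSE)
    roles[is.na(roles)] <- "ligand"
  }
  roles
}
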