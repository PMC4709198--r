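#' Configuration for the synthetic system generator
#'
#' Describes a toy membrane system emulating a tetrameric voltage-gated
#' channel in a bilayer with amphipathic fatty-acid-like ligands: a rigid
#' four-subunit helix-bundle protein (one backbone and one side-chain bead
#' per pseudo-residue), static two-leaflet lipid rods, and ligands built as
#' a carboxyl head (O1, O2, C1) plus a tail of carbons C2..C<n> carrying
#' explicit pseudo-hydrogens. Ligand lateral motion is 2D Brownian with a
#' planted diffusion constant; tail conformations are resampled each frame
#' from a trans/gauche torsional model whose gauche probability scales with
#' `flexibility`. Contacts are planted by overriding the ligand position
#' during declared intervals, which gives exact ground truth.
#'
#' @param n_subunits Number of protein subunits (0 for a protein-free
#'   membrane patch).
#' @param residues_per_region Named integer vector: residues per region per
#'   subunit (regions S1..S4, S3-S4_linker, pore).
#' @param n_ligands,n_lipids Molecule counts.
#' @param tail_length Tail carbons (C1..C<n>), default 22.
#' @param flexibility Tail torsional disorder in [0, 1]: 0 gives an
#'   all-trans chain, 1 a maximally disordered chain (gauche probability
#'   2/3).
#' @param planted_contacts List of planted contacts, each a list with
#'   `chain`, `resid`, `ligand` (1-based), `part` ("head" or "tail") and
#'   `intervals` (list of `c(start, end)` in ns, inclusive).
#' @param planted_D Lateral diffusion constant in cm^2/s (default the
#'   4e-9 cm^2/s regime typical of fatty acids in a bilayer).
#' @param box Orthorhombic box edges (Angstrom).
#' @param n_frames,dt_ns Frame count and spacing (ns).
#' @param seed Integer seed; the seed fully determines the output.
#' @param steer_distance Distance (Angstrom) at which the designated part
#'   atom is held from the target residue during planted intervals.
#' @param exclusion_margin Free (non-planted) ligands are reflected off a
#'   cylinder of radius protein-radius + `exclusion_margin` so that only
#'   planted contacts can occur.
#' @param ligand_resname Residue name given to ligands.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_subunits = 4,
                             residues_per_region = c(
                               S1 = 6, S2 = 6, S3 = 6, S4 = 6,
                               `S3-S4_linker` = 3, pore = 4),
                             n_ligands = 8, n_lipids = 40,
                             tail_length = 22, flexibility = 0.8,
                             planted_contacts = list(),
                             planted_D = 4e-9,
                             box = c(130, 130, 80),
                             n_frames = 1000, dt_ns = 1, seed = 1,
                             steer_distance = 3.0,
                             exclusion_margin = 14,
                             ligand_resname = "DHA") {
  cfg <- list(n_subunits = as.integer(n_subunits),
              residues_per_region = residues_per_region,
              n_ligands = as.integer(n_ligands),
              n_lipids = as.integer(n_lipids),
              tail_length = as.integer(tail_length),
              flexibility = flexibility,
              planted_contacts = planted_contacts,
              planted_D = planted_D, box = check_box(box),
              n_frames = as.integer(n_frames), dt_ns = dt_ns,
              seed = as.integer(seed),
              steer_distance = steer_distance,
              exclusion_margin = exclusion_margin,
              ligand_resname = ligand_resname)
  if (cfg$flexibility < 0 || cfg$flexibility > 1)
    stop("flexibility must lie in [0, 1]")
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  if (cfg$tail_length < 4) stop("tail_length must be >= 4")
  if (cfg$planted_D < 0) stop("planted_D must be >= 0")
  tmax <- (cfg$n_frames - 1) * cfg$dt_ns
  for (pc in cfg$planted_contacts) {
    need <- c("chain", "resid", "ligand", "part", "intervals")
    if (!all(need %in% names(pc)))
      stop("each planted contact needs fields: ",
           paste(need, collapse = ", "))
    if (!pc$part %in% c("head", "tail"))
      stop("planted contact part must be 'head' or 'tail'")
    if (pc$ligand < 1 || pc$ligand > cfg$n_ligands)
      stop("planted contact refers to ligand ", pc$ligand,
           " but n_ligands = ", cfg$n_ligands)
    for (iv in pc$intervals) {
      if (length(iv) != 2 || iv[1] > iv[2] || iv[1] < 0 || iv[2] > tmax)
        stop("planted interval [", paste(iv, collapse = ", "),
             "] outside trajectory span [0, ", tmax, "] ns")
    }
  }
  class(cfg) <- "generator_config"
  cfg
}

# Bond geometry of the torsional tail model.
CC_BOND <- 1.53
CC_ANGLE_DEG <- 111
CH_BOND <- 1.09
CO_BOND <- 1.25

#' Build a carbon chain from internal coordinates
#'
#' Natural-extension (NeRF) chain build with fixed bond length 1.53 A and
#' bond angle 111 degrees; dihedrals are supplied per rotatable bond. The
#' chain starts at the origin with its all-trans axis along +x and lies in
#' the z = 0 plane when all dihedrals are 180 degrees.
#'
#' @param n Number of carbons.
#' @param dihedrals_deg Numeric vector of length `n - 3` (degrees).
#' @return n x 3 coordinate matrix.
#' @export
build_chain <- function(n, dihedrals_deg) {
  if (n < 3) stop("chain needs at least 3 atoms")
  if (length(dihedrals_deg) != max(n - 3, 0))
    stop("need ", n - 3, " dihedrals for a ", n, "-carbon chain")
  b <- CC_BOND
  ang <- CC_ANGLE_DEG * pi / 180
  P <- matrix(0, n, 3)
  P[2, ] <- c(b, 0, 0)
  P[3, ] <- P[2, ] + b * c(cos(pi - ang), sin(pi - ang), 0)
  if (n >= 4) {
    tau <- dihedrals_deg * pi / 180
    sa <- sin(ang)
    ca <- cos(ang)
    for (i in 4:n) {
      A <- P[i - 3, ]; B <- P[i - 2, ]; C <- P[i - 1, ]
      bc <- normalize3(C - B)
      nv <- normalize3(cross3(B - A, bc))
      mv <- cross3(nv, bc)
      t1 <- tau[i - 3]
      d2 <- b * c(-ca, sa * cos(t1), sa * sin(t1))
      P[i, ] <- C + bc * d2[1] + mv * d2[2] + nv * d2[3]
    }
  }
  P
}

# Pseudo-hydrogen positions perpendicular to the local C-C-C plane, two
# per tail carbon (carbons 2..n). Returns a 2*(n-1) x 3 matrix in the
# order H2A, H2B, H3A, ... HnB.
chain_hydrogens <- function(P) {
  n <- nrow(P)
  H <- matrix(0, 2 * (n - 1), 3)
  row <- 1
  for (i in 2:n) {
    if (i < n) {
      v1 <- P[i - 1, ] - P[i, ]; v2 <- P[i + 1, ] - P[i, ]
    } else {
      v1 <- P[n - 2, ] - P[n, ]; v2 <- P[n - 1, ] - P[n, ]
    }
    nv <- cross3(v1, v2)
    nn <- sqrt(sum(nv * nv))
    if (nn < 1e-9) nv <- c(0, 0, 1) else nv <- nv / nn
    H[row, ] <- P[i, ] + CH_BOND * nv
    H[row + 1, ] <- P[i, ] - CH_BOND * nv
    row <- row + 2
  }
  H
}

ligand_atom_names <- function(tail_length) {
  c("O1", "O2", paste0("C", seq_len(tail_length)),
    as.vector(t(outer(2:tail_length, c("A", "B"),
                      function(k, s) paste0("H", k, s)))))
}

ligand_atom_elements <- function(tail_length) {
  c("O", "O", rep("C", tail_length), rep("H", 2 * (tail_length - 1)))
}

# Second carboxyl oxygen placed off the C1->C2 axis.
o2_position <- function(C1, dhat) {
  ref <- if (abs(dhat[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- normalize3(cross3(dhat, ref))
  C1 + CO_BOND * (-0.5 * dhat + 0.8660254 * u)
}

# Assemble one ligand conformation (atom order O1, O2, C1..Cn, H2A..HnB)
# from a carbon chain given in lab coordinates with C1 as the first row.
assemble_ligand <- function(chain_lab) {
  dhat <- normalize3(chain_lab[2, ] - chain_lab[1, ])
  O1 <- chain_lab[1, ] - CO_BOND * dhat
  O2 <- o2_position(chain_lab[1, ], dhat)
  rbind(O1, O2, chain_lab, chain_hydrogens(chain_lab))
}

# Rotation taking the canonical chain frame (all-trans axis +x, chain
# plane z = 0) into the lab frame with the axis along -z (tails point
# toward the membrane center).
R_TAIL_DOWN <- cbind(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0))

free_ligand_coords <- function(anchor_xy, z_head, tau_deg, tail_length) {
  chain <- build_chain(tail_length, tau_deg)
  lab <- chain %*% t(R_TAIL_DOWN)
  lab <- sweep(lab, 2, c(anchor_xy[1], anchor_xy[2], z_head) - lab[1, ],
               "+")
  assemble_ligand(lab)
}

# Planted (steered) conformation: all-trans chain laid out radially
# outward from the box center in the horizontal plane of the target
# residue's side-chain bead, with the designated part atom held at
# steer_distance from it. Head contacts put O1 innermost; tail contacts
# put the terminal carbon innermost; every other ligand atom is therefore
# strictly farther from the protein.
planted_ligand_coords <- function(cb, center_xy, part, steer,
                                  tail_length) {
  rhat <- normalize3(c(cb[1] - center_xy[1], cb[2] - center_xy[2], 0))
  P <- c(cb[1], cb[2], cb[3]) + steer * rhat
  chain <- build_chain(tail_length, rep(180, tail_length - 3))
  dir <- if (part == "head") rhat else -rhat
  Rz <- cbind(dir, c(-dir[2], dir[1], 0), c(0, 0, 1))
  lab <- chain %*% t(Rz)
  anchor_atom <- if (part == "head") {
    # O1 sits CO_BOND before C1 along the chain axis
    lab[1, ] - CO_BOND * normalize3(lab[2, ] - lab[1, ])
  } else {
    lab[tail_length, ]
  }
  lab <- sweep(lab, 2, P - anchor_atom, "+")
  assemble_ligand(lab)
}

build_protein <- function(cfg) {
  if (cfg$n_subunits == 0) return(NULL)
  rpr <- cfg$residues_per_region
  regions <- names(rpr)
  if (is.null(regions) || any(!nzchar(regions)))
    stop("residues_per_region must be a named vector")
  helix_regions <- setdiff(regions, c("pore", "S3-S4_linker"))
  offs <- stats::setNames(
    seq(-0.45, 0.45, length.out = max(length(helix_regions), 2))[
      seq_along(helix_regions)], helix_regions)
  center <- cfg$box / 2
  rise <- 3.2
  polar_cycle <- c("SER", "GLU", "THR", "ARG", "ASN", "ASP")
  hydro_cycle <- c("LEU", "ILE", "VAL", "PHE", "ALA", "MET")
  rows <- list()
  coords <- list()
  rmap <- list()
  for (s in seq_len(cfg$n_subunits)) {
    ch <- LETTERS[s]
    phi <- 2 * pi * (s - 1) / cfg$n_subunits
    resid <- 300L
    for (r in regions) {
      m <- rpr[[r]]
      if (m < 1) next
      if (r == "pore") {
        radius <- 6; delta <- 0
      } else if (r == "S3-S4_linker") {
        radius <- 14
        delta <- mean(offs[intersect(c("S3", "S4"), helix_regions)])
        if (!is.finite(delta)) delta <- 0
      } else {
        radius <- 14; delta <- offs[[r]]
      }
      xy <- center[1:2] + radius * c(cos(phi + delta), sin(phi + delta))
      zmax <- max(rpr[setdiff(regions, "S3-S4_linker")]) * rise / 2
      for (j in seq_len(m)) {
        z <- if (r == "S3-S4_linker") {
          center[3] + zmax + j * rise
        } else {
          center[3] + (j - (m + 1) / 2) * rise
        }
        resid <- resid + 1L
        extr <- z >= center[3]
        resname <- if (extr) polar_cycle[(j %% 6) + 1] else
          hydro_cycle[(j %% 6) + 1]
        rhat <- normalize3(c(xy[1] - center[1], xy[2] - center[2], 0))
        ca <- c(xy, z)
        cb <- ca + 3.0 * rhat
        rows[[length(rows) + 1]] <- data.frame(
          name = c("CA", "CB"), element = "C",
          resid = resid, resname = resname, chain = ch,
          role = "protein", stringsAsFactors = FALSE)
        coords[[length(coords) + 1]] <- rbind(ca, cb)
        rmap[[length(rmap) + 1]] <- data.frame(
          region = r, chain = ch, resid = resid, extracellular = extr,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(atoms = do.call(rbind, rows), coords = do.call(rbind, coords),
       region_map = do.call(rbind, rmap))
}

build_lipids <- function(cfg, protein_radius) {
  if (cfg$n_lipids == 0) return(NULL)
  center <- cfg$box / 2
  sp <- 8
  gx <- seq(5, cfg$box[1] - 5, by = sp)
  gy <- seq(5, cfg$box[2] - 5, by = sp)
  grid <- expand.grid(x = gx, y = gy)
  keep <- sqrt((grid$x - center[1])^2 + (grid$y - center[2])^2) >=
    protein_radius + 4
  grid <- grid[keep, , drop = FALSE]
  n_up <- ceiling(cfg$n_lipids / 2)
  n_dn <- cfg$n_lipids - n_up
  if (nrow(grid) < max(n_up, n_dn))
    stop("box too small to place ", cfg$n_lipids, " lipids; enlarge box")
  # spread leaflet occupancy evenly over the available grid
  grid <- grid[round(seq(1, nrow(grid), length.out = max(n_up, n_dn))), ,
               drop = FALSE]
  rows <- list(); coords <- list(); resid <- 0L
  place <- function(xy, leaflet) {
    zh <- center[3] + leaflet * 15
    zt <- zh - leaflet * 2.5 * (1:4)
    resid <<- resid + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      name = c("N", paste0("C", 1:4)), element = c("N", rep("C", 4)),
      resid = resid, resname = "POPC", chain = "L", role = "lipid",
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1]] <<- cbind(rep(xy[1], 5), rep(xy[2], 5),
                                           c(zh, zt))
  }
  for (i in seq_len(n_up)) place(as.numeric(grid[i, ]), +1)
  for (i in seq_len(n_dn)) place(as.numeric(grid[i, ]), -1)
  list(atoms = do.call(rbind, rows), coords = do.call(rbind, coords))
}

# Sample per-frame dihedrals from the trans/gauche model using
# pre-drawn uniforms, so that chains with different flexibility can share
# randomness (common random numbers).
dihedrals_from_uniforms <- function(u1, u2, flexibility) {
  gauche <- u1 < 2 * flexibility / 3
  ifelse(gauche, ifelse(u2 < 0.5, 60, -60), 180)
}

# 2D Brownian anchors with reflection off a central exclusion cylinder
# and wrapping into [0, box).
brownian_anchors <- function(starts, steps, box, center, r_excl) {
  n_lig <- nrow(starts)
  nf <- dim(steps)[3] + 1
  anchors <- array(0, c(n_lig, 2, nf))
  pos <- starts
  anchors[, , 1] <- pos
  if (nf == 1) return(anchors)
  for (t in 2:nf) {
    pos <- pos + steps[, , t - 1, drop = FALSE][, , 1]
    if (r_excl > 0) {
      d <- sweep(pos, 2, center[1:2], "-")
      for (k in 1:2) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
      r <- sqrt(rowSums(d^2))
      inside <- r < r_excl & r > 1e-9
      if (any(inside)) {
        fac <- (2 * r_excl - r[inside]) / r[inside]
        pos[inside, ] <- rep(center[1:2], each = sum(inside)) +
          d[inside, , drop = FALSE] * fac
      }
    }
    for (k in 1:2) pos[, k] <- pos[, k] - box[k] * floor(pos[, k] / box[k])
    anchors[, , t] <- pos
  }
  anchors
}

#' Generate a synthetic membrane system with planted ground truth
#'
#' Builds the topology and trajectory described by a [generator_config()]
#' together with the planted truth (contact intervals, diffusion constant,
#' tail-disorder level). All randomness flows through `set.seed(seed)`:
#' identical configurations give bitwise-identical output.
#'
#' @param cfg A [generator_config()].
#' @return Object of class `synthetic_system`: list with `topology`,
#'   `trajectory`, `ground_truth` and `config`.
#' @export
generate_system <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  center <- cfg$box / 2
  prot <- build_protein(cfg)
  protein_radius <- 0
  if (!is.null(prot)) {
    protein_radius <- max(sqrt((prot$coords[, 1] - center[1])^2 +
                               (prot$coords[, 2] - center[2])^2))
    for (pc in cfg$planted_contacts) {
      hit <- prot$atoms$chain == pc$chain & prot$atoms$resid == pc$resid
      if (!any(hit))
        stop("planted contact refers to nonexistent residue ",
             pc$chain, "/", pc$resid)
    }
  } else if (length(cfg$planted_contacts) > 0) {
    stop("cannot plant contacts without a protein (n_subunits = 0)")
  }
  lip <- build_lipids(cfg, protein_radius)
  nl <- cfg$n_ligands
  tl <- cfg$tail_length
  lig_atoms <- NULL
  if (nl > 0) {
    nms <- ligand_atom_names(tl)
    lig_atoms <- data.frame(
      name = rep(nms, nl), element = rep(ligand_atom_elements(tl), nl),
      resid = rep(seq_len(nl), each = length(nms)),
      resname = cfg$ligand_resname, chain = "X", role = "ligand",
      stringsAsFactors = FALSE)
  }
  atoms <- rbind(prot$atoms, lip$atoms, lig_atoms)
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("empty system: nothing to generate")
  top <- topology(atoms, region_map = prot$region_map)

  nf <- cfg$n_frames
  times <- (seq_len(nf) - 1) * cfg$dt_ns
  nat <- nrow(atoms)
  coords <- array(0, c(nat, 3, nf))
  n_static <- (if (is.null(prot)) 0 else nrow(prot$coords)) +
    (if (is.null(lip)) 0 else nrow(lip$coords))
  static <- rbind(prot$coords, lip$coords)
  if (n_static > 0)
    coords[1:n_static, , ] <- array(rep(static, nf),
                                    c(n_static, 3, nf))

  gt_contacts <- NULL
  if (nl > 0) {
    r_excl <- if (is.null(prot)) 0 else
      protein_radius + cfg$exclusion_margin
    r_max <- min(cfg$box[1:2]) / 2 - 5
    if (r_excl > 0 && r_excl >= r_max)
      stop("box too small for the ligand annulus; enlarge box")
    # draw order is fixed: starts, walk steps, tail uniforms
    if (r_excl > 0) {
      ang <- stats::runif(nl, 0, 2 * pi)
      rad <- sqrt(stats::runif(nl, r_excl^2, r_max^2))
      starts <- cbind(center[1] + rad * cos(ang),
                      center[2] + rad * sin(ang))
    } else {
      starts <- cbind(stats::runif(nl, 0, cfg$box[1]),
                      stats::runif(nl, 0, cfg$box[2]))
    }
    sd_step <- sqrt(2 * cfg$planted_D * 1e7 * cfg$dt_ns)
    steps <- if (nf > 1)
      array(stats::rnorm(nl * 2 * (nf - 1), sd = sd_step),
            c(nl, 2, nf - 1))
    else array(0, c(nl, 2, 0))
    anchors <- brownian_anchors(starts, steps, cfg$box, center, r_excl)
    nd <- tl - 3
    u1 <- u2 <- NULL
    if (cfg$flexibility > 0) {
      u1 <- array(stats::runif(nd * nl * nf), c(nd, nl, nf))
      u2 <- array(stats::runif(nd * nl * nf), c(nd, nl, nf))
    }
    z_head <- center[3] + 13
    lig_offset <- n_static
    npl <- length(ligand_atom_names(tl))
    trans_cache <- free_ligand_coords(c(0, 0), z_head, rep(180, nd), tl)
    for (t in seq_len(nf)) {
      for (l in seq_len(nl)) {
        rows <- lig_offset + (l - 1) * npl + seq_len(npl)
        if (cfg$flexibility > 0) {
          tau <- dihedrals_from_uniforms(u1[, l, t], u2[, l, t],
                                         cfg$flexibility)
          xyz <- free_ligand_coords(anchors[l, , t], z_head, tau, tl)
        } else {
          xyz <- sweep(trans_cache, 2,
                       c(anchors[l, , t] - trans_cache[3, 1:2], 0), "+")
        }
        coords[rows, , t] <- wrap_coords(xyz, cfg$box)
      }
    }
    # planted contacts override the Brownian placement
    for (pc in cfg$planted_contacts) {
      sel <- prot$atoms$chain == pc$chain & prot$atoms$resid == pc$resid &
        prot$atoms$name == "CB"
      cb <- prot$coords[which(sel)[1], ]
      conf <- planted_ligand_coords(cb, center[1:2], pc$part,
                                    cfg$steer_distance, tl)
      conf <- wrap_coords(conf, cfg$box)
      rows <- lig_offset + (pc$ligand - 1) * npl + seq_len(npl)
      for (iv in pc$intervals) {
        fr <- which(times >= iv[1] - 1e-9 & times <= iv[2] + 1e-9)
        for (t in fr) coords[rows, , t] <- conf
      }
      gt_contacts <- rbind(gt_contacts, data.frame(
        chain = pc$chain, resid = pc$resid, ligand = pc$ligand,
        part = pc$part,
        start_ns = vapply(pc$intervals, `[`, 0, 1),
        end_ns = vapply(pc$intervals, `[`, 0, 2),
        stringsAsFactors = FALSE))
    }
  }

  traj <- trajectory(top, coords, times, cfg$box)
  planted_ligands <- if (is.null(gt_contacts)) integer(0) else
    sort(unique(gt_contacts$ligand))
  gt <- list(
    planted_D_cm2_s = cfg$planted_D,
    flexibility = cfg$flexibility,
    steer_distance = cfg$steer_distance,
    contacts = gt_contacts,
    free_ligands = setdiff(seq_len(nl), planted_ligands))
  structure(list(topology = top, trajectory = traj, ground_truth = gt,
                 config = cfg),
            class = "synthetic_system")
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat("synthetic system (seed", x$config$seed, ")\n")
  print(x$topology)
  print(x$trajectory)
  nc <- if (is.null(x$ground_truth$contacts)) 0 else
    nrow(x$ground_truth$contacts)
  cat("  planted: D =", x$ground_truth$planted_D_cm2_s, "cm^2/s,",
      nc, "contact interval(s), flexibility",
      x$ground_truth$flexibility, "\n")
  invisible(x)
}

#' Generate a matched pair of single-ligand membrane-patch trajectories
#'
#' Two trajectories of one amphipathic ligand that share every random draw
#' (anchor walk and torsional uniforms) and differ only in the
#' tail-disorder parameter: a saturated-like chain (low flexibility) and a
#' polyunsaturated-like chain (high flexibility). With coupled randomness
#' the disordered chain is more compact frame by frame, which makes the
#' chain-descriptor contrasts (radius of gyration, head-to-tail distance,
#' order parameters) strict rather than merely statistical.
#'
#' @param flexibility_sat,flexibility_poly Tail disorder of the two
#'   chains; `flexibility_sat` must not exceed `flexibility_poly`.
#' @param n_frames,dt_ns,seed,tail_length,box As in [generator_config()].
#' @return List with trajectories `sat` and `poly` (residue names DA and
#'   DHA) and a `ground_truth` list of the two disorder levels.
#' @export
generate_fatty_acid_pair <- function(flexibility_sat = 0.1,
                                     flexibility_poly = 0.8,
                                     n_frames = 2000, seed = 1,
                                     dt_ns = 1, tail_length = 22,
                                     box = c(80, 80, 60)) {
  if (flexibility_sat > flexibility_poly)
    stop("flexibility_sat must be <= flexibility_poly")
  box <- check_box(box)
  tl <- as.integer(tail_length)
  nf <- as.integer(n_frames)
  nd <- tl - 3
  set.seed(as.integer(seed))
  start <- c(stats::runif(1, 10, box[1] - 10),
             stats::runif(1, 10, box[2] - 10))
  sd_step <- sqrt(2 * 4e-9 * 1e7 * dt_ns)
  steps <- if (nf > 1) matrix(stats::rnorm(2 * (nf - 1), sd = sd_step),
                              ncol = 2) else matrix(0, 0, 2)
  u1 <- matrix(stats::runif(nd * nf), nd, nf)
  u2 <- matrix(stats::runif(nd * nf), nd, nf)
  anchors <- matrix(0, nf, 2)
  anchors[1, ] <- start
  if (nf > 1) for (t in 2:nf) {
    p <- anchors[t - 1, ] + steps[t - 1, ]
    anchors[t, ] <- p - box[1:2] * floor(p / box[1:2])
  }
  z_head <- box[3] / 2 + 13
  make_one <- function(flex, resname) {
    atoms <- data.frame(
      name = ligand_atom_names(tl), element = ligand_atom_elements(tl),
      resid = 1L, resname = resname, chain = "X", role = "ligand",
      stringsAsFactors = FALSE)
    top <- topology(atoms)
    coords <- array(0, c(nrow(atoms), 3, nf))
    for (t in seq_len(nf)) {
      tau <- dihedrals_from_uniforms(u1[, t], u2[, t], flex)
      coords[, , t] <- wrap_coords(
        free_ligand_coords(anchors[t, ], z_head, tau, tl), box)
    }
    trajectory(top, coords, (seq_len(nf) - 1) * dt_ns, box)
  }
  list(sat = make_one(flexibility_sat, "DA"),
       poly = make_one(flexibility_poly, "DHA"),
       ground_truth = list(flexibility_sat = flexibility_sat,
                           flexibility_poly = flexibility_poly))
}

#' Write a synthetic system to disk
#'
#' Writes the first frame as PDB, the trajectory in the plaintext dialect,
#' the ground truth and the region map as YAML sidecars.
#'
#' @param sys A `synthetic_system` from [generate_system()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, a named list of the written paths.
#' @export
write_system <- function(sys, dir, prefix = "system") {
  stopifnot(inherits(sys, "synthetic_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  write_structure(sys$topology, frame_coords(sys$trajectory, 1),
                  p(".pdb"), box = sys$trajectory$box[1, ])
  write_trajectory(sys$trajectory, p(".traj"))
  gt <- sys$ground_truth
  gt$contacts <- if (is.null(gt$contacts)) list() else
    lapply(seq_len(nrow(gt$contacts)),
           function(i) as.list(gt$contacts[i, ]))
  yaml::write_yaml(gt, p("_truth.yaml"))
  rm <- sys$topology$region_map
  if (!is.null(rm))
    yaml::write_yaml(lapply(seq_len(nrow(rm)),
                            function(i) as.list(rm[i, ])),
                     p("_regions.yaml"))
  invisible(list(pdb = p(".pdb"), traj = p(".traj"),
                 truth = p("_truth.yaml"),
                 regions = if (is.null(rm)) NULL else p("_regions.yaml")))
}
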