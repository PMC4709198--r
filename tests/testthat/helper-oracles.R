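# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's vectorized code paths.

# Minimum-image distance by explicit enumeration of the 27 neighbor
# images (valid for points inside the primary cell).
bf_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- b + c(i, j, k) * box - a
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# All-pairs minimum distance between two point sets, scalar loops.
bf_set_min <- function(A, B, box) {
  A <- matrix(A, ncol = 3)
  B <- matrix(B, ncol = 3)
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, bf_min_image(A[i, ], B[j, ], box))
  best
}

# Per-residue-group contact flags against a point set, scalar loops.
bf_contacts <- function(P, res_index, L, box, cutoff) {
  out <- logical(max(res_index))
  for (r in seq_len(max(res_index))) {
    rows <- which(res_index == r)
    out[r] <- bf_set_min(P[rows, , drop = FALSE], L, box) <= cutoff
  }
  out
}

# Occupancy grid by scalar per-frame binning.
bf_occupancy <- function(frames_list, origin, voxel, dims) {
  counts <- array(0, dims)
  for (pts in frames_list) {
    hit <- array(FALSE, dims)
    for (i in seq_len(nrow(pts))) {
      ix <- floor((pts[i, ] - origin) / voxel) + 1
      ix <- pmin(pmax(ix, 1), dims)
      hit[ix[1], ix[2], ix[3]] <- TRUE
    }
    counts <- counts + hit
  }
  counts / length(frames_list)
}

# Pairwise-sum radius of gyration: Rg^2 = (1 / 2N^2) sum_ij d_ij^2.
bf_rg <- function(pts) {
  n <- nrow(pts)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + sum((pts[i, ] - pts[j, ])^2)
  sqrt(s / (2 * n^2))
}

# A bag of free atoms as a topology (one residue per atom by default).
point_topology <- function(n, role = "ligand", names = NULL,
                           resname = "LIG", chain = "X",
                           resid = seq_len(n), element = "C") {
  if (is.null(names)) names <- paste0("P", seq_len(n))
  topology(data.frame(
    name = names, element = rep_len(element, n),
    resid = rep_len(resid, n), resname = rep_len(resname, n),
    chain = rep_len(chain, n), role = rep_len(role, n),
    stringsAsFactors = FALSE))
}

# One-ligand topology with tail carbons C2..C<tl>, one pseudo-hydrogen
# per carbon, and a 3-atom head; used by the closed-form order-parameter
# and Rg tests. Returns the topology, a matching minimal schema, and the
# row indices of the carbons and hydrogens.
ch_fixture <- function(tl = 5) {
  carbons <- paste0("C", 2:tl)
  hydros <- paste0("H", 2:tl, "A")
  names <- c("O1", "O2", "C1", carbons, hydros)
  elem <- c("O", "O", "C", rep("C", length(carbons)),
            rep("H", length(hydros)))
  top <- topology(data.frame(
    name = names, element = elem, resid = 1L, resname = "LIG",
    chain = "X", role = "ligand", stringsAsFactors = FALSE))
  schema <- ligand_schema(
    tail_length = tl,
    ch_pairs = stats::setNames(as.list(hydros), carbons))
  list(top = top, schema = schema,
       c_rows = match(carbons, names), h_rows = match(hydros, names))
}

# Trajectory where every tail carbon's C-H bond points along `dirs`
# (a n_frames x 3 matrix of unit vectors).
ch_trajectory <- function(fix, dirs, box = c(100, 100, 100)) {
  nf <- nrow(dirs)
  nat <- nrow(fix$top$atoms)
  coords <- array(0, c(nat, 3, nf))
  base <- cbind(seq_len(nat) * 3, 10, 10)  # spread atoms out
  for (t in seq_len(nf)) {
    coords[, , t] <- base
    coords[fix$h_rows, , t] <- base[fix$c_rows, ] +
      matrix(dirs[t, ], length(fix$h_rows), 3, byrow = TRUE) * 1.09
  }
  trajectory(fix$top, coords, (seq_len(nf) - 1) * 1.0, box)
}

random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Apply one random rigid transform to an n x 3 matrix.
random_rigid <- function(x) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  sweep(x %*% t(R), 2, stats::rnorm(3, sd = 5), "+")
}

# Measure a 4-atom dihedral angle (degrees, in [0, 180]).
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  ang <- acos(pmin(pmax(sum(n1 * n2) /
                          sqrt(sum(n1^2) * sum(n2^2)), -1), 1))
  ang * 180 / pi
}
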