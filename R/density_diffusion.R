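#' Fractional-occupancy density grid
#'
#' Voxelizes space and records, per voxel, the fraction of frames in which
#' at least one selected atom lies inside it. With `align_to`, every frame
#' is first rigid-body superposed onto the first frame over that selection
#' (protein-aligned frame of reference); otherwise binning happens in the
#' raw lab frame. The grid covers the selection's bounding box over all
#' frames plus a margin.
#'
#' @param traj A [trajectory()].
#' @param selection Selection string for the atoms to bin.
#' @param voxel Voxel edge length in Angstrom (default 1).
#' @param align_to Optional selection string for the superposition
#'   reference (e.g. `"role:protein and name:CA"`).
#' @param margin Margin added around the bounding box, in voxels.
#' @return Object of class `occupancy_grid`: list with `origin`, `voxel`,
#'   `dim`, `occupancy` (3D array in [0, 1]) and metadata.
#' @export
occupancy_grid <- function(traj, selection, voxel = 1.0, align_to = NULL,
                           margin = 2) {
  if (voxel <= 0) stop("voxel edge must be > 0")
  top <- traj$topology
  sel <- resolve_selection(selection, top)
  if (length(sel) == 0) stop("selection is empty")
  nf <- n_frames(traj)
  pts <- vector("list", nf)
  if (!is.null(align_to)) {
    asel <- resolve_selection(align_to, top)
    if (length(asel) < 3) stop("align_to selection needs >= 3 atoms")
    ref <- matrix(traj$coords[asel, , 1], ncol = 3)
    for (t in seq_len(nf)) {
      fit <- kabsch(matrix(traj$coords[asel, , t], ncol = 3), ref)
      pts[[t]] <- fit$transform(matrix(traj$coords[sel, , t], ncol = 3))
    }
  } else {
    for (t in seq_len(nf))
      pts[[t]] <- matrix(traj$coords[sel, , t], ncol = 3)
  }
  all_pts <- do.call(rbind, pts)
  lo <- apply(all_pts, 2, min) - margin * voxel
  hi <- apply(all_pts, 2, max) + margin * voxel
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel)))
  counts <- array(0L, dims)
  for (t in seq_len(nf)) {
    ix <- floor(sweep(pts[[t]], 2, lo) / voxel) + 1L
    ix <- pmin(pmax(ix, 1L),
               matrix(dims, nrow(ix), 3, byrow = TRUE))
    lin <- unique(ix[, 1] + (ix[, 2] - 1L) * dims[1] +
                    (ix[, 3] - 1L) * dims[1] * dims[2])
    counts[lin] <- counts[lin] + 1L
  }
  structure(list(origin = lo, voxel = voxel, dim = dims,
                 occupancy = counts / nf, n_frames = nf,
                 selection = selection,
                 aligned = !is.null(align_to)),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat("occupancy grid:", paste(x$dim, collapse = " x "), "voxels of",
      x$voxel, "A over", x$n_frames, "frames; max occupancy",
      round(max(x$occupancy), 3), "\n")
  invisible(x)
}

#' Extract and export an iso-occupancy surface
#'
#' Thresholds the occupancy grid at a fractional occupancy and builds the
#' boundary surface of the above-threshold voxel set (quadrilateral faces
#' between above- and below-threshold voxels: the exact level set of the
#' voxelized field). Optionally writes the volumetric grid in OpenDX
#' format and the surface as Wavefront OBJ. An empty surface (no voxel
#' above threshold) is a warning, not an error.
#'
#' @param grid An [occupancy_grid()].
#' @param threshold Fractional occupancy in (0, 1).
#' @param dx_path Optional path for the OpenDX volumetric file.
#' @param obj_path Optional path for the OBJ surface file.
#' @return Object of class `iso_surface`: list with `n_voxels` (count
#'   above threshold), `vertices` (m x 3), `faces` (q x 4 vertex indices),
#'   `threshold`.
#' @export
iso_surface_export <- function(grid, threshold, dx_path = NULL,
                               obj_path = NULL) {
  stopifnot(inherits(grid, "occupancy_grid"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  occ <- grid$occupancy
  above <- occ >= threshold
  n_above <- sum(above)
  verts <- NULL
  faces <- NULL
  if (n_above == 0) {
    warning("no voxel at or above occupancy ", threshold,
            "; surface is empty")
  } else {
    idx <- which(above, arr.ind = TRUE)
    d <- grid$dim
    vox_above <- array(FALSE, d)
    vox_above[above] <- TRUE
    neighbor_clear <- function(ii, off) {
      jj <- sweep(ii, 2, off, "+")
      inside <- jj[, 1] >= 1 & jj[, 1] <= d[1] &
        jj[, 2] >= 1 & jj[, 2] <= d[2] & jj[, 3] >= 1 & jj[, 3] <= d[3]
      out <- rep(TRUE, nrow(jj))
      if (any(inside)) {
        lin <- jj[inside, 1] + (jj[inside, 2] - 1) * d[1] +
          (jj[inside, 3] - 1) * d[1] * d[2]
        out[inside] <- !vox_above[lin]
      }
      out
    }
    vlist <- list()
    flist <- list()
    nv <- 0L
    offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                  c(0, 0, -1), c(0, 0, 1))
    # corner offsets (in voxel units) of the quad for each face direction
    face_corners <- list(
      rbind(c(0,0,0), c(0,1,0), c(0,1,1), c(0,0,1)),
      rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1)),
      rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1)),
      rbind(c(0,1,0), c(1,1,0), c(1,1,1), c(0,1,1)),
      rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),
      rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1)))
    for (f in 1:6) {
      expose <- neighbor_clear(idx, offs[f, ])
      if (!any(expose)) next
      cells <- idx[expose, , drop = FALSE]
      for (r in seq_len(nrow(cells))) {
        base <- grid$origin + (cells[r, ] - 1) * grid$voxel
        quad <- sweep(face_corners[[f]] * grid$voxel, 2, base, "+")
        vlist[[length(vlist) + 1]] <- quad
        flist[[length(flist) + 1]] <- nv + 1:4
        nv <- nv + 4L
      }
    }
    verts <- do.call(rbind, vlist)
    faces <- do.call(rbind, flist)
  }
  if (!is.null(dx_path)) write_dx(grid, dx_path)
  if (!is.null(obj_path) && !is.null(verts))
    write_obj(verts, faces, obj_path)
  structure(list(n_voxels = n_above, vertices = verts, faces = faces,
                 threshold = threshold),
            class = "iso_surface")
}

#' Write an occupancy grid in OpenDX format
#'
#' Regular-grid OpenDX text format as read by common molecular viewers
#' (z varies fastest).
#'
#' @param grid An [occupancy_grid()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dim
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("object 1 class gridpositions counts %d %d %d\n",
              d[1], d[2], d[3]), file = con)
  cat(sprintf("origin %g %g %g\n", grid$origin[1], grid$origin[2],
              grid$origin[3]), file = con)
  cat(sprintf("delta %g 0 0\ndelta 0 %g 0\ndelta 0 0 %g\n",
              grid$voxel, grid$voxel, grid$voxel), file = con)
  cat(sprintf("object 2 class gridconnections counts %d %d %d\n",
              d[1], d[2], d[3]), file = con)
  cat(sprintf(
    "object 3 class array type double rank 0 items %d data follows\n",
    prod(d)), file = con)
  vals <- aperm(grid$occupancy, c(3, 2, 1))  # z fastest
  vals <- as.numeric(vals)
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%g %g %g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals))
    writeLines(paste(sprintf("%g", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  cat("attribute \"dep\" string \"positions\"\n", file = con)
  cat("object \"density\" class field\n", file = con)
  cat("component \"positions\" value 1\n", file = con)
  cat("component \"connections\" value 2\n", file = con)
  cat("component \"data\" value 3\n", file = con)
  invisible(path)
}

#' Write a quad-face surface as Wavefront OBJ
#'
#' @param vertices m x 3 vertex matrix.
#' @param faces q x 4 matrix of 1-based vertex indices.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_obj <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %g %g %g", vertices[, 1], vertices[, 2],
                     vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d %d", faces[, 1], faces[, 2],
                     faces[, 3], faces[, 4]), con)
  invisible(path)
}

#' Unwrap a wrapped coordinate track
#'
#' Removes periodic box jumps from a time series of wrapped coordinates by
#' accumulating minimum-image steps (valid while no physical single-step
#' displacement exceeds half the box).
#'
#' @param x n_frames x k matrix of wrapped coordinates (Angstrom).
#' @param box n_frames x k matrix (or length-k vector) of box edges.
#' @return Unwrapped n_frames x k matrix starting at the first frame's
#'   coordinates.
#' @export
unwrap_track <- function(x, box) {
  x <- as.matrix(x)
  if (!is.matrix(box))
    box <- matrix(box, nrow(x), length(box), byrow = TRUE)
  if (nrow(x) < 2) return(x)
  d <- diff(x)
  bb <- box[-1, , drop = FALSE]
  d <- d - bb * round(d / bb)
  out <- apply(rbind(x[1, , drop = FALSE], d), 2, cumsum)
  matrix(out, nrow = nrow(x))
}

#' Lateral (xy) diffusion from mean squared displacement
#'
#' Per-molecule center-of-geometry xy tracks are unwrapped (optionally in
#' the frame of a reference selection's center), the MSD is computed with
#' time- and ensemble-averaging over all overlapping origins, and the 2D
#' Einstein relation D = slope / 4 is fitted by least squares over a lag
#' window. A curvature diagnostic compares the slope in the first and
#' second halves of the window and flags non-linear (e.g. drift-driven,
#' super-diffusive) MSD curves.
#'
#' @param traj A [trajectory()].
#' @param molecule_selection Selection string; molecules are chain/resid
#'   groups within it.
#' @param fit_window Lag window as fractions of the trajectory length
#'   (default 2-20 percent; short lags carry the least statistical error
#'   for a time-averaged MSD).
#' @param center_on Optional selection string; its per-frame center of
#'   geometry is subtracted before unwrapping (protein-centered frame).
#' @return Object of class `lateral_diffusion`: list with `msd`
#'   data.frame (`lag_ns`, `msd`), `D_A2_ns`, `D_cm2_s`, `se_cm2_s` (fit
#'   standard error), `fit_window`, `n_molecules`, `nonlinear` flag and
#'   `tracks` (list of unwrapped xy matrices).
#' @export
lateral_diffusion <- function(traj, molecule_selection = "role:ligand",
                              fit_window = c(0.02, 0.20),
                              center_on = NULL) {
  top <- traj$topology
  nf <- n_frames(traj)
  if (nf < 2) stop("need >= 2 frames to estimate diffusion")
  groups <- ligand_groups(top, resolve_selection(molecule_selection, top))
  if (length(groups) == 0) stop("molecule selection is empty")
  ctr <- NULL
  if (!is.null(center_on)) {
    csel <- resolve_selection(center_on, top)
    ctr <- t(vapply(seq_len(nf), function(t)
      colMeans(matrix(traj$coords[csel, , t], ncol = 3))[1:2],
      numeric(2)))
  }
  tracks <- lapply(groups, function(g) {
    # unwrap each atom then average: robust to molecules straddling
    # the boundary
    cog <- t(vapply(seq_len(nf), function(t) {
      m <- matrix(traj$coords[g, , t], ncol = 3)
      ref <- m[1, ]
      rel <- min_image_disp(matrix(ref, nrow(m), 3, byrow = TRUE), m,
                            traj$box[t, ])
      ref[1:2] + colMeans(rel)[1:2]
    }, numeric(2)))
    un <- unwrap_track(cog, traj$box[, 1:2, drop = FALSE])
    if (!is.null(ctr)) un <- un - ctr
    un
  })
  msd_sum <- NULL
  for (tr in tracks) {
    m <- msd_fft(tr[, 1]) + msd_fft(tr[, 2])
    msd_sum <- if (is.null(msd_sum)) m else msd_sum + m
  }
  msd <- msd_sum / length(tracks)
  dt <- mean(diff(traj$times))
  lags <- seq_len(nf - 1)
  lag_ns <- lags * dt
  lo <- max(1L, floor(fit_window[1] * nf))
  hi <- min(nf - 1L, ceiling(fit_window[2] * nf))
  if (hi - lo + 1 < 3)
    stop("fewer than 3 lags in the fit window; widen fit_window or ",
         "supply more frames")
  w <- lo:hi
  fit <- stats::lm(msd[w + 1] ~ lag_ns[w])
  slope <- unname(stats::coef(fit)[2])
  slope_se <- summary(fit)$coefficients[2, 2]
  half <- lo + (hi - lo) %/% 2
  s1 <- (msd[half + 1] - msd[lo + 1]) / ((half - lo) * dt)
  s2 <- (msd[hi + 1] - msd[half + 1]) / ((hi - half) * dt)
  nonlinear <- is.finite(s1) && is.finite(s2) && s1 > 0 &&
    (s2 / s1 > 1.5 || s2 / s1 < 1 / 1.5)
  D_A2_ns <- slope / 4
  structure(list(
    msd = data.frame(lag_ns = c(0, lag_ns), msd = msd),
    D_A2_ns = D_A2_ns, D_cm2_s = D_A2_ns * 1e-7,
    se_cm2_s = slope_se / 4 * 1e-7,
    fit_window = c(lo, hi) * dt, n_molecules = length(tracks),
    nonlinear = nonlinear, tracks = tracks),
    class = "lateral_diffusion")
}

#' @export
print.lateral_diffusion <- function(x, ...) {
  cat("lateral diffusion:", x$n_molecules, "molecule(s); D =",
      signif(x$D_A2_ns, 4), "A^2/ns =", signif(x$D_cm2_s, 4),
      "cm^2/s (fit window", x$fit_window[1], "-", x$fit_window[2],
      "ns)", if (x$nonlinear) "[non-linear MSD flagged]" else "", "\n")
  invisible(x)
}

# Time-averaged MSD of a 1D track over all overlapping origins,
# FFT-based (O(N log N)). Returns msd for lags 0..N-1.
msd_fft <- function(x) {
  n <- length(x)
  # S2: autocorrelation via zero-padded FFT
  fx <- stats::fft(c(x, rep(0, n)))
  s2 <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:n] / (2 * n)
  # D_k = sum over valid origins of x_t^2 + x_{t+k}^2, computed
  # recursively
  x2 <- x^2
  q <- 2 * sum(x2)
  d <- numeric(n)
  d[1] <- q
  for (k in 2:n) {
    q <- q - x2[k - 1] - x2[n - k + 2]
    d[k] <- q
  }
  (d - 2 * s2) / (n - (0:(n - 1)))
}
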