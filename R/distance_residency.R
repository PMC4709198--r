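#' Segment-wise minimum distances per subunit
#'
#' For every subunit (chain) of the target selection and every ligand
#' segment, the per-frame minimum over (target atom, segment atom)
#' minimum-image distances, pooling all ligand copies. Two segmentation
#' modes: `"five_part"` (HEAD, TAIL-A..D) and `"head_tail12_22"` (head
#' group vs the analysis tail, C12-22 for a 22-carbon chain). The summary
#' reports each subunit's time mean, the cross-subunit mean, and the
#' standard error over subunits (sd of subunit means / sqrt(n_subunits)).
#'
#' @param traj A [trajectory()].
#' @param schema A [ligand_schema()].
#' @param target Selection string for the target atoms, e.g.
#'   `"role:protein"` or `"resid:310,325 and name:CB"`.
#' @param ligand_selection Selection string for ligand atoms.
#' @param segmentation `"five_part"` or `"head_tail12_22"`.
#' @param atom_policy `"heavy"` or `"all"`.
#' @return Object of class `segment_distance_profile`: list with
#'   `profile` (array n_subunits x n_segments x n_frames), `summary`
#'   data.frame (segment, subunit means, cross-subunit mean, se), frame
#'   times and the subunit/segment labels.
#' @export
segment_min_distances <- function(traj, schema,
                                  target = "role:protein",
                                  ligand_selection = "role:ligand",
                                  segmentation = c("five_part",
                                                   "head_tail12_22"),
                                  atom_policy = c("heavy", "all")) {
  segmentation <- match.arg(segmentation)
  atom_policy <- match.arg(atom_policy)
  top <- traj$topology
  tsel <- resolve_selection(target, top)
  lsel <- resolve_selection(ligand_selection, top)
  if (atom_policy == "heavy") {
    tsel <- heavy_atoms(top, tsel)
    lsel <- heavy_atoms(top, lsel)
  }
  if (length(tsel) == 0) stop("target selection is empty")
  if (length(lsel) == 0) stop("ligand selection is empty")
  segs <- if (segmentation == "five_part") schema$segments else
    list(head = schema$head_atoms, tail = schema$analysis_tail)
  seg_rows <- lapply(segs, function(nms)
    lsel[top$atoms$name[lsel] %in% nms])
  empty <- names(segs)[vapply(seg_rows, length, 0L) == 0]
  if (length(empty) > 0)
    stop("segment(s) with no atoms in the ligand selection: ",
         paste(empty, collapse = ", "))
  chains <- split(tsel, top$atoms$chain[tsel])
  if (any(lengths(chains) == 0))
    stop("subunit with empty target selection")
  nf <- n_frames(traj)
  prof <- array(NA_real_, c(length(chains), length(segs), nf),
                dimnames = list(names(chains), names(segs), NULL))
  for (t in seq_len(nf)) {
    box <- traj$box[t, ]
    for (si in seq_along(chains)) {
      Tm <- matrix(traj$coords[chains[[si]], , t], ncol = 3)
      for (gi in seq_along(seg_rows)) {
        Lm <- matrix(traj$coords[seg_rows[[gi]], , t], ncol = 3)
        prof[si, gi, t] <- min(pairwise_min_image(Tm, Lm, box))
      }
    }
  }
  sub_means <- apply(prof, c(1, 2), mean)
  n_sub <- length(chains)
  summ <- data.frame(
    segment = names(segs),
    mean = colMeans(sub_means),
    se = apply(sub_means, 2, stats::sd) / sqrt(n_sub),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  structure(list(profile = prof, subunit_means = sub_means,
                 summary = summ, times = traj$times,
                 subunits = names(chains), segments = names(segs),
                 segmentation = segmentation),
            class = "segment_distance_profile")
}

#' @export
print.segment_distance_profile <- function(x, ...) {
  cat("segment minimum distances (", x$segmentation, "), ",
      length(x$subunits), " subunits x ", length(x$segments),
      " segments x ", length(x$times), " frames\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Residency intervals of molecules near a target
#'
#' A probe molecule is resident in a frame when any of its atoms lies
#' within `cutoff` of the target selection. Continuous residence intervals
#' are computed on the frame grid; interruptions of at most `gap_frames`
#' frames are merged. Optionally the target is restricted to the vicinity
#' of a residue list (site-local residency).
#'
#' @param traj A [trajectory()].
#' @param target_selection Selection string for the target atoms.
#' @param probe_selection Selection string for probe molecules.
#' @param cutoff Distance cutoff in Angstrom (default 2).
#' @param gap_frames Number of interrupting frames to bridge (default 0,
#'   strict).
#' @param site_residues Optional data.frame with columns `chain`, `resid`
#'   restricting the target to those residues' atoms.
#' @param atom_policy `"heavy"` or `"all"`.
#' @return Object of class `residency_record`: list with `intervals`
#'   data.frame (molecule, start_ns, end_ns, duration_ns, n_frames) and
#'   `counts` data.frame (frame, time_ns, count).
#' @export
residency <- function(traj, target_selection, probe_selection,
                      cutoff = 2.0, gap_frames = 0, site_residues = NULL,
                      atom_policy = c("heavy", "all")) {
  atom_policy <- match.arg(atom_policy)
  top <- traj$topology
  check_cutoff_vs_box(cutoff, apply(traj$box, 2, min))
  tsel <- resolve_selection(target_selection, top)
  psel <- resolve_selection(probe_selection, top)
  if (!is.null(site_residues)) {
    keep <- paste(top$atoms$chain[tsel], top$atoms$resid[tsel]) %in%
      paste(site_residues$chain, site_residues$resid)
    tsel <- tsel[keep]
  }
  if (atom_policy == "heavy") {
    tsel <- heavy_atoms(top, tsel)
    psel <- heavy_atoms(top, psel)
  }
  if (length(tsel) == 0) stop("target selection is empty")
  if (length(psel) == 0) stop("probe selection is empty")
  psel <- setdiff(psel, tsel)
  groups <- ligand_groups(top, psel)
  nf <- n_frames(traj)
  gidx <- rep(seq_along(groups), lengths(groups))
  prows <- unlist(groups, use.names = FALSE)
  resident <- matrix(FALSE, length(groups), nf,
                     dimnames = list(names(groups), NULL))
  for (t in seq_len(nf)) {
    Tm <- matrix(traj$coords[tsel, , t], ncol = 3)
    Pm <- matrix(traj$coords[prows, , t], ncol = 3)
    dm <- pairwise_min_image(Pm, Tm, traj$box[t, ])
    amin <- do.call(pmin, as.data.frame(dm))
    resident[, t] <- vapply(split(amin, gidx), min, 0) <= cutoff
  }
  dur <- frame_durations(traj)
  ints <- list()
  for (mi in seq_len(nrow(resident))) {
    fl <- merge_gaps(resident[mi, ], gap_frames)
    if (!any(fl)) next
    r <- rle(fl)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      ints[[length(ints) + 1]] <- data.frame(
        molecule = rownames(resident)[mi],
        start_ns = traj$times[starts[j]], end_ns = traj$times[ends[j]],
        duration_ns = sum(dur[starts[j]:ends[j]]),
        n_frames = r$lengths[j], stringsAsFactors = FALSE)
    }
  }
  intervals <- if (length(ints) > 0) do.call(rbind, ints) else
    data.frame(molecule = character(0), start_ns = numeric(0),
               end_ns = numeric(0), duration_ns = numeric(0),
               n_frames = integer(0))
  structure(list(intervals = intervals,
                 counts = data.frame(frame = seq_len(nf),
                                     time_ns = traj$times,
                                     count = colSums(resident)),
                 resident = resident, cutoff = cutoff,
                 gap_frames = gap_frames),
            class = "residency_record")
}

merge_gaps <- function(flags, gap_frames) {
  if (gap_frames <= 0 || !any(flags)) return(flags)
  r <- rle(flags)
  n <- length(r$values)
  # bridge internal FALSE runs of length <= gap_frames
  for (i in seq_len(n)) {
    if (!r$values[i] && i > 1 && i < n && r$lengths[i] <= gap_frames)
      r$values[i] <- TRUE
  }
  inverse.rle(r)
}

#' @export
print.residency_record <- function(x, ...) {
  cat("residency: cutoff", x$cutoff, "A,", nrow(x$intervals),
      "interval(s) across", nrow(x$resident), "molecules; mean resident",
      round(mean(x$counts$count), 2), "per frame\n")
  invisible(x)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto `ref`
#' (SVD-based, reflection-corrected).
#'
#' @param mobile,ref n x 3 coordinate matrices (same n).
#' @return List with `R` (3 x 3 rotation), `t` (translation), and
#'   `transform(x)` applying them to an m x 3 matrix.
#' @export
kabsch <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref), ncol(mobile) == 3)
  if (nrow(mobile) < 3) stop("superposition needs >= 3 atoms")
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm)
  B <- sweep(ref, 2, cr)
  s <- svd(crossprod(A, B))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2)
    stop("degenerate (collinear) geometry: superposition is ill-defined")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- cr - as.numeric(R %*% cm)
  list(R = R, t = t_vec,
       transform = function(x) sweep(x %*% t(R), 2, t_vec, "+"))
}

#' Backbone RMSD against the trajectory-average structure
#'
#' Two-pass procedure: (1) every frame is superposed onto the first frame
#' over the given selection and the coordinate-average structure is
#' computed; (2) every frame is superposed onto that average and the RMSD
#' is reported. RMSD is invariant under rigid transformations of any
#' frame.
#'
#' @param traj A [trajectory()].
#' @param protein_selection Selection string for the backbone atoms (e.g.
#'   `"role:protein and name:CA"`).
#' @return data.frame of class `rmsd_series`: `frame`, `time_ns`, `rmsd`
#'   (Angstrom); the average structure is attached as attribute
#'   `"average"`.
#' @export
backbone_rmsd <- function(traj, protein_selection = "role:protein") {
  top <- traj$topology
  sel <- resolve_selection(protein_selection, top)
  if (length(sel) < 3) stop("need >= 3 atoms for RMSD superposition")
  nf <- n_frames(traj)
  ref <- matrix(traj$coords[sel, , 1], ncol = 3)
  fitted <- array(0, c(length(sel), 3, nf))
  for (t in seq_len(nf)) {
    x <- matrix(traj$coords[sel, , t], ncol = 3)
    fitted[, , t] <- kabsch(x, ref)$transform(x)
  }
  avg <- apply(fitted, c(1, 2), mean)
  rmsd <- vapply(seq_len(nf), function(t) {
    x <- matrix(traj$coords[sel, , t], ncol = 3)
    y <- kabsch(x, avg)$transform(x)
    sqrt(mean(rowSums((y - avg)^2)))
  }, 0)
  res <- data.frame(frame = seq_len(nf), time_ns = traj$times,
                    rmsd = rmsd)
  attr(res, "average") <- avg
  class(res) <- c("rmsd_series", class(res))
  res
}
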