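#' Head/tail/segment decomposition of an amphipathic ligand
#'
#' Declares, by atom name, which atoms form the carboxyl head, the ordered
#' tail carbons, the five-segment scheme (HEAD plus four tail quarters),
#' the reduced tail used for residue-proximity analyses, and the bonded
#' hydrogens of each tail carbon (for order parameters). For a 22-carbon
#' tail the segments are the conventional ones: TAIL-A = C2-6,
#' TAIL-B = C7-11, TAIL-C = C12-16, TAIL-D = C17-22; for other lengths the
#' tail is split into four near-equal consecutive runs. The analysis tail
#' is C12-22 for the 22-carbon chain (the terminal half), otherwise the
#' second half of the chain.
#'
#' @param tail_length Number of tail carbons (C1..C<n>); C1 belongs to the
#'   head (carboxyl carbon).
#' @param head_atoms Atom names of the head group.
#' @param head_oxygen The designated head oxygen for head-to-tail
#'   distances.
#' @param ch_pairs Named list: tail carbon name -> character vector of its
#'   bonded hydrogen names. Defaults to the generator's H<k>A/H<k>B
#'   convention.
#' @return Object of class `ligand_schema`.
#' @export
ligand_schema <- function(tail_length = 22,
                          head_atoms = c("O1", "O2", "C1"),
                          head_oxygen = "O1",
                          ch_pairs = NULL) {
  tl <- as.integer(tail_length)
  if (tl < 5) stop("tail_length must be >= 5")
  tail_atoms <- paste0("C", 2:tl)
  if (tl == 22) {
    seg_bounds <- list(`TAIL-A` = 2:6, `TAIL-B` = 7:11,
                       `TAIL-C` = 12:16, `TAIL-D` = 17:22)
    analysis_lo <- 12
  } else {
    cuts <- round(seq(2, tl + 1, length.out = 5))
    seg_bounds <- list(`TAIL-A` = cuts[1]:(cuts[2] - 1),
                       `TAIL-B` = cuts[2]:(cuts[3] - 1),
                       `TAIL-C` = cuts[3]:(cuts[4] - 1),
                       `TAIL-D` = cuts[4]:(cuts[5] - 1))
    analysis_lo <- cuts[3]
  }
  segments <- c(list(HEAD = head_atoms),
                lapply(seg_bounds, function(ks) paste0("C", ks)))
  if (is.null(ch_pairs)) {
    ch_pairs <- stats::setNames(
      lapply(2:tl, function(k) paste0("H", k, c("A", "B"))),
      tail_atoms)
  }
  structure(list(head_atoms = head_atoms, tail_atoms = tail_atoms,
                 tail_length = tl, segments = segments,
                 analysis_tail = paste0("C", analysis_lo:tl),
                 head_oxygen = head_oxygen,
                 terminal_carbon = paste0("C", tl),
                 ch_pairs = ch_pairs),
            class = "ligand_schema")
}

# Split the atoms of a ligand selection into per-molecule row-index lists,
# keyed by chain/resid.
ligand_groups <- function(top, sel) {
  a <- top$atoms[sel, , drop = FALSE]
  key <- paste(a$chain, a$resid)
  split(sel, factor(key, levels = unique(key)))
}

sel_by_name <- function(top, rows, names) {
  rows[top$atoms$name[rows] %in% names]
}

one_atom <- function(top, rows, name, what) {
  r <- sel_by_name(top, rows, name)
  if (length(r) != 1)
    stop(what, " '", name, "' is not uniquely resolvable in ligand ",
         top$atoms$chain[rows[1]], "/", top$atoms$resid[rows[1]])
  r
}

#' Deuterium order parameters per tail carbon
#'
#' S_CD(i) = <(3 cos^2 theta - 1) / 2>, theta the angle between each C-H
#' bond of tail carbon i and the membrane normal, averaged over frames,
#' ligand copies, and the carbon's hydrogens. Bounds: -0.5 (C-H
#' perpendicular to the normal) to 1 (parallel); 0 under isotropic
#' orientations. Requires explicit (pseudo-)hydrogens; with
#' `fallback_vectors = TRUE` carbons lacking hydrogens use the
#' C(i-1) -> C(i+1) axis instead (flagged per carbon in the result).
#'
#' @param traj A [trajectory()].
#' @param schema A [ligand_schema()].
#' @param ligand_selection Selection string for the ligand atoms
#'   (default all ligand-role atoms).
#' @param normal Membrane normal (default z).
#' @param fallback_vectors Use the carbon-axis fallback where hydrogens
#'   are missing.
#' @return data.frame of class `order_parameter_profile`: columns
#'   `carbon` (index), `atom` (name), `scd`, `se` (standard error over
#'   pooled ligand x frame x bond samples), `n`, `fallback`.
#' @export
order_parameters <- function(traj, schema,
                             ligand_selection = "role:ligand",
                             normal = c(0, 0, 1),
                             fallback_vectors = FALSE) {
  top <- traj$topology
  normal <- normalize3(as.numeric(normal))
  groups <- ligand_groups(top, resolve_selection(ligand_selection, top))
  if (length(groups) == 0) stop("ligand selection is empty")
  out <- lapply(schema$tail_atoms, function(cname) {
    svals <- numeric(0)
    fallback_used <- FALSE
    for (g in groups) {
      crow <- one_atom(top, g, cname, "tail carbon")
      hrows <- sel_by_name(top, g, schema$ch_pairs[[cname]])
      if (length(hrows) == 0) {
        if (!fallback_vectors)
          stop("no hydrogen of ", cname, " (expected ",
               paste(schema$ch_pairs[[cname]], collapse = ", "),
               ") found in the topology; set fallback_vectors = TRUE ",
               "to use the carbon-axis fallback")
        k <- as.integer(sub("^C", "", cname))
        prow <- one_atom(top, g, paste0("C", k - 1), "carbon")
        nxt <- one_atom(top, g, paste0("C", k + 1), "carbon")
        fallback_used <- TRUE
        v <- bond_vectors(traj, prow, nxt)
        svals <- c(svals, scd_from_vectors(v, normal))
      } else {
        for (h in hrows) {
          v <- bond_vectors(traj, crow, h)
          svals <- c(svals, scd_from_vectors(v, normal))
        }
      }
    }
    data.frame(carbon = as.integer(sub("^C", "", cname)), atom = cname,
               scd = mean(svals),
               se = stats::sd(svals) / sqrt(length(svals)),
               n = length(svals), fallback = fallback_used,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("order_parameter_profile", class(res))
  res
}

# Minimum-image bond vectors from atom row a to b, 3 x n_frames.
bond_vectors <- function(traj, a, b) {
  v <- matrix(traj$coords[b, , ] - traj$coords[a, , ], nrow = 3)
  for (k in 1:3)
    v[k, ] <- v[k, ] - traj$box[, k] * round(v[k, ] / traj$box[, k])
  v
}

scd_from_vectors <- function(v, normal) {
  nv <- sqrt(colSums(v * v))
  ct <- as.numeric(normal %*% v) / nv
  (3 * ct^2 - 1) / 2
}

#' Radius of gyration of the acyl tail
#'
#' Unweighted Rg over the tail carbon positions of each ligand in each
#' frame (head oxygens and C1 excluded). Positions are unwrapped relative
#' to the first tail carbon so molecules split across the periodic
#' boundary are handled correctly.
#'
#' @inheritParams order_parameters
#' @return data.frame of class `chain_shape_series`: `frame`, `time_ns`,
#'   `ligand`, `value` (Rg, Angstrom); attribute `summary` holds mean, sd,
#'   min, max.
#' @export
radius_of_gyration <- function(traj, schema,
                               ligand_selection = "role:ligand") {
  top <- traj$topology
  per_ligand_series(traj, ligand_selection, "rg", function(g) {
    rows <- vapply(schema$tail_atoms, function(nm)
      one_atom(top, g, nm, "tail carbon"), 0L)
    function(t) {
      xyz <- traj$coords[rows, , t]
      box <- traj$box[t, ]
      rel <- min_image_disp(
        matrix(xyz[1, ], nrow(xyz), 3, byrow = TRUE), xyz, box)
      ctr <- colMeans(rel)
      sqrt(mean(rowSums(sweep(rel, 2, ctr)^2)))
    }
  })
}

#' Head-oxygen to terminal-carbon distance
#'
#' Per-frame minimum-image distance between the schema-designated head
#' oxygen and the last tail carbon of each ligand; the summary mean is the
#' overall head-to-tail average. By default all ligand x frame samples are
#' pooled; `per_ligand = TRUE` averages per-ligand means instead.
#'
#' @inheritParams order_parameters
#' @param per_ligand Average per-ligand means rather than pooling.
#' @return data.frame of class `chain_shape_series` as in
#'   [radius_of_gyration()], with the head-to-tail distance as `value`.
#' @export
head_to_tail_distance <- function(traj, schema,
                                  ligand_selection = "role:ligand",
                                  per_ligand = FALSE) {
  top <- traj$topology
  per_ligand_series(traj, ligand_selection, "head_to_tail", function(g) {
    orow <- one_atom(top, g, schema$head_oxygen, "head oxygen")
    crow <- one_atom(top, g, schema$terminal_carbon, "terminal carbon")
    function(t) minimum_image_distance(traj$coords[orow, , t],
                                       traj$coords[crow, , t],
                                       traj$box[t, ])
  }, per_ligand = per_ligand)
}

# Shared driver: make_fun(g) returns a per-frame scalar function.
per_ligand_series <- function(traj, ligand_selection, measure, make_fun,
                              per_ligand = FALSE) {
  top <- traj$topology
  groups <- ligand_groups(top, resolve_selection(ligand_selection, top))
  if (length(groups) == 0) stop("ligand selection is empty")
  nf <- n_frames(traj)
  recs <- lapply(seq_along(groups), function(gi) {
    f <- make_fun(groups[[gi]])
    data.frame(frame = seq_len(nf), time_ns = traj$times,
               ligand = names(groups)[gi],
               value = vapply(seq_len(nf), f, 0),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, recs)
  v <- if (per_ligand)
    vapply(split(res$value, res$ligand), mean, 0) else res$value
  attr(res, "summary") <- c(mean = mean(v), sd = stats::sd(v),
                            min = min(res$value), max = max(res$value))
  attr(res, "measure") <- measure
  class(res) <- c("chain_shape_series", class(res))
  res
}

#' @export
print.chain_shape_series <- function(x, ...) {
  s <- attr(x, "summary")
  cat(attr(x, "measure"), "series:", nrow(x), "samples; mean",
      round(s[["mean"]], 3), "A, sd", round(s[["sd"]], 3), ", range [",
      round(s[["min"]], 3), ",", round(s[["max"]], 3), "] A\n")
  invisible(x)
}
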