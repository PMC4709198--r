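#' Contact criterion
#'
#' The dual-threshold contact definition: a residue is in contact with a
#' ligand part in a frame when the minimum atom-atom minimum-image
#' distance is at or below `distance_cutoff`; a (residue, part) pair
#' qualifies when its persistence measure exceeds (strictly)
#' `persistence_threshold`. The persistence measure is either the
#' cumulative contact time over the trajectory (default; contact
#' frequencies are cumulative-time fractions) or the longest continuous
#' contact interval.
#'
#' @param distance_cutoff Distance cutoff in Angstrom (default 3.5).
#' @param persistence_threshold Persistence threshold in ns (default 300).
#' @param persistence_mode `"cumulative"` or `"longest_continuous"`.
#' @param atom_policy `"heavy"` (default: hydrogens ignored) or `"all"`.
#' @return Object of class `contact_criterion`.
#' @export
contact_criterion <- function(distance_cutoff = 3.5,
                              persistence_threshold = 300,
                              persistence_mode = c("cumulative",
                                                   "longest_continuous"),
                              atom_policy = c("heavy", "all")) {
  if (distance_cutoff <= 0) stop("distance_cutoff must be > 0")
  if (persistence_threshold < 0)
    stop("persistence_threshold must be >= 0")
  structure(list(distance_cutoff = distance_cutoff,
                 persistence_threshold = persistence_threshold,
                 persistence_mode = match.arg(persistence_mode),
                 atom_policy = match.arg(atom_policy)),
            class = "contact_criterion")
}

check_cutoff_vs_box <- function(cutoff, box) {
  half <- min(box) / 2
  if (cutoff > half)
    stop("cutoff (", cutoff, " A) exceeds half the smallest box edge (",
         half, " A): minimum-image distances would be ambiguous")
}

# Partition ligand-selection rows into head/tail atom rows by schema.
part_rows <- function(top, lig_sel, schema, criterion) {
  rows <- list(
    head = lig_sel[top$atoms$name[lig_sel] %in% schema$head_atoms],
    tail = lig_sel[top$atoms$name[lig_sel] %in% schema$tail_atoms])
  if (criterion$atom_policy == "heavy")
    rows <- lapply(rows, function(r) heavy_atoms(top, r))
  rows
}

#' Detect per-frame residue contacts with ligand head and tail
#'
#' For every protein residue in `protein_selection` and every ligand part
#' (head, tail; all ligand copies pooled), marks the frames in which the
#' minimum atom-atom minimum-image distance is at or below the criterion's
#' cutoff. The computation is exact (vectorized all-pairs distances), so
#' it equals a brute-force evaluation by construction.
#'
#' @param traj A [trajectory()].
#' @param criterion A [contact_criterion()].
#' @param protein_selection Selection string for the target residues.
#' @param schema A [ligand_schema()].
#' @param ligand_selection Selection string for the ligand atoms.
#' @param per_ligand If TRUE, resolve contacts per ligand copy instead of
#'   pooling (residue keys gain a ligand column).
#' @return Object of class `contact_events`: logical array
#'   `n_residue_keys x 2 x n_frames` plus the residue key table and frame
#'   times.
#' @export
detect_contacts <- function(traj, criterion = contact_criterion(),
                            protein_selection = "role:protein",
                            schema = ligand_schema(),
                            ligand_selection = "role:ligand",
                            per_ligand = FALSE) {
  top <- traj$topology
  check_cutoff_vs_box(criterion$distance_cutoff, apply(traj$box, 2, min))
  psel <- resolve_selection(protein_selection, top)
  if (criterion$atom_policy == "heavy") psel <- heavy_atoms(top, psel)
  lsel <- resolve_selection(ligand_selection, top)
  if (length(psel) == 0) stop("protein selection is empty")
  if (length(lsel) == 0) stop("ligand selection is empty")
  parts <- part_rows(top, lsel, schema, criterion)
  if (length(parts$head) == 0 && length(parts$tail) == 0)
    stop("ligand selection contains no schema head or tail atoms")
  a <- top$atoms
  reskey <- paste(a$chain[psel], a$resid[psel])
  resf <- factor(reskey, levels = unique(reskey))
  res_tab <- data.frame(
    chain = a$chain[psel][!duplicated(resf)],
    resid = a$resid[psel][!duplicated(resf)],
    resname = a$resname[psel][!duplicated(resf)],
    stringsAsFactors = FALSE)
  res_rows <- split(seq_along(psel), resf)
  lig_units <- if (per_ligand) {
    lapply(parts, function(r) ligand_groups(top, r))
  } else {
    lapply(parts, function(r) list(pooled = r))
  }
  unit_names <- unique(unlist(lapply(lig_units, names)))
  nf <- n_frames(traj)
  nres <- nrow(res_tab)
  keys <- expand.grid(unit = unit_names, stringsAsFactors = FALSE)
  events <- array(FALSE, c(nres * length(unit_names), 2, nf),
                  dimnames = list(NULL, c("head", "tail"), NULL))
  for (t in seq_len(nf)) {
    P <- traj$coords[psel, , t, drop = FALSE][, , 1]
    box <- traj$box[t, ]
    for (pi in 1:2) {
      pname <- c("head", "tail")[pi]
      units <- lig_units[[pname]]
      for (ui in seq_along(unit_names)) {
        rows <- units[[unit_names[ui]]]
        if (is.null(rows) || length(rows) == 0) next
        L <- traj$coords[rows, , t, drop = FALSE][, , 1]
        if (is.null(dim(L))) L <- matrix(L, ncol = 3)
        if (is.null(dim(P))) P <- matrix(P, ncol = 3)
        dm <- pairwise_min_image(P, L, box)
        atom_min <- do.call(pmin, as.data.frame(dm))
        res_min <- vapply(res_rows, function(rr) min(atom_min[rr]), 0)
        events[(ui - 1) * nres + seq_len(nres), pi, t] <-
          res_min <= criterion$distance_cutoff
      }
    }
  }
  key_tab <- do.call(rbind, lapply(unit_names, function(u) {
    cbind(res_tab, ligand = u, stringsAsFactors = FALSE)
  }))
  structure(list(events = events, residues = key_tab,
                 times = traj$times, criterion = criterion,
                 per_ligand = per_ligand),
            class = "contact_events")
}

run_lengths_time <- function(flags, dur) {
  # longest continuous contact time given per-frame durations
  if (!any(flags)) return(0)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  max(vapply(which(r$values), function(i)
    sum(dur[starts[i]:ends[i]]), 0))
}

#' Contact table with persistence filtering
#'
#' Aggregates per-frame contact events into per-(residue, part) cumulative
#' contact times (ns) and contact frequencies (fraction of trajectory
#' time, in [0, 1]); attaches region labels, the extracellular-half flag,
#' and the residue chemical class (hydrophobic / polar / charged). The
#' filtered view keeps rows whose persistence measure strictly exceeds the
#' criterion threshold ("more than"); all raw rows with any contact are
#' retained.
#'
#' @param events A `contact_events` from [detect_contacts()].
#' @param top The [topology()] (for region attribution); optional.
#' @return Object of class `contact_table`: list with `raw`, `filtered`
#'   data.frames, `trajectory_ns`, and the criterion.
#' @export
contact_table <- function(events, top = NULL) {
  stopifnot(inherits(events, "contact_events"))
  times <- events$times
  nf <- length(times)
  dur <- if (nf == 1) 1 else {
    d <- diff(times); c(d, d[nf - 1])
  }
  total <- sum(dur)
  crit <- events$criterion
  rows <- list()
  for (pi in 1:2) {
    part <- c("head", "tail")[pi]
    ev <- matrix(events$events[, pi, ], nrow = nrow(events$residues))
    cum <- as.numeric(ev %*% dur)
    keep <- cum > 0
    if (!any(keep)) next
    persist <- if (crit$persistence_mode == "cumulative") cum[keep] else
      vapply(which(keep), function(i) run_lengths_time(ev[i, ], dur), 0)
    df <- cbind(events$residues[keep, , drop = FALSE],
                data.frame(part = part, cumulative_ns = cum[keep],
                           frequency = cum[keep] / total,
                           persistence_ns = persist,
                           stringsAsFactors = FALSE))
    rows[[part]] <- df
  }
  raw <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chain = character(0), resid = integer(0),
               resname = character(0), ligand = character(0),
               part = character(0), cumulative_ns = numeric(0),
               frequency = numeric(0), persistence_ns = numeric(0))
  rownames(raw) <- NULL
  raw <- annotate_residues(raw, top)
  filtered <- raw[raw$persistence_ns > crit$persistence_threshold, ,
                  drop = FALSE]
  rownames(filtered) <- NULL
  structure(list(raw = raw, filtered = filtered, trajectory_ns = total,
                 criterion = crit),
            class = "contact_table")
}

annotate_residues <- function(df, top) {
  df$region <- rep("unassigned", nrow(df))
  df$extracellular <- rep(NA, nrow(df))
  if (!is.null(top) && !is.null(top$region_map) && nrow(df) > 0) {
    rm <- top$region_map
    m <- match(paste(df$chain, df$resid), paste(rm$chain, rm$resid))
    df$region[!is.na(m)] <- rm$region[m[!is.na(m)]]
    df$extracellular[!is.na(m)] <- rm$extracellular[m[!is.na(m)]]
  }
  df$residue_class <- unname(AA_CLASS[toupper(df$resname)])
  df$residue_class[is.na(df$residue_class)] <- "other"
  df
}

#' @export
print.contact_table <- function(x, ...) {
  cat("contact table:", nrow(x$raw), "raw rows,", nrow(x$filtered),
      "pass the", x$criterion$persistence_mode, "persistence filter (>",
      x$criterion$persistence_threshold, "ns) over",
      x$trajectory_ns, "ns\n")
  invisible(x)
}

#' Region summary of a filtered contact table
#'
#' Counts and fractions of qualifying residues per region and per residue
#' chemical class, separately for head and tail contacts, plus the
#' tail-to-head contact-count ratio and the fraction of contacting
#' residues on the extracellular halves of S3 and S4.
#'
#' @param tab A [contact_table()].
#' @param which `"filtered"` (default) or `"raw"`.
#' @return Object of class `region_summary`: list with `per_region`
#'   data.frame (part, region, n, fraction), `per_class` data.frame,
#'   `tail_head_ratio`, and `extracellular_s3s4` (per part and overall
#'   fractions, NA when no contacts).
#' @export
region_summary <- function(tab, which = c("filtered", "raw")) {
  which <- match.arg(which)
  df <- tab[[which]]
  per_region <- NULL
  per_class <- NULL
  extr <- c(head = NA_real_, tail = NA_real_, overall = NA_real_)
  counts <- c(head = 0, tail = 0)
  for (part in c("head", "tail")) {
    d <- df[df$part == part, , drop = FALSE]
    counts[part] <- nrow(d)
    if (nrow(d) == 0) next
    tr <- table(d$region)
    per_region <- rbind(per_region, data.frame(
      part = part, region = names(tr), n = as.integer(tr),
      fraction = as.numeric(tr) / nrow(d), stringsAsFactors = FALSE))
    tc <- table(d$residue_class)
    per_class <- rbind(per_class, data.frame(
      part = part, class = names(tc), n = as.integer(tc),
      fraction = as.numeric(tc) / nrow(d), stringsAsFactors = FALSE))
    extr[part] <- mean(d$region %in% c("S3", "S4") &
                         d$extracellular %in% TRUE)
  }
  if (nrow(df) > 0)
    extr["overall"] <- mean(df$region %in% c("S3", "S4") &
                              df$extracellular %in% TRUE)
  structure(list(per_region = per_region, per_class = per_class,
                 n_contacts = counts,
                 tail_head_ratio = if (counts["head"] > 0)
                   unname(counts["tail"] / counts["head"]) else NA_real_,
                 extracellular_s3s4 = extr),
            class = "region_summary")
}

#' @export
print.region_summary <- function(x, ...) {
  cat("region summary: head", x$n_contacts["head"], "rows, tail",
      x$n_contacts["tail"], "rows; tail/head ratio",
      round(x$tail_head_ratio, 2), "\n")
  if (!is.null(x$per_region)) print(x$per_region)
  cat("fraction on extracellular S3/S4 (overall):",
      round(x$extracellular_s3s4["overall"], 3), "\n")
  invisible(x)
}

#' Per-frame proximity count
#'
#' Number of probe entities (whole molecules by default, single atoms with
#' `by_molecule = FALSE`) with any atom within `cutoff` of the target
#' selection, per frame. Atoms present in both selections are excluded
#' from the probe side (no self-pairing).
#'
#' @param traj A [trajectory()].
#' @param target_selection,probe_selection Selection strings.
#' @param cutoff Distance cutoff in Angstrom.
#' @param by_molecule Count whole molecules (chain/resid groups) rather
#'   than atoms.
#' @return data.frame: `frame`, `time_ns`, `count`.
#' @export
proximity_count <- function(traj, target_selection, probe_selection,
                            cutoff = 3.5, by_molecule = TRUE) {
  top <- traj$topology
  check_cutoff_vs_box(cutoff, apply(traj$box, 2, min))
  tsel <- resolve_selection(target_selection, top)
  psel <- resolve_selection(probe_selection, top)
  if (length(tsel) == 0 || length(psel) == 0)
    stop("target and probe selections must be non-empty")
  psel_eff <- setdiff(psel, tsel)
  groups <- if (by_molecule) ligand_groups(top, psel_eff) else
    as.list(psel_eff)
  nf <- n_frames(traj)
  counts <- integer(nf)
  if (length(psel_eff) > 0) {
    gidx <- rep(seq_along(groups), lengths(groups))
    prows <- unlist(groups, use.names = FALSE)
    for (t in seq_len(nf)) {
      Tm <- matrix(traj$coords[tsel, , t], ncol = 3)
      Pm <- matrix(traj$coords[prows, , t], ncol = 3)
      dm <- pairwise_min_image(Pm, Tm, traj$box[t, ])
      amin <- do.call(pmin, as.data.frame(dm))
      counts[t] <- sum(vapply(split(amin, gidx), min, 0) <= cutoff)
    }
  }
  data.frame(frame = seq_len(nf), time_ns = traj$times, count = counts)
}
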