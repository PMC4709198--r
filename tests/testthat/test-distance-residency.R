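test_that("segment minimum distances pick out a single nearby head atom", {
  # one ligand head 4.2 A from subunit A, everything else far away
  atoms <- rbind(
    data.frame(name = "CA", element = "C", resid = 1L, resname = "GLY",
               chain = c("A", "B"), role = "protein"),
    data.frame(name = c("O1", "O2", paste0("C", 1:22)),
               element = c("O", "O", rep("C", 22)),
               resid = 1L, resname = "DHA", chain = "X", role = "ligand"))
  top <- topology(atoms)
  nat <- nrow(atoms)
  coords <- array(0, c(nat, 3, 1))
  coords[1, , 1] <- c(50, 50, 50)          # subunit A
  coords[2, , 1] <- c(120, 120, 50)        # subunit B, far
  coords[3, , 1] <- c(50, 50, 54.2)        # O1
  coords[4, , 1] <- c(60, 50, 54.2)        # O2, off to the side
  for (k in 1:22) coords[4 + k, , 1] <- c(50, 50, 62 + k)
  tr <- trajectory(top, coords, 0, c(200, 200, 200))
  smd <- segment_min_distances(tr, ligand_schema())
  expect_equal(smd$profile["A", "HEAD", 1], 4.2)
  # a ligand equidistant from two subunits records the same value twice
  coords[2, , 1] <- c(50, 50, 58.4)  # B now symmetric about O1
  tr2 <- trajectory(top, coords, 0, c(200, 200, 200))
  smd2 <- segment_min_distances(tr2, ligand_schema())
  expect_equal(smd2$profile["A", "HEAD", 1], smd2$profile["B", "HEAD", 1])
})

test_that("the union of segment minima equals the unsegmented minimum", {
  sys <- generate_system(generator_config(
    n_frames = 25, n_ligands = 3, seed = 61,
    planted_contacts = list(list(chain = "A", resid = 305, ligand = 1,
                                 part = "tail",
                                 intervals = list(c(0, 24))))))
  tr <- sys$trajectory
  top <- sys$topology
  sch <- ligand_schema()
  smd <- segment_min_distances(tr, sch)
  lig_named <- which(top$atoms$role == "ligand" &
                       top$atoms$name %in% c(sch$head_atoms,
                                             sch$tail_atoms))
  for (t in c(1, 10, 25)) {
    for (ch in c("A", "C")) {
      prows <- which(top$atoms$role == "protein" &
                       top$atoms$chain == ch)
      ref <- set_min_distance(
        matrix(tr$coords[prows, , t], ncol = 3),
        matrix(tr$coords[lig_named, , t], ncol = 3), tr$box[t, ])
      expect_equal(min(smd$profile[ch, , t]), ref, tolerance = 1e-12)
    }
  }
  # head_tail12_22 mode restricts the tail to C12-22
  smd2 <- segment_min_distances(tr, sch, segmentation = "head_tail12_22")
  expect_setequal(smd2$segments, c("head", "tail"))
  tail12 <- which(top$atoms$role == "ligand" &
                    top$atoms$name %in% paste0("C", 12:22))
  ref <- set_min_distance(
    matrix(tr$coords[which(top$atoms$role == "protein" &
                             top$atoms$chain == "A"), , 1], ncol = 3),
    matrix(tr$coords[tail12, , 1], ncol = 3), tr$box[1, ])
  expect_equal(smd2$profile["A", "tail", 1], ref)
})

test_that("cross-subunit SE matches its definition", {
  sys <- generate_system(generator_config(n_frames = 30, n_ligands = 2,
                                          seed = 62))
  smd <- segment_min_distances(sys$trajectory, ligand_schema())
  sm <- smd$subunit_means
  for (j in seq_along(smd$segments)) {
    expect_equal(smd$summary$se[j], sd(sm[, j]) / sqrt(nrow(sm)))
    expect_equal(smd$summary$mean[j], mean(sm[, j]))
    # a set statistic: any permutation of the subunit means agrees
    expect_equal(sd(rev(sm[, j])), sd(sm[, j]))
  }
})

test_that("a planted open-vs-closed head offset is recovered", {
  plant_all <- function(steer, seed) {
    generate_system(generator_config(
      n_frames = 100, n_ligands = 4, seed = seed,
      steer_distance = steer,
      planted_contacts = lapply(1:4, function(s)
        list(chain = LETTERS[s], resid = 309 + s, ligand = s,
             part = "head", intervals = list(c(0, 99))))))
  }
  open_sys <- plant_all(2.8, 71)
  closed_sys <- plant_all(3.3, 72)
  sch <- ligand_schema()
  h_open <- segment_min_distances(open_sys$trajectory, sch)
  h_closed <- segment_min_distances(closed_sys$trajectory, sch)
  io <- which(h_open$summary$segment == "HEAD")
  diff_head <- h_closed$summary$mean[io] - h_open$summary$mean[io]
  se <- sqrt(h_open$summary$se[io]^2 + h_closed$summary$se[io]^2)
  expect_lt(abs(diff_head - 0.5), max(se, 1e-6))
})

test_that("residency intervals, counts and gap merging behave as defined", {
  # molecule inside the cutoff for frames 1..10 of 100
  atoms <- data.frame(
    name = c("CA", "P1"), element = c("C", "C"), resid = c(1L, 2L),
    resname = c("GLY", "POPC"), chain = c("A", "L"),
    role = c("protein", "lipid"))
  top <- topology(atoms)
  nf <- 100
  coords <- array(0, c(2, 3, nf))
  coords[1, , ] <- c(40, 40, 40)
  for (t in seq_len(nf))
    coords[2, , t] <- if (t <= 10) c(41, 40, 40) else c(10, 10, 10)
  tr <- trajectory(top, coords, (seq_len(nf) - 1) * 0.5, c(80, 80, 80))
  res <- residency(tr, "role:protein", "role:lipid", cutoff = 2)
  expect_equal(nrow(res$intervals), 1)
  expect_equal(res$intervals$n_frames, 10)
  expect_equal(res$intervals$duration_ns, 10 * 0.5)
  expect_equal(res$counts$count, c(rep(1, 10), rep(0, 90)))
  # never within the cutoff: empty interval list
  coords[2, , ] <- c(10, 10, 10)
  tr0 <- trajectory(top, coords, (seq_len(nf) - 1) * 0.5, c(80, 80, 80))
  expect_equal(nrow(residency(tr0, "role:protein", "role:lipid",
                              cutoff = 2)$intervals), 0)
  # a 1-frame gap merges with g = 1, splits with g = 0
  for (t in seq_len(nf))
    coords[2, , t] <- if (t %in% c(1:5, 7:12)) c(41, 40, 40) else
      c(10, 10, 10)
  trg <- trajectory(top, coords, (seq_len(nf) - 1) * 0.5, c(80, 80, 80))
  r0 <- residency(trg, "role:protein", "role:lipid", cutoff = 2,
                  gap_frames = 0)
  r1 <- residency(trg, "role:protein", "role:lipid", cutoff = 2,
                  gap_frames = 1)
  expect_equal(nrow(r0$intervals), 2)
  expect_equal(nrow(r1$intervals), 1)
  expect_equal(r1$intervals$n_frames, 12)
})

test_that("per-frame counts equal interval coverage (cross-check identity)", {
  sys <- generate_system(generator_config(
    n_frames = 120, n_ligands = 3, seed = 55,
    planted_contacts = list(
      list(chain = "A", resid = 311, ligand = 1, part = "head",
           intervals = list(c(10, 40), c(60, 80))),
      list(chain = "B", resid = 316, ligand = 2, part = "tail",
           intervals = list(c(0, 119))))))
  res <- residency(sys$trajectory, "role:protein", "role:ligand",
                   cutoff = 3.5)
  cover <- integer(120)
  for (i in seq_len(nrow(res$intervals))) {
    iv <- res$intervals[i, ]
    idx <- which(sys$trajectory$times >= iv$start_ns &
                   sys$trajectory$times <= iv$end_ns)
    cover[idx] <- cover[idx] + 1L
  }
  expect_equal(res$counts$count, cover)
  # planted full-span ligand is resident throughout
  expect_true(all(res$counts$count >= 1))
})

test_that("site-restricted residency only sees the site's vicinity", {
  sys <- generate_system(generator_config(
    n_frames = 50, n_ligands = 2, seed = 56,
    planted_contacts = list(
      list(chain = "A", resid = 311, ligand = 1, part = "head",
           intervals = list(c(0, 49))))))
  near <- residency(sys$trajectory, "role:protein", "role:ligand",
                    cutoff = 3.5,
                    site_residues = data.frame(chain = "A", resid = 311))
  far <- residency(sys$trajectory, "role:protein", "role:ligand",
                   cutoff = 3.5,
                   site_residues = data.frame(chain = "C", resid = 311))
  expect_equal(sum(near$counts$count), 50)
  expect_equal(sum(far$counts$count), 0)
})

test_that("RMSD is zero for identical or rigidly transformed frames", {
  set.seed(31)
  base <- matrix(runif(30, 0, 20), ncol = 3)
  top <- point_topology(10, role = "protein", names = rep("CA", 10),
                        resname = "GLY", chain = "A", resid = 1:10)
  coords <- array(0, c(10, 3, 4))
  coords[, , 1] <- base
  coords[, , 2] <- base
  # frame 3: rotated 90 degrees about z, translated
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  coords[, , 3] <- sweep(base %*% t(Rz), 2, c(5, -3, 2), "+")
  coords[, , 4] <- random_rigid(base)
  tr <- trajectory(top, coords, 0:3, c(500, 500, 500))
  r <- backbone_rmsd(tr, "role:protein and name:CA")
  expect_equal(r$rmsd, rep(0, 4), tolerance = 1e-9)
})

test_that("RMSD matches an independent superposition oracle", {
  # two-frame trajectory, one atom displaced by 1 A in frame 2
  set.seed(32)
  n <- 12
  base <- matrix(runif(3 * n, 0, 15), ncol = 3)
  moved <- base
  moved[1, ] <- moved[1, ] + c(1, 0, 0)
  top <- point_topology(n, role = "protein", names = rep("CA", n),
                        resname = "GLY", chain = "A", resid = 1:n)
  coords <- array(0, c(n, 3, 2))
  coords[, , 1] <- base
  coords[, , 2] <- random_rigid(moved)  # hide the displacement
  tr <- trajectory(top, coords, 0:1, c(500, 500, 500))
  r <- backbone_rmsd(tr, "role:protein and name:CA")
  # oracle: bio3d least-squares fit of each frame onto the two-pass
  # average, computed independently
  xyz1 <- as.numeric(t(base))
  fit2 <- suppressWarnings(
    bio3d::fit.xyz(fixed = xyz1, mobile = as.numeric(t(coords[, , 2]))))
  avg <- (matrix(xyz1, ncol = 3, byrow = TRUE) +
            matrix(fit2, ncol = 3, byrow = TRUE)) / 2
  ref_rmsd <- vapply(1:2, function(t) {
    fit <- suppressWarnings(
      bio3d::fit.xyz(fixed = as.numeric(t(avg)),
                     mobile = as.numeric(t(coords[, , t]))))
    sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - avg)^2)))
  }, 0)
  expect_equal(r$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("RMSD is invariant under random rigid transforms of each frame", {
  set.seed(33)
  n <- 8
  top <- point_topology(n, role = "protein", names = rep("CA", n),
                        resname = "GLY", chain = "A", resid = 1:n)
  coords <- array(runif(n * 3 * 5, 0, 10), c(n, 3, 5))
  tr <- trajectory(top, coords, 0:4, c(500, 500, 500))
  r0 <- backbone_rmsd(tr, "all")
  coords2 <- coords
  for (t in 1:5) coords2[, , t] <- random_rigid(coords[, , t])
  tr2 <- trajectory(top, coords2, 0:4, c(500, 500, 500))
  r2 <- backbone_rmsd(tr2, "all")
  expect_equal(r0$rmsd, r2$rmsd, tolerance = 1e-9)
  # degenerate (collinear) geometry errors
  line <- array(rep(cbind(1:4, 0, 0), 2), c(4, 3, 2))
  trl <- trajectory(point_topology(4, role = "protein"), line, 0:1,
                    c(100, 100, 100))
  expect_error(backbone_rmsd(trl, "all"), "collinear|degenerate")
})
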