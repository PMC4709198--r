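# Minimal one-residue / one-ligand system with scripted head distances.
scripted_contact_traj <- function(dists, dt = 10, box = c(100, 100, 100)) {
  atoms <- data.frame(
    name = c("CA", "O1", "C2"), element = c("C", "O", "C"),
    resid = c(1L, 1L, 1L), resname = c("LEU", "DHA", "DHA"),
    chain = c("A", "X", "X"), role = c("protein", "ligand", "ligand"))
  top <- topology(atoms)
  nf <- length(dists)
  coords <- array(0, c(3, 3, nf))
  for (t in seq_len(nf)) {
    coords[1, , t] <- c(50, 50, 50)
    coords[2, , t] <- c(50 + dists[t], 50, 50)
    coords[3, , t] <- c(50, 50, 10)  # tail far away
  }
  trajectory(top, coords, (seq_len(nf) - 1) * dt, box)
}

small_schema <- function() {
  ligand_schema(tail_length = 5,
                ch_pairs = stats::setNames(as.list(paste0("H", 2:5, "A")),
                                           paste0("C", 2:5)))
}

test_that("distance cutoff is inclusive at 3.5 A and excludes 3.6 A", {
  tr <- scripted_contact_traj(c(3.4, 3.6), dt = 1)
  ev <- detect_contacts(tr, contact_criterion(3.5, 0), schema = small_schema())
  expect_true(ev$events[1, "head", 1])
  expect_false(ev$events[1, "head", 2])
  expect_false(any(ev$events[, "tail", ]))
})

test_that("cumulative time exactly at the threshold is excluded (strict >)", {
  # contact in 30 of 100 frames at dt 10 ns: cumulative 300 ns,
  # frequency 0.3
  dists <- c(rep(3.0, 30), rep(20, 70))
  tr <- scripted_contact_traj(dists, dt = 10)
  ev <- detect_contacts(tr, contact_criterion(3.5, 300),
                        schema = small_schema())
  tab <- contact_table(ev, tr$topology)
  head_row <- tab$raw[tab$raw$part == "head", ]
  expect_equal(head_row$cumulative_ns, 300)
  expect_equal(head_row$frequency, 0.3)
  expect_equal(nrow(tab$filtered), 0)
  # one frame more crosses the boundary
  tr2 <- scripted_contact_traj(c(rep(3.0, 31), rep(20, 69)), dt = 10)
  tab2 <- contact_table(detect_contacts(tr2, contact_criterion(3.5, 300),
                                        schema = small_schema()),
                        tr2$topology)
  expect_equal(nrow(tab2$filtered), 1)
})

test_that("contact in every frame gives frequency 1", {
  tr <- scripted_contact_traj(rep(2.5, 20), dt = 1)
  tab <- contact_table(detect_contacts(tr, contact_criterion(3.5, 0),
                                       schema = small_schema()),
                       tr$topology)
  expect_equal(tab$raw$frequency[tab$raw$part == "head"], 1.0)
})

test_that("longest-continuous persistence differs from cumulative", {
  # two separated runs of 5 frames each at dt 1
  dists <- c(rep(3, 5), rep(20, 5), rep(3, 5), rep(20, 5))
  tr <- scripted_contact_traj(dists, dt = 1)
  evc <- detect_contacts(tr, contact_criterion(3.5, 7),
                         schema = small_schema())
  tabc <- contact_table(evc, tr$topology)
  expect_equal(nrow(tabc$filtered), 1)  # cumulative 10 > 7
  evl <- detect_contacts(tr, contact_criterion(
    3.5, 7, persistence_mode = "longest_continuous"),
    schema = small_schema())
  tabl <- contact_table(evl, tr$topology)
  expect_equal(nrow(tabl$filtered), 0)  # longest run 5 <= 7
})

test_that("contact detection equals the brute-force oracle on random instances", {
  set.seed(14)
  sch <- small_schema()
  for (trial in 1:25) {
    box <- runif(3, 15, 30)
    n_res <- sample(3:6, 1)
    n_patoms <- n_res * 2
    atoms <- data.frame(
      name = rep(c("CA", "CB"), n_res), element = "C",
      resid = rep(seq_len(n_res), each = 2), resname = "LEU",
      chain = "A", role = "protein")
    lig <- data.frame(
      name = c("O1", "C2", "C3"), element = c("O", "C", "C"),
      resid = 1L, resname = "DHA", chain = "X", role = "ligand")
    top <- topology(rbind(atoms, lig))
    nf <- 4
    coords <- array(runif((n_patoms + 3) * 3 * nf, 0, 1),
                    c(n_patoms + 3, 3, nf))
    for (k in 1:3) coords[, k, ] <- coords[, k, ] * box[k]
    tr <- trajectory(top, coords, 0:(nf - 1), box)
    cutoff <- runif(1, 2, 6)
    ev <- detect_contacts(tr, contact_criterion(cutoff, 0), "role:protein",
                          sch, "role:ligand")
    for (t in seq_len(nf)) {
      P <- coords[1:n_patoms, , t]
      ref_head <- bf_contacts(P, rep(seq_len(n_res), each = 2),
                              coords[n_patoms + 1, , t, drop = FALSE],
                              box, cutoff)
      ref_tail <- bf_contacts(P, rep(seq_len(n_res), each = 2),
                              coords[n_patoms + 2:3, , t], box, cutoff)
      expect_identical(unname(ev$events[, "head", t]), ref_head)
      expect_identical(unname(ev$events[, "tail", t]), ref_tail)
    }
  }
})

test_that("cutoff and threshold monotonicity hold", {
  set.seed(15)
  sys <- generate_system(generator_config(
    n_frames = 80, n_ligands = 2, seed = 44,
    planted_contacts = list(
      list(chain = "A", resid = 312, ligand = 1, part = "head",
           intervals = list(c(5, 50))))))
  sch <- ligand_schema()
  ev_small <- detect_contacts(sys$trajectory, contact_criterion(3.5, 0),
                              schema = sch)
  ev_large <- detect_contacts(sys$trajectory, contact_criterion(5.0, 0),
                              schema = sch)
  # enlarging the cutoff never removes a contact
  expect_true(all(ev_large$events[ev_small$events]))
  tab <- contact_table(ev_small, sys$topology)
  for (thr in c(0, 10, 30, 60)) {
    crit <- contact_criterion(3.5, thr)
    evt <- detect_contacts(sys$trajectory, crit, schema = sch)
    tabt <- contact_table(evt, sys$topology)
    expect_true(all(
      paste(tabt$filtered$resid, tabt$filtered$part) %in%
        paste(tab$raw$resid, tab$raw$part)))
    expect_lte(nrow(tabt$filtered),
               nrow(contact_table(detect_contacts(
                 sys$trajectory, contact_criterion(3.5, 0), schema = sch),
                 sys$topology)$filtered))
  }
})

test_that("planted intervals are recovered to frame quantization", {
  cfg <- generator_config(
    n_frames = 120, dt_ns = 0.1, n_ligands = 2, seed = 51,
    planted_contacts = list(
      list(chain = "B", resid = 308, ligand = 1, part = "head",
           intervals = list(c(2, 5), c(8, 9)))))
  sys <- generate_system(cfg)
  ev <- detect_contacts(sys$trajectory, contact_criterion(3.5, 0),
                        schema = ligand_schema())
  tab <- contact_table(ev, sys$topology)
  row <- tab$raw[tab$raw$part == "head" & tab$raw$resid == 308, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$cumulative_ns, 4.0, tolerance = 0.25)
})

test_that("filtered tables recover exactly the planted contact set", {
  sch <- ligand_schema()
  for (seed in 1:6) {
    set.seed(seed)
    n_plant <- sample(2:4, 1)
    chains <- sample(LETTERS[1:4], n_plant, replace = TRUE)
    # helix residues only: the steered ligand is laid out radially
    # outward, which is unobstructed from the S1-S4 ring
    resids <- sample(302:324, n_plant)
    parts <- sample(c("head", "tail"), n_plant, replace = TRUE)
    pcs <- lapply(seq_len(n_plant), function(i)
      list(chain = chains[i], resid = resids[i], ligand = i,
           part = parts[i], intervals = list(c(0, 250))))
    sys <- generate_system(generator_config(
      n_frames = 400, n_ligands = n_plant + 2, seed = seed * 100,
      planted_contacts = pcs))
    tab <- contact_table(detect_contacts(
      sys$trajectory, contact_criterion(3.5, 200), schema = sch),
      sys$topology)
    got <- sort(paste(tab$filtered$chain, tab$filtered$resid,
                      tab$filtered$part))
    want <- sort(unique(paste(chains, resids, parts)))
    expect_identical(got, want)
  }
})

test_that("region summary computes fractions, ratio, degenerate cases", {
  df <- data.frame(
    chain = "A", resid = 1:5, resname = "LEU",
    ligand = "pooled", part = "tail",
    cumulative_ns = 400, frequency = 0.4, persistence_ns = 400,
    region = c("S4", "S4", "S4", "S4", "S1"),
    extracellular = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    residue_class = "hydrophobic")
  tab <- structure(list(raw = df, filtered = df, trajectory_ns = 1000,
                        criterion = contact_criterion()),
                   class = "contact_table")
  rs <- region_summary(tab)
  pr <- rs$per_region[rs$per_region$part == "tail", ]
  expect_equal(pr$fraction[pr$region == "S4"], 0.8)
  expect_equal(sum(pr$fraction), 1)
  expect_equal(unname(rs$extracellular_s3s4["tail"]), 0.8)
  expect_true(is.na(rs$tail_head_ratio))  # no head rows
  # empty filtered table: counts zero, fractions absent
  tab$filtered <- df[0, ]
  rs0 <- region_summary(tab)
  expect_equal(unname(rs0$n_contacts), c(0, 0))
  expect_true(all(is.na(rs0$extracellular_s3s4)))
  expect_null(rs0$per_region)
})

test_that("proximity counts match placement and the brute-force oracle", {
  # two ions at 3.0 and 5.0 A from a single target atom
  atoms <- data.frame(
    name = c("CA", "NA", "NA"), element = c("C", "NA", "NA"),
    resid = 1:3, resname = c("GLY", "NA", "NA"), chain = c("A", "I", "I"),
    role = c("protein", "ion", "ion"))
  top <- topology(atoms)
  coords <- array(0, c(3, 3, 1))
  coords[1, , 1] <- c(25, 25, 25)
  coords[2, , 1] <- c(28, 25, 25)
  coords[3, , 1] <- c(30, 25, 25)
  tr <- trajectory(top, coords, 0, c(50, 50, 50))
  pc <- proximity_count(tr, "role:protein", "role:ion", cutoff = 3.5)
  expect_equal(pc$count, 1L)
  # probe == target: self-pairing excluded, count 0
  pc_self <- proximity_count(tr, "role:ion", "role:ion", cutoff = 3.5)
  expect_equal(pc_self$count, 0L)
  # random fixture against scalar brute force
  set.seed(16)
  for (trial in 1:8) {
    box <- runif(3, 12, 25)
    nt <- 4; np <- 6
    atoms <- data.frame(
      name = c(rep("CA", nt), rep("NA", np)),
      element = c(rep("C", nt), rep("NA", np)),
      resid = seq_len(nt + np),
      resname = c(rep("GLY", nt), rep("NA", np)),
      chain = c(rep("A", nt), rep("I", np)),
      role = c(rep("protein", nt), rep("ion", np)))
    top <- topology(atoms)
    coords <- array(runif((nt + np) * 3 * 2, 0, 1), c(nt + np, 3, 2))
    for (k in 1:3) coords[, k, ] <- coords[, k, ] * box[k]
    tr <- trajectory(top, coords, 0:1, box)
    cutoff <- runif(1, 2, 5)
    pc <- proximity_count(tr, "role:protein", "role:ion", cutoff)
    for (t in 1:2) {
      ref <- sum(vapply((nt + 1):(nt + np), function(i)
        bf_set_min(coords[i, , t, drop = FALSE],
                   coords[1:nt, , t], box) <= cutoff, TRUE))
      expect_equal(pc$count[t], ref)
    }
  }
})

test_that("oversized cutoffs are rejected (minimum-image ambiguity)", {
  tr <- scripted_contact_traj(c(3), dt = 1, box = c(10, 10, 10))
  expect_error(detect_contacts(tr, contact_criterion(6, 0),
                               schema = small_schema()),
               "half the smallest box edge")
})
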