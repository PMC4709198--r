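# amphitraj

Trajectory analysis for amphipathic-ligand interactions with membrane
proteins — built for studies of free fatty acids (e.g. the
polyunsaturated docosahexaenoic acid, DHA 22:6, vs its saturated
counterpart docosanoic acid, DA 22:0) modulating tetrameric voltage-gated
channels in a phospholipid bilayer. The package answers, from an MD
trajectory: *where* on the protein the ligand's charged carboxyl head and
lipophilic acyl tail bind, *how persistently*, and *how the tail's
conformational disorder shapes the interaction*.

## What it computes

* **Chain descriptors** — per-carbon deuterium order parameters
  S_CD = ⟨(3 cos²θ − 1)/2⟩ of each C–H bond against the membrane normal;
  acyl-tail radius of gyration; head-oxygen-to-terminal-carbon (O–C22)
  distances.
* **Contact fingerprints** — residue-level contacts against ligand head
  and tail under a dual threshold (within a distance cutoff, default
  3.5 Å, for *more than* a persistence threshold, default 300 ns,
  cumulative), with contact frequencies, helix-region attribution
  (S1–S4, S3–S4 linker, pore), extracellular-half flags and residue
  chemical classes; per-frame proximity counts (e.g. ions near the
  protein).
* **Segment distance profiles** — per-subunit minimum distances to HEAD
  and tail quarters TAIL-A (C2–6) … TAIL-D (C17–22), or head vs the
  C12–22 analysis tail, with standard errors across the four subunits.
* **Residency** — continuous residence intervals of whole molecules
  within a cutoff (default 2 Å) of the protein, optionally site-local,
  with per-frame resident counts and configurable gap tolerance.
* **Occupancy density** — voxelized fraction-of-frames occupancy grids
  with iso-surface export (OpenDX volume + OBJ surface).
* **Lateral diffusion** — unwrapped xy tracks, time/ensemble-averaged
  MSD, D = slope/4 (2D Einstein relation) in Å²/ns and cm²/s.
* **Stability** — backbone RMSD against the trajectory-average structure
  after optimal (Kabsch) superposition.
* **A synthetic generator** — seeded toy systems (tetramer in a bilayer,
  Brownian ligands with tunable tail disorder) with *planted* contacts,
  residencies and diffusion constants, so every stage is verifiable
  against known ground truth without running MD.

Inputs: PDB/GRO structures, DCD or a documented plaintext trajectory
dialect (one `t=<ns> box=<a b c>` header per frame, one `x y z` line per
atom), and a YAML run configuration with selections, region maps and
thresholds. Internal units are Å and ns.

## Worked example

Generate a small synthetic channel system with two planted contacts and
recover them:

```r
library(amphitraj)
sch <- ligand_schema()   # head O1/O2/C1, tail C2..C22, TAIL-A..D segments

cfg <- generator_config(
  n_frames = 400, n_ligands = 4, seed = 42,
  planted_contacts = list(
    list(chain = "A", resid = 316, ligand = 1, part = "head",
         intervals = list(c(0, 320))),
    list(chain = "C", resid = 322, ligand = 2, part = "tail",
         intervals = list(c(50, 399)))))
sys <- generate_system(cfg)

ev  <- detect_contacts(sys$trajectory, contact_criterion(3.5, 300),
                       schema = sch)
tab <- contact_table(ev, sys$topology)
tab$filtered[, c("chain", "resid", "resname", "part", "cumulative_ns",
                 "frequency", "region", "extracellular")]
#>   chain resid resname part cumulative_ns frequency region extracellular
#> 1     A   316     ASN head           321    0.8025     S3          TRUE
#> 2     C   322     ASN tail           350    0.8750     S4          TRUE
```

The filtered table is exactly the planted set: the head contact planted
on residue 316 (chain A, helix S3) for 0–320 ns is recovered with 321 ns
cumulative time (the interval covers 321 frames at 1 ns spacing) and
frequency 321/400 = 0.80; everything else stays below the 300 ns filter.

Disorder contrast and diffusion on matched synthetic ligands:

```r
p <- generate_fatty_acid_pair(0.1, 0.8, n_frames = 500, seed = 1)
attr(head_to_tail_distance(p$sat,  sch), "summary")[["mean"]]   # 24.3 A
attr(head_to_tail_distance(p$poly, sch), "summary")[["mean"]]   # 11.7 A

patch <- generate_system(generator_config(
  n_subunits = 0, n_lipids = 0, n_ligands = 8, n_frames = 10000,
  flexibility = 0, box = c(250, 250, 80), seed = 3))
lateral_diffusion(patch$trajectory)
#> lateral diffusion: 8 molecule(s); D = 0.04116 A^2/ns = 4.116e-09 cm^2/s
#>   (fit window 200 - 2000 ns)
```

The disordered (polyunsaturated-like) chain is ~12 Å shorter head-to-tail
than the extended saturated-like chain, and the fitted lateral diffusion
constant recovers the generator's planted 4×10⁻⁹ cm²/s within a few
percent.

The same battery runs end to end from a config file, on synthetic or
real input:

```sh
Rscript -e 'amphitraj::cli_main(c("report", "--config",
  system.file("extdata", "demo_config.yaml", package = "amphitraj")))'
```

which writes CSV tables (order parameters, chain shapes, contact tables,
segment distances, residency, RMSD, MSD), an OpenDX occupancy volume, an
OBJ iso-surface and a JSON manifest with checksums. Subcommands
`generate`, `chain-descriptors`, `contacts`, `mindist`, `residency`,
`density`, `diffusion` and `rmsd` run single stages; a thin wrapper
script is installed at `exec/amphitraj`.

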