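#' Read a run configuration from YAML
#'
#' A run configuration declares either a `synthetic` block (arguments for
#' [generator_config()]) or an `input` block (`topology`, `trajectory`
#' paths, optional `region_map` YAML and `dt_ns`), plus optional `schema`
#' (arguments for [ligand_schema()]), `criteria` (contact cutoff /
#' threshold / mode, residency cutoff and gap, density voxel and iso
#' threshold, diffusion fit window), `selections` (protein / ligand /
#' backbone), `output_dir` and `seed`.
#'
#' @param path YAML file path.
#' @return Object of class `run_config` (a validated list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$synthetic) && is.null(cfg$input))
    stop("config must declare either a 'synthetic' or an 'input' block")
  if (!is.null(cfg$input)) {
    for (f in c("topology", "trajectory"))
      if (is.null(cfg$input[[f]]))
        stop("config input block is missing '", f, "'")
  }
  cfg$output_dir <- cfg$output_dir %||% "amphitraj_out"
  cfg$seed <- cfg$seed %||% 1L
  cr <- cfg$criteria %||% list()
  cr$contact_cutoff <- cr$contact_cutoff %||% 3.5
  cr$contact_threshold_ns <- cr$contact_threshold_ns %||% 300
  cr$persistence_mode <- cr$persistence_mode %||% "cumulative"
  cr$residency_cutoff <- cr$residency_cutoff %||% 2.0
  cr$residency_gap_frames <- cr$residency_gap_frames %||% 0
  cr$density_voxel <- cr$density_voxel %||% 1.0
  cr$density_iso <- cr$density_iso %||% 0.27
  cr$diffusion_fit_window <- cr$diffusion_fit_window %||% c(0.02, 0.20)
  cfg$criteria <- cr
  sl <- cfg$selections %||% list()
  sl$protein <- sl$protein %||% "role:protein"
  sl$ligand <- sl$ligand %||% "role:ligand"
  sl$backbone <- sl$backbone %||% "role:protein and name:CA"
  cfg$selections <- sl
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a region map from a YAML sidecar
#'
#' @param path YAML file: a list of records with `region`, `chain`,
#'   `resid`, `extracellular`.
#' @return data.frame suitable for [topology()]'s `region_map`.
#' @export
read_region_map <- function(path) {
  rows <- yaml::read_yaml(path)
  do.call(rbind, lapply(rows, function(r)
    data.frame(region = r$region, chain = r$chain,
               resid = as.integer(r$resid),
               extracellular = isTRUE(r$extracellular),
               stringsAsFactors = FALSE)))
}

load_run_inputs <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    args <- cfg$synthetic
    args$seed <- args$seed %||% cfg$seed
    if (!is.null(args$residues_per_region))
      args$residues_per_region <- unlist(args$residues_per_region)
    if (!is.null(args$planted_contacts))
      args$planted_contacts <- lapply(args$planted_contacts, function(pc) {
        pc$intervals <- lapply(pc$intervals, as.numeric)
        pc
      })
    gen <- do.call(generator_config, args)
    sys <- generate_system(gen)
    list(traj = sys$trajectory, system = sys)
  } else {
    rmap <- NULL
    if (!is.null(cfg$input$region_map))
      rmap <- read_region_map(cfg$input$region_map)
    st <- read_structure(cfg$input$topology, region_map = rmap)
    traj <- read_trajectory(cfg$input$trajectory, st$topology,
                            dt_ns = cfg$input$dt_ns %||% 1,
                            box = cfg$input$box)
    list(traj = traj, system = NULL)
  }
}

#' Run the full analysis battery
#'
#' Executes, in order: chain descriptors (order parameters, radius of
#' gyration, head-to-tail distance), contact analysis (raw and filtered
#' tables, region summary), segment minimum distances, residency,
#' backbone RMSD, occupancy density (OpenDX + OBJ iso-surface) and
#' lateral diffusion. Each stage writes CSV/JSON/DX/OBJ outputs into the
#' configured output directory; a JSON manifest with MD5 checksums and a
#' provenance block is written last. Stage failures abort with a
#' stage-tagged error. Outputs are deterministic given config + inputs.
#'
#' @param cfg A `run_config` (see [read_run_config()]), or a path to one.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  msg <- function(...) message("[amphitraj] ", ...)

  inputs <- stage("load", load_run_inputs(cfg))
  traj <- inputs$traj
  schema <- do.call(ligand_schema, cfg$schema %||% list())
  cr <- cfg$criteria
  sl <- cfg$selections
  files <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  has_ligand <- any(traj$topology$atoms$role == "ligand")
  has_protein <- any(traj$topology$atoms$role == "protein")

  if (has_ligand) {
    msg("chain descriptors")
    stage("chain_descriptors", {
      scd <- order_parameters(traj, schema, sl$ligand)
      wcsv(scd, "order_parameters.csv")
      rg <- radius_of_gyration(traj, schema, sl$ligand)
      wcsv(rg, "radius_of_gyration.csv")
      h2t <- head_to_tail_distance(traj, schema, sl$ligand)
      wcsv(h2t, "head_to_tail.csv")
      summ <- rbind(
        data.frame(measure = "rg", t(attr(rg, "summary"))),
        data.frame(measure = "head_to_tail", t(attr(h2t, "summary"))))
      wcsv(summ, "chain_shape_summary.csv")
    })
  }

  if (has_ligand && has_protein) {
    msg("contact analysis")
    stage("contact_analysis", {
      crit <- contact_criterion(cr$contact_cutoff,
                                cr$contact_threshold_ns,
                                cr$persistence_mode)
      ev <- detect_contacts(traj, crit, sl$protein, schema, sl$ligand)
      tab <- contact_table(ev, traj$topology)
      wcsv(tab$raw, "contacts_raw.csv")
      wcsv(tab$filtered, "contacts_filtered.csv")
      rs <- region_summary(tab)
      if (!is.null(rs$per_region)) wcsv(rs$per_region, "contact_regions.csv")
      p <- file.path(out, "region_summary.json")
      jsonlite::write_json(list(
        n_contacts = as.list(rs$n_contacts),
        tail_head_ratio = rs$tail_head_ratio,
        extracellular_s3s4 = as.list(rs$extracellular_s3s4)),
        p, auto_unbox = TRUE, digits = NA, na = "null")
      files <- c(files, p)
    })
    msg("segment minimum distances")
    stage("distance_residency", {
      smd <- segment_min_distances(traj, schema, sl$protein, sl$ligand)
      wcsv(smd$summary, "segment_min_distances.csv")
      res <- residency(traj, sl$protein, sl$ligand,
                       cutoff = cr$residency_cutoff,
                       gap_frames = cr$residency_gap_frames)
      wcsv(res$intervals, "residency_intervals.csv")
      wcsv(res$counts, "residency_counts.csv")
    })
  }

  if (has_protein) {
    msg("backbone RMSD")
    stage("rmsd", {
      rmsd <- backbone_rmsd(traj, sl$backbone)
      wcsv(as.data.frame(rmsd), "backbone_rmsd.csv")
    })
  }

  if (has_ligand) {
    msg("occupancy density")
    stage("density", {
      grid <- occupancy_grid(traj, sl$ligand, voxel = cr$density_voxel,
                             align_to = if (has_protein) sl$backbone)
      dxp <- file.path(out, "occupancy.dx")
      objp <- file.path(out, "iso_surface.obj")
      iso <- suppressWarnings(
        iso_surface_export(grid, cr$density_iso, dx_path = dxp,
                           obj_path = objp))
      files <- c(files, dxp)
      if (!is.null(iso$vertices)) files <- c(files, objp)
    })
    if (n_frames(traj) >= 10) {
      msg("lateral diffusion")
      stage("diffusion", {
        ld <- lateral_diffusion(traj, sl$ligand,
                                fit_window = cr$diffusion_fit_window)
        wcsv(ld$msd, "msd.csv")
        p <- file.path(out, "diffusion.json")
        jsonlite::write_json(list(
          D_A2_ns = ld$D_A2_ns, D_cm2_s = ld$D_cm2_s,
          se_cm2_s = ld$se_cm2_s, n_molecules = ld$n_molecules,
          nonlinear = ld$nonlinear), p, auto_unbox = TRUE, digits = NA)
        files <- c(files, p)
      })
    }
  }

  manifest <- list(
    package = "amphitraj",
    version = as.character(utils::packageVersion("amphitraj")),
    config_hash = config_hash(cfg),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = lapply(files, function(p) list(
      file = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
  msg("wrote ", length(files), " outputs + manifest to ", out)
  invisible(manifest)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `amphitraj` script
#' (`inst/exec/amphitraj`). Subcommands:
#'
#' * `generate --config cfg.yaml [--seed N] [--out dir]`: write a
#'   synthetic system (PDB + plaintext trajectory + ground truth YAML).
#' * `report --config cfg.yaml [--seed N] [--out dir]`: run the full
#'   analysis battery ([run_pipeline()]).
#' * `chain-descriptors | contacts | mindist | residency | density |
#'   diffusion | rmsd`: run a single stage of the battery (same flags).
#'
#' Flags override config values (`--seed`, `--out`; for `contacts` also
#' `--cutoff`, `--min-time`).
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: amphitraj <subcommand> --config <cfg.yaml> [options]",
    "subcommands: generate, report, chain-descriptors, contacts,",
    "  mindist, residency, density, diffusion, rmsd",
    "options: --seed <int>  --out <dir>  --cutoff <A>  --min-time <ns>",
    "         --help", sep = "\n")
  if (length(args) == 0 || args[1] %in% c("--help", "-h", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  sub <- args[1]
  known <- c("generate", "report", "chain-descriptors", "contacts",
             "mindist", "residency", "density", "diffusion", "rmsd")
  if (!sub %in% known) {
    message("unknown subcommand '", sub, "'\n", usage)
    return(invisible(2L))
  }
  opts <- parse_cli_flags(args[-1])
  if (isTRUE(opts$help)) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  status <- tryCatch({
    if (is.null(opts$config)) stop("--config is required")
    cfg <- read_run_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) cfg$output_dir <- opts$out
    if (!is.null(opts$cutoff))
      cfg$criteria$contact_cutoff <- as.numeric(opts$cutoff)
    if (!is.null(opts$`min-time`))
      cfg$criteria$contact_threshold_ns <- as.numeric(opts$`min-time`)
    if (sub == "generate") {
      if (is.null(cfg$synthetic))
        stop("generate requires a 'synthetic' block in the config")
      inputs <- load_run_inputs(cfg)
      write_system(inputs$system, cfg$output_dir)
      message("[amphitraj] wrote synthetic system to ", cfg$output_dir)
    } else if (sub == "report") {
      run_pipeline(cfg)
    } else {
      run_single_stage(sub, cfg)
    }
    0L
  }, error = function(e) {
    message("amphitraj ", sub, ": error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--help", "-h")) {
      opts$help <- TRUE
      i <- i + 1
    } else if (startsWith(a, "--")) {
      if (i + 1 > length(args)) stop("flag ", a, " needs a value")
      opts[[substring(a, 3)]] <- args[i + 1]
      i <- i + 2
    } else {
      stop("unexpected argument '", a, "'")
    }
  }
  opts
}

run_single_stage <- function(sub, cfg) {
  # narrow the battery to one stage by disabling the others
  full <- cfg
  inputs <- load_run_inputs(cfg)
  traj <- inputs$traj
  schema <- do.call(ligand_schema, cfg$schema %||% list())
  cr <- cfg$criteria
  sl <- cfg$selections
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out, name), row.names = FALSE)
  switch(sub,
    `chain-descriptors` = {
      wcsv(order_parameters(traj, schema, sl$ligand),
           "order_parameters.csv")
      wcsv(radius_of_gyration(traj, schema, sl$ligand),
           "radius_of_gyration.csv")
      wcsv(head_to_tail_distance(traj, schema, sl$ligand),
           "head_to_tail.csv")
    },
    contacts = {
      crit <- contact_criterion(cr$contact_cutoff,
                                cr$contact_threshold_ns,
                                cr$persistence_mode)
      ev <- detect_contacts(traj, crit, sl$protein, schema, sl$ligand)
      tab <- contact_table(ev, traj$topology)
      wcsv(tab$raw, "contacts_raw.csv")
      wcsv(tab$filtered, "contacts_filtered.csv")
    },
    mindist = {
      smd <- segment_min_distances(traj, schema, sl$protein, sl$ligand)
      wcsv(smd$summary, "segment_min_distances.csv")
    },
    residency = {
      res <- residency(traj, sl$protein, sl$ligand,
                       cutoff = cr$residency_cutoff,
                       gap_frames = cr$residency_gap_frames)
      wcsv(res$intervals, "residency_intervals.csv")
      wcsv(res$counts, "residency_counts.csv")
    },
    density = {
      grid <- occupancy_grid(traj, sl$ligand, voxel = cr$density_voxel)
      suppressWarnings(iso_surface_export(
        grid, cr$density_iso, dx_path = file.path(out, "occupancy.dx"),
        obj_path = file.path(out, "iso_surface.obj")))
    },
    diffusion = {
      ld <- lateral_diffusion(traj, sl$ligand,
                              fit_window = cr$diffusion_fit_window)
      wcsv(ld$msd, "msd.csv")
    },
    rmsd = {
      wcsv(as.data.frame(backbone_rmsd(traj, sl$backbone)),
           "backbone_rmsd.csv")
    },
    stop("unhandled stage ", sub))
  message("[amphitraj] stage '", sub, "' written to ", out)
  invisible(NULL)
}
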