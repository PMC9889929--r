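#' Derive a per-stage RNG seed from the master seed
#'
#' Stable string-hash combination of the master seed and the stage name, so
#' each pipeline stage gets its own reproducible stream and inserting a new
#' stage never perturbs the others.
#'
#' @param master_seed integer master seed.
#' @param stage_name stage label (e.g. \code{"pack"}).
#' @return an integer in \code{[1, 2^31 - 2]}.
#' @export
stage_seed <- function(master_seed, stage_name) {
  p <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(as.character(stage_name))) {
    h <- (h * 131 + code) %% p
  }
  s <- ((as.numeric(master_seed) %% p) * 48271 + h) %% p
  as.integer(s %% (p - 2) + 1)
}

# Distribute an integer net charge over n beads in unit increments.
distribute_charge <- function(n_beads, q) {
  charges <- integer(n_beads)
  q <- as.integer(q)
  if (q == 0L) return(charges)
  per <- abs(q) %/% n_beads
  rem <- abs(q) %% n_beads
  charges <- rep(per, n_beads)
  if (rem > 0) charges[seq_len(rem)] <- charges[seq_len(rem)] + 1L
  charges * sign(q)
}

#' Resolve a manifest structure reference to a bead model
#'
#' \code{toy:<n_beads>:<radius_nm>} generates a synthetic [toy_protein()]
#' (seeded deterministically from the species id); any other reference is
#' read from disk with [read_structure()]. The manifest net charge is
#' distributed over the beads in either case.
#'
#' @param ref structure reference string.
#' @param net_charge net charge (e) from the manifest.
#' @param species_id species identifier (seeds toy structures).
#' @param base_seed build seed combined with the species id.
#' @return a [bead_model()].
#' @export
resolve_structure <- function(ref, net_charge = 0L, species_id = "X",
                              base_seed = 1L) {
  if (startsWith(ref, "toy:")) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3) abort(paste0("bad toy structure ref: ", ref),
                                  "minicell_validation_error")
    n <- as.integer(parts[2])
    r <- as.numeric(parts[3])
    return(toy_protein(n, r, charge = net_charge,
                       seed = stage_seed(base_seed, species_id),
                       name = substr(species_id, 1, 5)))
  }
  m <- read_structure(ref)
  m$charges <- distribute_charge(n_beads(m), net_charge)
  m
}

#' Whole-cell build configuration
#'
#' Collects everything a [build_cell()] run needs: geometry, genome source,
#' composition manifest, ribosome stand-ins, lipid composition, box and salt
#' settings, and the master seed from which all stage seeds derive.
#'
#' @param cell_radius membrane mid-surface radius (nm).
#' @param genome_bp genome length for a random synthetic sequence; ignored
#'   when \code{genome_fasta} is given. Must be a multiple of 10 (the
#'   continuum chromosome uses 10-bp monomers).
#' @param genome_fasta optional FASTA path for the genome sequence.
#' @param manifest a \code{composition_manifest} or path to one.
#' @param n_ribosomes number of ribosome stand-ins packed as obstacles.
#' @param ribosome_radius stand-in bounding radius (nm).
#' @param ribosome_charge net charge per stand-in (e); ribosomes are
#'   strongly negative (rRNA).
#' @param lipid_composition a [lipid_composition()].
#' @param surface_subdivisions icosphere subdivision level of the membrane
#'   surface.
#' @param box_padding clearance between cell and periodic image, per side
#'   (nm).
#' @param salt_molarity NaCl target concentration (mol/L).
#' @param water_density water bead density (beads/nm^3).
#' @param contact_threshold minimum cross-body bead distance (nm).
#' @param seed master seed.
#' @param bd_steps Brownian-dynamics relaxation steps for the chromosome.
#' @param minimize_steps clash-relaxation steps after DNA backmapping.
#' @param twist_per_bp equilibrium DNA twist (radians/bp).
#' @param stages named logical toggles (\code{chromosome}, \code{ribosomes},
#'   \code{cytosol}, \code{membrane}, \code{solvate}).
#' @return a validated \code{build_config}.
#' @export
build_config <- function(cell_radius, genome_bp = NULL, genome_fasta = NULL,
                         manifest = NULL, n_ribosomes = 0L,
                         ribosome_radius = 10, ribosome_charge = -30L,
                         lipid_composition = syn3a_lipid_composition(),
                         surface_subdivisions = 3L, box_padding = 5,
                         salt_molarity = 0.135, water_density = 8.33,
                         contact_threshold = 0.47, seed = 42L,
                         bd_steps = 1500L, minimize_steps = 30L,
                         twist_per_bp = 2 * pi / 10.5,
                         stages = list()) {
  stopifnot(cell_radius > 0, box_padding > 0, salt_molarity >= 0,
            water_density > 0, contact_threshold > 0)
  if (is.null(genome_fasta) && is.null(genome_bp)) {
    abort("either genome_bp or genome_fasta is required",
          "minicell_validation_error")
  }
  if (!is.null(genome_fasta) && !file.exists(genome_fasta)) {
    abort(paste0("genome FASTA not found: ", genome_fasta),
          "minicell_validation_error")
  }
  if (is.character(manifest)) manifest <- load_composition(manifest)
  if (!is.null(manifest) && !inherits(manifest, "composition_manifest")) {
    abort("manifest must be a composition_manifest or a path",
          "minicell_validation_error")
  }
  if (!is.null(genome_bp)) {
    genome_bp <- as.integer(genome_bp)
    if (genome_bp %% 10L != 0L || (genome_bp %/% 10L) %% 2L != 0L) {
      abort("genome_bp must give an even number of 10-bp monomers",
            "minicell_validation_error")
    }
  }
  default_stages <- list(chromosome = TRUE, ribosomes = TRUE, cytosol = TRUE,
                         membrane = TRUE, solvate = TRUE)
  default_stages[names(stages)] <- stages
  structure(list(
    cell_radius = cell_radius, genome_bp = genome_bp,
    genome_fasta = genome_fasta, manifest = manifest,
    n_ribosomes = as.integer(n_ribosomes),
    ribosome_radius = ribosome_radius,
    ribosome_charge = as.integer(ribosome_charge),
    lipid_composition = lipid_composition,
    surface_subdivisions = as.integer(surface_subdivisions),
    box_padding = box_padding, salt_molarity = salt_molarity,
    water_density = water_density, contact_threshold = contact_threshold,
    seed = as.integer(seed), bd_steps = as.integer(bd_steps),
    minimize_steps = as.integer(minimize_steps),
    twist_per_bp = twist_per_bp, stages = default_stages
  ), class = "build_config")
}

config_hash <- function(config) {
  p <- 2147483647
  h <- 0
  for (code in utf8ToInt(paste(deparse(unclass(config)), collapse = ""))) {
    h <- (h * 131 + code) %% p
  }
  sprintf("%08x", as.integer(h))
}

#' Build a whole mini-cell model
#'
#' Runs the full construction pipeline in order: chromosome (lattice growth,
#' Brownian-dynamics relaxation, spline interpolation, rotation-minimizing
#' frames, base-pair backmapping), ribosome placement, cytosol packing,
#' membrane construction, and solvation with neutralization and salt. Each
#' stage's output becomes the next stage's set of obstacles; the master seed
#' deterministically fixes every stage, so a config and seed fully determine
#' the output bytes.
#'
#' @param config a [build_config()].
#' @param gro optional output GRO path.
#' @param verbose log per-stage progress to stderr.
#' @return a \code{cell_model}: flattened bead arrays (\code{coords},
#'   \code{bead_names}, \code{resnames}, \code{resids}, \code{charges},
#'   \code{atom_equivalents}, \code{categories}), per-category molecule
#'   counts, \code{box}, \code{placements}, \code{ion_spec},
#'   \code{provenance}, and \code{report}.
#' @export
build_cell <- function(config, gro = NULL, verbose = FALSE) {
  t_all <- proc.time()[["elapsed"]]
  log_stage <- function(...) {
    if (verbose) message(sprintf("[minicell %6.1fs] ",
                                 proc.time()[["elapsed"]] - t_all),
                         sprintf(...))
  }
  seeds <- sapply(c("genome", "ribosomes", "grow", "bd", "pack", "membrane",
                    "ions"),
                  function(s) stage_seed(config$seed, s))
  comp <- config$lipid_composition
  R <- config$cell_radius
  t2 <- comp$thickness / 2
  thr <- config$contact_threshold
  r_pack <- R - t2 - thr          # cytosol region: clear of membrane beads
  r_chrom <- r_pack - 2.0         # path confinement: template extent margin

  coords_list <- list(); names_list <- list(); res_list <- list()
  chg_list <- list(); ae_list <- list(); cat_list <- list()
  molid_list <- list(); bodyid_list <- list()
  mol_counter <- 0L
  body_counter <- 0L
  mol_counts <- c()
  placements <- list()
  # residue_ids drive GRO residue numbering (e.g. one per base pair);
  # body_ids identify rigid bodies/molecules for the overlap contract and
  # the per-category molecule counts (e.g. the whole chromosome is one)
  add_component <- function(category, coords, names, resnames, charges,
                            atom_equivalents, residue_ids,
                            body_ids = residue_ids) {
    i <- length(coords_list) + 1L
    coords_list[[i]] <<- coords
    names_list[[i]] <<- names
    res_list[[i]] <<- resnames
    chg_list[[i]] <<- as.integer(charges)
    ae_list[[i]] <<- as.integer(rep_len(atom_equivalents, nrow(coords)))
    cat_list[[i]] <<- rep(category, nrow(coords))
    molid_list[[i]] <<- mol_counter + residue_ids
    bodyid_list[[i]] <<- body_counter + body_ids
    mol_counter <<- mol_counter + max(residue_ids)
    body_counter <<- body_counter + max(body_ids)
    mol_counts[category] <<- sum(mol_counts[category],
                                 length(unique(body_ids)), na.rm = TRUE)
    invisible(NULL)
  }

  # --- ribosome obstacles (placed first, frozen for later stages) ---
  ribo_spheres <- NULL
  ribo_beads <- matrix(numeric(0), 0, 3)
  if (config$stages$ribosomes && config$n_ribosomes > 0) {
    log_stage("placing %d ribosome stand-ins", config$n_ribosomes)
    ribo_model <- toy_protein(max(30L, round(8 * config$ribosome_radius)),
                              config$ribosome_radius,
                              charge = config$ribosome_charge,
                              seed = seeds[["ribosomes"]], name = "RIBO")
    reg <- pack_region("sphere", radius = r_pack)
    pl <- pack(list(list(model = ribo_model, species_id = "RIBO",
                         copies = config$n_ribosomes)),
               reg, seed = seeds[["ribosomes"]], threshold = thr)
    ribo_beads <- attr(pl, "beads")
    ribo_spheres <- cbind(pl$x, pl$y, pl$z,
                          config$ribosome_radius + 2.2)
    placements$ribosome <- pl
    add_component("ribosome", ribo_beads,
                  rep(ribo_model$bead_names, config$n_ribosomes),
                  rep("RIBO", nrow(ribo_beads)),
                  rep(ribo_model$charges, config$n_ribosomes), 9L,
                  rep(seq_len(config$n_ribosomes),
                      each = n_beads(ribo_model)))
  }

  # --- chromosome ---
  dna_beads_mat <- matrix(numeric(0), 0, 3)
  if (config$stages$chromosome) {
    sequence <- if (!is.null(config$genome_fasta)) {
      read_genome_fasta(config$genome_fasta)
    } else {
      random_sequence(config$genome_bp, 0.5, seeds[["genome"]])
    }
    n_bp <- nchar(sequence)
    if (n_bp %% 10L != 0L || (n_bp %/% 10L) %% 2L != 0L) {
      abort("genome length must give an even number of 10-bp monomers",
            "minicell_validation_error")
    }
    n_mono <- n_bp %/% 10L
    log_stage("growing %d-monomer chromosome ring", n_mono)
    params <- wlc_params(confinement_radius = r_chrom, k_confine = 25)
    ring <- grow_lattice_ring(n_mono, spacing = params$l0,
                              boundary_radius = r_chrom,
                              obstacles = ribo_spheres,
                              seed = seeds[["grow"]])
    log_stage("relaxing by Brownian dynamics (%d steps)", config$bd_steps)
    ring <- relax_bd(ring, params, config$bd_steps, seed = seeds[["bd"]],
                     obstacles = ribo_spheres)
    # settle thermal penetrations with a short zero-temperature descent
    params0 <- params; params0$kBT <- 0
    ring <- relax_bd(ring, params0, 200L, obstacles = ribo_spheres)
    log_stage("backmapping %d bp onto rotation-minimizing frames", n_bp)
    path <- interpolate_bp(ring, n_bp)
    frames <- rmf_frames(path, twist_per_bp = config$twist_per_bp)
    dna <- backmap_dna(frames, sequence)
    if (config$minimize_steps > 0) {
      dna$coords <- minimize_clashes(dna$coords, dna_relax_bonds(dna),
                                     groups = attr(dna, "bp_index"),
                                     n_steps = config$minimize_steps)
    }
    dna_beads_mat <- dna$coords
    add_component("dna", dna$coords, dna$bead_names, dna$resnames,
                  dna$charges, 5L, attr(dna, "bp_index"),
                  body_ids = rep(1L, nrow(dna$coords)))
  }

  # --- cytosol packing ---
  if (config$stages$cytosol && !is.null(config$manifest)) {
    man <- config$manifest
    cyt <- man[man$category %in% c("cytosolic", "peripheral", "unknown",
                                   "metabolite") & man$copies > 0, ,
               drop = FALSE]
    if (nrow(cyt) > 0) {
      log_stage("packing %d cytosolic molecules of %d species",
                sum(cyt$copies), nrow(cyt))
      bodies <- lapply(seq_len(nrow(cyt)), function(i) {
        list(model = resolve_structure(cyt$structure_ref[i],
                                       cyt$net_charge[i],
                                       cyt$species_id[i], config$seed),
             species_id = cyt$species_id[i], copies = cyt$copies[i])
      })
      # large bodies first: mirrors complex-then-protein packing order
      bodies <- bodies[order(vapply(bodies,
                                    function(b) b$model$bounding_radius, 1),
                             decreasing = TRUE)]
      reg <- pack_region("sphere", radius = r_pack,
                         obstacle_beads = rbind(ribo_beads, dna_beads_mat))
      pl <- pack(bodies, reg, seed = seeds[["pack"]], threshold = thr)
      placements$cytosol <- pl
      beads <- attr(pl, "beads")
      owner <- attr(pl, "bead_placement")
      models <- setNames(lapply(bodies, `[[`, "model"),
                         vapply(bodies, `[[`, "", "species_id"))
      per_bead_sp <- pl$species_id[owner]
      add_component("cytosolic", beads,
                    unlist(lapply(pl$species_id,
                                  function(s) models[[s]]$bead_names)),
                    substr(per_bead_sp, 1, 5),
                    unlist(lapply(pl$species_id,
                                  function(s) models[[s]]$charges)),
                    9L, owner)
    }
  }

  # --- membrane ---
  membrane <- NULL
  if (config$stages$membrane) {
    surface <- icosphere(R, config$surface_subdivisions)
    tm <- if (!is.null(config$manifest)) {
      m <- config$manifest
      m[m$category == "transmembrane" & m$copies > 0, , drop = FALSE]
    } else NULL
    proteins <- NULL
    if (!is.null(tm) && nrow(tm) > 0) {
      proteins <- lapply(seq_len(nrow(tm)), function(i) {
        list(model = resolve_structure(tm$structure_ref[i],
                                       tm$net_charge[i], tm$species_id[i],
                                       config$seed),
             species_id = tm$species_id[i], copies = tm$copies[i])
      })
    }
    log_stage("building membrane (R = %g nm)", R)
    membrane <- build_membrane(surface, comp, proteins,
                               seed = seeds[["membrane"]])
    lb <- membrane$lipid_beads
    add_component("lipid", lb$coords, lb$bead_names, lb$resnames,
                  lb$charges, 9L, attr(lb, "lipid_index"))
    if (!is.null(membrane$proteins)) {
      pb <- attr(membrane$proteins, "beads")
      owner <- attr(membrane$proteins, "bead_placement")
      tm_models <- setNames(lapply(proteins, `[[`, "model"),
                            vapply(proteins, `[[`, "", "species_id"))
      add_component("transmembrane", pb,
                    unlist(lapply(membrane$proteins$species_id,
                                  function(s) tm_models[[s]]$bead_names)),
                    substr(membrane$proteins$species_id[owner], 1, 5),
                    unlist(lapply(membrane$proteins$species_id,
                                  function(s) tm_models[[s]]$charges)),
                    9L, owner)
      placements$membrane_proteins <- membrane$proteins
    }
    placements$lipids <- membrane$lipids
  }

  # --- solute assembly + cross-stage overlap contract (cell frame) ---
  solute_coords <- do.call(rbind, coords_list)
  solute_mol <- unlist(bodyid_list)
  solute_cat <- unlist(cat_list)
  if (nrow(solute_coords) > 0) {
    pr <- grid_self_pairs(solute_coords, thr)
    if (nrow(pr) > 0) {
      cross <- solute_mol[pr[, 1]] != solute_mol[pr[, 2]]
      # adjacent lipids in a curved leaflet may brush below the bead
      # threshold deep in the tail region; only distinct non-lipid molecule
      # pairs violate the packing contract
      both_lipid <- solute_cat[pr[, 1]] == "lipid" &
        solute_cat[pr[, 2]] == "lipid"
      if (any(cross & !both_lipid)) {
        abort(sprintf("cross-stage contract violated: %d bead pairs below %g nm",
                      sum(cross & !both_lipid), thr),
              "minicell_contract_error")
      }
    }
  }

  # --- box, water, ions ---
  box <- make_box(2 * (R + t2), config$box_padding)
  ion_spec <- NULL
  if (config$stages$solvate) {
    ctr <- box_center(box)
    shifted <- sweep(solute_coords, 2, ctr, "+")
    fr <- fractional_coords(box, shifted)
    fr <- fr - floor(fr)
    solute_wrapped <- fr %*% box$vectors
    log_stage("tiling water (box volume %.0f nm^3)", box$volume)
    tw <- tile_water(box, solute_wrapped, density = config$water_density,
                     min_dist = 0.45, inside_radius = R)
    net_solute <- sum(unlist(chg_list))
    charged <- solute_wrapped[unlist(chg_list) != 0, , drop = FALSE]
    log_stage("ionizing: net solute charge %+d e, %d waters",
              net_solute, nrow(tw$coords))
    ion_spec <- ionize(net_solute, tw$coords, charged,
                       molarity = config$salt_molarity,
                       seed = seeds[["ions"]])
    solute_coords <- solute_wrapped
    nw <- nrow(ion_spec$waters)
    if (nw > 0) {
      add_component("water", ion_spec$waters, rep("W", nw), rep("W", nw),
                    integer(nw), 12L, seq_len(nw))
    }
    n_ion <- ion_spec$n_sodium + ion_spec$n_chloride
    if (n_ion > 0) {
      add_component("ion", rbind(ion_spec$sodium, ion_spec$chloride),
                    rep(c("NA", "CL"),
                        c(ion_spec$n_sodium, ion_spec$n_chloride)),
                    rep(c("NA", "CL"),
                        c(ion_spec$n_sodium, ion_spec$n_chloride)),
                    rep(c(1L, -1L),
                        c(ion_spec$n_sodium, ion_spec$n_chloride)),
                    1L, seq_len(n_ion))
    }
    # solute contribution was assembled pre-wrap; swap in wrapped coords
    n_solute <- nrow(solute_wrapped)
    flat_idx <- 0L
    for (i in seq_along(coords_list)) {
      ni <- nrow(coords_list[[i]])
      if (flat_idx + ni <= n_solute) {
        coords_list[[i]] <- solute_wrapped[flat_idx + seq_len(ni), ,
                                           drop = FALSE]
      }
      flat_idx <- flat_idx + ni
    }
    tw$coords <- NULL
    ion_spec$n_inside <- tw$n_inside
    ion_spec$n_outside <- tw$n_outside
  }

  model <- structure(list(
    coords = do.call(rbind, coords_list),
    bead_names = unlist(names_list),
    resnames = unlist(res_list),
    resids = unlist(molid_list),
    body_ids = unlist(bodyid_list),
    charges = unlist(chg_list),
    atom_equivalents = unlist(ae_list),
    categories = unlist(cat_list),
    molecule_count_by_category = mol_counts,
    box = box,
    placements = placements,
    ion_spec = ion_spec,
    provenance = list(seed = config$seed, stage_seeds = as.list(seeds),
                      config_hash = config_hash(config))
  ), class = "cell_model")
  if (config$stages$solvate && sum(model$charges) != 0L) {
    abort("electroneutrality contract violated", "minicell_contract_error")
  }
  model$report <- composition_report(model)
  if (!is.null(gro)) {
    log_stage("writing %d beads to %s", nrow(model$coords), gro)
    write_gro(model, box, gro,
              title = sprintf("minicell build seed=%d config=%s",
                              config$seed, model$provenance$config_hash))
  }
  log_stage("done: %d beads", nrow(model$coords))
  model
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("cell_model: %d beads, net charge %+d e\n",
              nrow(x$coords), sum(x$charges)))
  print(x$report)
  invisible(x)
}
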