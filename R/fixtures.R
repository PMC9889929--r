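#' Random genome sequence
#'
#' Draws an A/C/G/T sequence with independent bases; each position is G/C
#' with probability \code{gc_fraction} (G and C equiprobable), A/T otherwise.
#' Stands in for a real genome when building synthetic test cells.
#'
#' @param n_bp sequence length in base pairs.
#' @param gc_fraction target GC content in \code{[0, 1]}.
#' @param seed RNG seed (the sequence is a pure function of it).
#' @return a character string of length \code{n_bp}.
#' @export
random_sequence <- function(n_bp, gc_fraction = 0.5, seed = NULL) {
  stopifnot(n_bp >= 0, gc_fraction >= 0, gc_fraction <= 1)
  if (n_bp == 0) return("")
  with_seed(seed, {
    gc <- runif(n_bp) < gc_fraction
    half <- runif(n_bp) < 0.5
    chars <- ifelse(gc, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
    paste(chars, collapse = "")
  })
}

#' Toy protein bead blob
#'
#' A synthetic rigid body standing in for a CG protein: \code{n_beads} beads
#' drawn uniformly inside a sphere of the given radius, with the net charge
#' spread over the beads in integer units. Used to exercise packing and
#' assembly without shipping real structures.
#'
#' @param n_beads number of beads (>= 1).
#' @param radius bounding radius (nm); 0 collapses all beads to the origin.
#' @param charge net charge (e), distributed over beads.
#' @param seed RNG seed.
#' @param name bead/residue name stem.
#' @return a [bead_model()].
#' @export
toy_protein <- function(n_beads, radius, charge = 0L, seed = NULL,
                        name = "TOY") {
  stopifnot(n_beads >= 1, radius >= 0)
  with_seed(seed, {
    if (radius == 0) {
      coords <- matrix(0, n_beads, 3)
    } else {
      # uniform in the ball: direction x radius ~ U^(1/3)
      dir <- matrix(rnorm(3 * n_beads), ncol = 3)
      dir <- dir / pmax(vnorm(dir), 1e-12)
      coords <- dir * (radius * runif(n_beads)^(1 / 3))
    }
    charges <- integer(n_beads)
    q <- as.integer(charge)
    if (q != 0) {
      per <- q %/% n_beads
      rem <- abs(q) %% n_beads
      charges <- rep(per, n_beads)
      if (rem > 0) charges[seq_len(rem)] <- charges[seq_len(rem)] + sign(q)
      # %/% floors toward -Inf; rebalance so the sum is exactly q
      excess <- sum(charges) - q
      i <- 1L
      while (excess != 0) {
        charges[i] <- charges[i] - sign(excess)
        excess <- excess - sign(excess)
        i <- i %% n_beads + 1L
      }
    }
    bead_model(coords, names = paste0("B", seq_len(n_beads)),
               charges = charges, resnames = name)
  })
}

#' Packaged minimal-cell metadata
#'
#' Published bulk numbers for the JCVI-syn3A minimal cell used as build
#' defaults: 400-nm diameter, 543-kbp circular genome, the 452-protein
#' localization split (281 cytosolic / 63 transmembrane / 42 peripheral /
#' 66 unknown), the five-lipid membrane composition, 503 ribosomes and
#' 135 mM NaCl. Structures associated with these numbers are synthetic.
#'
#' @return a named list.
#' @export
syn3a_metadata <- function() {
  path <- system.file("extdata", "syn3a_metadata.yaml", package = "minicell")
  yaml::read_yaml(path)
}

#' Packaged synthetic Syn3A proteome manifest
#'
#' A 452-row composition manifest whose localization category counts follow
#' the published Syn3A proteome split; species identifiers, copy numbers,
#' charges and toy structure references are synthetic stand-ins.
#'
#' @return a \code{composition_manifest} (see [load_composition()]).
#' @export
syn3a_proteome <- function() {
  load_composition(system.file("extdata", "syn3a_proteome.tsv",
                               package = "minicell"))
}

#' Minimal-cell lipid composition
#'
#' The five-species membrane mixture of the minimal cell: cholesterol 59%,
#' sphingomyelin 18%, cardiolipin 17%, phosphatidylcholine 4%,
#' phosphatidylglycerol 2%, uniform across both leaflets.
#'
#' @param area_per_lipid mean area per lipid (nm^2).
#' @param thickness bilayer thickness (nm).
#' @return a [lipid_composition()].
#' @export
syn3a_lipid_composition <- function(area_per_lipid = 0.60, thickness = 4) {
  md <- syn3a_metadata()
  lipid_composition(species = names(md$lipid_fractions),
                    fractions = unlist(md$lipid_fractions),
                    area_per_lipid = area_per_lipid, thickness = thickness)
}

#' Write a composition manifest to TSV
#'
#' @param manifest a \code{composition_manifest}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic toy manifest used by the mini-cell configurations.
mini_cell_manifest <- function(n_cytosolic_species = 10L,
                               copies_per_species = 10L,
                               n_membrane_species = 4L,
                               membrane_copies = 3L) {
  cyt <- data.frame(
    species_id = sprintf("CYT%02d", seq_len(n_cytosolic_species)),
    category = "cytosolic",
    copies = copies_per_species,
    net_charge = rep_len(c(-3L, 0L, 2L, -1L, 0L), n_cytosolic_species),
    structure_ref = rep_len(c("toy:20:1.4", "toy:16:1.2", "toy:24:1.6"),
                            n_cytosolic_species),
    stringsAsFactors = FALSE)
  mem <- data.frame(
    species_id = sprintf("TM%02d", seq_len(n_membrane_species)),
    category = "transmembrane",
    copies = membrane_copies,
    net_charge = rep_len(c(0L, -2L), n_membrane_species),
    structure_ref = "toy:18:1.1",
    stringsAsFactors = FALSE)
  validate_manifest(rbind(cyt, mem))
}

#' Mini-cell build configurations
#'
#' Scaled-down replicas of a full minimal-cell build that exercise every
#' stage of the pipeline at desk scale. \code{tiny} is a 50-nm cell with a
#' 5-kbp ring, 100 toy cytosolic proteins and a membrane targeting about
#' 2,000 lipids; \code{small} is a 100-nm cell with a 20-kbp ring and about
#' 1,000 proteins. Both use the five-species minimal-cell lipid mixture and
#' 135 mM NaCl. Lipid area per lipid is inflated at these toy scales so the
#' membrane carries the stated lipid budget; the physical default (0.60
#' nm^2) applies to full-scale membranes.
#'
#' @param scale \code{"tiny"} or \code{"small"}.
#' @param seed master seed stored in the configuration.
#' @return a [build_config()].
#' @export
mini_cell_config <- function(scale = c("tiny", "small"), seed = 42L) {
  scale <- match.arg(scale)
  md <- syn3a_metadata()
  fr <- unlist(md$lipid_fractions)
  if (scale == "tiny") {
    radius <- 25; n_bp <- 5000L
    manifest <- mini_cell_manifest(10L, 10L, 4L, 3L)
    # (A_outer + A_inner)/apl ~ 2,000 lipids on a 50-nm vesicle
    apl <- 7.8; n_ribosomes <- 3L; ribosome_radius <- 4
    bd_steps <- 1500L; minimize_steps <- 30L
  } else {
    radius <- 50; n_bp <- 20000L
    manifest <- mini_cell_manifest(20L, 50L, 6L, 5L)
    apl <- 2.4; n_ribosomes <- 12L; ribosome_radius <- 6
    bd_steps <- 2500L; minimize_steps <- 30L
  }
  build_config(
    cell_radius = radius,
    genome_bp = n_bp,
    manifest = manifest,
    n_ribosomes = n_ribosomes,
    ribosome_radius = ribosome_radius,
    lipid_composition = lipid_composition(names(fr), fr,
                                          area_per_lipid = apl,
                                          thickness = 4),
    box_padding = 5,
    salt_molarity = md$salt_molarity,
    seed = seed,
    bd_steps = bd_steps,
    minimize_steps = minimize_steps
  )
}
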