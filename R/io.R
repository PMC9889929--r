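#' Read a composition manifest
#'
#' A composition manifest is a tab-separated table with a header line and
#' columns \code{species_id}, \code{category}, \code{copies},
#' \code{net_charge}, \code{structure_ref}. It lists every molecular species
#' in a build, its localization category, copy number and net charge; extra
#' columns are ignored. Categories follow the proteome localization classes
#' used for the minimal cell (cytosolic, transmembrane, peripheral, unknown)
#' plus the bookkeeping classes ribosome, lipid and metabolite.
#'
#' @param path path to a TSV manifest file.
#' @return a \code{composition_manifest}: a data frame with the five
#'   canonical columns, validated (unique species, non-negative copies, known
#'   categories, structure refs present for non-lipid species).
#' @export
load_composition <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path),
                                "minicell_parse_error")
  if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0) {
    return(empty_manifest())
  }
  df <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               comment.char = "#", quote = ""),
    error = function(e) abort(paste0("malformed manifest: ", conditionMessage(e)),
                              "minicell_parse_error"))
  if (nrow(df) == 0 && ncol(df) <= 1) return(empty_manifest())
  req <- c("species_id", "category", "copies", "net_charge", "structure_ref")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          "minicell_parse_error")
  }
  out <- df[req]
  out$species_id <- as.character(out$species_id)
  out$category <- as.character(out$category)
  out$structure_ref <- as.character(out$structure_ref)
  suppressWarnings({
    out$copies <- as.integer(out$copies)
    out$net_charge <- as.integer(out$net_charge)
  })
  validate_manifest(out)
}

manifest_categories <- c("cytosolic", "transmembrane", "peripheral",
                         "unknown", "ribosome", "lipid", "metabolite")

empty_manifest <- function() {
  structure(
    data.frame(species_id = character(), category = character(),
               copies = integer(), net_charge = integer(),
               structure_ref = character(), stringsAsFactors = FALSE),
    class = c("composition_manifest", "data.frame"))
}

validate_manifest <- function(df) {
  if (anyNA(df$copies)) abort("non-integer copies field",
                              "minicell_parse_error")
  if (anyNA(df$net_charge)) abort("non-integer net_charge field",
                                  "minicell_parse_error")
  if (anyDuplicated(df$species_id)) {
    abort(paste0("duplicate species_id: ",
                 df$species_id[duplicated(df$species_id)][1]),
          "minicell_validation_error")
  }
  bad <- setdiff(unique(df$category), manifest_categories)
  if (length(bad) > 0) abort(paste0("unknown category: ", bad[1]),
                             "minicell_validation_error")
  if (any(df$copies < 0)) abort("negative copy number",
                                "minicell_validation_error")
  need_ref <- df$category != "lipid"
  no_ref <- need_ref & (is.na(df$structure_ref) | df$structure_ref == "")
  if (any(no_ref)) {
    abort(paste0("missing structure_ref for species ",
                 df$species_id[no_ref][1]),
          "minicell_validation_error")
  }
  structure(df, class = c("composition_manifest", "data.frame"))
}

#' Read a CG structure file as a bead model
#'
#' Accepts GRO or PDB coordinate files and treats every atom record as one CG
#' bead. Coordinates are returned in nanometres (PDB Angstroms are divided by
#' 10 at the boundary); beads keep their input order.
#'
#' @param path path to a \code{.gro} or \code{.pdb} file.
#' @return a [bead_model()] (charges zero; charges come from the manifest).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("structure not found: ", path),
                                "minicell_format_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") return(read_gro(path))
  if (ext %in% c("pdb", "ent")) return(read_pdb(path))
  # sniff: PDB files carry ATOM/HETATM records
  ln <- readLines(path, n = 50L)
  if (any(grepl("^(ATOM|HETATM)", ln))) return(read_pdb(path))
  read_gro(path)
}

#' @rdname read_structure
#' @export
read_gro <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 2) abort("truncated GRO file", "minicell_format_error")
  n <- suppressWarnings(as.integer(trimws(ln[2])))
  if (is.na(n)) abort("bad atom count line in GRO file",
                      "minicell_format_error")
  if (n == 0) abort("GRO file contains no atoms",
                    "minicell_empty_structure_error")
  if (length(ln) < 2 + n) abort("GRO file shorter than declared atom count",
                                "minicell_format_error")
  rec <- ln[3:(2 + n)]
  resnames <- trimws(substr(rec, 6, 10))
  atnames <- trimws(substr(rec, 11, 15))
  x <- as.numeric(substr(rec, 21, 28))
  y <- as.numeric(substr(rec, 29, 36))
  z <- as.numeric(substr(rec, 37, 44))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    abort("unparseable coordinate field in GRO file", "minicell_format_error")
  }
  m <- bead_model(cbind(x, y, z), names = atnames, resnames = resnames)
  boxline <- trimws(ln[3 + n])
  if (!is.na(boxline) && nzchar(boxline)) {
    attr(m, "box") <- as.numeric(strsplit(boxline, "\\s+")[[1]])
  }
  m
}

#' @rdname read_structure
#' @export
read_pdb <- function(path) {
  ln <- readLines(path)
  rec <- ln[grepl("^(ATOM  |HETATM)", ln)]
  if (length(rec) == 0) abort("PDB file contains no ATOM/HETATM records",
                              "minicell_empty_structure_error")
  atnames <- trimws(substr(rec, 13, 16))
  resnames <- trimws(substr(rec, 18, 20))
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    abort("unparseable coordinate field in PDB file", "minicell_format_error")
  }
  bead_model(cbind(x, y, z) / 10, names = atnames, resnames = resnames)
}

#' Write a GRO coordinate file
#'
#' Fixed-column GRO records (resid \code{%5d}, resname \code{%-5s}, atom name
#' \code{%5s}, atom id \code{%5d}, coordinates \code{%8.3f} nm) followed by
#' the box line. Atom and residue indices wrap modulo 100,000 as required by
#' the fixed field width; true indices are kept in the in-memory model.
#' Triclinic boxes (e.g. the rhombic dodecahedron) are written as the
#' 9-component GRO box line.
#'
#' @param model a [bead_model()] or \code{cell_model} to write.
#' @param box a [simulation_box()], a length-3 numeric (cubic extents, nm), or
#'   \code{NULL} for a zero box.
#' @param path output file path.
#' @param title title line (provenance comments may be embedded here).
#' @return \code{path}, invisibly.
#' @export
write_gro <- function(model, box = NULL, path, title = "minicell model") {
  f <- flatten_beads(model)
  coords <- f$coords
  if (any(!is.finite(coords))) abort("non-finite coordinates",
                                     "minicell_format_error")
  if (any(abs(coords) > 9999.999 + 1e-9)) {
    abort("coordinate outside the +/-9999.999 nm GRO field width",
          "minicell_overflow_error")
  }
  neg_wide <- coords < 0 & abs(coords) > 999.999 + 1e-9
  if (any(neg_wide)) {
    abort("negative coordinate too wide for the 8-character GRO field",
          "minicell_overflow_error")
  }
  n <- nrow(coords)
  resid <- f$resids %% 100000L
  atomid <- seq_len(n) %% 100000L
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   resid, substr(f$resnames, 1, 5), substr(f$bead_names, 1, 5),
                   atomid, coords[, 1], coords[, 2], coords[, 3])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(title, sprintf("%d", n), lines, box_line(box)), con, sep = "\n")
  invisible(path)
}

box_line <- function(box) {
  if (is.null(box)) return(sprintf("%10.5f%10.5f%10.5f", 0, 0, 0))
  if (inherits(box, "simulation_box")) {
    v <- box$vectors
    offdiag <- c(v[1, 2], v[1, 3], v[2, 1], v[2, 3], v[3, 1], v[3, 2])
    if (all(abs(offdiag) < 1e-12)) {
      return(sprintf("%10.5f%10.5f%10.5f", v[1, 1], v[2, 2], v[3, 3]))
    }
    return(paste0(sprintf("%10.5f", c(v[1, 1], v[2, 2], v[3, 3], offdiag)),
                  collapse = ""))
  }
  sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
}

# Common flat view over bead_model and cell_model.
flatten_beads <- function(model) {
  if (inherits(model, "cell_model")) {
    return(list(coords = model$coords, bead_names = model$bead_names,
                resnames = model$resnames, resids = model$resids,
                charges = model$charges,
                atom_equivalents = model$atom_equivalents))
  }
  if (inherits(model, "bead_model")) {
    return(list(coords = model$coords, bead_names = model$bead_names,
                resnames = model$resnames,
                resids = rep(1L, nrow(model$coords)),
                charges = model$charges,
                atom_equivalents = model$atom_equivalents))
  }
  abort("expected a bead_model or cell_model", "minicell_validation_error")
}

#' Read a genome sequence from FASTA
#'
#' Reads the first record of a FASTA file and returns the sequence as an
#' upper-case A/C/G/T string (lowercase input accepted).
#'
#' @param path FASTA file path.
#' @return a single character string.
#' @export
read_genome_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(seqs) == 0) abort("empty FASTA file",
                               "minicell_empty_structure_error")
  s <- toupper(as.character(seqs[[1]]))
  if (!grepl("^[ACGT]*$", s)) abort("sequence contains non-ACGT characters",
                                    "minicell_sequence_alphabet_error")
  s
}

#' Write a single-record FASTA file
#'
#' @param sequence A/C/G/T character string.
#' @param path output path.
#' @param name record name.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(sequence, path, name = "synthetic_genome") {
  seqinr::write.fasta(sequences = sequence, names = name, file.out = path,
                      as.string = TRUE, nbchar = 70)
  invisible(path)
}

#' Default atom-equivalent table
#'
#' Atoms represented per CG bead, by bead name: a water bead stands for four
#' real waters (12 atoms), monatomic ion beads for 1 atom, and unlisted beads
#' fall back to \code{default} (9 atoms, roughly four heavy atoms plus
#' hydrogens). The table is configurable because the per-bead accounting
#' behind whole-cell atom totals is a modelling convention, not a measured
#' quantity.
#'
#' @param default atoms per bead for names not in the table.
#' @param overrides named integer vector merged over the built-in entries.
#' @return a named integer vector with a \code{"default"} entry.
#' @export
atom_equivalent_table <- function(default = 9L, overrides = NULL) {
  tab <- c(W = 12L, NA. = 1L, CL = 1L, default = as.integer(default))
  names(tab)[2] <- "NA"
  if (!is.null(overrides)) tab[names(overrides)] <- as.integer(overrides)
  tab
}

#' Composition and charge report
#'
#' Summarizes a model (or a manifest) per localization category: molecule and
#' bead counts, net charge, and total atom equivalents. Totals are exact
#' integer sums over the per-category parts; a finished solvated cell model
#' reports net charge zero.
#'
#' @param x a \code{cell_model} or [load_composition()] manifest.
#' @param ... passed to methods.
#' @return a \code{minicell_report} list with \code{by_category} (data frame),
#'   \code{total_beads}, \code{total_molecules}, \code{net_charge} and
#'   \code{total_atom_equivalents}.
#' @export
composition_report <- function(x, ...) UseMethod("composition_report")

#' @rdname composition_report
#' @param atom_map optional [atom_equivalent_table()]; when given it
#'   overrides the per-bead atom equivalents stored in the model, by bead
#'   name. Every bead name must then resolve (to an entry or the default).
#' @export
composition_report.cell_model <- function(x, atom_map = NULL, ...) {
  ae <- x$atom_equivalents
  if (!is.null(atom_map)) {
    if (!"default" %in% names(atom_map)) {
      abort("atom_map must carry a 'default' entry",
            "minicell_missing_mapping_error")
    }
    idx <- match(x$bead_names, names(atom_map))
    ae <- ifelse(is.na(idx), atom_map[["default"]], atom_map[idx])
  }
  cats <- x$categories
  lev <- sort(unique(cats))
  by_cat <- data.frame(
    category = lev,
    molecules = as.integer(x$molecule_count_by_category[lev]),
    beads = as.integer(table(factor(cats, levels = lev))),
    charge = as.integer(tapply(x$charges, factor(cats, levels = lev), sum)),
    atom_equivalents = as.numeric(tapply(ae, factor(cats, levels = lev), sum)),
    stringsAsFactors = FALSE)
  by_cat$charge[is.na(by_cat$charge)] <- 0L
  structure(list(
    by_category = by_cat,
    total_molecules = sum(by_cat$molecules),
    total_beads = sum(by_cat$beads),
    net_charge = sum(x$charges),
    total_atom_equivalents = sum(ae)
  ), class = "minicell_report")
}

#' @rdname composition_report
#' @export
composition_report.composition_manifest <- function(x, ...) {
  lev <- sort(unique(x$category))
  by_cat <- data.frame(
    category = lev,
    species = as.integer(table(factor(x$category, levels = lev))),
    molecules = as.integer(tapply(x$copies, factor(x$category, levels = lev),
                                  sum)),
    charge = as.integer(tapply(x$copies * x$net_charge,
                               factor(x$category, levels = lev), sum)),
    stringsAsFactors = FALSE)
  for (cc in c("molecules", "charge")) by_cat[[cc]][is.na(by_cat[[cc]])] <- 0L
  structure(list(
    by_category = by_cat,
    total_species = sum(by_cat$species),
    total_molecules = sum(by_cat$molecules),
    net_charge = sum(x$copies * x$net_charge)
  ), class = "minicell_report")
}

#' @export
print.minicell_report <- function(x, ...) {
  cat("minicell composition report\n")
  print(x$by_category, row.names = FALSE)
  for (f in setdiff(names(x), "by_category")) {
    cat(sprintf("  %s: %s\n", f, format(x[[f]], big.mark = ",")))
  }
  invisible(x)
}
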