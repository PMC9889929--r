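# A reduced but complete build exercised once and shared across blocks.
small_build_config <- function(seed = 7L) {
  man <- minicell:::mini_cell_manifest(4L, 5L, 2L, 2L)
  build_config(
    cell_radius = 16, genome_bp = 1000L, manifest = man,
    n_ribosomes = 1L, ribosome_radius = 3,
    lipid_composition = lipid_composition(
      c("CHOL", "SM", "CDL", "PC", "PG"),
      c(0.59, 0.18, 0.17, 0.04, 0.02), area_per_lipid = 4, thickness = 4),
    box_padding = 4, seed = seed, bd_steps = 300L, minimize_steps = 10L)
}

model <- build_cell(small_build_config())

test_that("build reports conserve the configured molecule counts", {
  counts <- model$molecule_count_by_category
  expect_identical(unname(counts["dna"]), 1L)
  expect_identical(unname(counts["ribosome"]), 1L)
  expect_identical(unname(counts["cytosolic"]), 20L)   # 4 species x 5
  expect_identical(unname(counts["transmembrane"]), 4L)
  rep <- model$report
  expect_identical(rep$total_beads, nrow(model$coords))
  expect_identical(rep$total_beads, sum(rep$by_category$beads))
  expect_identical(rep$total_molecules, sum(rep$by_category$molecules))
})

test_that("solvated builds are exactly electroneutral", {
  expect_identical(sum(model$charges), 0L)
  expect_identical(sum(model$charges) + 0L, model$report$net_charge)
  ions <- model$ion_spec
  expect_identical(ions$n_sodium - ions$n_chloride,
                   -sum(model$charges[!model$categories %in%
                                        c("water", "ion")]))
})

test_that("every bead lies inside the periodic box", {
  fr <- model$coords %*% solve(model$box$vectors)
  expect_true(all(fr >= -1e-9 & fr < 1 + 1e-9))
})

test_that("category bead counts equal the sums over placement templates", {
  rep <- model$report$by_category
  dna_beads <- rep$beads[rep$category == "dna"]
  expect_identical(dna_beads, dna_topology(strrep("A", 1000))$beads)
  expect_identical(rep$beads[rep$category == "cytosolic"],
                   sum(model$categories == "cytosolic"))
})

test_that("the exhaustive overlap oracle certifies the assembled solute", {
  solute <- !model$categories %in% c("water", "ion")
  x <- model$coords[solute, , drop = FALSE]
  own <- model$body_ids[solute]
  cat <- model$categories[solute]
  thr <- 0.47
  hits <- 0L
  block <- 1500L
  for (i0 in seq(1, nrow(x), by = block)) {
    ii <- i0:min(i0 + block - 1L, nrow(x))
    d2 <- outer(rowSums(x[ii, , drop = FALSE]^2), rowSums(x^2), "+") -
      2 * x[ii, , drop = FALSE] %*% t(x)
    close <- which(d2 < thr^2, arr.ind = TRUE)
    gi <- ii[close[, 1]]
    gj <- close[, 2]
    keep <- own[gi] != own[gj] &
      !(cat[gi] == "lipid" & cat[gj] == "lipid")
    hits <- hits + sum(keep)
  }
  expect_identical(hits, 0L)
})

test_that("water stays clear of the solute and splits inside/outside", {
  waters <- model$coords[model$categories == "water", , drop = FALSE]
  solute <- model$coords[!model$categories %in% c("water", "ion"), ,
                         drop = FALSE]
  # spot-check with the exhaustive oracle on a subsample
  set.seed(1)
  sub <- waters[sample.int(nrow(waters), 4000), ]
  expect_gte(brute_min_dist(sub, solute), 0.45)
  ions <- model$ion_spec
  expect_identical(ions$n_inside + ions$n_outside,
                   nrow(waters) + ions$n_sodium + ions$n_chloride)
})

test_that("rebuilding with the same master seed is byte-identical", {
  f1 <- tmpfile(".gro")
  f2 <- tmpfile(".gro")
  write_gro(model, model$box, f1,
            title = sprintf("minicell build seed=%d", 7L))
  m2 <- build_cell(small_build_config())
  write_gro(m2, m2$box, f2, title = sprintf("minicell build seed=%d", 7L))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the output
  m3 <- build_cell(small_build_config(seed = 8L))
  expect_false(identical(model$coords, m3$coords))
})

test_that("stage toggles skip stages cleanly", {
  cfg <- small_build_config()
  cfg$stages$solvate <- FALSE
  cfg$stages$cytosol <- FALSE
  m <- build_cell(cfg)
  expect_false("water" %in% m$categories)
  expect_false("cytosolic" %in% m$categories)
  expect_true(all(c("dna", "lipid") %in% m$categories))
})

test_that("invalid configurations are rejected up front", {
  expect_error(build_config(cell_radius = 10),
               class = "minicell_validation_error")
  expect_error(build_config(cell_radius = 10, genome_bp = 1005L),
               class = "minicell_validation_error")
  expect_error(build_config(cell_radius = 10, genome_bp = 1000L,
                            genome_fasta = "/no/such/file.fasta"),
               class = "minicell_validation_error")
})
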