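#' Triangulated icosphere
#'
#' Subdivided icosahedron projected onto a sphere: the standard triangulated
#' surface input for membrane backmapping. Subdivision 0 is the icosahedron
#' (12 vertices, 20 faces, 30 edges); each level quadruples the face count.
#'
#' @param radius sphere radius (nm).
#' @param subdivisions number of 4-way subdivision passes (>= 0).
#' @return a \code{triangulated_surface}: list with \code{vertices}
#'   (\code{V x 3} nm), \code{faces} (\code{F x 3} vertex indices, outward
#'   winding), \code{normals} (outward unit vertex normals), \code{area}
#'   (total nm^2) and \code{radius}.
#' @export
icosphere <- function(radius, subdivisions = 0L) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- edge_mid[[key]]
      if (!is.null(hit)) return(hit)
      p <- (verts[i, ] + verts[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      id <- nrow(verts)
      edge_mid[[key]] <- id
      id
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  v <- v * radius
  storage.mode(f) <- "integer"
  structure(list(vertices = v, faces = f, normals = v / radius,
                 area = surface_area(v, f), radius = radius),
            class = "triangulated_surface")
}

surface_area <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  ab <- b - a
  ac <- cc - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  sum(vnorm(cr)) / 2
}

#' Euler characteristic of a triangulated surface
#'
#' \eqn{V - E + F}; 2 for sphere topology.
#'
#' @param surface a \code{triangulated_surface}.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(surface) {
  f <- surface$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- unique(t(apply(edges, 1, sort)))
  nrow(surface$vertices) - nrow(edges) + nrow(f)
}

#' Lipid composition
#'
#' Species list with mole fractions (summing to 1), the mean area per lipid,
#' and the bilayer thickness. The per-species bead templates come from
#' [lipid_templates()]; all tails are modeled fully saturated.
#'
#' @param species character vector of lipid species names (must match
#'   template names).
#' @param fractions mole fractions, summing to 1 within 1e-9.
#' @param area_per_lipid mean area per lipid (nm^2); 0.60 is a typical CG
#'   bilayer value.
#' @param thickness bilayer thickness (nm).
#' @return a \code{lipid_composition} object.
#' @export
lipid_composition <- function(species, fractions, area_per_lipid = 0.60,
                              thickness = 4) {
  fractions <- as.numeric(fractions)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    abort("mole fractions must be non-negative and sum to 1",
          "minicell_composition_error")
  }
  stopifnot(length(species) == length(fractions), area_per_lipid > 0,
            thickness > 0)
  structure(list(species = as.character(species), fractions = fractions,
                 area_per_lipid = area_per_lipid, thickness = thickness),
            class = "lipid_composition")
}

#' Idealized CG lipid templates
#'
#' Minimal bead stacks used to realize lipids in space: beads are listed
#' head-first along the local outward normal (offsets in nm from the head
#' bead, increasing toward the bilayer midplane). Cholesterol is shorter
#' and headgroup-light; cardiolipin carries two phosphatidyl charges,
#' phosphatidylglycerol one. Tails are fully saturated palmitoyl stand-ins.
#' Geometry only; energetics are out of scope.
#'
#' @return named list of data frames (\code{name}, \code{depth},
#'   \code{charge}).
#' @export
lipid_templates <- function() {
  stack <- function(names, depths, charges = 0L) {
    data.frame(name = names, depth = depths,
               charge = rep_len(as.integer(charges), length(names)),
               stringsAsFactors = FALSE)
  }
  list(
    CHOL = stack(c("ROH", "R1", "R2", "C1"), c(0, 0.45, 0.90, 1.35)),
    SM = stack(c("NC3", "PO4", "AM1", "C1A", "C2A", "C3A"),
               c(0, 0.3, 0.7, 1.1, 1.5, 1.9), c(1L, -1L, 0L, 0L, 0L, 0L)),
    CDL = stack(c("GL0", "PO41", "PO42", "C1A", "C2A", "C1B", "C2B"),
                c(0, 0.25, 0.25, 0.9, 1.5, 0.9, 1.5),
                c(0L, -1L, -1L, 0L, 0L, 0L, 0L)),
    PC = stack(c("NC3", "PO4", "GL1", "C1A", "C2A", "C3A"),
               c(0, 0.3, 0.7, 1.1, 1.5, 1.9), c(1L, -1L, 0L, 0L, 0L, 0L)),
    PG = stack(c("GL0", "PO4", "GL1", "C1A", "C2A", "C3A"),
               c(0, 0.3, 0.7, 1.1, 1.5, 1.9), c(0L, -1L, 0L, 0L, 0L, 0L))
  )
}

offset_surface <- function(surface, offset) {
  v <- surface$vertices + surface$normals * offset
  list(vertices = v, faces = surface$faces,
       area = surface_area(v, surface$faces))
}

#' Curvature-corrected per-leaflet lipid counts
#'
#' The two leaflets of a curved bilayer have different areas; the counts are
#' taken from the areas of the surfaces offset by half the bilayer thickness
#' along the outward normals: \code{n_outer = round(A(+t/2)/apl)},
#' \code{n_inner = round(A(-t/2)/apl)}.
#'
#' @param surface a [icosphere()]-style \code{triangulated_surface}.
#' @param comp a [lipid_composition()].
#' @return list with \code{n_outer}, \code{n_inner} and the two leaflet
#'   areas.
#' @export
leaflet_counts <- function(surface, comp) {
  t2 <- comp$thickness / 2
  if (!is.null(surface$radius) && t2 >= surface$radius) {
    abort("inward leaflet offset exceeds the local radius",
          "minicell_geometry_error")
  }
  outer <- offset_surface(surface, +t2)
  inner <- offset_surface(surface, -t2)
  if (inner$area <= 0) abort("inward offset surface degenerate",
                             "minicell_geometry_error")
  as_count <- function(x) {
    x <- round(x)
    if (x < .Machine$integer.max) as.integer(x) else x
  }
  list(n_outer = as_count(outer$area / comp$area_per_lipid),
       n_inner = as_count(inner$area / comp$area_per_lipid),
       area_outer = outer$area, area_inner = inner$area)
}

#' Largest-remainder species allocation
#'
#' Splits \code{n} placements over species so the integer counts sum to
#' exactly \code{n} while deviating from \code{n * fraction} by less than 1.
#'
#' @param n total count.
#' @param fractions mole fractions summing to 1.
#' @return integer vector of per-species counts.
#' @export
allocate_species <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0), abs(sum(fractions) - 1) < 1e-9)
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    give <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

# Uniform random points on the triangles of a surface (area-weighted).
sample_surface_points <- function(vertices, faces, n) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  ab <- b - a
  ac <- cc - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  w <- vnorm(cr) / 2
  tri <- sample.int(nrow(faces), n, replace = TRUE, prob = w)
  u <- runif(n)
  v <- runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]
  v[flip] <- 1 - v[flip]
  a[tri, , drop = FALSE] + ab[tri, , drop = FALSE] * u +
    ac[tri, , drop = FALSE] * v
}

#' Build a vesicle membrane from a triangulated surface
#'
#' Realizes a bilayer on a closed triangulated surface. Membrane proteins
#' are inserted first at random surface sites (random in-plane rotation,
#' long axis along the local normal), each claiming a cylindrical footprint
#' of its in-plane bounding radius plus a clearance. Lipid head sites are
#' then dart-thrown on each offset leaflet surface, area-weighted over the
#' triangles, at one site per \code{area_per_lipid}, with a minimum
#' head--head spacing and exclusion of protein footprints; species are
#' assigned randomly according to [allocate_species()] counts per leaflet,
#' and each lipid's beads run head-outward (outer leaflet) or head-inward
#' (inner leaflet) along the local normal.
#'
#' @param surface a closed \code{triangulated_surface}.
#' @param comp a [lipid_composition()].
#' @param proteins optional list of entries (\code{model}, \code{species_id},
#'   \code{copies}) of transmembrane proteins to embed.
#' @param seed RNG seed.
#' @param min_spacing_factor minimum head spacing as a multiple of
#'   \code{sqrt(area_per_lipid)}; must stay below the random-sequential
#'   jamming density for exact leaflet counts to be reachable.
#' @param footprint_clearance extra footprint radius around proteins (nm).
#' @param max_attempts_per_site dart throws allowed per lipid site.
#' @return a \code{membrane_model}: list with \code{lipids} (data frame:
#'   species, leaflet, head position), \code{lipid_beads} (a [bead_model()]
#'   of all lipid beads), \code{proteins} (placement data frame with bead
#'   attribute), and \code{counts}.
#' @export
build_membrane <- function(surface, comp, proteins = NULL, seed = NULL,
                           min_spacing_factor = 0.7,
                           footprint_clearance = 0.5,
                           max_attempts_per_site = 200L) {
  lc <- leaflet_counts(surface, comp)
  if (lc$n_outer < length(comp$species) || lc$n_inner < length(comp$species)) {
    abort("leaflet counts below species count", "minicell_composition_error")
  }
  tpls <- lipid_templates()
  missing_tpl <- setdiff(comp$species, names(tpls))
  if (length(missing_tpl) > 0) {
    abort(paste0("no lipid template for ", missing_tpl[1]),
          "minicell_composition_error")
  }
  min_spacing <- min_spacing_factor * sqrt(comp$area_per_lipid)
  t2 <- comp$thickness / 2
  with_seed(seed, {
    # --- proteins first ---
    prot_centers <- matrix(numeric(0), 0, 3)
    prot_radius <- numeric(0)
    prot_rows <- list()
    prot_beads <- matrix(numeric(0), 0, 3)
    prot_bead_owner <- integer(0)
    if (!is.null(proteins)) {
      rowi <- 0L
      for (b in proteins) {
        for (cp in seq_len(b$copies)) {
          rowi <- rowi + 1L
          foot <- b$model$bounding_radius + footprint_clearance
          placedp <- FALSE
          for (trial in seq_len(max_attempts_per_site)) {
            pt <- drop(sample_surface_points(surface$vertices,
                                             surface$faces, 1))
            if (nrow(prot_centers) > 0 &&
                  any(vnorm(sweep(prot_centers, 2, pt)) <
                        prot_radius + foot)) next
            nrm <- pt / sqrt(sum(pt^2))
            # orthonormal in-plane axes with a random in-plane rotation
            ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
            e1 <- ref - sum(ref * nrm) * nrm
            e1 <- e1 / sqrt(sum(e1^2))
            e2 <- crossp(nrm, e1)
            ang <- runif(1, 0, 2 * pi)
            a1 <- cos(ang) * e1 + sin(ang) * e2
            a2 <- -sin(ang) * e1 + cos(ang) * e2
            local <- sweep(b$model$coords, 2, colMeans(b$model$coords))
            coords <- local[, 1, drop = FALSE] %*% a1 +
              local[, 2, drop = FALSE] %*% a2 +
              local[, 3, drop = FALSE] %*% nrm
            coords <- sweep(coords, 2, pt, "+")
            prot_centers <- rbind(prot_centers, pt)
            prot_radius <- c(prot_radius, foot)
            prot_rows[[rowi]] <- data.frame(
              species_id = b$species_id, x = pt[1], y = pt[2], z = pt[3],
              nx = nrm[1], ny = nrm[2], nz = nrm[3], angle = ang,
              stringsAsFactors = FALSE)
            prot_beads <- rbind(prot_beads, coords)
            prot_bead_owner <- c(prot_bead_owner, rep(rowi, nrow(coords)))
            placedp <- TRUE
            break
          }
          if (!placedp) {
            abort("membrane surface full: protein footprints cannot fit",
                  "minicell_surface_full_error")
          }
        }
      }
    }
    # --- lipid head sites per leaflet by dart throwing ---
    throw_leaflet <- function(n_sites, offset) {
      off <- offset_surface(surface, offset)
      sites <- matrix(0, n_sites, 3)
      placed <- 0L
      budget <- max_attempts_per_site * max(n_sites, 1L)
      batch <- min(4096L, max(256L, n_sites))
      while (placed < n_sites && budget > 0L) {
        cand <- sample_surface_points(off$vertices, off$faces, batch)
        budget <- budget - batch
        # drop darts inside protein footprints (cylinders along the local
        # normal: compare lateral distance, not 3D, because darts live on
        # the offset leaflet surface)
        keep <- rep(TRUE, nrow(cand))
        for (k in seq_len(nrow(prot_centers))) {
          ctr <- prot_centers[k, ]
          nrm <- ctr / sqrt(sum(ctr^2))
          d <- sweep(cand, 2, ctr)
          along <- d %*% nrm
          lat2 <- rowSums(d^2) - along^2
          keep <- keep & lat2 >= prot_radius[k]^2
        }
        # drop darts too close to already accepted sites (one grid query)
        if (placed > 0L && any(keep)) {
          keep[keep] <- !grid_any_close(cand[keep, , drop = FALSE],
                                        sites[seq_len(placed), ,
                                              drop = FALSE], min_spacing)
        }
        surv <- cand[keep, , drop = FALSE]
        if (nrow(surv) == 0L) next
        # greedy in-batch conflict resolution: keep a dart unless an
        # earlier kept dart lies within the minimum spacing
        acc <- rep(TRUE, nrow(surv))
        pr <- grid_self_pairs(surv, min_spacing)
        if (nrow(pr) > 0L) {
          for (k in order(pr[, 2])) {
            if (acc[pr[k, 1]]) acc[pr[k, 2]] <- FALSE
          }
        }
        surv <- surv[acc, , drop = FALSE]
        take <- min(nrow(surv), n_sites - placed)
        if (take > 0L) {
          sites[placed + seq_len(take), ] <- surv[seq_len(take), ,
                                                  drop = FALSE]
          placed <- placed + take
        }
      }
      if (placed < n_sites) {
        abort(sprintf(
          "placed %d of %d lipid sites; lower the spacing or density",
          placed, n_sites), "minicell_surface_full_error")
      }
      sites
    }
    sites_out <- throw_leaflet(lc$n_outer, +t2)
    sites_in <- throw_leaflet(lc$n_inner, -t2)
    # --- species assignment ---
    assign_species <- function(n) {
      counts <- allocate_species(n, comp$fractions)
      sample(rep(comp$species, counts))
    }
    sp_out <- assign_species(lc$n_outer)
    sp_in <- assign_species(lc$n_inner)
    lipids <- data.frame(
      species = c(sp_out, sp_in),
      leaflet = rep(c("outer", "inner"), c(lc$n_outer, lc$n_inner)),
      x = c(sites_out[, 1], sites_in[, 1]),
      y = c(sites_out[, 2], sites_in[, 2]),
      z = c(sites_out[, 3], sites_in[, 3]),
      stringsAsFactors = FALSE)
    # --- realize beads: head at the site, tail toward the midplane ---
    head_pos <- as.matrix(lipids[c("x", "y", "z")])
    nrm <- normalize_rows(head_pos)
    inward <- ifelse(lipids$leaflet == "outer", -1, +1)
    nbeads_per <- vapply(tpls[lipids$species], nrow, 1L)
    total_beads <- sum(nbeads_per)
    coords <- matrix(0, total_beads, 3)
    nms <- character(total_beads)
    chg <- integer(total_beads)
    res <- character(total_beads)
    resid <- integer(total_beads)
    pos <- 0L
    for (sp in unique(lipids$species)) {
      tpl <- tpls[[sp]]
      rows_l <- which(lipids$species == sp)
      k <- nrow(tpl)
      ii <- pos + seq_len(k * length(rows_l))
      fi <- rep(rows_l, each = k)
      depth <- rep(tpl$depth, times = length(rows_l))
      coords[ii, ] <- head_pos[fi, ] + nrm[fi, ] * (inward[fi] * depth)
      nms[ii] <- rep(tpl$name, length(rows_l))
      chg[ii] <- rep(tpl$charge, length(rows_l))
      res[ii] <- sp
      resid[ii] <- fi
      pos <- pos + length(ii)
    }
    ord <- order(resid, seq_len(total_beads))
    lipid_beads <- bead_model(coords[ord, ], names = nms[ord],
                              charges = chg[ord], atom_equivalents = 9L,
                              resnames = res[ord])
    attr(lipid_beads, "lipid_index") <- resid[ord]
    prot_df <- if (length(prot_rows) > 0) do.call(rbind, prot_rows) else NULL
    if (!is.null(prot_df)) {
      attr(prot_df, "beads") <- prot_beads
      attr(prot_df, "bead_placement") <- prot_bead_owner
    }
    structure(list(
      lipids = lipids, lipid_beads = lipid_beads, proteins = prot_df,
      counts = list(n_outer = lc$n_outer, n_inner = lc$n_inner,
                    by_species = table(lipids$species))),
      class = "membrane_model")
  })
}

#' Write a triangulated surface as ASCII OFF
#'
#' @param surface a \code{triangulated_surface}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_off <- function(surface, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("OFF",
               sprintf("%d %d 0", nrow(surface$vertices),
                       nrow(surface$faces)),
               sprintf("%.6f %.6f %.6f", surface$vertices[, 1],
                       surface$vertices[, 2], surface$vertices[, 3]),
               sprintf("3 %d %d %d", surface$faces[, 1] - 1L,
                       surface$faces[, 2] - 1L, surface$faces[, 3] - 1L)),
             con, sep = "\n")
  invisible(path)
}

#' Read an ASCII OFF surface
#'
#' @param path OFF file path.
#' @return a \code{triangulated_surface} (radius taken as the mean vertex
#'   norm).
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF") abort("not an OFF file",
                                             "minicell_format_error")
  hd <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- hd[1]; nf <- hd[2]
  vv <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  ff <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nf)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4]) + 1L))
  structure(list(vertices = vv, faces = ff, normals = normalize_rows(vv),
                 area = surface_area(vv, ff),
                 radius = mean(vnorm(vv))),
            class = "triangulated_surface")
}
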