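## synthetic_structures: PDB fixtures with clusters planted at known
## geometry, plus the ground-truth tables the tests compare against.

## Canonical residue geometry (fixture conventions, configurable here):
## Met bond lengths 1.81 / 1.79 A with a 100 degree CG-SD-CE wedge;
## Phe/Tyr rings are regular hexagons of circumradius 1.39 A; the Trp
## indole is an idealized fused pentagon/hexagon with 1.40 A edges.

MET_CG_SD <- 1.81
MET_SD_CE <- 1.79
MET_WEDGE_DEG <- 100
RING_CIRCUMRADIUS <- 1.39
INDOLE_EDGE <- 1.40

#' Canonical methionine pose
#'
#' The CG-SD-CE scaffold in the canonical frame: SD at the origin, CE
#' on +x, CG in the x,y-plane with positive y, plus a CB stub.
#'
#' @return List of named 3-vectors `cb`, `cg`, `sd`, `ce`.
#' @export
canonical_met <- function() {
  w <- MET_WEDGE_DEG * pi / 180
  cg <- MET_CG_SD * c(cos(w), sin(w), 0)
  cb_dir <- c(cos(w + 40 * pi / 180), sin(w + 40 * pi / 180), 0)
  list(cb = cg + 1.53 * cb_dir, cg = cg, sd = c(0, 0, 0),
       ce = c(MET_SD_CE, 0, 0))
}

# Planar ring template centered on the ring-atom centroid; returns
# coords (n x 3, z = 0), atom names, and an in-plane CB stub.
ring_template <- function(resname) {
  if (resname %in% c("PHE", "TYR")) {
    ang <- pi / 2 + (0:5) * (pi / 3)
    coords <- RING_CIRCUMRADIUS * cbind(cos(ang), sin(ang), 0)
    names <- RING_ATOMS[[resname]]             # consecutive around the ring
  } else if (resname == "TRP") {
    s <- INDOLE_EDGE
    # shared CD2-CE2 bond along y; hexagon center at +x, pentagon at -x
    hex_c <- c(s * sqrt(3) / 2, 0)
    pen_c <- c(-s / (2 * tan(pi / 5)), 0)
    r5 <- s / (2 * sin(pi / 5))
    hex_at <- function(deg) c(hex_c + s * c(cos(deg * pi / 180),
                                            sin(deg * pi / 180)))
    pen_at <- function(deg) c(pen_c + r5 * c(cos(deg * pi / 180),
                                             sin(deg * pi / 180)))
    pts <- rbind(CG  = pen_at(-108), CD1 = pen_at(180), NE1 = pen_at(108),
                 CE2 = pen_at(36),   CD2 = pen_at(-36),
                 CE3 = hex_at(-90),  CZ3 = hex_at(-30), CH2 = hex_at(30),
                 CZ2 = hex_at(90))
    # pentagon and hexagon agree on the shared bond by construction
    pts["CE2", ] <- hex_at(150)
    pts["CD2", ] <- hex_at(210)
    coords <- cbind(pts, 0)
    names <- rownames(pts)
  } else stop("no ring template for ", resname)
  coords <- sweep(coords, 2L, colMeans(coords))
  rownames(coords) <- names
  cg <- coords[match("CG", names), ]
  cb <- cg * (1 + 1.5 / vnorm(cg))
  list(coords = coords, names = names, cb = cb)
}

sph_unit <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# Orthonormal basis whose third column is the ring normal.
ring_basis <- function(normal, spin) {
  n <- vunit(normal)
  ref <- if (abs(n[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- vunit(vcross(ref, n))
  e2 <- vcross(n, e1)
  cs <- cos(spin); sn <- sin(spin)
  cbind(e1 * cs + e2 * sn, -e1 * sn + e2 * cs, n)
}

random_rotation <- function() {
  q <- stats::rnorm(4L)
  quat_to_rotmat(q / vnorm(q))
}

# One of the 24 proper axis-permutation rotations: keeps the 0.001 A
# coordinate grid exact, so grid-aligned planted distances survive the
# fixed-column file format unchanged.
grid_rotation <- function() {
  repeat {
    perm <- sample(3L)
    signs <- sample(c(-1, 1), 3L, replace = TRUE)
    R <- matrix(0, 3L, 3L)
    for (i in 1:3) R[i, perm[i]] <- signs[i]
    if (abs(det(R) - 1) < 1e-9) return(R)
  }
}

aromatic_atoms_at <- function(resname, centroid, normal, spin,
                              resno, chain, b) {
  tpl <- ring_template(resname)
  B <- ring_basis(normal, spin)
  ring <- sweep(tpl$coords %*% t(B), 2L, centroid, `+`)
  cb <- centroid + as.numeric(B %*% tpl$cb)
  atoms <- rbind(ring, CB = cb)
  data.frame(record = "ATOM", atom_name = rownames(atoms),
             alt_loc = "", residue_name = resname, chain_id = chain,
             residue_number = resno, insertion_code = "",
             x = atoms[, 1L], y = atoms[, 2L], z = atoms[, 3L],
             occupancy = 1, b_factor = b,
             element = ifelse(substr(rownames(atoms), 1L, 1L) == "N", "N", "C"),
             stringsAsFactors = FALSE)
}

met_atoms_at <- function(resno, chain, b, mse = FALSE) {
  m <- canonical_met()
  nm <- c("CB", "CG", if (mse) "SE" else "SD", "CE")
  xyz <- rbind(m$cb, m$cg, m$sd, m$ce)
  data.frame(record = if (mse) "HETATM" else "ATOM", atom_name = nm,
             alt_loc = "", residue_name = if (mse) "MSE" else "MET",
             chain_id = chain, residue_number = resno, insertion_code = "",
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             occupancy = 1, b_factor = b,
             element = c("C", "C", if (mse) "SE" else "S", "C"),
             stringsAsFactors = FALSE)
}

decoy_atoms_at <- function(center, resno, chain, b) {
  offs <- rbind(N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.3, 0.6, 0),
                O = c(1.6, 1.7, 0.4), CB = c(-0.4, -1.0, 1.0))
  data.frame(record = "ATOM", atom_name = rownames(offs),
             alt_loc = "", residue_name = "ALA", chain_id = chain,
             residue_number = resno, insertion_code = "",
             x = center[1L] + offs[, 1L], y = center[2L] + offs[, 2L],
             z = center[3L] + offs[, 3L], occupancy = 1, b_factor = b,
             element = substr(rownames(offs), 1L, 1L),
             stringsAsFactors = FALSE)
}

format_pdb_atom <- function(a, serial) {
  name4 <- if (nchar(a$atom_name) >= 4L) a$atom_name
           else sprintf("%-4s", paste0(" ", a$atom_name))
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, serial, name4,
          ifelse(nzchar(a$alt_loc), a$alt_loc, " "),
          a$residue_name, a$chain_id, a$residue_number,
          ifelse(nzchar(a$insertion_code), a$insertion_code, " "),
          a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
}

#' Write a fixture atom table as a fixed-column PDB file
#'
#' @param atoms Atom data frame as built by the `*_atoms_at` helpers.
#' @param path Output path.
#' @param structure_id Four-character identifier for the HEADER record
#'   (longer identifiers are carried by the file name instead).
#' @param ec_label Optional EC annotation for a COMPND record.
#' @param resolution Optional resolution for a REMARK 2 record.
#' @param model2_offset Optional 3-vector; when given, a second MODEL
#'   is emitted with all atoms translated by it (multi-model defect
#'   fixture).
#' @return The path, invisibly.
#' @export
write_structure_file <- function(atoms, path, structure_id = "XXXX",
                                 ec_label = NULL, resolution = NULL,
                                 model2_offset = NULL) {
  id4 <- if (nchar(structure_id) == 4L) toupper(structure_id) else "    "
  lines <- sprintf("HEADER    %-40s%9s   %4s", "SYNTHETIC FIXTURE",
                   "01-JAN-26", id4)
  lines <- c(lines, "COMPND    MOL_ID: 1;")
  if (!is.null(ec_label) && !is.na(ec_label))
    lines <- c(lines, sprintf("COMPND   2 EC: %s;", ec_label))
  if (!is.null(resolution) && !is.na(resolution))
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                              resolution))
  body <- vapply(seq_len(nrow(atoms)), function(i)
    format_pdb_atom(atoms[i, ], i), character(1L))
  if (is.null(model2_offset)) {
    lines <- c(lines, body)
  } else {
    shifted <- atoms
    shifted$x <- shifted$x + model2_offset[1L]
    shifted$y <- shifted$y + model2_offset[2L]
    shifted$z <- shifted$z + model2_offset[3L]
    body2 <- vapply(seq_len(nrow(shifted)), function(i)
      format_pdb_atom(shifted[i, ], i), character(1L))
    lines <- c(lines, "MODEL        1", body, "ENDMDL",
               "MODEL        2", body2, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build one synthetic structure with planted geometry
#'
#' Places a canonical methionine, aromatic partners at requested
#' SD-to-centroid spherical coordinates (in the canonical Met frame:
#' `theta` is the polar angle from +z, `phi` the azimuth from +x, in
#' degrees), and non-aromatic decoy residues, applies a seeded rigid
#' motion, and writes a fixed-column PDB file.
#'
#' Partner ring atoms are snapped so that, after the 0.001 A column
#' precision of the file format, the realized SD-centroid distance
#' matches the request to about 1e-4 A (exactly, for grid poses with
#' axis-aligned placements). The returned truth table stores the
#' achieved distances and canonical-frame centroid coordinates
#' recomputed from the file as written.
#'
#' @param path Output PDB path.
#' @param partners Data frame with columns `resname` (PHE/TYR/TRP),
#'   `r`, `theta`, `phi`. May have zero rows.
#' @param n_decoys Number of ALA decoy residues.
#' @param decoy_min_dist Exclusion radius (A) of decoys around SD and
#'   every planted centroid.
#' @param b_met,b_partners,b_decoys Per-residue B-factor plan
#'   (`b_partners` recycles over partners).
#' @param ec_label Optional EC string for the header.
#' @param resolution Header resolution (A).
#' @param seed Optional integer; the generator then uses its own RNG
#'   stream and leaves the caller's untouched.
#' @param pose `"random"` (arbitrary rigid motion), `"grid"`
#'   (axis-permutation rotation plus grid translation; preserves
#'   grid-aligned distances exactly), or `"none"`.
#' @param structure_id Identifier; defaults from the file name.
#' @param defect Optional planted parser challenge: `"altloc_sd"`,
#'   `"missing_ring_atom"`, `"mse"`, or `"multimodel"`.
#' @param chain Chain identifier.
#' @param met_number Residue number of the methionine.
#' @return Invisibly, a list with `path`, `truth` (one-row structure
#'   summary) and `partners` (per-partner achieved geometry).
#' @export
build_structure <- function(path, partners = data.frame(),
                            n_decoys = 3, decoy_min_dist = 9,
                            b_met = 20, b_partners = 18, b_decoys = 30,
                            ec_label = NULL, resolution = 2.0,
                            seed = NULL,
                            pose = c("random", "grid", "none"),
                            structure_id = NULL, defect = NULL,
                            chain = "A", met_number = 1L) {
  pose <- match.arg(pose)
  if (!is.null(defect))
    defect <- match.arg(defect, c("altloc_sd", "missing_ring_atom",
                                  "mse", "multimodel"))
  if (is.null(structure_id)) structure_id <- basename_id(path)
  n_partners <- nrow(partners)
  b_partners <- rep_len(b_partners, max(1L, n_partners))

  with_seed(seed, {
    ## rigid motion
    R <- switch(pose,
                none = diag(3),
                grid = grid_rotation(),
                random = random_rotation())
    tr <- switch(pose,
                 none = c(0, 0, 0),
                 grid = round(stats::runif(3L, -15, 15), 3L),
                 random = stats::runif(3L, -15, 15))
    place <- function(p) as.numeric(R %*% p) + tr

    mse <- identical(defect, "mse")
    met <- met_atoms_at(met_number, chain, b_met, mse = mse)
    met[, c("x", "y", "z")] <-
      round(t(apply(met[, c("x", "y", "z")], 1L, place)), 3L)
    sd_grid <- as.numeric(met[met$atom_name %in% c("SD", "SE"),
                              c("x", "y", "z")])

    atoms <- met
    partner_rows <- list()
    planted_centroids <- list()
    for (i in seq_len(n_partners)) {
      resname <- toupper(partners$resname[i])
      r <- partners$r[i]
      u0 <- sph_unit(partners$theta[i], partners$phi[i])
      u <- as.numeric(R %*% u0)
      target <- sd_grid + r * u
      normal <- vunit(stats::rnorm(3L))
      spin <- stats::runif(1L, 0, 2 * pi)
      resno <- 100L + i
      ar <- aromatic_atoms_at(resname, target, normal, spin, resno, chain,
                              b_partners[i])
      is_ring <- ar$atom_name %in% RING_ATOMS[[resname]]
      xyz <- as.matrix(ar[, c("x", "y", "z")])
      # recenter the ring on the target, round to the file grid, then
      # absorb the residual into the last ring atom so the rounded
      # ring centroid lands as close to the target as the grid allows
      xyz[is_ring, ] <- sweep(xyz[is_ring, , drop = FALSE], 2L,
                              target - colMeans(xyz[is_ring, , drop = FALSE]),
                              `+`)
      xyz <- round(xyz, 3L)
      ring_idx <- which(is_ring)
      nr <- length(ring_idx)
      last <- ring_idx[nr]
      xyz[last, ] <- round(nr * target, 3L) -
        colSums(xyz[ring_idx[-nr], , drop = FALSE])
      ar[, c("x", "y", "z")] <- xyz

      if (identical(defect, "missing_ring_atom") && i == 1L) {
        drop_atom <- if (resname == "TRP") "CH2" else "CZ"
        ar <- ar[ar$atom_name != drop_atom, , drop = FALSE]
      }

      achieved <- colMeans(xyz[ring_idx, , drop = FALSE])
      planted_centroids[[i]] <- achieved
      partner_rows[[i]] <- data.frame(
        structure_id = structure_id, residue_number = resno,
        resname = resname, r_planted = r,
        r_achieved = vnorm(achieved - sd_grid),
        theta = partners$theta[i], phi = partners$phi[i],
        stringsAsFactors = FALSE)
      atoms <- rbind(atoms, ar)
    }

    ## decoys: anywhere outside the exclusion radius of SD and centroids
    resno <- 200L
    for (k in seq_len(n_decoys)) {
      placed <- FALSE
      for (try in 1:200) {
        dir <- vunit(stats::rnorm(3L))
        center <- sd_grid + stats::runif(1L, decoy_min_dist,
                                         decoy_min_dist + 5) * dir
        clear <- vnorm(center - sd_grid) >= decoy_min_dist &&
          all(vapply(planted_centroids, function(cc)
            vnorm(center - cc) >= decoy_min_dist, logical(1L)))
        if (clear) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place decoy residue outside the ",
                        "exclusion radius")
      dc <- decoy_atoms_at(center, resno, chain, b_decoys)
      dc[, c("x", "y", "z")] <- round(dc[, c("x", "y", "z")], 3L)
      atoms <- rbind(atoms, dc)
      resno <- resno + 1L
    }

    if (identical(defect, "altloc_sd")) {
      sd_row <- which(atoms$atom_name %in% c("SD", "SE"))[1L]
      alt_b <- atoms[sd_row, ]
      atoms$alt_loc[sd_row] <- "A"
      atoms$occupancy[sd_row] <- 0.7
      alt_b$alt_loc <- "B"
      alt_b$occupancy <- 0.3
      alt_b$x <- alt_b$x + 0.35
      atoms <- rbind(atoms[seq_len(sd_row), ], alt_b,
                     atoms[-seq_len(sd_row), ])
    }

    write_structure_file(
      atoms, path, structure_id = structure_id, ec_label = ec_label,
      resolution = resolution,
      model2_offset = if (identical(defect, "multimodel")) c(25, 0, 0))

    ## truth: achieved local-frame coordinates recomputed from the
    ## rounded coordinates as written
    partner_df <- if (length(partner_rows)) do.call(rbind, partner_rows)
      else data.frame(structure_id = character(), residue_number = integer(),
                      resname = character(), r_planted = numeric(),
                      r_achieved = numeric(), theta = numeric(),
                      phi = numeric(), stringsAsFactors = FALSE)
    if (n_partners > 0L) {
      met_site <- list(
        ref = list(chain_id = chain, residue_number = met_number,
                   insertion_code = NA_character_,
                   residue_name = if (mse) "MSE" else "MET"),
        cg = as.numeric(atoms[match("CG", atoms$atom_name), c("x", "y", "z")]),
        sd = sd_grid,
        ce = as.numeric(atoms[match("CE", atoms$atom_name), c("x", "y", "z")]),
        structure_id = structure_id)
      class(met_site) <- "MetSite"
      tf <- met_frame_transform(met_site)
      local <- apply_frame(tf, do.call(rbind, planted_centroids))
      partner_df$local_x <- local[, 1L]
      partner_df$local_y <- local[, 2L]
      partner_df$local_z <- local[, 3L]
    } else {
      partner_df$local_x <- partner_df$local_y <- partner_df$local_z <-
        numeric(0L)
    }

    truth <- data.frame(
      structure_id = structure_id,
      file = path,
      n_partners = n_partners,
      planted_cluster = n_partners >= 3L,
      composition = if (n_partners >= 3L)
        paste(sort(toupper(partners$resname)), collapse = "-")
        else NA_character_,
      met_chain = chain, met_number = met_number,
      ec_label = if (is.null(ec_label)) NA_character_ else ec_label,
      stringsAsFactors = FALSE)

    invisible(list(path = path, truth = truth, partners = partner_df))
  })
}

# Largest-remainder allocation of `total` among proportions `p`.
allocate_counts <- function(p, total) {
  p <- p / sum(p)
  raw <- p * total
  counts <- floor(raw)
  rem <- total - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

default_composition_mix <- function() {
  # Phe-heavy mix mirroring the relative background frequencies of the
  # three aromatics (Phe > Tyr > Trp)
  c("PHE-PHE-PHE" = 0.20, "PHE-PHE-TYR" = 0.20, "PHE-TYR-TYR" = 0.15,
    "PHE-PHE-TRP" = 0.15, "PHE-TRP-TYR" = 0.10, "TYR-TYR-TYR" = 0.08,
    "PHE-TRP-TRP" = 0.05, "TRP-TYR-TYR" = 0.04, "TRP-TRP-TYR" = 0.02,
    "TRP-TRP-TRP" = 0.01)
}

#' Build a synthetic survey set
#'
#' Writes `n_structures` fixture files of which exactly
#' `round(n_structures * planting_rate)` contain a planted 3-bridge
#' cluster (deterministic allocation, not Bernoulli draws, so small
#' surveys hit the rate exactly). Non-planted structures carry 0-2
#' in-range aromatic partners (cycling deterministically) plus
#' out-of-range aromatics and decoys, so bridge orders below 3 are
#' exercised without creating accidental 3-bridges. Cluster
#' compositions follow `composition_mix` by largest-remainder
#' allocation. EC labels cycle over a fixed set with some structures
#' left unannotated.
#'
#' Same seed, same arguments: byte-identical file sets.
#'
#' @param dir Output directory (created if needed).
#' @param n_structures Number of structures.
#' @param planting_rate Fraction with a planted cluster, in `[0, 1]`.
#' @param composition_mix Named proportions over [composition_keys()];
#'   default is a Phe-heavy mix.
#' @param seed Integer seed (required; the contract is
#'   reproducibility).
#' @param n_decoys,decoy_min_dist Passed to [build_structure()].
#' @return Invisibly, a list with `dir`, `truth` (structure-level
#'   table, also written as `truth_table.csv`), `partners`
#'   (partner-level table) and `files`. Generation parameters are
#'   echoed to `generation_params.json`.
#' @export
build_survey <- function(dir, n_structures = 200, planting_rate = 0.12,
                         composition_mix = NULL, seed = 1,
                         n_decoys = 2, decoy_min_dist = 9) {
  stopifnot(planting_rate >= 0, planting_rate <= 1, n_structures >= 1)
  if (is.null(composition_mix)) composition_mix <- default_composition_mix()
  bad <- setdiff(names(composition_mix), composition_keys())
  if (length(bad)) stop("unknown composition key(s): ",
                        paste(bad, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  n_planted <- round(n_structures * planting_rate)
  ec_cycle <- c("1.11.1.5", "2.7.7.7", "3.2.1.14", NA, "3.1.1.1",
                "4.2.1.1", NA, "5.3.1.9", "6.3.2.1", NA)

  with_seed(seed, {
    planted_idx <- sort(sample.int(n_structures, n_planted))
    comp_counts <- allocate_counts(composition_mix, n_planted)
    comp_assign <- rep(names(composition_mix), comp_counts)

    truth_rows <- list(); partner_rows <- list(); files <- character()
    near_cycle <- c(0L, 1L, 2L)
    ci <- 0L
    for (i in seq_len(n_structures)) {
      id <- sprintf("S%04d", i)
      path <- file.path(dir, paste0(id, ".pdb"))
      planted <- i %in% planted_idx
      if (planted) {
        ci <- ci + 1L
        resnames <- strsplit(comp_assign[ci], "-")[[1L]]
        partners <- data.frame(
          resname = resnames,
          r = stats::runif(3L, 3.5, 5.0),
          theta = stats::runif(3L, 25, 155),
          phi = stats::runif(3L, 0, 360),
          stringsAsFactors = FALSE)
      } else {
        k <- near_cycle[(i %% 3L) + 1L]
        k_far <- 1L + (i %% 2L)
        partners <- data.frame(
          resname = sample(AROMATIC_RESNAMES, k + k_far, replace = TRUE),
          r = c(if (k > 0) stats::runif(k, 3.5, 5.0),
                stats::runif(k_far, 9.5, 12)),
          theta = stats::runif(k + k_far, 25, 155),
          phi = stats::runif(k + k_far, 0, 360),
          stringsAsFactors = FALSE)
      }
      out <- build_structure(
        path, partners = partners, n_decoys = n_decoys,
        decoy_min_dist = decoy_min_dist,
        ec_label = ec_cycle[(i %% length(ec_cycle)) + 1L],
        pose = "random", structure_id = id)
      tr <- out$truth
      # in-range partner count is the survey-level ground truth
      tr$n_partners_in_range <- sum(out$partners$r_planted <= 6.0)
      tr$planted_cluster <- tr$n_partners_in_range >= 3L
      truth_rows[[i]] <- tr
      partner_rows[[i]] <- out$partners
      files <- c(files, path)
    }
    truth <- do.call(rbind, truth_rows)
    partner_tab <- do.call(rbind, partner_rows)
    utils::write.csv(truth, file.path(dir, "truth_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_structures = n_structures, planting_rate = planting_rate,
           n_planted = n_planted, seed = seed,
           composition_mix = as.list(composition_mix)),
      file.path(dir, "generation_params.json"), auto_unbox = TRUE,
      digits = NA)
    invisible(list(dir = dir, truth = truth, partners = partner_tab,
                   files = files))
  })
}
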