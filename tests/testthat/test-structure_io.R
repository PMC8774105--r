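test_that("fixture files round-trip through the parser", {
  d <- withr::local_tempdir()
  p <- file.path(d, "RT01.pdb")
  out <- build_structure(p, partners = data.frame(
    resname = c("PHE", "TYR", "TRP"), r = c(4, 4.5, 5),
    theta = c(60, 100, 140), phi = c(10, 130, 250)),
    n_decoys = 3, seed = 5, pose = "random", ec_label = "1.2.3.4")

  n_atom_lines <- sum(grepl("^(ATOM|HETATM)", readLines(p)))
  model <- parse_structure(p)
  expect_s3_class(model, "StructureModel")
  expect_equal(nrow(model$atoms), n_atom_lines)
  expect_equal(model$ec_numbers, "1.2.3.4")
  expect_equal(model$resolution, 2.0)

  # coordinates and B-factors survive the fixed-column format
  mets <- extract_met_sites(model)
  expect_length(mets, 1L)
  written <- readLines(p)
  sd_line <- written[grepl("^ATOM.* SD ", written)]
  sd_planted <- as.numeric(c(substr(sd_line, 31, 38), substr(sd_line, 39, 46),
                             substr(sd_line, 47, 54)))
  expect_equal(mets[[1]]$sd, sd_planted, tolerance = 1e-9)
  expect_true(all(abs(model$atoms$b_factor -
                        round(model$atoms$b_factor, 2)) < 1e-9))
})

test_that("highest-occupancy altloc wins, with a warning", {
  d <- withr::local_tempdir()
  p <- file.path(d, "ALT1.pdb")
  build_structure(p, partners = data.frame(resname = "PHE", r = 4.5,
                                           theta = 45, phi = 45),
                  seed = 9, pose = "none", defect = "altloc_sd")
  expect_warning(model <- parse_structure(p), "alternate locations")
  sd_rows <- model$atoms[model$atoms$atom_name == "SD", ]
  expect_equal(nrow(sd_rows), 1L)
  expect_equal(sd_rows$occupancy, 0.7)
  # pose "none": the kept conformer is the true SD at the origin
  expect_equal(c(sd_rows$x, sd_rows$y, sd_rows$z), c(0, 0, 0))
})

test_that("selenomethionine is opt-in", {
  d <- withr::local_tempdir()
  p <- file.path(d, "MSE1.pdb")
  build_structure(p, partners = data.frame(resname = "TYR", r = 4.5,
                                           theta = 45, phi = 45),
                  seed = 9, pose = "random", defect = "mse")
  model <- parse_structure(p)
  expect_length(extract_met_sites(model, include_mse = FALSE), 0L)
  mse <- extract_met_sites(model, include_mse = TRUE)
  expect_length(mse, 1L)
  expect_equal(mse[[1]]$ref$residue_name, "MSE")
  # SE stands in for SD
  expect_true(all(is.finite(mse[[1]]$sd)))
})

test_that("incomplete residues are skipped with a warning", {
  d <- withr::local_tempdir()
  p <- file.path(d, "DEF1.pdb")
  build_structure(p, partners = data.frame(resname = c("TYR", "PHE"),
                                           r = c(4.5, 5), theta = c(45, 90),
                                           phi = c(45, 180)),
                  seed = 9, pose = "random", defect = "missing_ring_atom")
  model <- parse_structure(p)
  expect_warning(sites <- extract_aromatic_sites(model), "missing ring atom")
  expect_length(sites, 1L)
  expect_equal(sites[[1]]$resname, "PHE")

  # Met missing CE
  lines <- readLines(p)
  writeLines(lines[!grepl("^ATOM.* CE ", lines)], p)
  expect_warning(mets <- extract_met_sites(parse_structure(p)), "missing CE")
  expect_length(mets, 0L)
})

test_that("only the first model of a multi-model file is used", {
  d <- withr::local_tempdir()
  p <- file.path(d, "MM01.pdb")
  build_structure(p, partners = data.frame(resname = "PHE", r = 4.5,
                                           theta = 45, phi = 45),
                  seed = 9, pose = "none", defect = "multimodel",
                  n_decoys = 0)
  model <- parse_structure(p)
  single <- sum(grepl("^(ATOM|HETATM)", readLines(p))) / 2L
  expect_equal(nrow(model$atoms), single)
  # model 1 geometry, not the shifted second model
  expect_equal(extract_met_sites(model)[[1]]$sd, c(0, 0, 0))
})

test_that("empty and non-protein files give empty models", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "EMP1.pdb")
  writeLines(c("HEADER    EMPTY", "END"), p1)
  expect_warning(m1 <- parse_structure(p1), "no atoms")
  expect_equal(nrow(m1$atoms), 0L)

  p2 <- file.path(d, "WAT1.pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00 30.00           O",
    "END"), p2)
  m2 <- parse_structure(p2)
  expect_length(extract_met_sites(m2), 0L)
  expect_length(extract_aromatic_sites(m2), 0L)
})

test_that("extraction is invariant to atom order within a residue", {
  d <- withr::local_tempdir()
  p <- file.path(d, "ORD1.pdb")
  build_structure(p, partners = data.frame(resname = "TRP", r = 4.5,
                                           theta = 60, phi = 30),
                  n_decoys = 0, seed = 3, pose = "random")
  lines <- readLines(p)
  atom_idx <- grep("^ATOM", lines)
  shuffled <- lines
  shuffled[atom_idx] <- lines[rev(atom_idx)]
  p2 <- file.path(d, "ORD2.pdb")
  writeLines(shuffled, p2)

  s1 <- extract_aromatic_sites(parse_structure(p))[[1]]
  s2 <- extract_aromatic_sites(parse_structure(p2))[[1]]
  expect_equal(s1$centroid, s2$centroid)
  expect_equal(s1$ring_atoms, s2$ring_atoms)
})

test_that("ring centroids and midpoints follow the ring definitions", {
  # ideal hexagonal Phe ring centered at (3, -2, 7)
  phe <- aromatic_site_at("PHE", centroid = c(3, -2, 7))
  expect_equal(unname(phe$centroid), c(3, -2, 7), tolerance = 1e-9)
  expect_equal(nrow(phe$midpoints), 6L)

  trp <- aromatic_site_at("TRP", centroid = c(-1, 2, 5))
  expect_equal(unname(trp$centroid),
               unname(colMeans(trp$ring_atoms)), tolerance = 1e-12)
  expect_equal(nrow(trp$ring_atoms), 9L)
  expect_equal(nrow(trp$midpoints), 10L)  # fused bicycle, shared bond once

  # hexagon-only Trp centroid option
  atoms <- metbridge:::aromatic_atoms_at("TRP", c(0, 0, 5), c(0, 0, 1), 0,
                                         50L, "A", 15)
  hexa <- extract_aromatic_sites(model_from_atoms(atoms),
                                 trp_centroid = "hexagon")[[1]]
  hex_names <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  expect_equal(unname(hexa$centroid),
               unname(colMeans(hexa$ring_atoms[hex_names, ])),
               tolerance = 1e-12)
})

test_that("mmCIF files parse with model selection, altlocs and headers", {
  expect_warning(
    model <- parse_structure(test_path("fixtures", "synthetic_site.cif")),
    "alternate locations")
  expect_equal(model$structure_id, "SYN1")
  expect_equal(model$ec_numbers, "3.2.1.14")
  expect_equal(model$resolution, 1.85)
  # model 1 only; SD altloc pair resolved to occupancy 0.6
  expect_equal(nrow(model$atoms), 9L)
  sd <- model$atoms[model$atoms$atom_name == "SD", ]
  expect_equal(nrow(sd), 1L)
  expect_equal(sd$occupancy, 0.6)
  expect_equal(sd$x, 0)

  mets <- extract_met_sites(model)
  aros <- extract_aromatic_sites(model)
  expect_length(mets, 1L)
  expect_length(aros, 1L)
  expect_equal(unname(aros[[1]]$centroid), c(0, 0, 4.5), tolerance = 1e-9)
  pc <- met_aromatic_pairs(mets, aros,
                           detection_config(distance_metric = "sd_to_centroid"))
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$centroid_distance, 4.5, tolerance = 1e-9)
})

test_that("ID lists are de-duplicated, case-normalized and comment-proof", {
  f <- withr::local_tempfile(lines = c("2CYP", "5VWS", "2cyp", "",
                                       "# a comment", "1a4e  # trailing"))
  expect_equal(read_id_list(f), c("2CYP", "5VWS", "1A4E"))
  empty <- withr::local_tempfile(lines = c("", "# nothing"))
  expect_warning(ids <- read_id_list(empty), "empty")
  expect_length(ids, 0L)
})
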