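test_that("composition tallies cover all ten multisets and conserve totals", {
  empty <- composition_tally(list())
  expect_length(empty, 10L)
  expect_true(all(empty == 0L))
  expect_setequal(names(empty), composition_keys())

  clusters <- c(
    replicate(2, fake_cluster(c("PHE", "PHE", "TRP")), simplify = FALSE),
    replicate(3, fake_cluster(c("TYR", "TYR", "TYR")), simplify = FALSE))
  tally <- composition_tally(clusters)
  expect_equal(unname(tally["PHE-PHE-TRP"]), 2L)
  expect_equal(unname(tally["TYR-TYR-TYR"]), 3L)
  expect_equal(sum(tally), 5L)

  expect_error(composition_tally(list(fake_cluster(c("PHE", "TYR")))),
               "size >= 3")
})

test_that("oversize clusters tally by their three nearest partners", {
  big <- fake_cluster(c("TRP", "PHE", "PHE", "TYR"),
                      distances = c(5.5, 3.1, 3.9, 4.2))
  tally <- composition_tally(list(big))
  expect_equal(unname(tally["PHE-PHE-TYR"]), 1L)  # the Trp is farthest
  expect_equal(sum(tally), 1L)
  expect_equal(sum(composition_tally(list(big), oversize = "skip")), 0L)
})

test_that("EC classes tally over cluster-bearing structures", {
  ids <- sprintf("M%02d", 1:10)
  ecs <- c(rep(list("3.2.1.14"), 4), rep(list(character()), 3),
           rep(list("1.11.1.5"), 3))
  models <- Map(fake_model_with_ec, ids, ecs)
  clusters <- lapply(ids, function(id) fake_cluster(c("PHE", "PHE", "PHE"),
                                                    structure_id = id))
  tab <- ec_class_tally(models, clusters)
  expect_equal(tab$count[tab$class == "EC3"], 4L)
  expect_equal(tab$count[tab$class == "EC1"], 3L)
  expect_equal(tab$count[tab$class == "unclassified"], 3L)
  expect_equal(tab$percentage[tab$class == "EC3"], 40)
  expect_equal(sum(tab$percentage), 100, tolerance = 1e-9)

  # malformed EC strings are warned about and counted as unclassified
  bad <- fake_model_with_ec("MXX", "enzyme?")
  cl <- list(fake_cluster(c("PHE", "PHE", "PHE"), structure_id = "MXX"))
  expect_warning(tab2 <- ec_class_tally(list(bad), cl), "malformed")
  expect_equal(tab2$count[tab2$class == "unclassified"], 1L)

  # per-cluster weighting counts multi-cluster structures repeatedly
  two <- c(clusters[1], list(fake_cluster(c("TRP", "TRP", "TRP"),
                                          structure_id = ids[1])))
  tabc <- ec_class_tally(models[1], two, per = "cluster")
  expect_equal(tabc$count[tabc$class == "EC3"], 2L)
})

test_that("distance histograms use half-open left-closed bins", {
  h <- distance_histogram(3.7, bin_width = 1)
  expect_equal(h$count[h$lower == 3], 1L)
  expect_equal(sum(h$count), 1L)

  h2 <- distance_histogram(c(2.5, 2.5, 5.9), bin_width = 1)
  expect_equal(h2$count[h2$lower == 2], 2L)
  expect_equal(h2$count[h2$lower == 5], 1L)
  expect_equal(sum(h2$count), 3L)

  # boundary values fall in the bin they open
  h3 <- distance_histogram(c(2.0, 3.0), bin_width = 1, upper = 6)
  expect_equal(h3$count[h3$lower == 2], 1L)
  expect_equal(h3$count[h3$lower == 3], 1L)

  set.seed(5)
  x <- runif(500, 0, 6)
  expect_equal(sum(distance_histogram(x, bin_width = 0.5)$count), 500L)
})

test_that("B-factor context ranks the cluster within the protein", {
  d <- withr::local_tempdir()
  p <- file.path(d, "BF01.pdb")
  build_structure(p, partners = data.frame(
    resname = c("PHE", "TYR", "TRP"), r = c(4, 4.5, 5),
    theta = c(60, 100, 140), phi = c(10, 130, 250)),
    n_decoys = 0, seed = 23, pose = "random",
    b_met = 20, b_partners = 20)
  model <- parse_structure(p)
  mets <- extract_met_sites(model); aros <- extract_aromatic_sites(model)
  pc <- met_aromatic_pairs(mets, aros, detection_config())
  cl <- find_n_bridges(pc, mets, aros, n = 3)[[1]]

  # uniform B: cluster mean equals protein mean, midrank percentile 50
  ctx <- bfactor_context(cl, model)
  expect_equal(ctx$mean_b_cluster, 20)
  expect_equal(ctx$mean_b_protein, 20)
  expect_equal(ctx$percentile_of_cluster_mean, 50)
  expect_false(ctx$uninformative)

  # cold cluster in a hot protein ranks low
  d2 <- withr::local_tempdir()
  p2 <- file.path(d2, "BF02.pdb")
  build_structure(p2, partners = data.frame(
    resname = c("PHE", "TYR", "TRP"), r = c(4, 4.5, 5),
    theta = c(60, 100, 140), phi = c(10, 130, 250)),
    n_decoys = 90, decoy_min_dist = 8, seed = 23, pose = "random",
    b_met = 10, b_partners = 10, b_decoys = 50)
  model2 <- parse_structure(p2)
  mets2 <- extract_met_sites(model2); aros2 <- extract_aromatic_sites(model2)
  cl2 <- find_n_bridges(met_aromatic_pairs(mets2, aros2, detection_config()),
                        mets2, aros2, n = 3)[[1]]
  # ALA decoys carry B = 50 but only protein residues enter the rank
  ctx2 <- bfactor_context(cl2, model2)
  expect_equal(ctx2$mean_b_cluster, 10)
  expect_lt(ctx2$percentile_of_cluster_mean, 5)

  # percentile is invariant to affine rescaling of the B column
  model3 <- model2
  model3$atoms$b_factor <- 3 * model3$atoms$b_factor + 7
  cl3 <- cl2
  ctx3 <- bfactor_context(cl3, model3)
  expect_equal(ctx3$percentile_of_cluster_mean,
               ctx2$percentile_of_cluster_mean, tolerance = 1e-9)

  # all-zero B column is flagged uninformative
  model4 <- model2
  model4$atoms$b_factor <- 0
  expect_true(bfactor_context(cl2, model4)$uninformative)
})

test_that("survey aggregation is deterministic and order-independent", {
  d <- withr::local_tempdir()
  sv <- build_survey(d, n_structures = 12, planting_rate = 0.25, seed = 41)
  expect_equal(sum(sv$truth$planted_cluster), 3L)

  r1 <- survey_run(d)
  r2 <- survey_run(d)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$cluster_table, r2$cluster_table)

  ids <- sv$truth$structure_id
  r3 <- survey_run(d, ids = rev(ids))
  expect_identical(r1$summary, r3$summary)

  expect_equal(r1$summary$n_structures_scanned, 12L)
  expect_equal(r1$summary$n_structures_with_cluster, 3L)
  expect_equal(r1$summary$fraction_with_cluster, 25)
  expect_equal(sum(r1$summary$composition_counts),
               r1$summary$n_clusters_total)
  expect_equal(sum(r1$summary$distance_histogram$count),
               nrow(r1$contacts))
})

test_that("unparseable entries are isolated and excluded from denominators", {
  d <- withr::local_tempdir()
  build_survey(d, n_structures = 4, planting_rate = 0.5, seed = 43)
  writeLines("ATOM garbage not parseable", file.path(d, "S9999.pdb"))
  res <- suppressWarnings(survey_run(d))
  expect_equal(res$summary$n_structures_failed, 1L)
  expect_equal(res$summary$n_structures_scanned, 4L)
  expect_equal(res$summary$fraction_with_cluster, 50)
  expect_match(res$failures$file, "S9999")

  d2 <- withr::local_tempdir()
  expect_warning(res2 <- survey_run(d2), "no structures")
  expect_equal(res2$summary$n_structures_scanned, 0L)
  expect_true(is.na(res2$summary$fraction_with_cluster))
})
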