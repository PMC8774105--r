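## survey_stats: aggregate clusters across a survey -- composition,
## enzyme-class breakdown, distance histograms, B-factor context.

#' The ten size-3 aromatic compositions
#'
#' All multisets of size 3 over \{PHE, TYR, TRP\}, as sorted
#' `"-"`-joined keys (e.g. `"PHE-TRP-TYR"`).
#'
#' @return Character vector of length 10.
#' @export
composition_keys <- function() {
  g <- expand.grid(a = AROMATIC_RESNAMES, b = AROMATIC_RESNAMES,
                   c = AROMATIC_RESNAMES, stringsAsFactors = FALSE)
  keys <- apply(g, 1L, function(r) paste(sort(r), collapse = "-"))
  sort(unique(keys))
}

#' Tally cluster compositions
#'
#' Counts order-3 clusters over the ten possible aromatic
#' compositions. Clusters with more than three partners are tallied by
#' their three nearest partners (by contact distance) in the default
#' mode, or skipped with `oversize = "skip"`.
#'
#' @param clusters List of `BridgeCluster` (each with >= 3 partners).
#' @param oversize `"nearest"` (default) or `"skip"`.
#' @return Named integer vector over [composition_keys()]; zero-count
#'   keys are present.
#' @export
composition_tally <- function(clusters, oversize = c("nearest", "skip")) {
  oversize <- match.arg(oversize)
  counts <- stats::setNames(integer(10L), composition_keys())
  for (cl in clusters) {
    k <- length(cl$partners)
    if (k < 3L)
      stop("composition_tally requires clusters of size >= 3 (got ", k, ")")
    if (k == 3L) {
      resnames <- cl$composition
    } else if (oversize == "skip") {
      next
    } else {
      nearest <- order(cl$contacts$distance)[1:3]
      resnames <- sort(cl$contacts$aromatic_resname[nearest])
    }
    key <- paste(resnames, collapse = "-")
    counts[key] <- counts[key] + 1L
  }
  counts
}

# Primary EC class from a structure's EC annotation: first digit of the
# first listed EC number; absent or malformed -> "unclassified".
ec_primary_class <- function(ec_numbers, structure_id = NULL) {
  ec_numbers <- ec_numbers[!is.na(ec_numbers) & nzchar(ec_numbers)]
  if (!length(ec_numbers)) return("unclassified")
  m <- regmatches(ec_numbers[1L], regexpr("^\\s*([1-7])(\\.|$)", ec_numbers[1L]))
  if (!length(m)) {
    warning("malformed EC annotation \"", ec_numbers[1L], "\"",
            if (!is.null(structure_id)) paste0(" in ", structure_id),
            "; counted as unclassified", call. = FALSE)
    return("unclassified")
  }
  paste0("EC", gsub("[^1-7]", "", m))
}

#' Enzyme-class breakdown of cluster-bearing structures
#'
#' Assigns each structure its primary EC class (first digit of the
#' first listed EC number, or `"unclassified"`) and tallies over the
#' structures containing at least one cluster (`per = "structure"`,
#' default) or weighting each cluster once (`per = "cluster"`).
#'
#' @param models List of `StructureModel` (providers of the EC
#'   annotation).
#' @param clusters List of `BridgeCluster` (possibly from many
#'   structures).
#' @param per Count unit, `"structure"` or `"cluster"`.
#' @return Data frame with `class` (EC1..EC7, unclassified), `count`
#'   and `percentage` (summing to 100 when any counts exist).
#' @export
ec_class_tally <- function(models, clusters, per = c("structure", "cluster")) {
  per <- match.arg(per)
  levels <- c(paste0("EC", 1:7), "unclassified")
  model_ids <- vapply(models, `[[`, character(1L), "structure_id")
  classes <- vapply(seq_along(models), function(i)
    ec_primary_class(models[[i]]$ec_numbers, model_ids[i]), character(1L))
  names(classes) <- model_ids

  cl_struct <- vapply(clusters, `[[`, character(1L), "structure_id")
  unit <- if (per == "structure") unique(cl_struct) else cl_struct
  hit <- classes[unit]
  hit[is.na(hit)] <- "unclassified"
  counts <- table(factor(hit, levels = levels))
  total <- sum(counts)
  data.frame(class = levels,
             count = as.integer(counts),
             percentage = if (total > 0) 100 * as.integer(counts) / total
                          else rep(0, length(levels)),
             stringsAsFactors = FALSE)
}

#' Distance histogram
#'
#' Half-open, left-closed bins `[lo, hi)` of width `bin_width` starting
#' at 0. Counts conserve the number of finite inputs.
#'
#' @param x Numeric distances, or a `PairContact` data frame (its
#'   `distance` column is used).
#' @param bin_width Bin width in Angstrom (> 0). Default 0.5.
#' @param upper Upper edge; defaults to `bin_width` times the smallest
#'   integer covering the data (bins are extended so the maximum falls
#'   inside a half-open bin).
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
distance_histogram <- function(x, bin_width = 0.5, upper = NULL) {
  stopifnot(is.numeric(bin_width), bin_width > 0)
  if (is.data.frame(x)) x <- x$distance
  x <- x[is.finite(x)]
  if (is.null(upper)) {
    upper <- if (!length(x)) bin_width
             else bin_width * (floor(max(x) / bin_width) + 1L)
  }
  edges <- seq(0, upper, by = bin_width)
  if (edges[length(edges)] < upper) edges <- c(edges, upper)
  idx <- findInterval(x, edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(lower = edges[-length(edges)], upper = edges[-1L],
             count = counts)
}

#' B-factor context of a cluster
#'
#' Compares the mean B-factor over all atoms of the cluster residues
#' (the Met plus its aromatic partners) with the distribution of
#' per-residue mean B-factors across the whole protein, as a
#' flexibility proxy. The percentile is a midrank percentile (stable
#' under ties); with an all-zero B column the context is flagged
#' uninformative.
#'
#' @param cluster A `BridgeCluster`.
#' @param model The `StructureModel` the cluster came from.
#' @return A `BFactorContext` list: `mean_b_cluster`, `mean_b_protein`,
#'   `percentile_of_cluster_mean` (0-100) and `uninformative`.
#' @export
bfactor_context <- function(cluster, model) {
  stopifnot(inherits(cluster, "BridgeCluster"),
            inherits(model, "StructureModel"))
  atoms <- model$atoms[model$atoms$residue_name %in% PROTEIN_RESNAMES, ,
                       drop = FALSE]
  res_key <- function(chain, number, insert)
    paste(chain, number, ifelse(is.na(insert), "", insert), sep = "\r")
  akey <- res_key(atoms$chain_id, atoms$residue_number, atoms$insertion_code)

  member_refs <- c(list(cluster$met$ref), lapply(cluster$partners, `[[`, "ref"))
  mkeys <- vapply(member_refs, function(r)
    res_key(r$chain_id, r$residue_number, r$insertion_code), character(1L))

  in_cluster <- akey %in% mkeys
  mean_b_cluster <- mean(atoms$b_factor[in_cluster])
  mean_b_protein <- mean(atoms$b_factor)

  per_res <- tapply(atoms$b_factor, akey, mean)
  lower <- sum(per_res < mean_b_cluster)
  equal <- sum(abs(per_res - mean_b_cluster) < 1e-12)
  percentile <- 100 * (lower + equal / 2) / length(per_res)

  ctx <- list(mean_b_cluster = mean_b_cluster,
              mean_b_protein = mean_b_protein,
              percentile_of_cluster_mean = percentile,
              uninformative = all(abs(atoms$b_factor) < 1e-12))
  class(ctx) <- "BFactorContext"
  ctx
}

#' Run a survey over a set of structures
#'
#' Scans structures (files in a directory, optionally restricted to an
#' identifier list), runs detection and bridge enumeration on each, and
#' aggregates. Unparseable entries are isolated, logged and excluded
#' from denominators. Aggregation is deterministic: structures are
#' processed in sorted identifier order.
#'
#' @param dir Directory containing coordinate files.
#' @param ids Optional identifier vector (see [read_id_list()]); files
#'   are resolved as `<id>.pdb` / `<id>.cif` (case-insensitively).
#' @param config A [detection_config()].
#' @param n Bridge order (default 3).
#' @param mode Cluster counting mode, see [find_n_bridges()].
#' @param trp_centroid Trp centroid convention, see
#'   [extract_aromatic_sites()].
#' @param bin_width Histogram bin width (A).
#' @return A `SurveyResult` list: `summary` (a `SurveySummary`),
#'   `structures` (per-structure table), `clusters` (list of
#'   `BridgeCluster`), `cluster_table`, `local_points`, `contacts`,
#'   and `failures`.
#' @export
survey_run <- function(dir, ids = NULL, config = detection_config(), n = 3,
                       mode = c("maximal", "subsets"),
                       trp_centroid = c("indole", "hexagon"),
                       bin_width = 0.5) {
  mode <- match.arg(mode)
  trp_centroid <- match.arg(trp_centroid)
  files <- resolve_structure_files(dir, ids)
  if (!length(files)) warning("no structures to scan", call. = FALSE)

  per_structure <- list()
  clusters_all <- list()
  contacts_all <- list()
  models_all <- list()
  failures <- list()

  for (f in files) {
    res <- tryCatch({
      model <- parse_structure(f)
      mets <- extract_met_sites(model, include_mse = config$include_mse)
      aromatics <- extract_aromatic_sites(model, trp_centroid = trp_centroid)
      contacts <- met_aromatic_pairs(mets, aromatics, config)
      clusters <- find_n_bridges(contacts, mets, aromatics, n = n, mode = mode)
      list(model = model, mets = mets, aromatics = aromatics,
           contacts = contacts, clusters = clusters)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        file = f, message = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    models_all[[length(models_all) + 1L]] <- res$model
    clusters_all <- c(clusters_all, res$clusters)
    contacts_all[[length(contacts_all) + 1L]] <- res$contacts
    per_structure[[length(per_structure) + 1L]] <- data.frame(
      structure_id = res$model$structure_id,
      file = f,
      n_mets = length(res$mets),
      n_aromatics = length(res$aromatics),
      n_contacts = nrow(res$contacts),
      n_clusters = length(res$clusters),
      ec_class = ec_primary_class(res$model$ec_numbers,
                                  res$model$structure_id),
      stringsAsFactors = FALSE
    )
  }

  structures <- if (length(per_structure)) do.call(rbind, per_structure)
                else data.frame(structure_id = character(), file = character(),
                                n_mets = integer(), n_aromatics = integer(),
                                n_contacts = integer(), n_clusters = integer(),
                                ec_class = character(), stringsAsFactors = FALSE)
  contacts <- if (length(contacts_all)) do.call(rbind, contacts_all)
              else empty_contacts()
  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame(file = character(), message = character(),
                              stringsAsFactors = FALSE)

  n_scanned <- nrow(structures)
  n_with <- sum(structures$n_clusters > 0L)
  order3 <- Filter(function(cl) length(cl$partners) >= 3L, clusters_all)

  summary <- list(
    n_structures_scanned = n_scanned,
    n_structures_failed = nrow(failures),
    n_structures_with_cluster = n_with,
    n_clusters_total = length(clusters_all),
    fraction_with_cluster = if (n_scanned > 0) 100 * n_with / n_scanned
                            else NA_real_,
    composition_counts = composition_tally(order3),
    ec_counts = ec_class_tally(models_all, clusters_all),
    distance_histogram = distance_histogram(contacts, bin_width = bin_width),
    config = config,
    n = n,
    mode = mode
  )
  class(summary) <- "SurveySummary"

  out <- list(summary = summary,
              structures = structures,
              clusters = clusters_all,
              cluster_table = cluster_table(clusters_all),
              local_points = suppressWarnings(local_frame_table(clusters_all)),
              contacts = contacts,
              failures = failures)
  class(out) <- "SurveyResult"
  out
}

#' @export
print.SurveySummary <- function(x, ...) {
  cat("Survey of", x$n_structures_scanned, "structure(s) at bridge order",
      x$n, "\n")
  cat("  clusters:", x$n_clusters_total, "in", x$n_structures_with_cluster,
      "structure(s)")
  if (!is.na(x$fraction_with_cluster))
    cat(sprintf(" (%.1f%%)", x$fraction_with_cluster))
  cat("\n")
  if (x$n_structures_failed > 0)
    cat("  failed to parse:", x$n_structures_failed, "entr(ies), excluded",
        "from denominators\n")
  nz <- x$composition_counts[x$composition_counts > 0]
  if (length(nz))
    cat("  compositions:", paste(names(nz), nz, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

resolve_structure_files <- function(dir, ids = NULL) {
  if (is.null(ids)) {
    files <- list.files(dir, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE, ignore.case = TRUE)
    return(sort(files))
  }
  all_files <- list.files(dir, full.names = TRUE)
  stems <- toupper(sub("\\.(pdb|ent|cif|mmcif)$", "", basename(all_files),
                       ignore.case = TRUE))
  found <- all_files[match(toupper(ids), stems)]
  missing <- is.na(found)
  if (any(missing))
    warning("no coordinate file for identifier(s): ",
            paste(ids[missing], collapse = ", "), call. = FALSE)
  sort(found[!missing])
}
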