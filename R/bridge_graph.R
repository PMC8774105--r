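## bridge_graph: the residue interaction graph and n-bridge enumeration.

met_node_id <- function(chain, number, insert) {
  paste0("MET|", residue_label(chain, number, insert))
}

aro_node_id <- function(resname, chain, number, insert) {
  paste0(resname, "|", residue_label(chain, number, insert))
}

#' Build the residue interaction graph
#'
#' Met and aromatic residues become nodes of a bipartite graph; every
#' contact becomes an edge carrying its distances.
#'
#' @param contacts A `PairContact` data frame from
#'   [met_aromatic_pairs()] (one structure).
#' @return An [igraph][igraph::graph_from_data_frame] graph with vertex
#'   attributes `role` (`"met"`/`"aromatic"`) and `type` (logical
#'   bipartite marker), and edge attributes `distance` and
#'   `centroid_distance`.
#' @export
build_graph <- function(contacts) {
  met_ids <- met_node_id(contacts$met_chain, contacts$met_number,
                         contacts$met_insert)
  aro_ids <- aro_node_id(contacts$aromatic_resname, contacts$aromatic_chain,
                         contacts$aromatic_number, contacts$aromatic_insert)
  if (any(met_ids == aro_ids))
    stop("contact references the same residue as both Met and aromatic")
  if (nrow(contacts) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  vertices <- data.frame(
    name = c(unique(met_ids), unique(aro_ids)),
    role = c(rep("met", length(unique(met_ids))),
             rep("aromatic", length(unique(aro_ids)))),
    stringsAsFactors = FALSE
  )
  vertices$type <- vertices$role == "aromatic"
  edges <- data.frame(from = met_ids, to = aro_ids,
                      distance = contacts$distance,
                      centroid_distance = contacts$centroid_distance,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Enumerate n-bridge clusters
#'
#' An n-bridge is one methionine in contact with at least n aromatic
#' residues. In the default `"maximal"` mode each qualifying Met yields
#' exactly one cluster carrying all of its partners (a Met with 4
#' partners is one cluster of size 4, not four 3-subsets); `"subsets"`
#' emits every n-subset of partners, for sensitivity analysis of the
#' counting convention.
#'
#' @param contacts A `PairContact` data frame (one structure).
#' @param mets,aromatics The site lists the contacts were computed
#'   from (carriers of the coordinates the clusters need downstream).
#' @param n Bridge order, an integer >= 2. Default 3.
#' @param mode `"maximal"` (default) or `"subsets"`.
#' @return A list of `BridgeCluster` objects: `met` (`MetSite`),
#'   `partners` (list of `AromaticSite`, ordered by chain then residue
#'   number), `contacts` (matching rows), `composition` (sorted
#'   residue-name vector) and `n`.
#' @export
find_n_bridges <- function(contacts, mets, aromatics, n = 3,
                           mode = c("maximal", "subsets")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("bridge order n must be an integer >= 2")
  n <- as.integer(n)
  if (nrow(contacts) == 0L) return(list())

  met_key <- met_node_id(contacts$met_chain, contacts$met_number,
                         contacts$met_insert)
  clusters <- list()
  for (key in unique(met_key)) {
    rows <- contacts[met_key == key, , drop = FALSE]
    # deterministic partner order: chain, then residue number, insertion code
    ord <- order(rows$aromatic_chain, rows$aromatic_number,
                 ifelse(is.na(rows$aromatic_insert), "", rows$aromatic_insert))
    rows <- rows[ord, , drop = FALSE]
    if (nrow(rows) < n) next
    met <- mets[[rows$met_index[1L]]]
    partner_sets <- if (mode == "maximal") list(seq_len(nrow(rows)))
                    else asplit(utils::combn(nrow(rows), n), 2L)
    for (sel in partner_sets) {
      sub <- rows[sel, , drop = FALSE]
      cl <- list(met = met,
                 partners = aromatics[sub$aromatic_index],
                 contacts = sub,
                 composition = sort(sub$aromatic_resname),
                 n = n,
                 structure_id = met$structure_id)
      class(cl) <- "BridgeCluster"
      clusters[[length(clusters) + 1L]] <- cl
    }
  }
  clusters
}

#' @export
print.BridgeCluster <- function(x, ...) {
  cat("BridgeCluster (order >= ", x$n, ") in ", x$structure_id, ": Met ",
      residue_label(x$met$ref$chain_id, x$met$ref$residue_number,
                    x$met$ref$insertion_code),
      " + {", paste(vapply(x$partners, function(p)
        residue_label(p$ref$chain_id, p$ref$residue_number,
                      p$ref$insertion_code, p$resname), character(1L)),
        collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Tabulate clusters
#'
#' One row per cluster: structure, Met identity, partner count and
#' identities, composition key and the distance range.
#'
#' @param clusters List of `BridgeCluster`.
#' @return A data frame.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(structure_id = character(), met_chain = character(),
                      met_number = integer(), n_partners = integer(),
                      composition = character(), partners = character(),
                      min_distance = numeric(), max_distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(
      structure_id = cl$structure_id,
      met_chain = cl$met$ref$chain_id,
      met_number = cl$met$ref$residue_number,
      n_partners = length(cl$partners),
      composition = paste(cl$composition, collapse = "-"),
      partners = paste(vapply(cl$partners, function(p)
        residue_label(p$ref$chain_id, p$ref$residue_number,
                      p$ref$insertion_code, p$resname), character(1L)),
        collapse = ";"),
      min_distance = min(cl$contacts$distance),
      max_distance = max(cl$contacts$distance),
      stringsAsFactors = FALSE
    )
  }))
}
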