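## pair_detection: Met-aromatic contacts under the survey's distance
## criterion (6.0 A cutoff, angular filter disabled).

#' Detection configuration
#'
#' The survey criterion: a methionine and an aromatic residue are in
#' contact when the configured Met-side to ring-side distance is at
#' most `cutoff_distance` (inclusive). The default metric measures from
#' SD to the nearest ring-bond midpoint; `"sd_to_centroid"` measures to
#' the ring centroid instead. Both distances are reported on every
#' contact regardless of which one gates.
#'
#' The angular filter is disabled by default (`angle_cutoff_deg = 360`);
#' when enabled, a contact passes if the smaller of the two lone-pair
#' angles is at most the cutoff.
#'
#' @param cutoff_distance Contact cutoff in Angstrom (default 6.0).
#' @param distance_metric `"sd_to_nearest_midpoint"` (default) or
#'   `"sd_to_centroid"`.
#' @param angle_cutoff_deg Angular cutoff in degrees; 360 disables.
#' @param interchain Allow contacts across chains? Default `TRUE`.
#' @param include_mse Treat selenomethionine sites as Met? Default
#'   `FALSE`.
#' @return A `DetectionConfig` list.
#' @export
detection_config <- function(cutoff_distance = 6.0,
                             distance_metric = c("sd_to_nearest_midpoint",
                                                 "sd_to_centroid"),
                             angle_cutoff_deg = 360,
                             interchain = TRUE,
                             include_mse = FALSE) {
  distance_metric <- match.arg(distance_metric)
  stopifnot(is.numeric(cutoff_distance), length(cutoff_distance) == 1L,
            cutoff_distance > 0,
            is.numeric(angle_cutoff_deg), length(angle_cutoff_deg) == 1L,
            angle_cutoff_deg > 0, angle_cutoff_deg <= 360)
  cfg <- list(cutoff_distance = cutoff_distance,
              distance_metric = distance_metric,
              angle_cutoff_deg = angle_cutoff_deg,
              interchain = isTRUE(interchain),
              include_mse = isTRUE(include_mse))
  class(cfg) <- "DetectionConfig"
  cfg
}

#' Thioether lone-pair direction estimates
#'
#' Two unit vectors estimating the sulfur lone-pair directions of a
#' methionine: both lie in the plane spanned by the CG-SD-CE bisector
#' and the wedge normal, opposite the CG-SD-CE wedge, opened
#' symmetrically to the tetrahedral angle. Swapping CG and CE exchanges
#' the two vectors. These support the reported (never filtering, by
#' default) contact angles.
#'
#' @param met A `MetSite`.
#' @return A 2 x 3 matrix; rows are unit vectors.
#' @export
lone_pair_directions <- function(met) {
  stopifnot(inherits(met, "MetSite"))
  a <- vunit(met$cg - met$sd)
  b <- vunit(met$ce - met$sd)
  wedge <- vangle(a, b)
  if (wedge < pi / 180 || wedge > pi - pi / 180)
    stop("degenerate CG-SD-CE geometry (collinear) in ",
         residue_label(met$ref$chain_id, met$ref$residue_number,
                       met$ref$insertion_code, met$ref$residue_name),
         " of ", met$structure_id)
  u <- -vunit(a + b)            # anti-bisector of the wedge
  n <- vunit(vcross(a, b))      # wedge normal
  half <- acos(-1 / 3) / 2      # half the tetrahedral lone-pair spread
  lp <- rbind(u * cos(half) + n * sin(half),
              u * cos(half) - n * sin(half))
  lp / sqrt(rowSums(lp^2))
}

#' Find Met-aromatic contacts
#'
#' Applies the distance criterion of `config` to every (Met, aromatic)
#' pair from one structure. A Met paired with k aromatics yields k
#' contacts. The cutoff comparison is inclusive.
#'
#' @param mets List of `MetSite` ([extract_met_sites()]).
#' @param aromatics List of `AromaticSite`
#'   ([extract_aromatic_sites()]).
#' @param config A [detection_config()].
#' @return A data frame of class `PairContact`, one row per contact:
#'   identities of both residues, `distance` (the gating metric),
#'   `centroid_distance`, `midpoint_distance`, the lone-pair angles
#'   `met_theta_deg` / `met_phi_deg`, and the indices of the two sites
#'   in the input lists.
#' @export
met_aromatic_pairs <- function(mets, aromatics, config = detection_config()) {
  stopifnot(inherits(config, "DetectionConfig"))
  out <- empty_contacts()
  if (!length(mets) || !length(aromatics)) return(out)

  if (!config$include_mse) {
    keep <- vapply(mets, function(m) m$ref$residue_name != "MSE", logical(1L))
    mets <- mets[keep]
    met_index <- which(keep)
  } else met_index <- seq_along(mets)

  rows <- list()
  for (i in seq_along(mets)) {
    met <- mets[[i]]
    lp <- tryCatch(lone_pair_directions(met), error = function(e) NULL)
    for (j in seq_along(aromatics)) {
      aro <- aromatics[[j]]
      if (!config$interchain && !identical(met$ref$chain_id, aro$ref$chain_id))
        next
      d_cen <- vnorm(aro$centroid - met$sd)
      d_mid_all <- sqrt(rowSums(sweep(aro$midpoints, 2L, met$sd)^2))
      d_mid <- min(d_mid_all)
      distance <- if (config$distance_metric == "sd_to_centroid") d_cen else d_mid
      # inclusive cutoff with a 1e-9 A guard so that distances equal to
      # the cutoff up to floating-point representation are kept
      if (distance > config$cutoff_distance + 1e-9) next

      refpt <- if (config$distance_metric == "sd_to_centroid") aro$centroid
               else aro$midpoints[which.min(d_mid_all), ]
      v <- refpt - met$sd
      if (is.null(lp)) {
        theta <- phi <- NA_real_
      } else {
        theta <- vangle(v, lp[1L, ]) * 180 / pi
        phi   <- vangle(v, lp[2L, ]) * 180 / pi
      }
      if (config$angle_cutoff_deg < 360 &&
          (is.na(theta) || min(theta, phi) > config$angle_cutoff_deg))
        next

      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = met$structure_id,
        met_chain = met$ref$chain_id,
        met_number = met$ref$residue_number,
        met_insert = met$ref$insertion_code,
        met_resname = met$ref$residue_name,
        aromatic_chain = aro$ref$chain_id,
        aromatic_number = aro$ref$residue_number,
        aromatic_insert = aro$ref$insertion_code,
        aromatic_resname = aro$resname,
        distance = distance,
        centroid_distance = d_cen,
        midpoint_distance = d_mid,
        met_theta_deg = theta,
        met_phi_deg = phi,
        met_index = met_index[i],
        aromatic_index = j,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  class(out) <- c("PairContact", "data.frame")
  out
}

empty_contacts <- function() {
  out <- data.frame(
    structure_id = character(), met_chain = character(),
    met_number = integer(), met_insert = character(),
    met_resname = character(), aromatic_chain = character(),
    aromatic_number = integer(), aromatic_insert = character(),
    aromatic_resname = character(), distance = numeric(),
    centroid_distance = numeric(), midpoint_distance = numeric(),
    met_theta_deg = numeric(), met_phi_deg = numeric(),
    met_index = integer(), aromatic_index = integer(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("PairContact", "data.frame")
  out
}

#' Write contacts as CSV
#'
#' @param contacts A `PairContact` data frame.
#' @param path Output file.
#' @export
write_contacts_csv <- function(contacts, path) {
  cols <- c("structure_id", "met_chain", "met_number", "aromatic_chain",
            "aromatic_number", "aromatic_resname", "distance",
            "centroid_distance", "met_theta_deg", "met_phi_deg")
  utils::write.csv(as.data.frame(contacts)[, cols], path, row.names = FALSE)
  invisible(path)
}
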