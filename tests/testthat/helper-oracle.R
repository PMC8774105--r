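# Independent brute-force contact oracle: plain loops over the raw atom
# table with its own literal ring definitions, no shared code with
# met_aromatic_pairs().

ORACLE_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)
ORACLE_BONDS <- list(
  PHE = list(c("CG","CD1"), c("CD1","CE1"), c("CE1","CZ"), c("CZ","CE2"),
             c("CE2","CD2"), c("CD2","CG")),
  TYR = list(c("CG","CD1"), c("CD1","CE1"), c("CE1","CZ"), c("CZ","CE2"),
             c("CE2","CD2"), c("CD2","CG")),
  TRP = list(c("CG","CD1"), c("CD1","NE1"), c("NE1","CE2"), c("CE2","CD2"),
             c("CD2","CG"), c("CD2","CE3"), c("CE3","CZ3"), c("CZ3","CH2"),
             c("CH2","CZ2"), c("CZ2","CE2"))
)

oracle_contacts <- function(model, cutoff = 6.0,
                            metric = c("midpoint", "centroid")) {
  metric <- match.arg(metric)
  a <- model$atoms
  rkey <- paste(a$chain_id, a$residue_number, a$residue_name)
  out <- list()
  for (mk in unique(rkey[a$residue_name == "MET"])) {
    res <- a[rkey == mk, ]
    getp <- function(nm) {
      i <- which(res$atom_name == nm)
      if (!length(i)) return(NULL)
      c(res$x[i[1]], res$y[i[1]], res$z[i[1]])
    }
    sd <- getp("SD")
    if (is.null(sd) || is.null(getp("CG")) || is.null(getp("CE"))) next
    for (ak in unique(rkey[a$residue_name %in% c("PHE", "TYR", "TRP")])) {
      ares <- a[rkey == ak, ]
      resname <- ares$residue_name[1]
      pts <- lapply(ORACLE_RINGS[[resname]], function(nm) {
        i <- which(ares$atom_name == nm)
        if (!length(i)) NULL else c(ares$x[i[1]], ares$y[i[1]], ares$z[i[1]])
      })
      if (any(vapply(pts, is.null, logical(1)))) next
      names(pts) <- ORACLE_RINGS[[resname]]
      centroid <- Reduce(`+`, pts) / length(pts)
      d_cen <- sqrt(sum((centroid - sd)^2))
      d_mid <- min(vapply(ORACLE_BONDS[[resname]], function(b) {
        mp <- (pts[[b[1]]] + pts[[b[2]]]) / 2
        sqrt(sum((mp - sd)^2))
      }, numeric(1)))
      d <- if (metric == "centroid") d_cen else d_mid
      if (d <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          met = mk, aromatic = ak, distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(met = character(), aromatic = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$met, res$aromatic), , drop = FALSE]
}

# Contacts from the pipeline, reduced to the oracle's key format.
pipeline_contacts_keyed <- function(model, cutoff = 6.0,
                                    metric = c("midpoint", "centroid")) {
  metric <- match.arg(metric)
  cfg <- detection_config(
    cutoff_distance = cutoff,
    distance_metric = if (metric == "centroid") "sd_to_centroid"
                      else "sd_to_nearest_midpoint")
  pc <- met_aromatic_pairs(extract_met_sites(model),
                           extract_aromatic_sites(model), cfg)
  res <- data.frame(
    met = paste(pc$met_chain, pc$met_number, pc$met_resname),
    aromatic = paste(pc$aromatic_chain, pc$aromatic_number,
                     pc$aromatic_resname),
    distance = pc$distance, stringsAsFactors = FALSE)
  res[order(res$met, res$aromatic), , drop = FALSE]
}

# Random synthetic structure straddling the cutoff: partner distances
# span 2.5-8 A so both sides of the criterion are exercised.
random_oracle_structure <- function(path, seed) {
  k <- (seed %% 4L) + 1L
  build_structure(
    path,
    partners = data.frame(
      resname = sample(c("PHE", "TYR", "TRP"), k, replace = TRUE),
      r = runif(k, 2.5, 8.0),
      theta = runif(k, 10, 170),
      phi = runif(k, 0, 360)),
    n_decoys = 2, seed = seed, pose = "random")
  path
}
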