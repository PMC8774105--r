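# Shared builders for in-memory sites and models.

new_met_site <- function(cg, sd, ce, chain = "A", number = 1L,
                         structure_id = "TEST", resname = "MET") {
  structure(list(
    ref = list(chain_id = chain, residue_number = as.integer(number),
               insertion_code = NA_character_, residue_name = resname),
    cg = cg, sd = sd, ce = ce, structure_id = structure_id),
    class = "MetSite")
}

# A Met in general position from one RNG draw: random location and
# orientation, wedge angle between 60 and 140 degrees.
random_met_site <- function(number = 1L) {
  sd <- runif(3, -30, 30)
  a <- rand_unit()
  wedge <- runif(1, 60, 140) * pi / 180
  perp <- vunit_t(pracma_cross(a, rand_unit()))
  b <- cos(wedge) * a + sin(wedge) * perp
  new_met_site(cg = sd + 1.81 * a, sd = sd, ce = sd + 1.79 * b,
               number = number)
}

rand_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

vunit_t <- function(v) v / sqrt(sum(v^2))

vnorm_t <- function(v) sqrt(sum(v^2))

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Independent rigid motion (Rodrigues formula, no quaternions).
random_rigid_motion <- function() {
  axis <- rand_unit()
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  list(R = R, t = runif(3, -20, 20))
}

apply_motion_met <- function(met, motion) {
  mv <- function(p) as.numeric(motion$R %*% p) + motion$t
  new_met_site(mv(met$cg), mv(met$sd), mv(met$ce),
               chain = met$ref$chain_id, number = met$ref$residue_number,
               structure_id = met$structure_id,
               resname = met$ref$residue_name)
}

# StructureModel wrapper around a raw atom table (for tests that build
# geometry in memory rather than via files).
model_from_atoms <- function(atoms, structure_id = "TEST") {
  structure(list(structure_id = structure_id, atoms = atoms,
                 ec_numbers = character(), resolution = NA_real_,
                 source_path = NA_character_, dialect = "pdb"),
            class = "StructureModel")
}

# Aromatic site extracted from generator atoms placed at a centroid.
aromatic_site_at <- function(resname, centroid, number = 50L, chain = "A",
                             normal = c(0, 0, 1), spin = 0) {
  atoms <- metbridge:::aromatic_atoms_at(resname, centroid, normal, spin,
                                         as.integer(number), chain, 15)
  atoms$model_number <- 1L
  sites <- extract_aromatic_sites(model_from_atoms(atoms))
  sites[[1L]]
}

# Minimal BridgeCluster for statistics tests.
fake_cluster <- function(resnames, distances = NULL,
                         structure_id = "TEST", met_number = 1L) {
  if (is.null(distances)) distances <- seq(4, 5, length.out = length(resnames))
  met <- new_met_site(cg = c(1.81, 0, 0), sd = c(0, 0, 0),
                      ce = c(-0.31, 1.76, 0), number = met_number,
                      structure_id = structure_id)
  partners <- lapply(seq_along(resnames), function(i)
    aromatic_site_at(resnames[i], centroid = c(0, 0, 4 + i),
                     number = 100L + i))
  contacts <- data.frame(aromatic_resname = resnames, distance = distances,
                         stringsAsFactors = FALSE)
  structure(list(met = met, partners = partners, contacts = contacts,
                 composition = sort(resnames), n = 3L,
                 structure_id = structure_id),
            class = "BridgeCluster")
}

fake_model_with_ec <- function(structure_id, ec) {
  structure(list(structure_id = structure_id,
                 atoms = metbridge:::empty_atoms(),
                 ec_numbers = ec, resolution = NA_real_),
            class = "StructureModel")
}
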