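# Synthetic stand-in sites for published bridge examples. The real
# coordinate files are only reachable via the opt-in fetch helper;
# these fixtures reproduce the residue identities and bridge topology
# (not the experimental coordinates) with generator geometry, so the
# enumeration logic can be exercised against the expected partner sets.

place_met <- function(resno, chain, offset = c(0, 0, 0), b = 18) {
  a <- metbridge:::met_atoms_at(as.integer(resno), chain, b)
  a$x <- a$x + offset[1]; a$y <- a$y + offset[2]; a$z <- a$z + offset[3]
  a
}

place_aromatic <- function(resname, resno, chain, centroid, b = 16) {
  metbridge:::aromatic_atoms_at(resname, centroid,
                                normal = vunit_t(centroid + c(0.1, 0.2, 0.3)),
                                spin = 0.7, resno = as.integer(resno),
                                chain = chain, b = b)
}

# Cytochrome c peroxidase site: Met230 bridging Trp191 and Tyr187,
# Met231 bridging the same Trp191 and Phe202 (two 2-bridges sharing a
# node).
standin_ccp <- function(path) {
  atoms <- rbind(
    place_met(230, "A", c(0, 0, 0)),
    place_aromatic("TRP", 191, "A", c(0, 0, 4.6)),
    place_aromatic("TYR", 187, "A", c(0, -4.8, 1.0)),
    place_met(231, "A", c(0, 4.0, 7.0)),
    place_aromatic("PHE", 202, "A", c(0, 6.5, 11.0)))
  write_structure_file(atoms, path, structure_id = "XCCP",
                       ec_label = "1.11.1.5", resolution = 1.7)
  path
}

# Cytochrome P450 site: a 3-bridge on Met24 with Trp20, Trp31, Phe41.
standin_p450 <- function(path) {
  atoms <- rbind(
    place_met(24, "A", c(0, 0, 0)),
    place_aromatic("TRP", 20, "A", c(0, 0, 4.5)),
    place_aromatic("TRP", 31, "A", c(0, -4.5, 1.5)),
    place_aromatic("PHE", 41, "A", c(3.4, 3.2, -1.5)))
  write_structure_file(atoms, path, structure_id = "X450",
                       ec_label = "1.14.14.1", resolution = 2.0)
  path
}

# Yeast catalase sites: Met281 with {Tyr228, Trp300, Phe305} and Met209
# with {Phe108, Phe127, Tyr206}, well separated.
standin_catalase <- function(path) {
  off <- c(40, 0, 0)
  atoms <- rbind(
    place_met(281, "A", c(0, 0, 0)),
    place_aromatic("TYR", 228, "A", c(0, 0, 4.4)),
    place_aromatic("TRP", 300, "A", c(0, -4.5, 1.2)),
    place_aromatic("PHE", 305, "A", c(3.3, 3.1, -1.4)),
    place_met(209, "A", off),
    place_aromatic("PHE", 108, "A", off + c(0, 0, 4.4)),
    place_aromatic("PHE", 127, "A", off + c(0, -4.5, 1.2)),
    place_aromatic("TYR", 206, "A", off + c(3.3, 3.1, -1.4)))
  write_structure_file(atoms, path, structure_id = "XCAT",
                       ec_label = "1.11.1.6", resolution = 2.1)
  path
}

# Haloalkane dehalogenase site: a 3-bridge whose partners include
# Trp175, Phe190 and Phe290; Trp125 sits outside contact range.
standin_dehalogenase <- function(path) {
  atoms <- rbind(
    place_met(152, "A", c(0, 0, 0)),
    place_aromatic("TRP", 175, "A", c(0, 0, 4.5)),
    place_aromatic("PHE", 190, "A", c(0, -4.6, 1.2)),
    place_aromatic("PHE", 290, "A", c(3.4, 3.2, -1.4)),
    place_aromatic("TRP", 125, "A", c(0, 0, 11.0)))
  write_structure_file(atoms, path, structure_id = "XDHL",
                       ec_label = "3.8.1.5", resolution = 1.5)
  path
}

scan_standin <- function(path, n) {
  model <- parse_structure(path)
  mets <- extract_met_sites(model)
  aros <- extract_aromatic_sites(model)
  contacts <- met_aromatic_pairs(mets, aros, detection_config())
  find_n_bridges(contacts, mets, aros, n = n)
}

partner_labels <- function(cluster) {
  sort(vapply(cluster$partners, function(p)
    paste0(p$resname, p$ref$residue_number), character(1)))
}
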