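## structure_io: read coordinate files into a uniform structure model and
## extract the Met / aromatic geometry the survey needs.

#' Parse a PDB or mmCIF coordinate file
#'
#' Reads one coordinate file into a uniform `StructureModel`. Only the
#' first model of multi-model files is kept (the X-ray survey
#' convention), hydrogens are dropped, and alternate locations are
#' collapsed to the highest-occupancy conformer (ties resolved toward
#' altloc "A", with a warning).
#'
#' EC numbers are taken from `COMPND ... EC:` records (PDB) or
#' `_entity.pdbx_ec` (mmCIF); the resolution from `REMARK 2` or
#' `_refine.ls_d_res_high`. Both are optional.
#'
#' @param path Path to the coordinate file.
#' @param dialect `"pdb"`, `"mmcif"`, or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` are mmCIF, anything else fixed-column PDB).
#' @return A `StructureModel`: a list with `structure_id`, `atoms` (a
#'   data frame with one row per retained atom: `atom_name`, `element`,
#'   `chain_id`, `residue_name`, `residue_number`, `insertion_code`,
#'   `alt_loc`, `occupancy`, `b_factor`, `x`, `y`, `z`,
#'   `model_number`), `ec_numbers`, `resolution` and `source_path`.
#' @seealso [extract_met_sites()], [extract_aromatic_sites()]
#' @export
parse_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  model <- if (dialect == "pdb") parse_pdb_file(path) else parse_mmcif_file(path)
  model$source_path <- path
  model$dialect <- dialect
  model$atoms <- finalize_atoms(model$atoms, model$structure_id)
  if (nrow(model$atoms) == 0L)
    warning("structure ", model$structure_id, " contains no atoms", call. = FALSE)
  class(model) <- "StructureModel"
  model
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", x$structure_id, "-", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain_id)), "chain(s)\n")
  if (length(x$ec_numbers)) cat("  EC:", paste(x$ec_numbers, collapse = ", "), "\n")
  if (!is.na(x$resolution)) cat("  resolution:", x$resolution, "A\n")
  invisible(x)
}

## -- PDB dialect ------------------------------------------------------------

parse_pdb_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  structure_id <- basename_id(path)
  hdr <- lines[startsWith(lines, "HEADER")]
  if (length(hdr)) {
    id <- trimws(substr(hdr[1L], 63L, 66L))
    if (nzchar(id)) structure_id <- toupper(id)
  }
  ec <- parse_pdb_ec(lines)
  resolution <- parse_pdb_resolution(lines)

  if (!any(grepl("^(ATOM|HETATM)", lines))) {
    return(list(structure_id = structure_id, atoms = empty_atoms(),
                ec_numbers = ec, resolution = resolution))
  }
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    atom_name      = a$elety,
    element        = ifelse(is.na(a$elesy) | a$elesy == "",
                            guess_element(a$elety), toupper(a$elesy)),
    chain_id       = ifelse(is.na(a$chain), "", a$chain),
    residue_name   = a$resid,
    residue_number = as.integer(a$resno),
    insertion_code = a$insert,
    alt_loc        = a$alt,
    occupancy      = as.numeric(a$o),
    b_factor       = as.numeric(a$b),
    x = a$x, y = a$y, z = a$z,
    model_number   = 1L,
    stringsAsFactors = FALSE
  )
  list(structure_id = structure_id, atoms = atoms,
       ec_numbers = ec, resolution = resolution)
}

parse_pdb_ec <- function(lines) {
  compnd <- lines[startsWith(lines, "COMPND")]
  hits <- regmatches(compnd, regexpr("EC:\\s*[0-9][0-9.,n -]*", compnd))
  if (!length(hits)) return(character())
  raw <- unlist(strsplit(sub("EC:\\s*", "", hits), ","))
  ec <- trimws(sub(";.*$", "", raw))
  ec[nzchar(ec)]
}

parse_pdb_resolution <- function(lines) {
  rem <- lines[startsWith(lines, "REMARK   2 RESOLUTION")]
  m <- regmatches(rem, regexpr("[0-9]+\\.[0-9]+", rem))
  if (length(m)) as.numeric(m[1L]) else NA_real_
}

## -- mmCIF dialect ----------------------------------------------------------

# Minimal by-name mmCIF category reader: handles both the looped and the
# key-value forms, tolerates row wrapping, and resolves values by tag
# name rather than column position. Multi-line semicolon text blocks are
# not needed for the categories read here and are skipped.
cif_read_category <- function(lines, category) {
  prefix <- paste0("_", category, ".")
  n <- length(lines)
  i <- 1L
  kv <- list()
  while (i <= n) {
    line <- trimws(lines[i])
    if (identical(line, "loop_")) {
      j <- i + 1L
      tags <- character()
      while (j <= n && startsWith(trimws(lines[j]), "_")) {
        tags <- c(tags, trimws(lines[j])); j <- j + 1L
      }
      if (length(tags) && all(startsWith(tags, prefix))) {
        toks <- character()
        while (j <= n) {
          row <- trimws(lines[j])
          if (row == "" || row == "#" || startsWith(row, "_") ||
              row == "loop_" || startsWith(row, "data_")) break
          toks <- c(toks, cif_tokens(row)); j <- j + 1L
        }
        if (length(toks) %% length(tags) != 0L)
          stop("malformed mmCIF loop for category ", category)
        m <- matrix(toks, ncol = length(tags), byrow = TRUE)
        colnames(m) <- sub(prefix, "", tags, fixed = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        df[df == "." | df == "?"] <- NA
        return(df)
      }
      i <- j
    } else if (startsWith(line, prefix)) {
      toks <- cif_tokens(line)
      if (length(toks) >= 2L)
        kv[[sub(prefix, "", toks[1L], fixed = TRUE)]] <- toks[2L]
      i <- i + 1L
    } else i <- i + 1L
  }
  if (!length(kv)) return(NULL)
  df <- as.data.frame(kv, stringsAsFactors = FALSE)
  df[df == "." | df == "?"] <- NA
  df
}

cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1L]]
  toks <- regmatches(line, list(m))[[1L]]
  gsub("^['\"]|['\"]$", "", toks)
}

parse_mmcif_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entry <- cif_read_category(lines, "entry")
  structure_id <- if (!is.null(entry) && !is.na(entry$id[1L]))
    toupper(entry$id[1L]) else basename_id(path)

  ec <- character()
  ent <- cif_read_category(lines, "entity")
  if (!is.null(ent) && "pdbx_ec" %in% names(ent)) {
    raw <- unlist(strsplit(ent$pdbx_ec[!is.na(ent$pdbx_ec)], ","))
    ec <- trimws(raw)[nzchar(trimws(raw))]
  }
  resolution <- NA_real_
  for (cat in c("refine", "reflns")) {
    tab <- cif_read_category(lines, cat)
    fld <- if (cat == "refine") "ls_d_res_high" else "d_resolution_high"
    if (!is.null(tab) && fld %in% names(tab) && !is.na(tab[[fld]][1L])) {
      resolution <- as.numeric(tab[[fld]][1L]); break
    }
  }

  site <- cif_read_category(lines, "atom_site")
  if (is.null(site) || nrow(site) == 0L) {
    return(list(structure_id = structure_id, atoms = empty_atoms(),
                ec_numbers = ec, resolution = resolution))
  }
  pick <- function(...) {
    for (f in c(...)) if (f %in% names(site)) return(site[[f]])
    rep(NA_character_, nrow(site))
  }
  model_no <- suppressWarnings(as.integer(pick("pdbx_PDB_model_num")))
  model_no[is.na(model_no)] <- 1L
  atoms <- data.frame(
    atom_name      = pick("auth_atom_id", "label_atom_id"),
    element        = toupper(pick("type_symbol")),
    chain_id       = pick("auth_asym_id", "label_asym_id"),
    residue_name   = pick("auth_comp_id", "label_comp_id"),
    residue_number = suppressWarnings(as.integer(pick("auth_seq_id", "label_seq_id"))),
    insertion_code = pick("pdbx_PDB_ins_code"),
    alt_loc        = pick("label_alt_id"),
    occupancy      = suppressWarnings(as.numeric(pick("occupancy"))),
    b_factor       = suppressWarnings(as.numeric(pick("B_iso_or_equiv"))),
    x = suppressWarnings(as.numeric(pick("Cartn_x"))),
    y = suppressWarnings(as.numeric(pick("Cartn_y"))),
    z = suppressWarnings(as.numeric(pick("Cartn_z"))),
    model_number   = model_no,
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
    stop("malformed mmCIF atom_site coordinates in ", path)
  atoms <- atoms[atoms$model_number == atoms$model_number[1L], , drop = FALSE]
  atoms$chain_id[is.na(atoms$chain_id)] <- ""
  list(structure_id = structure_id, atoms = atoms,
       ec_numbers = ec, resolution = resolution)
}

## -- shared post-processing -------------------------------------------------

empty_atoms <- function() {
  data.frame(atom_name = character(), element = character(),
             chain_id = character(), residue_name = character(),
             residue_number = integer(), insertion_code = character(),
             alt_loc = character(), occupancy = numeric(),
             b_factor = numeric(), x = numeric(), y = numeric(),
             z = numeric(), model_number = integer(),
             stringsAsFactors = FALSE)
}

guess_element <- function(atom_name) {
  toupper(substr(gsub("[0-9' ]", "", atom_name), 1L, 1L))
}

# Drop hydrogens and collapse alternate locations: per atom slot, keep
# the highest-occupancy conformer; ties resolve toward altloc "A".
finalize_atoms <- function(atoms, structure_id) {
  if (nrow(atoms) == 0L) return(atoms)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("malformed coordinate record(s) in ", structure_id,
         ": non-finite positions")
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) return(atoms)

  alt <- ifelse(is.na(atoms$alt_loc), "", atoms$alt_loc)
  key <- paste(atoms$chain_id, atoms$residue_number,
               ifelse(is.na(atoms$insertion_code), "", atoms$insertion_code),
               atoms$residue_name, atoms$atom_name, sep = "\r")
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(atoms$occupancy), 1, atoms$occupancy)
    # order so that the preferred conformer of each slot comes first:
    # higher occupancy wins, then altloc "A" (alphabetical), then file order
    ord <- order(key, -occ, alt != "A", alt, seq_len(nrow(atoms)))
    keep <- !duplicated(key[ord])
    n_collapsed <- sum(!keep)
    atoms <- atoms[sort(ord[keep]), , drop = FALSE]
    warning("structure ", structure_id, ": collapsed alternate locations, ",
            "dropped ", n_collapsed, " lower-occupancy atom record(s)",
            call. = FALSE)
  }
  rownames(atoms) <- NULL
  atoms
}

basename_id <- function(path) {
  toupper(sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
              basename(path), ignore.case = TRUE))
}

residue_split <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_number,
               ifelse(is.na(atoms$insertion_code), "", atoms$insertion_code),
               atoms$residue_name, sep = "\r")
  split(atoms, factor(key, levels = unique(key)))
}

residue_ref <- function(res_atoms) {
  list(chain_id = res_atoms$chain_id[1L],
       residue_number = res_atoms$residue_number[1L],
       insertion_code = res_atoms$insertion_code[1L],
       residue_name = res_atoms$residue_name[1L])
}

atom_xyz <- function(res_atoms, name) {
  i <- match(name, res_atoms$atom_name)
  if (is.na(i)) return(NULL)
  c(res_atoms$x[i], res_atoms$y[i], res_atoms$z[i])
}

## -- site extraction --------------------------------------------------------

#' Extract methionine thioether sites
#'
#' One `MetSite` (the CG, SD, CE positions of the CH2-S-CH3 scaffold)
#' per methionine with a complete side-chain tip. Residues missing any
#' of the three atoms are skipped with a warning. Selenomethionine
#' (MSE) can be included on request, treating SE as SD.
#'
#' @param model A `StructureModel` from [parse_structure()].
#' @param include_mse Include MSE residues? Default `FALSE`.
#' @return A list of `MetSite` objects (fields `ref`, `cg`, `sd`, `ce`,
#'   `structure_id`).
#' @export
extract_met_sites <- function(model, include_mse = FALSE) {
  stopifnot(inherits(model, "StructureModel"))
  want <- if (include_mse) c("MET", "MSE") else "MET"
  atoms <- model$atoms[model$atoms$residue_name %in% want, , drop = FALSE]
  sites <- list()
  for (res in residue_split(atoms)) {
    ref <- residue_ref(res)
    cg <- atom_xyz(res, "CG")
    sd <- atom_xyz(res, "SD")
    if (is.null(sd) && ref$residue_name == "MSE") sd <- atom_xyz(res, "SE")
    ce <- atom_xyz(res, "CE")
    missing <- c("CG", "SD/SE", "CE")[c(is.null(cg), is.null(sd), is.null(ce))]
    if (length(missing)) {
      warning("skipping ", residue_label(ref$chain_id, ref$residue_number,
                                         ref$insertion_code, ref$residue_name),
              " in ", model$structure_id, ": missing ",
              paste(missing, collapse = ", "), call. = FALSE)
      next
    }
    d1 <- vnorm(cg - sd); d2 <- vnorm(sd - ce)
    if (d1 <= 1.0 || d1 >= 2.5 || d2 <= 1.0 || d2 >= 2.5)
      warning("implausible thioether bond length in ",
              residue_label(ref$chain_id, ref$residue_number,
                            ref$insertion_code, ref$residue_name),
              " of ", model$structure_id,
              " (|CG-SD| = ", round(d1, 2), " A, |SD-CE| = ", round(d2, 2),
              " A); site kept", call. = FALSE)
    site <- list(ref = ref, cg = cg, sd = sd, ce = ce,
                 structure_id = model$structure_id)
    class(site) <- "MetSite"
    sites[[length(sites) + 1L]] <- site
  }
  sites
}

#' Extract aromatic ring sites
#'
#' One `AromaticSite` per Phe/Tyr/Trp with a complete ring-atom set:
#' the named ring atoms, their unweighted centroid (the survey's
#' satellite point) and the midpoints of bonded ring-atom pairs (6 for
#' the Phe/Tyr hexagon; 10 for the Trp fused bicycle, the shared
#' CD2-CE2 bond counted once). Incomplete rings are skipped with a
#' warning; markedly non-planar rings are kept with a warning.
#'
#' @param model A `StructureModel`.
#' @param trp_centroid Use all 9 indole atoms for the Trp centroid
#'   (`"indole"`, default) or only the 6-membered ring (`"hexagon"`).
#' @return A list of `AromaticSite` objects (fields `ref`, `resname`,
#'   `ring_atoms` (matrix), `centroid`, `midpoints` (matrix),
#'   `structure_id`).
#' @export
extract_aromatic_sites <- function(model, trp_centroid = c("indole", "hexagon")) {
  stopifnot(inherits(model, "StructureModel"))
  trp_centroid <- match.arg(trp_centroid)
  atoms <- model$atoms[model$atoms$residue_name %in% AROMATIC_RESNAMES, ,
                       drop = FALSE]
  sites <- list()
  for (res in residue_split(atoms)) {
    ref <- residue_ref(res)
    resname <- ref$residue_name
    needed <- RING_ATOMS[[resname]]
    idx <- match(needed, res$atom_name)
    if (anyNA(idx)) {
      warning("skipping ", residue_label(ref$chain_id, ref$residue_number,
                                         ref$insertion_code, resname),
              " in ", model$structure_id, ": missing ring atom(s) ",
              paste(needed[is.na(idx)], collapse = ", "), call. = FALSE)
      next
    }
    ring <- cbind(res$x[idx], res$y[idx], res$z[idx])
    rownames(ring) <- needed
    colnames(ring) <- c("x", "y", "z")

    cen_atoms <- if (resname == "TRP" && trp_centroid == "hexagon")
      TRP_HEXAGON else needed
    centroid <- colMeans(ring[cen_atoms, , drop = FALSE])

    dev <- ring_planarity(ring)
    if (dev >= 0.25)
      warning("non-planar ring in ",
              residue_label(ref$chain_id, ref$residue_number,
                            ref$insertion_code, resname),
              " of ", model$structure_id,
              " (max out-of-plane deviation ", round(dev, 2), " A); site kept",
              call. = FALSE)

    bonds <- RING_BONDS[[resname]]
    midpoints <- (ring[bonds[, 1L], , drop = FALSE] +
                  ring[bonds[, 2L], , drop = FALSE]) / 2
    rownames(midpoints) <- paste(bonds[, 1L], bonds[, 2L], sep = "-")

    site <- list(ref = ref, resname = resname, ring_atoms = ring,
                 centroid = centroid, midpoints = midpoints,
                 structure_id = model$structure_id)
    class(site) <- "AromaticSite"
    sites[[length(sites) + 1L]] <- site
  }
  sites
}

# Max out-of-plane deviation from the least-squares ring plane.
ring_planarity <- function(ring) {
  centered <- sweep(ring, 2L, colMeans(ring))
  sv <- svd(centered)
  max(abs(centered %*% sv$v[, 3L]))
}

#' Read a survey identifier list
#'
#' Plain text, one structure identifier per line; blank lines and `#`
#' comments are tolerated. Identifiers are upper-cased and
#' de-duplicated preserving first occurrence.
#'
#' @param path Path to the list file.
#' @return Character vector of identifiers.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("cannot read ID list: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  ids <- unique(toupper(lines[nzchar(lines)]))
  if (!length(ids)) warning("ID list ", path, " is empty", call. = FALSE)
  ids
}
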