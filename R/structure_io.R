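#' Read a PDB file into a structure frame or trajectory
#'
#' Parses ATOM/HETATM records (via the bio3d reader) into the package's
#' containers. Alternate locations are resolved by keeping the
#' highest-occupancy copy of each atom, ties broken by lexicographic altloc
#' identifier — the standard crystallographic convention. HETATM records
#' (zinc, ions, glycans, ligands) are retained and flagged via the
#' `is_hetatm` column; they are excluded from Calpha selections by
#' construction.
#'
#' @param source path to a PDB file (single- or multi-MODEL).
#' @param model_policy `"first"` returns a [structure_frame()] built from the
#'   first MODEL; `"all"` returns a [trajectory()] with one frame per MODEL.
#' @param timestep frame spacing in ns used for trajectory times when the
#'   format carries no time information (PDB does not).
#' @return a `structure_frame` (`model_policy = "first"`) or a `trajectory`
#'   (`model_policy = "all"`).
#' @examples
#' pdb <- system.file("extdata", "regions", package = "hingescope") # see vignette
#' @export
read_pdb <- function(source, model_policy = c("first", "all"), timestep = 1) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(source))
    hs_stop("io_error", "PDB file not found: %s", source)
  pdb <- tryCatch(
    bio3d::read.pdb(source, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) hs_stop("parse_error", "cannot parse PDB '%s': %s",
                                source, conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    hs_stop("empty_structure", "no ATOM/HETATM records in '%s'", source)

  atoms <- pdb_atoms_to_df(pdb$atom)
  keep <- resolve_altlocs(atoms)
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL

  nmodels <- nrow(pdb$xyz)
  frame_coords <- function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    xyz[keep, , drop = FALSE]
  }
  if (model_policy == "first")
    return(structure_frame(atoms, frame_coords(1L)))
  frames <- array(0, dim = c(nmodels, nrow(atoms), 3L))
  for (m in seq_len(nmodels)) frames[m, , ] <- frame_coords(m)
  trajectory(atoms, frames, timestep = timestep)
}

# bio3d atom table -> package column conventions
pdb_atoms_to_df <- function(a) {
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  elem <- blank(a$elesy)
  need <- !nzchar(elem)
  if (any(need)) elem[need] <- infer_element(a$elety[need], a$type[need] == "HETATM")
  occ <- a$o
  occ[is.na(occ)] <- 1
  data.frame(
    serial = as.integer(a$eleno),
    atom_name = as.character(a$elety),
    element = toupper(elem),
    residue_name = as.character(a$resid),
    residue_number = as.integer(a$resno),
    insertion_code = blank(a$insert),
    chain_id = blank(a$chain),
    altloc = blank(a$alt),
    occupancy = occ,
    is_hetatm = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Element inference when the element column is absent: strip digits/primes,
# recognise common two-letter species (ions, metals), else first letter.
infer_element <- function(atom_name, is_het = FALSE) {
  two_letter <- c("ZN", "FE", "MG", "MN", "CA", "NA", "CL", "BR", "CU", "NI",
                  "CO", "CD", "HG", "SE", "LI")
  vapply(seq_along(atom_name), function(i) {
    nm <- gsub("[0-9']", "", toupper(atom_name[i]))
    if (!nzchar(nm)) return("X")
    if (is_het[i] && nm %in% two_letter) return(nm)
    substr(nm, 1L, 1L)
  }, character(1))
}

# Keep-index vector implementing max-occupancy altloc resolution.
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
               atoms$residue_name, atoms$atom_name, sep = "\r")
  if (!anyDuplicated(key)) return(seq_len(nrow(atoms)))
  keep <- vapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- atoms$occupancy[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1L) best <- best[order(atoms$altloc[best])][1L]
    best[1L]
  }, integer(1))
  sort(unname(keep))
}

#' Write a structure frame or trajectory to a PDB file
#'
#' Single frames produce a plain PDB; trajectories produce a multi-MODEL PDB
#' readable by [read_pdb()] with `model_policy = "all"`. Coordinates are
#' written at PDB precision (3 decimals, Angstrom).
#'
#' @param x a [structure_frame()] or [trajectory()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "structure_frame")) {
    atoms <- x$atoms
    xyz <- matrix(t(x$coords), nrow = 1L)
  } else if (inherits(x, "trajectory")) {
    atoms <- x$topology
    nt <- n_frames(x)
    xyz <- t(vapply(seq_len(nt),
                    function(m) as.numeric(t(x$frames[m, , , drop = TRUE])),
                    numeric(3L * nrow(atoms))))
  } else hs_stop("invalid_input", "write_pdb expects a structure_frame or trajectory")
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(atoms$is_hetatm, "HETATM", "ATOM"),
    eleno = atoms$serial, elety = atoms$atom_name,
    resid = atoms$residue_name, resno = atoms$residue_number,
    chain = atoms$chain_id, insert = ifelse(nzchar(atoms$insertion_code),
                                            atoms$insertion_code, NA),
    alt = ifelse(nzchar(atoms$altloc), atoms$altloc, NA),
    o = atoms$occupancy, b = rep(0, nrow(atoms)),
    elesy = atoms$element)
  invisible(path)
}

#' Select Calpha atom indices for residue ranges on a chain
#'
#' Resolves inclusive residue-number ranges (author numbering) to the indices
#' of the matching Calpha atoms, ordered by residue number then insertion
#' code. Residues listed in the ranges but absent from the structure are
#' reported in the `missing_residues` attribute and via a warning — crystal
#' structures routinely lack loop residues, so absence is not an error.
#' HETATM records never match (a calcium ion named CA is not a Calpha).
#'
#' @param x a [structure_frame()], [trajectory()], or atom data.frame.
#' @param region a list of inclusive `c(start, end)` residue ranges (or one
#'   bare two-vector), e.g. an element of a [region_set()].
#' @param chain_id chain to select on.
#' @return integer atom indices, with attribute `missing_residues` (integer
#'   vector of requested residue numbers not present).
#' @export
select_ca <- function(x, region, chain_id) {
  atoms <- if (inherits(x, "structure_frame")) x$atoms
           else if (inherits(x, "trajectory")) x$topology
           else as.data.frame(x)
  if (is.numeric(region) && length(region) == 2L) region <- list(region)
  if (!is.list(region) || length(region) == 0L)
    hs_stop("invalid_region", "region must be a non-empty list of ranges")
  wanted <- sort(unique(unlist(lapply(region, function(r) r[1]:r[2]))))
  het <- if (is.null(atoms$is_hetatm)) rep(FALSE, nrow(atoms)) else atoms$is_hetatm
  cand <- which(!het & atoms$atom_name == "CA" & atoms$element == "C" &
                  atoms$chain_id == chain_id &
                  atoms$residue_number %in% wanted)
  if (length(cand) == 0L)
    hs_stop("empty_selection",
            "no Calpha atoms match chain %s, residues %s",
            chain_id, paste(range(wanted), collapse = "-"))
  ins <- if (is.null(atoms$insertion_code)) rep("", nrow(atoms)) else
    atoms$insertion_code
  cand <- cand[order(atoms$residue_number[cand], ins[cand])]
  missing <- setdiff(wanted, atoms$residue_number[cand])
  if (length(missing) > 0L)
    hs_warn("missing_residues", "%d requested residues absent from structure: %s",
            length(missing), paste(utils::head(missing, 10), collapse = ","))
  attr(cand, "missing_residues") <- as.integer(missing)
  cand
}

#' Write a per-frame time-series table as CSV
#'
#' @param table data.frame of per-frame records (one row per frame; by
#'   convention the first column is `time_ns`). An empty table yields a
#'   header-only CSV.
#' @param destination file path.
#' @return `destination`, invisibly.
#' @export
write_timeseries <- function(table, destination) {
  table <- as.data.frame(table)
  ok <- tryCatch({
    utils::write.csv(table, destination, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) hs_stop("io_error", "cannot write time series to '%s'", destination)
  invisible(destination)
}

#' Read a per-frame time-series CSV written by [write_timeseries()]
#' @param source file path.
#' @return data.frame.
#' @export
read_timeseries <- function(source) {
  if (!file.exists(source)) hs_stop("io_error", "file not found: %s", source)
  utils::read.csv(source, stringsAsFactors = FALSE)
}
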