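# Trajectory I/O. Coordinates are stored in nm internally; PDB files are in
# Angstrom and converted on read/write. Plain PDB carries no frame times, so
# the reader takes the sampling interval as an argument.

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "HSD", "HSE", "HSP")

#' Default residue-name to category mapping for trajectories
#'
#' Standard amino acids map to `protein`; DOPS/POPS to `lipid_PS`;
#' DOPC/POPC to `lipid_PC`; CA/CAL to `ion_Ca`. Residue names not covered
#' by the mapping raise a warning and are treated as `protein` (and are
#' therefore never counted among lipid atoms).
#'
#' @return named character vector mapping residue names to categories.
#' @export
default_category_map <- function() {
  c(stats::setNames(rep("protein", length(AMINO_ACIDS)), AMINO_ACIDS),
    DOPS = "lipid_PS", POPS = "lipid_PS",
    DOPC = "lipid_PC", POPC = "lipid_PC",
    CA = "ion_Ca", CAL = "ion_Ca")
}

#' Default lipid headgroup atom names
#'
#' Atom names (phosphate, glycerol and choline/serine moieties) classified
#' as `headgroup`; every other lipid atom is `acyl`.
#'
#' @return character vector of atom names.
#' @export
default_headgroup_atoms <- function() {
  c("P", "O11", "O12", "O13", "O14", "N", "NC3", "C1", "C2", "C3",
    "C11", "C12", "C13", "C14", "C15", "O21", "O22", "O31", "O32",
    "C21", "C31", "HS", "C13A", "C13B", "C13C")
}

#' Molecular trajectory container
#'
#' @param atoms data.frame with columns `index`, `atom_name`, `resno`,
#'   `resname`, `category` (one of `protein`, `lipid_PS`, `lipid_PC`,
#'   `ion_Ca`), `lipid_region` (`headgroup`, `acyl` or `n/a`).
#' @param coords numeric array `n_atoms x 3 x n_frames`, nm.
#' @param times_ps strictly increasing frame times in ps.
#' @param box length-3 box edge lengths in nm (orthorhombic), or an
#'   `n_frames x 3` matrix.
#' @return object of class `md_traj`.
#' @export
md_trajectory <- function(atoms, coords, times_ps, box) {
  atoms <- as.data.frame(atoms)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  n_at <- dim(coords)[1L]
  n_fr <- dim(coords)[3L]
  if (nrow(atoms) != n_at)
    stopf("coords have %d atoms but atom table has %d rows", n_at,
          nrow(atoms), class = "guvmem_format_error")
  if (length(times_ps) != n_fr)
    stopf("times_ps length (%d) != number of frames (%d)", length(times_ps),
          n_fr, class = "guvmem_format_error")
  if (n_fr > 1L && any(diff(times_ps) <= 0))
    stopf("frame times must be strictly increasing")
  if (is.null(dim(box)))
    box <- matrix(rep(box, each = n_fr), nrow = n_fr, ncol = 3L)
  if (any(box <= 0)) stopf("box lengths must be positive")
  structure(list(atoms = atoms, coords = coords,
                 times_ps = as.numeric(times_ps), box = box),
            class = "md_traj")
}

#' @export
print.md_traj <- function(x, ...) {
  cat(sprintf(
    "<md_traj> %d atoms, %d frames (%.1f-%.1f ns), box %.2f x %.2f x %.2f nm\n",
    nrow(x$atoms), length(x$times_ps), min(x$times_ps) / 1000,
    max(x$times_ps) / 1000, x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  print(table(x$atoms$category))
  invisible(x)
}

n_frames <- function(traj) length(traj$times_ps)

assign_categories <- function(resname, atom_name, category_map,
                              headgroup_atoms) {
  category <- unname(category_map[resname])
  unknown <- is.na(category)
  if (any(unknown)) {
    warnf("unmapped residue name(s) %s treated as category 'protein'",
          paste(unique(resname[unknown]), collapse = ", "))
    category[unknown] <- "protein"
  }
  lipid_region <- ifelse(
    category %in% c("lipid_PS", "lipid_PC"),
    ifelse(atom_name %in% headgroup_atoms, "headgroup", "acyl"),
    "n/a")
  list(category = category, lipid_region = lipid_region)
}

parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0L) return(NULL)
  as.numeric(c(substr(cl[1L], 7, 15), substr(cl[1L], 16, 24),
               substr(cl[1L], 25, 33))) / 10  # Angstrom -> nm
}

# Ensure every MODEL block has the same number of coordinate records.
validate_model_blocks <- function(lines, path) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(invisible(1L))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stopf("'%s': unbalanced MODEL/ENDMDL records", path,
          class = "guvmem_format_error")
  counts <- mapply(function(s, e)
    sum(grepl("^(ATOM  |HETATM)", lines[s:e])), starts, ends)
  if (length(unique(counts)) != 1L)
    stopf("'%s': models have differing atom counts (%s)", path,
          paste(unique(counts), collapse = ", "),
          class = "guvmem_format_error")
  invisible(length(starts))
}

#' Read a trajectory from PDB files
#'
#' The topology (atom names, residue numbers/names) is read from a PDB
#' file; frames come from a multi-model PDB with the same atom order
#' (by default the same file). Categories are assigned from residue names
#' via `category_map` and lipid regions from `headgroup_atoms`.
#' Coordinates are converted from Angstrom to nm; the box is taken from
#' the CRYST1 record, which must be present.
#'
#' @param topology_path PDB file defining the atoms.
#' @param frames_path multi-model PDB with coordinates (default: the
#'   topology file itself).
#' @param dt_ps frame spacing in ps (plain PDB has no time axis).
#' @param t0_ps time of the first frame in ps.
#' @param category_map named vector, see [default_category_map()].
#' @param headgroup_atoms character vector, see [default_headgroup_atoms()].
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(topology_path, frames_path = topology_path,
                            dt_ps = 2000, t0_ps = 0,
                            category_map = default_category_map(),
                            headgroup_atoms = default_headgroup_atoms()) {
  top <- bio3d::read.pdb(topology_path, verbose = FALSE)
  lines <- readLines(frames_path)
  validate_model_blocks(lines, frames_path)
  box <- parse_cryst1(lines)
  if (is.null(box)) box <- parse_cryst1(readLines(topology_path))
  if (is.null(box))
    stopf("'%s': no CRYST1 record; an orthorhombic box is required",
          frames_path, class = "guvmem_format_error")
  frames <- bio3d::read.pdb(frames_path, multi = TRUE, verbose = FALSE)
  xyz <- frames$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_at <- nrow(top$atom)
  if (ncol(xyz) != 3L * n_at)
    stopf("atom count mismatch: topology has %d atoms, frames have %d",
          n_at, ncol(xyz) / 3, class = "guvmem_format_error")
  n_fr <- nrow(xyz)
  coords <- array(0, dim = c(n_at, 3L, n_fr))
  for (f in seq_len(n_fr))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE) / 10
  cats <- assign_categories(top$atom$resid, top$atom$elety, category_map,
                            headgroup_atoms)
  atoms <- data.frame(index = seq_len(n_at),
                      atom_name = top$atom$elety,
                      resno = top$atom$resno,
                      resname = top$atom$resid,
                      category = cats$category,
                      lipid_region = cats$lipid_region,
                      stringsAsFactors = FALSE)
  md_trajectory(atoms, coords, t0_ps + dt_ps * (seq_len(n_fr) - 1L), box)
}

#' Write a trajectory as a multi-model PDB
#'
#' Coordinates are converted nm to Angstrom (0.001 nm precision) and a
#' CRYST1 record stores the box. The file round-trips through
#' [read_trajectory()].
#'
#' @param traj an [md_trajectory()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_traj"))
  at <- traj$atoms
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                   traj$box[1, 1] * 10, traj$box[1, 2] * 10,
                   traj$box[1, 3] * 10)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(cryst, con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, seq_len(nrow(at)), f) * 10
    # resName left-justified in columns 18-21 so four-character lipid
    # names (DOPS/DOPC) stay parseable
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      at$index, at$atom_name, at$resname, "A", at$resno,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
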