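# Backbone superposition. Least-squares rigid alignment (Kabsch) with the
# proper-rotation sign correction, and an RMSD over a residue range with
# atoms paired by residue number and atom name.

#' Kabsch superposition of paired coordinate sets
#'
#' Finds the proper rotation (det = +1) and translation minimizing the
#' RMSD of `rotation %*% b + translation` onto `a`, and returns that
#' minimal RMSD. Degenerate geometry (fewer than 3 points, or collinear
#' point sets) is an error.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (same
#'   units; Angstrom for structures).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd`.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L)
    stopf("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(a)
  if (n < 3L) stopf("at least 3 point pairs are required")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2L, ca); B <- sweep(b, 2L, cb)
  H <- crossprod(B, A)             # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-300))
    stopf("degenerate (collinear) geometry: rotation not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  rot_b <- B %*% t(R)
  rmsd <- sqrt(sum((A - rot_b)^2) / n)
  list(rotation = R, translation = as.numeric(ca - R %*% cb), rmsd = rmsd)
}

#' Read a structure model from a PDB file
#'
#' Keeps coordinates in Angstrom; one row per atom with residue number,
#' residue name and atom name.
#'
#' @param path PDB file.
#' @return data.frame of class `struct_model` with columns `resno`,
#'   `resname`, `atom_name`, `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  p <- bio3d::read.pdb(path, verbose = FALSE)
  out <- data.frame(resno = p$atom$resno, resname = p$atom$resid,
                    atom_name = p$atom$elety, x = p$atom$x, y = p$atom$y,
                    z = p$atom$z, stringsAsFactors = FALSE)
  class(out) <- c("struct_model", "data.frame")
  out
}

#' Backbone RMSD between two models over a residue range
#'
#' Pairs backbone atoms (default N, CA, C, O) by residue number and atom
#' name across the inclusive residue range, then computes the Kabsch
#' superposition RMSD. Missing residues or atoms in the range are an
#' error listing the gaps. Residues are matched by author numbering, not
#' sequence alignment.
#'
#' @param model_a,model_b `struct_model` data.frames (see
#'   [read_structure()]).
#' @param residue_range inclusive `c(first, last)` residue numbers.
#' @param atoms backbone atom names to use; `c("N","CA","C","O")`
#'   (default) or e.g. `"CA"` for CA-only.
#' @return list with `rmsd` (Angstrom), `rotation`, `translation`,
#'   `n_atoms`, `residue_range`.
#' @export
backbone_rmsd <- function(model_a, model_b, residue_range,
                          atoms = c("N", "CA", "C", "O")) {
  stopifnot(length(residue_range) == 2L,
            residue_range[1L] <= residue_range[2L])
  resnos <- seq.int(residue_range[1L], residue_range[2L])
  pick <- function(m, label) {
    m <- as.data.frame(m)
    m <- m[m$resno %in% resnos & m$atom_name %in% atoms, , drop = FALSE]
    want <- expand.grid(atom_name = atoms, resno = resnos,
                        stringsAsFactors = FALSE)
    key_m <- paste(m$resno, m$atom_name)
    key_w <- paste(want$resno, want$atom_name)
    miss <- setdiff(key_w, key_m)
    if (length(miss) > 0L)
      stopf("model %s is missing %d backbone atom(s) in range: %s%s",
            label, length(miss),
            paste(head(miss, 8L), collapse = ", "),
            if (length(miss) > 8L) ", ..." else "")
    m[match(key_w, key_m), , drop = FALSE]
  }
  ma <- pick(model_a, "a")
  mb <- pick(model_b, "b")
  fit <- kabsch_superpose(as.matrix(ma[c("x", "y", "z")]),
                          as.matrix(mb[c("x", "y", "z")]))
  c(fit[c("rmsd", "rotation", "translation")],
    list(n_atoms = nrow(ma), residue_range = residue_range))
}
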