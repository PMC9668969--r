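## Distance-to-bound-configuration (DBC) coordinate: RMSD of lipid glycerol
## atoms relative to the bound pose after optimal superposition of the
## protein frame.

#' Reference geometry for the DBC coordinate
#'
#' @param frame_atom_coords n x 3 matrix of protein-frame atom coordinates
#'   (A); at least 3 non-collinear atoms.
#' @param glycerol_ref_coords m x 3 matrix of bound-pose glycerol atom
#'   coordinates (A).
#' @param wall upper flat-bottom wall (A, > 0); defaults to 6 A, the 95th
#'   percentile of the unbiased bound-state simulation in the source system.
#' @return object of class `dbc_reference`.
#' @export
dbc_reference <- function(frame_atom_coords, glycerol_ref_coords, wall = 6) {
  frame_atom_coords <- as.matrix(frame_atom_coords)
  glycerol_ref_coords <- as.matrix(glycerol_ref_coords)
  if (ncol(frame_atom_coords) != 3L || nrow(frame_atom_coords) < 3L) {
    .bad_param("frame_atom_coords", "must be an n x 3 matrix with n >= 3")
  }
  if (.is_collinear(frame_atom_coords)) {
    .bad_param("frame_atom_coords", "degenerate (collinear) frame geometry")
  }
  if (ncol(glycerol_ref_coords) != 3L) {
    .bad_param("glycerol_ref_coords", "must be an m x 3 matrix")
  }
  .check_num(wall, "wall", lower = 0, strict_lower = TRUE)
  structure(list(frame_atom_coords = frame_atom_coords,
                 glycerol_ref_coords = glycerol_ref_coords, wall = wall),
            class = "dbc_reference")
}

## Kabsch: rotation R (right-multiplication of row vectors) minimizing
## || (P - cP) R - (Q - cQ) ||
.kabsch <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, cP = cP, cQ = cQ)
}

#' DBC of one coordinate snapshot
#'
#' Optimally superposes the snapshot's frame atoms onto the reference frame
#' (Kabsch), applies the same rigid transform to the glycerol atoms, and
#' returns their RMSD against the reference glycerol coordinates.
#'
#' @param snapshot list with `frame` (n x 3) and `glycerol` (m x 3)
#'   coordinate matrices, atom counts matching the reference.
#' @param ref a [dbc_reference()].
#' @return DBC in Angstrom.
#' @export
dbc <- function(snapshot, ref) {
  if (!inherits(ref, "dbc_reference")) {
    stop("`ref` must be a dbc_reference", call. = FALSE)
  }
  P <- as.matrix(snapshot$frame); G <- as.matrix(snapshot$glycerol)
  if (nrow(P) != nrow(ref$frame_atom_coords)) {
    stop("snapshot frame atom count does not match reference", call. = FALSE)
  }
  if (nrow(G) != nrow(ref$glycerol_ref_coords)) {
    stop("snapshot glycerol atom count does not match reference",
         call. = FALSE)
  }
  if (.is_collinear(P)) {
    stop("degenerate frame geometry in snapshot", call. = FALSE)
  }
  k <- .kabsch(P, ref$frame_atom_coords)
  Gt <- sweep(G, 2, k$cP) %*% k$R
  Gt <- sweep(Gt, 2, k$cQ, `+`)
  sqrt(mean(rowSums((Gt - ref$glycerol_ref_coords)^2)))
}

#' Empirical percentile wall from a DBC sample
#'
#' @param dbc_values DBC values (A), at least 20.
#' @param q percentile in `[0, 100]` (default 95, the convention used to
#'   place the flat-bottom restraint wall).
#' @return the q-th percentile (linear-interpolation convention, R type 7).
#' @export
dbc_wall <- function(dbc_values, q = 95) {
  .check_num(dbc_values, "dbc_values", len = NULL, lower = 0)
  if (length(dbc_values) < 20L) {
    stop("need at least 20 DBC values for a percentile wall", call. = FALSE)
  }
  .check_num(q, "q", lower = 0, upper = 100)
  unname(quantile(dbc_values, q / 100, type = 7))
}
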