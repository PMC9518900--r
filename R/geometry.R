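## Reduced-representation geometry: torsions <-> Cartesian coordinates
## under ideal covalent geometry.

#' Ideal covalent geometry constants
#'
#' Bond lengths (Angstrom), bond angles (degrees) and the improper
#' dihedral used to place CB, as fixed during folding.  These are the
#' community-standard ideal values; the peptide bond omega is held at 180
#' degrees throughout.
#'
#' @return Named numeric vector of geometry constants.
#' @export
ideal_geometry <- function() cpp_ideal_geometry()

#' Build a protein model from backbone torsion angles
#'
#' Places N, H, CA, CB, C, O and a side-chain center (SC) pseudo-atom for
#' every residue by sequential internal-to-Cartesian (NeRF) construction
#' with all bond lengths and angles fixed at their ideal values.  The
#' first residue defines the canonical frame: N at the origin, CA on the
#' +x axis, C in the xy-plane.  Glycine carries CB = SC = CA.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @param phi,psi Backbone torsions in degrees, length `nchar(sequence)`.
#'   `phi[1]` and `psi[L]` are undefined; any value (e.g. the 999 sentinel)
#'   is accepted there and ignored.
#' @return A `protein_model`: list with `sequence`, `phi`, `psi` (degrees,
#'   sentinel 999 at undefined positions), `coords` (7L x 3 matrix, one
#'   row per atom in N/H/CA/CB/SC/C/O order) and `present` (logical mask;
#'   FALSE for the missing H of residue 1 and glycine CB/SC slots).
#' @export
build_coordinates <- function(sequence, phi, psi) {
  sequence <- validate_sequence(sequence)
  L <- nchar(sequence)
  if (L < 2) stop("sequence must have at least 2 residues")
  if (length(phi) != L || length(psi) != L)
    stop("phi and psi must have one entry per residue")
  if (any(!is.finite(phi[-1])) || any(!is.finite(psi[-L])))
    stop("torsions must be finite where defined")
  aa <- strsplit(sequence, "")[[1]]
  is_gly <- as.integer(aa == "G")
  scd <- unname(SC_DIST[aa])
  phir <- phi * pi / 180
  psir <- psi * pi / 180
  phir[1] <- 0
  psir[L] <- 0
  coords <- cpp_build_coords(is_gly, scd, phir, psir)
  model <- new_protein_model(sequence, phi, psi, coords)
  model$phi[1] <- TORSION_SENTINEL
  model$psi[L] <- TORSION_SENTINEL
  model
}

new_protein_model <- function(sequence, phi, psi, coords) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  present <- rep(TRUE, 7 * L)
  present[2] <- FALSE                       # residue 1 amide H
  gly <- which(aa == "G")
  present[(gly - 1) * 7 + 4] <- FALSE       # glycine CB slot (alias of CA)
  present[(gly - 1) * 7 + 5] <- FALSE       # glycine SC slot
  rownames(coords) <- paste0(rep(ATOM_NAMES, L), "_", rep(seq_len(L), each = 7))
  structure(list(sequence = sequence, phi = phi, psi = psi,
                 coords = coords, present = present),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> %d residues\n", nchar(x$sequence)))
  cat(" sequence:", x$sequence, "\n")
  invisible(x)
}

atom_rows <- function(L, slot) (seq_len(L) - 1) * 7 + slot

#' Extract coordinates of one atom type
#'
#' @param model A `protein_model`.
#' @param atom One of `"N"`, `"H"`, `"CA"`, `"CB"`, `"SC"`, `"C"`, `"O"`.
#'   `"CB"` returns CA for glycine rows (the contact/orientation
#'   convention).
#' @return L x 3 coordinate matrix.
#' @export
atom_coords <- function(model, atom = "CA") {
  slot <- match(atom, ATOM_NAMES)
  if (is.na(slot)) stop("unknown atom name: ", atom)
  L <- nchar(model$sequence)
  model$coords[atom_rows(L, slot), , drop = FALSE]
}

dihedral_points <- function(A, B, C, D) {
  ## IUPAC dihedral in degrees for coordinate row-vectors or matrices
  if (is.null(dim(A))) {
    A <- rbind(A); B <- rbind(B); C <- rbind(C); D <- rbind(D)
  }
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  nb2 <- sqrt(rowSums(b2^2))
  if (any(rowSums(n1^2) < 1e-20) || any(rowSums(n2^2) < 1e-20))
    stop("degenerate geometry: colinear atoms in dihedral")
  m1 <- cbind(b2[, 2] * n1[, 3] - b2[, 3] * n1[, 2],
              b2[, 3] * n1[, 1] - b2[, 1] * n1[, 3],
              b2[, 1] * n1[, 2] - b2[, 2] * n1[, 1]) / nb2
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  unname(atan2(y, x)) * 180 / pi
}

#' Backbone torsion angles from coordinates
#'
#' Computes IUPAC phi/psi dihedrals (degrees) from N, CA, C coordinates.
#' The inverse of [build_coordinates()]: rebuilding from the returned
#' torsions reproduces the structure up to a rigid motion.
#'
#' @param model A `protein_model`, or a list with elements `N`, `CA`, `C`
#'   (each an L x 3 matrix).
#' @return List with `phi` and `psi` in degrees; undefined entries carry
#'   the 999 sentinel.
#' @export
compute_torsions <- function(model) {
  if (inherits(model, "protein_model")) {
    N <- atom_coords(model, "N")
    CA <- atom_coords(model, "CA")
    C <- atom_coords(model, "C")
  } else {
    N <- model$N; CA <- model$CA; C <- model$C
  }
  L <- nrow(N)
  if (L < 2) stop("need at least 2 residues")
  phi <- rep(TORSION_SENTINEL, L)
  psi <- rep(TORSION_SENTINEL, L)
  if (L >= 2) {
    idx <- 2:L
    phi[idx] <- dihedral_points(C[idx - 1, , drop = FALSE],
                                N[idx, , drop = FALSE],
                                CA[idx, , drop = FALSE],
                                C[idx, , drop = FALSE])
    jdx <- 1:(L - 1)
    psi[jdx] <- dihedral_points(N[jdx, , drop = FALSE],
                                CA[jdx, , drop = FALSE],
                                C[jdx, , drop = FALSE],
                                N[jdx + 1, , drop = FALSE])
  }
  list(phi = phi, psi = psi)
}

#' Rebuild pseudo-atoms from backbone coordinates
#'
#' Given N/CA/C positions (e.g. read from a PDB file), places the ideal
#' CB, amide H, carbonyl O and side-chain center for every residue using
#' the same geometric rules as [build_coordinates()].
#'
#' @param sequence One-letter amino-acid string.
#' @param N,CA,C L x 3 backbone coordinate matrices.
#' @param O Optional L x 3 carbonyl oxygen matrix; rebuilt when `NULL`.
#' @param CB Optional L x 3 matrix of observed CB positions; missing rows
#'   (NA) are rebuilt.
#' @return A `protein_model` with all 7 atom slots filled and torsions
#'   computed from the backbone.
#' @export
place_pseudo_atoms <- function(sequence, N, CA, C, O = NULL, CB = NULL) {
  sequence <- validate_sequence(sequence)
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  tor <- compute_torsions(list(N = N, CA = CA, C = C))
  geo <- ideal_geometry()
  coords <- matrix(NA_real_, 7 * L, 3)
  coords[atom_rows(L, 1), ] <- N
  coords[atom_rows(L, 3), ] <- CA
  coords[atom_rows(L, 6), ] <- C
  nerf1 <- function(A, B, C, r, theta, chi) {
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    ab <- B - A
    n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    th <- theta * pi / 180; ch <- chi * pi / 180
    C + bc * (-r * cos(th)) + m * (r * sin(th) * cos(ch)) +
      n * (r * sin(th) * sin(ch))
  }
  for (i in seq_len(L)) {
    ## carbonyl O
    psi_eff <- if (i < L) tor$psi[i] else 180
    if (is.null(O) || anyNA(O[i, ])) {
      coords[(i - 1) * 7 + 7, ] <-
        nerf1(N[i, ], CA[i, ], C[i, ], geo[["b_c_o"]], geo[["a_ca_c_o"]],
              psi_eff + 180)
    } else coords[(i - 1) * 7 + 7, ] <- O[i, ]
    ## amide H
    if (i >= 2) {
      coords[(i - 1) * 7 + 2, ] <-
        nerf1(CA[i - 1, ], C[i - 1, ], N[i, ], geo[["b_n_h"]],
              geo[["a_c_n_h"]], 0)
    } else coords[(i - 1) * 7 + 2, ] <- N[i, ]
    ## CB and SC
    if (aa[i] == "G") {
      coords[(i - 1) * 7 + 4, ] <- CA[i, ]
      coords[(i - 1) * 7 + 5, ] <- CA[i, ]
    } else {
      cb <- if (!is.null(CB) && !anyNA(CB[i, ])) CB[i, ] else
        nerf1(C[i, ], N[i, ], CA[i, ], geo[["b_ca_cb"]], geo[["a_n_ca_cb"]],
              geo[["d_c_n_ca_cb"]])
      coords[(i - 1) * 7 + 4, ] <- cb
      u <- cb - CA[i, ]; u <- u / sqrt(sum(u^2))
      coords[(i - 1) * 7 + 5, ] <- CA[i, ] + u * SC_DIST[[aa[i]]]
    }
  }
  new_protein_model(sequence, tor$phi, tor$psi, coords)
}

#' Per-atom van der Waals radii for a model
#'
#' Unified pseudo-atom radii used by the clash penalty and clash counter:
#' backbone N/CA/C/CB carry heavy-atom radii, O the carbonyl radius, the
#' side-chain center a residue-specific radius, and the polar amide H is
#' excluded (radius 0).
#'
#' @param model A `protein_model`.
#' @return Numeric vector, one radius per atom row (0 = excluded).
#' @export
atom_radii <- function(model) {
  aa <- strsplit(model$sequence, "")[[1]]
  L <- length(aa)
  radii <- rep(ATOM_RADII[ATOM_NAMES], L)
  radii[atom_rows(L, 5)] <- SC_RADII[aa]
  radii[!model$present] <- 0
  radii[atom_rows(L, 4)][aa == "G"] <- 0
  unname(radii)
}
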