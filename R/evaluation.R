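## Model-quality metrics: Kabsch superposition / RMSD, TM-score with the
## standard fragment-seeded iterative search, top-n*L distance MAE,
## contact precision and a lightweight clash counter.

model_ca <- function(x) {
  if (inherits(x, "protein_model")) atom_coords(x, "CA") else as.matrix(x)
}

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Least-squares proper rotation (reflections corrected via the SVD
#' determinant) superposing `P` onto `Q`.
#'
#' @param P,Q n x 3 coordinate matrices (or `protein_model`s, whose CA
#'   atoms are used) with matching row correspondence, n >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation`, `rmsd`,
#'   `d` (per-point distances after superposition) and `transform` (the
#'   function mapping P-frame points into the Q frame).
#' @export
kabsch_rmsd <- function(P, Q) {
  P <- model_ca(P); Q <- model_ca(Q)
  if (nrow(P) != nrow(Q)) stop("point counts differ")
  if (nrow(P) < 3) stop("need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)   # maps centered P into centered Q
  Pr <- Pc %*% t(R)
  diffs <- sqrt(rowSums((Pr - Qc)^2))
  list(rotation = R, translation = cq - as.vector(R %*% cp),
       rmsd = sqrt(mean(rowSums((Pr - Qc)^2))), d = diffs,
       transform = function(X) sweep(sweep(X, 2, cp) %*% t(R), 2, cq, "+"))
}

tm_d0 <- function(L) max(1.24 * (max(L - 15, 0))^(1 / 3) - 1.8, 0.5)

tm_from_d <- function(d, d0, L) sum(1 / (1 + (d / d0)^2)) / L

#' TM-score between two same-length structures
#'
#' Sequence-dependent TM-score with the fixed residue correspondence:
#' `TM = max (1/L) sum 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8` (floored at 0.5 A), maximized over
#' superpositions found by the standard search: seed fragments of length
#' L, L/2 and L/4 at every offset, each refined by iterating "superpose
#' on the close subset, re-select residues within the distance cutoff"
#' to a fixed point.
#'
#' @param model,native `protein_model`s or L x 3 CA matrices of equal
#'   length.
#' @param d_cut Residue-selection cutoff of the refinement iteration;
#'   defaults to `max(d0, 4.5)`.
#' @return List with `tm`, `rmsd` (global-superposition RMSD), `d0` and
#'   `superposition` (the best [kabsch_rmsd()]-style result).
#' @export
tm_score <- function(model, native, d_cut = NULL) {
  P <- model_ca(model); Q <- model_ca(native)
  L <- nrow(P)
  if (nrow(Q) != L) stop("length mismatch between model and native")
  d0 <- tm_d0(L)
  if (is.null(d_cut)) d_cut <- max(d0, 4.5)
  frag_lens <- unique(pmax(c(L, floor(L / 2), floor(L / 4)), 4))
  best <- -Inf; best_sup <- NULL
  score_from_idx <- function(idx) {
    ## iterate subset-superposition to a fixed point, track the best TM
    local_best <- -Inf; local_sup <- NULL
    for (it in 1:30) {
      sup <- kabsch_rmsd(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
      d <- sqrt(rowSums((sup$transform(P) - Q)^2))
      tm <- tm_from_d(d, d0, L)
      if (tm > local_best) {
        local_best <- tm
        local_sup <- sup
        local_sup$d <- d
      }
      new_idx <- which(d <= d_cut)
      if (length(new_idx) < 4)
        new_idx <- order(d)[1:4]
      new_idx <- sort(new_idx)
      if (identical(new_idx, idx)) break
      idx <- new_idx
    }
    list(tm = local_best, sup = local_sup)
  }
  for (fl in frag_lens) {
    if (fl > L) next
    for (start in 1:(L - fl + 1)) {
      r <- score_from_idx(start:(start + fl - 1))
      if (r$tm > best) { best <- r$tm; best_sup <- r$sup }
    }
  }
  glob <- kabsch_rmsd(P, Q)
  list(tm = best, rmsd = glob$rmsd, d0 = d0, superposition = best_sup)
}

#' Distance MAE of the most confident restraints
#'
#' Mean absolute error between the argmax-bin-center predicted CB
#' distances and the model's CB distances over the top `floor(n * L)`
#' most confident pairs in the given sequence-separation class (all
#' available pairs are used when fewer exist).
#'
#' @param restraints A `restraint_set` with a `cb_distance` channel.
#' @param model A `protein_model` of matching length.
#' @param n Multiplier of L.
#' @param range_class `"short"`, `"medium"`, `"long"` (default) or
#'   `"all"`.
#' @return MAE in Angstrom.
#' @export
distance_mae <- function(restraints, model, n = 2, range_class = "long") {
  L <- restraints$L
  if (nchar(model$sequence) != L) stop("length mismatch")
  masks <- select_restraints(restraints,
                             list(kind = "top_nl", n = n,
                                  range_class = range_class),
                             channels = "cb_distance")
  mask <- masks$cb_distance
  idx <- which(mask & upper.tri(mask), arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no pairs available in range class ", range_class)
  sc <- bin_schema("cb_distance")
  pred <- apply(idx, 1, function(p) {
    sc$centers[which.max(restraints$cb_distance[p[1], p[2], ])]
  })
  aa <- strsplit(model$sequence, "")[[1]]
  CB <- atom_coords(model, "CB")
  CB[aa == "G", ] <- atom_coords(model, "CA")[aa == "G", ]
  obs <- sqrt(rowSums((CB[idx[, 1], , drop = FALSE] -
                         CB[idx[, 2], , drop = FALSE])^2))
  mean(abs(pred - obs))
}

#' Precision of the top predicted contacts
#'
#' Fraction of the `n` highest-probability predicted long-range contacts
#' (sequence separation > 23) whose native CB (CA for glycine) distance
#' is below 8 A.  When fewer than `n` long-range pairs exist, all are
#' used.
#'
#' @param restraints A `restraint_set` with a `cb_contact` channel.
#' @param native A `protein_model`.
#' @param n Number of top contacts (e.g. `L / 2`); must be positive.
#' @param range_class Separation class of eligible pairs (default
#'   `"long"`).
#' @return Fraction in \[0, 1\].
#' @export
contact_precision <- function(restraints, native, n, range_class = "long") {
  if (n <= 0) stop("n must be positive")
  L <- restraints$L
  prob <- restraints$cb_contact
  if (is.null(prob)) stop("no cb_contact channel")
  sep <- abs(row(prob) - col(prob))
  keep <- upper.tri(prob) & sep > 1
  if (!identical(range_class, "all")) {
    cls <- match(range_class, RANGE_NAMES)
    keep <- keep & !is.na(range_class_of(sep)) & range_class_of(sep) == cls
  }
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no pairs available in range class ", range_class)
  ord <- order(-prob[idx], idx[, 1], idx[, 2])
  take <- idx[ord[seq_len(min(floor(n), nrow(idx)))], , drop = FALSE]
  aa <- strsplit(native$sequence, "")[[1]]
  CB <- atom_coords(native, "CB")
  CB[aa == "G", ] <- atom_coords(native, "CA")[aa == "G", ]
  d <- sqrt(rowSums((CB[take[, 1], , drop = FALSE] -
                       CB[take[, 2], , drop = FALSE])^2))
  mean(d < 8)
}

#' Count steric clashes
#'
#' Number of non-bonded atom pairs closer than
#' `cutoff_ratio * (R_a + R_b)` under the shipped pseudo-atom radii,
#' excluding pairs within 2 covalent bonds.  A lightweight analogue of
#' full-atom clash scoring for the reduced representation.
#'
#' @param model A `protein_model`.
#' @param cutoff_ratio Fraction of the summed radii counting as a clash.
#' @return Integer count.
#' @export
clash_count <- function(model, cutoff_ratio = 0.6) {
  L <- nchar(model$sequence)
  radii <- atom_radii(model)
  keep <- which(radii > 0)
  X <- model$coords[keep, , drop = FALSE]
  r <- radii[keep]
  res <- (keep - 1) %/% 7 + 1
  slot <- (keep - 1) %% 7 + 1
  n <- length(keep)
  cnt <- 0L
  for (a in seq_len(n - 1)) {
    b <- (a + 1):n
    near <- b[abs(res[b] - res[a]) <= 1]
    excl <- near[vapply(near, function(bb)
      vdw_excluded_r(res[a], slot[a], res[bb], slot[bb]), TRUE)]
    d2 <- rowSums((X[b, , drop = FALSE] -
                     matrix(X[a, ], length(b), 3, byrow = TRUE))^2)
    lim <- (cutoff_ratio * (r[a] + r[b]))^2
    hit <- b[d2 < lim]
    cnt <- cnt + length(setdiff(hit, excl))
  }
  cnt
}

## R mirror of the compiled bonded-exclusion rule (path <= 2 bonds)
vdw_excluded_r <- function(ri, si, rj, sj) {
  if (ri > rj) { t <- ri; ri <- rj; rj <- t; t <- si; si <- sj; sj <- t }
  if (ri == rj) {
    a <- min(si, sj); b <- max(si, sj)
    return((a == 1 && b == 2) || (a == 1 && b == 3) || (a == 3 && b == 4) ||
             (a == 3 && b == 6) || (a == 4 && b == 5) || (a == 6 && b == 7) ||
             (a == 2 && b == 3) || (a == 1 && b == 4) || (a == 1 && b == 6) ||
             (a == 4 && b == 6) || (a == 3 && b == 5) || (a == 3 && b == 7))
  }
  if (rj == ri + 1) {
    return((si == 6 && sj %in% c(1, 2, 3)) || (si %in% c(3, 7) && sj == 1))
  }
  FALSE
}
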