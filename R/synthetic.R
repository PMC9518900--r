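## Synthetic fixtures: toy native structures built from ideal torsions,
## and binned restraint sets derived from any native structure with
## controllable sharpness, noise and coverage.  These emulate the output
## of a learned restraint predictor so the folding pipeline is testable
## end to end without one.

## fixed turn/loop torsions (degrees), chosen once so that the flanking
## elements of the toy folds pack back onto each other (see the methods
## vignette for the calibration)
HAIRPIN_TURN <- list(phi = c(-175, 63, -94, 41), psi = c(-174, -110, 56, 56))
BUNDLE_LOOP <- list(phi = c(65, -162, 69, 70), psi = c(99, -20, 163, -64))

#' Specification of one synthetic fixture
#'
#' @param length Number of residues.
#' @param fold_type `"helix"`, `"hairpin"`, `"helix_bundle"` or
#'   `"mixed"`.
#' @param sigma Distance-restraint sharpness (A): the standard deviation
#'   of the Gaussian histogram placed around each true distance.
#' @param sigma_angle Orientation-restraint sharpness (degrees).
#' @param noise Fraction of covered pairs replaced by uninformative
#'   uniform histograms.
#' @param coverage Fraction of pairs that carry real restraints; the rest
#'   are set to the no-interaction pattern.
#' @param jitter Optional torsion jitter (degrees, <= 5) applied to the
#'   ideal native torsions.
#' @param seed Integer seed controlling sequence choice, jitter, noise
#'   and coverage draws.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(length, fold_type = "helix", sigma = 0.5,
                         sigma_angle = 15, noise = 0, coverage = 1,
                         jitter = 0, seed = 0L) {
  if (!fold_type %in% c("helix", "hairpin", "helix_bundle", "mixed"))
    stop("unknown fold_type: ", fold_type)
  if (sigma <= 0) stop("sigma must be positive")
  stopifnot(sigma_angle > 0, noise >= 0, noise <= 1,
            coverage >= 0, coverage <= 1, jitter >= 0, jitter <= 5)
  if (fold_type %in% c("hairpin", "helix_bundle", "mixed") && length < 10)
    stop(fold_type, " fixtures require length >= 10")
  if (fold_type == "helix" && length < 5)
    stop("helix fixtures require length >= 5")
  structure(list(length = as.integer(length), fold_type = fold_type,
                 sigma = sigma, sigma_angle = sigma_angle, noise = noise,
                 coverage = coverage, jitter = jitter,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

toy_sequence <- function(spec) {
  with_seed(spec$seed + 101L, {
    L <- spec$length
    helix_aa <- c("A", "E", "L", "K", "Q", "R", "M")
    strand_aa <- c("V", "I", "T", "Y", "F", "L")
    pick <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]
    seq_parts <- switch(spec$fold_type,
      helix = pick(helix_aa, L),
      hairpin = {
        ns <- (L - 4) %/% 2
        c(pick(strand_aa, ns), c("N", "G", "G", "D"),
          pick(strand_aa, L - ns - 4))
      },
      helix_bundle = {
        nh <- (L - 4) %/% 2
        c(pick(helix_aa, nh), c("G", "G", "S", "G"),
          pick(helix_aa, L - nh - 4))
      },
      mixed = {
        nh <- max(6, (L - 4) %/% 2)
        rest <- L - nh - 4
        ns <- (rest - 4) %/% 2
        c(pick(helix_aa, nh), c("G", "G", "S", "G"),
          pick(strand_aa, ns), c("N", "G", "G", "D"),
          pick(strand_aa, rest - ns - 4))
      },
      stop("unknown fold type: ", spec$fold_type))
    paste(seq_parts, collapse = "")
  })
}

toy_torsions <- function(spec) {
  L <- spec$length
  helix <- c(-57, -47); strand <- c(-120, 120)
  span <- function(n, tors) list(phi = rep(tors[1], n), psi = rep(tors[2], n))
  cat2 <- function(...) {
    parts <- list(...)
    list(phi = unlist(lapply(parts, `[[`, "phi")),
         psi = unlist(lapply(parts, `[[`, "psi")))
  }
  tt <- switch(spec$fold_type,
    helix = span(L, helix),
    hairpin = {
      ns <- (L - 4) %/% 2
      cat2(span(ns, strand), HAIRPIN_TURN, span(L - ns - 4, strand))
    },
    helix_bundle = {
      nh <- (L - 4) %/% 2
      cat2(span(nh, helix), BUNDLE_LOOP, span(L - nh - 4, helix))
    },
    mixed = {
      nh <- max(6, (L - 4) %/% 2)
      rest <- L - nh - 4
      ns <- (rest - 4) %/% 2
      cat2(span(nh, helix), BUNDLE_LOOP, span(ns, strand), HAIRPIN_TURN,
           span(rest - ns - 4, strand))
    })
  if (spec$jitter > 0) {
    tt <- with_seed(spec$seed + 202L, {
      list(phi = tt$phi + runif(L, -spec$jitter, spec$jitter),
           psi = tt$psi + runif(L, -spec$jitter, spec$jitter))
    })
  }
  tt$phi[1] <- TORSION_SENTINEL
  tt$psi[L] <- TORSION_SENTINEL
  tt
}

#' Build a toy native structure
#'
#' Deterministically constructs an ideal-torsion native fold: a straight
#' alpha-helix at (-57, -47), a beta-hairpin (two (-120, 120) strands
#' joined by a fixed 4-residue turn), a two-helix bundle joined by a
#' fixed loop, or a mixed helix + hairpin topology.  The sequence is
#' drawn (seeded) from residue pools matching the local structure, with
#' glycine-rich connectors.
#'
#' @param spec A [fixture_spec()].
#' @return A `protein_model`.
#' @export
make_toy_protein <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  sequence <- toy_sequence(spec)
  tt <- toy_torsions(spec)
  build_coordinates(sequence, tt$phi, tt$psi)
}

## integrate a Gaussian over bins; lower/upper may be +-Inf
gauss_bin_mass <- function(center, sd, lower, upper) {
  pnorm((upper - center) / sd) - pnorm((lower - center) / sd)
}

## wrapped (period 360) Gaussian bin masses over the 24 dihedral bins
wrapped_bin_mass <- function(center, sd, edges) {
  lo <- edges[-length(edges)]; hi <- edges[-1]
  m <- 0
  for (k in -1:1)
    m <- m + (pnorm((hi - center + 360 * k) / sd) -
                pnorm((lo - center + 360 * k) / sd))
  m
}

## reflected (at 0 and 180) Gaussian masses over the planar-angle bins
reflected_bin_mass <- function(center, sd, edges) {
  lo <- edges[-length(edges)]; hi <- edges[-1]
  m <- 0
  for (c0 in c(center, -center, 360 - center))
    m <- m + (pnorm((hi - c0) / sd) - pnorm((lo - c0) / sd))
  m / sum(m)
}

#' Derive a binned restraint set from a native structure
#'
#' For every covered residue pair the true inter-residue geometry of the
#' native model is converted into probability histograms: distances get
#' Gaussian histograms of width `sigma` discretized into the 38-bin
#' schema (mass beyond 20 A collected in the final bin), orientations get
#' wrapped Gaussians of width `sigma_angle` over the 15-degree bins, and
#' contacts get `P(d < 8 A)` under the same Gaussian.  A fraction
#' `noise` of covered pairs is replaced by uniform histograms, and a
#' fraction `1 - coverage` of pairs carries the no-interaction pattern.
#' Pairs whose native CB distance is >= 20 A, and orientation entries
#' involving glycine, are always no-interaction.  Deterministic per seed.
#'
#' @param native A `protein_model`.
#' @param spec A [fixture_spec()] (its `length` must match the model).
#' @return A [restraint_set()] with all seven channels.
#' @export
restraints_from_structure <- function(native, spec) {
  stopifnot(inherits(native, "protein_model"), inherits(spec, "fixture_spec"))
  L <- nchar(native$sequence)
  if (spec$sigma <= 0) stop("sigma must be positive")
  if (L != spec$length) stop("spec length does not match the native model")
  aa <- strsplit(native$sequence, "")[[1]]
  CB <- atom_coords(native, "CB")   # CA for glycine rows
  gly <- aa == "G"
  CB[gly, ] <- atom_coords(native, "CA")[gly, ]
  CA <- atom_coords(native, "CA")
  N <- atom_coords(native, "N")

  dmat <- function(X) {
    d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
    sqrt(pmax(d2, 0))
  }
  Dcb <- dmat(CB); Dca <- dmat(CA)

  sc_d <- bin_schema("cb_distance")
  sc_o <- bin_schema("omega")
  sc_p <- bin_schema("phi_angle")
  edges_d <- sc_d$edges
  edges_o <- sc_o$edges
  edges_p <- sc_p$edges

  cbd <- array(0, c(L, L, 38)); cad <- array(0, c(L, L, 38))
  om <- array(0, c(L, L, 25)); th <- array(0, c(L, L, 25))
  ph <- array(0, c(L, L, 13))
  cbc <- matrix(0, L, L); cac <- matrix(0, L, L)
  ## default: no-interaction pattern everywhere
  cbd[, , 38] <- 1; cad[, , 38] <- 1
  om[, , 25] <- 1; th[, , 25] <- 1; ph[, , 13] <- 1

  pairs <- which(upper.tri(diag(L)) &
                   abs(row(diag(L)) - col(diag(L))) > 1, arr.ind = TRUE)
  draws <- with_seed(spec$seed + 303L, {
    list(cov = runif(nrow(pairs)) < spec$coverage,
         noi = runif(nrow(pairs)) < spec$noise)
  })

  dihe_rows <- function(A, B, C, D) dihedral_points(A, B, C, D)

  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!draws$cov[r]) next
    if (draws$noi[r]) {
      cbd[i, j, ] <- 1 / 38; cbd[j, i, ] <- 1 / 38
      cad[i, j, ] <- 1 / 38; cad[j, i, ] <- 1 / 38
      if (!gly[i] && !gly[j]) {
        om[i, j, ] <- 1 / 25; om[j, i, ] <- 1 / 25
        th[i, j, ] <- 1 / 25; th[j, i, ] <- 1 / 25
        ph[i, j, ] <- 1 / 13; ph[j, i, ] <- 1 / 13
      }
      cbc[i, j] <- 0.5; cbc[j, i] <- 0.5
      cac[i, j] <- 0.5; cac[j, i] <- 0.5
      next
    }
    hb <- gauss_bin_mass(Dcb[i, j], spec$sigma, edges_d[-39], edges_d[-1])
    cbd[i, j, ] <- hb; cbd[j, i, ] <- hb
    ha <- gauss_bin_mass(Dca[i, j], spec$sigma, edges_d[-39], edges_d[-1])
    cad[i, j, ] <- ha; cad[j, i, ] <- ha
    cbc[i, j] <- cbc[j, i] <- pnorm((8 - Dcb[i, j]) / spec$sigma)
    cac[i, j] <- cac[j, i] <- pnorm((8 - Dca[i, j]) / spec$sigma)
    if (Dcb[i, j] < 20 && !gly[i] && !gly[j]) {
      ## omega: CA(i)-CB(i)-CB(j)-CA(j), symmetric
      o <- dihe_rows(CA[i, ], CB[i, ], CB[j, ], CA[j, ])
      m <- wrapped_bin_mass(o, spec$sigma_angle, edges_o)
      om[i, j, ] <- c(m, 0); om[j, i, ] <- c(m, 0)
      ## theta: N-CA-CB(i) -> CB(j), directed
      t_ij <- dihe_rows(N[i, ], CA[i, ], CB[i, ], CB[j, ])
      t_ji <- dihe_rows(N[j, ], CA[j, ], CB[j, ], CB[i, ])
      th[i, j, ] <- c(wrapped_bin_mass(t_ij, spec$sigma_angle, edges_o), 0)
      th[j, i, ] <- c(wrapped_bin_mass(t_ji, spec$sigma_angle, edges_o), 0)
      ## phi: planar angle CA(i)-CB(i)-CB(j), directed
      ang_ij <- angle_points(CA[i, ], CB[i, ], CB[j, ])
      ang_ji <- angle_points(CA[j, ], CB[j, ], CB[i, ])
      ph[i, j, ] <- c(reflected_bin_mass(ang_ij, spec$sigma_angle, edges_p), 0)
      ph[j, i, ] <- c(reflected_bin_mass(ang_ji, spec$sigma_angle, edges_p), 0)
    }
  }
  restraint_set(L, cb_distance = cbd, ca_distance = cad, cb_contact = cbc,
                ca_contact = cac, omega = om, theta = th, phi_angle = ph)
}

angle_points <- function(A, B, C) {
  u <- A - B; v <- C - B
  c0 <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(c0, -1), 1)) * 180 / pi
}

#' Standard synthetic fixture suite
#'
#' The fixed 10-fixture suite used by the fold-recovery experiments:
#' lengths 30-60 spanning all four fold types, with noise-free restraints
#' (`sigma = 0.5` A, full coverage) by default.
#'
#' @param seed Base seed; fixture `k` uses `seed + k`.
#' @param sigma,noise,coverage Overrides applied to every fixture.
#' @return List of `fixture_spec` objects.
#' @export
standard_fixture_suite <- function(seed = 0L, sigma = 0.5, noise = 0,
                                   coverage = 1) {
  layout <- list(
    list(30, "helix"), list(34, "hairpin"), list(36, "helix"),
    list(40, "helix_bundle"), list(44, "hairpin"), list(46, "mixed"),
    list(50, "helix_bundle"), list(54, "helix"), list(56, "mixed"),
    list(60, "helix_bundle"))
  lapply(seq_along(layout), function(k)
    fixture_spec(layout[[k]][[1]], layout[[k]][[2]], sigma = sigma,
                 noise = noise, coverage = coverage,
                 seed = as.integer(seed + k)))
}

#' Hairpin fixture suite
#'
#' Beta-hairpin fixtures of graded lengths used by the orientation-
#' synergy experiment.
#'
#' @param seed Base seed.
#' @param n Number of fixtures.
#' @param sigma Distance sharpness (A).
#' @return List of `fixture_spec` objects.
#' @export
hairpin_fixture_suite <- function(seed = 0L, n = 8, sigma = 0.5) {
  lens <- seq(20, by = 4, length.out = n)
  lapply(seq_len(n), function(k)
    fixture_spec(lens[k], "hairpin", sigma = sigma,
                 seed = as.integer(seed + 100 + k)))
}
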