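## Composite folding energy: seven restraint terms (range-resolved
## weights) plus generic hydrogen-bond, van der Waals and torsion terms,
## with analytic gradients with respect to the backbone torsions.

#' Named weight vector for the composite energy
#'
#' The energy carries 24 weights: one per restraint channel and
#' sequence-separation range class (7 channels x short/medium/long) plus
#' the three generic terms (`hb`, `vdw`, `tor`).
#'
#' @param ... Named scalar overrides, e.g. `cb_distance.long = 4`.
#' @param base Starting vector; defaults to [default_weights()].
#' @return Named numeric vector of length 24, class `weight_vector`.
#' @export
fold_weights <- function(..., base = default_weights()) {
  w <- base
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), WEIGHT_NAMES)
    if (length(bad)) stop("unknown weight name(s): ", paste(bad, collapse = ", "))
    w[names(over)] <- unlist(over)
  }
  validate_weights(w)
  w
}

validate_weights <- function(w) {
  if (length(w) != 24 || !identical(names(w), WEIGHT_NAMES))
    stop("weight vector must carry the 24 named entries")
  if (any(w < 0) || any(w > 25))
    stop("weights must lie in [0, 25]")
  invisible(w)
}

#' Default energy weights
#'
#' Author-set defaults balancing the restraint channels against the
#' generic terms, validated on the synthetic fold-recovery suite; the
#' methods vignette discusses the choice.  [optimize_weights()]
#' re-derives weights for a new restraint source from training fixtures.
#'
#' @return Named numeric vector of length 24.
#' @export
default_weights <- function() {
  w <- c(
    cb_distance.short = 3.0, cb_distance.medium = 3.0, cb_distance.long = 4.0,
    ca_distance.short = 2.0, ca_distance.medium = 2.0, ca_distance.long = 2.5,
    cb_contact.short = 0.5, cb_contact.medium = 0.5, cb_contact.long = 1.0,
    ca_contact.short = 0.5, ca_contact.medium = 0.5, ca_contact.long = 1.0,
    omega.short = 1.0, omega.medium = 1.0, omega.long = 1.5,
    theta.short = 1.0, theta.medium = 1.0, theta.long = 1.5,
    phi_angle.short = 0.5, phi_angle.medium = 0.5, phi_angle.long = 1.0,
    hb = 0.5, vdw = 1.0, tor = 0.3)
  w[WEIGHT_NAMES]
}

## ---- compiled-evaluator payload builders ---------------------------------

seq_info <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  list(aa = aa, L = length(aa), is_gly = as.integer(aa == "G"),
       sc_dist = unname(SC_DIST[aa]))
}

cpp_channel_payload <- function(potentials) {
  channels <- list()
  for (ci in seq_along(CHANNEL_NAMES)) {
    ch <- CHANNEL_NAMES[ci]
    e <- potentials[[ch]]
    if (is.null(e)) next
    slot <- (ci - 1L) * 3L + e$class - 1L
    entry <- list(type = ch,
                  pairs = cbind(e$pairs[, 1] - 1L, e$pairs[, 2] - 1L),
                  slot = as.integer(slot))
    if (is_contact_kind(ch)) {
      entry$p <- e$p; entry$d_b <- e$d_b; entry$w_sw <- e$w_sw
    } else if (bin_schema(ch)$periodic) {
      entry$C <- e$C; entry$t0 <- e$t0; entry$h <- e$h
    } else {
      entry$Y <- e$Y; entry$M <- e$M; entry$t0 <- e$t0; entry$h <- e$h
      entry$rep_slope <- e$rep_slope; entry$cap_width <- e$cap_width
    }
    channels[[length(channels) + 1L]] <- entry
  }
  channels
}

cpp_generic_payload <- function(info, generic_on = c(hb = TRUE, vdw = TRUE,
                                                     tor = TRUE)) {
  L <- info$L
  radii <- rep(ATOM_RADII[ATOM_NAMES], L)
  radii[(seq_len(L) - 1) * 7 + 5] <- SC_RADII[info$aa]
  radii[(which(info$aa == "G") - 1) * 7 + 4] <- 0
  radii[2] <- 0  # residue 1 has no amide H
  list(vdw_on = isTRUE(generic_on[["vdw"]]),
       hb_on = isTRUE(generic_on[["hb"]]),
       tor_on = isTRUE(generic_on[["tor"]]),
       radii = unname(radii), vdw_sigma = 0.85,
       tor_coef = unname(torsion_table_coefficients()),
       tor_table = torsion_table_index(info$aa),
       tor_t0 = -172.5 * pi / 180, tor_h = 15 * pi / 180)
}

torsions_to_radians <- function(model) {
  L <- nchar(model$sequence)
  phir <- model$phi * pi / 180
  psir <- model$psi * pi / 180
  phir[1] <- 0
  psir[L] <- 0
  list(phi = phir, psi = psir)
}

eval_energy_cpp <- function(sequence, phi_rad, psi_rad, potentials, weights,
                            generic_on = c(hb = TRUE, vdw = TRUE, tor = TRUE),
                            want_grad = FALSE, coords = NULL) {
  info <- seq_info(sequence)
  channels <- if (is.null(potentials)) list() else
    cpp_channel_payload(potentials)
  if (!is.null(potentials) && !is.null(potentials$L) &&
      potentials$L != info$L)
    stop("potentials were fitted for a different sequence length")
  generic <- cpp_generic_payload(info, generic_on)
  cpp_energy(phi_rad, psi_rad, info$is_gly, info$sc_dist, channels,
             unname(weights), generic, want_grad, coords)
}

## ---- exported operations -------------------------------------------------

#' Total composite energy with per-term breakdown
#'
#' Evaluates the full energy
#' `E = sum_t w_t * E_t` over the seven restraint terms (split by
#' sequence-separation range class) and the three generic terms, at the
#' model's torsion angles under ideal covalent geometry.
#'
#' @param model A `protein_model`.
#' @param potentials A `spline_potential_set` from [fit_splines()], or
#'   `NULL` for the generic terms alone.
#' @param weights A 24-entry weight vector ([fold_weights()]).
#' @return An `energy_breakdown`: list with `total`, `terms` (unweighted
#'   per-slot values, named like the weights) and `weighted` (their
#'   weighted contributions, summing to `total`).
#' @export
total_energy <- function(model, potentials = NULL,
                         weights = default_weights()) {
  validate_weights(weights)
  tr <- torsions_to_radians(model)
  r <- eval_energy_cpp(model$sequence, tr$phi, tr$psi, potentials, weights)
  terms <- setNames(r$terms, WEIGHT_NAMES)
  structure(list(total = r$total, terms = terms,
                 weighted = terms * weights),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> total = %.6f\n", x$total))
  nz <- x$weighted != 0
  if (any(nz)) {
    for (nm in names(x$weighted)[nz])
      cat(sprintf("  %-20s %12.6f (raw %12.6f)\n", nm, x$weighted[nm],
                  x$terms[nm]))
  }
  invisible(x)
}

#' Analytic energy gradient in torsion space
#'
#' Gradient of the composite energy with respect to the defined backbone
#' torsions (radians), computed by chaining each term's Cartesian
#' derivatives through the torsion-axis rule: for an atom `a` downstream
#' of the rotating bond `b`, `d x_a / d chi_b = u_b x (x_a - x_b)`.
#'
#' @inheritParams total_energy
#' @return Numeric vector of length `2L - 2`: derivatives for
#'   `phi_2, ..., phi_L` then `psi_1, ..., psi_{L-1}`, named accordingly.
#' @export
energy_gradient <- function(model, potentials = NULL,
                            weights = default_weights()) {
  validate_weights(weights)
  tr <- torsions_to_radians(model)
  r <- eval_energy_cpp(model$sequence, tr$phi, tr$psi, potentials, weights,
                       want_grad = TRUE)
  L <- nchar(model$sequence)
  g <- c(r$dphi[-1], r$dpsi[-L])
  names(g) <- c(paste0("phi_", 2:L), paste0("psi_", 1:(L - 1)))
  g
}

#' Van der Waals clash penalty
#'
#' Soft quadratic overlap penalty over non-bonded atom pairs:
#' `sum (r_clash - d)^2` for `d < r_clash = sigma * (R_a + R_b)` with
#' `sigma = 0.85`, excluding pairs within 2 covalent bonds; evaluated on
#' the model's stored coordinates.
#'
#' @param model A `protein_model`.
#' @return Scalar penalty (unweighted).
#' @export
vdw_energy <- function(model) {
  tr <- torsions_to_radians(model)
  w <- setNames(rep(0, 24), WEIGHT_NAMES); w["vdw"] <- 1
  r <- eval_energy_cpp(model$sequence, tr$phi, tr$psi, NULL, w,
                       generic_on = c(hb = FALSE, vdw = TRUE, tor = FALSE),
                       coords = model$coords)
  unname(r$terms[23])
}

#' Backbone hydrogen-bond energy
#'
#' Distance-and-angle gated wells over backbone donor (N-H) / acceptor
#' (C=O) pairs: each bond contributes up to -1 when the H...O distance
#' lies in \[1.5, 2.6\] A and the N-H...O angle exceeds 120 degrees,
#' switched smoothly to zero outside; evaluated on the stored
#' coordinates.
#'
#' @param model A `protein_model`.
#' @return Scalar energy (unweighted, non-positive).
#' @export
hbond_energy <- function(model) {
  tr <- torsions_to_radians(model)
  w <- setNames(rep(0, 24), WEIGHT_NAMES); w["hb"] <- 1
  r <- eval_energy_cpp(model$sequence, tr$phi, tr$psi, NULL, w,
                       generic_on = c(hb = TRUE, vdw = FALSE, tor = FALSE),
                       coords = model$coords)
  unname(r$terms[22])
}

#' Backbone torsion-preference energy
#'
#' Sum over residues of the shipped coarse 15 x 15 degree statistical
#' torsion surface ([torsion_tables()]), interpolated with a periodic
#' bicubic spline; separate tables for glycine, proline and the general
#' residue class.
#'
#' @param model A `protein_model`.
#' @param tables Optional replacement tables (named list of 24 x 24
#'   matrices `general`, `gly`, `pro`).
#' @return Scalar energy (unweighted).
#' @export
torsion_energy <- function(model, tables = NULL) {
  tr <- torsions_to_radians(model)
  w <- setNames(rep(0, 24), WEIGHT_NAMES); w["tor"] <- 1
  info <- seq_info(model$sequence)
  generic <- cpp_generic_payload(info, c(hb = FALSE, vdw = FALSE, tor = TRUE))
  if (!is.null(tables)) {
    P <- get_periodic_operator(24)
    generic$tor_coef <- unname(lapply(tables, function(G) P %*% G %*% t(P)))
  }
  r <- cpp_energy(tr$phi, tr$psi, info$is_gly, info$sc_dist, list(),
                  unname(w), generic, FALSE, NULL)
  unname(r$terms[24])
}

## ---- weight optimization -------------------------------------------------

#' Coordinate-descent weight search
#'
#' Optimizes the 24 energy weights (or any lower-dimensional weight
#' vector) by one-at-a-time grid search: a first pass from the given
#' initialization at step 0.25 over \[0, 25\], then `refine_passes`
#' passes at step 0.1 over \[0, 25\], then a final pass perturbing each
#' weight by at most 2 at step 0.02.  A proposed value is accepted only
#' when the objective improves.  Deterministic for a deterministic
#' objective.
#'
#' @param objective Function mapping a weight vector to a scalar score to
#'   maximize (e.g. mean TM-score of folded training fixtures; see
#'   [make_fold_objective()]).
#' @param init Starting weights (default all zero, length 24).
#' @param lower,upper Search range.
#' @param refine_passes Number of step-0.1 passes.
#' @param final_pass Run the final +-2 perturbation pass at step 0.02.
#' @param verbose Print per-pass progress.
#' @return Weight vector of the same length/names as `init` with
#'   attribute `objective` holding the final score.
#' @export
optimize_weights <- function(objective, init = setNames(rep(0, 24),
                                                        WEIGHT_NAMES),
                             lower = 0, upper = 25, refine_passes = 3,
                             final_pass = TRUE, verbose = FALSE) {
  w <- init
  if (length(w) == 0) stop("empty weight vector")
  best <- objective(w)
  if (!is.finite(best)) stop("objective not finite at the initial point")
  sweep_pass <- function(w, best, grid_fn) {
    for (k in seq_along(w)) {
      cand <- grid_fn(w[k])
      cand <- cand[cand >= lower & cand <= upper]
      for (v in cand) {
        if (v == w[k]) next
        wt <- w; wt[k] <- v
        sc <- objective(wt)
        if (sc > best) { best <- sc; w <- wt }
      }
    }
    list(w = w, best = best)
  }
  r <- sweep_pass(w, best, function(cur) seq(lower, upper, by = 0.25))
  if (verbose) message(sprintf("pass 1 (step 0.25): %.6f", r$best))
  for (p in seq_len(refine_passes)) {
    r <- sweep_pass(r$w, r$best, function(cur) seq(lower, upper, by = 0.1))
    if (verbose) message(sprintf("refine pass %d (step 0.1): %.6f", p, r$best))
  }
  if (final_pass) {
    r <- sweep_pass(r$w, r$best,
                    function(cur) seq(cur - 2, cur + 2, by = 0.02))
    if (verbose) message(sprintf("final pass (step 0.02): %.6f", r$best))
  }
  structure(r$w, objective = r$best)
}

#' Folding objective for the weight search
#'
#' Builds the mean-TM-score objective used to train the default weights:
#' each fixture is folded with the candidate weights and scored against
#' its native structure.
#'
#' @param fixtures List of lists with elements `native` (a
#'   `protein_model`) and `restraints` (a `restraint_set`).
#' @param config Folding configuration ([fold_config()]); the search uses
#'   whatever round/step budget it specifies.
#' @return Function mapping a weight vector to mean TM-score.
#' @export
make_fold_objective <- function(fixtures, config = fold_config()) {
  if (length(fixtures) == 0) stop("empty fixture set")
  function(w) {
    config$weights <- w
    mean(vapply(fixtures, function(fx) {
      fr <- fold(fx$native$sequence, fx$restraints, config)
      tm_score(fr$model, fx$native)$tm
    }, numeric(1)))
  }
}
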