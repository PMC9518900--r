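## Binned restraint representation: bin schemas, probability histograms,
## conversion to continuous differentiable potentials, selection policies.

#' Bin schema for a restraint channel
#'
#' Distance channels use 38 bins: one below 2 A, 36 bins of width 0.5 A
#' covering \[2, 20) A, and one at >= 20 A.  Dihedral orientation channels
#' (omega, theta) use 24 bins of width 15 degrees covering (-180, 180\]
#' plus a no-interaction bin; the planar-angle channel (phi_angle) uses 12
#' bins of width 15 degrees over \[0, 180\] plus a no-interaction bin.
#' Contact channels carry a single probability per pair.
#'
#' @param kind One of `"cb_distance"`, `"ca_distance"`, `"omega"`,
#'   `"theta"`, `"phi_angle"`, `"cb_contact"`, `"ca_contact"`.
#' @return A `bin_schema`: list with `kind`, `edges` (bin boundaries; the
#'   open outer bins use -Inf/Inf for distances), `centers` (knot
#'   positions used for spline fitting), `nbins`,
#'   `has_no_interaction_bin`, `periodic`, and `symmetric`.
#' @export
bin_schema <- function(kind) {
  out <- switch(kind,
    cb_distance = ,
    ca_distance = list(
      edges = c(-Inf, seq(2, 20, by = 0.5), Inf),
      centers = seq(1.75, 20.25, by = 0.5),
      nbins = 38L, has_no_interaction_bin = FALSE,
      periodic = FALSE, symmetric = TRUE),
    omega = list(
      edges = seq(-180, 180, by = 15),
      centers = seq(-172.5, 172.5, by = 15),
      nbins = 25L, has_no_interaction_bin = TRUE,
      periodic = TRUE, symmetric = TRUE),
    theta = list(
      edges = seq(-180, 180, by = 15),
      centers = seq(-172.5, 172.5, by = 15),
      nbins = 25L, has_no_interaction_bin = TRUE,
      periodic = TRUE, symmetric = FALSE),
    phi_angle = list(
      edges = seq(0, 180, by = 15),
      centers = seq(7.5, 172.5, by = 15),
      nbins = 13L, has_no_interaction_bin = TRUE,
      periodic = FALSE, symmetric = FALSE),
    cb_contact = ,
    ca_contact = list(
      edges = numeric(0), centers = numeric(0), nbins = 1L,
      has_no_interaction_bin = FALSE, periodic = FALSE, symmetric = TRUE),
    stop("unknown restraint kind: ", kind))
  out$kind <- kind
  structure(out, class = "bin_schema")
}

is_distance_kind <- function(kind) kind %in% c("cb_distance", "ca_distance")
is_contact_kind <- function(kind) kind %in% c("cb_contact", "ca_contact")
is_orientation_kind <- function(kind) kind %in% c("omega", "theta", "phi_angle")

#' Assemble a restraint set from per-channel tensors
#'
#' @param L Sequence length.
#' @param cb_distance,ca_distance `L x L x 38` probability arrays.
#' @param cb_contact,ca_contact `L x L` contact probability matrices.
#' @param omega,theta `L x L x 25` arrays (24 angle bins + trailing
#'   no-interaction bin).
#' @param phi_angle `L x L x 13` array (12 angle bins + no-interaction).
#' @param validate Check normalization and symmetry invariants.
#' @return A `restraint_set`.  Channels may be `NULL` (absent).  The
#'   diagonal and `|i - j| <= 1` entries are ignored by all consumers.
#' @export
restraint_set <- function(L, cb_distance = NULL, ca_distance = NULL,
                          cb_contact = NULL, ca_contact = NULL,
                          omega = NULL, theta = NULL, phi_angle = NULL,
                          validate = TRUE) {
  rs <- structure(list(L = as.integer(L),
                       cb_distance = cb_distance, ca_distance = ca_distance,
                       cb_contact = cb_contact, ca_contact = ca_contact,
                       omega = omega, theta = theta, phi_angle = phi_angle),
                  class = "restraint_set")
  if (validate) validate_restraints(rs)
  rs
}

#' @export
print.restraint_set <- function(x, ...) {
  present <- CHANNEL_NAMES[vapply(CHANNEL_NAMES,
                                  function(ch) !is.null(x[[ch]]), TRUE)]
  cat(sprintf("<restraint_set> L = %d, channels: %s\n", x$L,
              paste(present, collapse = ", ")))
  invisible(x)
}

#' Validate restraint-set invariants
#'
#' Checks tensor shapes, histogram normalization (sum 1 within 1e-5 on
#' off-diagonal pairs), non-negativity, and symmetry of the symmetric
#' channels (distances, contacts, omega) within 1e-6.
#'
#' @param rs A `restraint_set`.
#' @return Invisibly `TRUE`; stops with a channel-named message otherwise.
#' @export
validate_restraints <- function(rs) {
  L <- rs$L
  off <- abs(row(diag(L)) - col(diag(L))) > 1
  for (ch in CHANNEL_NAMES) {
    x <- rs[[ch]]
    if (is.null(x)) next
    sc <- bin_schema(ch)
    if (is_contact_kind(ch)) {
      if (!is.matrix(x) || !all(dim(x) == c(L, L)))
        stop(sprintf("channel %s: expected %d x %d matrix", ch, L, L))
      if (any(x[off] < -1e-12) || any(x[off] > 1 + 1e-9))
        stop(sprintf("channel %s: probabilities outside [0, 1]", ch))
      if (max(abs(x - t(x))) > 1e-6)
        stop(sprintf("channel %s: matrix not symmetric", ch))
    } else {
      if (length(dim(x)) != 3 || !all(dim(x) == c(L, L, sc$nbins)))
        stop(sprintf("channel %s: expected %d x %d x %d array",
                     ch, L, L, sc$nbins))
      if (min(x) < -1e-12)
        stop(sprintf("channel %s: negative probabilities", ch))
      sums <- apply(x, c(1, 2), sum)
      if (max(abs(sums[off] - 1)) > 1e-5)
        stop(sprintf("channel %s: histograms not normalized", ch))
      if (sc$symmetric) {
        asym <- max(abs(x - aperm(x, c(2, 1, 3))))
        if (asym > 1e-6)
          stop(sprintf("channel %s: tensor not symmetric", ch))
      }
    }
  }
  invisible(TRUE)
}

#' Convert a probability histogram to per-bin energies
#'
#' The binned probabilities are turned into a statistical potential by a
#' negative log-ratio against a reference bin,
#' `E_b = -log((p_b + eps) / (p_ref + eps))`: the reference is the final
#' (>= 20 A) bin for distance channels and the no-interaction bin for
#' orientation channels.  Energies are finite for any valid histogram.
#'
#' @param probabilities Numeric vector (one histogram) or a matrix with
#'   one histogram per row, `schema$nbins` columns.
#' @param schema A [bin_schema()].
#' @param eps Regularizer guarding `log(0)`.
#' @return Energies over the spline knot bins (the no-interaction bin of
#'   orientation channels is consumed as the reference and dropped), same
#'   shape convention as the input.
#' @export
histogram_to_energy <- function(probabilities, schema, eps = 1e-4) {
  p <- if (is.matrix(probabilities)) probabilities else rbind(probabilities)
  if (ncol(p) != schema$nbins)
    stop(sprintf("expected %d bins for %s", schema$nbins, schema$kind))
  if (min(p) < -1e-12) stop("negative probabilities")
  if (is_contact_kind(schema$kind))
    stop("contact channels carry plain probabilities, not histograms")
  if (schema$has_no_interaction_bin) {
    pref <- p[, schema$nbins]
    pb <- p[, -schema$nbins, drop = FALSE]
  } else {
    pref <- p[, schema$nbins]
    pb <- p
  }
  E <- -log((pb + eps) / (pref + eps))
  if (is.matrix(probabilities)) E else drop(E)
}

## --- spline machinery -----------------------------------------------------

## Linear operator taking knot values y (rows) to natural-cubic-spline
## second derivatives M, for K uniform knots spaced h.
natural_spline_operator <- function(K, h) {
  if (K < 4) stop("spline fitting requires at least 4 knots")
  A <- diag(4, K - 2)
  A[cbind(1:(K - 3), 2:(K - 2))] <- 1
  A[cbind(2:(K - 2), 1:(K - 3))] <- 1
  ## D maps y (length K) to 6 * second differences / h^2
  D <- matrix(0, K - 2, K)
  for (i in 1:(K - 2))
    D[i, i:(i + 2)] <- c(1, -2, 1) * 6 / h^2
  Op <- matrix(0, K, K)
  Op[2:(K - 1), ] <- solve(A, D)
  Op
}

## Linear operator taking knot values to periodic uniform cubic B-spline
## coefficients (cyclic tridiagonal collocation (1, 4, 1) / 6).
periodic_bspline_operator <- function(n) {
  A <- diag(4 / 6, n)
  idx <- seq_len(n)
  A[cbind(idx, (idx %% n) + 1)] <- 1 / 6
  A[cbind(idx, ((idx - 2) %% n) + 1)] <- 1 / 6
  solve(A)
}

spline_cache <- new.env(parent = emptyenv())

get_natural_operator <- function(K, h) {
  key <- sprintf("nat_%d_%.6f", K, h)
  if (is.null(spline_cache[[key]]))
    spline_cache[[key]] <- natural_spline_operator(K, h)
  spline_cache[[key]]
}

get_periodic_operator <- function(n) {
  key <- sprintf("per_%d", n)
  if (is.null(spline_cache[[key]]))
    spline_cache[[key]] <- periodic_bspline_operator(n)
  spline_cache[[key]]
}

#' Fit continuous differentiable potentials to binned restraints
#'
#' Converts the selected pairs of every channel into spline potentials
#' over knots at the bin centers: natural cubic splines for distance and
#' planar-angle channels and periodic cubic splines for the dihedral
#' channels.  Distance potentials continue linearly below the first knot
#' with a steep repulsive slope (at least `rep_slope` energy units per A)
#' and ease out to slope zero within `cap_width` A beyond the last knot.
#' Contact channels become smooth flat-bottom wells of depth equal to the
#' contact probability, switched to zero over 1 A beyond `d_b`.
#'
#' @param restraints A [restraint_set()].
#' @param selection Selection masks as returned by [select_restraints()];
#'   `NULL` uses the default policy of [default_selection()].
#' @param d_b First-well width (A) of the contact potential.
#' @param eps Regularizer passed to [histogram_to_energy()].
#' @param rep_slope,cap_width Out-of-range behaviour of distance splines.
#' @return A `spline_potential_set`: per channel a list holding the pair
#'   index matrix, per-pair range class, knot layout and coefficient
#'   matrices ready for evaluation.
#' @export
fit_splines <- function(restraints, selection = NULL, d_b = 8,
                        eps = 1e-4, rep_slope = 10, cap_width = 1.75) {
  L <- restraints$L
  if (is.null(selection)) selection <- default_selection(restraints)
  out <- list(L = L, d_b = d_b)
  for (ch in CHANNEL_NAMES) {
    x <- restraints[[ch]]
    mask <- selection[[ch]]
    if (is.null(x) || is.null(mask) || !any(mask)) next
    sc <- bin_schema(ch)
    idx <- which(mask, arr.ind = TRUE)
    ## symmetric channels are stored once per unordered pair
    if (sc$symmetric) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[abs(idx[, 1] - idx[, 2]) > 1, , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    if (nrow(idx) == 0) next
    cls <- range_class_of(idx[, 2] - idx[, 1])
    entry <- list(pairs = idx, class = cls)
    if (is_contact_kind(ch)) {
      entry$p <- x[idx]
      entry$d_b <- d_b
      entry$w_sw <- 1
    } else {
      nb <- sc$nbins
      P <- matrix(x[cbind(rep(idx[, 1], nb), rep(idx[, 2], nb),
                          rep(seq_len(nb), each = nrow(idx)))],
                  nrow(idx), nb)
      Y <- histogram_to_energy(P, sc, eps = eps)
      if (!is.matrix(Y)) Y <- rbind(Y)
      if (sc$periodic) {
        n <- ncol(Y)
        entry$C <- Y %*% t(get_periodic_operator(n))
        entry$t0 <- sc$centers[1] * pi / 180
        entry$h <- 15 * pi / 180
      } else {
        K <- ncol(Y)
        h <- sc$centers[2] - sc$centers[1]
        if (is_distance_kind(ch)) {
          entry$t0 <- sc$centers[1]
          entry$h <- h
        } else {
          entry$t0 <- sc$centers[1] * pi / 180
          entry$h <- h * pi / 180
        }
        entry$Y <- Y
        entry$M <- Y %*% t(get_natural_operator(K, entry$h))
        entry$rep_slope <- rep_slope
        entry$cap_width <- cap_width
      }
    }
    out[[ch]] <- entry
  }
  structure(out, class = "spline_potential_set")
}

#' @export
print.spline_potential_set <- function(x, ...) {
  cat(sprintf("<spline_potential_set> L = %d\n", x$L))
  for (ch in CHANNEL_NAMES)
    if (!is.null(x[[ch]]))
      cat(sprintf("  %-12s %6d pairs\n", ch, nrow(x[[ch]]$pairs)))
  invisible(x)
}

#' Evaluate one fitted pair potential
#'
#' Mainly a testing and inspection hook: evaluates the spline (or contact
#' well) of channel `channel`, pair row `pair`, at coordinates `x`
#' (Angstrom for distances, degrees for angles).
#'
#' @param potentials A `spline_potential_set`.
#' @param channel Channel name.
#' @param pair Row index into `potentials[[channel]]$pairs`.
#' @param x Evaluation points.
#' @param deriv 0 for value, 1 for first derivative (per A or per degree).
#' @return Numeric vector of values or derivatives.
#' @export
spline_evaluate <- function(potentials, channel, pair, x, deriv = 0) {
  e <- potentials[[channel]]
  if (is.null(e)) stop("channel not fitted: ", channel)
  sc <- bin_schema(channel)
  ang <- !is_distance_kind(channel)
  xin <- if (ang) x * pi / 180 else x
  if (is_contact_kind(channel)) {
    p <- e$p[pair]
    sw <- pmin(pmax((x - e$d_b) / e$w_sw, 0), 1)
    s <- sw^2 * (3 - 2 * sw)
    if (deriv == 0) return(-p * (1 - s))
    ds <- 6 * sw * (1 - sw) / e$w_sw
    return(p * ds)
  }
  if (sc$periodic) {
    out <- cpp_eval_per_spline(e$C[rep(pair, length(x)), , drop = FALSE],
                               e$t0, e$h, xin)
  } else {
    out <- cpp_eval_nat_spline(e$Y[rep(pair, length(x)), , drop = FALSE],
                               e$M[rep(pair, length(x)), , drop = FALSE],
                               e$t0, e$h, xin,
                               is_distance_kind(channel),
                               e$rep_slope, e$cap_width)
  }
  v <- out[, deriv + 1]
  if (deriv == 1 && ang) v <- v * pi / 180
  v
}

## --- selection policies ---------------------------------------------------

#' Per-pair confidence scores of a channel
#'
#' Distance channels: summed probability of all bins below 20 A.
#' Orientation channels: one minus the no-interaction probability.
#' Contact channels: the contact probability itself.
#'
#' @param restraints A `restraint_set`.
#' @param channel Channel name.
#' @return L x L matrix of confidences (NA where the channel is absent).
#' @export
restraint_confidence <- function(restraints, channel) {
  x <- restraints[[channel]]
  if (is.null(x)) return(NULL)
  sc <- bin_schema(channel)
  if (is_contact_kind(channel)) return(x)
  if (is_distance_kind(channel)) {
    conf <- apply(x[, , -sc$nbins, drop = FALSE], c(1, 2), sum)
  } else {
    conf <- 1 - x[, , sc$nbins]
  }
  conf
}

#' Select restraints for the folding potential
#'
#' Two policies are supported.  `prob_cutoff` keeps every pair whose
#' confidence exceeds the cutoff (the default policy, cutoff 0.55 for
#' distances).  `top_nl` keeps the `floor(n * L)` highest-confidence
#' pairs within a sequence-separation class, ties broken by (i, j)
#' lexicographic order; when fewer pairs are available all are kept.
#'
#' @param restraints A `restraint_set`.
#' @param policy A list: `list(kind = "prob_cutoff", cutoff = 0.55)` or
#'   `list(kind = "top_nl", n = 20, range_class = "long")` with
#'   `range_class` one of `"short"`, `"medium"`, `"long"`, `"all"`.
#' @param channels Channels the policy applies to (default: the two
#'   distance channels, the usual selection target).
#' @return Named list of logical L x L masks, one per requested channel;
#'   symmetric channels return symmetric masks.
#' @export
select_restraints <- function(restraints, policy,
                              channels = c("cb_distance", "ca_distance")) {
  L <- restraints$L
  sep <- abs(row(diag(L)) - col(diag(L)))
  out <- list()
  for (ch in channels) {
    conf <- restraint_confidence(restraints, ch)
    if (is.null(conf)) next
    sc <- bin_schema(ch)
    mask <- matrix(FALSE, L, L)
    valid <- sep > 1
    if (identical(policy$kind, "prob_cutoff")) {
      mask[valid] <- conf[valid] > policy$cutoff
    } else if (identical(policy$kind, "top_nl")) {
      keep <- valid
      if (!identical(policy$range_class, "all")) {
        cls <- match(policy$range_class, RANGE_NAMES)
        if (is.na(cls)) stop("unknown range class: ", policy$range_class)
        keep <- keep & !is.na(range_class_of(sep)) &
          range_class_of(sep) == cls
      }
      ## rank unordered pairs for symmetric channels, directed otherwise
      idx <- which(keep, arr.ind = TRUE)
      if (sc$symmetric) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      if (nrow(idx)) {
        cf <- conf[idx]
        ord <- order(-cf, idx[, 1], idx[, 2])
        ntake <- min(floor(policy$n * L), nrow(idx))
        take <- idx[ord[seq_len(ntake)], , drop = FALSE]
        mask[take] <- TRUE
        if (sc$symmetric) mask[take[, c(2, 1), drop = FALSE]] <- TRUE
      }
    } else stop("unknown selection policy: ", policy$kind)
    if (sc$symmetric) mask <- mask | t(mask)
    mask[sep <= 1] <- FALSE
    out[[ch]] <- mask
  }
  out
}

#' Default channel selection
#'
#' Distance channels use the probability cutoff policy (`cutoff`,
#' default 0.55); orientation channels keep pairs whose no-interaction
#' probability is below 0.5 (those predicted to interact); contact
#' channels keep pairs with contact probability above 0.5.
#'
#' @param restraints A `restraint_set`.
#' @param cutoff Distance-channel confidence cutoff.
#' @return Named list of logical masks for all present channels.
#' @export
default_selection <- function(restraints, cutoff = 0.55) {
  masks <- select_restraints(restraints,
                             list(kind = "prob_cutoff", cutoff = cutoff),
                             channels = c("cb_distance", "ca_distance"))
  more <- select_restraints(restraints,
                            list(kind = "prob_cutoff", cutoff = 0.5),
                            channels = c("omega", "theta", "phi_angle",
                                         "cb_contact", "ca_contact"))
  c(masks, more)
}
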