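## Torsion-space L-BFGS with Armijo backtracking line search, multi-round
## schedule and lowest-energy model selection.

#' Folding configuration
#'
#' @param weights 24-entry energy weight vector.
#' @param m L-BFGS history size (curvature pairs retained).
#' @param rounds Maximum number of restart rounds (history cleared
#'   between rounds; the torsions continue from the current point).
#' @param steps Maximum quasi-Newton steps per round.
#' @param c1 Armijo sufficient-decrease constant.
#' @param backtrack Step-halving factor of the line search.
#' @param max_backtracks Backtracks before a round is declared converged.
#' @param tol_e Energy-change convergence tolerance (5 consecutive steps).
#' @param tol_g Infinity-norm gradient convergence tolerance.
#' @param conv_window Consecutive small-|dE| steps required to converge.
#' @param select_cutoff Distance-channel confidence cutoff of the default
#'   selection policy.
#' @param selection Optional explicit selection policy list (see
#'   [select_restraints()]); overrides `select_cutoff` for the distance
#'   channels when given.
#' @param channels Channels evaluated (default: all present).
#' @param generic_on Named logical vector switching the generic terms.
#' @param d_b Contact-potential first-well width (A).
#' @param init Initialization mode: `"random"`, `"extended"`,
#'   `"ss_guess"` or `"provided"`.
#' @param init_torsions List with `phi`/`psi` (degrees) for
#'   `init = "provided"`.
#' @param ss Optional secondary-structure string (H/E/C) for
#'   `init = "ss_guess"`.
#' @param seed Integer seed; the only entropy source of a fold.
#' @return A `fold_config` list.
#' @export
fold_config <- function(weights = default_weights(), m = 256L,
                        rounds = 10L, steps = 2000L, c1 = 1e-4,
                        backtrack = 0.5, max_backtracks = 30L,
                        tol_e = 1e-6, tol_g = 1e-6, conv_window = 5L,
                        select_cutoff = 0.55, selection = NULL,
                        channels = CHANNEL_NAMES,
                        generic_on = c(hb = TRUE, vdw = TRUE, tor = TRUE),
                        d_b = 8, init = "random", init_torsions = NULL,
                        ss = NULL, seed = 0L) {
  structure(list(weights = weights, m = as.integer(m),
                 rounds = as.integer(rounds), steps = as.integer(steps),
                 c1 = c1, backtrack = backtrack,
                 max_backtracks = as.integer(max_backtracks),
                 tol_e = tol_e, tol_g = tol_g,
                 conv_window = as.integer(conv_window),
                 select_cutoff = select_cutoff, selection = selection,
                 channels = channels, generic_on = generic_on, d_b = d_b,
                 init = init, init_torsions = init_torsions, ss = ss,
                 seed = as.integer(seed)),
            class = "fold_config")
}

#' L-BFGS search direction by the two-loop recursion
#'
#' Computes `d = -H^{-1} g` from the stored curvature pairs, with the
#' initial inverse Hessian `gamma * I` where
#' `gamma = s'y / y'y` of the most recent pair (identity when the history
#' is empty).  Falls back to steepest descent if the result is not a
#' descent direction.
#'
#' @param state List with `g` (current gradient) and histories `S`, `Y`
#'   (lists of step / gradient-change vectors, oldest first) and `rho`
#'   (numeric vector `1 / (y's)`).
#' @return Search direction vector.
#' @export
lbfgs_direction <- function(state) {
  g <- state$g
  if (any(!is.finite(g))) stop("non-finite gradient")
  k <- length(state$S)
  if (k == 0) return(-g)
  S <- matrix(unlist(state$S), length(g), k)
  Y <- matrix(unlist(state$Y), length(g), k)
  d <- cpp_lbfgs_direction(g, S, Y, state$rho, seq_len(k) - 1L)
  if (sum(g * d) >= 0) d <- -g
  d
}

#' Armijo backtracking line search
#'
#' Starting from `alpha0`, halves the step until the sufficient-decrease
#' condition `E(x + alpha d) <= E(x) + c1 * alpha * g'd` holds; gives up
#' (returning `alpha = 0`) after `max_backtracks` halvings.
#'
#' @param energy_fn Function of `x` returning the scalar energy.
#' @param x Current point.
#' @param d Descent direction (`g'd < 0` required).
#' @param grad Gradient at `x`.
#' @param alpha0 Initial trial step.
#' @param E0 Optional energy at `x` (avoids one evaluation).
#' @param c1,backtrack,max_backtracks See [fold_config()].
#' @return List with `alpha` (0 on failure), `E` (energy at the accepted
#'   point) and `evals` (number of energy evaluations).
#' @export
armijo_line_search <- function(energy_fn, x, d, grad, alpha0 = 1,
                               E0 = NULL, c1 = 1e-4, backtrack = 0.5,
                               max_backtracks = 30L) {
  gd <- sum(grad * d)
  if (!is.finite(gd) || gd >= 0)
    stop("line search requires a descent direction (g'd < 0)")
  if (is.null(E0)) E0 <- energy_fn(x)
  alpha <- alpha0
  evals <- 0L
  for (k in seq_len(max_backtracks + 1L)) {
    Et <- energy_fn(x + alpha * d)
    evals <- evals + 1L
    if (is.finite(Et) && Et <= E0 + c1 * alpha * gd)
      return(list(alpha = alpha, E = Et, evals = evals))
    alpha <- alpha * backtrack
  }
  list(alpha = 0, E = E0, evals = evals)
}

#' Initial backbone torsions
#'
#' Documented initializer standing in for a learned torsion predictor:
#' `"provided"` returns the given torsions verbatim; `"extended"` sets
#' every residue to (-120, 120); `"ss_guess"` draws per-residue angles
#' around helix (-57, -47) or strand (-120, 130) means (sd 10 degrees)
#' according to an H/E/C string, coil residues falling back to a random
#' basin; `"random"` draws uniformly within the allowed Ramachandran
#' basins.  All stochastic modes are fully determined by `seed`.
#'
#' @param sequence Amino-acid string.
#' @param mode One of `"provided"`, `"extended"`, `"ss_guess"`,
#'   `"random"`.
#' @param seed Integer seed.
#' @param torsions List with `phi`, `psi` (degrees) for `"provided"`.
#' @param ss Secondary-structure string for `"ss_guess"`.
#' @return List with `phi`, `psi` in degrees (sentinels at the undefined
#'   first phi / last psi).
#' @export
initialize_torsions <- function(sequence, mode = "random", seed = 0L,
                                torsions = NULL, ss = NULL) {
  sequence <- validate_sequence(sequence)
  L <- nchar(sequence)
  out <- switch(mode,
    provided = {
      if (is.null(torsions) || length(torsions$phi) != L ||
          length(torsions$psi) != L)
        stop("provided torsions must match the sequence length")
      list(phi = torsions$phi, psi = torsions$psi)
    },
    extended = list(phi = rep(-120, L), psi = rep(120, L)),
    ss_guess = with_seed(seed, {
      if (is.null(ss)) ss <- strrep("C", L)
      if (nchar(ss) != L) stop("secondary-structure string length mismatch")
      s <- strsplit(toupper(ss), "")[[1]]
      phi <- numeric(L); psi <- numeric(L)
      for (i in seq_len(L)) {
        if (s[i] == "H") {
          phi[i] <- rnorm(1, -57, 10); psi[i] <- rnorm(1, -47, 10)
        } else if (s[i] == "E") {
          phi[i] <- rnorm(1, -120, 10); psi[i] <- rnorm(1, 130, 10)
        } else {
          b <- sample.int(2, 1)
          if (b == 1) { phi[i] <- runif(1, -100, -40); psi[i] <- runif(1, -70, -10) }
          else { phi[i] <- runif(1, -150, -90); psi[i] <- runif(1, 100, 170) }
        }
      }
      list(phi = wrap_angle(phi), psi = wrap_angle(psi))
    }),
    random = with_seed(seed, {
      phi <- numeric(L); psi <- numeric(L)
      for (i in seq_len(L)) {
        b <- sample.int(2, 1)
        if (b == 1) { phi[i] <- runif(1, -100, -40); psi[i] <- runif(1, -70, -10) }
        else { phi[i] <- runif(1, -150, -90); psi[i] <- runif(1, 100, 170) }
      }
      list(phi = phi, psi = psi)
    }),
    stop("unknown initialization mode: ", mode))
  out$phi[1] <- TORSION_SENTINEL
  out$psi[L] <- TORSION_SENTINEL
  out
}

## pack/unpack the 2L-2 optimization vector (radians)
pack_x <- function(phi_rad, psi_rad, L) c(phi_rad[-1], psi_rad[-L])
unpack_x <- function(x, L) {
  list(phi = c(0, x[1:(L - 1)]), psi = c(x[L:(2 * L - 2)], 0))
}

#' Fold a sequence against a restraint set
#'
#' Runs up to `rounds` restart rounds of at most `steps` L-BFGS steps
#' each over the `2L - 2` defined backbone torsions.  A round ends when
#' the energy change stays below `tol_e` for `conv_window` consecutive
#' steps, the gradient infinity norm falls below `tol_g`, or the line
#' search fails.  The curvature history is cleared between rounds; the
#' first round starts from the configured initialization and every later
#' round from a fresh seeded draw (seed + round - 1), so the restart
#' schedule doubles as a deterministic multi-start.  The returned model
#' is the lowest-energy conformation over all accepted steps of all
#' rounds.  Fully deterministic given `config$seed`.
#'
#' @param sequence Amino-acid string (or a single-record FASTA path via
#'   [read_fasta()]).
#' @param restraints A [restraint_set()].
#' @param config A [fold_config()].
#' @return A `fold_result`: list with `model` (lowest-energy
#'   `protein_model`), `energy` (its [total_energy()] breakdown),
#'   `trajectory` (data frame `round, step, energy, grad_inf, alpha`, one
#'   row per accepted step), `initial` (starting torsions) and
#'   `termination` (per-round reason strings).
#' @export
fold <- function(sequence, restraints, config = fold_config()) {
  sequence <- validate_sequence(sequence)
  L <- nchar(sequence)
  if (!inherits(restraints, "restraint_set"))
    stop("restraints must be a restraint_set")
  if (restraints$L != L)
    stop(sprintf("restraint set is for L = %d, sequence has L = %d",
                 restraints$L, L))
  validate_weights(config$weights)

  selection <- default_selection(restraints, cutoff = config$select_cutoff)
  if (!is.null(config$selection)) {
    override <- select_restraints(restraints, config$selection)
    selection[names(override)] <- override
  }
  selection <- selection[intersect(names(selection), config$channels)]
  potentials <- fit_splines(restraints, selection, d_b = config$d_b)

  info <- seq_info(sequence)
  channels <- cpp_channel_payload(potentials)
  generic <- cpp_generic_payload(info, config$generic_on)
  w <- unname(config$weights)

  ctx <- cpp_make_context(info$is_gly, info$sc_dist, channels, w, generic)
  efun <- function(x) {
    t <- unpack_x(x, L)
    cpp_energy_ctx(ctx, t$phi, t$psi, FALSE)$total
  }
  egfun <- function(x) {
    t <- unpack_x(x, L)
    r <- cpp_energy_ctx(ctx, t$phi, t$psi, TRUE)
    list(E = r$total, g = c(r$dphi[-1], r$dpsi[-L]))
  }

  init <- initialize_torsions(sequence, config$init, config$seed,
                              torsions = config$init_torsions,
                              ss = config$ss)
  phir <- init$phi * pi / 180; phir[1] <- 0
  psir <- init$psi * pi / 180; psir[L] <- 0
  x <- pack_x(phir, psir, L)

  nv <- 2L * L - 2L
  traj <- matrix(0, 512, 5)
  ntraj <- 0L
  best_x <- x
  cur <- egfun(x)
  best_E <- cur$E
  termination <- character(0)
  Sbuf <- matrix(0, nv, config$m)
  Ybuf <- matrix(0, nv, config$m)
  rhobuf <- numeric(config$m)

  for (round in seq_len(config$rounds)) {
    if (round > 1) {
      ri <- initialize_torsions(sequence, "random",
                                config$seed + round - 1L)
      x <- pack_x(ri$phi * pi / 180, ri$psi * pi / 180, L)
      cur <- egfun(x)
      if (cur$E < best_E) { best_E <- cur$E; best_x <- x }
    }
    nhist <- 0L          # pairs stored
    head <- 0L           # column of the newest pair
    small_de <- 0L
    reason <- "max_steps"
    for (step in seq_len(config$steps)) {
      if (max(abs(cur$g)) < config$tol_g) { reason <- "grad_tol"; break }
      if (nhist == 0L) {
        d <- -cur$g
      } else {
        ord <- if (nhist < config$m) seq_len(nhist) - 1L else
          c(head + seq_len(config$m - head), seq_len(head)) - 1L
        d <- cpp_lbfgs_direction(cur$g, Sbuf, Ybuf, rhobuf, ord)
        if (sum(cur$g * d) >= 0) d <- -cur$g
      }
      ls <- armijo_line_search(efun, x, d, cur$g, alpha0 = 1, E0 = cur$E,
                               c1 = config$c1, backtrack = config$backtrack,
                               max_backtracks = config$max_backtracks)
      if (ls$alpha == 0) { reason <- "line_search"; break }
      s_vec <- ls$alpha * d
      x <- wrap_rad(x + s_vec)
      nxt <- egfun(x)
      y_vec <- nxt$g - cur$g
      ys <- sum(y_vec * s_vec)
      if (ys > 1e-12) {
        head <- if (nhist < config$m) nhist + 1L else head %% config$m + 1L
        Sbuf[, head] <- s_vec
        Ybuf[, head] <- y_vec
        rhobuf[head] <- 1 / ys
        nhist <- min(nhist + 1L, config$m)
      }
      dE <- cur$E - nxt$E
      cur <- nxt
      ntraj <- ntraj + 1L
      if (ntraj > nrow(traj))
        traj <- rbind(traj, matrix(0, nrow(traj), 5))
      traj[ntraj, ] <- c(round, step, cur$E, max(abs(cur$g)), ls$alpha)
      if (cur$E < best_E) { best_E <- cur$E; best_x <- x }
      if (abs(dE) < config$tol_e) {
        small_de <- small_de + 1L
        if (small_de >= config$conv_window) { reason <- "energy_tol"; break }
      } else small_de <- 0L
    }
    termination <- c(termination, reason)
  }

  tmat <- traj[seq_len(ntraj), , drop = FALSE]
  trajectory <- data.frame(round = as.integer(tmat[, 1]),
                           step = as.integer(tmat[, 2]),
                           energy = tmat[, 3], grad_inf = tmat[, 4],
                           alpha = tmat[, 5])

  tb <- unpack_x(best_x, L)
  phi_deg <- wrap_angle(tb$phi * 180 / pi)
  psi_deg <- wrap_angle(tb$psi * 180 / pi)
  phi_deg[1] <- TORSION_SENTINEL
  psi_deg[L] <- TORSION_SENTINEL
  model <- build_coordinates(sequence, phi_deg, psi_deg)
  structure(list(model = model,
                 energy = total_energy(model, potentials, config$weights),
                 trajectory = trajectory,
                 initial = init,
                 termination = termination,
                 config = config),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %d residues, best energy %.4f, %d accepted steps (%d rounds: %s)\n",
              nchar(x$model$sequence), x$energy$total,
              nrow(x$trajectory), length(x$termination),
              paste(x$termination, collapse = ", ")))
  invisible(x)
}
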