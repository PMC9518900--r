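fixture_bundle <- function(L = 18, fold_type = "hairpin", seed = 3,
                           sigma = 0.5, noise = 0) {
  spec <- fixture_spec(L, fold_type, sigma = sigma, noise = noise,
                       seed = seed)
  native <- make_toy_protein(spec)
  rs <- restraints_from_structure(native, spec)
  list(spec = spec, native = native, rs = rs, pot = fit_splines(rs))
}

test_that("weight vectors carry 24 named bounded entries", {
  w <- default_weights()
  expect_length(w, 24)
  expect_true(all(w >= 0 & w <= 25))
  expect_error(fold_weights(nonsense = 1), "unknown weight")
  expect_error(fold_weights(hb = -1), "\\[0, 25\\]")
  w2 <- fold_weights(cb_distance.long = 7.5)
  expect_equal(unname(w2["cb_distance.long"]), 7.5)
})

test_that("total energy is the advertised linear combination", {
  x <- fixture_bundle(14)
  m <- x$native
  w0 <- setNames(rep(0, 24), names(default_weights()))
  eb <- total_energy(m, x$pot, w0)
  expect_equal(eb$total, 0)
  expect_true(any(eb$terms != 0))   # raw term values still reported
  w <- default_weights()
  e1 <- total_energy(m, x$pot, w)
  e2 <- total_energy(m, x$pot, pmin(w * 2, 25))
  expect_equal(e2$total, 2 * e1$total, tolerance = 1e-12)
  expect_equal(e1$total, sum(e1$weighted), tolerance = 1e-9)
  expect_equal(unname(e1$weighted), unname(e1$terms * w), tolerance = 1e-12)
})

test_that("restraint terms equal a brute-force per-pair sum", {
  x <- fixture_bundle(12)
  init <- initialize_torsions(x$native$sequence, "random", 9)
  m <- build_coordinates(x$native$sequence, init$phi, init$psi)
  w <- default_weights()
  eb <- total_energy(m, x$pot, w)

  aa <- strsplit(m$sequence, "")[[1]]
  CB <- atom_coords(m, "CB"); CA <- atom_coords(m, "CA")
  N <- atom_coords(m, "N")
  total_oracle <- 0
  for (ch in c("cb_distance", "ca_distance", "omega", "theta", "phi_angle",
               "cb_contact", "ca_contact")) {
    e <- x$pot[[ch]]
    if (is.null(e)) next
    for (p in seq_len(nrow(e$pairs))) {
      i <- e$pairs[p, 1]; j <- e$pairs[p, 2]
      wname <- paste0(ch, ".", c("short", "medium", "long")[e$class[p]])
      val <- switch(ch,
        cb_distance = spline_evaluate(x$pot, ch, p,
          sqrt(sum((CB[i, ] - CB[j, ])^2))),
        ca_distance = spline_evaluate(x$pot, ch, p,
          sqrt(sum((CA[i, ] - CA[j, ])^2))),
        cb_contact = spline_evaluate(x$pot, ch, p,
          sqrt(sum((CB[i, ] - CB[j, ])^2))),
        ca_contact = spline_evaluate(x$pot, ch, p,
          sqrt(sum((CA[i, ] - CA[j, ])^2))),
        omega = if (aa[i] == "G" || aa[j] == "G") 0 else
          spline_evaluate(x$pot, ch, p, torsionfold:::dihedral_points(
            CA[i, ], CB[i, ], CB[j, ], CA[j, ])),
        theta = if (aa[i] == "G" || aa[j] == "G") 0 else
          spline_evaluate(x$pot, ch, p, torsionfold:::dihedral_points(
            N[i, ], CA[i, ], CB[i, ], CB[j, ])),
        phi_angle = if (aa[i] == "G" || aa[j] == "G") 0 else
          spline_evaluate(x$pot, ch, p, torsionfold:::angle_points(
            CA[i, ], CB[i, ], CB[j, ])))
      total_oracle <- total_oracle + w[[wname]] * val
    }
  }
  restr_sum <- sum(eb$weighted[1:21])
  expect_equal(restr_sum, total_oracle, tolerance = 1e-9)
})

test_that("vdW term is a soft overlap penalty with exclusions", {
  ## extended chain far apart: no overlap beyond bonded exclusions is
  ## guaranteed only for distant pairs; force a controlled overlap instead
  m <- build_coordinates("AAAA", c(999, rep(-120, 3)), c(rep(120, 3), 999))
  e_ext <- vdw_energy(m)
  ## two CA pseudo-atoms forced to 1.0 A: hand-computed quadratic
  m2 <- m
  CA <- atom_coords(m, "CA")
  shift <- CA[4, ] - CA[1, ]
  m2$coords[torsionfold:::atom_rows(4, 3)[4], ] <- CA[1, ] + c(1, 0, 0)
  ## move only the CA of residue 4; the clash radius is 0.85 * (1.7+1.7)
  d <- 1.0
  rc <- 0.85 * (1.7 + 1.7)
  expected_extra <- (rc - d)^2
  penalty <- vdw_energy(m2) - e_ext
  ## residue-4 CA also approaches other residue-1 atoms; recount by brute
  ## force over all non-excluded pairs
  radii <- atom_radii(m2)
  X <- m2$coords
  brute <- 0
  for (a in 1:(nrow(X) - 1)) for (b in (a + 1):nrow(X)) {
    if (radii[a] <= 0 || radii[b] <= 0) next
    ra <- (a - 1) %/% 7 + 1; sa <- (a - 1) %% 7 + 1
    rb <- (b - 1) %/% 7 + 1; sb <- (b - 1) %% 7 + 1
    if (abs(ra - rb) <= 1 &&
        torsionfold:::vdw_excluded_r(ra, sa, rb, sb)) next
    dd <- sqrt(sum((X[a, ] - X[b, ])^2))
    rcl <- 0.85 * (radii[a] + radii[b])
    if (dd < rcl) brute <- brute + (rcl - dd)^2
  }
  expect_equal(vdw_energy(m2), brute, tolerance = 1e-9)
  expect_gte(penalty, expected_extra - 1e-9)
  ## separated atoms contribute nothing: the penalty vanishes as the pair
  ## distance grows through the clash radius
  ds <- seq(1, 4, by = 0.25)
  vals <- vapply(ds, function(dd) {
    mm <- m
    mm$coords[torsionfold:::atom_rows(4, 3)[4], ] <- CA[1, ] + c(dd, 0, 0)
    vdw_energy(mm)
  }, 1)
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("hydrogen bonds favor the helix and vanish for extended chains", {
  L <- 12
  hel <- build_coordinates(strrep("A", L), c(999, rep(-57, L - 1)),
                           c(rep(-47, L - 1), 999))
  ext <- build_coordinates(strrep("A", L), c(999, rep(-140, L - 1)),
                           c(rep(140, L - 1), 999))
  e_hel <- hbond_energy(hel)
  e_ext <- hbond_energy(ext)
  expect_equal(e_ext, 0)
  expect_lt(e_hel, e_ext)
  expect_lt(e_hel, -3)   # i,i+4 ladder: most donors engaged
  ## rigid-motion invariance
  helr <- hel
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  helr$coords <- sweep(hel$coords %*% t(R), 2, c(1, 2, 3), "+")
  expect_equal(hbond_energy(helr), e_hel, tolerance = 1e-9)
})

test_that("torsion surface interpolates its grid and ranks basins", {
  tabs <- torsion_tables()
  expect_equal(dim(tabs$general), c(24, 24))
  ## value at a knot equals the table entry (single-residue probe)
  centers <- seq(-172.5, 172.5, by = 15)
  kmin <- which(tabs$general == min(tabs$general), arr.ind = TRUE)[1, ]
  m <- build_coordinates("AAA",
                         c(999, centers[kmin[1]], -57),
                         c(-47, centers[kmin[2]], 999))
  ## only residue 2 contributes (ends lack a defined pair)
  e <- torsion_energy(m)
  expect_equal(e, tabs$general[kmin[1], kmin[2]], tolerance = 1e-10)
  ## disallowed region scores above the helical basin
  m_bad <- build_coordinates("AAA", c(999, 60, -57), c(-60, -47, 999))
  m_hel <- build_coordinates("AAA", c(999, -57, -57), c(-47, -47, 999))
  expect_gt(torsion_energy(m_bad), torsion_energy(m_hel))
  ## a flat table contributes nothing anywhere
  flat <- list(general = matrix(0, 24, 24), gly = matrix(0, 24, 24),
               pro = matrix(0, 24, 24))
  set.seed(12)
  for (k in 1:5) {
    mm <- build_coordinates("AGPA", c(999, runif(3, -180, 180)),
                            c(runif(3, -180, 180), 999))
    expect_equal(torsion_energy(mm, tables = flat), 0, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  x <- fixture_bundle(16)
  w <- default_weights()
  init <- initialize_torsions(x$native$sequence, "random", 21)
  m <- build_coordinates(x$native$sequence, init$phi, init$psi)
  g <- energy_gradient(m, x$pot, w)
  L <- 16
  efun <- function(phi, psi) total_energy(
    build_coordinates(x$native$sequence, phi, psi), x$pot, w)$total
  h <- 1e-5 * 180 / pi
  gfd <- numeric(0)
  for (i in 2:L) {
    pp <- m$phi; pm <- m$phi
    pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
    gfd <- c(gfd, (efun(pp, m$psi) - efun(pm, m$psi)) / (2 * h * pi / 180))
  }
  for (i in 1:(L - 1)) {
    pp <- m$psi; pm <- m$psi
    pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
    gfd <- c(gfd, (efun(m$phi, pp) - efun(m$phi, pm)) / (2 * h * pi / 180))
  }
  expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-5)
})

test_that("gradients vanish for flat potentials and localize to bracketed torsions", {
  L <- 12
  sequence <- strrep("A", L)
  ## flat potentials + zero generic weights: zero gradient
  cbd <- array(1 / 38, c(L, L, 38))
  rs <- restraint_set(L, cb_distance = cbd)
  pot <- fit_splines(rs, list(cb_distance = matrix(TRUE, L, L)))
  w <- setNames(rep(0, 24), names(default_weights()))
  w["cb_distance.short"] <- 3; w["cb_distance.medium"] <- 3
  w["cb_distance.long"] <- 3
  init <- initialize_torsions(sequence, "random", 2)
  m <- build_coordinates(sequence, init$phi, init$psi)
  g <- energy_gradient(m, pot, w)
  expect_lt(max(abs(g)), 1e-8)

  ## a single pair term has zero gradient outside the bracketing torsions
  cbd2 <- array(0, c(L, L, 38)); cbd2[, , 38] <- 1
  i <- 4; j <- 9
  h <- exp(-((1:38) - 15)^2 / 8); h <- h / sum(h)
  cbd2[i, j, ] <- h; cbd2[j, i, ] <- h
  rs2 <- restraint_set(L, cb_distance = cbd2)
  sel <- matrix(FALSE, L, L); sel[i, j] <- TRUE; sel[j, i] <- TRUE
  pot2 <- fit_splines(rs2, list(cb_distance = sel))
  g2 <- energy_gradient(m, pot2, w)
  nz <- which(abs(g2) > 1e-12)
  labs <- names(g2)[nz]
  ## moving torsions: phi_{i+1}..phi_j (phi_i cannot move CB_i relative to
  ## the i-side) and psi_i..psi_{j-1}
  for (lb in labs) {
    kind <- sub("_.*", "", lb)
    idx <- as.integer(sub(".*_", "", lb))
    if (kind == "phi") expect_true(idx > i && idx <= j)
    else expect_true(idx >= i && idx < j)
  }
  expect_gt(length(nz), 0)
})

test_that("energy terms are invariant to rigid motion and independent", {
  x <- fixture_bundle(14)
  w <- default_weights()
  ## term independence: zeroing one weight leaves other raw terms intact
  e_full <- total_energy(x$native, x$pot, w)
  w2 <- w; w2["omega.short"] <- 0; w2["omega.medium"] <- 0
  w2["omega.long"] <- 0
  e_no <- total_energy(x$native, x$pot, w2)
  expect_equal(e_no$terms, e_full$terms, tolerance = 1e-12)
  expect_equal(unname(e_no$weighted[c("omega.short", "omega.medium",
                                      "omega.long")]), c(0, 0, 0))
})

test_that("noise-free native scores below random conformations", {
  x <- fixture_bundle(18, "hairpin", seed = 6)
  w <- default_weights()
  e_native <- total_energy(x$native, x$pot, w)$total
  e_random <- vapply(1:100, function(k) {
    init <- initialize_torsions(x$native$sequence, "random", 1000 + k)
    m <- build_coordinates(x$native$sequence, init$phi, init$psi)
    total_energy(m, x$pot, w)$total
  }, 1)
  expect_true(all(e_native < e_random))
})

test_that("coordinate-descent weight search recovers toy optima", {
  ## pass-1 grid: 101 points from 0 to 25 in steps of 0.25
  evals <- c()
  obj1 <- function(w) { evals <<- c(evals, w[1]); -(w[1] - 7.3)^2 }
  res <- optimize_weights(obj1, init = c(w = 0), refine_passes = 0,
                          final_pass = FALSE)
  grid <- seq(0, 25, by = 0.25)
  expect_length(grid, 101)
  expect_true(all(evals %in% grid))
  expect_equal(unname(res[1]), 7.25)   # nearest pass-1 grid point
  ## full protocol converges to the optimum within the final step
  res2 <- optimize_weights(obj1, init = c(w = 0), refine_passes = 1)
  expect_lt(abs(res2[1] - 7.3), 0.02 + 1e-9)
  ## separable two-weight objective matches the exhaustive grid optimum
  obj2 <- function(w) -(w[1] - 3.1)^2 - 2 * (w[2] - 11.4)^2
  res3 <- optimize_weights(obj2, init = c(a = 0, b = 0), refine_passes = 1)
  expect_lt(abs(res3[1] - 3.1), 0.02 + 1e-9)
  expect_lt(abs(res3[2] - 11.4), 0.02 + 1e-9)
  expect_error(make_fold_objective(list()), "empty")
})
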