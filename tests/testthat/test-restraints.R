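test_that("bin schemas match the published binning", {
  sc <- bin_schema("cb_distance")
  expect_equal(sc$nbins, 38L)
  expect_equal(sc$edges[2], 2)                   # first upper edge
  expect_equal(sc$edges[length(sc$edges) - 1], 20)  # last lower edge
  expect_equal(unique(round(diff(sc$edges[2:38]), 10)), 0.5)
  expect_true(bin_schema("ca_distance")$symmetric)
  for (k in c("omega", "theta"))
    expect_equal(bin_schema(k)$nbins, 25L)       # 360/15 + no-interaction
  expect_equal(bin_schema("phi_angle")$nbins, 13L)
  expect_equal(bin_schema("cb_contact")$nbins, 1L)
  expect_false(bin_schema("theta")$symmetric)
  expect_error(bin_schema("xyz"), "unknown")
})

test_that("histogram-to-energy is the negative log-ratio map", {
  sc <- bin_schema("cb_distance")
  set.seed(10)
  p <- runif(38); p <- p / sum(p)
  E <- histogram_to_energy(p, sc)
  eps <- 1e-4
  E_oracle <- -log((p + eps) / (p[38] + eps))
  expect_equal(E, E_oracle, tolerance = 1e-12)
  ## orientation channels: reference is the no-interaction bin, dropped
  so <- bin_schema("omega")
  q <- runif(25); q <- q / sum(q)
  Eo <- histogram_to_energy(q, so)
  expect_length(Eo, 24)
  expect_equal(Eo, -log((q[1:24] + eps) / (q[25] + eps)), tolerance = 1e-12)
  ## a concentrated bin is the unique minimum
  pk <- rep(1e-6, 38); pk[17] <- 1 - 37e-6
  expect_equal(which.min(histogram_to_energy(pk, sc)), 17L)
  expect_error(histogram_to_energy(c(-0.1, rep(0.1, 37)), sc), "negative")
})

make_small_restraints <- function(L = 16, sigma = 0.5, seed = 3,
                                  fold_type = "hairpin") {
  spec <- fixture_spec(L, fold_type, sigma = sigma, seed = seed)
  native <- make_toy_protein(spec)
  list(spec = spec, native = native,
       rs = restraints_from_structure(native, spec))
}

test_that("fitted splines interpolate, are C1, and dihedrals are periodic", {
  x <- make_small_restraints(20)
  pot <- fit_splines(x$rs)
  sc <- bin_schema("cb_distance")
  e <- pot$cb_distance
  npair <- min(nrow(e$pairs), 10)
  for (p in seq_len(npair)) {
    ## knot interpolation
    vals <- spline_evaluate(pot, "cb_distance", p, sc$centers)
    expect_equal(vals, unname(e$Y[p, ]), tolerance = 1e-10)
    ## C1 by central finite differences at random interior points
    set.seed(p)
    xs <- runif(50, 2.2, 19.8)
    d_ana <- spline_evaluate(pot, "cb_distance", p, xs, deriv = 1)
    h <- 1e-5
    d_fd <- (spline_evaluate(pot, "cb_distance", p, xs + h) -
               spline_evaluate(pot, "cb_distance", p, xs - h)) / (2 * h)
    expect_equal(d_ana, d_fd, tolerance = 1e-6)
  }
  ## natural-spline values match stats::splinefun in the knot range
  p <- 1
  sf <- stats::splinefun(sc$centers, e$Y[p, ], method = "natural")
  xs <- seq(2, 20, by = 0.13)
  expect_equal(spline_evaluate(pot, "cb_distance", p, xs), sf(xs),
               tolerance = 1e-9)
  ## periodic omega spline: value and derivative match at -180/+180
  eo <- pot$omega
  for (p in seq_len(min(nrow(eo$pairs), 10))) {
    expect_equal(spline_evaluate(pot, "omega", p, -180),
                 spline_evaluate(pot, "omega", p, 180), tolerance = 1e-10)
    expect_equal(spline_evaluate(pot, "omega", p, -180, deriv = 1),
                 spline_evaluate(pot, "omega", p, 180, deriv = 1),
                 tolerance = 1e-10)
    ## interpolation at the angular knots
    sco <- bin_schema("omega")
    vals <- spline_evaluate(pot, "omega", p, sco$centers)
    Yo <- histogram_to_energy(
      x$rs$omega[eo$pairs[p, 1], eo$pairs[p, 2], ], sco)
    expect_equal(vals, Yo, tolerance = 1e-10)
  }
})

test_that("uniform histograms give flat potentials", {
  L <- 12
  cbd <- array(1 / 38, c(L, L, 38))
  rs <- restraint_set(L, cb_distance = cbd)
  sel <- list(cb_distance = matrix(TRUE, L, L))
  pot <- fit_splines(rs, sel)
  xs <- seq(2, 20, by = 0.1)
  expect_lt(max(abs(spline_evaluate(pot, "cb_distance", 1, xs, deriv = 1))),
            1e-8)
})

test_that("distance splines extrapolate repulsively below and flat above", {
  x <- make_small_restraints(16)
  pot <- fit_splines(x$rs)
  p <- 1
  ## repulsive wall below the first knot: slope at least 10 units/A
  d1 <- spline_evaluate(pot, "cb_distance", p, c(1.0, 1.5), deriv = 1)
  expect_true(all(d1 <= -10))
  ## beyond 22 A the potential is constant
  v <- spline_evaluate(pot, "cb_distance", p, c(22, 23, 30))
  expect_lt(diff(range(v)), 1e-12)
  expect_equal(spline_evaluate(pot, "cb_distance", p, 25, deriv = 1), 0)
})

test_that("energy shift invariance: constant bin-energy offsets leave the gradient unchanged", {
  x <- make_small_restraints(14)
  pot <- fit_splines(x$rs)
  w <- default_weights()
  init <- initialize_torsions(x$native$sequence, "random", 7)
  m <- build_coordinates(x$native$sequence, init$phi, init$psi)
  g0 <- energy_gradient(m, pot, w)
  pot2 <- pot
  pot2$cb_distance$Y <- pot2$cb_distance$Y + 5.0   # second differences, and
  ## hence the spline curvature coefficients, are unchanged by a shift
  g1 <- energy_gradient(m, pot2, w)
  expect_equal(g0, g1, tolerance = 1e-9)
  e0 <- total_energy(m, pot, w)$terms[["cb_distance.short"]]
  e1 <- total_energy(m, pot2, w)$terms[["cb_distance.short"]]
  expect_gt(abs(e1 - e0), 1)   # the energies themselves do shift
})

test_that("selection policies follow the confidence rules", {
  L <- 30
  set.seed(11)
  cbd <- array(0, c(L, L, 38))
  conf_target <- matrix(runif(L * L), L, L)
  conf_target <- (conf_target + t(conf_target)) / 2
  for (i in 1:L) for (j in 1:L) {
    ## split conf over the sub-20A bins, remainder in the >=20A bin
    cbd[i, j, 10] <- conf_target[i, j]
    cbd[i, j, 38] <- 1 - conf_target[i, j]
  }
  rs <- restraint_set(L, cb_distance = cbd)
  conf <- restraint_confidence(rs, "cb_distance")
  expect_equal(conf[2, 10], conf_target[2, 10], tolerance = 1e-12)

  ## probability cutoff: > c selected, <= c not
  cbd2 <- cbd
  cbd2[1, 10, 10] <- 0.60; cbd2[1, 10, 38] <- 0.40
  cbd2[10, 1, ] <- cbd2[1, 10, ]
  cbd2[1, 12, 10] <- 0.50; cbd2[1, 12, 38] <- 0.50
  cbd2[12, 1, ] <- cbd2[1, 12, ]
  rs2 <- restraint_set(L, cb_distance = cbd2)
  mask <- select_restraints(rs2, list(kind = "prob_cutoff", cutoff = 0.55),
                            "cb_distance")$cb_distance
  expect_true(mask[1, 10])
  expect_false(mask[1, 12])

  ## monotonicity: lower cutoff keeps a superset
  m1 <- select_restraints(rs, list(kind = "prob_cutoff", cutoff = 0.3),
                          "cb_distance")$cb_distance
  m2 <- select_restraints(rs, list(kind = "prob_cutoff", cutoff = 0.6),
                          "cb_distance")$cb_distance
  expect_true(all(m1 | !m2))

  ## all-zero maps select nothing
  rs0 <- restraint_set(L, cb_distance = {
    z <- array(0, c(L, L, 38)); z[, , 38] <- 1; z
  })
  m0 <- select_restraints(rs0, list(kind = "prob_cutoff", cutoff = 0.0),
                          "cb_distance")$cb_distance
  expect_false(any(m0))

  ## top-n*L against a brute-force sort oracle
  mask2 <- select_restraints(rs, list(kind = "top_nl", n = 2,
                                      range_class = "all"),
                             "cb_distance")$cb_distance
  idx <- which(upper.tri(conf) & abs(row(conf) - col(conf)) > 1,
               arr.ind = TRUE)
  ord <- order(-conf[idx], idx[, 1], idx[, 2])
  expected <- idx[ord[1:(2 * L)], ]
  expect_equal(sum(mask2[upper.tri(mask2)]), 2 * L)
  expect_true(all(mask2[expected]))

  ## long-range class has fewer than n*L pairs: all are kept
  mask3 <- select_restraints(rs, list(kind = "top_nl", n = 2,
                                      range_class = "long"),
                             "cb_distance")$cb_distance
  sep <- abs(row(conf) - col(conf))
  expect_equal(sum(mask3[upper.tri(mask3)]), sum(sep > 23 & upper.tri(conf)))
})

test_that("sequence-separation classes partition all pairs", {
  sep <- 2:59
  cls <- torsionfold:::range_class_of(sep)
  expect_false(anyNA(cls))
  expect_equal(unname(table(cls)[["1"]]), sum(sep <= 11))
  expect_true(all(cls[sep > 23] == 3))
  expect_true(all(cls[sep > 11 & sep <= 23] == 2))
  expect_true(is.na(torsionfold:::range_class_of(1)))
})

test_that("restraint sets validate normalization and symmetry", {
  L <- 8
  bad <- array(1 / 38, c(L, L, 38))
  bad[2, 5, ] <- bad[2, 5, ] * 2   # breaks normalization and symmetry
  expect_error(restraint_set(L, cb_distance = bad), "normalized|symmetric")
  neg <- array(1 / 38, c(L, L, 38))
  neg[3, 6, 1] <- -0.1; neg[6, 3, 1] <- -0.1
  expect_error(restraint_set(L, cb_distance = neg), "negative")
})

test_that("DFR files round-trip restraint sets", {
  x <- make_small_restraints(12)
  path <- tempfile(fileext = ".dfr")
  write_dfr(x$rs, path, digits = 10)
  rs2 <- read_dfr(path)
  expect_equal(rs2$L, x$rs$L)
  for (ch in c("cb_distance", "omega", "theta", "phi_angle", "cb_contact"))
    expect_equal(rs2[[ch]], x$rs[[ch]], tolerance = 1e-8)
  ## malformed files are rejected with the channel named
  writeLines(c("#DFR v1 L=5", "#cb_distance 5 12 1", "0 2 0 1"),
             path)
  expect_error(read_dfr(path), "cb_distance")
  writeLines("plain text", path)
  expect_error(read_dfr(path), "not a DFR")
})
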