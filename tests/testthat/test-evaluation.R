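rigid_move <- function(X, seed = 1) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rz <- matrix(c(cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1]), 0,
                 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  sweep(X %*% t(Rz %*% Ry), 2, rnorm(3, sd = 5), "+")
}

test_that("Kabsch superposition matches a brute-force rotation search", {
  set.seed(20)
  P <- matrix(rnorm(30, sd = 3), 10, 3)
  expect_equal(kabsch_rmsd(P, P)$rmsd, 0, tolerance = 1e-12)
  Q <- rigid_move(P, 2)
  expect_lt(kabsch_rmsd(P, Q)$rmsd, 1e-9)
  sup <- kabsch_rmsd(P, Q)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  ## asymmetric 4-point fixture vs a perturbed copy
  P4 <- matrix(c(0, 0, 0, 1.5, 0, 0, 1.1, 2.2, 0, -0.4, 0.8, 1.9), 4, 3,
               byrow = TRUE)
  Q4 <- rigid_move(P4, 3) + matrix(c(0.1, -0.05, 0.08, 0.02, 0.11, -0.07,
                                     -0.03, 0.04, 0.1, 0.06, -0.09, 0.05),
                                   4, 3, byrow = TRUE)
  expect_equal(kabsch_rmsd(P4, Q4)$rmsd, oracle_superpose_rmsd(P4, Q4),
               tolerance = 1e-6)
  expect_error(kabsch_rmsd(P, Q[1:5, ]), "differ")
  expect_error(kabsch_rmsd(P[1:2, ], Q[1:2, ]), "at least 3")
})

test_that("TM-score handles identity, rigid motion and the exhaustive oracle", {
  spec <- fixture_spec(30, "hairpin", seed = 7)
  m <- make_toy_protein(spec)
  CA <- atom_coords(m, "CA")
  expect_equal(tm_score(CA, CA)$tm, 1.0, tolerance = 1e-12)
  expect_equal(tm_score(rigid_move(CA, 5), CA)$tm, 1.0, tolerance = 1e-6)
  ## a genuinely different pair: fold a distorted copy
  spec2 <- fixture_spec(30, "hairpin", seed = 7, jitter = 5)
  m2 <- make_toy_protein(spec2)
  CA2 <- atom_coords(m2, "CA")
  r <- tm_score(CA, CA2)
  expect_equal(r$tm, oracle_tm_score(CA, CA2), tolerance = 1e-6)
  expect_true(r$tm > 0 && r$tm <= 1)
  ## symmetry under swapping the roles (same correspondence)
  expect_equal(tm_score(CA2, CA)$tm, r$tm, tolerance = 1e-6)
  ## never below the single global-superposition bound
  glob <- kabsch_rmsd(CA, CA2)
  d0 <- max(1.24 * (30 - 15)^(1 / 3) - 1.8, 0.5)
  lower <- mean(1 / (1 + (glob$d / d0)^2))
  expect_gte(r$tm + 1e-12, lower)
  expect_error(tm_score(CA, CA2[1:10, ]), "mismatch")
})

test_that("TM-score recovers partial matches better than global RMSD alone", {
  ## half the structure matches exactly, half is scrambled: the iterative
  ## search should superpose the matching half
  spec <- fixture_spec(40, "helix_bundle", seed = 8)
  m <- make_toy_protein(spec)
  CA <- atom_coords(m, "CA")
  CA2 <- CA
  set.seed(9)
  CA2[21:40, ] <- CA2[21:40, ] + matrix(rnorm(60, sd = 8), 20, 3)
  r <- tm_score(CA2, CA)
  expect_equal(r$tm, oracle_tm_score(CA2, CA), tolerance = 1e-6)
  d_best <- sqrt(rowSums((r$superposition$transform(CA2) - CA)^2))
  expect_lt(max(d_best[1:20]), 0.5)
})

test_that("distance MAE follows the hand-computed definition", {
  spec <- fixture_spec(30, "hairpin", sigma = 0.4, seed = 10)
  native <- make_toy_protein(spec)
  rs <- restraints_from_structure(native, spec)
  ## hand recount over the same top-n*L selection
  mae_pkg <- distance_mae(rs, native, n = 1, range_class = "all")
  sc <- bin_schema("cb_distance")
  conf <- restraint_confidence(rs, "cb_distance")
  idx <- which(upper.tri(conf) & abs(row(conf) - col(conf)) > 1,
               arr.ind = TRUE)
  ord <- order(-conf[idx], idx[, 1], idx[, 2])
  take <- idx[ord[1:30], , drop = FALSE]
  aa <- strsplit(native$sequence, "")[[1]]
  CB <- atom_coords(native, "CB")
  CB[aa == "G", ] <- atom_coords(native, "CA")[aa == "G", ]
  vals <- apply(take, 1, function(p) {
    pred <- sc$centers[which.max(rs$cb_distance[p[1], p[2], ])]
    abs(pred - sqrt(sum((CB[p[1], ] - CB[p[2], ])^2)))
  })
  expect_equal(mae_pkg, mean(vals), tolerance = 1e-12)
  ## the noise-free argmax predictions sit within half a bin of the truth
  expect_lt(mae_pkg, 0.3)
  ## clamping: requesting more pairs than exist uses all of them
  mae_all <- distance_mae(rs, native, n = 1000, range_class = "all")
  expect_true(is.finite(mae_all))
  expect_no_error(distance_mae(rs, native, n = 2, range_class = "long"))
  ## MAE shrinks as the histograms sharpen
  sharp <- restraints_from_structure(native,
    fixture_spec(30, "hairpin", sigma = 0.1, seed = 10))
  expect_lte(distance_mae(sharp, native, n = 1, range_class = "all"),
             mae_pkg + 1e-12)
})

test_that("contact precision counts true contacts among the top predictions", {
  spec <- fixture_spec(30, "hairpin", sigma = 0.3, seed = 12)
  native <- make_toy_protein(spec)
  rs <- restraints_from_structure(native, spec)
  ## noise-free restraints from the native have perfect precision
  expect_equal(contact_precision(rs, native, n = 5, range_class = "all"),
               1.0)
  ## exhaustive recount oracle
  n <- 15
  p_pkg <- contact_precision(rs, native, n = n, range_class = "all")
  prob <- rs$cb_contact
  idx <- which(upper.tri(prob) & abs(row(prob) - col(prob)) > 1,
               arr.ind = TRUE)
  ord <- order(-prob[idx], idx[, 1], idx[, 2])
  take <- idx[ord[1:n], , drop = FALSE]
  aa <- strsplit(native$sequence, "")[[1]]
  CB <- atom_coords(native, "CB")
  CB[aa == "G", ] <- atom_coords(native, "CA")[aa == "G", ]
  hits <- mean(apply(take, 1, function(p)
    sqrt(sum((CB[p[1], ] - CB[p[2], ])^2)) < 8))
  expect_equal(p_pkg, hits)
  ## contacts predicted on far pairs score zero: predict only on the most
  ## distant native pair
  L <- 30
  D <- as.matrix(dist(CB))
  D[abs(row(D) - col(D)) <= 1] <- 0
  worst <- which(D == max(D), arr.ind = TRUE)[1, ]
  expect_gt(D[worst[1], worst[2]], 8)
  far <- matrix(0, L, L)
  far[worst[1], worst[2]] <- far[worst[2], worst[1]] <- 0.9
  rs_far <- restraint_set(L, cb_contact = far)
  expect_equal(contact_precision(rs_far, native, n = 1, range_class = "all"),
               0.0)
  expect_error(contact_precision(rs, native, n = 0), "positive")
})

test_that("clash counting matches a brute-force recount and ignores rigid motion", {
  L <- 12
  hel <- build_coordinates(strrep("A", L), c(999, rep(-57, L - 1)),
                           c(rep(-47, L - 1), 999))
  expect_equal(clash_count(hel), 0L)
  ## force two residues to overlap
  bad <- hel
  rows <- torsionfold:::atom_rows(L, 3)
  bad$coords[rows[8], ] <- bad$coords[rows[2], ] + c(0.4, 0, 0)
  cc <- clash_count(bad)
  expect_gte(cc, 1)
  ## brute-force recount
  radii <- atom_radii(bad)
  X <- bad$coords
  brute <- 0L
  for (a in 1:(nrow(X) - 1)) for (b in (a + 1):nrow(X)) {
    if (radii[a] <= 0 || radii[b] <= 0) next
    ra <- (a - 1) %/% 7 + 1; sa <- (a - 1) %% 7 + 1
    rb <- (b - 1) %/% 7 + 1; sb <- (b - 1) %% 7 + 1
    if (abs(ra - rb) <= 1 &&
        torsionfold:::vdw_excluded_r(ra, sa, rb, sb)) next
    if (sqrt(sum((X[a, ] - X[b, ])^2)) < 0.6 * (radii[a] + radii[b]))
      brute <- brute + 1L
  }
  expect_equal(cc, brute)
  moved <- bad
  moved$coords <- rigid_move(bad$coords, 4)
  expect_equal(clash_count(moved), cc)
})
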