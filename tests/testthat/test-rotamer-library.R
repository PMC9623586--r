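test_that("equilibrium populations are Boltzmann and shift-invariant", {
  expect_equal(equilibrium_populations(rep(2.5, 4)), rep(0.25, 4))
  kT <- 0.0019872041 * 298
  expect_equal(equilibrium_populations(c(0, kT * log(2))), c(2 / 3, 1 / 3))
  expect_equal(equilibrium_populations(5), 1)
  expect_error(equilibrium_populations(numeric(0)), "empty")
  set.seed(29)
  for (i in 1:20) {
    f <- rnorm(6, sd = 2)
    p <- equilibrium_populations(f)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(equilibrium_populations(f + 37.1), p, tolerance = 1e-12)
  }
})

test_that("cluster statistics use circular means and the singleton rule", {
  r <- cluster_to_rotamer(matrix(c(58, 62), ncol = 1), c(0.1, 0.2))
  expect_equal(r$chi_mean, 60)
  expect_equal(r$chi_sd, 2)
  expect_equal(r$probability, 0.3)
  wrap <- cluster_to_rotamer(matrix(c(179, -179), ncol = 1), c(0.5, 0.5))
  expect_equal(wrap$chi_mean, 180)
  expect_equal(wrap$chi_sd, 1)
  single <- cluster_to_rotamer(matrix(c(45, 100), 1, 2), 0.3)
  expect_equal(single$chi_sd, c(1.0, 1.0))
  expect_equal(single$probability, 0.3)
  expect_equal(single$member_count, 1L)
  expect_error(cluster_to_rotamer(matrix(numeric(0), 0, 1), numeric(0)),
               "empty")
})

test_that("library construction prunes below 0.005 and keeps the boundary", {
  kT <- 0.0019872041 * 298
  probs <- c(0.990, 0.006, 0.004)
  fe <- -kT * log(probs)
  ens <- conformation_ensemble(matrix(c(-60, 60, 180), ncol = 1), fe)
  lib <- rotamer_library(list("GLY-SER-GLY" = ens))
  expect_equal(nrow(lib$entries), 2L)
  expect_equal(lib$entries$probability, c(0.990, 0.006), tolerance = 1e-9)
  # probability exactly 0.005 is retained ("less than" is removed)
  fe2 <- -kT * log(c(0.995, 0.005))
  lib2 <- rotamer_library(list("GLY-SER-GLY" =
    conformation_ensemble(matrix(c(-60, 120), ncol = 1), fe2)))
  expect_equal(nrow(lib2$entries), 2L)
  # a single conformation gives one rotamer with probability one
  lib3 <- rotamer_library(list("GLY-SER-GLY" =
    conformation_ensemble(matrix(-65, 1, 1), 0)))
  expect_equal(lib3$entries$probability, 1.0)
  expect_equal(lib3$entries$chi1_sd, 1.0)
})

test_that("probabilities within a context sum to one before pruning", {
  set.seed(31)
  centers <- rbind(c(-60, -60), c(60, 180), c(180, 60))
  ens <- sample_planted_ensemble(centers, c(0, 0.5, 1.1), n_draws = 90)
  lib <- rotamer_library(list("GLY-LEU-GLY" = ens), prune = 0)
  expect_equal(sum(lib$entries$probability), 1, tolerance = 1e-9)
})

test_that("central residues without chi dihedrals are rejected", {
  ens <- conformation_ensemble(matrix(0, 1, 1), 0)
  expect_error(rotamer_library(list("GLY-ALA-GLY" = ens)), "no chi")
  expect_error(rotamer_library(list("GLY-SER" = ens)), "malformed context")
})

test_that("matching uses a strict per-chi criterion and prefers probability", {
  kT <- 0.0019872041 * 298
  ens <- conformation_ensemble(matrix(c(-60, 60, 180), ncol = 1),
                               -kT * log(c(0.7, 0.2, 0.1)))
  lib <- rotamer_library(list("GLY-SER-GLY" = ens))
  cand <- library_context(lib, "GLY-SER-GLY")
  expect_equal(match_sidechain(-60, cand)$probability, 0.7, tolerance = 1e-9)
  expect_equal(match_sidechain(-60 + 39, cand)$probability, 0.7,
               tolerance = 1e-9)
  expect_null(match_sidechain(c(5), cand[cand$chi1_mean == -60, ]))
  # self-match always succeeds
  for (i in seq_len(nrow(cand)))
    expect_equal(match_sidechain(cand$chi1_mean[i], cand)$chi1_mean,
                 cand$chi1_mean[i])
  expect_error(match_sidechain(c(0, 0), cand), "chi dihedrals")
})

test_that("nearest distance is the min over candidates of the max per chi", {
  cand <- data.frame(prev = "GLY", central = "LEU", nxt = "GLY", n_chi = 2L,
                     chi1_mean = c(0, 50), chi2_mean = c(0, 40),
                     chi3_mean = NA, chi4_mean = NA,
                     chi1_sd = 1, chi2_sd = 1, chi3_sd = NA, chi4_sd = NA,
                     probability = c(0.6, 0.4), member_count = 1L)
  expect_equal(nearest_distance(c(0, 0), cand), 0)
  expect_equal(nearest_distance(c(10, 30), cand[1, ]), 30)
  # offsets max 25 to the first rotamer, max 50 to the second: min wins
  expect_equal(nearest_distance(c(0, 25), cand[c(2, 1), ]), 25)
  expect_error(nearest_distance(c(0, 0), cand[0, ]), "no candidate")
})

test_that("coverage reporting counts matches per residue type", {
  kT <- 0.0019872041 * 298
  lib <- rotamer_library(list(
    "GLY-SER-GLY" = conformation_ensemble(matrix(c(-60, 60), ncol = 1),
                                          -kT * log(c(0.7, 0.3))),
    "GLY-CYS-GLY" = conformation_ensemble(matrix(c(180), ncol = 1), 0)))
  test_set <- data.frame(prev = "GLY", central = c("SER", "SER", "SER", "CYS"),
                         nxt = "GLY", chi1 = c(-60, 65, 120, 170),
                         chi2 = NA, chi3 = NA, chi4 = NA)
  rep <- coverage_report(test_set, lib)
  expect_equal(rep$total_percent, 75)  # 3 of 4 within tolerance
  ser <- rep$by_residue[rep$by_residue$central == "SER", ]
  expect_equal(ser$percent, 100 * 2 / 3)
  expect_equal(ser$mean_rotamers, 2)
  # exact library means are always covered
  exact <- data.frame(prev = "GLY", central = "SER", nxt = "GLY",
                      chi1 = c(-60, 60), chi2 = NA, chi3 = NA, chi4 = NA)
  expect_equal(coverage_report(exact, lib)$total_percent, 100)
  # unresolved contexts are excluded and counted
  u <- data.frame(prev = "ALA", central = "SER", nxt = "ALA",
                  chi1 = 0, chi2 = NA, chi3 = NA, chi4 = NA)
  rep_u <- coverage_report(rbind(test_set, u), lib)
  expect_equal(rep_u$n_unresolved, 1L)
  expect_equal(rep_u$total_percent, 75)
  expect_error(coverage_report(test_set[0, ], lib), "empty")
})

test_that("reference rotamer tracking reports planted probabilities", {
  kT <- 0.0019872041 * 298
  lib <- rotamer_library(list(
    "GLY-SER-GLY" = conformation_ensemble(matrix(c(-60, 60), ncol = 1),
                                          -kT * log(c(0.6, 0.4))),
    "ALA-SER-ALA" = conformation_ensemble(matrix(c(-60, 60), ncol = 1),
                                          -kT * log(c(0.2, 0.8))),
    "TRP-SER-TRP" = conformation_ensemble(matrix(175, 1, 1), 0)))
  probs <- reference_rotamer_tracking(lib, "GLY-SER-GLY")
  expect_equal(probs[["GLY-SER-GLY"]], 0.6, tolerance = 1e-9)
  expect_equal(probs[["ALA-SER-ALA"]], 0.2, tolerance = 1e-9)
  expect_equal(probs[["TRP-SER-TRP"]], 0)  # nothing within 40 deg per chi
  expect_error(reference_rotamer_tracking(lib, "LYS-SER-LYS"), "absent")
})

test_that("generic HIS contexts fall back to the delta-protonated state", {
  lib <- rotamer_library(list(
    "GLY-HID-GLY" = conformation_ensemble(matrix(c(-60, 170), 1, 2), 0)))
  cand <- library_context(lib, "GLY-HIS-GLY")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$central, "HID")
})

test_that("planted rotamer libraries are recovered within tolerance", {
  set.seed(37)
  centers <- rbind(c(-60, -60), c(60, 180), c(180, 60))
  fe <- c(0, 0.4, 1.0)
  planted <- equilibrium_populations(fe)
  ens <- sample_planted_ensemble(centers, fe, n_draws = 200, noise_sd = 5)
  lib <- rotamer_library(list("GLY-LEU-GLY" = ens))
  e <- lib$entries
  expect_equal(nrow(e), 3L)
  for (i in seq_len(3)) {
    d <- apply(cbind(e$chi1_mean, e$chi2_mean), 1, function(m)
      max(periodic_angle_distance(m, centers[i, ])))
    j <- which.min(d)
    expect_lt(d[j], 3)
    expect_lt(abs(e$probability[j] - planted[i]), 0.02)
  }
})

test_that("library predict and summary methods work on new observations", {
  kT <- 0.0019872041 * 298
  lib <- rotamer_library(list(
    "GLY-SER-GLY" = conformation_ensemble(matrix(c(-60, 60), ncol = 1),
                                          -kT * log(c(0.7, 0.3)))))
  nd <- data.frame(prev = "GLY", central = "SER", nxt = "GLY",
                   chi1 = c(-55, 130), chi2 = NA, chi3 = NA, chi4 = NA)
  pr <- predict(lib, nd)
  expect_equal(pr$matched, c(TRUE, FALSE))
  expect_equal(pr$probability[1], 0.7, tolerance = 1e-9)
  s <- summary(lib)
  expect_equal(s$by_residue$rotamers, 2L)
  expect_output(print(lib), "rotamer library")
})
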