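test_that("local minimization reaches stationary points", {
  bowl <- toy_quadratic_well(k = rep(2, 3))
  rec <- local_minimize(bowl, c(1, 1, 1))
  expect_true(rec$converged)
  expect_equal(rec$energy, 0, tolerance = 1e-10)
  expect_equal(rec$coordinates, c(0, 0, 0), tolerance = 1e-6)
  # starting at the minimum returns immediately
  rec0 <- local_minimize(bowl, c(0, 0, 0))
  expect_equal(rec0$energy, 0)
  expect_lte(rec0$evaluations, 5L)
  # 1-D double well from x = 0.1 falls into the +1 well
  dw <- toy_double_well()
  recd <- local_minimize(dw, 0.1)
  expect_equal(recd$coordinates, 1, tolerance = 1e-5)
  expect_equal(recd$energy, -1, tolerance = 1e-9)
  expect_lte(recd$energy, dw$energy(0.1))
  expect_error(local_minimize(dw, NaN), "non-finite")
})

test_that("harmonic free energies match the closed form", {
  kB <- 0.0019872041
  # 2-D anisotropic quadratic: F - V = kB T sum(log omega), omega = sqrt(k)
  pot <- toy_quadratic_well(k = c(1, 4))
  rec <- local_minimize(pot, c(0.3, -0.2))
  Fh <- harmonic_free_energy(pot, rec, temperature = 298)
  expect_equal(Fh - rec$energy, kB * 298 * sum(log(sqrt(c(1, 4)))),
               tolerance = 1e-6)
  # the finite-difference Hessian path agrees with the analytic one
  pot_fd <- bh_potential(pot$energy, pot$gradient)
  expect_equal(harmonic_free_energy(pot_fd, rec), Fh, tolerance = 1e-6)
  # equal-depth wells with omega ratio 2 -> population ratio 2
  F1 <- harmonic_free_energy(toy_quadratic_well(k = 1),
                             local_minimize(toy_quadratic_well(k = 1), 0.1))
  F2 <- harmonic_free_energy(toy_quadratic_well(k = 4),
                             local_minimize(toy_quadratic_well(k = 4), 0.1))
  p <- equilibrium_populations(c(F1, F2))
  expect_equal(p[1] / p[2], 2, tolerance = 1e-6)
  # identical wells have zero free-energy difference
  expect_equal(F1 - harmonic_free_energy(toy_quadratic_well(k = 1), 0), 0,
               tolerance = 1e-9)
  # a saddle is rejected
  saddle <- bh_potential(function(x) x[1]^2 - x[2]^2,
                         function(x) c(2 * x[1], -2 * x[2]))
  expect_error(harmonic_free_energy(saddle, c(0, 0)), "not a minimum")
})

test_that("Metropolis acceptance has the right limits and frequency", {
  expect_true(metropolis_accept(-1, 1.3))
  expect_true(metropolis_accept(0, 1.3))
  expect_error(metropolis_accept(1, 0), "positive")
  set.seed(47)
  temp <- 1.3
  acc <- mean(replicate(1e4, metropolis_accept(temp * log(2), temp)))
  expect_equal(acc, 0.5, tolerance = 0.02 / 0.5)
})

test_that("Cartesian displacement moves respect their bounds", {
  set.seed(53)
  x <- rnorm(30)
  expect_identical(cartesian_displacement_move(x, 0), x)
  y <- cartesian_displacement_move(x, 1)
  expect_true(all(abs(y - x) <= 1))
  norms <- sqrt(rowSums(matrix(y - x, ncol = 3, byrow = TRUE)^2))
  expect_true(all(norms <= sqrt(3)))
  set.seed(99); a <- cartesian_displacement_move(x, 0.7)
  set.seed(99); b <- cartesian_displacement_move(x, 0.7)
  expect_identical(a, b)
})

test_that("torsional moves preserve the bonded topology", {
  chain <- cached_chain(2, 2, seed = 3)
  x <- chain$start_coordinates
  bond_lengths <- function(x) {
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    apply(chain$topology$bonds, 1, function(b)
      sqrt(sum((xyz[b[1], ] - xyz[b[2], ])^2)))
  }
  set.seed(59)
  y <- group_rotation_move(x, chain, selection_prob = 0.5)
  expect_equal(bond_lengths(y), bond_lengths(x), tolerance = 1e-9)
  # selection probability 0 is the identity move
  expect_equal(group_rotation_move(x, chain, selection_prob = 0), x)
  lib <- cached_toy_library(chain, "2x2")
  z <- rotamer_move(x, chain, lib, n_SC = 2)
  expect_equal(bond_lengths(z), bond_lengths(x), tolerance = 1e-9)
})

test_that("rotamer moves impose library chi values and leave the backbone", {
  chain <- cached_chain(2, 2, seed = 3)
  lib <- cached_toy_library(chain, "2x2")
  # single-rotamer library forces the draw
  top1 <- lib
  top1$entries <- do.call(rbind, lapply(
    split(lib$entries, lib$entries$central),
    function(g) g[which.max(g$probability), ]))
  set.seed(61)
  x <- chain$start_coordinates
  y <- rotamer_move(x, chain, top1, n_SC = 2)
  chi_after <- chain_chi(chain, y)
  for (r in 1:2) {
    want <- top1$entries$chi1_mean[top1$entries$central ==
                                     sprintf("T%02d", r)]
    expect_equal(periodic_angle_distance(chi_after[r], want), 0,
                 tolerance = 1e-6)
  }
  # backbone dihedrals untouched
  bb <- function(x) {
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    sapply(Filter(function(d) d$type == "backbone", chain$topology$dihedrals),
           function(d) dihedral_angle(xyz[d$quad[1], ], xyz[d$quad[2], ],
                                      xyz[d$quad[3], ], xyz[d$quad[4], ]))
  }
  expect_equal(bb(y), bb(x), tolerance = 1e-9)
  # unknown context errors with its name
  broken <- lib
  broken$entries <- lib$entries[lib$entries$central != "T01", ]
  set.seed(67)
  expect_error(rotamer_move(x, chain, broken, n_SC = 2), "T01")
})

test_that("rotamer draws follow library occupation probabilities", {
  chain <- cached_chain(1, 2, seed = 13)
  lib <- list(entries = data.frame(
    prev = "CAP", central = "T01", nxt = "CAP", n_chi = 1L,
    chi1_mean = chain$wells$chi[[1]], chi2_mean = NA, chi3_mean = NA,
    chi4_mean = NA, chi1_sd = 1, chi2_sd = NA, chi3_sd = NA, chi4_sd = NA,
    probability = c(0.8, 0.2), member_count = 1L),
    metadata = list(temperature = 298, cutoff = 40, prune = 0))
  class(lib) <- "rotamer_library"
  set.seed(71)
  x <- chain$start_coordinates
  draws <- replicate(1e4, {
    chi <- chain_chi(chain, rotamer_move(x, chain, lib, n_SC = 1))
    which.min(periodic_angle_distance(chi, lib$entries$chi1_mean))
  })
  expect_equal(mean(draws == 1), 0.8, tolerance = 0.02 / 0.8)
})

test_that("basin-hopping bookkeeping is consistent", {
  chain <- cached_chain(2, 2, seed = 3)
  lib <- cached_toy_library(chain, "2x2")
  sch <- bh_scheme("rotamer", n_SC = 1, f_SC = 1, n_BB = 1, f_BB = 2,
                   temperature = 1.3)
  run <- run_basin_hopping(chain, chain$start_coordinates, sch, n_steps = 60,
                           seed = 5, library = lib,
                           reference_energy = chain$global_minimum$energy)
  r <- run$records
  expect_equal(nrow(r), 61L)
  expect_equal(run$best_energy, min(r$energy))
  # every record satisfies the force criterion, and re-minimizing one
  # barely changes its energy
  expect_true(all(r$rms_gradient <= 1e-6))
  i <- which(r$accepted)[5]
  re <- local_minimize(chain, run$coordinates[i, ])
  expect_lt(abs(re$energy - r$energy[i]), 1e-9)
  # recorded deltas match energies relative to the running chain minimum
  cur <- r$energy[1]
  for (i in 2:nrow(r)) {
    expect_equal(r$delta[i], r$energy[i] - cur, tolerance = 1e-12)
    if (r$accepted[i]) cur <- r$energy[i]
  }
  # move cadence: backbone moves only every 2nd step
  expect_true(all(grepl("SC", r$move[-1])))
  expect_equal(grepl("BB", r$move[-1]), (seq_len(60) %% 2) == 0)
})

test_that("zero steps and infinite temperature behave as limits", {
  chain <- cached_chain(2, 2, seed = 3)
  lib <- cached_toy_library(chain, "2x2")
  sch <- bh_scheme("rotamer", n_SC = 1, f_SC = 1, n_BB = 1, f_BB = 1)
  run0 <- run_basin_hopping(chain, chain$start_coordinates, sch, n_steps = 0,
                            seed = 1, library = lib)
  expect_equal(nrow(run0$records), 1L)
  expect_true(run0$records$accepted[1])
  hot <- bh_scheme("rotamer", n_SC = 1, f_SC = 1, n_BB = 1, f_BB = 1,
                   temperature = 1e9)
  rh <- run_basin_hopping(chain, chain$start_coordinates, hot, n_steps = 40,
                          seed = 2, library = lib)
  expect_true(all(rh$records$accepted))
})

test_that("the Markov chain samples basins with Boltzmann weights", {
  # 1-D double well; proposals drawn independently of the current state,
  # so the proposal density is exactly symmetric and the accepted chain
  # must sample the two basins with Boltzmann weights of their minima
  dw <- toy_double_well(bias = 0.8)
  mins <- lapply(c(-1, 1), function(s) local_minimize(dw, s))
  dV <- mins[[1]]$energy - mins[[2]]$energy  # left minus right (> 0)
  temp <- 1.3
  # center the proposal window on the barrier so both basins receive
  # exactly half of the proposal mass (plain Metropolis needs a
  # symmetric proposal)
  barrier <- uniroot(function(x) dw$gradient(x), c(-0.6, 0))$root
  set.seed(83)
  n <- 20000
  cur <- 2L  # start in the right basin
  occ <- integer(n)
  E <- c(mins[[1]]$energy, mins[[2]]$energy)
  for (i in seq_len(n)) {
    prop <- local_minimize(dw, barrier + runif(1, -2, 2))$coordinates
    basin <- if (prop > barrier) 2L else 1L
    if (metropolis_accept(E[basin] - E[cur], temp)) cur <- basin
    occ[i] <- cur
  }
  p_right <- mean(occ == 2L)
  expect_right <- 1 / (1 + exp(-dV / temp))
  batches <- colMeans(matrix(occ == 2L, ncol = 20))
  se <- sd(batches) / sqrt(length(batches))
  expect_lt(abs(p_right - expect_right), 3 * se)
})

test_that("free-energy acceptance shifts occupation by mode stiffness", {
  # equal-depth 2-D wells with a twofold-ish transverse stiffness
  # contrast: under free-energy acceptance the occupation follows the
  # harmonic free energies, not the (equal) well depths
  pot <- toy_double_well_2d(k0 = 1, delta = 0.9, beta = 4)
  mins <- lapply(c(-1, 1), function(s) local_minimize(pot, c(s, 0)))
  F <- vapply(mins, function(m) harmonic_free_energy(pot, m), numeric(1))
  dF <- F[1] - F[2]
  temp <- 1.3
  set.seed(89)
  n <- 8000
  cur <- 2L
  occ <- integer(n)
  for (i in seq_len(n)) {
    # propose on the y = 0 line: the basin boundary there is exactly
    # x = 0, so the two basins receive equal proposal mass
    xy <- c(runif(1, -2, 2), 0)
    basin <- if (local_minimize(pot, xy)$coordinates[1] > 0) 2L else 1L
    if (metropolis_accept(F[basin] - F[cur], temp)) cur <- basin
    occ[i] <- cur
  }
  p_right <- mean(occ == 2L)
  expect_right <- 1 / (1 + exp(-dF / temp))
  batches <- colMeans(matrix(occ == 2L, ncol = 20))
  se <- sd(batches) / sqrt(length(batches))
  expect_lt(abs(p_right - expect_right), 3 * se)
})

test_that("rotamer schemes find the enumerated global minimum", {
  chain <- cached_chain(4, 3, seed = 7)
  lib <- cached_toy_library(chain, "4x3")
  presets <- scheme_presets()
  for (s in 1:2) {
    run <- run_basin_hopping(chain, chain$start_coordinates,
                             presets[["rotamer 2"]], n_steps = 800,
                             seed = 200 + s, library = lib,
                             reference_energy = chain$global_minimum$energy)
    expect_false(is.na(run$success_step))
    expect_lt(run$best_energy, chain$global_minimum$energy + 1)
  }
})

test_that("run diagnostics report proposal energies and chain distances", {
  chain <- cached_chain(2, 2, seed = 3)
  lib <- cached_toy_library(chain, "2x2")
  sch <- bh_scheme("rotamer", n_SC = 1, f_SC = 1, n_BB = 1, f_BB = 1)
  run <- run_basin_hopping(chain, chain$start_coordinates, sch, n_steps = 40,
                           seed = 7, library = lib)
  d <- markov_diagnostics(run)
  expect_length(d$delta_e, 40L)
  expect_length(d$delta_d, sum(run$records$accepted) - 1L)
  expect_true(all(d$delta_d >= 0))
  expect_equal(d$median_delta_e, median(d$delta_e))
  # a rigidly rotated copy of a structure is at distance zero
  fake <- run
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- matrix(run$coordinates[1, ], ncol = 3, byrow = TRUE) %*% R
  fake$records <- run$records[c(1, 1), ]
  fake$records$accepted <- TRUE
  fake$coordinates <- rbind(run$coordinates[1, ], as.numeric(t(xyz)))
  d2 <- markov_diagnostics(fake)
  expect_equal(d2$delta_d, 0, tolerance = 1e-6)
  # a stationary chain has all-zero diagnostics
  bowl <- toy_quadratic_well(k = rep(1, 9),
                             x0 = c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0))
  still <- bh_scheme("group_rotation", n_SC = 0, f_SC = 1, n_BB = 0,
                     f_BB = 1, displacement_amplitude = 0)
  rs <- run_basin_hopping(bowl, rep(0.5, 9), still, n_steps = 10, seed = 3)
  ds <- markov_diagnostics(rs)
  expect_true(all(abs(ds$delta_e) < 1e-12))
  expect_true(all(ds$delta_d < 1e-6))
})

test_that("trajectory tables are deterministic given the seed", {
  chain <- cached_chain(2, 2, seed = 3)
  lib <- cached_toy_library(chain, "2x2")
  sch <- bh_scheme("rotamer", n_SC = 1, f_SC = 1, n_BB = 1, f_BB = 1)
  p1 <- tempfile(); p2 <- tempfile()
  for (p in c(p1, p2)) {
    run <- run_basin_hopping(chain, chain$start_coordinates, sch,
                             n_steps = 30, seed = 11, library = lib)
    write_trajectory(run, p)
  }
  expect_identical(readLines(p1), readLines(p2))
})
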