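test_that("f1 damping vanishes at contact, saturates, and is monotone", {
  expect_equal(damping_f1(2.5, 0), 0)
  expect_equal(damping_f1(2.5, 1e4), 1)
  expect_equal(damping_f1(1, 1), 1 - exp(-1), tolerance = 1e-12)
  r <- seq(0, 4, by = 0.02)   # below the double-precision saturation of e^-Kr
  f <- damping_f1(3.1, r)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))
  expect_error(damping_f1(0, 1), "> 0")
})

test_that("f2 damping is symmetric with a correct equal-K branch", {
  for (r in c(0.5, 2, 7)) {
    expect_equal(damping_f2(2.1, 4.4, r), damping_f2(4.4, 2.1, r))
  }
  expect_equal(damping_f2(2.1, 4.4, 0), 0, tolerance = 1e-12)
  expect_equal(damping_f2(3, 3, 0), 0)
  expect_equal(damping_f2(2.1, 4.4, 1e3), 1)

  # equal-K analytic branch equals the epsilon -> 0 limit of the
  # two-exponential form (odd epsilon terms cancel in the +/- average)
  K <- 2.7
  for (r in c(0.3, 1.5, 4, 9)) {
    lim <- sapply(c(1e-4, 1e-5, 1e-6), function(eps) {
      (damping_f2(K * (1 + eps), K, r) + damping_f2(K * (1 - eps), K, r)) / 2
    })
    expect_equal(damping_f2(K, K, r), lim[[3]], tolerance = 1e-8)
    expect_equal(damping_f2(K, K, r), 1 - exp(-K * r) * (1 - K * r / 2),
                 tolerance = 1e-12)
  }
})

test_that("overlap S is 1 at contact and strictly decreasing", {
  expect_equal(overlap_s(0.7, 0.9, 0), 1)
  expect_equal(overlap_s(1, 1, 1), (1 / 3 + 1 + 1) * exp(-1), tolerance = 1e-12)
  r <- seq(0, 25, by = 0.05)
  s <- overlap_s(0.6, 1.1, r)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
  expect_error(overlap_s(-1, 1, 1), "> 0")
})

test_that("Tang-Toennies damping matches its series and is ordered in n", {
  expect_equal(tt_damping(6, 1.5, 0), 0)
  expect_equal(tt_damping(6, 1.5, 1e3), 1)
  # independent series oracle at x = 1 (f as a function of x)
  x <- 1
  expect_equal(saptfit:::tt_f_of_x(6, x),
               1 - exp(-1) * sum(1 / factorial(0:6)), tolerance = 1e-14)
  xs <- seq(0, 40, by = 0.1)
  f6 <- saptfit:::tt_f_of_x(6, xs)
  f8 <- saptfit:::tt_f_of_x(8, xs)
  f10 <- saptfit:::tt_f_of_x(10, xs)
  expect_true(all(f6 >= f8 & f8 >= f10))
  expect_true(all(f6 >= 0 & f10 <= 1))
  expect_error(tt_damping(7, 1, 1), "6, 8 or 10")
})

test_that("C6 combination is symmetric with the homoatomic identity", {
  expect_equal(combine_c6(5, 5, 2, 2), -5)
  expect_equal(combine_c6(2, 8, 3, 3), -2 * 16 / 10)
  expect_equal(combine_c6(2, 8, 1.3, 2.9), combine_c6(8, 2, 2.9, 1.3))
  expect_true(combine_c6(4, 9, 1, 5) < 0)
  expect_error(combine_c6(-1, 1, 1, 1), "> 0")
})

test_that("C8/C10 rules keep the 49/40 identity exactly", {
  cc <- compute_c8_c10(-1, 1, 1)
  expect_equal(cc$c8, -3)
  expect_equal(cc$c10, (49 / 40) * 9 / (-1))
  expect_equal(compute_c8_c10(-2, 4, 1)$c8, 3 * (-2) * 2)
  set.seed(9)
  for (i in 1:25) {
    fac <- free_atom_constants(sample(c("C", "H", "O", "S", "Br"), 2, TRUE))
    h <- runif(2, 0.6, 1.3)
    sc <- scale_dispersion_inputs(fac$c6_free, fac$alpha_free, h)
    c6 <- combine_c6(sc$c6[1], sc$c6[2], sc$alpha[1], sc$alpha[2])
    q <- effective_q(fac$z_nuc, fac$r2, fac$r4)
    cc <- compute_c8_c10(c6, q[1], q[2])
    expect_equal(cc$c10 * c6 / cc$c8^2, 49 / 40, tolerance = 1e-12)
    expect_equal(sign(cc$c8), sign(c6))
    expect_equal(sign(cc$c10), sign(c6))
  }
  expect_error(compute_c8_c10(0, 1, 1), "non-zero")
})

test_that("interaction tensors equal finite differences of 1/r", {
  expect_equal(interaction_tensors(c(2, 0, 0), 0)$T0, 0.5)
  expect_equal(interaction_tensors(c(1, 0, 0), 1)$T1, c(-1, 0, 0))
  set.seed(5)
  for (i in 1:10) {
    r <- rnorm(3); r <- r / sqrt(sum(r^2)) * runif(1, 1, 6)
    tt <- interaction_tensors(r)
    g0 <- fd_grad(function(x) interaction_tensors(x, 0)$T0, r)
    expect_equal(g0, tt$T1, tolerance = 1e-6)
    g1 <- t(sapply(1:3, function(b)
      fd_grad(function(x) interaction_tensors(x, 1)$T1[b], r)))
    expect_equal(g1, tt$T2, tolerance = 1e-6)
  }
  expect_error(interaction_tensors(c(0, 0, 0)), "zero separation")
})

test_that("multipole contractions match the point-charge oracle", {
  set.seed(21)
  for (i in 1:6) {
    R <- rnorm(3); R <- R / sqrt(sum(R^2)) * runif(1, 4, 8)
    tt <- interaction_tensors(R)
    qi <- rnorm(1); qj <- rnorm(1)
    mui <- rnorm(3) * 0.5; muj <- rnorm(3) * 0.5
    thi <- rand_quad(); thj <- rand_quad()
    e_an <- saptfit:::contract_multipole_multipole(tt, qi, mui, thi, qj, muj, thj)
    e_or <- multipole_energy_oracle(qi, mui, thi, qj, muj, thj, R)
    expect_equal(e_an, e_or, tolerance = 1e-5)
  }
})

test_that("Thole tensors damp to the bare tensors and keep lambda order", {
  r <- c(1.5, -2, 0.8)
  bare <- interaction_tensors(r, 2)
  td <- thole_tensors(r, 1e-4, 1e-4, max_rank = 2)  # u enormous
  expect_equal(td$T1, bare$T1, tolerance = 1e-10)
  expect_equal(td$T2, bare$T2, tolerance = 1e-10)
  expect_equal(thole_tensors(c(1, 0, 0), 1, 1)$u, 1)
  u <- seq(0.01, 6, by = 0.01)
  au3 <- 0.39 * u^3
  l3 <- 1 - exp(-au3); l5 <- 1 - (1 + au3) * exp(-au3)
  expect_true(all(l5 <= l3 & l3 <= 1))
  # damped T2 is the gradient of damped T1 (derivative consistency)
  set.seed(3)
  for (i in 1:5) {
    rv <- rnorm(3); rv <- rv / sqrt(sum(rv^2)) * runif(1, 1.5, 5)
    ai <- runif(1, 2, 12); aj <- runif(1, 2, 12)
    tt <- thole_tensors(rv, ai, aj, max_rank = 3)
    g <- t(sapply(1:3, function(b)
      fd_grad(function(x) thole_tensors(x, ai, aj, max_rank = 1)$T1[b], rv)))
    expect_equal(g, tt$T2, tolerance = 1e-6)
  }
})

test_that("electrostatics reduces to bare Coulomb for two point nuclei", {
  # two Br atoms (typable as single-atom monomers), charges Z = 1,
  # all multipoles zero, 1 bohr apart
  a2 <- 0.52917721
  ma <- assign_atom_types(perceive_bonds(monomer("Br", c(0, 0, 0))))
  mb <- assign_atom_types(perceive_bonds(monomer("Br", c(a2, 0, 0))))
  d <- build_dimer(ma, mb, "ionpair")
  mk_props <- function(Z) {
    atomic_properties("Br", q = 0, mu = c(0, 0, 0),
                      theta = array(0, c(3, 3, 1)), Z = Z, sigma = 0.9, h = 1)
  }
  params <- global_parameters()
  params$K_elst[params$species == "Br"] <- 3.5
  e <- elst_energy(d, list(a = mk_props(1), b = mk_props(1)), params)
  expect_equal(e, 627.509, tolerance = 1e-9)
  zero <- elst_energy(d, list(a = mk_props(0), b = mk_props(0)), params)
  expect_equal(zero, 0)
})

test_that("damped monopole electrostatics approaches bare Coulomb at long range", {
  # net charges via Z + q: Z = 1, q = -0.7 -> net +0.3 on each atom
  r_bohr <- 15
  a2 <- 0.52917721
  ma <- assign_atom_types(perceive_bonds(monomer("Br", c(0, 0, 0))))
  mb <- assign_atom_types(perceive_bonds(monomer("Br", c(r_bohr * a2, 0, 0))))
  d <- build_dimer(ma, mb, "farpair")
  pr <- atomic_properties("Br", q = -0.7, mu = c(0, 0, 0),
                          theta = array(0, c(3, 3, 1)), Z = 1, sigma = 0.9, h = 1)
  params <- global_parameters()
  params$K_elst[params$species == "Br"] <- 4   # K r = 60: damping saturated
  e <- elst_energy(d, list(a = pr, b = pr), params)
  expect_equal(e, 627.509 * 0.3^2 / r_bohr, tolerance = 1e-6)
})

test_that("exchange energy equals the explicit overlap sum and decays", {
  fx <- fixture_dimer(c("methane", "formaldehyde"), seed = 5)
  d <- fx$dimers[[2]]
  pr <- fixture_props(d, fx$props)
  e <- exch_energy(d, pr, fx$params)
  # independent pair loop
  b2a <- 1 / 0.52917721
  acc <- 0
  for (i in seq_along(d$monomer_a$element)) {
    for (j in seq_along(d$monomer_b$element)) {
      r <- sqrt(sum((d$monomer_a$xyz[i, ] - d$monomer_b$xyz[j, ])^2)) * b2a
      s <- overlap_s(pr$a$sigma[i], pr$b$sigma[j], r)
      kij <- sqrt(param_lookup(fx$params, d$monomer_a$species[i], "K_exch") *
                    param_lookup(fx$params, d$monomer_b$species[j], "K_exch"))
      acc <- acc + kij * s
    }
  }
  expect_equal(e, acc * 627.509, tolerance = 1e-9)
  expect_gt(e, 0)
  # rigid separation cuts the overlap down
  far <- d
  far$monomer_b$xyz <- far$monomer_b$xyz + 20
  expect_lt(exch_energy(far, pr, fx$params), 1e-8)
})

test_that("dispersion decays like the damped C6 sum at long range", {
  a2 <- 0.52917721
  ma <- assign_atom_types(perceive_bonds(monomer("Br", c(0, 0, 0))))
  params <- ground_truth_parameters(1)
  mk <- function(r_bohr) {
    mb <- assign_atom_types(perceive_bonds(monomer("Br", c(r_bohr * a2, 0, 0))))
    build_dimer(ma, mb, "brpair")
  }
  pr1 <- atomic_properties("Br", q = -7, mu = c(0, 0, 0),
                           theta = array(0, c(3, 3, 1)), Z = 7, sigma = 0.9, h = 1)
  pr <- list(a = pr1, b = pr1)
  fac <- free_atom_constants("Br")
  c6_pair <- combine_c6(fac$c6_free, fac$c6_free, fac$alpha_free, fac$alpha_free)
  # with the C8/C10 channel switched off the tail is pure damped C6
  p6 <- params
  p6$K_disp[] <- 1e-12
  for (r in c(25, 35)) {
    e_h <- disp_energy(mk(r), pr, p6) / 627.509
    expect_equal(e_h * r^6, c6_pair, tolerance = 1e-4)
  }
  expect_lt(abs(disp_energy(mk(60), pr, params)), 1e-5)
  expect_lt(disp_energy(mk(8), pr, params), 0)
  # the fitted channel adds attraction on top of the C6 tail
  expect_lt(disp_energy(mk(12), pr, params), disp_energy(mk(12), pr, p6))
})

test_that("induced dipoles solve the coupled polarization equations", {
  set.seed(14)
  fx <- fixture_dimer(c("methanol", "methylamine"), seed = 9)
  for (d in fx$dimers[1:3]) {
    pr <- fixture_props(d, fx$props)
    mu_it <- induced_dipoles(d, pr)
    mu_dir <- saptfit:::induced_dipoles_direct(d, pr)
    expect_lt(max(abs(mu_it - mu_dir)), 10 * 1e-8)
  }
})

test_that("zero permanent multipoles induce nothing", {
  a2 <- 0.52917721
  ma <- assign_atom_types(perceive_bonds(monomer("Br", c(0, 0, 0))))
  mb <- assign_atom_types(perceive_bonds(monomer("Br", c(6 * a2, 0, 0))))
  d <- build_dimer(ma, mb, "quiet")
  pr1 <- atomic_properties("Br", q = 0, mu = c(0, 0, 0),
                           theta = array(0, c(3, 3, 1)), Z = 0, sigma = 0.9, h = 1)
  mu <- induced_dipoles(d, list(a = pr1, b = pr1))
  expect_equal(max(abs(mu)), 0)
})

test_that("a single polarizable atom in a charge's field follows alpha E", {
  a2 <- 0.52917721
  r_bohr <- 9
  ma <- assign_atom_types(perceive_bonds(monomer("Br", c(0, 0, 0))))
  mb <- assign_atom_types(perceive_bonds(monomer("Br", c(r_bohr * a2, 0, 0))))
  d <- build_dimer(ma, mb, "polpair")
  # A polarizable (h = 1), B carries net charge +1 (Z=1, q=0) and is made
  # effectively unpolarizable with a tiny Hirshfeld ratio
  pa <- atomic_properties("Br", q = 0, mu = c(0, 0, 0),
                          theta = array(0, c(3, 3, 1)), Z = 0, sigma = 0.9, h = 1)
  pb <- atomic_properties("Br", q = 0, mu = c(0, 0, 0),
                          theta = array(0, c(3, 3, 1)), Z = 1, sigma = 0.9, h = 1e-9)
  mu <- induced_dipoles(d, list(a = pa, b = pb))
  fac <- free_atom_constants("Br")
  alpha <- fac$alpha_free * 1
  # field magnitude q/r^2 toward the charge; Thole damping ~ 1 at u >> 1
  expect_equal(mu[1, 1], -alpha / r_bohr^2, tolerance = 1e-4)
  expect_lt(max(abs(mu[2, ])), 1e-8)

  # pure polarization energy is stabilizing: -alpha E^2 with K_indu -> 0
  params <- global_parameters()
  params$K_indu[] <- 1e-12
  e <- indu_energy(d, list(a = pa, b = pb), params)
  expect_equal(e / 627.509, -alpha / r_bohr^4, tolerance = 1e-3)
  expect_lt(e, 0)
})

test_that("every component is invariant to swap, rigid motion and reordering", {
  fx <- fixture_dimer(c("methanol", "methanethiol"), seed = 21)
  d <- fx$dimers[[3]]
  pr <- fixture_props(d, fx$props)
  # tight polarization tolerance: the invariance is exact only up to the
  # fixed-point stopping point
  cst <- model_constants(pol_tol = 1e-12)
  e <- total_energy(d, pr, fx$params, cst)
  expect_equal(e$total, e$elst + e$exch + e$indu + e$disp, tolerance = 1e-9)

  sw <- total_energy(swap_dimer(d), list(a = pr$b, b = pr$a), fx$params, cst)
  expect_equal(unlist(sw), unlist(e), tolerance = 1e-12)

  set.seed(2)
  R <- saptfit:::random_rotation()
  rot <- rotate_fixture(d, pr, R, c(4, -1, 2))
  er <- total_energy(rot$dimer, rot$props, fx$params, cst)
  expect_lt(max(abs(unlist(er) - unlist(e))), 1e-9)

  perm <- sample(length(d$monomer_a$element))
  ma <- d$monomer_a
  ma$element <- ma$element[perm]; ma$xyz <- ma$xyz[perm, ]
  ma$bonds <- NULL; ma$species <- NULL
  ma <- assign_atom_types(perceive_bonds(ma))
  ep <- total_energy(build_dimer(ma, d$monomer_b, d$id),
                     list(a = saptfit:::subset_properties(pr$a, perm), b = pr$b),
                     fx$params, cst)
  expect_lt(max(abs(unlist(ep) - unlist(e))), 1e-9)
})

test_that("all four components vanish at large separation", {
  fx <- fixture_dimer(c("methanol", "formaldehyde"), seed = 2)
  d <- fx$dimers[[1]]
  pr <- fixture_props(d, fx$props)
  d$monomer_b$xyz <- d$monomer_b$xyz + 60
  e <- total_energy(d, pr, fx$params)
  expect_lt(max(abs(unlist(e)[1:4])), 2e-3)
})

test_that("missing species parameters are reported by name", {
  fx <- fixture_dimer(c("methanol", "formaldehyde"), seed = 2)
  d <- fx$dimers[[1]]
  pr <- fixture_props(d, fx$props)
  p <- fx$params
  p$K_exch[p$species == "O2"] <- NA
  expect_error(exch_energy(d, pr, p), "O2")
})

test_that("sapt records enforce the component-sum invariant", {
  r <- sapt_record(-1, 2, -0.5, -0.8)
  expect_equal(r$total, -0.3)
  expect_error(sapt_record(NaN, 0, 0, 0), "non-finite")
})
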