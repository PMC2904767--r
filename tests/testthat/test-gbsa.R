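test_that("bundled parameter charges sum to each residue's formal charge", {
  path <- system.file("extdata", "gb_params.txt", package = "tailsolv")
  raw <- utils::read.table(path, header = TRUE, comment.char = "#")
  # independent summation of the file, OXT excluded (terminal-only atom)
  sums <- tapply(raw$charge[raw$elety != "OXT"],
                 raw$resid[raw$elety != "OXT"], sum)
  formal <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1)
  for (r in names(sums)) {
    expect_equal(unname(sums[r]),
                 if (r %in% names(formal)) formal[[r]] else 0,
                 tolerance = 1e-9)
  }
  ps <- default_parameter_set()
  expect_true(all(ps$rho > 0.09))
  expect_true(all(ps$screen > 0 & ps$screen < 1.5))
})

test_that("terminal handling gives the expected net charges", {
  lys <- free_residue("K")
  charged <- assign_parameters(lys, termini = "charged")
  expect_equal(sum(charged$charge), 1, tolerance = 1e-9)  # zwitterion +1
  neutral <- assign_parameters(lys, termini = "neutral")
  expect_equal(sum(neutral$charge), 1 - 0.775, tolerance = 1e-9)
  # a neutral poly-glycine chain has zero net charge with neutral caps
  cfg <- generator_config(seed = 5, core_length = 12,
                          tail_lengths = c(0, 0),
                          core_composition = c(G = 1))
  g <- generate_globule(cfg)
  gg <- g[g$elety != "OXT", ]
  expect_equal(sum(assign_parameters(gg, termini = "neutral")$charge), 0,
               tolerance = 1e-9)
  expect_error(assign_parameters(atom_row(0, 0, 0, elety = "XX")),
               class = "tailsolv_parameterization_error")
})

test_that("an isolated atom's effective radius is the reduced intrinsic radius", {
  ion <- analytic_fixtures()$single_ion
  expect_equal(effective_born_radii(ion)$reff, 4.09 - 0.09)
  lone <- atom_row(0, 0, 0)
  lone$charge <- 0; lone$rho <- 1.70; lone$screen <- 0.72
  expect_equal(effective_born_radii(lone)$reff, 1.61)
})

test_that("burial strictly increases the effective Born radius", {
  centre <- atom_row(0, 0, 0)
  centre$charge <- -1; centre$rho <- 1.52; centre$screen <- 0.85
  u <- matrix(rnorm(3 * 60), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 4.0
  shell <- dplyr::bind_rows(lapply(seq_len(nrow(u)), function(i) {
    r <- atom_row(u[i, 1], u[i, 2], u[i, 3], resindex = 2L)
    r$charge <- 0; r$rho <- 1.70; r$screen <- 0.72
    r
  }))
  free_r <- effective_born_radii(centre)$reff
  buried_r <- effective_born_radii(dplyr::bind_rows(centre, shell))$reff[1]
  expect_gt(buried_r, free_r)
  expect_error(
    effective_born_radii(dplyr::bind_rows(centre, centre)),
    class = "tailsolv_geometry_error")
})

test_that("two-atom descreening matches a numerical volume integral", {
  a <- atom_row(0, 0, 0); a$charge <- 0; a$rho <- 1.70; a$screen <- 0.72
  b <- atom_row(4.5, 0, 0, resindex = 2L)
  b$charge <- 0; b$rho <- 1.55; b$screen <- 0.79
  pair <- dplyr::bind_rows(a, b)
  st <- gbsa_settings()
  rho_red <- pair$rho - st$offset
  I <- tailsolv:::hct_integrals_cpp(as.matrix(pair[, c("x", "y", "z")]),
                                    rho_red, pair$screen * rho_red)
  set.seed(42)
  oracle <- mc_descreen_integral(d = 4.5, s = pair$screen[2] * rho_red[2],
                                 rho_red1 = rho_red[1])
  expect_lt(abs(I[1] - oracle) / oracle, 0.02)
})

test_that("the single-ion polar energy equals the Born formula", {
  ion <- effective_born_radii(analytic_fixtures()$single_ion)
  st <- gbsa_settings()
  e <- gb_polar_energy(ion, st)
  born <- -0.5 * (1 / st$eps_in - 1 / st$eps_solv) *
    st$coulomb_constant * st$kcal_to_kj / ion$reff
  expect_lt(abs(e - born) / abs(born), 1e-12)
  expect_lt(e, 0)   # charged atom always favourable
  ion0 <- ion; ion0$charge <- 0
  expect_equal(gb_polar_energy(ion0, st), 0)
})

test_that("the GB double sum is order-invariant and matches a cutoff path", {
  cfg <- generator_config(seed = 9, core_length = 60,
                          tail_lengths = c(0, 0))
  g <- generate_globule(cfg)
  at <- effective_born_radii(assign_parameters(g))
  expect_gte(nrow(at), 400)
  e_exact <- gb_polar_energy(at, gbsa_settings())
  perm <- at[sample(nrow(at)), ]
  expect_equal(gb_polar_energy(perm, gbsa_settings()), e_exact,
               tolerance = 1e-12)
  e_cut <- gb_polar_energy(at, gbsa_settings(cutoff = 50))
  expect_lt(abs(e_cut - e_exact) / abs(e_exact), 0.001)
})

test_that("the nonpolar term is the surface tension times total area", {
  one <- atom_row(0, 0, 0)
  st <- gbsa_settings()
  expect_equal(sa_nonpolar_energy(one, st),
               st$surface_tension * 4 * pi * (1.7 + 1.4)^2)
  st2 <- gbsa_settings(surface_tension = 2 * st$surface_tension)
  expect_equal(sa_nonpolar_energy(one, st2),
               2 * sa_nonpolar_energy(one, st))
  m <- tiny_construct()$model
  expect_equal(sa_nonpolar_energy(m, st),
               st$surface_tension * sum(shrake_rupley(m)$area))
})

test_that("hydration free energy is frame-independent and composes its parts", {
  m <- tiny_construct()$model
  h <- hydration_free_energy(m)
  expect_equal(h$total, h$polar + h$nonpolar)
  expect_equal(h$normalized, h$total / h$n_residues)
  th <- 1.2
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  m2 <- m
  co <- as.matrix(m[, c("x", "y", "z")]) %*% R
  m2$x <- co[, 1] - 8; m2$y <- co[, 2] + 3; m2$z <- co[, 3] + 15
  h2 <- hydration_free_energy(m2)
  expect_lt(abs(h2$total - h$total) / abs(h$total), 0.005)
})

test_that("removing a charged surface residue makes the polar term less negative", {
  m <- tiny_construct()$model
  tab <- relative_accessibility(residue_sasa(m))
  charged <- tab[tab$code1 %in% c("K", "R", "D", "E") & tab$rel_sa > 0.4, ]
  # hydrophilic tails guarantee exposed charged residues away from the ends
  drop_idx <- charged$resindex[charged$resindex > 1 &
                                 charged$resindex < max(tab$resindex)][1]
  expect_false(is.na(drop_idx))
  pruned <- m[m$resindex != drop_idx, ]
  e_full <- gb_polar_energy(effective_born_radii(assign_parameters(m)))
  e_prun <- gb_polar_energy(effective_born_radii(assign_parameters(pruned)))
  expect_gt(e_prun, e_full)
})

test_that("transfer scaling follows the inverse-dielectric difference", {
  m <- tiny_construct()$model
  st <- gbsa_settings()
  h <- hydration_free_energy(m, settings = st)
  expect_equal(transfer_scaling(h, st$eps_in, st$eps_solv, st), h$total)
  expect_equal(transfer_scaling(h, 10, 10, st), h$nonpolar)
  eps_b <- c(2, 4, 10, 78.5)
  scaled <- vapply(eps_b, function(e) transfer_scaling(h, 1, e, st),
                   numeric(1))
  expect_true(all(diff(scaled) < 0))   # larger 1/a - 1/b, more negative
})
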