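# Shared fixtures and independent oracles, all built in code.

# One atom row of a structure tibble.
atom_row <- function(x, y, z, elety = "C", element = "C", resindex = 1L,
                     resid = "GLY", chain = "A", model = 1L) {
  tibble::tibble(model = model, chain = chain,
                 resindex = as.integer(resindex),
                 resno = as.integer(resindex), insert = "", resid = resid,
                 elety = elety, element = element, x = x, y = y, z = z)
}

# CA-only chain with a given one-letter sequence (for sequence/slicing
# tests that need no side-chain geometry).
ca_chain <- function(seq1, chain = "A", spacing = 3.8) {
  three <- setNames(names(tailsolv:::AA_THREE_TO_ONE),
                    unname(tailsolv:::AA_THREE_TO_ONE))
  rows <- lapply(seq_along(seq1), function(i) {
    atom_row(spacing * i, 0, 0, elety = "CA", resindex = i,
             resid = three[[seq1[i]]], chain = chain)
  })
  dplyr::bind_rows(rows)
}

# Small cached synthetic construct shared across tests.
tiny_construct <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(seed = 7, core_length = 20,
                              tail_lengths = c(8, 6), ensemble_size = 3,
                              noise_scale = 0.4)
      cache <<- list(cfg = cfg,
                     model = attach_tails(generate_globule(cfg), cfg))
    }
    cache
  }
})

# Monte-Carlo SASA oracle: uniform random points on each atom's expanded
# sphere, accessibility tested against all neighbours. Returns per-atom
# areas and their sampling standard errors.
mc_sasa <- function(coords, radii, probe = 1.4, n_pts = 3000) {
  n <- nrow(coords)
  area <- se <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i] + probe
    u <- matrix(stats::rnorm(3 * n_pts), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * ri, 2, coords[i, ], "+")
    acc <- rep(TRUE, n_pts)
    for (j in seq_len(n)) {
      if (j == i) next
      rj <- radii[j] + probe
      d2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
      acc <- acc & d2 >= rj^2
    }
    p <- mean(acc)
    area[i] <- 4 * pi * ri^2 * p
    se[i] <- 4 * pi * ri^2 * sqrt(p * (1 - p) / n_pts)
  }
  list(area = area, se = se)
}

# Monte-Carlo oracle for the pairwise descreening integral of atom 1 by a
# descreening sphere (radius s) centred at distance d: the volume
# integral of 1/r^4 over the sphere, excluding the region inside atom 1's
# reduced radius, divided by 4*pi.
mc_descreen_integral <- function(d, s, rho_red1, n_pts = 4e5) {
  u <- matrix(stats::rnorm(3 * n_pts), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rr <- s * stats::runif(n_pts)^(1 / 3)
  pts <- u * rr
  pts[, 1] <- pts[, 1] + d
  r2 <- rowSums(pts^2)
  f <- ifelse(r2 > rho_red1^2, 1 / r2^2, 0)
  vol <- 4 / 3 * pi * s^3
  vol * mean(f) / (4 * pi)
}
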