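# GB/SA hydration free energy: generalized Born polar term with
# OBC(II)-corrected effective radii from HCT pairwise descreening, plus a
# surface-tension nonpolar term. Works in united heavy-atom mode: the
# bundled parameter file carries, for every standard heavy atom, a partial
# charge (with bonded hydrogens' charges collapsed in), an intrinsic
# radius and an HCT screening scale.

#' Settings for GB/SA energy evaluation
#'
#' @param eps_in Solute dielectric constant.
#' @param eps_solv Solvent dielectric constant.
#' @param offset Intrinsic-radius offset in Angstrom (reduced radius
#'   `rho - offset` enters the descreening integrals).
#' @param obc_alpha,obc_beta,obc_gamma Coefficients of the OBC tanh
#'   correction (model II defaults).
#' @param surface_tension Nonpolar surface coefficient, kJ/(mol A^2).
#' @param coulomb_constant Electrostatic constant, kcal A / (mol e^2).
#' @param kcal_to_kj Unit conversion applied once to reported energies.
#' @param cutoff Pair-distance cutoff in Angstrom for the GB double sum;
#'   `Inf` (default) is the exact reference path.
#' @return List of class `gbsa_settings`.
#' @export
gbsa_settings <- function(eps_in = 1.0, eps_solv = 78.5, offset = 0.09,
                          obc_alpha = 1.0, obc_beta = 0.8, obc_gamma = 4.85,
                          surface_tension = 0.0209,
                          coulomb_constant = 332.0636, kcal_to_kj = 4.184,
                          cutoff = Inf) {
  stopifnot(eps_solv > eps_in, eps_in >= 1, surface_tension >= 0, offset >= 0)
  structure(list(eps_in = eps_in, eps_solv = eps_solv, offset = offset,
                 obc_alpha = obc_alpha, obc_beta = obc_beta,
                 obc_gamma = obc_gamma, surface_tension = surface_tension,
                 coulomb_constant = coulomb_constant,
                 kcal_to_kj = kcal_to_kj, cutoff = cutoff),
            class = "gbsa_settings")
}

#' Bundled united heavy-atom parameter set
#'
#' Reads the plain-text parameter file shipped with the package: one line
#' per (residue, heavy atom) with partial charge (e; hydrogens collapsed
#' onto their bonded heavy atom), intrinsic radius (A) and HCT screening
#' scale. Each residue's charges sum to its integer formal charge.
#'
#' @param path Parameter file; default the bundled table.
#' @return Tibble with `resid`, `elety`, `charge`, `rho`, `screen`.
#' @export
default_parameter_set <- function(path = system.file("extdata",
                                                     "gb_params.txt",
                                                     package = "tailsolv")) {
  if (!nzchar(path) || !file.exists(path)) {
    abort("parameter file not found", class = "tailsolv_io_error")
  }
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Assign GB parameters to the atoms of a structure
#'
#' Joins the parameter set onto the heavy atoms and applies terminal
#' adjustments: by default each chain gets a charged N-terminus (+1 folded
#' onto the backbone nitrogen) and a charged C-terminus (-1 spread over
#' the carboxylate oxygens, using `OXT` when present). With
#' `termini = "neutral"` no adjustment is made.
#'
#' @param x Atom tibble (single model).
#' @param params Parameter set from [default_parameter_set()].
#' @param termini `"charged"` (default) or `"neutral"`.
#' @return Heavy-atom tibble with `charge`, `rho`, `screen` columns.
#' @export
assign_parameters <- function(x, params = default_parameter_set(),
                              termini = c("charged", "neutral")) {
  termini <- match.arg(termini)
  m <- one_model(x)
  m <- m[m$element != "H", , drop = FALSE]
  key <- paste(m$resid, m$elety)
  pk <- paste(params$resid, params$elety)
  hit <- match(key, pk)
  if (anyNA(hit)) {
    bad <- m[is.na(hit), ][1, ]
    abort(paste0("no GB parameters for atom ", bad$elety, " in residue ",
                 bad$resid, " ", bad$resindex),
          class = "tailsolv_parameterization_error")
  }
  m$charge <- params$charge[hit]
  m$rho <- params$rho[hit]
  m$screen <- params$screen[hit]

  if (termini == "charged") {
    for (ch in unique(m$chain)) {
      in_ch <- m$chain == ch
      idx <- range(m$resindex[in_ch])
      # N-terminus: NH3+ united onto the backbone nitrogen
      nt <- in_ch & m$resindex == idx[1] & m$elety == "N"
      m$charge[nt] <- m$charge[nt] + 1.0
      # C-terminus: carboxylate; residue total drops by exactly 1
      ct <- in_ch & m$resindex == idx[2]
      if (any(ct & m$elety == "OXT")) {
        m$charge[ct & m$elety == "O"] <- -0.775
        m$charge[ct & m$elety == "OXT"] <- -0.775
      } else {
        m$charge[ct & m$elety == "O"] <- -1.55
      }
    }
  }
  m
}

#' Effective Born radii (HCT descreening + OBC correction)
#'
#' Computes the pairwise-descreening integral of each atom over all other
#' atoms and applies the OBC tanh rescaling:
#' `1/R = 1/rho_red - tanh(alpha*Psi - beta*Psi^2 + gamma*Psi^3) / rho`,
#' with `Psi = I * rho_red` and `rho_red = rho - offset`. An isolated atom
#' has `R = rho - offset`; burial only increases `R`. Radii are clamped to
#' stay at least `rho_red`.
#'
#' @param atoms Parameterized atoms from [assign_parameters()].
#' @param settings [gbsa_settings()].
#' @return `atoms` with an added `reff` column (Angstrom).
#' @export
effective_born_radii <- function(atoms, settings = gbsa_settings()) {
  co <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(co) > 1 && min_pair_distance_cpp(co) < 1e-6) {
    abort("overlapping identical coordinates",
          class = "tailsolv_geometry_error")
  }
  rho_red <- atoms$rho - settings$offset
  stopifnot(all(rho_red > 0))
  I <- as.numeric(hct_integrals_cpp(co, rho_red, atoms$screen * rho_red))
  psi <- I * rho_red
  inv <- 1 / rho_red -
    tanh(settings$obc_alpha * psi - settings$obc_beta * psi^2 +
           settings$obc_gamma * psi^3) / atoms$rho
  # clamp: effective radius is never below the reduced intrinsic radius;
  # runaway (non-positive inverse) values are capped at a large burial radius
  bad <- !is.finite(inv) | inv <= 0
  reff <- ifelse(bad, 100, 1 / inv)
  reff <- pmax(reff, rho_red)
  atoms$reff <- reff
  atoms
}

#' Generalized Born polar solvation energy
#'
#' `dG_pol = -1/2 (1/eps_in - 1/eps_solv) k_C sum_{i,j} q_i q_j / f_GB`
#' over all atom pairs including self-terms (`f_GB = R_i` for `i = j`),
#' with `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))`.
#'
#' @param atoms Atoms with `charge` and `reff` columns
#'   ([effective_born_radii()]).
#' @param settings [gbsa_settings()].
#' @return Energy in kJ/mol (non-positive for any real charge set).
#' @export
gb_polar_energy <- function(atoms, settings = gbsa_settings()) {
  tau <- 1 / settings$eps_in - 1 / settings$eps_solv
  kc <- settings$coulomb_constant * settings$kcal_to_kj
  cut <- if (is.finite(settings$cutoff)) settings$cutoff else -1
  S <- gb_pair_sum_cpp(as.matrix(atoms[, c("x", "y", "z")]),
                       atoms$charge, atoms$reff, cut)
  -tau * kc * S
}

#' Surface-area nonpolar solvation term
#'
#' `surface_tension * total SASA` of the structure's heavy atoms.
#'
#' @param x Atom tibble (single model).
#' @param settings [gbsa_settings()].
#' @param sasa_settings [sasa_settings()].
#' @return Energy in kJ/mol (non-negative).
#' @export
sa_nonpolar_energy <- function(x, settings = gbsa_settings(),
                               sasa_settings = tailsolv::sasa_settings()) {
  settings$surface_tension * sum(shrake_rupley(x, sasa_settings)$area)
}

#' GB/SA hydration free energy of a structure
#'
#' Polar (generalized Born) plus nonpolar (surface area) solvation energy,
#' absolute and normalized by residue count. Multi-model inputs give one
#' row per model.
#'
#' @param x Atom tibble (single model or ensemble).
#' @param params Parameter set.
#' @param settings [gbsa_settings()].
#' @param sasa_settings [sasa_settings()].
#' @param termini Passed to [assign_parameters()].
#' @param label Optional structure label for the output.
#' @return Tibble with one row per model: `label`, `model`, `polar`,
#'   `nonpolar`, `total`, `normalized` (kJ/mol/residue), `n_residues`.
#' @export
hydration_free_energy <- function(x, params = default_parameter_set(),
                                  settings = gbsa_settings(),
                                  sasa_settings = tailsolv::sasa_settings(),
                                  termini = "charged",
                                  label = "structure") {
  models <- split_models(x)
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    at <- assign_parameters(m, params, termini = termini)
    at <- effective_born_radii(at, settings)
    pol <- gb_polar_energy(at, settings)
    np <- sa_nonpolar_energy(m, settings, sasa_settings)
    nres <- n_residues(m)
    tibble(label = label, model = unique(m$model)[1], polar = pol,
           nonpolar = np, total = pol + np,
           normalized = (pol + np) / nres, n_residues = nres)
  })
  bind_rows(rows)
}

#' Rescale a hydration free energy to a different dielectric transfer
#'
#' The polar part of a transfer free energy between media is proportional
#' to the difference of the inverse dielectric constants. This rescales
#' the polar component of a computed result from the settings' transfer
#' (`eps_in -> eps_solv`) to an arbitrary pair (`eps_a -> eps_b`), leaving
#' the nonpolar term unchanged.
#'
#' @param result One row of [hydration_free_energy()] output.
#' @param eps_a,eps_b Dielectric constants of the two media (>= 1).
#' @param settings The [gbsa_settings()] used to compute `result`.
#' @return Scaled total energy in kJ/mol.
#' @export
transfer_scaling <- function(result, eps_a, eps_b,
                             settings = gbsa_settings()) {
  stopifnot(eps_a >= 1, eps_b >= 1)
  base <- 1 / settings$eps_in - 1 / settings$eps_solv
  scale <- (1 / eps_a - 1 / eps_b) / base
  result$polar * scale + result$nonpolar
}
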