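# Seeded synthetic-structure generator. Builds compact globular cores of
# typical composition, low-complexity hydrophilic terminal tails in
# extended or collapsed conformations, perturbed conformer ensembles,
# filter-test metadata, and small analytic fixtures. Geometry is the
# package's coarse idealized template (see geometry.R): correct
# composition, compactness class, and clash-freedom are the contract, not
# covalent realism.

HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Generator configuration
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   its configuration.
#' @param core_length Core residues (>= 12).
#' @param tail_lengths Integer pair: N- and C-terminal tail lengths.
#' @param tail_composition Named amino-acid probabilities of the tails;
#'   the default is hydrophilic and low-complexity (glycine/proline plus
#'   charged and polar residues).
#' @param core_composition Named probabilities for the core; default the
#'   background composition of globular proteins.
#' @param tail_conformation `"extended"` or `"collapsed"`.
#' @param ensemble_size Number of conformers for [generate_ensemble()].
#' @param noise_scale Core jitter in Angstrom for ensemble conformers.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             core_length = 150,
                             tail_lengths = c(80, 40),
                             tail_composition = c(G = 0.20, P = 0.10,
                                                  R = 0.175, K = 0.175,
                                                  S = 0.10, E = 0.10,
                                                  Q = 0.05, D = 0.05,
                                                  N = 0.05),
                             core_composition = AA_BACKGROUND_FREQ,
                             tail_conformation = c("extended", "collapsed"),
                             ensemble_size = 20,
                             noise_scale = 0.5) {
  tail_conformation <- match.arg(tail_conformation)
  stopifnot(abs(sum(tail_composition) - 1) < 1e-6,
            abs(sum(core_composition) - 1) < 1e-6,
            all(tail_lengths >= 0), noise_scale >= 0, ensemble_size >= 1)
  structure(list(seed = as.integer(seed),
                 core_length = as.integer(core_length),
                 tail_lengths = as.integer(tail_lengths),
                 tail_composition = tail_composition,
                 core_composition = core_composition,
                 tail_conformation = tail_conformation,
                 ensemble_size = as.integer(ensemble_size),
                 noise_scale = noise_scale),
            class = "generator_config")
}

# Run code with a private RNG stream, restoring the caller's state.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rodrigues rotation of vector v about unit axis a by angle (radians).
#' @keywords internal
rotate_about <- function(v, a, ang) {
  v * cos(ang) + c(a[2] * v[3] - a[3] * v[2],
                   a[3] * v[1] - a[1] * v[3],
                   a[1] * v[2] - a[2] * v[1]) * sin(ang) +
    a * sum(a * v) * (1 - cos(ang))
}
# Grow a decorated self-avoiding chain: CA positions and residue
# orientations are chosen together, with backtracking, so side chains
# never paint the chain into a corner. Residues are grown in the order of
# `codes1`/`resindices` (tails grow outward from their anchor; an N-tail
# therefore passes its residues in reversed order). Returns the atom
# tibble in residue-index order, or NULL on failure.
#' @keywords internal
grow_decorated_chain <- function(codes1, resindices, chain, anchor, dir0,
                                 interior, step = 4.0, min_sep = 4.2,
                                 straightness = 0.6, center = NULL,
                                 radius = Inf, prior_atoms = NULL,
                                 prior_ca = NULL, anchor_is_first = TRUE,
                                 oxt_at = integer(0), n_ca_cand = 36,
                                 max_backtrack = 250, clash = 2.0,
                                 junction_relax = 0L) {
  n <- length(codes1)
  stopifnot(length(resindices) == n)
  codes3 <- unname(AA_ONE_TO_THREE[codes1])
  # pre-resolve templates; all growth below works on bare matrices
  tpls <- lapply(seq_len(n), function(i) {
    residue_template_offsets(codes3[i], with_oxt = i %in% oxt_at)
  })
  placed_xyz <- vector("list", n)   # per-residue coordinate matrices
  ca_list <- matrix(NA_real_, n, 3)
  dirs <- matrix(NA_real_, n, 3)
  clash2 <- clash^2
  min2 <- min_sep^2
  i <- 1L
  backtracks <- 0L

  orientation_fit <- function(i, p, e, atoms_m) {
    rad <- p - interior
    nr <- sqrt(sum(rad^2))
    rad <- if (nr < 1e-6) { v <- rnorm(3); v / sqrt(sum(v^2)) } else rad / nr
    side0 <- if (codes1[i] %in% HYDROPHOBIC_AA) -rad else rad
    off <- tpls[[i]]$offsets
    near <- if (!is.null(atoms_m) && nrow(atoms_m) > 0) {
      atoms_m[abs(atoms_m[, 1] - p[1]) < 15 &
                abs(atoms_m[, 2] - p[2]) < 15 &
                abs(atoms_m[, 3] - p[3]) < 15, , drop = FALSE]
    } else NULL
    angles <- c(0, 45, -45, 90, -90, 135, -135, 180) * pi / 180
    try_frame <- function(fr) {
      cm <- off %*% t(fr)
      cm[, 1] <- cm[, 1] + p[1]; cm[, 2] <- cm[, 2] + p[2]
      cm[, 3] <- cm[, 3] + p[3]
      if (!is.null(near) && nrow(near) > 0) {
        for (k in seq_len(nrow(cm))) {
          dx <- near[, 1] - cm[k, 1]; dy <- near[, 2] - cm[k, 2]
          dz <- near[, 3] - cm[k, 3]
          if (min(dx * dx + dy * dy + dz * dz) < clash2) return(NULL)
        }
      }
      cm
    }
    for (a in angles) {
      F0 <- make_frame(e, rotate_about(side0, e, a))
      cm <- try_frame(F0)
      if (!is.null(cm)) return(cm)
      F1 <- F0; F1[, 2] <- -F1[, 2]
      cm <- try_frame(F1)
      if (!is.null(cm)) return(cm)
    }
    for (j in 1:4) {
      v <- rnorm(3)
      cm <- try_frame(make_frame(e, v / sqrt(sum(v^2))))
      if (!is.null(cm)) return(cm)
    }
    NULL
  }

  atoms_m <- prior_atoms   # running matrix of all placed atoms
  n_prior <- if (is.null(prior_atoms)) 0L else nrow(prior_atoms)
  atom_counts <- integer(n)

  while (i <= n) {
    fixed_first <- i == 1L && anchor_is_first
    prev <- if (i == 1L) anchor else ca_list[i - 1L, ]
    base_dir <- if (i == 1L) dir0 else dirs[i - 1L, ]
    base_dir <- base_dir / sqrt(sum(base_dir^2))
    success <- FALSE
    # residues right at a tail/core junction get relaxed constraints:
    # crowded anchors need a variable step and freedom from the CA-CA
    # spacing rule (atom-level clash checks still apply in full)
    relaxed <- !anchor_is_first && i <= junction_relax
    n_try <- if (fixed_first) 12L else if (relaxed) 150L else n_ca_cand
    for (t in seq_len(n_try)) {
      if (fixed_first) {
        p <- anchor
        d <- base_dir
      } else {
        # widen to fully random directions once the biased cone stalls
        d <- if (t > n_try / 2) rnorm(3)
             else straightness * base_dir + rnorm(3)
        d <- d / sqrt(sum(d^2))
        step_i <- if (relaxed) runif(1, 3.8, 4.5) else step
        p <- prev + step_i * d
        if (!is.null(center) && sum((p - center)^2) > radius^2) next
        if (i > 2L) {
          na <- ca_list[seq_len(i - 2L), , drop = FALSE]
          if (min(rowSums(sweep(na, 2, p)^2)) < min2) next
        }
        if (!relaxed && !is.null(prior_ca) && nrow(prior_ca) > 0 &&
            min(rowSums(sweep(prior_ca, 2, p)^2)) < min2) next
      }
      cm <- orientation_fit(i, p, d, atoms_m)
      if (!is.null(cm)) {
        ca_list[i, ] <- p
        dirs[i, ] <- d
        placed_xyz[[i]] <- cm
        atom_counts[i] <- nrow(cm)
        atoms_m <- rbind(atoms_m, cm)
        success <- TRUE
        break
      }
    }
    if (success) { i <- i + 1L; next }
    backtracks <- backtracks + 1L
    if (backtracks > max_backtrack) return(NULL)
    drop_to <- max(1L, i - 2L)
    keep <- n_prior + sum(atom_counts[seq_len(drop_to - 1L)])
    atoms_m <- atoms_m[seq_len(keep), , drop = FALSE]
    for (k in drop_to:min(i, n)) {
      placed_xyz[k] <- list(NULL); atom_counts[k] <- 0L
    }
    i <- drop_to
  }
  rows <- lapply(seq_len(n), function(i) {
    cm <- placed_xyz[[i]]
    nm <- tpls[[i]]$name
    tibble(
      model = 1L, chain = chain, resindex = as.integer(resindices[i]),
      resno = as.integer(resindices[i]), insert = "", resid = codes3[i],
      elety = nm, element = element_from_name(nm),
      x = cm[, 1], y = cm[, 2], z = cm[, 3]
    )
  })
  out <- bind_rows(rows)
  out[order(out$resindex), , drop = FALSE]
}

# Probe whether a chain terminus can host the first residue of a tail:
# try candidate CA positions one step out from the terminal CA with
# clash-checked orientations of a bulky (arginine) template. Termini that
# fail the probe would make tail attachment intractable, so globules are
# regenerated until both ends pass.
#' @keywords internal
anchor_feasible <- function(ca_end, outward, atoms_m, n_try = 400,
                            need = 3, clash = 2.0) {
  off <- residue_template_offsets("ARG")$offsets
  clash2 <- clash^2
  hits <- 0L
  for (t in seq_len(n_try)) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    if (sum(d * outward) < -0.2) next
    p <- ca_end + runif(1, 3.8, 4.5) * d
    near <- atoms_m[abs(atoms_m[, 1] - p[1]) < 14 &
                      abs(atoms_m[, 2] - p[2]) < 14 &
                      abs(atoms_m[, 3] - p[3]) < 14, , drop = FALSE]
    v <- rnorm(3)
    fr <- make_frame(d, v / sqrt(sum(v^2)))
    cm <- sweep(off %*% t(fr), 2, p, "+")
    ok <- TRUE
    if (nrow(near) > 0) {
      for (k in seq_len(nrow(cm))) {
        dx <- near[, 1] - cm[k, 1]; dy <- near[, 2] - cm[k, 2]
        dz <- near[, 3] - cm[k, 3]
        if (min(dx * dx + dy * dy + dz * dz) < clash2) { ok <- FALSE; break }
      }
    }
    if (ok) {
      hits <- hits + 1L
      if (hits >= need) return(TRUE)
    }
  }
  FALSE
}

#' Generate a compact synthetic globule
#'
#' Builds a clash-free compact core: a confined self-avoiding CA trace
#' decorated with coarse residue templates, sequence drawn from the
#' configured core composition. Hydrophobic side chains are biased toward
#' the interior and hydrophilic ones outward, emulating the surface
#' composition of globular proteins. The radius of gyration is kept
#' consistent with globular scaling (`Rg ~ 2.2 N^0.38` Angstrom, within
#' 30 percent).
#'
#' @param config [generator_config()].
#' @return Single-model atom tibble (chain "A", residues
#'   `1..core_length`).
#' @export
generate_globule <- function(config = generator_config()) {
  n <- config$core_length
  if (n < 12) abort("core_length must be >= 12",
                    class = "tailsolv_generation_error")
  with_seed(config$seed, {
    seq1 <- sample(names(config$core_composition), n, replace = TRUE,
                   prob = config$core_composition)
    rg_target <- 2.2 * n^0.38
    r_conf <- 1.35 * rg_target
    for (attempt in 1:60) {
      d0 <- rnorm(3); d0 <- d0 / sqrt(sum(d0^2))
      at <- grow_decorated_chain(seq1, seq_len(n), "A",
                                 anchor = c(0, 0, 0), dir0 = d0,
                                 interior = c(0, 0, 0),
                                 center = c(0, 0, 0), radius = r_conf,
                                 anchor_is_first = TRUE, oxt_at = n)
      if (is.null(at)) next
      ca <- as.matrix(at[at$elety == "CA", c("x", "y", "z")])
      rg_ca <- sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
      if (rg_ca < 0.72 * rg_target || rg_ca > 1.28 * rg_target) next
      if (min_pair_distance_cpp(as.matrix(at[, c("x", "y", "z")])) < 2.0)
        next
      # both termini must be able to host a tail's first residue
      atoms_m <- as.matrix(at[, c("x", "y", "z")])
      cen <- colMeans(atoms_m)
      ends_ok <- TRUE
      for (end in c(1L, n)) {
        ae <- ca[end, ]
        outw <- ae - cen
        outw <- if (sqrt(sum(outw^2)) < 1e-6) c(0, 0, 1)
                else outw / sqrt(sum(outw^2))
        if (!anchor_feasible(ae, outw, atoms_m)) { ends_ok <- FALSE; break }
      }
      if (ends_ok) return(at)
    }
    abort("could not generate a clash-free globule; try another seed",
          class = "tailsolv_generation_error")
  })
}

# Geometry-only tail construction (sequences fixed by the caller); used
# by both attach_tails and the ensemble re-sampler so conformers share
# one sequence. Assumes an RNG stream is already active. `core2` must
# already carry the final residue numbering of the core block.
#' @keywords internal
build_tails <- function(core2, seqs, seqc, conformation) {
  nN <- length(seqs); nC <- length(seqc)
  ncore <- n_residues(core2)
  centroid <- colMeans(as.matrix(core2[, c("x", "y", "z")]))
  ca_core <- as.matrix(core2[core2$elety == "CA", c("x", "y", "z")])
  if (nC > 0) {   # the C-tail supplies the new terminus
    core2 <- core2[core2$elety != "OXT", , drop = FALSE]
  }
  core_atoms <- as.matrix(core2[, c("x", "y", "z")])
  straight <- if (conformation == "extended") 6 else 0.6
  for (attempt in 1:40) {
    parts <- list()
    placed <- core_atoms
    ok <- TRUE
    if (nN > 0) {
      a1 <- ca_core[1, ]
      outw <- a1 - centroid
      if (sqrt(sum(outw^2)) < 1e-6) outw <- rnorm(3)
      outw <- outw / sqrt(sum(outw^2))
      conf <- if (conformation == "collapsed") {
        list(center = a1 + outw * (2.9 * nN^0.38) * 0.7,
             radius = max(8, 2.9 * nN^0.38))
      } else list(center = NULL, radius = Inf)
      at <- grow_decorated_chain(rev(seqs), nN:1, "A", anchor = a1,
                                 dir0 = outw, interior = centroid,
                                 straightness = straight,
                                 center = conf$center,
                                 radius = conf$radius,
                                 prior_atoms = placed,
                                 prior_ca = ca_core[-1, , drop = FALSE],
                                 anchor_is_first = FALSE,
                                 junction_relax = 2L)
      if (is.null(at)) ok <- FALSE
      else {
        parts$ntail <- at
        placed <- rbind(placed, as.matrix(at[, c("x", "y", "z")]))
      }
    }
    if (ok && nC > 0) {
      aL <- ca_core[nrow(ca_core), ]
      outw <- aL - centroid
      if (sqrt(sum(outw^2)) < 1e-6) outw <- rnorm(3)
      outw <- outw / sqrt(sum(outw^2))
      conf <- if (conformation == "collapsed") {
        list(center = aL + outw * (2.9 * nC^0.38) * 0.7,
             radius = max(8, 2.9 * nC^0.38))
      } else list(center = NULL, radius = Inf)
      avoid <- ca_core[-nrow(ca_core), , drop = FALSE]
      if (!is.null(parts$ntail)) {
        avoid <- rbind(avoid,
                       as.matrix(parts$ntail[parts$ntail$elety == "CA",
                                             c("x", "y", "z")]))
      }
      at <- grow_decorated_chain(seqc,
                                 (nN + ncore + 1):(nN + ncore + nC), "A",
                                 anchor = aL, dir0 = outw,
                                 interior = centroid,
                                 straightness = straight,
                                 center = conf$center,
                                 radius = conf$radius,
                                 prior_atoms = placed, prior_ca = avoid,
                                 anchor_is_first = FALSE,
                                 oxt_at = nC, junction_relax = 2L)
      if (is.null(at)) ok <- FALSE
      else parts$ctail <- at
    }
    if (!ok) next
    out <- bind_rows(parts$ntail, core2, parts$ctail)
    out <- out[order(out$resindex), , drop = FALSE]
    # growth already guarantees tail atoms clear everything by the clash
    # threshold; the core itself is taken as given (it may be a jittered
    # conformer whose internal spacing is the ensemble's business)
    return(out)
  }
  NULL
}

#' Attach disordered terminal tails to a core
#'
#' Appends an N-terminal and a C-terminal tail with sequence drawn from
#' the configured tail composition (hydrophilic and low-complexity by
#' default) in an extended or collapsed conformation, clash-checked
#' against the core. Residues are renumbered `1..(nN + core + nC)` so the
#' N-tail is `1..nN`, the core `nN+1..nN+core`, the C-tail the remainder.
#'
#' @param core Atom tibble from [generate_globule()].
#' @param config [generator_config()].
#' @return Single-model atom tibble with tails attached, plus attribute
#'   `segments`: a segment tibble naming `ntail`, `core`, `ctail`.
#' @export
attach_tails <- function(core, config = generator_config()) {
  nN <- config$tail_lengths[1]; nC <- config$tail_lengths[2]
  ncore <- n_residues(core)
  core2 <- core
  core2$resindex <- core2$resindex + nN
  core2$resno <- core2$resno + nN
  if (nN == 0 && nC == 0) {
    attr(core2, "segments") <- segment("core", "A", 1, ncore)
    return(core2)
  }
  with_seed(config$seed + 104729L, {
    seqs <- if (nN > 0)
      sample(names(config$tail_composition), nN, replace = TRUE,
             prob = config$tail_composition) else character(0)
    seqc <- if (nC > 0)
      sample(names(config$tail_composition), nC, replace = TRUE,
             prob = config$tail_composition) else character(0)
    built <- NULL
    for (sub in 0:10) {   # deterministic reseeds; sequence stays fixed
      if (sub > 0) set.seed(config$seed + 104729L + 7577L * sub)
      built <- build_tails(core2, seqs, seqc, config$tail_conformation)
      if (!is.null(built)) break
    }
    if (is.null(built)) {
      abort("could not attach clash-free tails; try another seed",
            class = "tailsolv_generation_error")
    }
    segs <- bind_rows(
      if (nN > 0) segment("ntail", "A", 1, nN),
      segment("core", "A", nN + 1, nN + ncore),
      if (nC > 0) segment("ctail", "A", nN + ncore + 1, nN + ncore + nC)
    )
    attr(built, "segments") <- segs
    built
  })
}

#' Generate an ensemble of perturbed conformers
#'
#' Produces `ensemble_size` conformers of a tailed construct: core atoms
#' are jittered with Gaussian noise of scale `noise_scale` (low
#' diversity), tails are conformationally re-sampled from scratch (high
#' diversity) while keeping the same sequence and atom naming, emulating
#' disordered tails around a stable core. A tail-less model is jittered
#' only.
#'
#' @param model Atom tibble from [attach_tails()] (its `segments`
#'   attribute identifies the tails).
#' @param config [generator_config()].
#' @return Multi-model atom tibble with the `segments` attribute carried
#'   over.
#' @export
generate_ensemble <- function(model, config = generator_config()) {
  segs <- attr(model, "segments")
  nN <- config$tail_lengths[1]; nC <- config$tail_lengths[2]
  has_tails <- !is.null(segs) && any(segs$name %in% c("ntail", "ctail")) &&
    (nN > 0 || nC > 0)
  core_seg <- if (!is.null(segs)) segs[segs$name == "core", ] else NULL
  res_tbl <- residue_table(model)
  models <- vector("list", config$ensemble_size)
  for (m in seq_len(config$ensemble_size)) {
    models[[m]] <- with_seed(config$seed + 7919L * m, {
      if (!has_tails) {
        out <- model
        jit <- matrix(rnorm(3 * nrow(out), sd = config$noise_scale),
                      ncol = 3)
        out$x <- out$x + jit[, 1]; out$y <- out$y + jit[, 2]
        out$z <- out$z + jit[, 3]
        out
      } else {
        core <- extract_segment(model, core_seg)
        jit <- matrix(rnorm(3 * nrow(core), sd = config$noise_scale),
                      ncol = 3)
        core$x <- core$x + jit[, 1]; core$y <- core$y + jit[, 2]
        core$z <- core$z + jit[, 3]
        seqs <- if (nN > 0)
          res_tbl$code1[res_tbl$resindex <= nN] else character(0)
        seqc <- if (nC > 0)
          res_tbl$code1[res_tbl$resindex >
                          max(res_tbl$resindex) - nC] else character(0)
        built <- NULL
        for (sub in 0:20) {
          if (sub > 0) set.seed(config$seed + 7919L * m + 13L * sub)
          built <- build_tails(core, seqs, seqc, config$tail_conformation)
          if (!is.null(built)) break
        }
        if (is.null(built)) {
          abort("could not re-sample clash-free tails for a conformer",
                class = "tailsolv_generation_error")
        }
        built
      }
    })
    models[[m]]$model <- m
  }
  out <- bind_rows(models)
  attr(out, "segments") <- segs
  out
}

#' Generate labelled metadata fixtures for the reference-set filters
#'
#' Produces a metadata table with known ground truth: `n_accept` clean
#' records plus one record failing each individual filter predicate. The
#' `expected_accept` column carries the design label.
#'
#' @param config [generator_config()] (only the seed is used).
#' @param n_accept Number of designed-accept records.
#' @return Metadata tibble with an `expected_accept` column.
#' @export
generate_metadata <- function(config = generator_config(), n_accept = 5) {
  with_seed(config$seed + 2971L, {
    clean <- function(id) tibble(
      id = id, method = "X-ray",
      resolution = round(runif(1, 1.0, 2.5), 2),
      r_factor = round(runif(1, 0.15, 0.29), 3),
      length = sample(40:600, 1),
      has_chain_breaks = FALSE, has_nonstandard = FALSE,
      all_side_chains_resolved = TRUE, is_mutant = FALSE,
      is_complexed = FALSE, is_fragment = FALSE, is_membrane = FALSE,
      expected_accept = TRUE
    )
    accepts <- bind_rows(lapply(sprintf("OK%02d", seq_len(n_accept)),
                                clean))
    spoil <- function(id, field, value) {
      r <- clean(id); r[[field]] <- value; r$expected_accept <- FALSE; r
    }
    rejects <- bind_rows(
      spoil("BADMETH", "method", "NMR"),
      spoil("BADRES", "resolution", 2.6),
      spoil("BADRFAC", "r_factor", 0.35),
      spoil("BADLEN", "length", 39L),
      spoil("BADBRK", "has_chain_breaks", TRUE),
      spoil("BADNST", "has_nonstandard", TRUE),
      spoil("BADSC", "all_side_chains_resolved", FALSE),
      spoil("BADMUT", "is_mutant", TRUE),
      spoil("BADCPX", "is_complexed", TRUE),
      spoil("BADFRG", "is_fragment", TRUE),
      spoil("BADMEM", "is_membrane", TRUE)
    )
    out <- bind_rows(accepts, rejects)
    out[sample(nrow(out)), ]
  })
}

#' Analytic test fixtures
#'
#' Small exactly-solvable structures: a single ion (one charged atom with
#' GB parameters attached), a two-sphere pair at a chosen separation, a
#' symmetric dumbbell, a continuous ideal CA helix and the same helix
#' with one residue deleted mid-chain.
#'
#' @param separation Centre distance of the two-sphere pair and dumbbell
#'   (Angstrom).
#' @param helix_length Residues in the helix fixtures.
#' @return Named list of atom tibbles.
#' @export
analytic_fixtures <- function(separation = 4.0, helix_length = 12) {
  atom_row <- function(x, y, z, elety = "C", element = "C",
                       resindex = 1L, resid = "GLY") {
    tibble(model = 1L, chain = "A", resindex = as.integer(resindex),
           resno = as.integer(resindex), insert = "", resid = resid,
           elety = elety, element = element, x = x, y = y, z = z)
  }
  single_ion <- atom_row(0, 0, 0, elety = "ION", element = "N")
  single_ion$charge <- 1.0
  single_ion$rho <- 4.09
  single_ion$screen <- 0.8

  two_sphere <- bind_rows(atom_row(0, 0, 0),
                          atom_row(separation, 0, 0, resindex = 2L))

  helix <- function(n, skip = integer(0)) {
    kept <- setdiff(seq_len(n), skip)
    rows <- lapply(seq_along(kept), function(i) {
      k <- kept[i]
      atom_row(2.3 * cos(k * 100 * pi / 180),
               2.3 * sin(k * 100 * pi / 180), 1.5 * k,
               elety = "CA", resindex = i, resid = "ALA")
    })
    out <- bind_rows(rows)
    out$resno <- as.integer(kept)  # numbering keeps the gap visible
    out
  }
  list(single_ion = single_ion,
       two_sphere = two_sphere,
       dumbbell = two_sphere,
       helix_continuous = helix(helix_length),
       helix_with_gap = helix(helix_length,
                              skip = ceiling(helix_length / 2)))
}

#' Small deterministic demo construct
#'
#' A 24-residue synthetic globule with short hydrophilic tails, handy for
#' examples and quick checks.
#' @return Single-model atom tibble.
#' @export
synthetic_globule_demo <- function() {
  cfg <- generator_config(seed = 42, core_length = 24,
                          tail_lengths = c(6, 4), ensemble_size = 2)
  attach_tails(generate_globule(cfg), cfg)
}
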