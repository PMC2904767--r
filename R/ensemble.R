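# Ensemble structural descriptors: radius of gyration, Kabsch
# superposition, backbone RMSD, all-against-all RMSD statistics,
# trajectory time-series summaries, and percentile placement of a query
# against a reference distribution.

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the heavy atoms from the
#' centre of mass, per model.
#'
#' @param x Atom tibble (single model or ensemble).
#' @param mass_weighted Use atomic masses (default); otherwise uniform
#'   weights.
#' @return Tibble with `model` and `rg` (Angstrom).
#' @export
radius_of_gyration <- function(x, mass_weighted = TRUE) {
  rows <- lapply(split_models(x), function(m) {
    h <- m[m$element != "H", , drop = FALSE]
    stopifnot(nrow(h) >= 1)
    w <- if (mass_weighted) unname(ELEMENT_MASS[h$element]) else
      rep(1, nrow(h))
    co <- as.matrix(h[, c("x", "y", "z")])
    com <- colSums(co * w) / sum(w)
    d2 <- rowSums(sweep(co, 2, com)^2)
    tibble(model = m$model[1], rg = sqrt(sum(w * d2) / sum(w)))
  })
  bind_rows(rows)
}

# Matched coordinate matrices for two structures on an atom-name selection.
#' @keywords internal
matched_coords <- function(a, b, atom_names = c("N", "CA", "C", "O")) {
  a <- one_model(a); b <- one_model(b)
  a <- a[a$elety %in% atom_names, , drop = FALSE]
  b <- b[b$elety %in% atom_names, , drop = FALSE]
  ka <- paste(a$chain, a$resindex, a$elety)
  kb <- paste(b$chain, b$resindex, b$elety)
  hit <- match(ka, kb)
  if (anyNA(hit) || nrow(a) != nrow(b)) {
    abort("structures do not share the selected atoms",
          class = "tailsolv_correspondence_error")
  }
  list(a = as.matrix(a[, c("x", "y", "z")]),
       b = as.matrix(b[hit, c("x", "y", "z")]))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `target` over a matched
#' atom selection; always a proper rotation (determinant +1).
#'
#' @param mobile,target Single-model atom tibbles with corresponding
#'   residues.
#' @param atom_names Atom-name selection (default backbone N, CA, C, O).
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   over the selection, and `transformed` (the full mobile tibble moved
#'   into the target frame).
#' @export
kabsch_superpose <- function(mobile, target,
                             atom_names = c("N", "CA", "C", "O")) {
  mc <- matched_coords(mobile, target, atom_names)
  A <- mc$a; B <- mc$b
  if (nrow(A) < 3) {
    abort("need at least 3 atoms for superposition",
          class = "tailsolv_degenerate_geometry_error")
  }
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (qr(A0)$rank < 2) {
    abort("selected atoms are collinear",
          class = "tailsolv_degenerate_geometry_error")
  }
  s <- svd(t(A0) %*% B0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cb - as.vector(R %*% ca)
  fit <- sweep(A0 %*% t(R), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  moved <- mobile
  co <- as.matrix(moved[, c("x", "y", "z")]) %*% t(R)
  co <- sweep(co, 2, t_vec, "+")
  moved$x <- co[, 1]; moved$y <- co[, 2]; moved$z <- co[, 3]
  list(rotation = R, translation = t_vec, rmsd = rmsd, transformed = moved)
}

#' Backbone RMSD after optimal superposition
#'
#' @param a,b Single-model atom tibbles with identical sequences.
#' @param atom_names Backbone selection (N, CA, C, O by default).
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(a, b, atom_names = c("N", "CA", "C", "O")) {
  kabsch_superpose(a, b, atom_names)$rmsd
}

#' All-against-all pairwise RMSD matrix
#'
#' Backbone RMSD between every unordered pair of ensemble models,
#' restricted to a segment when given; superposition is performed on the
#' segment itself (tails fitted on tails, cores on cores).
#'
#' @param ensemble Multi-model atom tibble (>= 2 models).
#' @param seg Optional segment tibble restricting the comparison.
#' @return Symmetric matrix of RMSDs with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(ensemble, seg = NULL) {
  models <- split_models(ensemble)
  n <- length(models)
  if (n < 2) {
    abort("need at least 2 models", class = "tailsolv_ensemble_error")
  }
  if (!is.null(seg)) models <- lapply(models, extract_segment, seg = seg)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- backbone_rmsd(models[[i]], models[[j]])
    }
  }
  dimnames(M) <- list(names(models), names(models))
  M
}

#' Mean and SD of pairwise RMSDs
#'
#' @param ensemble Multi-model atom tibble.
#' @param seg Optional segment restriction.
#' @return Tibble with `segment`, `n_models`, `n_pairs`, `mean_rmsd`,
#'   `sd_rmsd` (sample SD; 0 for a single pair).
#' @export
pairwise_rmsd_stats <- function(ensemble, seg = NULL) {
  M <- pairwise_rmsd_matrix(ensemble, seg)
  v <- M[upper.tri(M)]
  tibble(segment = if (is.null(seg)) "all" else paste(seg$name,
                                                      collapse = "+"),
         n_models = nrow(M), n_pairs = length(v),
         mean_rmsd = mean(v),
         sd_rmsd = if (length(v) > 1) sd(v) else 0)
}

#' Frame-wise statistics across trajectories
#'
#' Given per-frame scalars from several trajectories (rows = trajectories,
#' columns = frames, or a long tibble with `trajectory`, `frame`, `value`),
#' returns the per-frame mean and sample SD across trajectories.
#'
#' @param trajectories Numeric matrix or long tibble.
#' @return Tibble with `frame`, `mean`, `sd`, `n`.
#' @export
timeseries_stats <- function(trajectories) {
  if (is.data.frame(trajectories)) {
    need <- c("trajectory", "frame", "value")
    if (!all(need %in% names(trajectories))) {
      abort("long input needs trajectory/frame/value columns",
            class = "tailsolv_shape_error")
    }
    wide <- tidyr::pivot_wider(trajectories[, need],
                               names_from = "frame",
                               values_from = "value")
    M <- as.matrix(wide[, -1, drop = FALSE])
    frames <- names(wide)[-1]
    num <- suppressWarnings(as.numeric(frames))
    if (!anyNA(num)) frames <- num
  } else {
    M <- as.matrix(trajectories)
    frames <- seq_len(ncol(M))
  }
  if (anyNA(M)) {
    abort("ragged trajectories: all trajectories must cover every frame",
          class = "tailsolv_shape_error")
  }
  tibble(
    frame = frames,
    mean = unname(colMeans(M)),
    sd = if (nrow(M) > 1) unname(apply(M, 2, sd)) else rep(0, ncol(M)),
    n = nrow(M)
  )
}

#' Reference distribution of per-protein scalars
#'
#' @param values Numeric vector (e.g. size-normalized hydration free
#'   energies of a reference set).
#' @param labels Optional labels, recycled/defaulted to indices.
#' @return Object of class `ref_distribution`.
#' @export
ref_distribution <- function(values, labels = NULL) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  if (is.null(labels)) labels <- as.character(seq_along(values))
  structure(list(values = as.numeric(values), labels = labels),
            class = "ref_distribution")
}

#' Percentage of reference values more positive than a query
#'
#' Strictly greater-than count: ties are not counted as more positive.
#'
#' @param ref A `ref_distribution` or numeric vector.
#' @param query Scalar query value.
#' @return Percentage in `[0, 100]`.
#' @export
percentile_more_positive <- function(ref, query) {
  v <- if (inherits(ref, "ref_distribution")) ref$values else ref
  stopifnot(length(v) >= 1)
  100 * sum(v > query) / length(v)
}

#' Summary of a reference distribution
#'
#' @param ref A `ref_distribution` or numeric vector.
#' @return Tibble with `mean`, `sd` (sample SD; 0 with `sd_defined =
#'   FALSE` for a single value) and `n`.
#' @export
distribution_summary <- function(ref) {
  v <- if (inherits(ref, "ref_distribution")) ref$values else ref
  stopifnot(length(v) >= 1)
  tibble(mean = mean(v),
         sd = if (length(v) > 1) sd(v) else 0,
         sd_defined = length(v) > 1,
         n = length(v))
}

#' Fixed-width histogram bins of a reference distribution
#'
#' @param ref A `ref_distribution` or numeric vector.
#' @param n_bins Number of equal-width bins.
#' @return Tibble with `bin_mid`, `bin_lo`, `bin_hi`, `count`.
#' @export
distribution_bins <- function(ref, n_bins = 20) {
  v <- if (inherits(ref, "ref_distribution")) ref$values else ref
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  ct <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
  tibble(bin_lo = br[-length(br)], bin_hi = br[-1],
         bin_mid = (br[-1] + br[-length(br)]) / 2, count = ct)
}
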