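# Sequence Shannon entropy of composite surface sequences: residues of a
# segment whose relative solvent accessibility clears a cutoff are strung
# together (order is irrelevant) and their amino-acid frequencies
# summarised by H = -sum p_i ln p_i.

#' Composite sequence of solvent-exposed residues
#'
#' Collects the one-letter codes of the residues of a segment (or the
#' whole structure) whose relative accessibility is at least `cutoff`.
#' At cutoff 0 the composite is the full segment sequence.
#'
#' @param table Accessibility table with `rel_sa` filled
#'   ([relative_accessibility()]).
#' @param seg Segment tibble, or `NULL` for the whole structure.
#' @param cutoff Relative-accessibility cutoff.
#' @return Character scalar (possibly empty) of one-letter codes.
#' @export
composite_sequence <- function(table, seg = NULL, cutoff = 0) {
  rows <- surface_residues(table, cutoff)
  if (!is.null(seg)) {
    keep <- rep(FALSE, nrow(rows))
    for (i in seq_len(nrow(seg))) {
      keep <- keep | (rows$chain == seg$chain[i] &
                        rows$resindex >= seg$first[i] &
                        rows$resindex <= seg$last[i])
    }
    rows <- rows[keep, , drop = FALSE]
  }
  paste(rows$code1, collapse = "")
}

#' Shannon entropy of an amino-acid sequence
#'
#' `H = -sum_i p_i ln(p_i)` over the amino-acid types present, where `p_i`
#' is the relative frequency of type `i` in the sequence. Natural
#' logarithm, so the maximum (uniform use of all 20 types) is
#' `ln 20 ~ 2.996`. Independent of residue order.
#'
#' @param seq One-letter amino-acid string.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(seq) {
  letters_ <- strsplit(seq, "")[[1]]
  if (length(letters_) == 0) {
    abort("entropy of an empty sequence is undefined",
          class = "tailsolv_empty_sequence_error")
  }
  p <- table(letters_) / length(letters_)
  -sum(p * log(p))
}

#' Entropy of a composition vector
#'
#' Same statistic as [shannon_entropy()] evaluated directly on amino-acid
#' probabilities (e.g. a generator's requested composition).
#' @param p Named or unnamed probability vector (summing to 1).
#' @return Entropy in nats.
#' @export
composition_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy sweep over accessibility cutoffs
#'
#' For each (segment, cutoff) pair, builds the composite sequence of
#' residues at or above the cutoff and evaluates its Shannon entropy.
#' Composites that become empty are kept as rows with `NA` entropy and
#' flagged, never silently dropped.
#'
#' @param table Accessibility table with `rel_sa` filled.
#' @param segs Segment tibble; a row with name "all" and `NA` chain may be
#'   used for the whole structure, or pass `include_whole = TRUE`.
#' @param cutoffs Ascending numeric cutoffs (default 0 to 0.5 by 0.05).
#' @param include_whole Also sweep the whole structure as segment "all".
#' @return Tibble: `segment`, `cutoff`, `n_residues`, `entropy`, `empty`.
#' @export
entropy_sweep <- function(table, segs,
                          cutoffs = seq(0, 0.5, by = 0.05),
                          include_whole = FALSE) {
  stopifnot(!is.unsorted(cutoffs))
  work <- lapply(seq_len(nrow(segs)), function(i) {
    list(name = segs$name[i], seg = segs[i, , drop = FALSE])
  })
  if (include_whole) work <- c(work, list(list(name = "all", seg = NULL)))
  out <- lapply(work, function(w) {
    rows <- lapply(cutoffs, function(ct) {
      cs <- composite_sequence(table, w$seg, ct)
      n <- nchar(cs)
      tibble(segment = w$name, cutoff = ct, n_residues = n,
             entropy = if (n > 0) shannon_entropy(cs) else NA_real_,
             empty = n == 0)
    })
    bind_rows(rows)
  })
  out <- bind_rows(out)
  if (any(out$empty)) {
    warn(paste0(sum(out$empty), " empty composite(s) in entropy sweep"))
  }
  structure(out, class = c("entropy_sweep", class(out)))
}

#' Ensemble entropy statistics
#'
#' Computes the entropy sweep for every model of an ensemble (each model
#' gets its own accessibility table) and then averages: mean and sample
#' standard deviation of the per-model entropies for each (segment,
#' cutoff). Empty composites are excluded from the statistics with a
#' warning.
#'
#' @param ensemble Multi-model atom tibble.
#' @param segs Segment tibble.
#' @param cutoffs Ascending cutoffs.
#' @param settings [sasa_settings()].
#' @param include_whole Also sweep the whole structure.
#' @return Tibble: `segment`, `cutoff`, `n_models`, `mean_entropy`,
#'   `sd_entropy`.
#' @export
ensemble_entropy_stats <- function(ensemble, segs,
                                   cutoffs = seq(0, 0.5, by = 0.05),
                                   settings = sasa_settings(),
                                   include_whole = FALSE) {
  models <- split_models(ensemble)
  stopifnot(length(models) >= 1)
  ref <- max_sa_reference(settings)
  per_model <- lapply(seq_along(models), function(i) {
    tab <- relative_accessibility(residue_sasa(models[[i]], settings), ref)
    sw <- suppressWarnings(
      entropy_sweep(tab, segs, cutoffs, include_whole = include_whole))
    sw$model <- i
    sw
  })
  all <- bind_rows(per_model)
  if (any(all$empty)) {
    warn(paste0(sum(all$empty),
                " empty composite(s) excluded from ensemble entropy means"))
  }
  all %>%
    group_by(.data$segment, .data$cutoff) %>%
    summarise(
      n_models = sum(!is.na(.data$entropy)),
      mean_entropy = mean(.data$entropy, na.rm = TRUE),
      sd_entropy = if (sum(!is.na(.data$entropy)) > 1)
        sd(.data$entropy, na.rm = TRUE) else 0,
      .groups = "drop"
    )
}
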