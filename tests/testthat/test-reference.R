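meta_row <- function(...) {
  base <- tibble::tibble(
    id = "X", method = "X-ray", resolution = 2.0, r_factor = 0.2,
    length = 100L, has_chain_breaks = FALSE, has_nonstandard = FALSE,
    all_side_chains_resolved = TRUE, is_mutant = FALSE,
    is_complexed = FALSE, is_fragment = FALSE, is_membrane = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("filter thresholds accept and reject at the documented bounds", {
  ok <- passes_filters(meta_row(resolution = 2.4, r_factor = 0.25,
                                length = 100L))
  expect_true(ok$accept)
  expect_equal(ok$reasons, "")
  res <- passes_filters(meta_row(resolution = 2.6))
  expect_false(res$accept)
  expect_match(res$reasons, "resolution")
  expect_false(passes_filters(meta_row(length = 39L))$accept)
  expect_true(passes_filters(meta_row(length = 40L))$accept)
  expect_true(passes_filters(meta_row(resolution = 2.5,
                                      r_factor = 0.3))$accept)
  expect_false(passes_filters(meta_row(method = "NMR"))$accept)
  expect_error(passes_filters(meta_row()[, -3]),
               class = "tailsolv_metadata_error")
})

test_that("the filter is a pure conjunction: relaxing a threshold never shrinks the set", {
  md <- generate_metadata(generator_config(seed = 31))
  strict <- passes_filters(md)
  for (relax in list(c(max_resolution = 3.5), c(max_r_factor = 0.5),
                     c(min_length = 10))) {
    loose <- do.call(passes_filters, c(list(md), as.list(relax)))
    expect_true(all(loose$accept[strict$accept]))
  }
})

test_that("designed metadata reproduces its ground-truth accept set exactly", {
  md <- generate_metadata(generator_config(seed = 13))
  out <- passes_filters(md)
  expect_equal(out$accept, out$expected_accept)
  # every predicate appears as a designed failure
  fails <- unlist(strsplit(out$reasons[!out$accept], ";"))
  expect_setequal(unique(fails),
                  c("method", "resolution", "r_factor", "length",
                    "chain_breaks", "nonstandard", "side_chains",
                    "mutant", "complexed", "fragment", "membrane"))
  # shuffling the records does not change who is accepted
  md2 <- md[rev(seq_len(nrow(md))), ]
  out2 <- passes_filters(md2)
  expect_setequal(out$id[out$accept], out2$id[out2$accept])
})

test_that("chain breaks are found by CA gap or numbering jump", {
  fx <- analytic_fixtures(helix_length = 14)
  expect_equal(nrow(detect_chain_breaks(fx$helix_continuous)), 0)
  brk <- detect_chain_breaks(fx$helix_with_gap)
  expect_equal(nrow(brk), 1)
  expect_true(brk$numbering_gap)
  # brute-force distance scan on a continuous chain agrees at any cutoff
  ca <- fx$helix_continuous
  for (cut in c(3.0, 3.5)) {
    got <- detect_chain_breaks(ca, max_ca_gap = cut)
    co <- as.matrix(ca[, c("x", "y", "z")])
    d <- sqrt(rowSums((co[-1, ] - co[-nrow(co), ])^2))
    expect_equal(nrow(got), sum(d > cut))
  }
  noca <- atom_row(0, 0, 0, elety = "CB")
  expect_error(detect_chain_breaks(noca),
               class = "tailsolv_geometry_error")
})

test_that("generator-produced chains are always break-free", {
  for (s in c(2, 9)) {
    cfg <- generator_config(seed = s, core_length = 25,
                            tail_lengths = c(6, 4))
    m <- attach_tails(generate_globule(cfg), cfg)
    expect_equal(nrow(detect_chain_breaks(m, max_ca_gap = 4.5)), 0)
  }
})

test_that("reference distributions are per-model hydration energies", {
  expect_error(build_reference_distribution(list()),
               class = "tailsolv_input_error")
  cfgs <- lapply(c(41, 42, 43), function(s)
    generator_config(seed = s, core_length = 15, tail_lengths = c(0, 0)))
  globs <- lapply(cfgs, generate_globule)
  ref <- build_reference_distribution(globs)
  expect_length(ref$values, 3)
  direct <- vapply(globs, function(g)
    hydration_free_energy(g)$normalized, numeric(1))
  expect_equal(ref$values, direct)
  one <- build_reference_distribution(globs[1])
  expect_length(one$values, 1)
})
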