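# Fixtures built in code: ideal helices, minimal custom fragments, and
# small landscape/sample bundles shared across test files.

fixture_helix <- function(n = 12, seq = NULL, first = 1L) {
  seq <- seq %||% paste(rep(c("A", "E", "L", "K", "L"), length.out = n),
                        collapse = "")
  build_ideal_helix(seq, first_residue = first)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-residue fragment with atoms at explicit positions (nm)
fixture_residue <- function(resno, ca, extra = NULL, extra_name = "CB",
                            extra_element = "C") {
  coords <- rbind(ca, extra)
  names <- c("CA", if (!is.null(extra)) rep(extra_name, nrow(coords) - 1))
  elements <- c("C", if (!is.null(extra)) rep(extra_element, nrow(coords) - 1))
  new_fragment(residue_ids = resno, sequence = "A",
               atom_names = names, elements = elements,
               coords = coords, atom_resno = rep(resno, nrow(coords)))
}

# wrap a bare PMF curve in the hp_pmf container for bookkeeping tests
fixture_pmf <- function(d, G, sem = rep(0, length(d)),
                        bin_width = d[2] - d[1],
                        reference_range = range(d), orientation = "fixture") {
  structure(list(profile = data.frame(d = d, G = G, sem = sem,
                                      n = rep(1e4, length(d))),
                 bin_width = bin_width, reference_range = reference_range,
                 orientation = orientation, angle_targets = c(0, 0),
                 window_free_energies = numeric(),
                 temperature_K = 300),
            class = "hp_pmf")
}

# manual window-sample container for decomposition tests
fixture_samples <- function(series, d0 = 1.0, k = 2000,
                            targets = c(0, 0)) {
  structure(list(window = new_window(d0, k),
                 angle_bias = new_angle_bias(targets),
                 series = series, stride = 1L, seed = 1L),
            class = "hp_window_samples")
}
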