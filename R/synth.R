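# Gaussian-band basis shapes for far-UV CD simulation.
#
# Band parameters (centre nm, width nm, amplitude in delta-epsilon per
# molar residue) are package-defined constants chosen to reproduce the
# canonical far-UV shapes: alpha-helix with negative bands near 222 and
# 208 nm and a strong positive band near 193 nm; beta-sheet with a
# negative band near 218 nm and a positive one near 196 nm; random coil
# with a strong negative band near 198 nm and a weak positive one near
# 220 nm; plus a weak "folded other" (turn-like) shape. They are tuned
# for plausibility, not to match any measured protein spectrum.
BASIS_BANDS <- data.frame(
  component = c("helix", "helix", "helix",
                "sheet", "sheet",
                "turn", "turn", "turn",
                "coil", "coil"),
  centre_nm = c(193, 208, 222,   196, 218,   188, 206, 222,   198, 220),
  width_nm  = c(6.5, 7.5, 9.0,   7.0, 9.5,   6.0, 8.0, 10.0,  7.0, 11.0),
  amplitude = c(21.5, -11.0, -11.5,  7.5, -4.8,  -6.0, 2.8, -1.0,  -12.0, 0.9),
  stringsAsFactors = FALSE)

gauss_band <- function(wl, centre, width, amp) {
  amp * exp(-(wl - centre)^2 / (2 * width^2))
}

#' Basis spectra for synthetic CD data
#'
#' Pure-component far-UV CD shapes (alpha-helix, beta-sheet, turn-like
#' folded "other", random coil) built as sums of Gaussian bands; see
#' `cd_basis()$bands` for the parameter table.
#'
#' @param grid a [wavelength_grid()].
#' @return An object of class `cd_basis` with the band table and a
#'   `spectra` matrix (rows helix, sheet, turn, coil).
#' @export
cd_basis <- function(grid = wavelength_grid()) {
  wl <- grid$wavelengths
  comps <- c("helix", "sheet", "turn", "coil")
  M <- t(vapply(comps, function(cp) {
    b <- BASIS_BANDS[BASIS_BANDS$component == cp, ]
    Reduce(`+`, lapply(seq_len(nrow(b)), function(i)
      gauss_band(wl, b$centre_nm[i], b$width_nm[i], b$amplitude[i])))
  }, numeric(length(wl))))
  structure(list(grid = grid, bands = BASIS_BANDS, spectra = M),
            class = "cd_basis")
}

#' Synthesise a CD spectrum from 5-class structure fractions
#'
#' Helix and sheet use their own basis shapes; turn and bend use the
#' folded-other shape; loop and any unannotated residual use the
#' random-coil shape (only genuinely disordered mass pulls the spectrum
#' toward the coil signature).
#'
#' @param s5 a [structure_fractions5()].
#' @param basis a [cd_basis()].
#' @param label,temperature_C passed to [cd_spectrum()].
#' @return A [cd_spectrum()].
#' @export
synth_spectrum <- function(s5, basis = cd_basis(), label = "",
                           temperature_C = NULL) {
  stopifnot(inherits(s5, "structure_fractions5"), inherits(basis, "cd_basis"))
  B <- basis$spectra
  v <- s5["helix"] * B["helix", ] + s5["sheet"] * B["sheet", ] +
    (s5["turn"] + s5["bend"]) * B["turn", ] +
    (s5["loop"] + (1 - sum(s5))) * B["coil", ]
  cd_spectrum(as.numeric(v), basis$grid, label, temperature_C)
}

#' The synthetic random-coil reference spectrum
#'
#' The coil basis spectrum, labelled `"RC"` — a synthetic stand-in for an
#' unfolded-peptide reference spectrum, with the characteristic strong
#' negative band near 198 nm and near-zero 222 nm intensity.
#'
#' @param basis a [cd_basis()].
#' @return A [cd_spectrum()].
#' @export
make_rc_spectrum <- function(basis = cd_basis()) {
  cd_spectrum(as.numeric(basis$spectra["coil", ]), basis$grid, label = "RC")
}

# Dirichlet sample via gamma draws
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic structure-annotated reference set
#'
#' Entries sample realistic folded compositions (Dirichlet over helix,
#' sheet, turn, bend, loop and an unannotated residual, with loop kept
#' small for folded proteins), augmented — mirroring how experimental
#' reference sets are augmented for unfolded-domain work — with a few
#' near-fully-unfolded and near-fully-helical entries. Spectra are
#' fraction-weighted basis combinations plus i.i.d. Gaussian noise; the
#' generating fractions are recorded as the annotations, so ground truth
#' is known exactly.
#'
#' @param n number of entries (>= 1).
#' @param seed integer random seed; generation is deterministic given it.
#' @param noise_sd Gaussian noise standard deviation in delta-epsilon
#'   units (0 for noiseless).
#' @param basis a [cd_basis()].
#' @return A [reference_set()] with entries named `ref01`, `ref02`, ...
#' @export
make_reference_set <- function(n, seed = 1L, noise_sd = 0,
                               basis = cd_basis()) {
  if (!is.numeric(n) || n < 1) stop("n must be at least 1")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  n_unf <- if (n >= 12) 4L else if (n >= 6) 2L else if (n >= 3) 1L else 0L
  n_hel <- if (n >= 12) 2L else if (n >= 6) 1L else 0L
  kind <- c(rep("unfolded", n_unf), rep("helical", n_hel),
            rep("folded", n - n_unf - n_hel))
  kind <- kind[sample.int(n)]  # scatter the augmentation through the set
  P <- length(basis$grid)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    s5 <- switch(
      kind[i],
      unfolded = {
        lp <- stats::runif(1, 0.85, 0.95)
        structure_fractions5(0, 0, stats::runif(1, 0, (1 - lp) / 2), 0, lp)
      },
      helical = {
        h <- stats::runif(1, 0.9, 1.0)
        structure_fractions5(h, 0, stats::runif(1, 0, (1 - h) / 2), 0, 0)
      },
      folded = {
        f <- rdirichlet1(c(2.2, 1.6, 1.1, 0.9, 0.35, 0.35))
        structure_fractions5(f[1], f[2], f[3], f[4], f[5])
      })
    nm <- sprintf("ref%02d", i)
    sp <- synth_spectrum(s5, basis, label = nm)
    if (noise_sd > 0)
      sp <- cd_spectrum(sp$values + stats::rnorm(P, 0, noise_sd), basis$grid,
                        label = nm)
    entries[[i]] <- reference_entry(sp, s5, nm, i)
  }
  reference_set(entries)
}

#' Generate a synthetic thermal melting series
#'
#' Emulates two-state partial unfolding: at each temperature the spectrum
#' is `(1 - f) * core + f * RC` plus optional Gaussian noise, where `core`
#' is the folded-protein spectrum built from 3-class fractions (helix and
#' sheet use their basis shapes; core "other" uses the folded turn-like
#' shape) and `f` follows the supplied schedule. Optionally the core helix
#' content itself decays linearly with temperature (transferred into core
#' "other") to emulate proteins that also rearrange internally. The
#' per-temperature ground truth (core fractions, `f`, and the regenerated
#' fractions of the full protein) is recorded in `$truth`.
#'
#' @param core a [structure_fractions3()] of the folded core at the lowest
#'   temperature.
#' @param f_schedule random-coil fractions in `[0, 1]`, one per
#'   temperature.
#' @param temperatures_C strictly increasing temperatures (default 20--100
#'   in steps of 10).
#' @param noise_sd Gaussian noise sd in delta-epsilon units.
#' @param seed integer random seed.
#' @param basis a [cd_basis()].
#' @param helix_decay_per_C core helix fraction lost per degree above the
#'   first temperature (default 0).
#' @return An object of class `melt_series` with `temperatures_C`,
#'   `spectra` and `truth`.
#' @export
make_melting_series <- function(core, f_schedule,
                                temperatures_C = seq(20, 100, by = 10),
                                noise_sd = 0, seed = 1L, basis = cd_basis(),
                                helix_decay_per_C = 0) {
  stopifnot(inherits(core, "structure_fractions3"))
  if (length(f_schedule) != length(temperatures_C))
    stop("f_schedule and temperatures_C lengths differ")
  if (any(diff(temperatures_C) <= 0))
    stop("temperatures must be strictly increasing")
  if (any(f_schedule < 0 | f_schedule > 1)) stop("f_schedule must lie in [0, 1]")
  set.seed(as.integer(seed))
  rc <- make_rc_spectrum(basis)
  P <- length(basis$grid)
  spectra <- vector("list", length(temperatures_C))
  truth <- vector("list", length(temperatures_C))
  for (i in seq_along(temperatures_C)) {
    tc <- temperatures_C[i]
    f <- f_schedule[i]
    h <- max(0, unname(core["helix"]) - helix_decay_per_C * (tc - temperatures_C[1]))
    core_i <- structure_fractions3(h, unname(core["sheet"]),
                                   1 - h - unname(core["sheet"]))
    core_spec <- synth_spectrum(
      structure_fractions5(core_i["helix"], core_i["sheet"],
                           turn = unname(core_i["other"])),
      basis)
    v <- (1 - f) * core_spec$values + f * rc$values
    if (noise_sd > 0) v <- v + stats::rnorm(P, 0, noise_sd)
    spectra[[i]] <- cd_spectrum(v, basis$grid,
                                label = sprintf("melt %gC", tc),
                                temperature_C = tc)
    regen <- regenerate(core_i, min(f, 1 - 1e-12))
    truth[[i]] <- data.frame(
      temperature_C = tc, f_rc = f,
      core_helix = unname(core_i["helix"]), core_sheet = unname(core_i["sheet"]),
      core_other = unname(core_i["other"]),
      regen_helix = unname(regen["helix"]), regen_sheet = unname(regen["sheet"]),
      regen_other = unname(regen["other"]))
  }
  structure(
    list(temperatures_C = temperatures_C, spectra = spectra,
         truth = do.call(rbind, truth)),
    class = "melt_series")
}

#' @export
print.melt_series <- function(x, ...) {
  cat(sprintf("<melt_series> %d temperatures (%g-%g C), f_rc %g-%g\n",
              length(x$temperatures_C), min(x$temperatures_C),
              max(x$temperatures_C), min(x$truth$f_rc), max(x$truth$f_rc)))
  invisible(x)
}
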