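#' Derandomize a CD spectrum
#'
#' Removes a fraction `f_rc` of a random-coil spectrum and renormalises,
#' exposing the spectrum of the folded "core":
#' `de_derand(lambda) = (de_exp(lambda) - f_rc * de_rc(lambda)) / (1 - f_rc)`.
#' This is the exact per-molar-residue inversion of the two-population
#' mixture `de_exp = (1 - f) * de_core + f * de_rc`; because all spectra
#' are normalised per molar residue, residue counts cancel. At large
#' `f_rc` the result can be noisy or non-physical; no clipping is applied
#' — NRMSD filtering downstream handles poor candidates.
#'
#' @param exp a [cd_spectrum()] of the full experimental protein.
#' @param rc the random-coil reference [cd_spectrum()] on the same grid.
#' @param f_rc random-coil fraction in `[0, 1)`.
#' @return The derandomized [cd_spectrum()].
#' @export
derandomize <- function(exp, rc, f_rc) {
  stopifnot(inherits(exp, "cd_spectrum"), inherits(rc, "cd_spectrum"))
  if (!same_grid(exp$grid, rc$grid))
    stop("experimental and random-coil spectra are on different grids")
  if (!is.numeric(f_rc) || f_rc < 0 || f_rc >= 1)
    stop("f_rc must lie in [0, 1)")
  if (f_rc == 0) return(exp)
  cd_spectrum((exp$values - f_rc * rc$values) / (1 - f_rc), exp$grid,
              label = sprintf("%s -%d%% RC", exp$label, round(100 * f_rc)),
              temperature_C = exp$temperature_C)
}

#' Regenerate the original protein's structure fractions
#'
#' Adds the removed random-coil content back into a 3-class structure
#' estimate of the derandomized core: helix and sheet scale by
#' `(1 - f_rc)` and the coil mass joins "other", so the output sums to 1.
#'
#' @param derand a [structure_fractions3()] fitted to the derandomized
#'   spectrum.
#' @param f_rc the random-coil fraction that was removed, in `[0, 1)`.
#' @return A [structure_fractions3()] for the original protein.
#' @examples
#' # 60 C fit: 20% RC removed, core 77% helix -> original 62% helix
#' regenerate(structure_fractions3(0.77, 0.00, 0.23), 0.20)
#' @export
regenerate <- function(derand, f_rc) {
  stopifnot(inherits(derand, "structure_fractions3"))
  if (!is.numeric(f_rc) || f_rc < 0 || f_rc >= 1)
    stop("f_rc must lie in [0, 1)")
  structure_fractions3((1 - f_rc) * derand["helix"],
                       (1 - f_rc) * derand["sheet"],
                       (1 - f_rc) * derand["other"] + f_rc)
}

#' Default derandomization sweep fractions
#'
#' 0% plus 10--90% in steps of 10%. 0 is included so the un-derandomized
#' fit always competes as a candidate.
#'
#' @return Numeric vector `c(0, 0.1, ..., 0.9)`.
#' @export
default_sweep_fractions <- function() seq(0, 0.9, by = 0.1)

new_derand_candidate <- function(f_rc, derand_spectrum, fit) {
  s3 <- fit$structure3
  structure(
    list(f_rc = f_rc, derand_spectrum = derand_spectrum, fit = fit,
         derand_structure = s3, regenerated_structure = regenerate(s3, f_rc),
         nrmsd = fit$nrmsd, co_optimal = NA),
    class = "derand_candidate")
}

#' @export
print.derand_candidate <- function(x, ...) {
  r <- x$regenerated_structure
  cat(sprintf(
    "<candidate> %d%% RC: NRMSD %.4f, regenerated helix %.2f sheet %.2f other %.2f%s\n",
    round(100 * x$f_rc), x$nrmsd, r["helix"], r["sheet"], r["other"],
    if (isTRUE(x$co_optimal)) " [co-optimal]" else ""))
  invisible(x)
}

#' Derandomization sweep over random-coil fractions
#'
#' For each fraction: derandomize, fit against the map, collapse to three
#' classes and regenerate the original protein's fractions. Order follows
#' `fractions`. With `refine = TRUE` the sweep is extended with
#' `refine_step`-spaced fractions around the minimum-NRMSD candidate
#' (within one coarse step either side), then re-sorted by fraction.
#'
#' @param exp experimental [cd_spectrum()].
#' @param rc random-coil [cd_spectrum()].
#' @param map a [trained_map()] with node structures.
#' @param fractions random-coil fractions in `[0, 1)`; default
#'   [default_sweep_fractions()].
#' @param refine logical; add a fine local sweep around the winner.
#' @param refine_step spacing of the fine sweep (default 0.05).
#' @param neighbour_radius passed to [som_predict()].
#' @return List of `derand_candidate` objects (one per fraction).
#' @export
derand_sweep <- function(exp, rc, map, fractions = default_sweep_fractions(),
                         refine = FALSE, refine_step = 0.05,
                         neighbour_radius = 3) {
  if (any(fractions < 0 | fractions >= 1)) stop("fractions must lie in [0, 1)")
  run_one <- function(f) {
    ds <- derandomize(exp, rc, f)
    new_derand_candidate(f, ds, som_predict(map, ds,
                                            neighbour_radius = neighbour_radius))
  }
  cands <- lapply(fractions, run_one)
  if (refine && length(fractions) > 1) {
    best_f <- fractions[which.min(vapply(cands, `[[`, numeric(1), "nrmsd"))]
    coarse <- min(diff(sort(fractions)))
    fine <- seq(max(0, best_f - coarse), min(best_f + coarse, 1 - 1e-9),
                by = refine_step)
    fine <- setdiff(round(fine, 10), round(fractions, 10))
    if (length(fine)) {
      cands <- c(cands, lapply(fine, run_one))
      cands <- cands[order(vapply(cands, `[[`, numeric(1), "f_rc"))]
    }
  }
  cands
}

#' Analyse a melting series by sweep, filter and selection
#'
#' Runs a full derandomization sweep at every temperature, discards
#' candidates with NRMSD above `nrmsd_threshold` (inclusive rule: a
#' candidate exactly at the threshold is kept), and auto-selects the
#' minimum-NRMSD survivor (ties go to the smaller fraction). When no
#' candidate passes, the row is marked `"no acceptable fit"` and the best
#' of the full sweep is reported anyway. Candidates within 15% of the best
#' NRMSD are marked co-optimal for human review.
#'
#' @param series a `melt_series` (see [make_melting_series()]) or a list of
#'   temperature-labelled [cd_spectrum()] objects.
#' @param rc random-coil [cd_spectrum()].
#' @param map a [trained_map()].
#' @param fractions sweep fractions.
#' @param nrmsd_threshold acceptance bound (default 0.03).
#' @param ... passed to [derand_sweep()].
#' @return An object of class `melt_analysis`: `table` (one row per
#'   temperature, ready for [write_results_table()]), `candidates` (per
#'   temperature, ranked), `selected` (per temperature).
#' @export
analyze_series <- function(series, rc, map,
                           fractions = default_sweep_fractions(),
                           nrmsd_threshold = 0.03, ...) {
  spectra <- if (inherits(series, "melt_series")) series$spectra else series
  temps <- vapply(seq_along(spectra), function(i) {
    tc <- spectra[[i]]$temperature_C
    if (is.null(tc)) NA_real_ else tc
  }, numeric(1))
  rows <- vector("list", length(spectra))
  all_cands <- vector("list", length(spectra))
  selected <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    cands <- derand_sweep(spectra[[i]], rc, map, fractions, ...)
    kept <- filter_candidates(cands, nrmsd_threshold)
    note <- if (length(kept) == 0) "no acceptable fit" else ""
    ranked <- rank_candidates(if (length(kept)) kept else cands)
    best <- ranked[[1]]
    if (nzchar(note) == FALSE &&
        sum(vapply(ranked, function(c) isTRUE(c$co_optimal), logical(1))) > 1)
      note <- "co-optimal candidates; inspect"
    d3 <- best$derand_structure
    r3 <- best$regenerated_structure
    rows[[i]] <- data.frame(
      temperature_C = temps[i], best_nrmsd = best$nrmsd, rc_added = best$f_rc,
      derand_helix = unname(d3["helix"]), derand_sheet = unname(d3["sheet"]),
      derand_other = unname(d3["other"]),
      regen_helix = unname(r3["helix"]), regen_sheet = unname(r3["sheet"]),
      regen_other = unname(r3["other"]), note = note,
      stringsAsFactors = FALSE)
    all_cands[[i]] <- ranked
    selected[[i]] <- best
  }
  structure(
    list(table = do.call(rbind, rows), candidates = all_cands,
         selected = selected, temperatures_C = temps,
         nrmsd_threshold = nrmsd_threshold),
    class = "melt_analysis")
}

#' @export
print.melt_analysis <- function(x, ...) {
  cat(sprintf("<melt_analysis> %d temperatures, NRMSD threshold %.3g\n",
              nrow(x$table), x$nrmsd_threshold))
  print(x$table, digits = 3)
  invisible(x)
}
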