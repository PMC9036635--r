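cand_nrmsd <- function(cands) vapply(cands, `[[`, numeric(1), "nrmsd")
cand_frc <- function(cands) vapply(cands, `[[`, numeric(1), "f_rc")

#' Discard poorly fitting derandomization candidates
#'
#' Keeps candidates with NRMSD at or below `threshold` (fits are discarded
#' only when strictly above it), preserving order. An empty result is
#' allowed and carries attribute `status = "no acceptable fit"`.
#'
#' @param candidates list of `derand_candidate` objects.
#' @param threshold positive NRMSD bound (default 0.03).
#' @return The surviving sublist.
#' @export
filter_candidates <- function(candidates, threshold = 0.03) {
  stopifnot(is.numeric(threshold), threshold > 0)
  kept <- candidates[cand_nrmsd(candidates) <= threshold]
  if (length(kept) == 0) attr(kept, "status") <- "no acceptable fit"
  kept
}

#' Rank candidates by goodness of fit
#'
#' Sorts ascending by NRMSD with ties going to the smaller random-coil
#' fraction. Candidates whose NRMSD is within `co_optimal_tol` (relative)
#' of the best are marked `co_optimal`: such near-ties should be resolved
#' by a human using spectral-shape diagnostics and BMU inspection (see
#' [inspect_candidate()]), not silently.
#'
#' @param candidates list of `derand_candidate` objects.
#' @param co_optimal_tol relative NRMSD tolerance for the co-optimal mark
#'   (default 0.15, i.e. within 15% of the best).
#' @return The same candidates, reordered, each with `co_optimal` set.
#' @export
rank_candidates <- function(candidates, co_optimal_tol = 0.15) {
  if (length(candidates) == 0) return(candidates)
  nr <- cand_nrmsd(candidates)
  ord <- order(nr, cand_frc(candidates))
  out <- candidates[ord]
  best <- nr[ord][1]
  for (i in seq_along(out))
    out[[i]]$co_optimal <- out[[i]]$nrmsd <= best * (1 + co_optimal_tol)
  out
}

# x-positions where a piecewise-linear curve crosses zero
zero_crossings <- function(wl, v) {
  s <- sign(v)
  out <- numeric(0)
  for (i in seq_len(length(v) - 1)) {
    if (v[i] == 0) out <- c(out, wl[i])
    else if (s[i] * s[i + 1] < 0)
      out <- c(out, wl[i] + (wl[i + 1] - wl[i]) * v[i] / (v[i] - v[i + 1]))
  }
  if (v[length(v)] == 0) out <- c(out, wl[length(v)])
  unique(out)
}

shape_diag <- function(spec, lo = 190, hi = 210) {
  wl <- spec$grid$wavelengths
  keep <- which(wl >= lo & wl <= hi)
  w <- wl[keep]
  v <- spec$values[keep]
  list(zero_crossings_nm = zero_crossings(w, v),
       max_nm = w[which.max(v)], max_value = max(v),
       min_nm = w[which.min(v)], min_value = min(v))
}

#' Inspect a candidate's best matching units for beta-II ambiguity
#'
#' Far-UV CD cannot distinguish beta-II sheet from random coil or
#' polyproline II. Whenever a beta-II-listed reference protein occupies or
#' neighbours a best matching unit, the apparent sheet/coil split of the
#' fit is suspect. This report gathers the BMU-neighbour reference names,
#' raises `beta2_flag` if any is beta-II-listed, and computes shape
#' diagnostics in the informative 190--210 nm window (zero-crossing
#' wavelengths and the positions/signs of the extrema of the experimental
#' and predicted spectra) to support the visual comparison that resolves
#' near-ties.
#'
#' @param candidate a `derand_candidate` (from [derand_sweep()]).
#' @param refset optional [reference_set()]; when given, beta-II flags
#'   stored on its entries extend `beta2_names`.
#' @param beta2_names beta-II reference names (case-insensitive match);
#'   default [default_beta2_names()].
#' @param map unused placeholder for API symmetry; the BMU neighbourhood is
#'   already recorded on the candidate's fit.
#' @return An object of class `inspection_report`.
#' @export
inspect_candidate <- function(candidate, refset = NULL,
                              beta2_names = default_beta2_names(),
                              map = NULL) {
  stopifnot(inherits(candidate, "derand_candidate"))
  if (!is.null(refset)) {
    flagged <- refset_names(refset)[
      vapply(refset$entries, `[[`, logical(1), "beta2")]
    beta2_names <- unique(c(beta2_names, flagged))
  }
  neigh <- candidate$fit$neighbour_references
  nms <- if (is.null(neigh)) character(0) else unique(neigh$name)
  flag <- any(tolower(nms) %in% tolower(beta2_names))
  structure(
    list(f_rc = candidate$f_rc, nrmsd = candidate$nrmsd,
         bmu_reference_names = nms, beta2_flag = flag,
         caveat = if (flag)
           "beta-sheet here may be beta-II, random coil or polyproline II - spectroscopically indistinguishable"
         else NULL,
         experimental = shape_diag(candidate$derand_spectrum),
         predicted = shape_diag(candidate$fit$predicted_spectrum)),
    class = "inspection_report")
}

#' @export
print.inspection_report <- function(x, ...) {
  cat(sprintf("<inspection> %d%% RC, NRMSD %.4f\n", round(100 * x$f_rc), x$nrmsd))
  cat("  BMU neighbours:",
      if (length(x$bmu_reference_names)) paste(x$bmu_reference_names, collapse = ", ")
      else "(none within radius)", "\n")
  cat(sprintf("  beta-II flag: %s\n", x$beta2_flag))
  if (!is.null(x$caveat)) cat("  caveat:", x$caveat, "\n")
  fmt <- function(d, lab) cat(sprintf(
    "  %s 190-210 nm: zeros at [%s], max %+.3g at %g nm, min %+.3g at %g nm\n",
    lab, paste(signif(d$zero_crossings_nm, 4), collapse = ", "),
    d$max_value, d$max_nm, d$min_value, d$min_nm))
  fmt(x$experimental, "experimental")
  fmt(x$predicted, "predicted  ")
  invisible(x)
}

#' Serialise an inspection report as JSON
#'
#' @param report an [inspect_candidate()] result.
#' @return A JSON string.
#' @export
inspection_json <- function(report) {
  stopifnot(inherits(report, "inspection_report"))
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}
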