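#' Five-class secondary-structure fractions
#'
#' The annotation scheme of the reference sets: alpha-helix, beta-sheet,
#' bonded turn, bend and loop, each a fraction of residues in `[0, 1]` with
#' total at most 1. Any residual `1 - sum` is treated as unannotated/other.
#'
#' @param helix,sheet,turn,bend,loop fractions in `[0, 1]`.
#' @return A named numeric vector of class `structure_fractions5`.
#' @export
structure_fractions5 <- function(helix, sheet, turn = 0, bend = 0, loop = 0) {
  v <- c(helix = as.numeric(helix), sheet = as.numeric(sheet),
         turn = as.numeric(turn), bend = as.numeric(bend),
         loop = as.numeric(loop))
  if (any(!is.finite(v))) stop("structure fractions must be finite")
  tol <- 1e-6
  if (any(v < -tol) || any(v > 1 + tol))
    stop(sprintf("structure fractions must lie in [0, 1]; got (%s)",
                 paste(signif(v, 4), collapse = ", ")))
  v <- pmin(pmax(v, 0), 1)
  if (sum(v) > 1 + tol)
    stop(sprintf("structure fractions sum to %.6f > 1", sum(v)))
  structure(v, class = "structure_fractions5")
}

#' Three-class secondary-structure fractions
#'
#' The reporting unit of the package: far-UV CD carries only enough
#' information for three classes, broadly alpha-helix, beta-sheet and
#' "other". Fractions must sum to 1.
#'
#' @param helix,sheet,other fractions in `[0, 1]` summing to 1 (tolerance
#'   1e-6).
#' @return A named numeric vector of class `structure_fractions3`.
#' @export
structure_fractions3 <- function(helix, sheet, other) {
  v <- c(helix = as.numeric(helix), sheet = as.numeric(sheet),
         other = as.numeric(other))
  if (any(!is.finite(v))) stop("structure fractions must be finite")
  tol <- 1e-6
  if (any(v < -tol) || any(v > 1 + tol))
    stop(sprintf("structure fractions must lie in [0, 1]; got (%s)",
                 paste(signif(v, 4), collapse = ", ")))
  v <- pmin(pmax(v, 0), 1)
  if (abs(sum(v) - 1) > tol)
    stop(sprintf("three-class fractions must sum to 1; got %.6f", sum(v)))
  structure(v, class = "structure_fractions3")
}

#' Collapse five structure classes to three
#'
#' Helix and sheet are kept; turn, bend, loop and any unannotated residual
#' are pooled into "other", so the output always sums to exactly 1.
#'
#' @param s5 a [structure_fractions5()].
#' @return A [structure_fractions3()].
#' @examples
#' collapse_structure(structure_fractions5(0.4, 0.1, 0.2, 0.1, 0.2))
#' @export
collapse_structure <- function(s5) {
  stopifnot(inherits(s5, "structure_fractions5"))
  h <- unname(s5["helix"])
  s <- unname(s5["sheet"])
  structure_fractions3(h, s, 1 - h - s)
}

#' @export
print.structure_fractions5 <- function(x, ...) {
  cat(sprintf(
    "<structure5> helix %.3f sheet %.3f turn %.3f bend %.3f loop %.3f (other %.3f)\n",
    x["helix"], x["sheet"], x["turn"], x["bend"], x["loop"], 1 - sum(x)))
  invisible(x)
}

#' @export
print.structure_fractions3 <- function(x, ...) {
  cat(sprintf("<structure3> helix %.3f sheet %.3f other %.3f\n",
              x["helix"], x["sheet"], x["other"]))
  invisible(x)
}
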