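# Evaluation metrics and convergence-trace bookkeeping shared by the solvers.

#' Relative energy changes from an energy sequence
#'
#' For an ordered energy sequence `E^1 .. E^K` returns
#' `Sigma^{k+1} = |E^{k+1} - E^k| / |E^k|`, one value per consecutive pair.
#' When `|E^k| < 1e-12` the absolute difference is used instead (the
#' relative change is undefined at a vanishing energy).
#'
#' @param energies Numeric vector of objective values, one per iteration.
#' @return Numeric vector of length `length(energies) - 1` (length 0 for
#'   fewer than two energies).
#' @export
sigma_from_energies <- function(energies) {
  n <- length(energies)
  if (n < 2L) return(numeric(0))
  d <- abs(diff(energies))
  ref <- abs(energies[-n])
  ifelse(ref >= 1e-12, d / ref, d)
}

#' Convergence trace of an iterative solver
#'
#' Bundles the per-iteration objective values `E^k`, the derived relative
#' changes `Sigma^k` (always recomputable from the energies via
#' [sigma_from_energies()]), the iteration count, and the per-iteration dual
#' feasibility gap `max(|p| - g)` recorded by the solvers.
#'
#' @param energies Numeric vector of objective values (one per iteration).
#' @param feasibility Optional numeric vector, same length, of dual
#'   feasibility gaps.
#' @return An object of class `"convergence_trace"`: a list with elements
#'   `energies`, `sigmas`, `iterations`, `feasibility`.
#' @export
convergence_trace <- function(energies, feasibility = NULL) {
  energies <- as.numeric(energies)
  if (!is.null(feasibility) && length(feasibility) != length(energies))
    stop_invalid("feasibility must have one entry per energy")
  structure(
    list(energies   = energies,
         sigmas     = sigma_from_energies(energies),
         iterations = length(energies),
         feasibility = feasibility),
    class = "convergence_trace")
}

#' @export
as.data.frame.convergence_trace <- function(x, ...) {
  data.frame(iteration = seq_len(x$iterations),
             energy    = x$energies,
             sigma     = c(NA_real_, x$sigmas))
}

#' @export
print.convergence_trace <- function(x, ...) {
  cat("<convergence_trace> ", x$iterations, " iterations", sep = "")
  if (x$iterations >= 2L)
    cat(", final energy ", format(x$energies[x$iterations]),
        ", final sigma ", format(x$sigmas[x$iterations - 1L]), sep = "")
  cat("\n")
  invisible(x)
}

#' Check the relative-change stopping criterion
#'
#' Declares convergence when the most recent relative energy change
#' `Sigma = |E^{k+1} - E^k| / |E^k|` falls at or below `tol` (absolute
#' difference when `|E^k| < 1e-12`). With fewer than two recorded energies
#' the criterion is not ready and the function returns `FALSE`.
#'
#' @param trace A [convergence_trace()] (or a bare numeric energy vector).
#' @param tol Positive tolerance; the solvers default to `0.001`.
#' @return `TRUE` if converged, otherwise `FALSE`.
#' @export
check_convergence <- function(trace, tol) {
  assert_positive(tol, "tol")
  energies <- if (inherits(trace, "convergence_trace")) trace$energies
              else as.numeric(trace)
  if (length(energies) < 2L) return(FALSE)
  s <- sigma_from_energies(energies)
  s[length(s)] <= tol
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in decibels; higher means closer to the
#' reference. Identical inputs have zero MSE and return `Inf`.
#'
#' @param u,ref Numeric matrices of the same shape.
#' @param peak Peak intensity; defaults to 255 (8-bit scale).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(u, ref, peak = 255) {
  if (!identical(dim(u), dim(ref)))
    stop_invalid("u and ref must have the same shape")
  assert_positive(peak, "peak")
  mse <- mean((u - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`: 1 for identical non-empty sets, 0 for
#' disjoint non-empty sets, and 0 whenever exactly one set is empty. Two
#' empty sets coincide and score 1.
#'
#' @param seg,gt Binary matrices (values exactly 0/1, or logical) of the
#'   same shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(seg, gt) {
  if (is.logical(seg)) seg <- seg + 0
  if (is.logical(gt)) gt <- gt + 0
  if (!identical(dim(seg), dim(gt)))
    stop_invalid("seg and gt must have the same shape")
  if (!all(seg %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop_invalid("dice requires binary inputs (values 0/1)")
  ns <- sum(seg)
  ng <- sum(gt)
  if (ns + ng == 0) return(1)
  2 * sum(seg * gt) / (ns + ng)
}
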