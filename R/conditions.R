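# Classed conditions so callers (and the CLI) can distinguish bad inputs,
# bad parameters, degenerate segmentation regions and I/O failures.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("dualelastica_invalid_input", "dualelastica_error")))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("dualelastica_parameter_error", "dualelastica_error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("dualelastica_degenerate_region", "dualelastica_error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("dualelastica_io_error", "dualelastica_error")))
}

stop_usage <- function(...) {
  stop(errorCondition(paste0(...),
    class = c("dualelastica_usage_error", "dualelastica_error")))
}

# An image is a finite numeric matrix with at least 3 rows and columns
# (central differences need interior pixels).
assert_image <- function(u, name = "image") {
  if (!is.matrix(u) || !is.numeric(u))
    stop_invalid(name, " must be a numeric matrix")
  if (nrow(u) < 3L || ncol(u) < 3L)
    stop_invalid(name, " must be at least 3x3, got ",
                 nrow(u), "x", ncol(u))
  if (!all(is.finite(u)))
    stop_invalid(name, " contains non-finite values")
  invisible(u)
}

assert_field <- function(p, dim = NULL, name = "vector field") {
  if (!is.list(p) || is.null(p$comp1) || is.null(p$comp2))
    stop_invalid(name, " must be a list with components comp1 and comp2")
  if (!identical(dim(p$comp1), dim(p$comp2)))
    stop_invalid(name, ": comp1 and comp2 have different shapes")
  if (!all(is.finite(p$comp1)) || !all(is.finite(p$comp2)))
    stop_invalid(name, " contains non-finite values")
  if (!is.null(dim) && !identical(dim(p$comp1), dim))
    stop_invalid(name, " shape does not match the image")
  invisible(p)
}

assert_mask <- function(mask, dim, name = "mask") {
  if (!is.matrix(mask) || !identical(dim(mask), dim))
    stop_invalid(name, " must be a matrix with the same shape as the image")
  if (!all(mask %in% c(0, 1)))
    stop_invalid(name, " must be binary (values exactly 0 or 1)")
  if (!any(mask == 1))
    stop_invalid(name, " marks every pixel damaged; some data must exist")
  invisible(mask)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param(name, " must be a positive number")
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_param(name, " must be a non-negative number")
  invisible(x)
}

match_scheme <- function(scheme) {
  if (!is.character(scheme) || length(scheme) < 1L)
    stop_param("scheme must be \"adjoint\" or \"central\"")
  scheme <- scheme[[1L]]
  if (!scheme %in% c("adjoint", "central"))
    stop_param("unknown scheme \"", scheme, "\"")
  scheme
}
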