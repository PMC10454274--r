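#' Dome ladder of groove widths
#'
#' A dome ladder is the ordered set of JVP-dome groove widths available to the
#' examiner, listed from coarsest (easiest) to finest (hardest).  Groove width
#' indexes task difficulty in the grating orientation task: the narrower the
#' grooves, the harder it is to report whether the grating lies along or
#' across the finger.
#'
#' @param widths Numeric vector of groove widths in mm, strictly decreasing,
#'   all positive.
#'
#' @return An object of class `dome_ladder`, a list with element `widths`.
#' @seealso [default_ladder()] for the standard 11-dome set.
#' @examples
#' ladder <- dome_ladder(c(3, 2, 1, 0.5))
#' length(ladder)
#' @export
dome_ladder <- function(widths) {
  if (!is.numeric(widths) || length(widths) < 2L) {
    stop("`widths` must be a numeric vector with at least two groove widths",
         call. = FALSE)
  }
  widths <- as.numeric(widths)
  if (any(!is.finite(widths)) || any(widths <= 0)) {
    stop("groove widths must be finite and strictly positive", call. = FALSE)
  }
  if (any(diff(widths) >= 0)) {
    stop("groove widths must be strictly decreasing, coarsest first",
         call. = FALSE)
  }
  structure(list(widths = widths), class = "dome_ladder")
}

#' Default 11-dome ladder
#'
#' The standard set of 11 groove widths, in mm, coarsest first:
#' 5, 4, 3, 2.5, 2, 1.5, 1.25, 1, 0.75, 0.5, 0.35.  The 5- and 4-mm domes
#' extend the classic JVP range upward for middle-aged and clinical testing,
#' and the 2.5-mm dome smooths the otherwise abrupt 3-to-2 mm difficulty step.
#'
#' @return A `dome_ladder` of length 11.
#' @export
default_ladder <- function() {
  dome_ladder(c(5, 4, 3, 2.5, 2, 1.5, 1.25, 1, 0.75, 0.5, 0.35))
}

#' @export
length.dome_ladder <- function(x) length(x$widths)

#' @export
print.dome_ladder <- function(x, ...) {
  cat("Dome ladder:", length(x$widths), "groove widths (mm), coarsest first\n")
  cat(" ", paste(format(x$widths, trim = TRUE), collapse = ", "), "\n")
  invisible(x)
}

#' Position of a groove width on a ladder
#'
#' @param ladder A [dome_ladder()].
#' @param width_mm Groove width in mm.
#' @return Integer index into `ladder$widths`, or an error if absent.
#' @export
ladder_index <- function(ladder, width_mm) {
  stopifnot(inherits(ladder, "dome_ladder"), is.numeric(width_mm),
            length(width_mm) == 1L)
  i <- which(abs(ladder$widths - width_mm) < 1e-9)
  if (length(i) != 1L) {
    stop(sprintf("width %g mm is not on the ladder", width_mm), call. = FALSE)
  }
  i
}

#' Neighbouring domes on the ladder
#'
#' `finer_neighbor()` returns the next narrower groove width (one step harder);
#' `coarser_neighbor()` the next wider one (one step easier).  At the end of
#' the ladder the neighbour does not exist and `NA` is returned.
#'
#' @inheritParams ladder_index
#' @return Groove width in mm, or `NA_real_` at a ladder boundary.
#' @examples
#' finer_neighbor(default_ladder(), 4)   # 3
#' coarser_neighbor(default_ladder(), 4) # 5
#' @export
finer_neighbor <- function(ladder, width_mm) {
  i <- ladder_index(ladder, width_mm)
  if (i == length(ladder$widths)) NA_real_ else ladder$widths[i + 1L]
}

#' @rdname finer_neighbor
#' @export
coarser_neighbor <- function(ladder, width_mm) {
  i <- ladder_index(ladder, width_mm)
  if (i == 1L) NA_real_ else ladder$widths[i - 1L]
}
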