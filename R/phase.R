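# Nucleotide-to-phase map. Each nucleotide is assigned a complex number by
# projecting the nucleotide tetrahedron onto the complex plane
# (A = 1+j, C = -1-j, G = -1+j, T = 1-j, R = j, Y = -j, S = -1, W = 1,
# M = K = N = 0); the phase signal keeps only the arguments of those
# numbers. W is taken as phase 0 (not 2*pi) so every phase lies in
# (-pi, pi]; the unresolved codes M, K, N, B, D, H, V all map to 0.
.wgp_phase_values <- c(
  A =  pi / 4, C = -3 * pi / 4, G = 3 * pi / 4, T = -pi / 4,
  R =  pi / 2, Y = -pi / 2,     S = pi,         W = 0,
  M = 0, K = 0, N = 0, B = 0, D = 0, H = 0, V = 0)

# Byte-indexed lookup (offset by 1), both cases; NA marks invalid symbols.
.phase_lookup <- local({
  tab <- rep(NA_real_, 256L)
  up <- utf8ToInt(paste(names(.wgp_phase_values), collapse = ""))
  lo <- utf8ToInt(tolower(paste(names(.wgp_phase_values), collapse = "")))
  tab[up + 1L] <- .wgp_phase_values
  tab[lo + 1L] <- .wgp_phase_values
  tab
})

#' Phase of a single nucleotide symbol
#'
#' Maps IUPAC nucleotide codes to phase values in radians:
#' A = pi/4, C = -3pi/4, G = 3pi/4, T = -pi/4, R = pi/2, Y = -pi/2,
#' S = pi, W = 0, and M = K = N = B = D = H = V = 0. Case-insensitive.
#'
#' @param symbol Character vector of single nucleotide symbols.
#' @return Numeric vector of phases (radians).
#' @examples
#' phase_of_symbol(c("A", "c", "N"))
#' @export
phase_of_symbol <- function(symbol) {
  stopifnot(is.character(symbol))
  if (any(nchar(symbol) != 1L))
    stop("each element must be a single symbol", call. = FALSE)
  out <- .phase_lookup[utf8ToInt(paste(symbol, collapse = "")) + 1L]
  bad <- which(is.na(out))
  if (length(bad))
    stop("unrecognized symbol '", symbol[bad[1L]], "' at position ",
         bad[1L], call. = FALSE)
  out
}

#' Phase signal of a sequence
#'
#' Converts a nucleotide sequence into its phase signal: one phase value per
#' residue under the map documented in [phase_of_symbol()]. The signal has
#' the same length as the sequence.
#'
#' @param x A `wgp_genome`, the output of [rearrange_genome()], or a
#'   character scalar sequence.
#' @return Numeric vector of phases (radians), length `L`.
#' @examples
#' phase_signal("ACGT")
#' @export
phase_signal <- function(x) {
  s <- as_sequence_string(x)
  if (nchar(s) < 1L) stop("empty sequence", call. = FALSE)
  out <- .phase_lookup[utf8ToInt(s) + 1L]
  bad <- which(is.na(out))
  if (length(bad))
    stop("unrecognized symbol '", substr(s, bad[1L], bad[1L]),
         "' at position ", bad[1L], call. = FALSE)
  out
}

#' Recover a sequence from a phase signal
#'
#' Inverts the nucleotide-to-phase map. The inversion is exact for signals
#' produced from A/C/G/T/R/Y/S residues; a phase of 0 is ambiguous (W and
#' all unresolved codes share it) and is rendered as `N`.
#'
#' @param values Numeric vector of phase values (radians).
#' @param tol Matching tolerance against the canonical phase values.
#' @return Character scalar sequence.
#' @examples
#' phase_to_sequence(phase_signal("ACGT"))
#' @export
phase_to_sequence <- function(values, tol = 1e-9) {
  stopifnot(is.numeric(values))
  canon <- .wgp_phase_values[c("A", "C", "G", "T", "R", "Y", "S")]
  idx <- vapply(values, function(v) {
    d <- abs(canon - v)
    j <- which.min(d)
    if (d[j] <= tol) j else if (abs(v) <= tol) 0L else NA_integer_
  }, integer(1L))
  if (anyNA(idx))
    stop("value ", values[which(is.na(idx))[1L]],
         " does not match any nucleotide phase", call. = FALSE)
  paste(ifelse(idx == 0L, "N", names(canon)[pmax(idx, 1L)]), collapse = "")
}

#' Cumulated phase signal
#'
#' Running sum of the phase signal. For A/C/G/T-only sequences the value at
#' position k equals the closed form
#' `pi/4 * (3 * (nG - nC) + (nA - nT))` in the prefix counts up to k. The
#' global trend of this signal tracks strand-composition skew along the
#' genome; for typical bacterial chromosomes its global minimum marks the
#' replication origin region.
#'
#' @param x A `wgp_genome`, `wgp_rearranged`, or character scalar sequence.
#' @return An object of class `wgp_cphase`: list with `values` (numeric,
#'   length L), `argmax` and `argmin` (1-based positions of the global
#'   extrema, first occurrence on ties).
#' @examples
#' cumulated_phase("AAAGGG")$values
#' @export
cumulated_phase <- function(x) {
  p <- phase_signal(x)
  new_cphase(cumsum(p))
}

# Internal constructor; also used to wrap externally built signals in tests.
new_cphase <- function(values) {
  structure(list(values = values,
                 argmax = which.max(values),
                 argmin = which.min(values)),
            class = "wgp_cphase")
}

#' @export
print.wgp_cphase <- function(x, ...) {
  L <- length(x$values)
  cat("<wgp_cphase> length ", L,
      ", max ", format(x$values[x$argmax]), " @ ", x$argmax,
      ", min ", format(x$values[x$argmin]), " @ ", x$argmin, "\n", sep = "")
  invisible(x)
}
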