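# The four whole-genome descriptors. All are computed from the phase and
# cumulated-phase signals of the (origin-anchored) sequence; each is cheap
# -- a handful of vectorized passes over the signal -- and independent of
# every other genome in a dataset, so they can be precomputed and stored.

.wgp_parameter_names <- c("diff_p", "tr_0", "tr_cg", "a_cp")

.check_phase_len <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) < 2L)
    stop("signal of length >= 2 required", call. = FALSE)
  p
}

#' Mean absolute difference of adjacent phase values
#'
#' `diff_p = (1/L) * sum_{k=1}^{L-1} |p_k - p_{k+1}|`. The divisor is the
#' signal length L (not the number L-1 of adjacent pairs), matching the
#' defining formula and its worked values (`diff_p("AAAGGG")` is pi/2/6).
#' Order-sensitive: permuting the residues changes the value.
#'
#' @param phase Numeric phase signal (see [phase_signal()]), length >= 2.
#' @return Non-negative scalar (radians per position).
#' @examples
#' diff_p(phase_signal("AAAGGG"))  # 0.2618
#' diff_p(phase_signal("AGAGAG"))  # 1.3090
#' @export
diff_p <- function(phase) {
  p <- .check_phase_len(phase)
  sum(abs(diff(p))) / length(p)
}

#' Zero-crossing fraction of the phase signal
#'
#' Fraction of the L-1 adjacent pairs in which the phase changes sign
#' (strictly positive to strictly negative or vice versa). On A/C/G/T
#' sequences this equals the fraction of dinucleotides in
#' {AC, AT, CA, CG, GC, GT, TA, TG}. Pairs involving a zero phase
#' (W or unresolved codes) contribute no transition.
#'
#' @inheritParams diff_p
#' @return Fraction in [0, 1].
#' @examples
#' tr_0(phase_signal("CAGGCAG"))  # 3/6
#' @export
tr_0 <- function(phase) {
  p <- .check_phase_len(phase)
  sum(p[-length(p)] * p[-1L] < 0) / (length(p) - 1L)
}

#' C/G transition fraction of the phase signal
#'
#' Fraction of the L-1 adjacent pairs in which both phases belong to C or G
#' (absolute value 3*pi/4), i.e. the fraction of dinucleotides in
#' {CC, CG, GC, GG}.
#'
#' @inheritParams diff_p
#' @return Fraction in [0, 1].
#' @examples
#' tr_cg(phase_signal("CAGGCAG"))  # 2/6
#' @export
tr_cg <- function(phase) {
  p <- .check_phase_len(phase)
  cg <- abs(p) == 3 * pi / 4
  sum(cg[-length(cg)] & cg[-1L]) / (length(cg) - 1L)
}

#' Average growth angle of the cumulated phase
#'
#' Samples the cumulated phase at `n` positions evenly spaced between the
#' signal start and the global maximum (`i = round(k * i_max / n)`, clamped
#' to `[1, i_max]`, for k = 1..n) and averages the angles
#' `atan(c_i / i)`. The signal is expected to be origin-anchored
#' ([rearrange_genome()]), so the angles describe the growth of the leading
#' half of the skew curve; averaging over several positions smooths local
#' unevenness of the rise. The default `n = 10` trades precision against
#' cost.
#'
#' @param signal A `wgp_cphase` (rearranged) or numeric vector.
#' @param n Number of sampled positions; must not exceed the position of the
#'   global maximum.
#' @return Angle in radians, in (-pi/2, pi/2).
#' @examples
#' a_cp(cumulated_phase(rearrange_genome(strrep("GGAT", 50))))
#' @export
a_cp <- function(signal, n = 10L) {
  sig <- if (inherits(signal, "wgp_cphase")) signal else new_cphase(signal)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  i_max <- sig$argmax
  if (i_max < n)
    stop("global maximum at position ", i_max, " < n = ", n,
         "; use a smaller n for such short signals", call. = FALSE)
  i <- pmin(pmax(round(seq_len(n) * i_max / n), 1), i_max)
  mean(atan(sig$values[i] / i))
}

#' Compute the four descriptors of a genome
#'
#' Origin-anchors the genome (unless `rearrange = FALSE`), recomputes the
#' phase and cumulated-phase signals from the rotated sequence, and returns
#' the four descriptors together with the genome id and length.
#' Deterministic for a fixed input.
#'
#' Skipping the rearrangement is offered for ablation studies; anchoring at
#' the replication-origin proxy is what makes the descriptors insensitive to
#' the arbitrary start position of the deposited record.
#'
#' @param x A `wgp_genome`, a `wgp_rearranged` (reused as-is), or a
#'   character scalar sequence.
#' @param n_acp Number of sampled positions for [a_cp()].
#' @param rearrange Logical; apply the origin-anchoring rotation first.
#' @return One-row data.frame with columns `genome_id`, `length`, `diff_p`,
#'   `tr_0`, `tr_cg`, `a_cp`.
#' @examples
#' compute_parameters(wgp_genome(strrep("GGACT", 20), id = "toy"), n_acp = 5)
#' @export
compute_parameters <- function(x, n_acp = 10L, rearrange = TRUE) {
  if (inherits(x, "wgp_rearranged")) {
    g <- x$genome
    sig <- x$signal
  } else {
    g <- if (inherits(x, "wgp_genome")) x else wgp_genome(x, id = "genome")
    if (rearrange) {
      r <- rearrange_genome(g)
      g <- r$genome
      sig <- r$signal
    } else {
      sig <- cumulated_phase(g)
    }
  }
  p <- phase_signal(g)
  data.frame(genome_id = g$id,
             length = nchar(g$seq),
             diff_p = diff_p(p),
             tr_0 = tr_0(p),
             tr_cg = tr_cg(p),
             a_cp = a_cp(sig, n = n_acp),
             stringsAsFactors = FALSE)
}

#' Compute a parameter table for a set of genomes
#'
#' Applies [compute_parameters()] to each genome and binds the rows. The
#' resulting table is the unit of storage and reuse: delineation never needs
#' the sequences again.
#'
#' @param genomes List of `wgp_genome` objects (or character sequences).
#' @inheritParams compute_parameters
#' @return data.frame with one row per genome and attributes `n_acp` and
#'   `rearranged` recording how the values were produced.
#' @export
compute_parameter_table <- function(genomes, n_acp = 10L, rearrange = TRUE) {
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  rows <- lapply(genomes, compute_parameters,
                 n_acp = n_acp, rearrange = rearrange)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$genome_id))
    stop("duplicate genome ids: ",
         paste(unique(out$genome_id[duplicated(out$genome_id)]),
               collapse = ", "), call. = FALSE)
  attr(out, "n_acp") <- as.integer(n_acp)
  attr(out, "rearranged") <- isTRUE(rearrange)
  out
}

# Validate a parameter table coming from compute_parameter_table() or
# read_parameter_table().
.check_parameter_table <- function(params) {
  need <- c("genome_id", .wgp_parameter_names)
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(params$genome_id))
    stop("duplicate genome ids in parameter table", call. = FALSE)
  for (q in .wgp_parameter_names)
    if (!all(is.finite(params[[q]])))
      stop("non-finite values in column '", q, "'", call. = FALSE)
  params
}
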