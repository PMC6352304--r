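# Light-weight genome container: an id plus a single uppercase residue
# string. Whole closed bacterial genomes are a few Mbp, which a character
# scalar plus integer-code views handle comfortably.

# IUPAC symbols accepted anywhere in the package.
.wgp_alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W",
                   "M", "K", "N", "B", "D", "H", "V")

#' Construct a genome object
#'
#' Wraps a nucleotide sequence and an identifier into a `wgp_genome`.
#' Residues are upper-cased on ingest; any symbol outside the IUPAC
#' nucleotide alphabet (A, C, G, T, R, Y, S, W, M, K, N, B, D, H, V) is
#' rejected with its position.
#'
#' @param seq Character scalar: the nucleotide sequence.
#' @param id Character scalar identifier (FASTA-style first token).
#' @param circular Logical; whether the molecule is circular. Rotation-based
#'   rearrangement warns when applied to a non-circular record.
#' @return An object of class `wgp_genome` with elements `id`, `seq`
#'   (uppercase) and `circular`.
#' @examples
#' g <- wgp_genome("acgtACGT", id = "toy")
#' genome_length(g)
#' @export
wgp_genome <- function(seq, id = "genome", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (nchar(seq) < 1L)
    stop("genome '", id, "': sequence is empty", call. = FALSE)
  codes <- utf8ToInt(seq)
  bad <- which(is.na(.phase_lookup[codes + 1L]))
  if (length(bad))
    stop("genome '", id, "': unrecognized symbol '",
         substr(seq, bad[1L], bad[1L]), "' at position ", bad[1L],
         call. = FALSE)
  structure(list(id = as.character(id), seq = seq,
                 circular = isTRUE(circular)),
            class = "wgp_genome")
}

#' @export
print.wgp_genome <- function(x, ...) {
  L <- nchar(x$seq)
  head <- substr(x$seq, 1L, min(40L, L))
  cat("<wgp_genome> ", x$id, ": ", L, " bp",
      if (!x$circular) " (linear)", "\n  ", head,
      if (L > 40L) "...", "\n", sep = "")
  invisible(x)
}

#' Genome length in base pairs
#' @param x A `wgp_genome` or character scalar.
#' @return Integer length.
#' @export
genome_length <- function(x) {
  nchar(as_sequence_string(x))
}

# Accept either a wgp_genome or a bare character scalar in signal-level
# functions; returns the residue string.
as_sequence_string <- function(x) {
  if (inherits(x, "wgp_genome")) return(x$seq)
  if (inherits(x, "wgp_rearranged")) return(x$genome$seq)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("expected a wgp_genome or a single character string", call. = FALSE)
}

genome_id <- function(x, default = "genome") {
  if (inherits(x, "wgp_genome")) x$id
  else if (inherits(x, "wgp_rearranged")) x$genome$id
  else default
}

#' Rotate a genome
#'
#' Moves the first `offset` residues to the end of the sequence, treating the
#' molecule as circular. Used internally by [rearrange_genome()] and useful
#' for constructing rotation-invariance checks.
#'
#' @param x A `wgp_genome` or character scalar.
#' @param offset Number of leading residues moved to the back (0-based;
#'   reduced modulo the length).
#' @return Same type as the input (`wgp_genome` in, `wgp_genome` out).
#' @export
rotate_genome <- function(x, offset) {
  s <- as_sequence_string(x)
  L <- nchar(s)
  offset <- as.integer(offset %% L)
  rot <- if (offset == 0L) s else
    paste0(substr(s, offset + 1L, L), substr(s, 1L, offset))
  if (inherits(x, "wgp_genome")) {
    x$seq <- rot
    x
  } else rot
}
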