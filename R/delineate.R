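# Dataset-level delineation. Each parameter's pairwise absolute differences
# are normalized by the parameter's range over the whole dataset (max - min
# of its values, which equals the largest pairwise difference), averaged
# over the chosen parameter subset, and converted to percentage similarity
# s = 100 * (1 - d). The normalization makes the similarity explicitly
# dataset-dependent: adding a genome that widens a range changes all
# similarities of that parameter.

#' Resolve a parameter subset
#'
#' Presets follow the convention of averaging progressively more
#' parameters: `"s2"` = {tr_cg, diff_p}, `"s3"` = {tr_cg, diff_p, tr_0},
#' `"s4"` = all four. A character vector of parameter names is used as-is.
#'
#' @param subset Preset name or character vector drawn from
#'   `c("diff_p", "tr_0", "tr_cg", "a_cp")`.
#' @return Character vector of parameter names.
#' @export
resolve_subset <- function(subset = "s4") {
  stopifnot(is.character(subset), length(subset) >= 1L)
  if (length(subset) == 1L && subset %in% c("s2", "s3", "s4"))
    subset <- switch(subset,
                     s2 = c("tr_cg", "diff_p"),
                     s3 = c("tr_cg", "diff_p", "tr_0"),
                     s4 = c("tr_cg", "diff_p", "tr_0", "a_cp"))
  bad <- setdiff(subset, .wgp_parameter_names)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unique(subset)
}

#' Range-normalized pairwise distance tables
#'
#' For each of the four parameters, computes the matrix of pairwise absolute
#' differences divided by the parameter's range over the dataset. When a
#' parameter has zero range (every genome shares its value) all its
#' distances are defined as 0: identical values carry no discriminative
#' signal.
#'
#' @param params Parameter table ([compute_parameter_table()] or
#'   [read_parameter_table()]), at least 2 rows, unique ids.
#' @return List with `distances` (named list of symmetric matrices with
#'   entries in [0, 1]) and `ranges` (data.frame of per-parameter min, max,
#'   range).
#' @export
normalized_distances <- function(params) {
  params <- .check_parameter_table(params)
  if (nrow(params) < 2L)
    stop("at least 2 genomes required", call. = FALSE)
  ids <- params$genome_id
  dist <- list()
  rng <- data.frame(parameter = .wgp_parameter_names,
                    min = NA_real_, max = NA_real_, range = NA_real_)
  for (k in seq_along(.wgp_parameter_names)) {
    q <- .wgp_parameter_names[k]
    v <- params[[q]]
    r <- max(v) - min(v)
    d <- abs(outer(v, v, "-"))
    if (r > 0) d <- d / r else d[] <- 0
    dimnames(d) <- list(ids, ids)
    dist[[q]] <- d
    rng$min[k] <- min(v); rng$max[k] <- max(v); rng$range[k] <- r
  }
  list(distances = dist, ranges = rng)
}

#' Percentage similarity matrix
#'
#' Averages the range-normalized distances over a parameter subset and
#' converts to percentage similarity `s = 100 * (1 - dbar)`. The matrix is
#' symmetric with a diagonal of 100; a pair of genomes spanning a
#' parameter's full range in a single-parameter subset attains similarity 0.
#'
#' @inheritParams normalized_distances
#' @param subset Parameter subset (see [resolve_subset()]); default `"s4"`.
#' @return A `wgp_similarity` object: numeric matrix (ids as dimnames) with
#'   attributes `subset` and `ranges`.
#' @examples
#' pt <- data.frame(genome_id = c("a", "b", "c"), length = 10L,
#'                  diff_p = c(0.2, 0.3, 0.6), tr_0 = 0.5,
#'                  tr_cg = 0.2, a_cp = 0.1)
#' similarity_matrix(pt, subset = "diff_p")
#' @export
similarity_matrix <- function(params, subset = "s4") {
  members <- resolve_subset(subset)
  nd <- normalized_distances(params)
  dbar <- Reduce(`+`, nd$distances[members]) / length(members)
  s <- 100 * (1 - dbar)
  diag(s) <- 100
  structure(s, subset = members, ranges = nd$ranges,
            class = c("wgp_similarity", class(s)))
}

#' @export
print.wgp_similarity <- function(x, ...) {
  cat("<wgp_similarity> ", nrow(x), " genomes, parameters {",
      paste(attr(x, "subset"), collapse = ", "), "}\n", sep = "")
  print(round(x[, ], 2), ...)
  invisible(x)
}

#' Same-species calls from a similarity matrix
#'
#' Emits one call per unordered pair of genomes, in lexicographic id order.
#' A pair is called same-species when its similarity exceeds the threshold;
#' the comparison is strict by default (a pair sitting exactly on the
#' threshold is called different), which is the conservative choice against
#' false positives, and can be relaxed with `strict = FALSE`.
#'
#' @param sim A `wgp_similarity` matrix.
#' @param threshold Percentage threshold in (0, 100); default 96.
#' @param strict Logical; `TRUE` uses `>`, `FALSE` uses `>=`.
#' @return data.frame with columns `id_a`, `id_b`, `similarity`,
#'   `same_species`; attribute `threshold`.
#' @export
delineate <- function(sim, threshold = 96, strict = TRUE) {
  stopifnot(inherits(sim, "wgp_similarity"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 100)
  ids <- sort(rownames(sim))
  if (length(ids) < 2L)
    stop("at least 2 genomes required for delineation", call. = FALSE)
  pr <- combn(ids, 2L)
  s <- sim[cbind(pr[1L, ], pr[2L, ])]
  same <- if (strict) s > threshold else s >= threshold
  out <- data.frame(id_a = pr[1L, ], id_b = pr[2L, ],
                    similarity = s, same_species = same,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}
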