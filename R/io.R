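# File formats: FASTA for genomes (via Biostrings), TSV everywhere else
# (dot decimal separator, UTF-8). The parameter table is the interface
# between the per-genome stage and the delineation stage; it carries a
# provenance comment line so tables computed under different settings are
# not silently mixed.

#' Read a whole-genome FASTA file
#'
#' Accepts exactly one record by default: the method is designed for closed
#' genomes, and a multi-record file usually means a draft assembly in
#' scaffolds, for which the signal-based descriptors are not meaningful.
#' `concatenate = TRUE` overrides this by joining the records in file order
#' with no spacer (with a warning).
#'
#' @param path Path to a FASTA file.
#' @param concatenate Logical; join multiple records instead of rejecting.
#' @param circular Logical flag stored on the genome.
#' @return A `wgp_genome`; the id is the first whitespace-delimited token of
#'   the (first) header.
#' @export
read_genome_fasta <- function(path, concatenate = FALSE, circular = TRUE) {
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  if (length(recs) > 1L) {
    if (!concatenate)
      stop(path, " contains ", length(recs), " records; the method ",
           "requires a single closed genome per file (use ",
           "concatenate = TRUE to force joining scaffolds)", call. = FALSE)
    warning("concatenating ", length(recs), " records from ", path,
            " in file order; descriptors of multi-scaffold assemblies ",
            "depend on scaffold order", call. = FALSE)
  }
  id <- strsplit(names(recs)[1L], "\\s+")[[1L]][1L]
  seq <- paste(as.character(recs), collapse = "")
  wgp_genome(seq, id = id, circular = circular)
}

#' Write a genome (or rearranged genome) as FASTA
#'
#' For a `wgp_rearranged` input the header carries a
#' `rotated_by=<offset>` note so the rotation is traceable.
#'
#' @param x A `wgp_genome` or `wgp_rearranged`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(x, path) {
  if (inherits(x, "wgp_rearranged")) {
    nm <- paste0(x$genome$id, " rotated_by=", x$rotation_offset)
    seq <- x$genome$seq
  } else {
    stopifnot(inherits(x, "wgp_genome"))
    nm <- x$id
    seq <- x$seq
  }
  dss <- Biostrings::DNAStringSet(setNames(seq, nm))
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}

#' Write / read a parameter table
#'
#' The TSV starts with a provenance comment line
#' `# wgp_parameter_table version=... n_acp=... rearranged=...` followed by
#' a header and one row per genome. Numeric fields are serialized with 17
#' significant digits so that `read_parameter_table(write_parameter_table(x))`
#' reproduces the values exactly.
#'
#' @param params Parameter table from [compute_parameter_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_parameter_table <- function(params, path) {
  params <- .check_parameter_table(params)
  prov <- sprintf("# wgp_parameter_table\tversion=%s\tn_acp=%s\trearranged=%s",
                  as.character(packageVersion("wgp")),
                  attr(params, "n_acp") %||% NA,
                  attr(params, "rearranged") %||% NA)
  cols <- c("genome_id", "length", .wgp_parameter_names)
  out <- params[, intersect(cols, names(params))]
  for (q in .wgp_parameter_names) out[[q]] <- sprintf("%.17g", out[[q]])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(prov, con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_parameter_table
#' @return `read_parameter_table()` returns the parameter table with
#'   attributes `n_acp` and `rearranged` restored from the provenance line
#'   (when present).
#' @export
read_parameter_table <- function(path) {
  first <- readLines(path, n = 1L)
  tab <- read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("genome_id", .wgp_parameter_names)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (q in .wgp_parameter_names) {
    if (!is.numeric(tab[[q]]))
      stop(path, ": column '", q, "' is not numeric", call. = FALSE)
    bad <- which(!is.finite(tab[[q]]))
    if (length(bad))
      stop(path, ": non-finite '", q, "' in data row ", bad[1L],
           call. = FALSE)
  }
  if (anyDuplicated(tab$genome_id))
    stop(path, ": duplicate genome ids", call. = FALSE)
  if (startsWith(first, "# wgp_parameter_table")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^\t]+", first))[[1L]]
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), kv, value = TRUE)
      if (length(hit)) sub(".*=", "", hit[1L]) else NA_character_
    }
    attr(tab, "n_acp") <- suppressWarnings(as.integer(get("n_acp")))
    attr(tab, "rearranged") <- identical(get("rearranged"), "TRUE")
  }
  tab
}

#' Merge parameter tables
#'
#' Binds tables computed in separate runs. Overlapping genome ids are an
#' error (precomputed databases must stay unambiguous); differing `n_acp`
#' settings raise a warning because the `a_cp` columns are then not
#' comparable.
#'
#' @param ... Parameter tables.
#' @return Combined parameter table.
#' @export
merge_parameter_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  ids <- unlist(lapply(tabs, `[[`, "genome_id"))
  if (anyDuplicated(ids))
    stop("overlapping genome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  ns <- unique(unlist(lapply(tabs, function(t) attr(t, "n_acp"))))
  ns <- ns[!is.na(ns)]
  if (length(ns) > 1L)
    warning("merging tables with different n_acp settings (",
            paste(ns, collapse = ", "), "); a_cp values are not comparable",
            call. = FALSE)
  out <- do.call(rbind, lapply(tabs, function(t) {
    t[, c("genome_id", "length", .wgp_parameter_names)]
  }))
  rownames(out) <- NULL
  if (length(ns) == 1L) attr(out, "n_acp") <- ns
  .check_parameter_table(out)
}

#' Write / read a similarity matrix as square TSV
#'
#' Square layout with genome ids as both header row and first column.
#'
#' @param sim A `wgp_similarity` matrix.
#' @param path Output path.
#' @return Invisibly, `path`; the reader returns a `wgp_similarity`.
#' @export
write_similarity_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "wgp_similarity"))
  m <- unclass(sim)
  df <- data.frame(genome_id = rownames(m),
                   formatC(m, format = "g", digits = 17),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, colnames(df)[-1L])
  structure(m, class = c("wgp_similarity", class(m)))
}

#' Read / write species labels
#'
#' Two-column TSV with header `genome_id` and `species`.
#'
#' @param path Path to the labels TSV.
#' @return data.frame with columns `genome_id`, `species`.
#' @export
read_species_labels <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("genome_id", "species") %in% names(tab)))
    stop(path, ": expected columns 'genome_id' and 'species'",
         call. = FALSE)
  tab[, c("genome_id", "species")]
}

#' @rdname read_species_labels
#' @param labels data.frame with columns `genome_id`, `species`.
#' @export
write_species_labels <- function(labels, path) {
  stopifnot(all(c("genome_id", "species") %in% names(labels)))
  write.table(labels[, c("genome_id", "species")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
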