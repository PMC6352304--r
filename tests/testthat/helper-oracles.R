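# Independent oracles used across the suite. These deliberately work on the
# symbolic sequence (character-level counting) rather than on the signals,
# so they share no code with the implementation they check.

rand_seq <- function(L, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, L, replace = TRUE), collapse = "")
}

# Eq.-style closed form of the cumulated phase from prefix nucleotide
# counts (A/C/G/T only).
closed_form_cphase <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  pi / 4 * (3 * (cumsum(ch == "G") - cumsum(ch == "C")) +
              (cumsum(ch == "A") - cumsum(ch == "T")))
}

# Dinucleotide-fraction oracles (count on the symbols, divide by L - 1).
dinuc_fraction <- function(seq, members) {
  ch <- strsplit(seq, "")[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  sum(di %in% members) / (length(ch) - 1)
}

oracle_tr_0 <- function(seq) {
  dinuc_fraction(seq, c("AC", "AT", "CA", "CG", "GC", "GT", "TA", "TG"))
}

oracle_tr_cg <- function(seq) {
  dinuc_fraction(seq, c("CC", "CG", "GC", "GG"))
}

# Residue multiset as a named count vector, for rotation checks.
residue_counts <- function(seq) {
  table(factor(strsplit(seq, "")[[1]],
               levels = c("A", "C", "G", "T", "R", "Y", "S", "W",
                          "M", "K", "N", "B", "D", "H", "V")))
}

# Species labels of a simulated cluster set as a named vector.
label_vector <- function(sim) {
  setNames(sim$labels$species, sim$labels$genome_id)
}

# Intra/inter similarity split of a similarity matrix under labels.
split_similarities <- function(sim_matrix, labels) {
  ids <- rownames(sim_matrix)
  same <- outer(labels[ids], labels[ids], "==")
  ut <- upper.tri(sim_matrix)
  list(intra = sim_matrix[ut & same], inter = sim_matrix[ut & !same])
}
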