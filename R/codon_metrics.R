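.es_cache <- new.env(parent = emptyenv())

#' All 64 DNA codons, alphabetically
#' @return Character vector of the 64 triplets.
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
}

# codon -> one-letter amino acid ("*" for stop), standard genetic code
codon_amino_acids <- function() {
  if (is.null(.es_cache$aa)) {
    codons <- all_codons()
    aa <- vapply(codons, function(cd)
      seqinr::translate(seqinr::s2c(tolower(cd))), character(1))
    names(aa) <- codons
    .es_cache$aa <- aa
  }
  .es_cache$aa
}

#' Construct a codon usage table
#'
#' @param frequencies Named numeric vector over all 64 DNA codons
#'   (RNA-style `U` accepted and converted); per-thousand frequencies and
#'   raw counts are treated identically because relative adaptiveness and
#'   codon averaging only use within-family proportions.
#' @param species Species label.
#' @return A list of class `codon_usage_table` with elements `species` and
#'   `frequencies`.
#' @export
codon_usage_table <- function(frequencies, species = "unknown") {
  if (is.null(names(frequencies)))
    es_stop("frequencies must be named by codon", "es_table_error")
  codons <- toupper(gsub("U", "T", names(frequencies), fixed = TRUE))
  names(frequencies) <- codons
  expected <- all_codons()
  if (length(codons) != 64 || anyDuplicated(codons) || !setequal(codons, expected))
    es_stop("a codon usage table must cover the 64 DNA codons exactly once",
            "es_table_error")
  if (any(!is.finite(frequencies)) || any(frequencies < 0))
    es_stop("codon frequencies must be finite and non-negative", "es_table_error")
  structure(list(species = species, frequencies = frequencies[expected]),
            class = "codon_usage_table")
}

#' Read a codon usage table file
#'
#' Accepts Kazusa-style free text (`UUU 17.6( 714298)` fields, with or
#' without the parenthesized counts) and plain two-column codon/frequency
#' TSV. RNA codons are converted to DNA.
#'
#' @param path File path.
#' @param species Species label (defaults to the file name).
#' @return A [codon_usage_table()].
#' @export
read_codon_table <- function(path, species = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\(\\s*[0-9]+\\s*\\)", " ", txt)  # drop Kazusa count fields
  m <- gregexpr("\\b([ACGTUacgtu]{3})[\t ]+([0-9]+\\.?[0-9]*)", txt, perl = TRUE)
  hits <- regmatches(txt, m)[[1]]
  if (length(hits) == 0) es_stop("no codon/frequency pairs found", "es_table_error")
  codons <- toupper(sub("^([ACGTUacgtu]{3}).*", "\\1", hits))
  freqs <- as.numeric(sub("^[ACGTUacgtu]{3}[\t ]+", "", hits))
  codon_usage_table(stats::setNames(freqs, codons),
                    species = species %||% tools::file_path_sans_ext(basename(path)))
}

#' Relative adaptiveness weights of codons
#'
#' Standard precomputation for the codon adaptation index: zero
#' frequencies are replaced by a small pseudo-frequency (0.5 counts by
#' convention) and each codon's weight is its frequency divided by the
#' highest frequency within its synonymous family, so every family's best
#' codon has `w = 1` and all weights lie in `(0, 1]`.
#'
#' @param table A [codon_usage_table()].
#' @param pseudo Pseudo-frequency substituted for zeros.
#' @return Named numeric vector of class `adaptiveness_table` (codon ->
#'   `w`), with the species label as attribute.
#' @export
relative_adaptiveness <- function(table, pseudo = 0.5) {
  if (!inherits(table, "codon_usage_table"))
    es_stop("`table` must be a codon_usage_table", "es_table_error")
  f <- table$frequencies
  f[f == 0] <- pseudo
  aa <- codon_amino_acids()
  w <- f
  for (fam in split(names(aa), aa)) {
    w[fam] <- f[fam] / max(f[fam])
  }
  structure(w, species = table$species, class = "adaptiveness_table")
}

#' Default CAI codon exclusions
#'
#' Methionine (ATG), tryptophan (TGG) and the stop codons carry no
#' synonymous choice and are conventionally excluded from the geometric
#' mean.
#' @return Character vector of excluded codons.
#' @export
cai_default_exclusions <- function() c("ATG", "TGG", "TAA", "TAG", "TGA")

split_codons <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0)
    es_stop("coding sequence length must be divisible by 3", "es_sequence_error")
  if (grepl("[^ACGT]", cds))
    es_stop("coding sequence must contain only A, C, G, T", "es_sequence_error")
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Codon adaptation index of a coding sequence
#'
#' Geometric mean of the relative adaptiveness weights over all
#' non-excluded codons, computed in the log domain to avoid underflow on
#' long sequences.
#'
#' @param cds DNA coding sequence (A/C/G/T, length divisible by 3).
#' @param weights An `adaptiveness_table` from [relative_adaptiveness()].
#' @param exclusions Codons skipped in the mean (default: ATG, TGG, stops).
#'   Use `character(0)` to keep every codon, matching tools that retain the
#'   `w = 1` terms.
#' @return CAI value in `(0, 1]`.
#' @export
cai <- function(cds, weights, exclusions = cai_default_exclusions()) {
  codons <- split_codons(cds)
  codons <- codons[!(codons %in% exclusions)]
  if (length(codons) == 0)
    es_stop("all codons excluded: CAI undefined", "es_undefined_cai")
  w <- unclass(weights)[codons]
  if (any(!is.finite(w)) || any(w <= 0))
    es_stop("weights must be positive for every scored codon", "es_table_error")
  exp(mean(log(w)))
}

#' Translate a coding sequence
#'
#' @param cds DNA coding sequence.
#' @return One-letter amino acid string (`*` for stop codons).
#' @export
translate_cds <- function(cds) {
  paste(codon_amino_acids()[split_codons(cds)], collapse = "")
}

amino_acid_letters <- function() unique(unname(codon_amino_acids()))

#' Codon-usage-driven back-translation ("codon averaging")
#'
#' Back-translates a protein (or re-codes a coding sequence) using a
#' species codon usage table. `most_frequent` deterministically picks each
#' amino acid's highest-frequency codon (ties broken by alphabetical
#' codon); `usage_weighted` samples each codon from its family's usage
#' proportions with the given seed, the usage-guided randomization used by
#' codon-averaging tools. The output always translates back to the input
#' protein.
#'
#' @param protein_or_cds Protein string (one-letter, `*` allowed as
#'   terminal stop) or DNA coding sequence without internal stops.
#' @param table A [codon_usage_table()].
#' @param mode `"most_frequent"` or `"usage_weighted"`.
#' @param seed Integer seed for `usage_weighted` sampling.
#' @return DNA coding sequence string.
#' @export
codon_average <- function(protein_or_cds, table,
                          mode = c("most_frequent", "usage_weighted"),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(table, "codon_usage_table"))
    es_stop("`table` must be a codon_usage_table", "es_table_error")
  x <- toupper(protein_or_cds)
  is_cds <- !grepl("[^ACGT]", x) && nchar(x) %% 3 == 0 && nchar(x) > 0
  protein <- if (is_cds) translate_cds(x) else x
  residues <- strsplit(protein, "")[[1]]
  if (any(!(residues %in% amino_acid_letters())))
    es_stop("protein contains unknown residues", "es_sequence_error")
  if ("*" %in% residues && which.max(residues == "*") < length(residues))
    es_stop("internal stop codon in input", "es_sequence_error")

  aa <- codon_amino_acids()
  f <- table$frequencies
  families <- split(names(aa), aa)  # codons within each family are alphabetical
  pick_most_frequent <- vapply(families, function(fam) {
    if (all(f[fam] == 0))
      es_stop("amino acid family with no positive-frequency codon", "es_table_error")
    fam[which.max(f[fam])]
  }, character(1))

  codons <- if (mode == "most_frequent") {
    pick_most_frequent[residues]
  } else {
    with_seed(seed, vapply(residues, function(r) {
      fam <- families[[r]]
      p <- f[fam]
      if (sum(p) == 0)
        es_stop("amino acid family with no positive-frequency codon", "es_table_error")
      sample(fam, 1, prob = p / sum(p))
    }, character(1)))
  }
  paste(codons, collapse = "")
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_cds_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(seqs, function(s) as.character(s[[1]]), character(1))),
                  names(seqs))
}

#' Per-sequence, per-species CAI report
#'
#' @param sequences Named character vector of coding sequences.
#' @param tables Named list of [codon_usage_table()]s (one per species).
#' @param pseudo Pseudo-frequency for [relative_adaptiveness()].
#' @param exclusions Passed to [cai()].
#' @return Data frame with columns `sequence`, `species`, `cai`.
#' @export
cai_report <- function(sequences, tables, pseudo = 0.5,
                       exclusions = cai_default_exclusions()) {
  weights <- lapply(tables, relative_adaptiveness, pseudo = pseudo)
  out <- expand.grid(sequence = names(sequences), species = names(tables),
                     stringsAsFactors = FALSE)
  out$cai <- mapply(function(sq, sp)
    cai(sequences[[sq]], weights[[sp]], exclusions), out$sequence, out$species)
  out
}
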