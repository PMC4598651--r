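#' The 64-codon state space and the standard genetic code
#'
#' The channel models in this package act on the 64 RNA codons, ordered
#' lexicographically over the base order U < C < A < G with the first codon
#' position most significant. `codon_table()` returns the standard genetic
#' code (NCBI translation table 1) as a tibble in that fixed order; all
#' matrices in the package are indexed by it.
#'
#' @param exclude_stop Drop the three stop codons (UAA, UAG, UGA) from the
#'   amino-acid class partition? The codon alphabet itself always has 64
#'   states; this switch only controls whether the stop class participates
#'   in input ensembles.
#' @return A tibble with columns `codon` (RNA triplet), `amino_acid`
#'   (single-letter code, `*` for stop) and `index` (1-based position in the
#'   fixed codon order).
#' @examples
#' tab <- codon_table()
#' subset(tab, amino_acid == "F") # Phe is exactly {UUU, UUC}
#' @export
codon_table <- function() {
  codons <- codon_alphabet()
  aa <- unname(Biostrings::GENETIC_CODE[chartr("U", "T", codons)])
  tibble::tibble(codon = codons, amino_acid = aa, index = seq_along(codons))
}

#' @rdname codon_table
#' @details `codon_alphabet()` returns the bare ordered codon vector;
#'   `rna_bases()` the base order used throughout.
#' @export
codon_alphabet <- function() {
  b <- rna_bases()
  g <- expand.grid(b3 = b, b2 = b, b1 = b,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' @rdname codon_table
#' @export
rna_bases <- function() c("U", "C", "A", "G")

#' @rdname codon_table
#' @return `aa_classes()`: a named list mapping each amino-acid class (21
#'   classes under the standard code, stop included) to the integer indices
#'   of its synonymous codons. Class names sort alphabetically with the stop
#'   class `*` first, a fixed order used for ensemble priors.
#' @export
aa_classes <- function(exclude_stop = FALSE) {
  tab <- codon_table()
  cls <- split(tab$index, tab$amino_acid)
  if (exclude_stop) cls[["*"]] <- NULL
  cls
}

#' Map codons to their 1-based index in the fixed codon order
#'
#' @param codons Character vector of RNA triplets over U, C, A, G.
#' @return Integer vector of positions in [`codon_alphabet()`].
#' @export
codon_index <- function(codons) {
  idx <- match(codons, codon_alphabet())
  if (anyNA(idx)) {
    stop("not valid RNA codons: ",
         paste(codons[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Single-base neighbors of a codon
#'
#' Every codon has exactly nine Hamming-distance-1 neighbors (three
#' positions times three alternative bases). Under the single-error-per-stage
#' truncation these are the only states reachable in one stage, and an error
#' in one stage can be reverted by the complementary error in the next,
#' which is what makes multi-stage path interference possible.
#'
#' @param codon A single RNA triplet.
#' @return Character vector of the nine neighbors, ordered by position then
#'   by base order U < C < A < G.
#' @examples
#' single_base_neighbors("UUU")
#' @export
single_base_neighbors <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      !all(strsplit(codon, "")[[1]] %in% rna_bases())) {
    stop("'codon' must be one RNA triplet over U,C,A,G", call. = FALSE)
  }
  out <- character(9)
  j <- 0L
  for (i in 1:3) {
    for (b in rna_bases()) {
      if (b != substr(codon, i, i)) {
        x <- codon
        substr(x, i, i) <- b
        j <- j + 1L
        out[j] <- x
      }
    }
  }
  out
}

#' Adjacency matrix of the single-base-neighbor graph
#'
#' The 9-regular graph on the 64 codons (the Hamming graph H(3, 4)); the
#' single-stage transition structure of every codon-level model here.
#'
#' @return A 64 x 64 0/1 matrix with codon dimnames.
#' @export
neighbor_matrix <- function() {
  codons <- codon_alphabet()
  M <- matrix(0, 64, 64, dimnames = list(codons, codons))
  for (cd in codons) M[cd, single_base_neighbors(cd)] <- 1
  M
}

#' Dump the genetic code partition as CSV
#'
#' @param path File to write (columns `codon`, `amino_acid`).
#' @return `path`, invisibly.
#' @export
write_code_table_csv <- function(path) {
  utils::write.csv(codon_table()[, c("codon", "amino_acid")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
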