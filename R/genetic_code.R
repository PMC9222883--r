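#' Genetic code tables
#'
#' A genetic code maps each of the 64 codons (3-letter strings over T, C, A,
#' G) to an amino-acid symbol, with `*` marking stop codons. The default is
#' the standard nuclear code (61 sense codons; stops TAA, TAG, TGA), which
#' corresponds to the common `icode 0` convention of codon-model software.
#' Codons are ordered with T < C < A < G and the first position varying
#' slowest, the ordering used throughout the package for rate-matrix states.
#'
#' @param id Code identifier. Only `"standard"` is built in; a custom code
#'   can be supplied as a named character vector of length 64 (names =
#'   codons, values = amino-acid symbols, `"*"` = stop).
#' @return An object of class `genetic_code`: a list with elements `id`,
#'   `table` (named character vector over all 64 codons), `sense_codons`
#'   (codons encoding an amino acid, in canonical order) and `stop_codons`.
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons)  # 61
#' gc$stop_codons           # TAA, TAG, TGA
#' @export
genetic_code <- function(id = "standard") {
  if (is.character(id) && length(id) == 64L && !is.null(names(id))) {
    tab <- id
    id <- "custom"
  } else if (identical(id, "standard") || identical(id, 0L) || identical(id, 0)) {
    id <- "standard"
    # amino acids in TCAG codon order, first position slowest
    aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
    tab <- stats::setNames(aa, all_codons())
  } else {
    stop("unknown genetic code id: ", id)
  }
  if (length(tab) != 64L || !setequal(names(tab), all_codons()))
    stop("a genetic code must map exactly the 64 codons over {T,C,A,G}")
  tab <- tab[all_codons()]
  structure(
    list(id = id, table = tab,
         sense_codons = names(tab)[tab != "*"],
         stop_codons  = names(tab)[tab == "*"]),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$id, "-", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stop codons (", paste(x$stop_codons, collapse = ", "), ")\n")
  invisible(x)
}

# all 64 codons, T < C < A < G, first position slowest
all_codons <- function() {
  b <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

is_stop_codon <- function(codon, code = genetic_code()) {
  unname(code$table[codon] == "*")
}

translate_codon <- function(codon, code = genetic_code()) {
  unname(code$table[codon])
}

#' Classify single-nucleotide codon changes at one codon position
#'
#' Enumerates all unordered pairs of the 64 codons that differ only at the
#' given position (96 pairs per position: 16 contexts times choose(4,2)
#' nucleotide pairs) and classifies each as synonymous or nonsynonymous.
#' A pair is synonymous when both codons encode the same amino acid or both
#' are stop codons; every sense-to-stop change and every amino-acid change
#' counts as nonsynonymous. Under the standard code roughly 96% of changes
#' at the first position and 33% at the third alter the protein, while the
#' remaining ~4% and ~67% are silent — the redundancy structure of the
#' genetic code that makes the dN/dS contrast informative.
#'
#' @param code A [genetic_code()].
#' @param position Codon position, 1, 2 or 3.
#' @return An object of class `substitution_class_stats`: list with
#'   `position`, `n_pairs`, `n_synonymous`, `n_nonsynonymous`,
#'   `pct_synonymous`, `pct_nonsynonymous` (percentages rounded to the
#'   nearest integer) and unrounded `pct_*_exact` values.
#' @examples
#' classify_position_changes(genetic_code(), 1)$pct_nonsynonymous  # 96
#' classify_position_changes(genetic_code(), 3)$pct_synonymous     # 67
#' @export
classify_position_changes <- function(code = genetic_code(), position) {
  if (!inherits(code, "genetic_code")) stop("'code' must be a genetic_code")
  if (length(position) != 1L || !position %in% 1:3)
    stop("'position' must be 1, 2 or 3")
  codons <- names(code$table)
  bases <- c("T", "C", "A", "G")
  n_syn <- 0L
  n_non <- 0L
  # context = the two fixed positions; vary the chosen one
  for (ctx in unique(sub_position(codons, position, "."))) {
    members <- vapply(bases, function(b) sub("\\.", b, ctx), "")
    aa <- code$table[members]
    for (i in 1:3) for (j in (i + 1):4) {
      syn <- (aa[i] == aa[j])  # covers both same-aa and stop-stop pairs
      if (syn) n_syn <- n_syn + 1L else n_non <- n_non + 1L
    }
  }
  n <- n_syn + n_non
  structure(
    list(position = as.integer(position),
         n_pairs = n, n_synonymous = n_syn, n_nonsynonymous = n_non,
         pct_synonymous = round(100 * n_syn / n),
         pct_nonsynonymous = round(100 * n_non / n),
         pct_synonymous_exact = 100 * n_syn / n,
         pct_nonsynonymous_exact = 100 * n_non / n),
    class = "substitution_class_stats")
}

#' @export
print.substitution_class_stats <- function(x, ...) {
  cat(sprintf("Codon position %d: %d single-nucleotide pairs, %d nonsynonymous (%d%%), %d synonymous (%d%%)\n",
              x$position, x$n_pairs, x$n_nonsynonymous, x$pct_nonsynonymous,
              x$n_synonymous, x$pct_synonymous))
  invisible(x)
}

# replace codon position 'pos' by 'repl' in each codon string
sub_position <- function(codons, pos, repl) {
  substr(codons, pos, pos) <- repl
  codons
}
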