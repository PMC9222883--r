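#' Codon alignments
#'
#' A codon alignment holds an in-frame multiple sequence alignment split
#' into codon columns. By convention the first sequence is the outgroup /
#' reference: all site numbering in reports refers to the codons of that
#' sequence after gap cleaning.
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (equal length, length divisible by 3), or a character matrix of codons
#'   (taxa x codon columns).
#' @param taxa Optional taxon names (defaults to `names(sequences)`).
#' @return An object of class `codon_alignment`: list with `taxa` and
#'   `codons`, a character matrix (rows = taxa, columns = codon sites) of
#'   upper-case 3-letter codons (`"---"` for a gap codon).
#' @export
codon_alignment <- function(sequences, taxa = names(sequences)) {
  if (is.matrix(sequences)) {
    codons <- sequences
    if (is.null(taxa)) taxa <- rownames(codons)
    if (is.null(taxa)) stop("codon matrix must have row names (taxon names)")
    if (ncol(codons) && any(nchar(codons) != 3L))
      stop("codon matrix entries must be 3-letter strings")
  } else {
    if (is.null(taxa)) stop("sequences must be named (taxon names)")
    n <- unique(nchar(sequences))
    if (length(n) != 1L)
      stop("sequences have unequal lengths: ", paste(nchar(sequences), collapse = ", "))
    if (n %% 3L != 0L)
      stop("alignment length (", n, " nt) is not divisible by 3")
    codons <- t(vapply(toupper(sequences), split_codons, character(n / 3)))
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon names: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  dimnames(codons) <- list(taxa, NULL)
  structure(list(taxa = taxa, codons = codons), class = "codon_alignment")
}

split_codons <- function(s) {
  if (nchar(s) == 0L) return(character(0))
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$taxa), "taxa x", ncol(x$codons), "codons",
      "(reference:", x$taxa[1], ")\n")
  invisible(x)
}

#' @export
ncodons <- function(alignment) ncol(alignment$codons)

#' Read an in-frame FASTA alignment
#'
#' Reads a (wrapped or unwrapped) FASTA file and interprets the sequences as
#' an in-frame codon alignment. Header lines are taken verbatim as taxon
#' names up to the first whitespace. `U` is converted to `T`.
#'
#' @param file Path to a FASTA file.
#' @return A [codon_alignment()].
#' @export
read_codon_fasta <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", file)
  id <- cumsum(hdr)
  names <- sub("^>\\s*", "", lines[hdr])
  names <- sub("\\s.*$", "", names)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")), "")
  seqs <- chartr("u", "T", chartr("U", "T", toupper(seqs)))
  codon_alignment(stats::setNames(seqs, names))
}

#' Write a codon alignment to FASTA
#'
#' @param alignment A [codon_alignment()].
#' @param file Output path.
#' @param width Line width in nucleotides (default 60).
#' @return `file`, invisibly.
#' @export
write_codon_fasta <- function(alignment, file, width = 60L) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$taxa)) {
    writeLines(paste0(">", alignment$taxa[i]), con)
    s <- paste(alignment$codons[i, ], collapse = "")
    if (nchar(s))
      writeLines(substring(s, seq(1L, nchar(s), width),
                           pmin(seq(width, nchar(s) + width - 1L, width), nchar(s))), con)
  }
  invisible(file)
}

#' Validate a coding alignment for selection analysis
#'
#' Checks every sequence for the requirements of codon-model analysis: a
#' nucleotide count divisible by three (an intact reading frame), no stop
#' codons (internal or terminal), and no characters outside `T, C, A, G, N,
#' -`. Terminal stop codons are reported as violations rather than silently
#' stripped; see [strip_terminal_stops()]. An empty report means the
#' alignment is ready for analysis (possibly after codon-wise gap removal).
#'
#' @param alignment A [codon_alignment()].
#' @param code A [genetic_code()].
#' @return A data frame of violations with columns `taxon`, `codon_index`
#'   (NA for whole-sequence problems), `type` and `message`; zero rows iff
#'   the alignment is clean.
#' @export
validate_cds_alignment <- function(alignment, code = genetic_code()) {
  stopifnot(inherits(alignment, "codon_alignment"))
  out <- list()
  add <- function(taxon, idx, type, msg)
    out[[length(out) + 1L]] <<- data.frame(taxon = taxon, codon_index = idx,
                                           type = type, message = msg,
                                           stringsAsFactors = FALSE)
  for (i in seq_along(alignment$taxa)) {
    tx <- alignment$taxa[i]
    cods <- alignment$codons[i, ]
    bad <- grepl("[^TCAGN-]", cods)
    for (j in which(bad))
      add(tx, j, "invalid_character",
          sprintf("codon %d ('%s') contains characters outside {T,C,A,G,N,-}", j, cods[j]))
    stop_at <- which(cods %in% code$stop_codons)
    for (j in stop_at) {
      where <- if (j == length(cods)) "terminal" else "internal"
      add(tx, j, "stop_codon",
          sprintf("%s stop codon %s at codon %d", where, cods[j], j))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(taxon = character(), codon_index = integer(),
                  type = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Strip a shared terminal stop codon
#'
#' Removes the final codon column when it is a stop codon (or gap) in every
#' sequence. Explicit opt-in utility: validation otherwise rejects terminal
#' stops, because analysis expects coding sequence excluding the stop.
#'
#' @param alignment A [codon_alignment()].
#' @param code A [genetic_code()].
#' @return A [codon_alignment()] without the terminal stop column (unchanged
#'   if the last column is not a shared stop).
#' @export
strip_terminal_stops <- function(alignment, code = genetic_code()) {
  nc <- ncol(alignment$codons)
  if (nc == 0L) return(alignment)
  last <- alignment$codons[, nc]
  if (all(last %in% c(code$stop_codons, "---")))
    codon_alignment(alignment$codons[, -nc, drop = FALSE], alignment$taxa)
  else alignment
}

#' Remove gap codons column-wise
#'
#' Deletes every codon column in which any sequence has a gap codon, so that
#' all downstream methods see the identical gap-free alignment. A codon
#' containing `N` is treated like a gap codon and removed column-wise. A
#' codon mixing gap and nucleotide characters (for example `"A-G"`) breaks
#' the reading frame and is a hard error. The operation is idempotent.
#'
#' @param alignment A [codon_alignment()].
#' @return A list with `alignment` (the cleaned [codon_alignment()]) and
#'   `column_map`, an integer vector mapping cleaned codon index to the
#'   original codon index (strictly increasing).
#' @export
remove_gap_codons <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  cods <- alignment$codons
  partial <- grepl("-", cods) & cods != "---"
  if (any(partial)) {
    w <- which(partial, arr.ind = TRUE)[1, ]
    stop(sprintf("frame-breaking partial gap in codon %d of '%s' ('%s'): gaps must span whole codons",
                 w[2], alignment$taxa[w[1]], cods[w[1], w[2]]))
  }
  gap <- cods == "---" | grepl("N", cods, fixed = TRUE)
  keep <- which(!apply(gap, 2, any))
  list(alignment = codon_alignment(cods[, keep, drop = FALSE], alignment$taxa),
       column_map = keep)
}

#' Codon frequency estimation
#'
#' Estimates the stationary codon frequencies used by the rate matrix.
#' `F3x4` (the default, corresponding to the common `CodonFreq 2` setting)
#' computes nucleotide frequencies separately at the three codon positions
#' over all sequences and takes products, renormalized over the sense
#' codons. `F1x4` uses a single pooled nucleotide distribution and `equal`
#' assigns 1/61 to every sense codon.
#'
#' @param alignment A cleaned [codon_alignment()] (no gaps, no stops).
#' @param code A [genetic_code()].
#' @param estimator One of `"F3x4"`, `"F1x4"`, `"equal"`.
#' @return An object of class `codon_frequencies`: numeric vector of
#'   frequencies named by the sense codons (summing to 1), with attribute
#'   `estimator`.
#' @export
codon_frequencies <- function(alignment = NULL, code = genetic_code(),
                              estimator = c("F3x4", "F1x4", "equal")) {
  estimator <- match.arg(estimator)
  sense <- code$sense_codons
  if (estimator == "equal") {
    pi <- stats::setNames(rep(1 / length(sense), length(sense)), sense)
    return(structure(pi, estimator = "equal", class = "codon_frequencies"))
  }
  stopifnot(inherits(alignment, "codon_alignment"))
  cods <- as.vector(alignment$codons)
  cods <- cods[cods != "---"]
  bases <- c("T", "C", "A", "G")
  posfreq <- function(chars) {
    f <- table(factor(chars, levels = bases))
    if (sum(f) == 0) stop("no counted nucleotides at a codon position")
    as.numeric(f) / sum(f)
  }
  if (estimator == "F3x4") {
    fr <- lapply(1:3, function(p) posfreq(substr(cods, p, p)))
  } else {
    all3 <- unlist(lapply(1:3, function(p) substr(cods, p, p)))
    fr <- rep(list(posfreq(all3)), 3)
  }
  for (p in 1:3)
    if (all(fr[[p]] == 0)) stop("all-zero nucleotide frequencies at position ", p)
  names(fr[[1]]) <- names(fr[[2]]) <- names(fr[[3]]) <- bases
  pi <- vapply(sense, function(cd)
    fr[[1]][substr(cd, 1, 1)] * fr[[2]][substr(cd, 2, 2)] * fr[[3]][substr(cd, 3, 3)],
    numeric(1))
  if (sum(pi) <= 0) stop("degenerate codon frequencies: all sense codons have zero probability")
  pi <- pi / sum(pi)
  structure(stats::setNames(pi, sense), estimator = estimator, class = "codon_frequencies")
}

#' @rdname codon_frequencies
#' @export
f3x4_frequencies <- function(alignment, code = genetic_code()) {
  codon_frequencies(alignment, code, estimator = "F3x4")
}

#' @export
print.codon_frequencies <- function(x, ...) {
  cat("Codon frequencies (", attr(x, "estimator"), "), ", length(x),
      " sense codons, sum = ", format(sum(x)), "\n", sep = "")
  invisible(x)
}
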