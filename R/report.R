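# Result compilation: summary file, per-codon overview table, highlighted
# FASTA and p-value-annotated trees.

#' Compile the results of a full analysis
#'
#' Collects the likelihood-ratio tests, empirical-Bayes site records and the
#' FEL scan into one object, recomputing every p-value from the stored
#' log-likelihoods (so the summary can never drift from the fits), and
#' renders the plain-text summary.
#'
#' @param outputs A list with elements `label`, `s` (significance
#'   threshold), `alignment` (cleaned [codon_alignment()]), `column_map`
#'   (cleaned index to original index), `tests` (character subset of
#'   `c("1","2","3","h")`), `site_fits` (named list, models `M1a`, `M2a`,
#'   `M7`, `M8`), `branch_site` / `branch` (lists per topology:
#'   `topology`, `null`, `alt`), `fel` (a [fel_scan()] result), `failed`
#'   (data frame of task id / error).
#' @param code A [genetic_code()].
#' @return An object of class `compiled_results`.
#' @export
compile_results <- function(outputs, code = genetic_code()) {
  s <- outputs$s
  res <- list(label = outputs$label, s = s,
              alignment = outputs$alignment,
              column_map = outputs$column_map,
              tests = outputs$tests,
              failed = outputs$failed %||% data.frame(task = character(),
                                                      error = character()))

  # test 1: site models + their site records
  res$site_tests <- list()
  res$site_records <- empty_site_records()
  if ("1" %in% outputs$tests && !is.null(outputs$site_fits)) {
    sf <- outputs$site_fits
    for (pr in c("M1a/M2a", "M7/M8")) {
      nm <- strsplit(pr, "/")[[1]]
      if (all(nm %in% names(sf))) {
        lrt <- model_comparison(pr, list(null = sf[[nm[1]]], alt = sf[[nm[2]]]))
        res$site_tests[[pr]] <- lrt
        for (method in c("NEB", "BEB")) {
          rec <- site_posteriors(sf[[nm[2]]], method, lrt = lrt, s = s)
          res$site_records <- rbind(res$site_records, rec)
        }
      }
    }
  }

  # tests 2 and 3: per-foreground-branch comparisons
  res$branch_site <- compile_branch_table(outputs$branch_site, "branch-site", s)
  res$branch <- compile_branch_table(outputs$branch, "branch", s)
  res$branch_site_records <- empty_site_records()
  res$branch_site_records$foreground <- character(0)
  if (!is.null(outputs$branch_site)) {
    for (entry in outputs$branch_site) {
      lrt <- model_comparison("branch-site", list(null = entry$null, alt = entry$alt))
      if (lrt$p_value <= s) {
        rec <- site_posteriors(entry$alt, "NEB", lrt = lrt, s = s)
        if (nrow(rec)) {
          rec$foreground <- entry$alt$foreground
          res$branch_site_records <- rbind(res$branch_site_records, rec)
        }
      }
    }
  }

  res$fel <- outputs$fel
  structure(res, class = "compiled_results")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_site_records <- function() {
  data.frame(codon_index = integer(), reference_codon = character(),
             test = character(), method = character(), posterior = numeric(),
             direction = character(), significant = logical(),
             stringsAsFactors = FALSE)
}

compile_branch_table <- function(entries, pair, s) {
  if (is.null(entries) || !length(entries))
    return(data.frame(index = integer(), foreground = character(),
                      lnL_null = numeric(), lnL_alt = numeric(),
                      statistic = numeric(), df = integer(), p_value = numeric(),
                      significant = logical(), newick = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(entries, function(entry) {
    lrt <- model_comparison(pair, list(null = entry$null, alt = entry$alt))
    data.frame(index = entry$topology$index,
               foreground = entry$alt$foreground,
               lnL_null = lrt$lnL_null, lnL_alt = lrt$lnL_alt,
               statistic = lrt$statistic, df = lrt$df, p_value = lrt$p_value,
               significant = lrt$p_value <= s,
               newick = write_labelled_newick(entry$topology),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$index), , drop = FALSE]
}

#' @export
print.compiled_results <- function(x, ...) {
  cat(summary_text(x), sep = "\n")
  invisible(x)
}

#' Render the plain-text summary
#'
#' @param results A [compile_results()] object.
#' @return Character vector of lines.
#' @export
summary_text <- function(results) {
  x <- results
  fmtp <- function(p) sprintf("%.6g", p)
  star <- function(sig) if (isTRUE(sig)) " *" else ""
  lines <- c("Selection analysis summary",
             "==========================",
             sprintf("Dataset: %s", x$label %||% "(unnamed)"),
             sprintf("Alignment: %d taxa x %d codons (cleaned); reference: %s",
                     length(x$alignment$taxa), ncol(x$alignment$codons),
                     x$alignment$taxa[1]),
             sprintf("Significance threshold: %g", x$s),
             "")
  if ("1" %in% x$tests) {
    lines <- c(lines, "Test 1: site models")
    for (pr in names(x$site_tests)) {
      lrt <- x$site_tests[[pr]]
      lines <- c(lines, sprintf(
        "  %-8s lnL %0.6f vs %0.6f | 2dlnL = %0.6f, df = %d, p = %s%s",
        pr, lrt$lnL_null, lrt$lnL_alt, lrt$statistic, lrt$df,
        fmtp(lrt$p_value), star(lrt$p_value <= x$s)))
    }
    sig <- x$site_records[x$site_records$significant, , drop = FALSE]
    if (nrow(sig)) {
      for (key in unique(paste(sig$test, sig$method))) {
        sel <- sig[paste(sig$test, sig$method) == key, ]
        lines <- c(lines, sprintf("  %s sites (posterior >= %g): %s",
                                  key, 1 - x$s,
                                  paste(sel$codon_index, collapse = ", ")))
      }
    } else {
      lines <- c(lines, "  no positively selected sites")
    }
    lines <- c(lines, "")
  }
  branch_block <- function(tab, title) {
    out <- c(title)
    if (!nrow(tab)) return(c(out, "  (no branches tested)", ""))
    for (i in seq_len(nrow(tab))) {
      out <- c(out, sprintf("  [%02d] %-30s 2dlnL = %0.6f, p = %s%s",
                            tab$index[i], tab$foreground[i], tab$statistic[i],
                            fmtp(tab$p_value[i]), star(tab$significant[i])))
    }
    c(out, "")
  }
  if ("2" %in% x$tests) {
    lines <- c(lines, branch_block(x$branch_site,
                                   "Test 2: branch-site models (one foreground branch each)"))
    if (nrow(x$branch_site_records)) {
      for (fg in unique(x$branch_site_records$foreground)) {
        sel <- x$branch_site_records[x$branch_site_records$foreground == fg &
                                       x$branch_site_records$significant, ]
        if (nrow(sel))
          lines <- c(lines, sprintf("  sites on %s: %s", fg,
                                    paste(sel$codon_index, collapse = ", ")), "")
      }
    }
  }
  if ("3" %in% x$tests)
    lines <- c(lines, branch_block(x$branch, "Test 3: branch models"))
  if ("h" %in% x$tests && !is.null(x$fel)) {
    lines <- c(lines,
               "Test h: FEL per-site scan",
               sprintf("  %d codons: %d positively, %d negatively selected (p <= %g)",
                       nrow(x$fel), attr(x$fel, "n_positive"),
                       attr(x$fel, "n_negative"), x$s))
    sig <- x$fel[x$fel$direction != "none", , drop = FALSE]
    for (d in c("positive", "negative")) {
      sel <- sig[sig$direction == d, ]
      if (nrow(sel))
        lines <- c(lines, sprintf("  %s: %s", d,
                                  paste(sel$codon_index, collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  if (nrow(results$failed)) {
    lines <- c(lines, "Failed tasks:",
               sprintf("  %s: %s", results$failed$task, results$failed$error))
  } else {
    lines <- c(lines, "Failed tasks: none")
  }
  lines
}

#' Per-codon overview table
#'
#' One row per codon of the cleaned alignment, mapping every site-specific
#' result back to the reference sequence: original codon index, reference
#' codon and amino acid, M2a and M8 empirical-Bayes posteriors (NEB and
#' BEB) with significance flags, FEL alpha/beta/p/direction and the
#' foreground branches on which the branch-site model flags the codon.
#'
#' @param results A [compile_results()] object.
#' @param code A [genetic_code()].
#' @return A data frame with one row per cleaned codon, stable column
#'   order.
#' @export
codon_overview_table <- function(results, code = genetic_code()) {
  aln <- results$alignment
  n <- ncol(aln$codons)
  ref <- aln$codons[1, ]
  tab <- data.frame(codon_index = seq_len(n),
                    original_index = results$column_map %||% seq_len(n),
                    reference_codon = ref,
                    reference_aa = unname(code$table[ref]),
                    stringsAsFactors = FALSE)
  rec <- results$site_records
  for (test in c("M2a", "M8")) for (method in c("NEB", "BEB")) {
    cn <- paste0(test, "_", method)
    sel <- rec[rec$test == test & rec$method == method, ]
    tab[[cn]] <- NA_real_
    tab[[paste0(cn, "_sig")]] <- ""
    if (nrow(sel)) {
      tab[[cn]][sel$codon_index] <- round(sel$posterior, 6)
      tab[[paste0(cn, "_sig")]][sel$codon_index[sel$significant]] <- "*"
    }
  }
  if (!is.null(results$fel)) {
    f <- results$fel
    tab$fel_alpha <- round(f$alpha[match(tab$codon_index, f$codon_index)], 6)
    tab$fel_beta <- round(f$beta[match(tab$codon_index, f$codon_index)], 6)
    tab$fel_p <- round(f$p_value[match(tab$codon_index, f$codon_index)], 6)
    tab$fel_direction <- f$direction[match(tab$codon_index, f$codon_index)]
  } else {
    tab$fel_alpha <- NA_real_; tab$fel_beta <- NA_real_
    tab$fel_p <- NA_real_; tab$fel_direction <- ""
  }
  bs <- results$branch_site_records
  tab$branch_site_hits <- vapply(seq_len(n), function(j) {
    sel <- bs[bs$codon_index == j & bs$significant, ]
    paste(sel$foreground, collapse = ";")
  }, "")
  tab
}

#' Highlighted FASTA of selected codons
#'
#' Writes the cleaned alignment in lower case, with every codon that any
#' site-specific test flags as significant set in upper case, ready for
#' re-alignment against original sequences.
#'
#' @param alignment The cleaned [codon_alignment()].
#' @param significant_sites Integer vector of significant codon indices.
#' @return Character vector of FASTA lines.
#' @export
highlight_fasta <- function(alignment, significant_sites) {
  out <- character(0)
  for (i in seq_along(alignment$taxa)) {
    cods <- tolower(alignment$codons[i, ])
    cods[significant_sites] <- toupper(cods[significant_sites])
    out <- c(out, paste0(">", alignment$taxa[i]), paste(cods, collapse = ""))
  }
  out
}

#' Significant site set of a compiled analysis
#'
#' Union of codons flagged by any site-specific test: site-model
#' empirical Bayes (NEB/BEB), branch-site hits, and FEL (either
#' direction).
#'
#' @param results A [compile_results()] object.
#' @return Sorted integer vector of codon indices.
#' @export
significant_sites <- function(results) {
  idx <- c(results$site_records$codon_index[results$site_records$significant],
           results$branch_site_records$codon_index[results$branch_site_records$significant])
  if (!is.null(results$fel))
    idx <- c(idx, results$fel$codon_index[results$fel$direction != "none"])
  sort(unique(idx))
}

#' Annotated Newick trees with per-branch p-values
#'
#' For the branch and branch-site tests, renders one line per foreground
#' topology: the branch identifier, the p-value and the `#1`-labelled
#' Newick string (copy-paste reproducible), plus a final tree whose branch
#' comments (`[p=...]`) carry the p-values of all branches.
#'
#' @param results A [compile_results()] object.
#' @param which `"branch"` or `"branch-site"`.
#' @return Character vector of lines (empty if the test was not run).
#' @export
annotated_trees <- function(results, which = c("branch", "branch-site")) {
  which <- match.arg(which)
  tab <- if (which == "branch") results$branch else results$branch_site
  if (!nrow(tab)) return(character(0))
  lines <- sprintf("%s\tp=%.6g%s\t%s", tab$foreground, tab$p_value,
                   ifelse(tab$significant, "\t*", "\t"), tab$newick)
  # one combined tree: p-value comment on every tested branch
  first <- parse_newick(tab$newick[1])$tree
  ann <- annotate_tree_newick(first, stats::setNames(tab$p_value, tab$foreground))
  c(lines, ann)
}

# serialize a phylo with [p=...] comments appended to each branch
annotate_tree_newick <- function(tree, p_by_branch) {
  ntip <- ape::Ntip(tree)
  lab <- function(node) {
    id <- branch_id(tree, node)
    p <- p_by_branch[[id]]
    if (is.null(p) || is.na(p)) "" else sprintf("[p=%.6g]", p)
  }
  rec <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) return(paste0(tree$tip.label[node], lab(node)))
    inner <- paste(vapply(kids, rec, ""), collapse = ",")
    ann <- if (node == tree$edge[1, 1]) "" else lab(node)
    paste0("(", inner, ")", ann)
  }
  paste0(rec(tree$edge[1, 1]), ";")
}
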