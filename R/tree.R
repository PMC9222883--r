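#' Parse a Newick tree, honouring foreground branch labels
#'
#' Parses a Newick string or file into an `ape` `phylo` object and extracts
#' any foreground branch mark of the form `#1` attached to a tip or to an
#' internal clade (the label dialect used by codon-model software to mark
#' the foreground branch of branch and branch-site models). Whitespace
#' around labels is tolerated, so `(A #1,B,C);` and `(A#1,B,C);` are
#' equivalent.
#'
#' @param text A Newick string, or `NULL` when `file` is given.
#' @param file Optional path to a `.tre`/`.tree`/`.nwk` file.
#' @return A list of class `phylo_input` with elements `tree` (a `phylo`
#'   with clean labels), `foreground` (branch id of the `#1` branch, or
#'   `NULL`) and `has_lengths`.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- gsub("[[:space:]]+", "", text)
  if (!nzchar(text)) stop("empty Newick input")
  if (!identical(lengths(regmatches(text, gregexpr("\\(", text))),
                 lengths(regmatches(text, gregexpr("\\)", text)))))
    stop("unbalanced parentheses in Newick input")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  if (ape::Ntip(tree) < 2L) stop("tree has fewer than 2 leaves")

  fg_node <- integer(0)
  lab_rx <- "#[0-9]+$"
  hit_tip <- grepl(lab_rx, tree$tip.label)
  if (any(hit_tip)) {
    fg_node <- c(fg_node, which(hit_tip))
    tree$tip.label <- sub(lab_rx, "", tree$tip.label)
  }
  if (!is.null(tree$node.label)) {
    hit_nd <- grepl(lab_rx, tree$node.label)
    if (any(hit_nd)) {
      fg_node <- c(fg_node, ape::Ntip(tree) + which(hit_nd))
      tree$node.label <- sub(lab_rx, "", tree$node.label)
    }
    if (all(!nzchar(tree$node.label))) tree$node.label <- NULL
  }
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (length(fg_node) > 1L)
    stop("more than one '#' foreground label in tree")
  fg <- if (length(fg_node) == 1L) branch_id(tree, fg_node) else NULL
  structure(list(tree = tree, foreground = fg,
                 has_lengths = !is.null(tree$edge.length)),
            class = "phylo_input")
}

#' @export
print.phylo_input <- function(x, ...) {
  cat("Phylogenetic tree:", ape::Ntip(x$tree), "leaves",
      if (x$has_lengths) "(with branch lengths)" else "(no branch lengths)", "\n")
  if (!is.null(x$foreground)) cat("Foreground branch:", x$foreground, "\n")
  invisible(x)
}

#' Stable branch identifier
#'
#' Identifies a branch by the sorted leaf set of the clade below it, joined
#' by `"|"`. The identifier survives Newick serialization, re-rooting of the
#' basal trifurcation and parallel execution, so tasks and reports can refer
#' to branches unambiguously.
#'
#' @param tree A `phylo`.
#' @param node The child node of the branch (tip number or internal node
#'   number in `ape` convention).
#' @return A character scalar.
#' @export
branch_id <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  leaves <- if (node <= ntip) tree$tip.label[node]
            else tree$tip.label[unlist(phangorn_descendants(tree, node))]
  paste(sort(leaves), collapse = "|")
}

# tips below an internal node (simple stack walk; avoids extra deps)
phangorn_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

#' Enumerate all single-foreground-branch topologies
#'
#' Produces one labelled topology per branch of the tree: every terminal and
#' internal branch in turn is marked as the foreground (`#1`) branch, which
#' is how branch and branch-site tests scan the whole phylogeny for lineages
#' under selection. Rooted input is treated as unrooted (the two basal
#' branches of a bifurcating root are one branch), so a fully resolved tree
#' with n leaves yields exactly 2n - 3 topologies; polytomies yield one
#' topology per actual edge. Any pre-existing `#` labels are cleared first.
#' Order is deterministic: depth-first over the edge matrix, children in
#' input order.
#'
#' @param tree A `phylo` or [parse_newick()] result.
#' @return A list of `labelled_topology` objects, each with `tree` (the
#'   unrooted base `phylo`), `foreground_edge` (row of `tree$edge`),
#'   `foreground` (branch id) and `index`.
#' @export
enumerate_foreground_topologies <- function(tree) {
  tree <- as_phylo(tree)
  if (ape::Ntip(tree) < 3L) stop("need at least 3 leaves to test branches")
  tree$node.label <- NULL
  base <- unroot_keep_order(tree)
  lapply(seq_len(nrow(base$edge)), function(i) {
    structure(list(tree = base,
                   foreground_edge = i,
                   foreground = branch_id(base, base$edge[i, 2]),
                   index = i),
              class = "labelled_topology")
  })
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo_input")) tree$tree
  else if (inherits(tree, "labelled_topology")) tree$tree
  else if (inherits(tree, "phylo")) tree
  else stop("not a tree object")
}

# ape::unroot, then restore cladewise edge ordering for determinism
unroot_keep_order <- function(tree) {
  if (!ape::is.rooted(tree)) return(ape::reorder.phylo(tree, "cladewise"))
  ape::reorder.phylo(ape::unroot(tree), "cladewise")
}

#' @export
print.labelled_topology <- function(x, ...) {
  cat("Labelled topology", x$index, "- foreground branch:", x$foreground, "\n")
  cat(" ", write_labelled_newick(x), "\n")
  invisible(x)
}

#' Serialize a labelled topology to Newick
#'
#' Writes the topology with `#1` appended to exactly one branch (after the
#' name or the closing parenthesis of the subtended clade, before any branch
#' length), the dialect expected by codon-model software.
#'
#' @param topology A `labelled_topology`.
#' @return A Newick string.
#' @export
write_labelled_newick <- function(topology) {
  stopifnot(inherits(topology, "labelled_topology"))
  tree <- topology$tree
  node <- tree$edge[topology$foreground_edge, 2]
  ntip <- ape::Ntip(tree)
  if (node <= ntip) {
    tree$tip.label[node] <- paste0(tree$tip.label[node], "#1")
  } else {
    nl <- tree$node.label
    if (is.null(nl)) nl <- rep("", tree$Nnode)
    nl[node - ntip] <- paste0(nl[node - ntip], "#1")
    tree$node.label <- nl
  }
  ape::write.tree(tree)
}

#' Check that tree leaves and alignment taxa agree
#'
#' Every taxon of the alignment must appear as a leaf and vice versa; model
#' fitting refuses to run otherwise.
#'
#' @param tree A `phylo` (or wrapper).
#' @param alignment A [codon_alignment()].
#' @return `TRUE` invisibly; error on mismatch.
#' @export
check_tree_alignment <- function(tree, alignment) {
  tree <- as_phylo(tree)
  tl <- sort(tree$tip.label)
  al <- sort(alignment$taxa)
  if (!identical(tl, al)) {
    only_t <- setdiff(tl, al)
    only_a <- setdiff(al, tl)
    stop("tree and alignment name mismatch.",
         if (length(only_t)) paste0(" Only in tree: ", paste(only_t, collapse = ", "), "."),
         if (length(only_a)) paste0(" Only in alignment: ", paste(only_a, collapse = ", "), "."))
  }
  invisible(TRUE)
}
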