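#' Parse a Newick string into a validated phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is an
#' ordinary `"phylo"` object, checked for the properties every downstream
#' statistic relies on: all edges carry a finite, non-negative branch length,
#' and tip labels are unique and non-empty. Node labels are ignored.
#'
#' @param text A single Newick string (must end in `";"`).
#' @param default_branch_length Optional numeric used for edges that carry no
#'   length in the string. The default (`NULL`) rejects such trees.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((B:0.5,C:0.5):0.5,A:1.0);")
#' tree_depths(tr)
#' @export
parse_newick <- function(text, default_branch_length = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_balanced_parens(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick string: could not be parsed", call. = FALSE)
  if (is.null(tr$edge.length)) {
    if (is.null(default_branch_length))
      stop("tree has no branch lengths; supply 'default_branch_length' to accept it",
           call. = FALSE)
    tr$edge.length <- rep(default_branch_length, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (is.null(default_branch_length))
      stop("some edges are missing branch lengths", call. = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- default_branch_length
  }
  validate_tree(tr)
  tr
}

# Report the character offset of the first unbalanced parenthesis, a failure
# mode ape reports unhelpfully.
.check_balanced_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick string: unmatched ')' at character %d", i),
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop(sprintf("malformed Newick string: %d unclosed '(' (last opened before character %d)",
                 depth, nchar(text)), call. = FALSE)
  invisible(TRUE)
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks the invariants assumed throughout the package: a rooted binary-or-
#' polytomous tree with unique non-empty tip labels and finite, non-negative
#' branch lengths. Zero-length terminal branches are legal but trigger a
#' warning because duplicated zero-depth tips make the phylogenetic covariance
#' singular.
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("branch lengths must be finite", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip labels", call. = FALSE)
  if (anyDuplicated(labs))
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  term <- tree$edge[, 2] <= length(labs)
  if (any(tree$edge.length[term] == 0))
    warning("zero-length terminal branch(es); covariance matrix may be singular",
            call. = FALSE)
  invisible(tree)
}

#' Write a phylogeny to a Newick string
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; when `NULL` the string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Rename tips of a phylogeny (proxy-species substitution)
#'
#' Comparative datasets often place a species on the tree at the position of
#' its closest sequenced relative. This relabels tips without touching
#' topology or branch lengths.
#'
#' @param tree A `"phylo"` object.
#' @param mapping Named character vector, `old label -> new label`.
#' @return The relabelled tree.
#' @examples
#' tr <- parse_newick("((B:0.5,C:0.5):0.5,A:1.0);")
#' substitute_tips(tr, c(A = "Noctua_pronuba"))
#' @export
substitute_tips <- function(tree, mapping) {
  validate_tree(tree)
  if (length(mapping) == 0L) return(tree)
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  old <- names(mapping)
  missing <- setdiff(old, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  new_labels <- tree$tip.label
  idx <- match(old, tree$tip.label)
  new_labels[idx] <- unname(mapping)
  if (anyDuplicated(new_labels))
    stop("label collision after substitution: ",
         paste(unique(new_labels[duplicated(new_labels)]), collapse = ", "),
         call. = FALSE)
  tree$tip.label <- new_labels
  tree
}

#' Restrict a phylogeny to a set of species
#'
#' Drops all other tips and collapses the resulting degree-2 internal nodes,
#' summing branch lengths, so that path lengths between retained tips are
#' preserved exactly.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned tree.
#' @export
prune_to_species <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(keep)
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("tips not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(keep) < 2L)
    stop("at least 2 tips must be retained", call. = FALSE)
  out <- ape::keep.tip(tree, keep)
  out$root.edge <- NULL
  # when every kept tip descends from one child of the old root, ape collapses
  # the stem; keep it as a root edge so root-to-tip depths (and hence the
  # covariance matrix) are preserved, not just tip-to-tip path lengths
  stem <- unname(tree_depths(tree)[keep[1]] - .depths_raw(out)[keep[1]])
  if (stem > 1e-12) out$root.edge <- stem
  out
}

#' Root-to-tip path lengths
#'
#' Includes any root (stem) edge carried by the tree, e.g. after pruning.
#'
#' @param tree A `"phylo"` object.
#' @return Named numeric vector of tip depths, in `tree$tip.label` order.
#' @export
tree_depths <- function(tree) {
  d <- .depths_raw(tree)
  if (!is.null(tree$root.edge)) d <- d + tree$root.edge
  d
}

.depths_raw <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the covariance of two tips equals the branch length
#' shared on their root-to-tip paths, i.e. the depth of their most recent
#' common ancestor. This computes that matrix by a single pre-order traversal:
#' each edge's length is added to the covariance block of all tip pairs that
#' descend from it.
#'
#' @param tree A `"phylo"` object with at least 2 tips.
#' @return An `n x n` symmetric positive semi-definite matrix with tip labels
#'   as dimnames, diagonal equal to root-to-tip depths.
#' @examples
#' vcv_matrix(parse_newick("((B:0.5,C:0.5):0.5,A:1.0);"))
#' @export
vcv_matrix <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n < 2L) stop("at least 2 tips required", call. = FALSE)
  # tips below each node, accumulated from a postorder edge sweep
  edge <- tree$edge
  nn <- max(edge)
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (e in seq_len(nrow(edge))) {
    tips <- desc[[edge[e, 2]]]
    C[tips, tips] <- C[tips, tips] + tree$edge.length[e]
  }
  # a root (stem) edge is shared history of every tip pair
  if (!is.null(tree$root.edge)) C <- C + tree$root.edge
  C
}

# Canonical species-label form: trimmed, underscores for internal whitespace.
normalize_labels <- function(x) {
  x <- trimws(x)
  gsub("[[:space:]]+", "_", x)
}

#' Reconcile species labels across tree and tables
#'
#' Label matching is exact after whitespace trimming and underscore/space
#' unification. Any species present in one input but not the other is a hard
#' error listing the offenders.
#'
#' @param tree_labels Tip labels of the phylogeny.
#' @param table_labels Species labels of a data table.
#' @param table_name Name used in error messages.
#' @return Invisibly, the normalized common label set.
#' @export
check_species_match <- function(tree_labels, table_labels,
                                table_name = "table") {
  a <- normalize_labels(tree_labels)
  b <- unique(normalize_labels(table_labels))
  only_tree <- setdiff(a, b)
  only_tab <- setdiff(b, a)
  if (length(only_tree) || length(only_tab))
    stop("species mismatch between tree and ", table_name, ":",
         if (length(only_tree))
           paste0("\n  tree only: ", paste(only_tree, collapse = ", ")) else "",
         if (length(only_tab))
           paste0("\n  ", table_name, " only: ", paste(only_tab, collapse = ", ")) else "",
         call. = FALSE)
  invisible(intersect(a, b))
}
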