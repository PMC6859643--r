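#' Rooted binary phylogenetic trees
#'
#' Internal representation built on top of an `ape::phylo` object: integer
#' node ids (tips `1..n`, internal `n+1..`, ape convention), a parent
#' pointer, a children list, the branch length from each node to its parent,
#' and a postorder traversal.  Only rooted, strictly binary trees with
#' branch lengths on every edge are accepted; polytomies must be resolved by
#' the caller.
#'
#' @param phy An `ape::phylo` object.
#' @return An object of class `phylo_tree`.
#' @export
as_phylo_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected an ape phylo object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (!ape::is.binary(phy)) stop("tree must be strictly binary; resolve polytomies first")
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  ntip <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label)) stop("leaf names must be unique")
  nnode <- ntip + phy$Nnode
  parent <- rep(NA_integer_, nnode)
  edge_len <- rep(NA_real_, nnode)
  children <- vector("list", nnode)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    parent[ch] <- p
    edge_len[ch] <- phy$edge.length[e]
    children[[p]] <- c(children[[p]], ch)
  }
  root <- ntip + 1L
  # postorder: children before parents
  po <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    po <- c(po, nd)
    stack <- c(stack, children[[nd]])
  }
  po <- rev(po)
  node_label <- rep(NA_character_, nnode)
  node_label[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label) && length(phy$node.label) == phy$Nnode) {
    lbl <- phy$node.label
    lbl[!nzchar(lbl)] <- NA_character_
    node_label[(ntip + 1L):nnode] <- lbl
  }
  structure(list(phy = phy, ntip = ntip, nnode = nnode, root = root,
                 parent = parent, children = children, edge_len = edge_len,
                 tip_labels = phy$tip.label, node_label = node_label,
                 postorder = po),
            class = "phylo_tree")
}

#' @export
print.phylo_tree <- function(x, ...) {
  cat(sprintf("<phylo_tree: %d tips, total length %.4g>\n",
              x$ntip, sum(x$edge_len, na.rm = TRUE)))
  invisible(x)
}

#' Read and write Newick trees
#'
#' Thin wrappers over `ape` that enforce the package's tree contract
#' (rooted, binary, every edge with a branch length).
#' @param path File path, or for `read_newick(text=)` a Newick string.
#' @param text Optional Newick string instead of a file.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  phy <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(phy)) stop("failed to parse Newick input")
  as_phylo_tree(phy)
}

#' @rdname read_newick
#' @param tree A `phylo_tree`.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree$phy)
  if (!is.null(path)) { writeLines(txt, path); invisible(path) } else txt
}

#' Extract the target lineage (concestor path)
#'
#' The path from the target leaf `c_0` up to the root `c_M`.  Each internal
#' node on the path is a concestor of the target and some extant clade;
#' `b_k` is the sibling of `c_(k-1)` under `c_k`.  `s_k` are the cumulative
#' fractions of the leaf-to-root path length `tbar` at each concestor.
#'
#' @param tree A `phylo_tree`.
#' @param target Leaf name of the target species.
#' @return A `target_lineage`: concestor node ids `c` (c_0 .. c_M), sibling
#'   ids `b` (b_1 .. b_M), per-edge lengths `t_edge`, cumulative times from
#'   the leaf `time` (length M+1, starting at 0), fractions `s`, and `tbar`.
#' @export
extract_lineage <- function(tree, target) {
  c0 <- match(target, tree$tip_labels)
  if (is.na(c0)) stop("unknown target species: ", target)
  path <- c0
  while (!is.na(tree$parent[path[length(path)]]))
    path <- c(path, tree$parent[path[length(path)]])
  M <- length(path) - 1L
  if (M < 1L) stop("target lineage has no edges")
  sib <- integer(M)
  for (k in seq_len(M)) {
    kids <- tree$children[[path[k + 1]]]
    sib[k] <- kids[kids != path[k]]
  }
  t_edge <- tree$edge_len[path[seq_len(M)]]
  time <- c(0, cumsum(t_edge))
  tbar <- time[M + 1]
  s <- if (tbar > 0) time / tbar else c(rep(0, M), 1)
  structure(list(c = path, b = sib, t_edge = t_edge, time = time,
                 s = s, tbar = tbar, M = M,
                 names = tree$node_label[path], target = target),
            class = "target_lineage")
}
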