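# Shared fixtures and independent oracles used across the suite.

jc_model <- function(mu = 1 / 3) {
  build_strand_symmetric(mu, mu, mu, mu, mu, mu)
}

table2_model <- function(normalize = FALSE) {
  build_strand_symmetric(0.16, 0.57, 0.20, 0.24, 0.59, 0.25,
                         normalize = normalize)
}

random_symmetric_model <- function() {
  r <- stats::runif(6, 0.05, 1)
  build_strand_symmetric(r[1], r[2], r[3], r[4], r[5], r[6])
}

tree5 <- function() {
  read_newick(text = "(((hum:0.1,chp:0.12):0.15,mus:0.4):0.2,gal:0.6);")
}

tree6 <- function() {
  read_newick(
    text = "(((hum:0.1,chp:0.12):0.15,(mus:0.25,rat:0.3):0.18):0.2,gal:0.6);")
}

col_on <- function(tree, ...) {
  v <- c(...)
  matrix(v, length(v), 1, dimnames = list(names(v), NULL))
}

complement_cols <- function(cols) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- cols
  obs <- !is.na(cols) & toupper(cols) %in% names(comp)
  out[obs] <- comp[toupper(cols[obs])]
  out
}

# Brute-force column likelihood: enumerate all internal-node states.
brute_force_Z <- function(tree, model, column) {
  P <- lapply(seq_len(tree$nnode), function(n)
    if (!is.na(tree$parent[n])) transition_matrix(model, tree$edge_len[n]))
  internal <- (tree$ntip + 1L):tree$nnode
  grid <- expand.grid(rep(list(1:4), length(internal)))
  leaf_state <- match(toupper(column[tree$tip_labels]), c("A", "C", "G", "T"))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(tree$nnode)
    st[internal] <- as.integer(grid[g, ])
    pr <- model$pi[st[tree$root]]
    for (n in seq_len(tree$nnode)) {
      p <- tree$parent[n]
      if (is.na(p)) next
      if (n <= tree$ntip) {
        if (!is.na(leaf_state[n])) pr <- pr * P[[n]][leaf_state[n], st[p]]
      } else {
        pr <- pr * P[[n]][st[n], st[p]]
      }
    }
    total <- total + pr
  }
  unname(total)
}

# Brute-force joint P(X_node = i, Y) by enumeration.
brute_force_node_marginal <- function(tree, model, column, node) {
  P <- lapply(seq_len(tree$nnode), function(n)
    if (!is.na(tree$parent[n])) transition_matrix(model, tree$edge_len[n]))
  internal <- (tree$ntip + 1L):tree$nnode
  grid <- expand.grid(rep(list(1:4), length(internal)))
  leaf_state <- match(toupper(column[tree$tip_labels]), c("A", "C", "G", "T"))
  marg <- numeric(4)
  for (g in seq_len(nrow(grid))) {
    st <- integer(tree$nnode)
    st[internal] <- as.integer(grid[g, ])
    if (node <= tree$ntip) st[node] <- leaf_state[node]
    pr <- model$pi[st[tree$root]]
    for (n in seq_len(tree$nnode)) {
      p <- tree$parent[n]
      if (is.na(p)) next
      if (n <= tree$ntip) {
        if (!is.na(leaf_state[n])) pr <- pr * P[[n]][leaf_state[n], st[p]]
      } else {
        pr <- pr * P[[n]][st[n], st[p]]
      }
    }
    marg[st[node]] <- marg[st[node]] + pr
  }
  marg
}

# Brute-force alpha_D(c_k, a): lineage pinned to a with no-substitution
# propagators on lineage edges; sibling subtrees marginalized exactly.
brute_force_alphaD <- function(tree, model, column, lineage, k) {
  a <- match(toupper(column[lineage$target]), c("A", "C", "G", "T"))
  val <- 1
  for (j in seq_len(k)) {
    val <- val * exp(lineage$t_edge[j] * model$RD[a])
    bsub <- lineage$b[j]
    # emission of sibling subtree given parent state a: sum over sibling state
    Pb <- transition_matrix(model, tree$edge_len[bsub])
    leaves <- mrsub:::subtree_leaves(tree, bsub)
    gam <- 0
    for (x in 1:4) {
      sub <- subtree_brute_inside(tree, model, column, bsub, x)
      gam <- gam + Pb[x, a] * sub
    }
    val <- val * gam
  }
  unname(val)
}

# inside probability of a subtree by enumeration, given root state
subtree_brute_inside <- function(tree, model, column, node, state) {
  if (node <= tree$ntip) {
    ls <- match(toupper(column[tree$tip_labels[node]]), c("A", "C", "G", "T"))
    return(if (is.na(ls)) 1 else as.numeric(ls == state))
  }
  kids <- tree$children[[node]]
  out <- 1
  for (ch in kids) {
    Pc <- transition_matrix(model, tree$edge_len[ch])
    acc <- 0
    for (x in 1:4)
      acc <- acc + Pc[x, state] * subtree_brute_inside(tree, model, column, ch, x)
    out <- out * acc
  }
  out
}

rel_diff_vec <- function(x, y) {
  sqrt(sum((x - y)^2)) / max(sqrt(sum(x^2)), sqrt(sum(y^2)))
}
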