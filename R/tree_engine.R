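is_missing_symbol <- function(x) {
  is.na(x) | !(toupper(x) %in% BASES)
}

#' Build an alignment-column batch
#'
#' Columns are held as a character matrix with one row per species and one
#' column per alignment site.  Entries outside A,C,G,T (gaps `-`, IUPAC
#' ambiguity codes, `NA` for unaligned) are treated as missing data in all
#' computations; species absent from the matrix are likewise missing.
#'
#' @param ... Named character vectors, one per species, equal length.
#' @return Character matrix (species x sites).
#' @export
column_matrix <- function(...) {
  rows <- list(...)
  stopifnot(length(rows) > 0, !is.null(names(rows)), all(nzchar(names(rows))))
  mat <- do.call(rbind, lapply(rows, toupper))
  rownames(mat) <- names(rows)
  mat
}

edge_P_matrices <- function(tree, model) {
  P <- vector("list", tree$nnode)
  for (n in seq_len(tree$nnode)) {
    if (!is.na(tree$parent[n])) P[[n]] <- transition_matrix(model, tree$edge_len[n])
  }
  P
}

#' Inside (pruning) table
#'
#' `alpha[[n]][i, c]` is the probability of the observed bases at the leaves
#' below node `n` in column `c`, given state `i` at `n`.  Missing leaves
#' contribute all-ones vectors, which makes estimates identical to those on
#' the tree with the missing leaves pruned.
#'
#' @param tree A `phylo_tree`.
#' @param model A `rate_model`.
#' @param cols Character matrix from [column_matrix()] (species x sites).
#' @param P Optional precomputed per-edge transition matrices.
#' @return List with `alpha` (per-node 4 x C matrices), `Z` (column
#'   likelihoods) and `P`.
#' @export
inside_fill <- function(tree, model, cols, P = edge_P_matrices(tree, model)) {
  C <- ncol(cols)
  alpha <- vector("list", tree$nnode)
  for (n in tree$postorder) {
    kids <- tree$children[[n]]
    if (length(kids) == 0) {
      A <- matrix(1, 4, C)
      sp <- tree$tip_labels[n]
      if (sp %in% rownames(cols)) {
        sym <- cols[sp, ]
        idx <- match(toupper(sym), BASES)
        obs <- !is.na(idx)
        if (any(obs)) {
          A[, obs] <- 0
          A[cbind(idx[obs], which(obs))] <- 1
        }
      }
      alpha[[n]] <- A
    } else {
      A <- crossprod(P[[kids[1]]], alpha[[kids[1]]])
      for (ch in kids[-1]) A <- A * crossprod(P[[ch]], alpha[[ch]])
      alpha[[n]] <- A
    }
  }
  Z <- as.numeric(colSums(model$pi * alpha[[tree$root]]))
  list(alpha = alpha, Z = Z, P = P)
}

#' Outside table
#'
#' `beta[[n]][i, c]` is the joint probability of the observed bases outside
#' the subtree of `n`, together with state `i` at the parent of `n`
#' (root prior included).  Satisfies, at every non-root node,
#' `sum_{i,j} beta[[n]][i,] * P_n[j,i] * alpha[[n]][j,] = Z`.
#'
#' @inheritParams inside_fill
#' @param inside Result of [inside_fill()].
#' @return List of per-node 4 x C matrices (NULL at the root).
#' @export
outside_fill <- function(tree, model, cols, inside) {
  alpha <- inside$alpha; P <- inside$P
  beta <- vector("list", tree$nnode)
  for (n in rev(tree$postorder)) {
    u <- tree$parent[n]
    if (is.na(u)) next
    sibs <- setdiff(tree$children[[u]], n)
    g <- matrix(1, 4, ncol(alpha[[n]]))
    for (m in sibs) g <- g * crossprod(P[[m]], alpha[[m]])
    if (is.na(tree$parent[u])) {
      beta[[n]] <- model$pi * g
    } else {
      beta[[n]] <- (P[[u]] %*% beta[[u]]) * g
    }
  }
  beta
}

#' No-substitution inside prefix along the target lineage
#'
#' `alpha_D(c_k, i)` is nonzero only at the observed target base `a`:
#' it is the probability of emitting the leaves below concestor `c_k` while
#' the lineage stays in state `a` from the leaf up to `c_k`,
#' `alpha_D(c_k, a) = prod_{j<=k} exp(t_j R_D[a,a]) * gamma(b_j, a)`.
#'
#' @inheritParams inside_fill
#' @param lineage A [target_lineage][extract_lineage()].
#' @param inside Result of [inside_fill()].
#' @return Matrix `(M+1) x C`; row `k+1` is `alpha_D(c_k, a)` per column.
#'   Columns whose target symbol is missing get `NA`.
#' @export
inside_no_sub <- function(tree, model, cols, lineage, inside = NULL) {
  if (is.null(inside)) inside <- inside_fill(tree, model, cols)
  C <- ncol(cols)
  a_idx <- target_state(cols, lineage$target)
  D <- matrix(NA_real_, lineage$M + 1L, C)
  ok <- !is.na(a_idx)
  cur <- rep(1, C); cur[!ok] <- NA
  D[1, ] <- cur
  for (k in seq_len(lineage$M)) {
    g <- crossprod(inside$P[[lineage$b[k]]], inside$alpha[[lineage$b[k]]])
    ga <- g[cbind(a_idx, seq_len(C))]
    pd <- exp(lineage$t_edge[k] * model$RD[a_idx])
    cur <- cur * pd * ga
    D[k + 1, ] <- cur
  }
  D
}

target_state <- function(cols, target) {
  if (!target %in% rownames(cols)) stop("target species not present in columns: ", target)
  idx <- match(toupper(cols[target, ]), BASES)
  idx
}

#' Mixed no-substitution/full propagator integral for lineage edge k
#'
#' Row `a` of `kappa_k`, i.e.
#' `kappa_k(a, j) = t_k sum_l U[a,l] Uinv[l,j] K(t_k R_D[a,a], t_k lambda_l)`
#' which equals `tbar * int_{s_{k-1}}^{s_k} [exp((s-s_{k-1}) tbar R_D)
#' exp((s_k - s) tbar R)]_{aj} ds` with `t_k` the k-th lineage edge length.
#'
#' @inheritParams inside_no_sub
#' @param k Lineage edge index, 1..M (edge from `c_(k-1)` to `c_k`).
#' @param a Target base (character or 1..4).
#' @param j Optional column state; if `NULL` the full row is returned.
#' @export
kappa_edge <- function(model, lineage, k, a, j = NULL) {
  stopifnot(k >= 1, k <= lineage$M)
  row <- as.numeric(Re(kappa_row(model, lineage$t_edge[k], base_index(a))))
  if (is.null(j)) row else row[base_index(j)]
}

kappa_row <- function(model, tk, ia) {
  (tk * (model$U[ia, ] * kernel_K(tk * model$RD[ia], tk * model$lambda))) %*% model$Uinv
}

kappa_prime_row <- function(model, tk, ia) {
  (tk * tk * (model$U[ia, ] * kernel_K_prime(tk * model$RD[ia], tk * model$lambda))) %*% model$Uinv
}

#' Per-column estimates of t_MRS, sigma and q on a phylogenetic tree
#'
#' Exact dynamic program over the target lineage.  Writing `D_(k-1)` for the
#' no-substitution prefix ([inside_no_sub()]), `beta` for the outside table
#' and `kappa_k` for the edge propagator integrals,
#' `t_MRS = (1/Z) sum_k D_(k-1)(a) sum_j kappa_k(a,j) beta(c_(k-1), j)`;
#' the second moment adds the `K'` kernel and the cumulative-time cross
#' term; `q = (1/Z) exp(tbar R_D[a,a]) prod_k gamma(b_k, a) pi_a`.
#' Columns whose target symbol is a gap or ambiguity code are flagged
#' `skipped` and get `NA` estimates.
#'
#' @inheritParams inside_fill
#' @param target Name of the target species (a leaf).
#' @param lineage Optional precomputed [target_lineage][extract_lineage()].
#' @return A data.frame with one row per column: `target_base`, `tmrs`,
#'   `sigma`, `q`, `logZ`, `skipped`.
#' @export
estimate_columns <- function(tree, model, cols, target,
                             lineage = extract_lineage(tree, target)) {
  C <- ncol(cols)
  inside <- inside_fill(tree, model, cols)
  if (any(inside$Z <= 0)) stop_numerical("impossible column (Z = 0) at index ",
                               which(inside$Z <= 0)[1])
  beta <- outside_fill(tree, model, cols, inside)
  a_idx <- target_state(cols, target)
  tmrs <- sigma <- q <- rep(NA_real_, C)
  M <- lineage$M
  for (a in 1:4) {
    sel <- which(!is.na(a_idx) & a_idx == a)
    if (!length(sel)) next
    D <- rep(1, length(sel))
    num1 <- num2 <- numeric(length(sel))
    for (k in seq_len(M)) {
      tk <- lineage$t_edge[k]
      krow <- kappa_row(model, tk, a)
      kprow <- kappa_prime_row(model, tk, a)
      B <- beta[[lineage$c[k]]][, sel, drop = FALSE]
      num1 <- num1 + D * as.numeric(Re(krow %*% B))
      num2 <- num2 + D * as.numeric(Re((2 * (lineage$time[k] * krow + kprow)) %*% B))
      g <- crossprod(inside$P[[lineage$b[k]]], inside$alpha[[lineage$b[k]]])
      D <- D * exp(tk * model$RD[a]) * g[a, sel]
    }
    Z <- inside$Z[sel]
    tmrs[sel] <- num1 / Z
    v <- num2 / Z - (num1 / Z)^2
    if (any(v < -1e-9 * max(1, lineage$tbar^2)))
      stop_numerical("negative variance beyond round-off in tree estimate")
    sigma[sel] <- sqrt(pmax(0, v))
    q[sel] <- pmin(1, D * model$pi[a] / Z)
  }
  data.frame(target_base = cols[target, ], tmrs = tmrs, sigma = sigma, q = q,
             logZ = log(inside$Z), skipped = is.na(a_idx),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname estimate_columns
#' @param column A single named character vector (one symbol per species).
#' @export
estimate_site <- function(tree, model, column, target) {
  cols <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  estimate_columns(tree, model, cols, target)[1, ]
}

#' Marginal-posterior ancestral reconstruction along the target lineage
#'
#' For each concestor `c_k` (k >= 1) returns the base maximizing
#' `P(X_{c_k} = i | Y) = alpha(c_k, i) * outer(c_k, i) / Z`.  Ties are
#' broken by the fixed base order A < C < G < T.
#'
#' @inheritParams estimate_columns
#' @return Character matrix `M x C` of reconstructed bases, rows
#'   `c_1 .. c_M` (most recent concestor first).
#' @export
reconstruct_ancestors <- function(tree, model, cols, target,
                                  lineage = extract_lineage(tree, target)) {
  inside <- inside_fill(tree, model, cols)
  beta <- outside_fill(tree, model, cols, inside)
  M <- lineage$M
  out <- matrix(NA_character_, M, ncol(cols))
  for (k in seq_len(M)) {
    n <- lineage$c[k + 1]
    post <- if (n == tree$root) {
      model$pi * inside$alpha[[n]]
    } else {
      inside$alpha[[n]] * (inside$P[[n]] %*% beta[[n]])
    }
    out[k, ] <- BASES[apply(post, 2, which.max)]
  }
  rownames(out) <- ifelse(is.na(lineage$names[-1]),
                          paste0("c", seq_len(M)), lineage$names[-1])
  out
}

#' Node posteriors P(X_n = i | Y) for every node
#'
#' @inheritParams estimate_columns
#' @return List of 4 x C matrices, one per node, each column summing to 1.
#' @export
node_posteriors <- function(tree, model, cols) {
  inside <- inside_fill(tree, model, cols)
  beta <- outside_fill(tree, model, cols, inside)
  lapply(seq_len(tree$nnode), function(n) {
    post <- if (n == tree$root) model$pi * inside$alpha[[n]]
            else inside$alpha[[n]] * (inside$P[[n]] %*% beta[[n]])
    sweep(post, 2, colSums(post), "/")
  })
}
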