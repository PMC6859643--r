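#' Deduplicate alignment columns
#'
#' Collapses identical columns and records multiplicities; the likelihood is
#' unchanged and evaluation cost drops with the number of distinct patterns.
#'
#' @param cols Character matrix (species x sites).
#' @return List with `cols` (distinct columns) and `counts`.
#' @export
dedupe_columns <- function(cols) {
  key <- apply(cols, 2, paste, collapse = "\r")
  tab <- table(factor(key, levels = unique(key)))
  keep <- match(names(tab), key)
  list(cols = cols[, keep, drop = FALSE], counts = as.numeric(tab))
}

# Structure matrices dR/dtheta_p for the six strand-symmetric rates,
# including the Markov-condition diagonal.
symmetric_structures <- function() {
  mk <- function(cells) {
    S <- matrix(0, 4, 4)
    for (cl in cells) S[cl[1], cl[2]] <- 1
    diag(S) <- -colSums(S)
    S
  }
  list(alpha   = mk(list(c(1, 2), c(4, 3))),
       beta    = mk(list(c(1, 3), c(4, 2))),
       gamma   = mk(list(c(1, 4), c(4, 1))),
       delta   = mk(list(c(2, 3), c(3, 2))),
       epsilon = mk(list(c(2, 4), c(3, 1))),
       eta     = mk(list(c(2, 1), c(3, 4))))
}

# Frechet derivative of exp(tR) in direction S via the eigensystem:
# dexp(tR)[S] = U ((Uinv S U) * Phi) Uinv, Phi_lm = t K(t lambda_l, t lambda_m).
dexp_frechet <- function(model, t, S) {
  lam <- model$lambda
  Phi <- t * kernel_K(t * matrix(lam, 4, 4), t * matrix(lam, 4, 4, byrow = TRUE))
  Re(model$U %*% ((model$Uinv %*% S %*% model$U) * Phi) %*% model$Uinv)
}

# d pi / d theta_p: differentiate R pi = 0, sum(pi) = 1.
dpi_dtheta <- function(model, S) {
  A <- rbind(model$R, rep(1, 4))
  rhs <- c(-as.numeric(S %*% model$pi), 0)
  as.numeric(qr.solve(A, rhs))
}

#' Log likelihood of alignment columns under a model and tree
#'
#' Sum over columns (weighted by multiplicities) of the log column
#' likelihood `log Z(Y)` from the inside algorithm.
#'
#' @param tree A `phylo_tree`.
#' @param model A `rate_model`.
#' @param cols Character matrix (species x sites).
#' @param counts Column multiplicities (default all 1).
#' @export
log_likelihood <- function(tree, model, cols, counts = rep(1, ncol(cols))) {
  Z <- inside_fill(tree, model, cols)$Z
  if (any(!is.finite(Z) | Z <= 0))
    stop_numerical("non-finite likelihood at column ", which(!is.finite(Z) | Z <= 0)[1])
  sum(counts * log(Z))
}

#' Exact gradient of the log likelihood
#'
#' Inside-outside gradient: for each edge the expected joint state
#' distribution `beta(n, i) alpha(n, j) / Z` is contracted with the
#' derivative of the edge transition matrix (a Daleckii-Krein divided
#' difference in the model eigenbasis for rate parameters, `R exp(tR)` for
#' branch lengths); the root term uses the derivative of the stationary
#' distribution.
#'
#' @inheritParams log_likelihood
#' @return Numeric vector: six rate derivatives (alpha..eta) followed by one
#'   derivative per non-root node's branch length (in node-id order).
#' @export
gradient <- function(tree, model, cols, counts = rep(1, ncol(cols))) {
  if (model$type != "symmetric") stop("gradients implemented for the strand-symmetric model")
  inside <- inside_fill(tree, model, cols)
  beta <- outside_fill(tree, model, cols, inside)
  Z <- inside$Z
  structs <- symmetric_structures()
  nonroot <- which(!is.na(tree$parent))
  g_rates <- numeric(6)
  g_edges <- numeric(length(nonroot))
  wts <- counts / Z
  for (e in seq_along(nonroot)) {
    n <- nonroot[e]
    tn <- tree$edge_len[n]
    an <- inside$alpha[[n]]; bn <- beta[[n]]
    # branch length: dP/dt = R exp(tR)
    dP <- model$R %*% inside$P[[n]]
    g_edges[e] <- sum(wts * colSums(bn * crossprod(dP, an)))
    for (p in 1:6) {
      dPp <- dexp_frechet(model, tn, structs[[p]])
      g_rates[p] <- g_rates[p] + sum(wts * colSums(bn * crossprod(dPp, an)))
    }
  }
  aroot <- inside$alpha[[tree$root]]
  for (p in 1:6) {
    dpi <- dpi_dtheta(model, structs[[p]])
    g_rates[p] <- g_rates[p] + sum(wts * colSums(dpi * aroot))
  }
  names(g_rates) <- names(structs)
  c(g_rates, stats::setNames(g_edges, paste0("t", nonroot)))
}

#' Relative difference between two parameter vectors
#'
#' `|theta1 - theta2| / max(|theta1|, |theta2|)` with `|.|` the Euclidean
#' norm; defined as 0 when both vectors are zero.
#' @param theta1,theta2 Numeric vectors of equal length.
#' @export
relative_difference <- function(theta1, theta2) {
  stopifnot(length(theta1) == length(theta2))
  denom <- max(sqrt(sum(theta1^2)), sqrt(sum(theta2^2)))
  if (denom == 0) return(0)
  sqrt(sum((theta1 - theta2)^2)) / denom
}

set_tree_lengths <- function(tree, lengths) {
  nonroot <- which(!is.na(tree$parent))
  stopifnot(length(lengths) == length(nonroot))
  tree$edge_len[nonroot] <- lengths
  for (e in seq_len(nrow(tree$phy$edge)))
    tree$phy$edge.length[e] <- tree$edge_len[tree$phy$edge[e, 2]]
  tree
}

#' Maximum-likelihood fit of rates and branch lengths
#'
#' Bounded quasi-Newton (L-BFGS-B) optimization of the six strand-symmetric
#' rates and all branch lengths on a fixed topology, using the exact
#' [gradient()].  Parameters are optimized on the log scale inside the box
#' `[1e-6, 1e3]` to enforce positivity.  Because the likelihood is invariant
#' under `(R -> cR, t -> t/c)`, the fitted model is rescaled afterwards to
#' expected rate 1 with the scale absorbed into the branch lengths.
#'
#' @inheritParams log_likelihood
#' @param init_rates Initial six rates (alpha..eta).
#' @param init_lengths Initial branch lengths (default: the tree's own).
#' @param maxit Maximum optimizer iterations.
#' @param dedupe Deduplicate columns before fitting.
#' @return List with `model` (normalized), `tree` (fitted branch lengths),
#'   `rates`, `logLik`, `convergence`, `counts_used`.
#' @export
fit <- function(tree, cols, init_rates = rep(0.5, 6), init_lengths = NULL,
                counts = rep(1, ncol(cols)), maxit = 200, dedupe = TRUE) {
  if (dedupe) {
    key <- apply(cols, 2, paste, collapse = "\r")
    agg <- tapply(counts, factor(key, levels = unique(key)), sum)
    cols <- cols[, match(names(agg), key), drop = FALSE]
    counts <- as.numeric(agg)
  }
  nonroot <- which(!is.na(tree$parent))
  if (is.null(init_lengths)) init_lengths <- pmax(tree$edge_len[nonroot], 1e-4)
  x0 <- log(pmin(pmax(c(init_rates, init_lengths), 1e-6), 1e3))
  unpack <- function(x) {
    th <- exp(x)
    list(rates = th[1:6], lengths = th[-(1:6)])
  }
  objective <- function(x) {
    p <- unpack(x)
    m <- build_strand_symmetric(p$rates[1], p$rates[2], p$rates[3],
                                p$rates[4], p$rates[5], p$rates[6])
    tr <- set_tree_lengths(tree, p$lengths)
    -log_likelihood(tr, m, cols, counts)
  }
  grad_fn <- function(x) {
    p <- unpack(x)
    m <- build_strand_symmetric(p$rates[1], p$rates[2], p$rates[3],
                                p$rates[4], p$rates[5], p$rates[6])
    tr <- set_tree_lengths(tree, p$lengths)
    -gradient(tr, m, cols, counts) * exp(x)
  }
  opt <- stats::optim(x0, objective, grad_fn, method = "L-BFGS-B",
                      lower = log(1e-6), upper = log(1e3),
                      control = list(maxit = maxit))
  if (opt$convergence != 0)
    warning("optimizer did not report convergence (code ", opt$convergence,
            "); returning best parameters found")
  p <- unpack(opt$par)
  m <- build_strand_symmetric(p$rates[1], p$rates[2], p$rates[3],
                              p$rates[4], p$rates[5], p$rates[6])
  scale <- m$rate
  m_norm <- normalize_model(m)
  tr <- set_tree_lengths(tree, p$lengths * scale)
  list(model = m_norm, tree = tr, rates = m_norm$params,
       lengths = p$lengths * scale,
       logLik = -opt$value, convergence = opt$convergence,
       counts_used = sum(counts))
}
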