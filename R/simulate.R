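# Evolve a vector of states along one branch (competing-rates simulation).
# Returns end states and, per history, the distance from the *child* end of
# the branch to the last substitution (NA if the branch had none).
evolve_branch <- function(model, states, t, record = FALSE) {
  n <- length(states)
  if (t == 0)
    return(list(end = states, dist_last = rep(NA_real_, n),
                events = if (record) rep(list(NULL), n)))
  elapsed <- numeric(n)
  last_event <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  events <- if (record) rep(list(NULL), n)
  jump_prob <- lapply(1:4, function(s) {
    p <- model$R[, s]; p[s] <- 0
    tot <- sum(p); if (tot > 0) p / tot else p
  })
  while (any(active)) {
    idx <- which(active)
    rate <- -model$RD[states[idx]]
    wait <- rep(Inf, length(idx))
    pos <- rate > 0
    if (any(pos)) wait[pos] <- stats::rexp(sum(pos), rate = rate[pos])
    tnew <- elapsed[idx] + wait
    done <- tnew >= t
    active[idx[done]] <- FALSE
    move <- idx[!done]
    if (length(move)) {
      elapsed[move] <- tnew[!done]
      last_event[move] <- elapsed[move]
      old <- states[move]
      for (s in 1:4) {
        grp <- move[old == s]
        if (length(grp))
          states[grp] <- sample.int(4, length(grp), replace = TRUE,
                                    prob = jump_prob[[s]])
      }
      if (record) {
        for (i in move)
          events[[i]] <- rbind(events[[i]],
                               data.frame(time = elapsed[i], state = states[i]))
      }
    }
  }
  list(end = states, dist_last = t - last_event, events = events)
}

#' Forward simulation of alignment columns with true substitution histories
#'
#' Draws the root state from the model equilibrium and simulates the
#' continuous-time substitution process down every branch (exponential
#' waiting times, competing rates).  For each column the true time
#' `true_T` from the target leaf back to the most recent substitution on
#' the target lineage is recorded (`tbar` of the lineage if there was
#' none, in which case `true_q = 1`).
#'
#' @param tree A `phylo_tree`.
#' @param model A `rate_model`.
#' @param n Number of columns to simulate.
#' @param target Target species (leaf name).
#' @param seed Optional RNG seed for reproducibility.
#' @param keep_history If `TRUE`, also return per-branch event lists
#'   (times measured from the parent end, and the new state).
#' @return List with `cols` (species x n character matrix), `true_T`,
#'   `true_q` (0/1), `lineage`, and optionally `history`.
#' @export
forward_simulate <- function(tree, model, n, target, seed = NULL,
                             keep_history = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  lin <- extract_lineage(tree, target)
  states <- vector("list", tree$nnode)
  states[[tree$root]] <- sample.int(4, n, replace = TRUE, prob = model$pi)
  history <- if (keep_history) vector("list", tree$nnode)
  best <- rep(Inf, n)  # distance from target leaf to most recent lineage event
  lineage_branch <- match(seq_len(tree$nnode), lin$c)  # k+1 if node is c_k
  for (nd in rev(tree$postorder)) {
    p <- tree$parent[nd]
    if (is.na(p)) next
    ev <- evolve_branch(model, states[[p]], tree$edge_len[nd],
                        record = keep_history)
    states[[nd]] <- ev$end
    if (keep_history) history[[nd]] <- ev$events
    k1 <- lineage_branch[nd]
    if (!is.na(k1) && k1 <= lin$M) {
      # branch from c_k down to c_(k-1): child end sits at lin$time[k1]
      d <- lin$time[k1] + ev$dist_last
      hit <- !is.na(ev$dist_last) & d < best
      best[hit] <- d[hit]
    }
  }
  cols <- do.call(rbind, lapply(seq_len(tree$ntip), function(i) BASES[states[[i]]]))
  rownames(cols) <- tree$tip_labels
  no_sub <- !is.finite(best)
  out <- list(cols = cols, true_T = ifelse(no_sub, lin$tbar, best),
              true_q = as.numeric(no_sub), lineage = lin)
  if (keep_history) out$history <- history
  out
}

#' Synthetic missing-data template
#'
#' Stands in for the gap/coverage structure of real genome alignments when
#' none is available: each species is missing independently per column with
#' a probability that increases logistically with its path distance from
#' the target (distant genomes align less often).  The target itself is
#' never missing.
#'
#' @inheritParams forward_simulate
#' @param n Number of template columns.
#' @param p_max Missing probability of the most distant species.
#' @return Character matrix (species x n) with `"-"` marking missing.
#' @export
synthetic_gap_template <- function(tree, target, n, seed = NULL, p_max = 0.8) {
  if (!is.null(seed)) set.seed(seed)
  d <- path_distances_to_leaf(tree, target)
  d0 <- stats::median(d[d > 0])
  sc <- max(diff(range(d)) / 8, 1e-6)
  p <- p_max * stats::plogis((d - d0) / sc)
  p[tree$tip_labels == target] <- 0
  tmpl <- matrix("A", tree$ntip, n, dimnames = list(tree$tip_labels, NULL))
  for (i in seq_len(tree$ntip))
    tmpl[i, stats::runif(n) < p[i]] <- "-"
  tmpl
}

path_distances_to_leaf <- function(tree, target) {
  lin <- extract_lineage(tree, target)
  depth <- numeric(tree$nnode)
  for (nd in rev(tree$postorder)) {
    p <- tree$parent[nd]
    if (!is.na(p)) depth[nd] <- depth[p] + tree$edge_len[nd]
  }
  # distance target -> tip via their MRCA on the lineage
  onpath <- rep(FALSE, tree$nnode); onpath[lin$c] <- TRUE
  anc_on_path <- integer(tree$ntip)
  for (i in seq_len(tree$ntip)) {
    nd <- i
    while (!onpath[nd]) nd <- tree$parent[nd]
    anc_on_path[i] <- nd
  }
  k <- match(anc_on_path, lin$c)
  tips <- seq_len(tree$ntip)
  # leaf-to-MRCA along the lineage, plus MRCA-to-tip
  lin$time[k] + (depth[tips] - depth[anc_on_path])
}

#' Mask simulated columns with a missing-data template
#'
#' Species that are missing (gap or ambiguity) in the template column become
#' missing (`-`) in the simulated column; the target row is never masked.
#' If the template has a different number of columns, template columns are
#' drawn with replacement.
#'
#' @param cols Character matrix (species x sites).
#' @param template Character matrix over the same species.
#' @param target Target species name (never masked).
#' @export
apply_gap_mask <- function(cols, template, target) {
  if (!all(rownames(cols) %in% rownames(template)))
    stop("template is missing species: ",
         paste(setdiff(rownames(cols), rownames(template)), collapse = ","))
  pick <- if (ncol(template) == ncol(cols)) seq_len(ncol(cols))
          else sample.int(ncol(template), ncol(cols), replace = TRUE)
  tm <- template[rownames(cols), pick, drop = FALSE]
  mask <- is_missing_symbol(tm)
  mask[rownames(cols) == target, ] <- FALSE
  cols[mask] <- "-"
  cols
}

#' Posterior sampling of substitution histories (validation oracle)
#'
#' Discretizes every branch into segments (the total number of discrete
#' points is spread over branches proportionally to length), runs the
#' inside algorithm on the augmented tree, and samples full state histories
#' conditioned on the column by forward sampling from the root.  Each
#' sampled history yields a draw of the time `T` to the most recent state
#' change on the target lineage (segment midpoint; `tbar` when the lineage
#' never changes state).  Sample means of `T`, its spread and the
#' no-change frequency converge to the exact `t_MRS`, `sigma`, `q` as both
#' the number of samples and the discretization grow.
#'
#' @inheritParams forward_simulate
#' @param column Named character vector (one symbol per species).
#' @param n_samples Number of sampled histories.
#' @param n_points Total number of discrete points on the tree.
#' @return List with `T` (length `n_samples`), `no_sub` (logical),
#'   `tmrs_hat`, `sigma_hat`, `q_hat`.
#' @export
posterior_sample_histories <- function(tree, model, column, target,
                                       n_samples, n_points, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lin <- extract_lineage(tree, target)
  cols <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  total_len <- sum(tree$edge_len, na.rm = TRUE)
  nseg <- integer(tree$nnode)
  Pseg <- vector("list", tree$nnode)
  Achain <- vector("list", tree$nnode)  # inside vectors at chain points
  # leaf/inside pass on augmented tree
  alpha <- vector("list", tree$nnode)
  for (nd in tree$postorder) {
    kids <- tree$children[[nd]]
    if (length(kids) == 0) {
      a <- rep(1, 4)
      sp <- tree$tip_labels[nd]
      if (sp %in% rownames(cols) && !is_missing_symbol(cols[sp, 1]))
        a <- as.numeric(BASES == toupper(cols[sp, 1]))
      alpha[[nd]] <- a
    } else {
      a <- rep(1, 4)
      for (ch in kids) a <- a * Achain[[ch]][, nseg[ch] + 1]
      alpha[[nd]] <- a
    }
    p <- tree$parent[nd]
    if (!is.na(p)) {
      nseg[nd] <- max(1L, round(n_points * tree$edge_len[nd] / total_len))
      Pseg[[nd]] <- transition_matrix(model, tree$edge_len[nd] / nseg[nd])
      A <- matrix(0, 4, nseg[nd] + 1)
      A[, 1] <- alpha[[nd]]
      for (j in seq_len(nseg[nd])) A[, j + 1] <- crossprod(Pseg[[nd]], A[, j])
      Achain[[nd]] <- A
    }
  }
  Zvec <- model$pi * alpha[[tree$root]]
  Z <- sum(Zvec)
  if (Z <= 0) stop_numerical("impossible column (Z = 0)")
  states <- vector("list", tree$nnode)
  states[[tree$root]] <- sample.int(4, n_samples, replace = TRUE, prob = Zvec / Z)
  onpath_k <- match(seq_len(tree$nnode), lin$c)
  T_cur <- rep(NA_real_, n_samples)
  sample_step <- function(parent_states, W) {
    # W[x, i]: unnormalized P(child point = x | parent point = i)
    out <- integer(length(parent_states))
    for (i in 1:4) {
      grp <- which(parent_states == i)
      if (length(grp)) {
        w <- W[, i]
        if (sum(w) <= 0) stop("inconsistent sampling weights")
        out[grp] <- sample.int(4, length(grp), replace = TRUE, prob = w)
      }
    }
    out
  }
  for (nd in rev(tree$postorder)) {
    p <- tree$parent[nd]
    if (is.na(p)) next
    cur <- states[[p]]
    m <- nseg[nd]
    delta <- tree$edge_len[nd] / m
    k1 <- onpath_k[nd]
    on_lineage <- !is.na(k1) && k1 <= lin$M
    for (j in m:1) {
      W <- Pseg[[nd]] * Achain[[nd]][, j]   # rows x: Pseg[x, i] * A_{j-1}[x]
      nxt <- sample_step(cur, W)
      if (on_lineage) {
        changed <- nxt != cur
        if (any(changed)) {
          mid <- lin$time[k1] + (j - 1) * delta + delta / 2
          T_cur[changed] <- mid
        }
      }
      cur <- nxt
    }
    states[[nd]] <- cur
  }
  no_sub <- is.na(T_cur)
  Tv <- ifelse(no_sub, lin$tbar, T_cur)
  list(T = Tv, no_sub = no_sub,
       tmrs_hat = mean(Tv),
       sigma_hat = sqrt(mean(Tv^2) - mean(Tv)^2),
       q_hat = mean(no_sub))
}

#' Baseline estimators of t_MRS and q
#'
#' `baseline_reconstruction` assigns each concestor its maximum-posterior
#' base and returns the midpoint of the edge below the most recent
#' concestor whose reconstructed base differs from the target base
#' (`q = 1` when none differs, `q = 0` otherwise).
#' `baseline_alignment` ignores the model: it returns the midpoint of the
#' edge below the most recent concestor whose observed descendant leaves
#' contain a base different from the target base.
#'
#' @inheritParams estimate_columns
#' @return data.frame with `t_est` and `q_est` (0/1) per column; `t_est` is
#'   the lineage length `tbar` when `q_est = 1`, `NA` for skipped columns.
#' @export
baseline_reconstruction <- function(tree, model, cols, target,
                                    lineage = extract_lineage(tree, target)) {
  rec <- reconstruct_ancestors(tree, model, cols, target, lineage)
  a <- toupper(cols[target, ])
  ok <- !is_missing_symbol(a)
  first_diff <- apply(rec != rep(a, each = nrow(rec)), 2,
                      function(x) if (any(x)) which(x)[1] else NA_integer_)
  midpoint_result(first_diff, lineage, ok)
}

#' @rdname baseline_reconstruction
#' @export
baseline_alignment <- function(tree, cols, target,
                               lineage = extract_lineage(tree, target)) {
  a <- toupper(cols[target, ])
  ok <- !is_missing_symbol(a)
  C <- ncol(cols)
  diff_any <- matrix(FALSE, lineage$M, C)
  for (k in seq_len(lineage$M)) {
    leaves <- subtree_leaves(tree, lineage$b[k])
    sp <- intersect(tree$tip_labels[leaves], rownames(cols))
    if (length(sp)) {
      sub <- cols[sp, , drop = FALSE]
      obs <- !is_missing_symbol(sub)
      dif <- obs & (toupper(sub) != rep(a, each = nrow(sub)))
      diff_any[k, ] <- colSums(dif) > 0
    }
  }
  cum <- apply(diff_any, 2, cumsum) > 0
  if (lineage$M == 1) cum <- matrix(cum, nrow = 1)
  first_diff <- apply(cum, 2, function(x) if (any(x)) which(x)[1] else NA_integer_)
  midpoint_result(first_diff, lineage, ok)
}

midpoint_result <- function(first_diff, lineage, ok) {
  t_est <- ifelse(is.na(first_diff), lineage$tbar,
                  (lineage$time[first_diff] + lineage$time[first_diff + 1]) / 2)
  q_est <- as.numeric(is.na(first_diff))
  t_est[!ok] <- NA; q_est[!ok] <- NA
  data.frame(t_est = t_est, q_est = q_est)
}

subtree_leaves <- function(tree, node) {
  if (node <= tree$ntip) return(node)
  out <- integer(0); stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$children[[nd]]
    if (length(kids) == 0) out <- c(out, nd) else stack <- c(stack, kids)
  }
  out
}

#' Model-free column statistics
#'
#' `column_entropy` is the Shannon entropy (natural log) of the observed
#' base frequencies; `pairwise_identity` the fraction of identical pairs
#' among all pairs of observed bases.
#'
#' @param cols Character matrix (species x sites).
#' @return Numeric vector, `NA` where fewer than 1 (entropy) or 2
#'   (pairwise) bases are observed.
#' @export
column_entropy <- function(cols) {
  apply(cols, 2, function(x) {
    x <- toupper(x); x <- x[x %in% BASES]
    if (!length(x)) return(NA_real_)
    f <- table(factor(x, levels = BASES)) / length(x)
    f <- f[f > 0]
    -sum(f * log(f))
  })
}

#' @rdname column_entropy
#' @export
pairwise_identity <- function(cols) {
  apply(cols, 2, function(x) {
    x <- toupper(x); x <- x[x %in% BASES]
    n <- length(x)
    if (n < 2) return(NA_real_)
    cnt <- table(factor(x, levels = BASES))
    sum(cnt * (cnt - 1) / 2) / (n * (n - 1) / 2)
  })
}

#' Evaluate estimators against simulated truth
#'
#' For each threshold in `q_grid`: the positive fraction (`q` below the
#' threshold), the false discovery rate for "there was a substitution"
#' calls (fraction of truly substitution-free columns among positives), and
#' the mean per-cent error of `t_MRS` relative to the lineage length.
#'
#' @param est data.frame with columns `tmrs` and `q` (e.g. from
#'   [estimate_columns()]).
#' @param true_T,true_q Truth annotations from [forward_simulate()].
#' @param tbar Total lineage length (error denominator).
#' @param q_grid Thresholds on `q`.
#' @return data.frame with one row per threshold.
#' @export
evaluate_filtering <- function(est, true_T, true_q, tbar,
                               q_grid = c(0.01, 0.1, 0.5, 1)) {
  keep <- !est$skipped & !is.na(est$q)
  rows <- lapply(q_grid, function(th) {
    sel <- keep & est$q < th
    if (!any(sel)) {
      warning("no positives at threshold ", th)
      return(data.frame(q_threshold = th, positive_fraction = 0,
                        fdr_no_mutation = NA_real_, pct_error = NA_real_))
    }
    data.frame(q_threshold = th,
               positive_fraction = mean(sel[keep]),
               fdr_no_mutation = mean(true_q[sel] == 1),
               pct_error = 100 * mean(abs(est$tmrs[sel] - true_T[sel])) / tbar)
  })
  do.call(rbind, rows)
}

#' Spearman correlation of an estimator with the true substitution time
#'
#' Computed on the columns passing `filter` (typically truth `q < 1`, as
#' when ranking estimators against simulated histories).
#'
#' @param est_values Estimator output per column.
#' @param true_T Truth.
#' @param filter Logical vector selecting columns.
#' @export
spearman_vs_truth <- function(est_values, true_T, filter = rep(TRUE, length(true_T))) {
  sel <- filter & !is.na(est_values) & !is.na(true_T)
  stats::cor(est_values[sel], true_T[sel], method = "spearman")
}
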