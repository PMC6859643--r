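#' Single-edge estimators of the time to the most recent substitution
#'
#' For one branch of length `t` with base `b` at the ancestral end and base
#' `a` observed at the recent end, the posterior expectation of the time
#' `T` back to the most recent substitution (with `T = t` when the history
#' has no substitution) has the closed form
#' `t_MRS = (t/Z) sum_i U[a,i] Uinv[i,b] K(t R_D[a], t lambda_i)` with
#' `Z = [exp(tR)]_{ab}`; the second moment is
#' `E[T^2] = (2 t^2 / Z) sum_i U[a,i] Uinv[i,b] K'(t R_D[a], t lambda_i)`
#' (from `E[T^2] = 2 int_0^t u P(T >= u) du`), and the probability of no
#' substitution is `q = exp(t R_D[a]) delta_ab / Z`.
#'
#' @param model A [rate_model][build_strand_symmetric].
#' @param a Observed base at the recent end (character or 1..4).
#' @param b Base at the ancestral end.
#' @param t Branch length (>= 0), substitutions per site.
#' @return `tmrs_edge` the expectation, `second_moment_edge` `E[T^2]`,
#'   `sigma_edge` the standard deviation, `q_edge` the no-substitution
#'   probability.
#' @export
tmrs_edge <- function(model, a, b, t) {
  e <- edge_terms(model, a, b, t)
  re_checked(t / e$Z * sum(e$row * kernel_K(t * e$rdaa, t * model$lambda)))
}

#' @rdname tmrs_edge
#' @export
second_moment_edge <- function(model, a, b, t) {
  e <- edge_terms(model, a, b, t)
  re_checked(2 * t * t / e$Z * sum(e$row * kernel_K_prime(t * e$rdaa, t * model$lambda)))
}

#' @rdname tmrs_edge
#' @export
sigma_edge <- function(model, a, b, t) {
  m1 <- tmrs_edge(model, a, b, t)
  m2 <- second_moment_edge(model, a, b, t)
  v <- m2 - m1 * m1
  if (v < -1e-12 * max(1, t * t)) stop_numerical("negative variance beyond round-off: ", v)
  sqrt(max(0, v))
}

#' @rdname tmrs_edge
#' @export
q_edge <- function(model, a, b, t) {
  ia <- base_index(a); ib <- base_index(b)
  Z <- edge_Z(model, ia, ib, t)
  if (ia != ib) return(0)
  exp(t * model$RD[ia]) / Z
}

edge_Z <- function(model, ia, ib, t) {
  Z <- Re(sum(model$U[ia, ] * exp(t * model$lambda) * model$Uinv[, ib]))
  if (Z <= 0) stop_numerical("unreachable endpoint pair: Z = ", Z)
  Z
}

edge_terms <- function(model, a, b, t) {
  stopifnot(t >= 0)
  ia <- base_index(a); ib <- base_index(b)
  list(Z = edge_Z(model, ia, ib, t),
       row = model$U[ia, ] * model$Uinv[, ib],
       rdaa = model$RD[ia])
}

re_checked <- function(z, tol = 1e-8) {
  if (abs(Im(z)) > tol * max(1, abs(Re(z))))
    stop_numerical("non-negligible imaginary part: ", Im(z))
  Re(z)
}

#' Discrete-chain oracle for the single-edge estimators
#'
#' Independent check by exact computation in the discretized model with
#' transition matrix `Q = I + tR/N`: the time to the most recent
#' substitution is `(t/N) * L` where `L` is the length of the terminal run
#' of identical states, and `P(L >= l) = [Q_D^l Q^(N-l)]_{ab} / [Q^N]_{ab}`.
#' Converges to the closed forms as `N -> Inf`.
#'
#' @inheritParams tmrs_edge
#' @param N Number of discrete steps (>= 10); `t * max|R_ii| / N` must be
#'   below 1 so that `Q` is a stochastic matrix.
#' @return List with `tmrs`, `second_moment`, `q`.
#' @export
discrete_chain_oracle <- function(model, a, b, t, N) {
  stopifnot(N >= 10, t >= 0)
  ia <- base_index(a); ib <- base_index(b)
  if (t * max(abs(model$RD)) / N >= 1)
    stop("Q has negative entries; increase N")
  Q <- diag(4) + t * model$R / N
  qa <- Q[ia, ia]
  # w[m + 1] = [Q^m]_{ab}, m = 0..N
  w <- numeric(N + 1)
  v <- numeric(4); v[ib] <- 1
  w[1] <- v[ia]
  for (m in seq_len(N)) {
    v <- Q %*% v
    w[m + 1] <- v[ia]
  }
  ZN <- w[N + 1]
  if (ZN <= 0) stop_numerical("unreachable endpoint pair in discrete chain")
  l <- seq_len(N)
  surv <- exp(l * log(qa)) * w[N - l + 1]  # P(L >= l) * ZN
  list(tmrs = (t / N) * sum(surv) / ZN,
       second_moment = (t / N)^2 * sum((2 * l - 1) * surv) / ZN,
       q = if (ia == ib) exp(N * log(qa)) / ZN else 0)
}

#' Monte-Carlo simulation of substitution histories on a single branch
#'
#' Vectorized competing-rates (Gillespie) simulation of `n` histories of
#' duration `t` started in base `b`.  Used as an independent stochastic
#' oracle: conditioning on the end state reproduces the closed-form
#' estimators within Monte-Carlo error.
#'
#' @inheritParams tmrs_edge
#' @param n Number of histories.
#' @return A list with integer `end` (final base 1..4), numeric `T`
#'   (time from the recent end back to the last substitution; `t` if none)
#'   and logical `no_sub`.
#' @export
gillespie_histories <- function(model, b, t, n) {
  ib <- base_index(b)
  state <- rep.int(ib, n)
  elapsed <- numeric(n)
  last_event <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  R <- model$R
  jump_prob <- lapply(1:4, function(s) {
    p <- R[, s]; p[s] <- 0
    tot <- sum(p)
    if (tot > 0) p / tot else p
  })
  while (any(active)) {
    idx <- which(active)
    rate <- -model$RD[state[idx]]
    wait <- ifelse(rate > 0, stats::rexp(length(idx), rate = pmax(rate, 1e-300)), Inf)
    tnew <- elapsed[idx] + wait
    done <- tnew >= t
    active[idx[done]] <- FALSE
    move <- idx[!done]
    if (length(move)) {
      elapsed[move] <- tnew[!done]
      last_event[move] <- elapsed[move]
      old <- state[move]
      for (s in 1:4) {
        grp <- move[old == s]
        if (length(grp))
          state[grp] <- sample.int(4, length(grp), replace = TRUE, prob = jump_prob[[s]])
      }
    }
  }
  no_sub <- is.na(last_event)
  list(end = state, T = ifelse(no_sub, t, t - last_event), no_sub = no_sub)
}
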