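BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

base_index <- function(a) {
  if (is.character(a)) {
    i <- match(toupper(a), BASES)
    if (anyNA(i)) stop("unknown nucleotide: ", paste(a[is.na(i)], collapse = ","))
    i
  } else {
    a <- as.integer(a)
    if (any(a < 1L | a > 4L)) stop("base index out of range 1..4")
    a
  }
}

#' Substitution rate models
#'
#' A `rate_model` bundles a 4x4 instantaneous rate matrix `R` (entry
#' `R[a, i]` is the rate of the substitution `i -> a`, so columns are indexed
#' by the source state and sum to zero), its diagonal `R_D`, the
#' eigendecomposition `R = U diag(lambda) U^-1` (kept in complex arithmetic:
#' the strand-symmetric matrix is in general non-reversible and may have
#' complex eigenpairs), and the equilibrium distribution `pi` over A,C,G,T.
#'
#' @param alpha,beta,gamma,delta,epsilon,eta Non-negative substitution rates.
#'   `alpha` is the rate of A<-C (and its complement T<-G), `beta` A<-G,
#'   `gamma` A<-T, `delta` C<-G, `epsilon` C<-T, `eta` C<-A; the remaining
#'   entries are fixed by strand symmetry `R[comp(a), comp(b)] = R[a, b]`.
#' @param normalize If `TRUE`, rescale so the expected substitution rate at
#'   equilibrium is 1 (time then reads in substitutions per site).
#' @return An object of class `rate_model`.
#' @examples
#' m <- build_strand_symmetric(0.16, 0.57, 0.20, 0.24, 0.59, 0.25)
#' round(m$pi, 2)
#' @export
build_strand_symmetric <- function(alpha, beta, gamma, delta, epsilon, eta,
                                   normalize = FALSE) {
  rates <- stats::setNames(as.numeric(c(alpha, beta, gamma, delta, epsilon, eta)),
                           c("alpha", "beta", "gamma", "delta", "epsilon", "eta"))
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  if (all(rates == 0)) stop("degenerate model: all rates are zero")
  R <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  R["A", ] <- c(0, rates[["alpha"]], rates[["beta"]], rates[["gamma"]])
  R["C", ] <- c(rates[["eta"]], 0, rates[["delta"]], rates[["epsilon"]])
  R["G", ] <- c(rates[["epsilon"]], rates[["delta"]], 0, rates[["eta"]])
  R["T", ] <- c(rates[["gamma"]], rates[["beta"]], rates[["alpha"]], 0)
  diag(R) <- -colSums(R)
  m <- finish_model(R, type = "symmetric", params = rates)
  if (normalize) normalize_model(m) else m
}

#' General time reversible model
#'
#' Builds a GTR rate matrix with `R[a, b] = pi_a * x(a, b)` for symmetric
#' exchangeabilities `x`; detailed balance `R[a,b] pi_b = R[b,a] pi_a` holds
#' by construction and `pi` is the stationary distribution.
#'
#' @param rates Six exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#' @param pi Base frequencies over A,C,G,T; must be positive and sum to 1.
#' @inheritParams build_strand_symmetric
#' @export
build_gtr <- function(rates, pi, normalize = FALSE) {
  if (length(rates) != 6 || any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be six finite non-negative exchangeabilities")
  if (length(pi) != 4 || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be four positive frequencies summing to 1")
  pi <- as.numeric(pi) / sum(pi)
  X <- matrix(0, 4, 4)
  X[1, 2] <- X[2, 1] <- rates[1]  # A-C
  X[1, 3] <- X[3, 1] <- rates[2]  # A-G
  X[1, 4] <- X[4, 1] <- rates[3]  # A-T
  X[2, 3] <- X[3, 2] <- rates[4]  # C-G
  X[2, 4] <- X[4, 2] <- rates[5]  # C-T
  X[3, 4] <- X[4, 3] <- rates[6]  # G-T
  R <- pi * X  # R[a, b] = pi_a * x_ab
  dimnames(R) <- list(BASES, BASES)
  diag(R) <- -colSums(R)
  names(rates) <- c("ac", "ag", "at", "cg", "ct", "gt")
  m <- finish_model(R, type = "gtr", params = rates, pi = pi)
  if (normalize) normalize_model(m) else m
}

finish_model <- function(R, type, params, pi = NULL) {
  es <- eigen(R)
  U <- es$vectors
  lambda <- es$values
  Uinv <- solve(U)
  err <- max(abs(U %*% diag(lambda) %*% Uinv - R))
  if (err > 1e-6 * max(1, max(abs(R))))
    stop("eigendecomposition reconstruction error ", err)
  if (is.null(pi)) {
    i0 <- which.min(abs(lambda))
    pi <- Re(U[, i0])
    pi <- pi / sum(pi)
    if (any(pi < -1e-12)) stop("negative stationary probabilities")
    pi <- pmax(pi, 0); pi <- pi / sum(pi)
  }
  names(pi) <- BASES
  m <- structure(list(type = type, params = params, R = R,
                      RD = unname(diag(R)), U = U, lambda = lambda, Uinv = Uinv,
                      pi = pi, rate = -sum(pi * diag(R))),
                 class = "rate_model")
  m
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model: %s, expected rate %.4f>\n", x$type, x$rate))
  print(round(x$R, 4))
  cat("pi:", paste(sprintf("%s=%.4f", BASES, x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Transition probability matrix exp(tR)
#'
#' @param model A `rate_model`.
#' @param t Elapsed time (>= 0), substitutions per site.
#' @return A 4x4 column-stochastic matrix; `P[a, b]` is the probability of
#'   observing `a` at time `t` given `b` at time 0.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(t >= 0)
  Pc <- model$U %*% (exp(t * model$lambda) * model$Uinv)
  P <- Re(Pc)
  if (max(abs(Im(Pc))) > 1e-9 * max(1, max(abs(P))))
    stop_numerical("non-negligible imaginary part in transition matrix")
  neg <- min(P)
  if (neg < -1e-9) stop_numerical("transition matrix entry below -1e-9: ", neg)
  P[P < 0] <- 0
  P <- sweep(P, 2, colSums(P), "/")
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Probability of no substitution over time t starting (and staying) in base a
#' @inheritParams transition_matrix
#' @param a Base (character or index 1..4).
#' @export
no_substitution_prob <- function(model, a, t) {
  stopifnot(all(t >= 0))
  unname(exp(t * model$RD[base_index(a)]))
}

#' Integral kernel K(x, y) = int_0^1 exp(s x) exp((1-s) y) ds
#'
#' Equals `(e^x - e^y)/(x - y)` for `x != y` and `e^x` at `x = y`; evaluated
#' through the midpoint form `e^((x+y)/2) sinh(d/2)/(d/2)` with a series
#' branch for `|d| < 1e-8` to control cancellation.  Accepts complex input.
#' @param x,y Finite scalars or vectors (recycled).
#' @export
kernel_K <- function(x, y) {
  m <- (x + y) / 2
  u <- (x - y) / 2
  small <- abs(u) < 1e-8
  big <- abs(u) >= 30  # sinh overflows long before the true value does
  us <- u; us[small | big] <- 1
  out <- exp(m) * sinh(us) / us
  out[small] <- (exp(m) * (1 + u * u / 6))[small]
  out[big] <- ((exp(x) - exp(y)) / (x - y))[big]
  out
}

#' Partial derivative of `kernel_K` with respect to x
#'
#' Equals `int_0^1 s exp(s x) exp((1-s) y) ds`; `kernel_K_prime(x, x)` is
#' `e^x / 2`.
#' @inheritParams kernel_K
#' @export
kernel_K_prime <- function(x, y) {
  m <- (x + y) / 2
  u <- (x - y) / 2
  small <- abs(u) < 1e-6
  big <- abs(u) >= 30
  us <- u; us[small | big] <- 1
  h <- sinh(us) / us
  # d/du [sinh(u)/u] = (u cosh(u) - sinh(u)) / u^2 ~ u/3 + u^3/30
  hp <- (us * cosh(us) - sinh(us)) / (us * us)
  out <- exp(m) * (h + hp) / 2
  out[small] <- (exp(m) * ((1 + u * u / 6) + (u / 3 + u^3 / 30)) / 2)[small]
  d <- x - y; d[!big] <- 1
  out[big] <- ((exp(x) * (d - 1) + exp(y)) / (d * d))[big]
  out
}

#' Transition/transversion rate ratio of a strand-symmetric model
#'
#' Unweighted mean of the two transition rates (A<-G and C<-T) over the
#' unweighted mean of the four transversion rates.
#' @inheritParams transition_matrix
#' @export
titv_ratio <- function(model) {
  if (model$type != "symmetric") stop("titv_ratio is defined for the strand-symmetric model")
  p <- model$params
  mean(p[c("beta", "epsilon")]) / mean(p[c("alpha", "gamma", "delta", "eta")])
}

#' Rescale a model so the expected substitution rate at equilibrium is 1
#' @inheritParams transition_matrix
#' @export
normalize_model <- function(model) {
  s <- model$rate
  if (s <= 0) stop("cannot normalize a rate-0 model")
  if (model$type == "symmetric") {
    p <- model$params / s
    build_strand_symmetric(p["alpha"], p["beta"], p["gamma"],
                           p["delta"], p["epsilon"], p["eta"])
  } else {
    build_gtr(model$params / s, model$pi)
  }
}

#' Read / write a rate model as plain-text key=value lines
#'
#' @param path File path.
#' @return `read_model` returns a `rate_model`.
#' @export
read_model <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !grepl("^\\s*#", ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  named <- stats::setNames(vals, keys)
  type <- if ("model" %in% keys) named[["model"]] else "symmetric"
  num <- function(k) as.numeric(named[[k]])
  normalize <- isTRUE(tolower(named["normalized"]) %in% c("true", "1", "yes"))
  if (type == "symmetric") {
    build_strand_symmetric(num("alpha"), num("beta"), num("gamma"),
                           num("delta"), num("epsilon"), num("eta"),
                           normalize = normalize)
  } else if (type == "gtr") {
    build_gtr(vapply(c("ac", "ag", "at", "cg", "ct", "gt"), num, 0),
              vapply(c("pi_a", "pi_c", "pi_g", "pi_t"), num, 0),
              normalize = normalize)
  } else stop("unknown model type: ", type)
}

#' @rdname read_model
#' @inheritParams transition_matrix
#' @export
write_model <- function(model, path) {
  ln <- c(paste0("model=", model$type),
          sprintf("%s=%.17g", names(model$params), model$params))
  if (model$type == "gtr")
    ln <- c(ln, sprintf("pi_%s=%.17g", tolower(BASES), model$pi))
  writeLines(ln, path)
  invisible(path)
}

#' Default strand-symmetric model
#'
#' Loads the packaged six-rate parameter set estimated from fourfold
#' degenerate sites of human-referenced vertebrate alignments
#' (alpha=0.16, beta=0.57, gamma=0.20, delta=0.24, epsilon=0.59, eta=0.25).
#' @inheritParams build_strand_symmetric
#' @export
default_model <- function(normalize = FALSE) {
  m <- read_model(system.file("extdata", "params_symmetric_default.txt",
                              package = "mrsub", mustWork = TRUE))
  if (normalize) normalize_model(m) else m
}
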