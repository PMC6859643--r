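test_that("extract_lineage orders concestors, siblings and fractions", {
  tr <- read_newick(text = "(A:0.3,B:0.5);")
  lin <- extract_lineage(tr, "A")
  expect_equal(lin$M, 1)
  expect_equal(lin$tbar, 0.3)
  expect_equal(lin$s, c(0, 1))
  expect_equal(tr$tip_labels[lin$b], "B")
  tr6 <- tree6()
  lin6 <- extract_lineage(tr6, "hum")
  expect_equal(lin6$M, 3)
  expect_equal(lin6$t_edge, c(0.1, 0.15, 0.2))
  expect_equal(lin6$time, cumsum(c(0, 0.1, 0.15, 0.2)))
  expect_equal(lin6$s * lin6$tbar, lin6$time)
  # siblings: cherry mate, then the other cherry's root, then gal
  expect_equal(tr6$tip_labels[lin6$b[1]], "chp")
  expect_equal(tr6$tip_labels[lin6$b[3]], "gal")
  expect_error(extract_lineage(tr6, "dog"), "unknown")
})

test_that("trees violating the contract are rejected", {
  expect_error(read_newick(text = "(A:0.1,B:0.2,C:0.3);"), "rooted|binary")
  expect_error(read_newick(text = "(A,B);"), "branch length")
})

test_that("inside algorithm matches brute-force enumeration and collapses missing data", {
  m <- table2_model()
  tr <- tree5()
  set.seed(31)
  for (rep in 1:6) {
    column <- stats::setNames(sample(c("A", "C", "G", "T", "-"), 4, replace = TRUE),
                              tr$tip_labels)
    column["hum"] <- sample(c("A", "C", "G", "T"), 1)
    cols <- matrix(column, 4, 1, dimnames = list(names(column), NULL))
    Z <- inside_fill(tr, m, cols)$Z
    expect_equal(Z, brute_force_Z(tr, m, column), tolerance = 1e-12)
  }
  # all leaves missing except target: Z = pi_a
  colA <- col_on(tr, hum = "G", chp = "-", mus = "N", gal = "-")
  expect_equal(inside_fill(tr, m, colA)$Z, unname(m$pi["G"]), tolerance = 1e-14)
  # single observed leaf inside vector is an indicator
  ins <- inside_fill(tr, m, colA)
  expect_equal(as.numeric(ins$alpha[[match("hum", tr$tip_labels)]]), c(0, 0, 1, 0))
})

test_that("likelihoods over all possible columns sum to one", {
  m <- table2_model()
  tr <- tree5()
  combs <- expand.grid(rep(list(c("A", "C", "G", "T")), 4), stringsAsFactors = FALSE)
  cols <- t(as.matrix(combs))
  rownames(cols) <- tr$tip_labels
  expect_equal(sum(inside_fill(tr, m, cols)$Z), 1, tolerance = 1e-12)
})

test_that("outside table satisfies the node-marginal identity and posteriors normalize", {
  m <- table2_model()
  tr <- tree6()
  cols <- col_on(tr, hum = "A", chp = "C", mus = "G", rat = "-", gal = "T")
  ins <- inside_fill(tr, m, cols)
  beta <- outside_fill(tr, m, cols, ins)
  for (n in which(!is.na(tr$parent))) {
    cons <- colSums(beta[[n]] * crossprod(ins$P[[n]], ins$alpha[[n]]))
    expect_equal(as.numeric(cons), ins$Z, tolerance = 1e-12)
  }
  post <- node_posteriors(tr, m, cols)
  for (n in seq_len(tr$nnode)) expect_equal(as.numeric(colSums(post[[n]])), 1)
  # brute-force check of an internal-node posterior
  column <- cols[, 1]
  marg <- brute_force_node_marginal(tr, m, column, tr$root)
  expect_equal(as.numeric(post[[tr$root]]), marg / sum(marg), tolerance = 1e-12)
})

test_that("no-substitution prefix matches brute-force path-pinned enumeration", {
  m <- table2_model()
  tr <- tree5()
  lin <- extract_lineage(tr, "hum")
  column <- c(hum = "A", chp = "C", mus = "A", gal = "G")
  cols <- matrix(column, 4, 1, dimnames = list(names(column), NULL))
  D <- inside_no_sub(tr, m, cols, lin)
  expect_equal(D[1, 1], 1)
  for (k in 1:lin$M)
    expect_equal(D[k + 1, 1], brute_force_alphaD(tr, m, column, lin, k),
                 tolerance = 1e-12)
  # zero-length lineage edges leave only the sibling emissions
  tr0 <- read_newick(text = "((hum:0.0,chp:0.12):0.0,gal:0.6);")
  lin0 <- extract_lineage(tr0, "hum")
  cols0 <- col_on(tr0, hum = "A", chp = "C", gal = "G")
  D0 <- inside_no_sub(tr0, m, cols0, lin0)
  ins0 <- inside_fill(tr0, m, cols0)
  g1 <- crossprod(ins0$P[[lin0$b[1]]], ins0$alpha[[lin0$b[1]]])[1, 1]
  expect_equal(D0[2, 1], unname(g1), tolerance = 1e-14)
})

test_that("kappa matches numeric quadrature of the propagator integral", {
  m <- table2_model()
  tr <- tree6()
  lin <- extract_lineage(tr, "hum")
  for (k in c(1, 3)) {
    tk <- lin$t_edge[k]
    for (a in c(1, 3)) {
      row <- kappa_edge(m, lin, k, a)
      for (j in 1:4) {
        f <- function(u) vapply(u, function(ui) {
          exp(ui * m$RD[a]) * transition_matrix(m, tk - ui)[a, j]
        }, 0)
        quad <- stats::integrate(f, 0, tk, rel.tol = 1e-10)$value
        expect_equal(row[j], quad, tolerance = 1e-8)
      }
    }
  }
  # zero-length edge gives a zero row
  tr0 <- read_newick(text = "((hum:0.0,chp:0.12):0.3,gal:0.6);")
  lin0 <- extract_lineage(tr0, "hum")
  expect_equal(kappa_edge(m, lin0, 1, 2), rep(0, 4))
})

test_that("a two-leaf tree reduces to the single-edge estimators mixed over the root prior", {
  m <- table2_model()
  tr <- read_newick(text = "(hum:0.4,chp:0.3);")
  cols <- col_on(tr, hum = "A", chp = "C")
  est <- estimate_columns(tr, m, cols, "hum")
  P1 <- transition_matrix(m, 0.4); P2 <- transition_matrix(m, 0.3)
  num1 <- num2 <- Z <- 0
  for (b in 1:4) {
    w <- P1[1, b] * P2[2, b] * m$pi[b]
    Z <- Z + w
    num1 <- num1 + tmrs_edge(m, 1, b, 0.4) * w
    num2 <- num2 + second_moment_edge(m, 1, b, 0.4) * w
  }
  expect_equal(est$tmrs, unname(num1 / Z), tolerance = 1e-12)
  expect_equal(est$sigma, unname(sqrt(num2 / Z - (num1 / Z)^2)), tolerance = 1e-10)
  expect_equal(est$q, unname(exp(0.4 * m$RD[1]) * P2[2, 1] * m$pi[1] / Z), tolerance = 1e-12)
  expect_equal(est$logZ, unname(log(Z)), tolerance = 1e-12)
})

test_that("columns with only the target observed collapse to the prior-mixed single edge", {
  m <- table2_model()
  tr <- tree6()
  cols <- col_on(tr, hum = "A", chp = "-", mus = "-", rat = "-", gal = "-")
  est <- estimate_columns(tr, m, cols, "hum")
  tbar <- extract_lineage(tr, "hum")$tbar
  P <- transition_matrix(m, tbar)
  num1 <- num2 <- Z <- 0
  for (b in 1:4) {
    w <- P[1, b] * m$pi[b]
    Z <- Z + w
    num1 <- num1 + tmrs_edge(m, 1, b, tbar) * w
    num2 <- num2 + second_moment_edge(m, 1, b, tbar) * w
  }
  expect_equal(est$tmrs, unname(num1 / Z), tolerance = 1e-12)
  expect_equal(est$sigma, unname(sqrt(num2 / Z - (num1 / Z)^2)), tolerance = 1e-10)
  expect_equal(est$q, unname(exp(tbar * m$RD[1]) * m$pi[1] / Z), tolerance = 1e-12)
})

test_that("missing-data pruning invariance holds exactly", {
  m <- table2_model()
  tr <- tree6()
  # rat missing: its parent edge merges with mus's edge
  trA <- read_newick(text = "(((hum:0.1,chp:0.12):0.15,mus:0.43):0.2,gal:0.6);")
  # mus and rat missing: whole cherry pruned, edges merge
  trB <- read_newick(text = "((hum:0.1,chp:0.12):0.35,gal:0.6);")
  for (base in c("A", "C", "G", "T")) {
    cA_full <- col_on(tr, hum = base, chp = "C", mus = "T", rat = "-", gal = "G")
    cA_red <- col_on(trA, hum = base, chp = "C", mus = "T", gal = "G")
    eA1 <- estimate_columns(tr, m, cA_full, "hum")
    eA2 <- estimate_columns(trA, m, cA_red, "hum")
    for (f in c("tmrs", "sigma", "q", "logZ"))
      expect_equal(eA1[[f]], eA2[[f]], tolerance = 1e-12)
    cB_full <- col_on(tr, hum = base, chp = "C", mus = "-", rat = "N", gal = "G")
    cB_red <- col_on(trB, hum = base, chp = "C", gal = "G")
    eB1 <- estimate_columns(tr, m, cB_full, "hum")
    eB2 <- estimate_columns(trB, m, cB_red, "hum")
    for (f in c("tmrs", "sigma", "q", "logZ"))
      expect_equal(eB1[[f]], eB2[[f]], tolerance = 1e-12)
  }
})

test_that("estimates are invariant under complementing the column", {
  m <- table2_model()
  tr <- tree6()
  set.seed(32)
  for (rep in 1:5) {
    column <- stats::setNames(sample(c("A", "C", "G", "T", "-"), 5, replace = TRUE),
                              tr$tip_labels)
    column["hum"] <- sample(c("A", "C", "G", "T"), 1)
    cols <- matrix(column, 5, 1, dimnames = list(names(column), NULL))
    e1 <- estimate_columns(tr, m, cols, "hum")
    e2 <- estimate_columns(tr, m, complement_cols(cols), "hum")
    for (f in c("tmrs", "sigma", "q", "logZ"))
      expect_equal(e1[[f]], e2[[f]], tolerance = 1e-10)
  }
})

test_that("estimates stay in range and respond to evidence of recent substitution", {
  m <- table2_model()
  tr <- tree6()
  lin <- extract_lineage(tr, "hum")
  ladder <- list(
    c(hum = "A", chp = "A", mus = "A", rat = "A", gal = "A"),  # conserved
    c(hum = "A", chp = "A", mus = "A", rat = "A", gal = "C"),  # deep difference
    c(hum = "A", chp = "A", mus = "C", rat = "C", gal = "C"),  # middle
    c(hum = "A", chp = "C", mus = "C", rat = "C", gal = "C"))  # recent
  est <- lapply(ladder, function(cc)
    estimate_columns(tr, m, matrix(cc, 5, 1, dimnames = list(names(cc), NULL)), "hum"))
  tm <- vapply(est, function(e) e$tmrs, 0)
  qv <- vapply(est, function(e) e$q, 0)
  expect_true(all(tm >= 0 & tm <= lin$tbar))
  expect_true(all(qv >= 0 & qv <= 1))
  expect_true(all(diff(tm) < 0))
  expect_true(all(diff(qv) < 0))
  # skipped targets are flagged, not scored
  sk <- estimate_columns(tr, m, col_on(tr, hum = "-", chp = "A", mus = "A",
                                       rat = "A", gal = "A"), "hum")
  expect_true(sk$skipped)
  expect_true(is.na(sk$tmrs))
})

test_that("ancestral reconstruction matches brute-force posterior argmax", {
  m <- table2_model()
  tr <- tree5()
  lin <- extract_lineage(tr, "hum")
  set.seed(33)
  for (rep in 1:5) {
    column <- stats::setNames(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                              tr$tip_labels)
    cols <- matrix(column, 4, 1, dimnames = list(names(column), NULL))
    rec <- reconstruct_ancestors(tr, m, cols, "hum")
    for (k in 1:lin$M) {
      marg <- brute_force_node_marginal(tr, m, column, lin$c[k + 1])
      expect_equal(unname(rec[k, 1]), c("A", "C", "G", "T")[which.max(marg)])
    }
  }
  # all leaves identical: every concestor reconstructed to that base
  cols <- col_on(tr, hum = "G", chp = "G", mus = "G", gal = "G")
  expect_true(all(reconstruct_ancestors(tr, m, cols, "hum") == "G"))
})

test_that("tree q agrees with the posterior mass of substitution-free histories", {
  m <- normalize_model(table2_model())
  tr <- tree5()
  column <- c(hum = "A", chp = "A", mus = "A", gal = "A")
  cols <- matrix(column, 4, 1, dimnames = list(names(column), NULL))
  ex <- estimate_columns(tr, m, cols, "hum")
  set.seed(34)
  ps <- posterior_sample_histories(tr, m, column, "hum", 2e4, 600)
  se <- sqrt(ex$q * (1 - ex$q) / 2e4)
  expect_lt(abs(ps$q_hat - ex$q), 4 * se + 0.01)
})
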