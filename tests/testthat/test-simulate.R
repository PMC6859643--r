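test_that("forward simulation respects degenerate and ergodic limits", {
  m <- table2_model()
  tr0 <- read_newick(text = "((hum:0.0,chp:0.0):0.0,gal:0.0);")
  sim0 <- forward_simulate(tr0, m, 200, "hum", seed = 51)
  expect_true(all(apply(sim0$cols, 2, function(x) length(unique(x)) == 1)))
  expect_true(all(sim0$true_q == 1))
  # long branch: leaf base frequency approaches pi
  trL <- read_newick(text = "(hum:8,chp:8);")
  simL <- forward_simulate(trL, m, 4000, "hum", seed = 52)
  f <- tabulate(match(simL$cols["chp", ], c("A", "C", "G", "T")), 4) / 4000
  for (a in 1:4)
    expect_lt(abs(f[a] - m$pi[a]), 3 * sqrt(m$pi[a] * (1 - m$pi[a]) / 4000) + 0.005)
  # reproducible by seed
  s1 <- forward_simulate(tr0, m, 50, "hum", seed = 53)
  s2 <- forward_simulate(tr0, m, 50, "hum", seed = 53)
  expect_identical(s1$cols, s2$cols)
  expect_identical(s1$true_T, s2$true_T)
})

test_that("recorded histories are consistent with endpoint states and truth", {
  m <- table2_model()
  tr <- tree5()
  sim <- forward_simulate(tr, m, 60, "hum", seed = 54, keep_history = TRUE)
  lin <- sim$lineage
  states_root <- NULL
  for (i in 1:60) {
    # walk down the lineage replaying events; final state must equal the leaf
    for (k in seq(lin$M, 1)) {
      child <- lin$c[k]
      ev <- sim$history[[child]][[i]]
      if (!is.null(ev)) {
        expect_true(all(ev$time >= 0 & ev$time <= tr$edge_len[child]))
      }
    }
    # truth bounds
    expect_gt(sim$true_T[i], 0)
    expect_lte(sim$true_T[i], lin$tbar)
    if (sim$true_q[i] == 1) expect_equal(sim$true_T[i], lin$tbar)
  }
  # true_T agrees with the lineage event lists
  for (i in 1:60) {
    d <- Inf
    for (k in seq_len(lin$M)) {
      child <- lin$c[k]
      ev <- sim$history[[child]][[i]]
      if (!is.null(ev))
        d <- min(d, lin$time[k] + tr$edge_len[child] - max(ev$time))
    }
    expect_equal(sim$true_T[i], if (is.finite(d)) d else lin$tbar, tolerance = 1e-12)
  }
})

test_that("simulated no-substitution frequency matches exact q per column pattern", {
  m <- normalize_model(table2_model())
  tr <- tree5()
  sim <- forward_simulate(tr, m, 20000, "hum", seed = 55)
  est <- estimate_columns(tr, m, sim$cols, "hum")
  key <- apply(sim$cols, 2, paste, collapse = "")
  for (kk in names(sort(table(key), decreasing = TRUE)[1:5])) {
    sel <- key == kk
    n <- sum(sel)
    phat <- mean(sim$true_q[sel])
    qex <- est$q[sel][1]
    expect_lt(abs(phat - qex), 3 * sqrt(max(qex * (1 - qex), 1e-4) / n))
  }
})

test_that("gap masking copies the template pattern and spares the target", {
  m <- table2_model()
  tr <- tree5()
  sim <- forward_simulate(tr, m, 300, "hum", seed = 56)
  # empty mask is the identity
  tmpl0 <- matrix("A", 4, 300, dimnames = list(tr$tip_labels, NULL))
  expect_identical(apply_gap_mask(sim$cols, tmpl0, "hum"), sim$cols)
  # fully masked non-target rows
  tmpl1 <- tmpl0; tmpl1[c("chp", "mus", "gal"), ] <- "-"
  masked <- apply_gap_mask(sim$cols, tmpl1, "hum")
  expect_true(all(masked[c("chp", "mus", "gal"), ] == "-"))
  expect_identical(masked["hum", ], sim$cols["hum", ])
  # mask frequency is preserved per species for same-width templates
  set.seed(57)
  tmpl <- synthetic_gap_template(tr, "hum", 300)
  masked2 <- apply_gap_mask(sim$cols, tmpl, "hum")
  for (sp in c("chp", "mus", "gal"))
    expect_equal(mean(masked2[sp, ] == "-"), mean(tmpl[sp, ] == "-"), tolerance = 1e-12)
  expect_error(apply_gap_mask(sim$cols, tmpl[1:2, ], "hum"), "missing species")
})

test_that("fully masked non-target rows reproduce the prior-collapsed estimate", {
  m <- table2_model()
  tr <- tree5()
  sim <- forward_simulate(tr, m, 5, "hum", seed = 58)
  tmpl <- matrix("-", 4, 5, dimnames = list(tr$tip_labels, NULL))
  masked <- apply_gap_mask(sim$cols, tmpl, "hum")
  est <- estimate_columns(tr, m, masked, "hum")
  onlyT <- masked; onlyT[setdiff(rownames(onlyT), "hum"), ] <- "-"
  est2 <- estimate_columns(tr, m, onlyT, "hum")
  expect_equal(est$tmrs, est2$tmrs, tolerance = 1e-12)
})

test_that("posterior sampling reproduces exact values and is seed-stable", {
  m <- normalize_model(table2_model())
  tr <- tree5()
  column <- c(hum = "A", chp = "C", mus = "A", gal = "G")
  ex <- estimate_site(tr, m, column, "hum")
  ps <- posterior_sample_histories(tr, m, column, "hum", 2e4, 500, seed = 59)
  expect_lt(abs(ps$tmrs_hat - ex$tmrs) / ex$tmrs, 0.03)
  expect_lt(abs(ps$sigma_hat - ex$sigma) / ex$sigma, 0.05)
  expect_lt(abs(ps$q_hat - ex$q), 0.02)
  ps2 <- posterior_sample_histories(tr, m, column, "hum", 2e4, 500, seed = 59)
  expect_identical(ps$T, ps2$T)
})

test_that("baseline estimators follow their decision rules", {
  m <- table2_model()
  tr <- tree6()
  lin <- extract_lineage(tr, "hum")
  # all concestors/leaves agree with target: q = 1
  consA <- col_on(tr, hum = "A", chp = "A", mus = "A", rat = "A", gal = "A")
  br <- baseline_reconstruction(tr, m, consA, "hum")
  ba <- baseline_alignment(tr, consA, "hum")
  expect_equal(br$q_est, 1); expect_equal(ba$q_est, 1)
  # sister leaf differs: alignment midpoint of first edge
  sis <- col_on(tr, hum = "A", chp = "C", mus = "A", rat = "A", gal = "A")
  ba2 <- baseline_alignment(tr, sis, "hum")
  expect_equal(ba2$q_est, 0)
  expect_equal(ba2$t_est, (lin$time[1] + lin$time[2]) / 2)
  # gap-heavy column: only observed leaves matter
  gap <- col_on(tr, hum = "A", chp = "-", mus = "C", rat = "-", gal = "-")
  ba3 <- baseline_alignment(tr, gap, "hum")
  expect_equal(ba3$t_est, (lin$time[2] + lin$time[3]) / 2)
  # reconstruction difference first at c_1 gives the first-edge midpoint
  rec <- col_on(tr, hum = "A", chp = "C", mus = "C", rat = "C", gal = "C")
  br2 <- baseline_reconstruction(tr, m, rec, "hum")
  expect_equal(br2$q_est, 0)
  expect_equal(br2$t_est, (lin$time[1] + lin$time[2]) / 2)
})

test_that("column entropy and pairwise identity follow their definitions", {
  cols <- cbind(c("A", "A", "A", "A"), c("A", "C", "G", "T"),
                c("A", "A", "C", "C"), c("A", "-", "N", "C"),
                c("-", "-", "-", "-"), c("A", "-", "-", "-"))
  rownames(cols) <- paste0("s", 1:4)
  ent <- column_entropy(cols)
  pid <- pairwise_identity(cols)
  expect_equal(ent[1], 0)
  expect_equal(pid[1], 1)
  expect_equal(ent[2], log(4))
  expect_equal(pid[2], 0)
  expect_equal(ent[3], log(2))
  expect_equal(pid[3], 2 / 6)
  expect_equal(pid[4], 0)        # A vs C
  expect_true(is.na(ent[5]))
  expect_true(is.na(pid[6]))
  expect_equal(ent[6], 0)
})

test_that("evaluation harness scores a perfect oracle with zero FDR", {
  true_q <- c(1, 1, 0, 0, 0)
  true_T <- c(1, 1, 0.2, 0.5, 0.9)
  est <- data.frame(tmrs = true_T, q = true_q, skipped = FALSE)
  ev <- evaluate_filtering(est, true_T, true_q, tbar = 1, q_grid = c(0.5, 1))
  expect_equal(ev$fdr_no_mutation[1], 0)
  expect_equal(ev$pct_error[1], 0)
  expect_equal(ev$positive_fraction[1], 0.6)
  all_conserved <- data.frame(tmrs = 1, q = 1, skipped = FALSE)
  expect_warning(evaluate_filtering(all_conserved, 1, 1, 1, q_grid = 0.5),
                 "no positives")
})
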