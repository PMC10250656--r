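test_that("null model recovers closed-form fits and detects degeneracies", {
  y <- rep(c(1, 0), each = 10)
  null <- fit_null(y)
  expect_equal(unname(null$mu), rep(0.5, 20))
  y2 <- c(rep(1, 6), rep(0, 14))
  expect_equal(unname(fit_null(y2)$mu), rep(0.3, 20))
  set.seed(1)
  X <- cbind(rnorm(100), rbinom(100, 1, 0.5))
  y3 <- rbinom(100, 1, 0.5)
  n3 <- fit_null(y3, X)
  expect_lt(abs(sum(n3$residuals)), 1e-6)
  expect_true(all(n3$mu > 0 & n3$mu < 1))
  # a perfect predictor triggers the separation error
  expect_error(fit_null(y3, cbind(X, y3)), "separation|converge")
  expect_error(fit_null(rep(1, 10)), "single class")
  # missing covariates are dropped with a message
  X[1, 1] <- NA
  expect_message(n4 <- fit_null(y3, X), "dropped")
  expect_equal(length(n4$mu), 99L)
})

test_that("score statistic obeys its algebraic identities", {
  null <- fit_null(c(1, 1, 0, 0))  # residuals +/- 0.5
  G <- cbind(c(2, 2, 0, 0), c(0, 0, 2, 2))  # scores S = (2, -2)
  w <- c(1, 1)
  expect_equal(score_statistic(G, null, w, rho = 0), 8)
  expect_equal(score_statistic(G, null, w, rho = 1), 0)
  expect_equal(score_statistic(G, null, w, rho = 0.3), 0.7 * 8)
  # single variant: Q(rho) = w^2 S^2 for every rho
  for (rho in c(0, 0.25, 1)) {
    expect_equal(score_statistic(G[, 1, drop = FALSE], null, 2, rho),
                 4 * 2^2)
  }
  # zero variants: untested, not p = 1
  expect_true(is.na(score_statistic(G[, 0, drop = FALSE], null)))
})

test_that("quadratic-form tail probabilities match chi-square analytics", {
  expect_equal(pvalue_quadform(3.841, 1), 0.05, tolerance = 1e-3)
  expect_equal(pvalue_quadform(5.991, c(1, 1)), 0.05, tolerance = 1e-3)
  expect_equal(pvalue_quadform(qchisq(0.99, 3), c(1, 1, 1)), 0.01,
               tolerance = 1e-6)
  expect_equal(pvalue_quadform(2 * qchisq(0.95, 2), c(2, 2)), 0.05,
               tolerance = 1e-6)
  expect_equal(pvalue_quadform(0, c(1, 2)), 1)
  expect_true(is.na(pvalue_quadform(5, numeric(0))))
})

test_that("quadratic-form tail matches a Monte-Carlo oracle", {
  set.seed(17)
  for (rep in 1:3) {
    lambda <- runif(sample(2:6, 1), 0.2, 3)
    Q <- sum(lambda) * runif(1, 0.8, 2.5)
    draws <- colSums(lambda * matrix(rchisq(length(lambda) * 2e5, df = 1),
                                     nrow = length(lambda)))
    mc <- mean(draws > Q)
    se <- sqrt(mc * (1 - mc) / 2e5)
    expect_lt(abs(pvalue_quadform(Q, lambda) - mc), 3 * se + 1e-12)
  }
})

test_that("SKAT-O reduces to SKAT and burden at the grid endpoints", {
  set.seed(3)
  n <- 300
  G <- simulate_dosages(n, runif(6, 0.02, 0.1))
  y <- rbinom(n, 1, 0.4)
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  null <- fit_null(y, X)
  w <- runif(6, 0.5, 2)
  full <- skat_o(G, null, weights = w)
  skat <- skat_o(G, null, weights = w, rho_grid = 0)
  burden <- skat_o(G, null, weights = w, rho_grid = 1)
  expect_equal(skat$p_value, full$p_by_rho[1])
  expect_equal(burden$p_value, full$p_by_rho[8])
  # min-p combination is bracketed by [min p, grid size * min p]
  pmin_v <- min(full$p_by_rho)
  expect_gte(full$p_value, pmin_v)
  expect_lte(full$p_value, min(1, 8 * pmin_v) + 1e-12)
})

test_that("single-variant genes collapse to the single score test", {
  set.seed(4)
  n <- 200
  G <- simulate_dosages(n, 0.05)
  y <- rbinom(n, 1, 0.5)
  null <- fit_null(y)
  res <- skat_o(G, null)
  expect_true(all(abs(res$p_by_rho - res$p_by_rho[1]) < 1e-10))
  expect_equal(res$p_value, res$p_by_rho[1])
})

test_that("analytic SKAT-O agrees with the label-permutation oracle", {
  # comparison in the decision-relevant tail regime; at central p-values the
  # asymptotic null departs from the exact permutation null by more than
  # Monte-Carlo noise at this sample size (see the methods vignette)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200; m <- 10
    G <- simulate_dosages(n, runif(m, 0.1, 0.3))
    eta <- -0.3 + 0.45 * scale(G %*% runif(m, 0, 1))
    y <- rbinom(n, 1, plogis(eta))
    null <- fit_null(y)
    a <- skat_o(G, null)$p_value
    p <- skat_o(G, null, method = "permutation", n_perm = 10000)$p_value
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(a - p), 3 * se + 1e-12)
  }
})

test_that("empty and monomorphic cells are reported untested", {
  null <- fit_null(rep(c(1, 0), 50))
  expect_false(skat_o(matrix(numeric(0), 100, 0), null)$tested)
  expect_false(skat_o(matrix(0, 100, 3), null)$tested)
})

test_that("significance flags implement the gene-count Bonferroni rule", {
  expect_equal(round(0.05 / 47, 3), 0.001)
  res <- data.frame(p_value = c(0.0022, 0.0315, 0.05, 0.0005, NA),
                    tested = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- significance_flags(res, 47)
  expect_equal(out$suggestive, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$significant, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(attr(out, "bonferroni_threshold"), 0.05 / 47)
})

test_that("burden scan counts carriers independently of variant order", {
  cfg <- sim_config(n_cases = 60, n_controls = 60, genes = c("TH", "ANO3"),
                    variants_per_gene = 12, seed = 5)
  co <- simulate_cohort(cfg, as_cohort = TRUE)
  panel <- load_panel(data.frame(symbol = c("TH", "ANO3"),
                                 inheritance = c("AR", "AD")))
  res <- run_burden_scan(co, panel)
  # recompute carrier counts from scratch for each tested cell
  memb <- subgroup_membership(co$annotations)
  for (i in which(res$tested)) {
    cell <- paste0(res$variant_subgroup[i], "@",
                   sub("^0", "0", format(res$maf_threshold[i],
                                         drop0trailing = TRUE)))
    vids <- co$annotations$variant_id[
      co$annotations$gene == res$gene[i] & memb[, cell]]
    G <- co$dosages[, rev(vids), drop = FALSE]  # reversed order
    carrier <- rowSums(!is.na(G) & G >= 1) > 0
    is_case <- co$samples$status == "case"
    expect_equal(res$case_carriers[i], sum(carrier & is_case))
    expect_equal(res$control_carriers[i], sum(carrier & !is_case))
  }
  # a cohort devoid of panel variants yields only untested cells
  panel2 <- load_panel(data.frame(symbol = "GNAL", inheritance = "AD"))
  res2 <- run_burden_scan(co, panel2)
  expect_true(all(!res2$tested))
  expect_true(all(is.na(res2$p_value)))
})

test_that("the scan refuses mixed case subgroups", {
  co <- load_example_fixture("table1_ar")  # sEOPD + sLOPD + FPD_AR cases
  expect_error(run_burden_scan(co, dyt_panel()), "exactly one case subgroup")
})
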