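test_that("residual scaling follows the per-measurement-type rule", {
  dat <- tiny_parental_data
  pred <- dat$value
  r <- her_residuals_scaled(dat, pred)
  expect_equal(unname(as.vector(r)), rep(0, nrow(dat)))
  expect_equal(her_rmse(r), 0)

  # one record off by exactly its type scale contributes residual 1.0
  sc <- her_scales(dat)
  pred2 <- dat$value
  pred2[5] <- pred2[5] + sc[[dat$measurement[5]]]
  r2 <- her_residuals_scaled(dat, pred2, sc)
  expect_equal(as.vector(r2)[5], 1.0)
  expect_equal(sum(r2 != 0), 1L)

  # doubling data and predictions leaves scaled residuals unchanged
  dat2 <- dat; dat2$value <- 2 * dat$value
  r3 <- her_residuals_scaled(dat2, 2 * pred2, her_scales(dat2))
  expect_equal(as.vector(r3), as.vector(r2))

  expect_error(her_residuals_scaled(dat, pred[-1]), "one prediction")
  expect_error(her_residuals_scaled(dat, replace(pred, 2, NA)), "missing")
})

test_that("the free-parameter search space matches the estimation contract", {
  b <- herdimer:::.free_bounds()
  expect_equal(nrow(b), 47L)
  ku <- b[grepl("^ku", b$name), ]
  pf <- b[grepl("^pf", b$name), ]
  expect_equal(nrow(ku), 20L)
  expect_equal(nrow(pf), 26L)
  expect_true(all(ku$lower == 1e-3 & ku$upper == 1e3))
  expect_true(all(pf$lower == 1e-6 & pf$upper == 1))
  expect_equal(b[b$name == "delta1", c("lower", "upper")],
               data.frame(lower = 0.1, upper = 10,
                          row.names = which(b$name == "delta1")))
})

test_that("a fit started at the truth stays at the truth", {
  g <- herdimer:::.param_groups()
  start <- truth_free[g$her1]
  fit <- her_fit_single(tiny_parental_data, truth_params, start,
                        maxiter = 20)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(unname(fit$par / start), rep(1, length(start)),
               tolerance = 0.01)
})

test_that("fitting descends from a perturbed start and recovers", {
  g <- herdimer:::.param_groups()
  start <- truth_free[g$her1]
  start[c("pf11ees", "ku11ees")] <- start[c("pf11ees", "ku11ees")] * 3
  fn <- herdimer:::.make_objective(tiny_parental_data, truth_params,
                                   g$her1, her_cell_lines(),
                                   her_scales(tiny_parental_data),
                                   1e-7, 1e-9)
  rmse0 <- her_rmse(fn(herdimer:::.encode_free(start)))
  fit <- her_fit_single(tiny_parental_data, truth_params, start,
                        maxiter = 80)
  expect_lt(fit$rmse, rmse0)          # descent contract
  expect_lt(fit$rmse, 1e-4)
  expect_equal(fit$par[["pf11ees"]], truth_free[["pf11ees"]],
               tolerance = 0.1)
  expect_equal(fit$par[["ku11ees"]], truth_free[["ku11ees"]],
               tolerance = 0.1)
})

test_that("simulation failure yields a finite penalty, not an error", {
  g <- herdimer:::.param_groups()
  broken <- her_cell_lines()
  broken <- broken[broken$name != "parental", ]   # profile lookup fails
  fn <- herdimer:::.make_objective(tiny_parental_data, truth_params,
                                   g$her1, broken,
                                   her_scales(tiny_parental_data),
                                   1e-7, 1e-9)
  r <- fn(herdimer:::.encode_free(truth_free[g$her1]))
  expect_true(all(is.finite(r)))
  expect_equal(unique(r), 10)
})

test_that("stage-1 free set excludes HER2/HER3-related parameters", {
  g <- herdimer:::.param_groups()
  expect_false(any(grepl("2|3", sub("delta1", "", g$her1))))
  expect_equal(sort(unlist(g, use.names = FALSE)), sort(her_free_names()))
  expect_equal(length(unlist(g)), 47L)
})

test_that("well-separated solution blobs cluster at k = 2", {
  set.seed(5)
  nm <- her_free_names()
  centre1 <- truth_free
  centre2 <- truth_free
  ku_pf <- nm[nm != "delta1"]
  centre2[ku_pf] <- pmin(centre2[ku_pf] * 100, 900)  # 2 decades apart
  jitter_sol <- function(centre, n) {
    t(vapply(seq_len(n), function(i) {
      v <- centre
      v[ku_pf] <- v[ku_pf] * 10^rnorm(length(ku_pf), 0, 0.01)
      v
    }, centre))
  }
  par_mat <- rbind(jitter_sol(centre1, 6), jitter_sol(centre2, 6))
  rmse <- rep(c(0.01, 0.011), each = 6)
  cl <- her_cluster_solutions(par_mat, rmse, rmse_margin = 1.5)
  expect_equal(cl$k, 2L)
  expect_equal(sort(table(cl$labels)), sort(table(rep(1:2, each = 6))),
               ignore_attr = TRUE)
  # representatives carry the minimum RMSE within their cluster
  for (g2 in seq_len(cl$k)) {
    members <- cl$retained[cl$labels == g2]
    expect_equal(min(rmse[members]),
                 rmse[intersect(cl$representatives, members)])
  }
})

test_that("identical solutions collapse to a single cluster", {
  par_mat <- matrix(rep(truth_free, each = 5), nrow = 5,
                    dimnames = list(NULL, her_free_names()))
  cl <- her_cluster_solutions(par_mat, rep(0.02, 5))
  expect_equal(cl$k, 1L)
  expect_equal(cl$representatives, 1L)
})

test_that("the RMSE retention filter is honoured", {
  par_mat <- matrix(rep(truth_free, each = 6), nrow = 6,
                    dimnames = list(NULL, her_free_names()))
  rmse <- c(0.01, 0.011, 0.012, 0.02, 0.5, 1)
  cl <- her_cluster_solutions(par_mat, rmse, rmse_margin = 1.2)
  expect_setequal(cl$retained, 1:3)
})
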