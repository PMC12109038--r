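sweep_3x3 <- NULL

test_that("sweep cells cross the requested axes", {
  cells <- sweep_cells(lik_vars = c(1, 10), prior_vars = c(2, 20, 40))
  expect_equal(nrow(cells), 6L)
  expect_named(cells, c("lik_var", "prior_var"))
  cells <- sweep_cells(lik_range = c(1, 3), prior_range = c(1, 3), step = 1)
  expect_equal(nrow(cells), 9L)
  expect_error(sweep_cells(lik_vars = c(0, 1)),
               class = "epigain_parameter_error")
})

test_that("every sweep cell satisfies the ordering and positive fluctuation", {
  grid <- run_sweep(sweep_cells(lik_vars = c(1, 10, 50),
                                prior_vars = c(1, 10, 50)))
  sweep_3x3 <<- grid
  expect_equal(nrow(grid), 9L)
  expect_true(all(grid$d_s > 0))
  expect_true(all(grid$delta_kld <= grid$delta_ig))
  expect_true(all(grid$delta_ig <= grid$delta_bs))
  g <- glance(grid)
  expect_true(g$ordering_ok)
  expect_true(g$all_d_s_positive)
  expect_equal(g$n_cells, 9L)
})

test_that("a single-cell sweep reproduces find_optima exactly", {
  cell <- run_sweep(sweep_cells(lik_vars = 1, prior_vars = 10))
  direct <- glance(find_optima(prior_var = 10, lik_var = 1))
  expect_equal(cell$delta_bs, direct$delta_bs)
  expect_equal(cell$max_ig, direct$max_ig)
  expect_equal(cell$d_s, direct$d_s)
})

test_that("sweeps are deterministic and checkpoint resume is exact", {
  cells <- sweep_cells(lik_vars = c(1, 5), prior_vars = c(2, 8))
  a <- run_sweep(cells)
  b <- run_sweep(cells)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # byte-identical serialization
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_gain_csv(a, f1)
  write_gain_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))

  # resume: seed the checkpoint with a partial run, then complete
  ck <- withr::local_tempfile(fileext = ".csv")
  partial <- run_sweep(cells[1:2, ], checkpoint = ck)
  expect_true(file.exists(ck))
  resumed <- run_sweep(cells, checkpoint = ck)
  expect_equal(as.data.frame(resumed), as.data.frame(a), tolerance = 1e-12)
})

test_that("paper-regime trends hold where the model implies them", {
  grid <- sweep_3x3
  rep <- trend_report(grid)
  expect_s3_class(rep, "trend_report")
  pick <- function(trend, quantity) {
    rep$pass[rep$trend == trend & rep$quantity %in% quantity]
  }
  # maximum gains fall as observation noise grows
  expect_true(all(pick("max_gain_vs_lik", c("max_kld", "max_bs", "max_ig"))))
  # optimal prediction errors expand with either uncertainty
  expect_true(all(rep$pass[rep$trend %in%
                             c("opt_delta_vs_lik", "opt_delta_vs_prior")]))
  # open-mindedness lowers the evidence-seeking surprise optimum
  expect_true(pick("surprise_vs_prior", "s_kld"))
  expect_true(pick("surprise_vs_lik", "s_kld"))
  expect_true(pick("surprise_vs_lik", "s_ig"))
  # exploration range d_s widens with precision and open-mindedness
  expect_true(pick("d_s_vs_lik", "d_s"))
  expect_true(pick("d_s_vs_prior", "d_s"))
  expect_true(pick("corner_max_ig", "max_ig"))
})

test_that("degenerate single-column grids mark row trends not applicable", {
  grid <- run_sweep(sweep_cells(lik_vars = 1, prior_vars = c(1, 10, 50)))
  rep <- trend_report(grid)
  expect_true(all(is.na(rep$pass[rep$axis == "lik_var"])))
  expect_true(all(!is.na(rep$pass[rep$axis == "prior_var"])))
  expect_true(is.na(rep$pass[rep$trend == "corner_max_ig"]))
})

test_that("the trend checker rejects scrambled grids", {
  grid <- sweep_3x3
  set.seed(61)
  scram <- grid
  value_cols <- setdiff(names(grid), c("lik_var", "prior_var"))
  perm <- sample(nrow(grid))
  scram[value_cols] <- grid[perm, value_cols]
  rep_ok <- trend_report(grid)
  rep_bad <- trend_report(scram)
  was_passing <- !is.na(rep_ok$pass) & rep_ok$pass
  expect_gt(sum(was_passing & !rep_bad$pass, na.rm = TRUE), 0)
})

test_that("sweep heatmaps assemble without evaluation errors", {
  p <- autoplot(sweep_3x3, metric = "d_s")
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})
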