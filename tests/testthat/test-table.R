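# quantity table: precompute, lookup, persistence

test_that("lookup returns stored values exactly at grid nodes and is exact on planes", {
  tab <- test_table()
  i <- 12; j <- 2
  v <- lookup(tab, tab$mu[i], tab$sigma[j], c("r_inf", "lam1_re"))
  expect_identical(v$r_inf, tab$arrays$r_inf[i, j])
  expect_identical(v$lam1_re, tab$arrays$lam1_re[i, j])
  # bilinear interpolation reproduces affine fields exactly
  tab2 <- tab
  tab2$arrays$plane <- outer(tab$mu, tab$sigma, function(m, s) 2 * m - 3 * s + 1)
  q <- lookup(tab2, 1.23, 1.37, "plane")
  expect_equal(q$plane, 2 * 1.23 - 3 * 1.37 + 1, tolerance = 1e-12)
})

test_that("midpoint interpolation of the rate is close to a direct solve", {
  tab <- test_table()
  np <- np_default()
  g <- build_voltage_grid(np, dV = 0.02)
  mu_q <- (tab$mu[25] + tab$mu[26]) / 2
  sg_q <- 1.5
  v <- lookup(tab, mu_q, sg_q, "r_inf")$r_inf
  st <- solve_stationary(mu_q, sg_q, g, np)
  # the test table is 4x coarser in mu than the production spacing, so the
  # quadratic midpoint interpolation error bound scales up by 16x from the
  # sub-1% production figure
  expect_lt(abs(v / st$r_inf - 1), 0.03)
})

test_that("out-of-range queries clamp (or error when clamping is disabled)", {
  tab <- test_table()
  v_edge <- lookup(tab, max(tab$mu), 1.5, "r_inf")$r_inf
  expect_warning(v_out <- lookup(tab, max(tab$mu) + 5, 1.5, "r_inf",
                                 warn = TRUE)$r_inf, "clamped")
  expect_identical(v_out, v_edge)
  expect_error(lookup(tab, max(tab$mu) + 5, 1.5, "r_inf", clamp = FALSE),
               "outside")
  expect_error(lookup(tab, 1, 1.5, "no_such_array"), "not in table")
})

test_that("interpolated rate inherits nonnegativity", {
  tab <- test_table()
  set.seed(2)
  for (k in 1:50) {
    mu_q <- runif(1, min(tab$mu), max(tab$mu))
    sg_q <- runif(1, min(tab$sigma), max(tab$sigma))
    expect_gte(lookup(tab, mu_q, sg_q, "r_inf")$r_inf, 0)
  }
})

test_that("save/load roundtrip is bit-exact and tampering is detected", {
  tab <- test_table()
  f <- tempfile(fileext = ".json")
  save_quantity_table(tab, f)
  tab2 <- load_quantity_table(f)
  for (nm in names(tab$arrays))
    expect_identical(unname(tab2$arrays[[nm]]), unname(tab$arrays[[nm]]),
                     info = nm)
  expect_identical(tab2$hash, tab$hash)
  # tamper with the stored neuron parameters
  p <- jsonlite::read_json(f, simplifyVector = TRUE)
  p$meta$neuron$g_L <- 11
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(p, f2, digits = I(17), auto_unbox = TRUE)
  expect_error(load_quantity_table(f2), "hash mismatch")
})

test_that("partial (stationary-only) tables load and report missing arrays clearly", {
  np <- np_default()
  gs <- grid_spec(0, 1, 0.5, 1.0, 2.0, 0.5)
  tab <- precompute_quantities(np, gs, which = "stationary", dV = 0.1)
  f <- tempfile(fileext = ".json")
  save_quantity_table(tab, f)
  tab2 <- load_quantity_table(f)
  expect_true("r_inf" %in% names(tab2$arrays))
  expect_false("lam1_re" %in% names(tab2$arrays))
  expect_error(lookup(tab2, 0.5, 1.5, "lam1_re"), "not in table")
  cp <- coupling_params(K = 0)
  sig <- const_signals(0.5, 2.25, T = 10)
  expect_error(run_rate_model("spec1", tab2, np, cp, sig$mu, sig$s2, T = 10),
               "lacks arrays")
})

test_that("the table is keyed by the EIF parameters only", {
  tab <- test_table()
  np_adapt <- neuron_params(a = 10, b = 100, tau_w = 50)
  expect_identical(fprate:::params_hash(np_adapt), tab$hash)
  np_eif <- neuron_params(Delta_T = 2.0)
  expect_false(identical(fprate:::params_hash(np_eif), tab$hash))
  # and a model run with different adaptation parameters accepts the table
  cp <- coupling_params(K = 0)
  sig <- const_signals(2, 2.25, T = 50)
  tr <- run_rate_model("lnexp", tab, np_adapt, cp, sig$mu, sig$s2, T = 50)
  expect_true(all(is.finite(tr$rate$values)))
})

test_that("tracked eigenvalue arrays respect the spectral constraints", {
  tab <- test_table()
  expect_lt(max(tab$arrays$lam1_re, na.rm = TRUE), 1e-9)
  expect_lt(max(tab$arrays$lam2_re, na.rm = TRUE), 1e-9)
  expect_true(all(tab$arrays$r_inf >= 0))
  expect_true(all(tab$arrays$tau_mu > 0))
  expect_true(all(tab$arrays$tau_sigma >= 0))
})
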