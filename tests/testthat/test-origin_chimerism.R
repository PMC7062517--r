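test_that("sex assignment follows the expression-greater-than-zero rule", {
  expect_equal(assign_sex(3, 0), "female")
  expect_equal(assign_sex(0, 2), "male")
  expect_equal(assign_sex(1, 2), "both")
  expect_equal(assign_sex(0, 0), "neither")
  expect_equal(assign_sex(c(3, 0, 1, 0), c(0, 2, 2, 0)),
               c("female", "male", "both", "neither"))
  expect_error(assign_sex(-1, 0), "nonnegative")
})

test_that("origin mapping reflects the transplant direction", {
  fm <- sample_meta("s1", "female", "male")     # female recipient, male donor
  mf <- sample_meta("s2", "male", "female")
  calls <- c("female", "male", "both", "neither")
  expect_equal(map_origin(calls, fm)$origin,
               c("recipient", "donor", "ambiguous", "unassigned"))
  # the same female cell is donor-derived when the donor is female
  expect_equal(map_origin(calls, mf)$origin,
               c("donor", "recipient", "ambiguous", "unassigned"))
  expect_error(map_origin(calls, sample_meta("s3", "male", "male")))
  expect_error(sample_meta("s4", "female", "male",
                           months_post_transplant = -1))
})

test_that("macrophage gating modes behave as documented", {
  m <- Matrix::Matrix(matrix(c(4, 0,   4, 2,   0, 0), nrow = 2,
                             dimnames = list(c("CD68", "MARCO"),
                                             c("c1", "c2", "c3"))),
                      sparse = TRUE)
  expect_equal(gate_macrophages(m, mode = "off"), rep(TRUE, 3))
  expect_equal(unname(gate_macrophages(m, mode = "any_positive")),
               c(TRUE, TRUE, FALSE))
  expect_equal(unname(gate_macrophages(m, mode = "all_positive")),
               c(FALSE, TRUE, FALSE))
  expect_error(gate_macrophages(m[1, , drop = FALSE], mode = "any_positive"),
               "MARCO")
})

test_that("chimerism summaries are exact arithmetic over call categories", {
  meta <- sample_meta("s1", "female", "male")
  calls <- map_origin(c(rep("female", 60), rep("male", 10), rep("both", 5),
                        rep("neither", 25)), meta)
  sm <- summarize_chimerism(calls, meta)
  expect_equal(sm$n_cells, 100)
  expect_equal(sm$pct_xist_pos, 60)
  expect_equal(sm$pct_rps4y1_pos, 10)
  expect_equal(sm$pct_ambiguous, 5)
  expect_equal(sm$pct_unassigned, 25)
  expect_equal(sm$pct_recipient, 100 * 60 / 70)
  expect_equal(sm$pct_xist_pos + sm$pct_rps4y1_pos + sm$pct_ambiguous +
                 sm$pct_unassigned, 100, tolerance = 1e-9)
  # all cells unassigned: split undefined, not 0/0
  sm0 <- summarize_chimerism(map_origin(rep("neither", 10), meta), meta)
  expect_equal(sm0$pct_unassigned, 100)
  expect_true(is.na(sm0$pct_recipient))
  expect_true(is.na(sm0$pct_donor))
})

test_that("swapping recipient and donor sexes swaps the split exactly", {
  set.seed(501)
  sexes <- sample(c("female", "male", "both", "neither"), 200, replace = TRUE)
  a <- summarize_chimerism(map_origin(sexes, sample_meta("x", "female", "male")),
                           sample_meta("x", "female", "male"))
  b <- summarize_chimerism(map_origin(sexes, sample_meta("x", "male", "female")),
                           sample_meta("x", "male", "female"))
  expect_equal(a$pct_recipient, b$pct_donor)
  expect_equal(a$pct_donor, b$pct_recipient)
  expect_equal(a$pct_xist_pos, b$pct_xist_pos)
})

test_that("normalization never changes an origin call", {
  sim <- simulate_counts(sim_config(n_cells = 100, n_ambient_droplets = 0,
                                    mean_cell_umis = 300,
                                    mean_ambient_umis = 5, seed = 8))
  m <- sim$counts
  raw <- assign_sex(m["XIST", ], m["RPS4Y1", ])
  norm <- normalize_log(m)
  after <- assign_sex(norm["XIST", ], norm["RPS4Y1", ])
  expect_identical(raw, after)
})

test_that("dropout-corrected chimerism estimation recovers the truth", {
  meta <- sample_meta("s1", "female", "male")
  # saturating detection: estimate reduces to the raw split
  calls <- map_origin(c(rep("female", 70), rep("male", 30)), meta)
  sm <- summarize_chimerism(calls, meta)
  est <- estimate_chimerism_fraction(sm, lambda_recipient = 50,
                                     lambda_donor = 50)
  expect_equal(est$estimate, 0.7, tolerance = 1e-6)
  expect_true(est$lower < 0.7 && est$upper > 0.7)
  # unequal detection rates are corrected for
  f <- 0.6
  lam_r <- 1.0
  lam_d <- 2.0
  cfg <- sim_config(n_cells = 5000, n_ambient_droplets = 0,
                    chimerism_fraction = f, lambda_xist = lam_r,
                    lambda_rps4y1 = lam_d, mean_cell_umis = 200,
                    mean_ambient_umis = 5, seed = 17)
  sim <- simulate_counts(cfg)
  cells <- sim$truth$is_cell
  calls <- map_origin(assign_sex(sim$counts["XIST", cells],
                                 sim$counts["RPS4Y1", cells]), meta)
  est2 <- estimate_chimerism_fraction(summarize_chimerism(calls, meta),
                                      lam_r, lam_d)
  expect_lt(abs(est2$estimate - f), 0.05)
  expect_true(est2$lower <= f && f <= est2$upper)
  # undefined when nothing is assignable
  sm0 <- summarize_chimerism(map_origin(rep("neither", 5), meta), meta)
  expect_error(estimate_chimerism_fraction(sm0, 1, 1), "undefined")
})

test_that("the estimator is consistent as sample size grows", {
  meta <- sample_meta("s1", "female", "male")
  f <- 0.7
  lam <- 1.2
  for (n in c(500, 2000, 8000)) {
    cfg <- sim_config(n_cells = n, n_ambient_droplets = 0,
                      chimerism_fraction = f, lambda_xist = lam,
                      lambda_rps4y1 = lam, mean_cell_umis = 150,
                      mean_ambient_umis = 5, seed = 1000 + n)
    sim <- simulate_counts(cfg)
    calls <- map_origin(assign_sex(sim$counts["XIST", ],
                                   sim$counts["RPS4Y1", ]), meta)
    est <- estimate_chimerism_fraction(summarize_chimerism(calls, meta),
                                       lam, lam)
    # error bounded by 3 binomial SE at the assignable-cell count
    se <- sqrt(f * (1 - f) / est$n_assignable)
    expect_lt(abs(est$estimate - f), 3 * se)
  }
})
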