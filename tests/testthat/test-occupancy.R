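# Frozen expected values below were computed with an independent oracle
# (Pade matrix exponential + nested adaptive integration, rel.tol <= 1e-8),
# rounded to 3 decimals.

test_that("conditional occupancy matches the independent oracle", {
  mod <- kidney_model()
  occ <- cmsm_occupancy(mod, "eGFR", mode = "conditional", u = 1)
  w <- occupancy_wide(occ)
  expect_equal(unlist(w[w$start == 1, c("state_1", "state_2", "state_3")],
                      use.names = FALSE),
               c(4.670, 0.304, 0.026), tolerance = 1e-3)
  expect_equal(unlist(w[w$start == 3, c("state_1", "state_2", "state_3")],
                      use.names = FALSE),
               c(1.497, 1.392, 2.111), tolerance = 1e-3)
  occ_pu <- cmsm_occupancy(mod, "PU", start = 1, mode = "conditional")
  expect_equal(occ_pu$years, c(3.244, 1.667, 0.089), tolerance = 1e-3)
})

test_that("frailty-averaged occupancy matches the independent oracle", {
  mod <- kidney_model()
  occ <- cmsm_occupancy(mod, "eGFR", start = 3, mode = "marginal")
  expect_equal(occ$years, c(2.065, 1.080, 1.855), tolerance = 1e-3)
  occ_pu <- cmsm_occupancy(mod, "PU", start = 3, mode = "marginal")
  expect_equal(occ_pu$years, c(2.518, 1.831, 0.650), tolerance = 1e-3)
})

test_that("occupancy conserves total time and is stable under refinement", {
  set.seed(5)
  for (i in 1:5) {
    sp <- bd_spec(sample(c("none", "simple", "inverse"), 1))
    m <- cmsm_model(sp, intensities = list(p1 = runif(4, 0, 2),
                                           p2 = runif(4, 0, 2)),
                    theta = if (sp$link == "none") NULL else runif(1, 0.2, 1))
    h <- runif(1, 1, 8)
    occ <- cmsm_occupancy(m, mode = if (sp$link == "none") "conditional"
                          else "marginal", horizon = h)
    expect_true(all(occ$years >= 0))
    sums <- tapply(occ$years, interaction(occ$process, occ$start), sum)
    expect_equal(unname(as.numeric(sums)), rep(h, length(sums)),
                 tolerance = 1e-6)
  }
  # halving / doubling the time rule leaves the published-table scale intact
  mod <- kidney_model()
  o1 <- cmsm_occupancy(mod, "eGFR", start = 3, mode = "marginal", n_t = 48)
  o2 <- cmsm_occupancy(mod, "eGFR", start = 3, mode = "marginal", n_t = 192)
  expect_lt(max(abs(o1$years - o2$years)), 5e-4)
})

test_that("degenerate frailty limits collapse to the typical-subject answer", {
  mod <- kidney_model(theta = 1e-8)
  occ_m <- cmsm_occupancy(mod, "eGFR", mode = "marginal")
  occ_c <- cmsm_occupancy(mod, "eGFR", mode = "conditional", u = 1)
  expect_equal(occ_m$years, occ_c$years, tolerance = 1e-3)
  occ_mc <- cmsm_occupancy(mod, "eGFR", mode = "mc", draws = 50, seed = 1)
  expect_equal(occ_mc$years, occ_c$years, tolerance = 1e-3)
})

test_that("Monte Carlo frailty averaging agrees with quadrature and is reproducible", {
  mod <- kidney_model()
  quadr <- cmsm_occupancy(mod, "eGFR", start = 3, mode = "marginal")
  mc1 <- cmsm_occupancy(mod, "eGFR", start = 3, mode = "mc",
                        draws = 8000, seed = 77)
  mc2 <- cmsm_occupancy(mod, "eGFR", start = 3, mode = "mc",
                        draws = 8000, seed = 77)
  expect_identical(mc1$years, mc2$years)
  expect_lt(max(abs(mc1$years - quadr$years)), 0.05)
})

test_that("joint occupancy marginalises to single-process occupancy and conserves time", {
  mod <- kidney_model()
  joint <- cmsm_occupancy_joint(mod, start = c(1, 2), mode = "re_averaged")
  expect_equal(sum(joint$years), 5, tolerance = 1e-5)
  # summing over the second process's states recovers the first process
  single <- cmsm_occupancy(mod, "eGFR", start = 1, mode = "marginal")
  by1 <- tapply(joint$years, joint$state_1, sum)
  expect_equal(unname(as.numeric(by1)), single$years, tolerance = 1e-5)

  jm <- cmsm_occupancy_joint(kidney_marginal_model(), start = c(3, 3),
                             mode = "marginal")
  expect_equal(sum(jm$years), 5, tolerance = 1e-5)
  expect_error(cmsm_occupancy_joint(mod, start = c(0, 1)), "valid states")
})

test_that("published joint-table corner entries are reproduced", {
  jm <- cmsm_occupancy_joint(kidney_marginal_model(), start = c(1, 1),
                             mode = "marginal")
  expect_equal(jm$years[jm$state_1 == 1 & jm$state_2 == 1], 3.466,
               tolerance = 1e-3)
  jr <- cmsm_occupancy_joint(kidney_model(), start = c(1, 1),
                             mode = "re_averaged")
  expect_equal(jr$years[jr$state_1 == 1 & jr$state_2 == 1], 3.296,
               tolerance = 1e-3)
})

test_that("occupancy refuses dynamic covariates", {
  spc <- cmsm_spec(processes = c("eGFR", "PU"), link = "none",
                   covariates = list(eGFR = "x"))
  beta <- matrix(0.5, 4, 1, dimnames = list(spc$labels, "x"))
  m <- cmsm_model(spc,
    intensities = list(eGFR = c(0.1, 0.4, 0.1, 0.4), PU = c(0.3, 0.6, 0.2, 1)),
    beta = list(eGFR = beta))
  expect_error(cmsm_occupancy(m, "eGFR"), "covariates")
  # but fixed covariate values are accepted
  occ <- cmsm_occupancy(m, "eGFR", covariates = c(x = 0.5))
  expect_equal(sum(occ$years[occ$start == 1]), 5, tolerance = 1e-6)
})
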