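test_that("degenerate subjects and closed forms", {
  mod <- kidney_model()
  single <- tibble::tibble(id = "s", time = 0, eGFR = 1L, PU = 2L)
  expect_warning(ll <- cmsm_loglik(single, mod), "single visit")
  expect_equal(ll, 0, tolerance = 1e-9)
  expect_equal(suppressWarnings(cmsm_loglik(single, mod, u = 1)), 0)

  # one interval, effectively 2-state: observed 1 -> 1 over dt = 1
  sp <- cmsm_spec(n_states = 2, processes = c("p1", "p2"), link = "none",
                  transitions = c("1->2", "2->1"))
  m2 <- cmsm_model(sp, intensities = list(p1 = c(0.3, 0.7), p2 = c(0, 0)))
  pan <- tibble::tibble(id = "x", time = c(0, 1), p1 = c(1L, 1L), p2 = c(1L, 1L))
  b <- 0.7; a <- 0.3
  expect_equal(cmsm_loglik(pan, m2, u = 1),
               log(b / (a + b) + a / (a + b) * exp(-1)), tolerance = 1e-10)
})

test_that("conditional likelihood factorises over processes at fixed frailty", {
  mod <- kidney_model()
  panel <- tiny_panel()
  names(panel) <- c("id", "time", "eGFR", "PU")
  for (u in c(0.4, 1, 2.7)) {
    both <- cmsm_loglik(panel, mod, u = u)
    only1 <- panel; only1$PU <- NA_integer_
    only2 <- panel; only2$eGFR <- NA_integer_
    expect_equal(both, cmsm_loglik(only1, mod, u = u) +
                       cmsm_loglik(only2, mod, u = u), tolerance = 1e-12)
  }
})

test_that("no-frailty likelihood equals the sum of per-process marginal fits' objectives", {
  modn <- kidney_marginal_model()
  panel <- tiny_panel()
  names(panel) <- c("id", "time", "eGFR", "PU")
  sp1 <- cmsm_spec(processes = "eGFR", link = "none")
  sp2 <- cmsm_spec(processes = "PU", link = "none")
  m1 <- cmsm_model(sp1, intensities = list(eGFR = modn$intensities$eGFR))
  m2 <- cmsm_model(sp2, intensities = list(PU = modn$intensities$PU))
  expect_equal(cmsm_loglik(panel, modn),
               cmsm_loglik(panel[c("id", "time", "eGFR")], m1) +
                 cmsm_loglik(panel[c("id", "time", "PU")], m2),
               tolerance = 1e-12)
})

test_that("a near-degenerate frailty distribution recovers the conditional likelihood", {
  mod <- kidney_model(theta = 1e-8)
  panel <- tiny_panel()
  names(panel) <- c("id", "time", "eGFR", "PU")
  cond <- cmsm_loglik(panel, mod, u = 1)
  expect_equal(cmsm_loglik(panel, mod), cond, tolerance = 1e-4)
  expect_equal(cmsm_loglik(panel, mod, quad = quad_control("fixed")), cond,
               tolerance = 1e-4)
})

test_that("integrated subject likelihood matches a dense trapezoid oracle", {
  mod <- kidney_model(theta = 0.5)
  times <- c(0, 1.1, 2.3)
  states <- list(eGFR = c(1L, 2L, 1L), PU = c(2L, 3L, 2L))
  orc <- oracle_subject(times, states, mod, theta = 0.5)
  panel <- tibble::tibble(id = "f", time = times,
                          eGFR = states$eGFR, PU = states$PU)
  got_ad <- cmsm_loglik(panel, mod)
  got_fx <- cmsm_loglik(panel, mod, quad = quad_control("fixed"))
  expect_equal(got_ad, orc$loglik, tolerance = 1e-6)
  expect_equal(got_fx, orc$loglik, tolerance = 1e-6)
})

test_that("total likelihood of a simulated panel matches per-subject oracle terms", {
  panel <- sim_cohort(20, visits = 0:4, seed = 99)
  mod <- attr(panel, "truth")
  # grid step 5e-4 over the gamma's support (upper tail mass beyond 20 ~ 1e-14)
  orc <- oracle_panel_integrated(panel, mod, theta = mod$theta,
                                 n = 40000, u_max = 20)
  got <- cmsm_loglik(panel, mod, by_subject = TRUE)
  expect_equal(got$loglik, orc, tolerance = 1e-6)
  expect_equal(cmsm_loglik(panel, mod), sum(orc), tolerance = 1e-6)
})

test_that("total likelihood is invariant to subject order and panel splits", {
  panel <- sim_cohort(12, visits = 0:4, seed = 7)
  mod <- attr(panel, "truth")
  ll <- cmsm_loglik(panel, mod)

  ids <- unique(panel$id)
  set.seed(1)
  shuf <- panel[order(match(panel$id, sample(ids)), panel$time), ]
  expect_equal(cmsm_loglik(shuf, mod), ll, tolerance = 1e-9)

  half <- ids[1:6]
  expect_equal(cmsm_loglik(panel[panel$id %in% half, ], mod) +
                 cmsm_loglik(panel[!panel$id %in% half, ], mod),
               ll, tolerance = 1e-9)
})

test_that("mixture bound: integrated likelihood cannot beat the best conditional one", {
  panel <- sim_cohort(8, visits = 0:4, seed = 3)
  mod <- attr(panel, "truth")
  per <- cmsm_loglik(panel, mod, by_subject = TRUE)$loglik
  best <- do.call(pmax, lapply(exp(seq(log(0.05), log(20), length.out = 60)),
                               function(u) cmsm_loglik(panel, mod, u = u,
                                                       by_subject = TRUE)$loglik))
  expect_true(all(per <= best + 1e-8))
})

test_that("quadrature is stable under doubling of effort", {
  sp <- cmsm_spec(processes = "p1", link = "simple")
  m <- cmsm_model(sp, intensities = list(p1 = c(0.4, 0.8, 0.2, 0.6)),
                  theta = 0.5)
  pan <- tibble::tibble(id = "x", time = c(0, 1.3), p1 = c(1L, 2L))
  l96 <- cmsm_loglik(pan, m, quad = quad_control("fixed", n_nodes = 96))
  l192 <- cmsm_loglik(pan, m, quad = quad_control("fixed", n_nodes = 192))
  expect_equal(l96, l192, tolerance = 1e-8)
})

test_that("missing states are bridged per process without touching the other", {
  modn <- kidney_marginal_model()
  panel <- tibble::tibble(
    id = "m", time = c(0, 1, 2.5),
    eGFR = c(1L, NA, 2L),   # bridged: one interval 0 -> 2.5
    PU = c(1L, 2L, 2L)      # untouched: two intervals
  )
  lam <- build_generator(modn, "eGFR")
  mu <- build_generator(modn, "PU")
  manual <- log(transition_matrix(lam, 2.5)[1, 2]) +
    log(transition_matrix(mu, 1)[1, 2]) +
    log(transition_matrix(mu, 1.5)[2, 2])
  expect_equal(cmsm_loglik(panel, modn), manual, tolerance = 1e-12)
})

test_that("separate frailties factorise into per-process integrals", {
  sp <- bd_spec("separate")
  m <- cmsm_model(sp, intensities = list(p1 = c(0.1, 0.5, 0.1, 0.4),
                                         p2 = c(0.3, 0.6, 0.15, 1.2)),
                  theta = c(0.4, 0.8))
  panel <- tiny_panel()
  sp1 <- cmsm_spec(processes = "p1", link = "inverse")
  sp2 <- cmsm_spec(processes = "p2", link = "inverse")
  m1 <- cmsm_model(sp1, intensities = m$intensities["p1"], theta = 0.4)
  m2 <- cmsm_model(sp2, intensities = m$intensities["p2"], theta = 0.8)
  expect_equal(cmsm_loglik(panel, m),
               cmsm_loglik(panel[c("id", "time", "p1")], m1) +
                 cmsm_loglik(panel[c("id", "time", "p2")], m2),
               tolerance = 1e-9)
})
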