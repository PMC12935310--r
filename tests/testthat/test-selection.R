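test_that("bridge estimate matches the closed-form conjugate evidence", {
  # Gaussian mean with known noise: y_i ~ N(mu, s2), mu ~ N(0, t2).
  set.seed(1)
  n <- 30; s2 <- 1.3; t2 <- 4
  y <- rnorm(n, 1.2, sqrt(s2))
  post_var <- 1 / (n / s2 + 1 / t2)
  post_mean <- post_var * sum(y) / s2
  logml_exact <- sum(dnorm(y, 0, sqrt(s2), log = TRUE)) +
    0.5 * log(post_var / t2) + 0.5 * post_mean^2 / post_var
  log_q <- function(mu) {
    sum(dnorm(y, mu, sqrt(s2), log = TRUE)) + dnorm(mu, 0, sqrt(t2), log = TRUE)
  }
  draws <- matrix(rnorm(2000, post_mean, sqrt(post_var)), ncol = 1)
  est <- bridge_sampling(draws, log_q, n_proposal = 1000, seed = 2)
  expect_true(est$converged)
  expect_lt(abs(est$logml - logml_exact), 3 * est$se + 1e-3)

  # doubling the draws does not move the estimate beyond combined error
  draws2 <- matrix(rnorm(4000, post_mean, sqrt(post_var)), ncol = 1)
  est2 <- bridge_sampling(draws2, log_q, n_proposal = 1000, seed = 3)
  expect_lt(abs(est2$logml - est$logml), 3 * sqrt(est$se^2 + est2$se^2) + 1e-3)

  # two seeds agree within combined standard errors
  est3 <- bridge_sampling(draws, log_q, n_proposal = 1000, seed = 99)
  expect_lt(abs(est3$logml - est$logml), 3 * sqrt(est$se^2 + est3$se^2) + 1e-3)
})

test_that("bridge estimate is exact for a pure Gaussian integrand", {
  # integral of exp(-z^2 / 2) is sqrt(2 pi): log normaliser known exactly
  set.seed(4)
  draws <- matrix(rnorm(3000), ncol = 1)
  est <- bridge_sampling(draws, function(z) -0.5 * z^2, seed = 5)
  expect_lt(abs(est$logml - 0.5 * log(2 * pi)), 3 * est$se + 1e-3)
})

test_that("Bayes factors and evidence categories honour the scale boundaries", {
  expect_equal(bayes_factor(-10, -10)$bf, 1)
  expect_equal(bayes_factor(-10, -10)$category, "bare_mention")
  expect_equal(bayes_factor(log(3.2), 0)$category, "substantial")
  expect_equal(bayes_factor(log(3.2) - 1e-9, 0)$category, "bare_mention")
  expect_equal(bayes_factor(log(10), 0)$category, "strong")
  expect_equal(bayes_factor(log(100), 0)$category, "decisive")
  expect_equal(bayes_factor(log(100) - 1e-9, 0)$category, "strong")
})

test_that("the model family has 17 members with consistent parameterisations", {
  ids <- model_ids()
  expect_length(ids, 17)
  expect_length(unique(ids), 17)
  expect_equal(par_names("M0"),
               c("tau", "kappa", "alpha", "v_minus", "v_plus", "L",
                 "p_coh", "p_incoh"))
  expect_true("v_minus_1" %in% par_names("Ma_vm"))
  expect_true("tau_rate" %in% par_names("Mt_vmtau"))
  # round trip theta <-> params for every model
  set.seed(6)
  for (m in ids) {
    th <- sample_prior(m, n = 1)[1, ]
    pp <- theta_to_params(m, th, dt = 2.05)
    expect_equal(params_to_theta(m, pp$params, pp$sp), th)
  }
})

test_that("nesting network is acyclic with every model reachable from vanilla", {
  edges <- model_network_edges(model_ids())
  expect_true(all(edges$from != edges$to))
  # topological order exists because edges increase subset size
  sz <- vapply(edges$to, metakin:::model_subset_size, 0L) -
    vapply(edges$from, metakin:::model_subset_size, 0L)
  expect_true(all(sz == 1))
  # reachability from M0 by following edges
  reach <- "M0"
  repeat {
    nxt <- unique(edges$to[edges$from %in% reach])
    if (all(nxt %in% reach)) break
    reach <- union(reach, nxt)
  }
  expect_setequal(reach, model_ids())
})

test_that("selection rules: empty kept set, dominance, order invariance", {
  cand <- asym_candidates()
  # all BF below threshold: vanilla wins
  lm <- setNames(c(0, log(2), log(1.5), log(3), log(1.1)), cand)
  expect_equal(select_preferred_model(lm)$preferred, "M0")
  # one dominant model wins regardless of table order
  lm2 <- setNames(c(0, log(50), log(2), log(200), log(8)), cand)
  s1 <- select_preferred_model(lm2)
  expect_equal(s1$preferred, "Ma_vmvp")
  perm <- sample(length(lm2))
  expect_equal(select_preferred_model(lm2[perm])$preferred, "Ma_vmvp")
  # a complex model must also beat its kept simpler parent
  lm3 <- setNames(c(0, log(50), log(2), log(100), log(8)), cand)
  # Ma_vmvp has BF 2 over kept parent Ma_vm -> pruned; Ma_vm wins
  expect_equal(select_preferred_model(lm3)$preferred, "Ma_vm")
  # missing marginal errors and names the model
  lm4 <- lm2; lm4["Ma_vp"] <- NA
  expect_error(select_preferred_model(lm4), "Ma_vp")
})

test_that("parsimony tie-break prefers the simpler of near-tied models", {
  cand <- c("M0", "Ma_vm", "Ma_vmvp")
  lm <- setNames(c(0, log(40), log(40 * 3.3)), cand)
  se <- setNames(c(0, 0.1, 2), cand)
  # Ma_vmvp beats Ma_vm by > 3.2 so survives, but its BF lead is within s.e.
  expect_equal(select_preferred_model(lm, se)$preferred, "Ma_vm")
  expect_equal(select_preferred_model(lm)$preferred, "Ma_vmvp")
})
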