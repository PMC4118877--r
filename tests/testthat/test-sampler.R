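# Sampler state handling: initialization, determinism, audits, joint
# likelihood closed forms, parameter estimation.

test_that("initialization is deterministic and audit-consistent", {
  set.seed(21)
  cp <- random_corpus(D = 6, W = 8)
  ctl <- atam_control(A = 3, Z = 2, iterations = 0)
  o1 <- atam_init(cp, NULL, ctl, seed = 99)
  o2 <- atam_init(cp, NULL, ctl, seed = 99)
  expect_identical(o1$a, o2$a)
  expect_identical(o1$tstate, o2$tstate)
  expect_true(all(o1$a %in% 1:3))
  expect_true(all(o1$tstate %in% 1:4))
  audit_state(o1)
  expect_error(atam_init(corpus_from_texts(character(0)), NULL, ctl),
               "empty corpus")
})

test_that("count conservation holds after initialization and sweeps on random corpora", {
  set.seed(22)
  for (r in 1:25) {
    cp <- random_corpus(D = sample(2:6, 1), W = sample(4:9, 1))
    ctl <- atam_control(A = sample(2:3, 1), Z = sample(2:3, 1),
                        iterations = 0, ll_every = 0)
    obj <- atam_init(cp, NULL, ctl)
    expect_true(audit_state(obj))
    obj <- gibbs_sweep(obj, 2)
    expect_true(audit_state(obj))
    lobj <- lda_init(cp, ctl)
    lobj <- gibbs_sweep(lobj, 2)
    expect_true(audit_state(lobj))
  }
})

test_that("sweeps are reproducible from the seed and degenerate dimensions behave", {
  set.seed(23)
  cp <- random_corpus(D = 5, W = 6)
  ctl <- atam_control(A = 2, Z = 2, iterations = 0, ll_every = 0)
  run <- function() {
    obj <- atam_init(cp, NULL, ctl, seed = 7)
    gibbs_sweep(obj, 5)
  }
  o1 <- run(); o2 <- run()
  expect_identical(o1$a, o2$a)
  expect_identical(o1$tstate, o2$tstate)
  # A = 1, Z = 1: the ailment cannot change; tokens still move over
  # {background, ailment, topic}
  ctl1 <- atam_control(A = 1, Z = 1, iterations = 0, ll_every = 0)
  obj <- atam_init(cp, NULL, ctl1, seed = 8)
  obj <- gibbs_sweep(obj, 3)
  expect_true(all(obj$a == 1L))
  expect_true(all(obj$tstate %in% 1:3))
  audit_state(obj)
})

test_that("collapsed joint log likelihood matches closed forms and the oracle", {
  # no active documents: every normalizer ratio cancels
  cp <- manual_corpus(list(1L), list(1L), W = 2)
  ctl <- atam_control(A = 3, Z = 2, lambda = 0.2, beta = 0.01,
                      iterations = 0)
  obj0 <- atam_init(cp, NULL, ctl, seed = 1, active = integer(0))
  expect_equal(joint_log_likelihood(obj0), 0)
  # single background token: log(1/A) + log(1 - lambda) + log(beta / (W beta))
  obj1 <- atam_init(cp, NULL, ctl, seed = 1)
  obj1 <- set_state(obj1, a = 2L, tstate = 1L)
  expect_equal(joint_log_likelihood(obj1),
               log(1 / 3) + log(0.8) + log(0.01 / 0.02))
  # random instances against the independent enumeration-free oracle
  set.seed(24)
  for (r in 1:10) {
    obj <- tiny_atam(A = 2, Z = 2)
    expect_equal(joint_log_likelihood(obj), oracle_atam_logjoint(obj),
                 tolerance = 1e-12)
    lobj <- tiny_lda(Z = 2)
    expect_equal(joint_log_likelihood(lobj), oracle_lda_logjoint(lobj),
                 tolerance = 1e-12)
  }
})

test_that("parameter estimates are posterior means of the collapsed counts", {
  # eta with ailment counts (3,1) and sigma = 1 -> (4/6, 2/6)
  cp <- manual_corpus(rep(list(integer(0)), 4), rep(list(integer(0)), 4),
                      W = 2)
  ctl <- atam_control(A = 2, Z = 2, sigma = 1, iterations = 0)
  obj <- atam_init(cp, NULL, ctl, seed = 2)
  obj <- set_state(obj, a = c(1L, 1L, 1L, 2L))
  est <- estimate_parameters(obj)
  expect_equal(est$eta, c(4, 2) / 6)
  # with no counts at all, estimates equal the prior means
  obj0 <- atam_init(cp, ailment_priors(rbind(c(.7, .3), c(.4, .6)), s = 10),
                    ctl, active = integer(0))
  est0 <- estimate_parameters(obj0)
  expect_equal(est0$eta, c(0.5, 0.5))
  expect_equal(est0$phi_A[1, 1, ], c(0.7, 0.3))
  expect_equal(est0$phi_A[2, 3, ], c(0.4, 0.6))
  expect_equal(est0$phi_T[1, ], c(0.5, 0.5))
  expect_equal(est0$phi_B[2, ], c(0.5, 0.5))
})

test_that("ailment word estimates approach the generating distributions with more data", {
  pars <- separated_params(A = 2, Z = 2, W = 40, block_mass = 0.9)
  m <- t(vapply(1:2, function(i)
    colSums(pars$aspect_probs[i, ] * pars$phi_A[i, , ]), numeric(40)))
  pri <- ailment_priors(m, s = 30)
  l1_at <- function(D, seed) {
    sim <- simulate_corpus(pars, D = D, N = 10, seed = seed)
    fit <- atam(sim$corpus, priors = pri,
                control = atam_control(A = 2, Z = 2, iterations = 150,
                                       ll_every = 0), seed = seed + 1)
    recovery_report(sim$truth, fit)$phi_A_l1
  }
  expect_lt(l1_at(600, 31), l1_at(60, 33))
})

test_that("LDA-bg with one topic and lambda 1 sends every token to that topic", {
  set.seed(25)
  cp <- random_corpus(D = 4, W = 5)
  obj <- lda_init(cp, atam_control(Z = 1, lambda = 1, iterations = 0,
                                   ll_every = 0))
  obj <- gibbs_sweep(obj, 1)
  expect_true(all(obj$tstate == 2L))
})
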