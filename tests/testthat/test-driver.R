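# Training orchestration: schedule allocation, incremental data, sharded
# pooling, checkpoint/resume.

test_that("schedule spends more sweeps on smaller data fractions and sums exactly", {
  s <- make_schedule(10, 10)
  expect_equal(s$fraction, seq(0.1, 1, by = 0.1))
  expect_equal(s$sweeps, rep(1L, 10))
  set.seed(51)
  for (r in 1:60) {
    inc <- sample(2:10, 1)
    total <- inc + sample.int(3000, 1)
    s <- make_schedule(total, inc)
    expect_equal(sum(s$sweeps), total)
    expect_true(all(diff(s$sweeps) <= 0))
    expect_true(all(s$sweeps >= 1L))
    expect_equal(s$fraction[inc], 1)
  }
  expect_error(make_schedule(5, 10))
  expect_error(make_schedule(10, 0))
})

test_that("extending with new documents is a no-op for none and audit-clean otherwise", {
  set.seed(52)
  for (r in 1:10) {
    cp <- random_corpus(D = 8, W = 8)
    ctl <- atam_control(A = 2, Z = 2, iterations = 0, ll_every = 0)
    obj <- atam_init(cp, NULL, ctl, active = 1:4)
    obj <- gibbs_sweep(obj, 3)
    same <- extend_data(obj, integer(0))
    expect_identical(same$a, obj$a)
    expect_identical(same$stats, obj$stats)
    obj2 <- extend_data(obj, 5:8)
    expect_true(all(!is.na(obj2$a)))
    expect_true(audit_state(obj2))
    expect_error(extend_data(obj2, 3L), "already active")
  }
})

test_that("greedy extension favours the background path when noise dominates", {
  set.seed(53)
  cp <- random_corpus(D = 6, W = 5)
  # lambda near 0: the background branch dominates every token conditional
  ctl <- atam_control(A = 1, Z = 1, lambda = 1e-4, iterations = 0,
                      ll_every = 0)
  obj <- atam_init(cp, NULL, ctl, active = 1:3)
  obj <- gibbs_sweep(obj, 2)
  obj <- extend_data(obj, 4:6, mode = "argmax")
  new_tokens <- unlist(lapply(4:6, function(d) {
    ptr <- obj$flat$doc_ptr
    if (ptr[d] < ptr[d + 1]) obj$tstate[(ptr[d] + 1L):ptr[d + 1]]
    else integer(0)
  }))
  expect_true(all(new_tokens == 1L))
})

test_that("pooling with one shard is identical to a plain sweep", {
  set.seed(54)
  cp <- random_corpus(D = 8, W = 8)
  ctl <- atam_control(A = 2, Z = 2, iterations = 0, ll_every = 0)
  base <- atam_init(cp, NULL, ctl, seed = 55)
  o1 <- gibbs_sweep({set.seed(56); base}, 3)
  set.seed(56)
  o2 <- pooled_sweep(base, shards = 1L, nsweeps = 3)
  expect_identical(o1$a, o2$a)
  expect_identical(o1$tstate, o2$tstate)
  expect_equal(o1$stats, o2$stats)
})

test_that("multi-shard pooling rebuilds global tables exactly and allows empty shards", {
  set.seed(57)
  cp <- random_corpus(D = 10, W = 8)
  ctl <- atam_control(A = 2, Z = 3, iterations = 0, ll_every = 0)
  obj <- atam_init(cp, NULL, ctl)
  obj <- pooled_sweep(obj, shards = 3L, nsweeps = 2)
  expect_true(audit_state(obj))
  obj <- pooled_sweep(obj, shards = list(1:5, 6:10, integer(0)))
  expect_true(audit_state(obj))
  expect_error(pooled_sweep(obj, shards = list(1:6, 6:10)), "overlap")
  expect_error(pooled_sweep(obj, shards = list(1:5, 7:10)), "cover")
})

test_that("training improves the joint likelihood and follows the increment schedule", {
  sim <- simulate_corpus(separated_params(A = 2, Z = 2, W = 40), D = 80,
                         N = 8, seed = 58)
  fit1 <- atam(sim$corpus,
               control = atam_control(A = 2, Z = 2, iterations = 40,
                                      min_group = 2, ll_every = 1),
               seed = 59)
  expect_gt(mean(tail(fit1$loglik, 3)), fit1$loglik[1])
  ctl <- atam_control(A = 2, Z = 2, iterations = 60, increments = 4,
                      min_group = 2, ll_every = 5)
  fit <- atam(sim$corpus, control = ctl, seed = 59)
  expect_true(all(!is.na(fit$a)))
  expect_true(audit_state(fit))
  expect_equal(fit$sweeps_done, 60L)
  # more sweeps are spent on smaller fractions
  expect_true(all(diff(fit$plan$sweeps) <= 0))
})

test_that("checkpoint plus resume reproduces the uninterrupted run bit-exactly", {
  sim <- simulate_corpus(separated_params(A = 2, Z = 2, W = 30), D = 40,
                         N = 6, seed = 60)
  dir <- withr::local_tempdir()
  ctl_ck <- atam_control(A = 2, Z = 2, iterations = 40, min_group = 2,
                         ll_every = 2, checkpoint_every = 20,
                         checkpoint_dir = dir)
  full <- atam(sim$corpus, control = ctl_ck, seed = 61)
  mid <- file.path(dir, "checkpoint-000020.json")
  expect_true(file.exists(mid))
  resumed <- atam_resume(mid, sim$corpus)
  expect_identical(resumed$a, full$a)
  expect_identical(resumed$tstate, full$tstate)
  expect_equal(resumed$loglik, full$loglik)
  expect_equal(resumed$alpha, full$alpha)
  expect_equal(resumed$s, full$s)
  # a wrong corpus is rejected by the vocabulary hash
  other <- corpus_from_texts(c("completely different words here"))
  expect_error(load_checkpoint(mid, other), "does not match")
})

test_that("prediction assigns held-out documents without touching the fit", {
  pars <- separated_params(A = 2, Z = 2, W = 40)
  sim <- simulate_corpus(pars, D = 150, N = 10, seed = 62)
  m <- t(vapply(1:2, function(i)
    colSums(pars$aspect_probs[i, ] * pars$phi_A[i, , ]), numeric(40)))
  fit <- atam(sim$corpus, priors = ailment_priors(m, s = 50),
              control = atam_control(A = 2, Z = 2, iterations = 120,
                                     ll_every = 0), seed = 63)
  new <- simulate_corpus(pars, D = 60, N = 10, seed = 64)
  rep_fit <- recovery_report(sim$truth, fit)
  relabel <- integer(2)
  relabel[rep_fit$ailment_perm] <- 1:2
  pred <- predict(fit, new$corpus)
  expect_length(pred, 60L)
  expect_gt(mean(relabel[pred] == new$truth$a), 0.5)
})
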