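# Generator limits, component matching, recovery scoring.

perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(p >= i, p + 1L, p))))
}

test_that("generator limits follow the generative story", {
  pars <- separated_params(A = 2, Z = 2, W = 30)
  p0 <- atam_params(eta = pars$eta, alpha = pars$alpha, phi_A = pars$phi_A,
                    phi_T = pars$phi_T, phi_B = pars$phi_B, lambda = 0)
  sim0 <- simulate_corpus(p0, D = 30, N = 6, seed = 71)
  expect_true(all(sim0$truth$tstate == 1L))  # everything background
  p1 <- atam_params(eta = c(1, 0), alpha = pars$alpha, phi_A = pars$phi_A,
                    phi_T = pars$phi_T, phi_B = pars$phi_B, lambda = 0.5)
  sim1 <- simulate_corpus(p1, D = 30, N = 6, seed = 72)
  expect_true(all(sim1$truth$a == 1L))
  expect_error(atam_params(eta = c(0.5, 0.5), alpha = pars$alpha,
                           phi_A = pars$phi_A[1, , , drop = FALSE],
                           phi_T = pars$phi_T, phi_B = pars$phi_B))
})

test_that("empirical word marginals match the implied mixture", {
  set.seed(73)
  A <- 2; Z <- 2; W <- 24
  pars <- atam_params(eta = c(0.6, 0.4),
                      alpha = rbind(c(2, 0.5), c(0.5, 2)),
                      phi_A = array(rdir(A * 3, rep(0.6, W)), c(A, 3, W)),
                      phi_T = rdir(Z, rep(0.6, W)),
                      phi_B = rdir(3, rep(0.6, W)),
                      lambda = 0.3)
  # theta has mean alpha_i / sum(alpha_i); pi has mean 1/2 under Beta(1,1)
  abar <- pars$alpha / rowSums(pars$alpha)
  marg <- numeric(W)
  for (i in 1:A) for (j in 1:3) {
    mix <- (1 - pars$lambda) * pars$phi_B[j, ] +
      pars$lambda * (0.5 * pars$phi_A[i, j, ] +
                       0.5 * colSums(abar[i, ] * pars$phi_T))
    marg <- marg + pars$eta[i] * pars$aspect_probs[i, j] * mix
  }
  sim <- simulate_corpus(pars, D = 10000, N = 10, seed = 74)
  cnt <- tabulate(unlist(sim$corpus$word), W)
  n <- sum(cnt)
  se <- sqrt(marg * (1 - marg) / n)
  expect_true(all(abs(cnt / n - marg) <= 3 * se))
})

test_that("lexicon-mediated generation reproduces aspects through keyphrase matching", {
  pars <- separated_params(A = 2, Z = 2, W = 30)
  sim <- simulate_corpus(pars, D = 40, N = 8, seed = 75, lexicon_mode = TRUE)
  expect_false(is.null(sim$lexicon))
  relabeled <- unlist(lapply(sim$corpus$surface, label_aspects,
                             lexicon = sim$lexicon))
  expect_identical(relabeled, sim$truth$y)
  expect_identical(unlist(sim$corpus$aspect), sim$truth$y)
})

test_that("component matching finds the optimal permutation", {
  set.seed(76)
  true <- rdir(4, rep(0.5, 12))
  shuffle <- sample(4)
  est <- true[shuffle, ]
  p <- match_components(true, est)
  expect_equal(as.integer(p), order(shuffle))
  expect_equal(attr(p, "cost"), 0)
  # 2x2 distance-matrix example: identity permutation, cost 0.2
  t2 <- rbind(c(1, 0), c(0, 1))
  e2 <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  p2 <- match_components(t2, e2)
  expect_equal(as.integer(p2), c(1L, 2L))
  expect_equal(attr(p2, "cost"), 0.2)
  expect_error(match_components(t2, rbind(e2, e2)), "equal dimensions")
  # agrees with exhaustive search for up to 6 components
  for (n in 2:6) {
    a <- rdir(n, rep(0.4, 8))
    b <- rdir(n, rep(0.4, 8))
    cost <- outer(seq_len(n), seq_len(n),
                  Vectorize(function(i, j) sum(abs(a[i, ] - b[j, ]))))
    best <- min(apply(perms(n), 1, function(pp)
      sum(cost[cbind(seq_len(n), pp)])))
    expect_equal(attr(match_components(a, b), "cost"), best)
  }
})

test_that("recovery scoring is exact in the perfect and maximally-wrong cases", {
  pars <- separated_params(A = 2, Z = 2, W = 20)
  sim <- simulate_corpus(pars, D = 20, N = 5, seed = 77)
  fit <- atam_init(sim$corpus, NULL,
                   atam_control(A = 2, Z = 2, iterations = 0), seed = 78)
  # estimates identical to the truth: accuracy 1, all distances 0
  fit$a <- sim$truth$a
  fit$est_accum <- list(eta = pars$eta, pi = NULL, theta = NULL,
                        phi_T = pars$phi_T, phi_A = pars$phi_A,
                        phi_B = pars$phi_B)
  rep1 <- recovery_report(sim$truth, fit)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$phi_A_l1, 0)
  expect_equal(rep1$phi_T_l1, 0)
  expect_equal(rep1$eta_abs_err, 0)
  # uniform estimates against one-hot truths: L1 = 2(W-1)/W per row
  W <- 20
  onehot <- function(k) { v <- rep(0, W); v[k] <- 1; v }
  pars2 <- atam_params(eta = c(1, 0),
                       alpha = pars$alpha,
                       phi_A = array(t(sapply(1:6, onehot)), c(2, 3, W)),
                       phi_T = rbind(onehot(7), onehot(8)),
                       phi_B = rbind(onehot(9), onehot(10), onehot(11)))
  sim2 <- simulate_corpus(pars2, D = 10, N = 4, seed = 79)
  fit2 <- atam_init(sim2$corpus, NULL,
                    atam_control(A = 2, Z = 2, iterations = 0), seed = 80)
  fit2$a <- sim2$truth$a
  fit2$est_accum <- list(eta = c(0.5, 0.5), pi = NULL, theta = NULL,
                         phi_T = matrix(1 / W, 2, W),
                         phi_A = array(1 / W, c(2, 3, W)),
                         phi_B = matrix(1 / W, 3, W))
  rep2 <- recovery_report(sim2$truth, fit2)
  expect_equal(rep2$phi_A_l1, 2 * (W - 1) / W)
  expect_equal(rep2$phi_T_l1, 2 * (W - 1) / W)
})

test_that("the phi_A array built by simulation respects its dimensions", {
  pars <- separated_params(A = 3, Z = 2, W = 33)
  expect_equal(dim(pars$phi_A), c(3L, 3L, 33L))
  expect_true(all(abs(apply(pars$phi_A, c(1, 2), sum) - 1) < 1e-12))
  expect_true(all(abs(rowSums(pars$phi_T) - 1) < 1e-12))
})
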