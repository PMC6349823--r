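test_that("Jacobian factors have the documented shapes and are deterministic", {
  fm <- tiny_fm()
  s <- c(0.3, 0.7, 0.1, -0.2)
  jac <- build_jacobians(fm, s)
  expect_equal(dim(jac$A), c(4, 4))
  expect_equal(dim(jac$B), c(2, 4, 4))
  expect_equal(dim(jac$C), c(4, 2))
  expect_length(jac$o, 4)
  expect_identical(jac, build_jacobians(fm, s))
  # scalar-offset variant broadcasts o to all four coordinates
  fm1 <- tiny_fm(o_dim = 1)
  expect_length(build_jacobians(fm1, s)$o, 4)
  expect_equal(length(unique(build_jacobians(fm1, s)$o)), 1L)
})

test_that("the assembled mean is exactly linear in the action", {
  fm <- tiny_fm()
  set.seed(1)
  s <- rand_state()
  a <- c(0.8, -1.2)
  jac <- build_jacobians(fm, s)
  eps <- 1e-5
  for (i in 1:2) {
    da <- c(0, 0); da[i] <- eps
    fd <- (predict_forward(fm, s, a + da)$mean -
             predict_forward(fm, s, a - da)$mean) / (2 * eps)
    expected <- jac$C[, i] + drop(jac$B[i, , ] %*% s)
    expect_equal(fd, expected, tolerance = 1e-6)
  }
})

test_that("A + sum_i a_i B_i is the state Jacobian of the local affine map", {
  fm <- tiny_fm()
  set.seed(2)
  s <- rand_state()
  a <- c(-0.4, 1.6)
  jac <- build_jacobians(fm, s)
  f_frozen <- function(ss)
    drop((jac$A + a[1] * jac$B[1, , ] + a[2] * jac$B[2, , ]) %*% ss +
           jac$C %*% a) + jac$o
  J_expected <- jac$A + a[1] * jac$B[1, , ] + a[2] * jac$B[2, , ]
  eps <- 1e-6
  J_fd <- sapply(1:4, function(j) {
    ds <- numeric(4); ds[j] <- eps
    (f_frozen(s + ds) - f_frozen(s - ds)) / (2 * eps)
  })
  expect_equal(J_fd, J_expected, tolerance = 1e-6)
})

test_that("identity dynamics give mean = s and covariance sigma^2 I", {
  fm <- tiny_fm(sigma_s = 0.1)
  fm$net <- zero_net(fm$net)
  fm$net$par$b_A <- as.vector(diag(4))  # A = I, B = C = o = 0
  s <- c(0.2, 0.9, -0.3, 0.5)
  b <- predict_forward(fm, s, c(1.3, -0.7))
  expect_equal(b$mean, s)
  expect_equal(b$cov, 0.01 * diag(4))
})

test_that("zero action gives covariance A Sigma A'", {
  fm <- tiny_fm(sigma_s = 0.05)
  s <- rand_state()
  jac <- build_jacobians(fm, s)
  b <- predict_forward(fm, s, c(0, 0))
  expect_equal(b$cov, 0.05^2 * tcrossprod(jac$A), tolerance = 1e-12)
})

test_that("sampled forward beliefs reproduce J Sigma J'", {
  fm <- tiny_fm(sigma_s = 0.5)
  set.seed(9)
  s <- rand_state()
  a <- c(1.1, 0.3)
  b <- predict_forward(fm, s, a)
  X <- sample_belief(b, 1e5)
  expect_equal(colMeans(X), b$mean, tolerance = 0.02)
  expect_equal(cov(X), b$cov, tolerance = 0.05)
})

test_that("Householder matrices are orthogonal reflections", {
  expect_equal(householder_orthogonal(c(1, 0, 0, 0)), diag(c(-1, 1, 1, 1)))
  set.seed(4)
  for (i in 1:20) {
    u <- rnorm(4)
    H <- householder_orthogonal(u)
    expect_equal(H %*% t(H), diag(4), tolerance = 1e-12)
    expect_equal(H, t(H), tolerance = 1e-12)
    expect_equal(det(H), -1, tolerance = 1e-10)
    x <- rnorm(4)
    expect_equal(sqrt(sum((H %*% x)^2)), sqrt(sum(x^2)), tolerance = 1e-10)
    expect_equal(householder_orthogonal(2 * u), H, tolerance = 1e-12)
  }
  expect_error(householder_orthogonal(c(0, 0, 0, 0)), "nonzero")
})

test_that("meta covariance is H D H' with spectrum d", {
  mm <- tiny_mm()
  # force d = (1, 1, 1, 1): covariance is I regardless of u
  mm1 <- mm
  mm1$d <- zero_net(mm1$d)
  mm1$d$par$b_out <- rep(log(exp(1) - 1), 4)  # softplus^-1(1)
  b <- meta_predict(mm1, c(0.5, 0.2, 0, 0))
  expect_equal(b$cov, diag(4), tolerance = 1e-12)
  # d = (4, 1, 1, 1), u = e1: covariance diag(4, 1, 1, 1)
  mm2 <- mm1
  mm2$d$par$b_out <- log(exp(c(4, 1, 1, 1)) - 1)
  mm2$u <- zero_net(mm2$u)
  mm2$u$par$b_out <- c(1, 0, 0, 0)
  b2 <- meta_predict(mm2, c(0.5, 0.2, 0, 0))
  expect_equal(b2$cov, diag(c(4, 1, 1, 1)), tolerance = 1e-10)
  # generic state: eigenvalues equal d up to ordering, covariance symmetric
  set.seed(6)
  for (i in 1:10) {
    s <- rand_state()
    b3 <- meta_predict(mm, s)
    expect_equal(b3$cov, t(b3$cov), tolerance = 1e-10)
    expect_equal(sort(eigen(b3$cov, symmetric = TRUE)$values), sort(b3$d),
                 tolerance = 1e-6)
    expect_true(all(b3$d > 0))
  }
})

test_that("the covariance construction is invariant to flipping u", {
  set.seed(8)
  d <- exp(rnorm(4))
  u <- rnorm(4)
  expect_equal(hhvg:::.meta_cov(d, u)$cov, hhvg:::.meta_cov(d, -u)$cov,
               tolerance = 1e-12)
})

test_that("closed-form Gaussian KL matches its special cases", {
  p <- gaussian_belief(rep(0, 4), diag(4))
  expect_equal(gaussian_kl(p, p, jitter = 0), 0)
  mu <- c(1, -2, 0.5, 0)
  q <- gaussian_belief(mu, diag(4))
  expect_equal(gaussian_kl(p, q, jitter = 0), sum(mu^2) / 2)
  set.seed(10)
  for (i in 1:200) {
    a <- rand_belief()
    b <- rand_belief()
    expect_gte(gaussian_kl(a, b, jitter = 0), 0)
  }
  sing <- gaussian_belief(rep(0, 4), matrix(0, 4, 4))
  expect_error(gaussian_kl(p, sing, jitter = 0), "jitter")
})

test_that("closed-form KL agrees with a Monte-Carlo estimate", {
  res <- kl_mc_check(n_pairs = 3, n_samples = 2e5, seed = 2)
  expect_true(all(abs(res$closed_form - res$mc) < 4 * res$se))
})

test_that("devaluation objective composes the forward and meta beliefs", {
  fm <- tiny_fm()
  mm <- tiny_mm()
  s <- c(0.4, 0.6, 0.2, -0.1)
  a <- c(0.8, -0.4)
  expect_equal(devaluation_objective(fm, mm, s, a),
               gaussian_kl(predict_forward(fm, s, a), meta_predict(mm, s)))
  expect_gte(devaluation_objective(fm, mm, s, a), 0)
})

test_that("one devaluation step decreases the batch objective", {
  fm <- tiny_fm()
  mm <- tiny_mm()
  set.seed(12)
  S <- rand_state(16)
  Acc <- cbind(runif(16, -2, 2), runif(16, -2, 2))
  fmout <- hhvg:::.fm_predict_batch(fm, S, Acc)
  opts <- list(mu = adam_init(mm$mu$par), d = adam_init(mm$d$par),
               u = adam_init(mm$u$par))
  up <- hhvg:::.mm_update(mm, opts, fmout, S, lr = 1e-3, fm$sigma_s^2)
  kl_after <- hhvg:::.kl_pairs(fmout, hhvg:::.mm_outputs(up$mm, S),
                               fm$sigma_s^2)$kl
  expect_lt(mean(kl_after), mean(up$kl_before))
})
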