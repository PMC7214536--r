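test_that("the remodeling rate has the contractile fixed point", {
  expect_equal(rest_length_rate(l = 2.3, L = 1, gamma = 0.2, eps_c = 1.3), 0)
  expect_equal(rest_length_rate(l = 5, L = 1, gamma = 0, eps_c = 0), 0)
  expect_equal(rest_length_rate(l = 2, L = 1, gamma = 0.2, eps_c = 0), 0.2)
  expect_error(rest_length_rate(1, -1, 0.2, 0), "positive")
})

test_that("the theta update solves the linear relation exactly", {
  # stationary input stays stationary
  expect_equal(theta_update(2.3, 2.3, 1, dt = 0.5, gamma = 0.2, eps_c = 1.3), 1)
  # frozen-length benchmark against the closed-form linear solve
  expect_equal(theta_update(2, 2, 1, dt = 0.1, gamma = 0.2, eps_c = 0),
               (1 * (1 - 0.1 * 0.2 * 0.5) + 0.1 * 0.2 * 2) / (1 + 0.1 * 0.2 * 0.5),
               tolerance = 1e-12)
  expect_equal(theta_update(2, 2, 1, dt = 0.1, gamma = 0.2, eps_c = 0),
               1.019802, tolerance = 1e-6)
  expect_error(theta_update(1, 1, 1, dt = -1, gamma = 0.2, eps_c = 0), "positive")
})

test_that("theta = 0.5 is second order, theta = 1 first order vs the ODE", {
  l_fun <- function(t) 2 + 0.5 * sin(t)
  exact <- ode_rest_length(l_fun, L0 = 1, t_end = 1, gamma = 0.4, eps_c = 0.3,
                           dt = 1e-4)
  err <- function(theta, n) {
    dt <- 1 / n
    L <- 1
    for (k in seq_len(n)) {
      L <- theta_update(l_fun((k - 1) * dt), l_fun(k * dt), L, dt,
                        gamma = 0.4, eps_c = 0.3, theta = theta)
    }
    abs(L - exact)
  }
  ns <- c(8, 16, 32, 64)
  e05 <- sapply(ns, err, theta = 0.5)
  e10 <- sapply(ns, err, theta = 1)
  ord05 <- mean(log2(e05[-length(e05)] / e05[-1]))
  ord10 <- mean(log2(e10[-length(e10)] / e10[-1]))
  expect_gt(ord05, 1.8)
  expect_lt(abs(ord10 - 1), 0.35)
})

test_that("rest lengths stay positive under the stability precondition", {
  # positivity requires the explicit fraction of the step to be stable:
  # dt * gamma * (1 - theta) * (1 + eps_c) <= 1
  set.seed(4)
  for (i in 1:50) {
    L <- runif(1, 0.01, 5)
    l <- runif(1, 0, 5)
    gamma <- runif(1, 0, 1)
    eps_c <- runif(1, 0, 2)
    theta <- 0.5
    dt_max <- 1 / (gamma * (1 - theta) * (1 + eps_c))
    dt <- runif(1, 0.05, min(2, dt_max))
    Lp <- theta_update(l, l, L, dt = dt, gamma = gamma, eps_c = eps_c,
                       theta = theta)
    expect_gt(Lp, 0)
  }
})

test_that("for eps_c = 0 a step strain relaxes like a Maxwell element", {
  k_V <- 1; l <- 2; L <- 1
  tension <- numeric(60)
  for (k in 1:60) {
    L <- theta_update(l, l, L, dt = 0.25, gamma = 0.3, eps_c = 0)
    tension[k] <- k_V * (l - L)
  }
  expect_true(all(diff(tension) < 0))
  expect_lt(tension[60], 0.02 * (l - 1))
})
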