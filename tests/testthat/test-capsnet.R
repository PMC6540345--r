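test_that("squash preserves direction and maps norm n to n^2/(1+n^2)", {
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- squash(c(1, 0))
  expect_equal(sqrt(sum(v^2)), 0.5)
  expect_equal(v[2], 0)
  # saturation, against the closed form
  long <- squash(c(1000, 0))
  expect_lt(abs(sqrt(sum(long^2)) - 1), 1e-3)
  expect_equal(sqrt(sum(long^2)), 1000^2 / (1 + 1000^2))
  set.seed(3)
  for (i in 1:10) {
    s <- rnorm(5) * 10^runif(1, -2, 2)
    out <- squash(s)
    n <- sqrt(sum(s^2))
    expect_equal(sqrt(sum(out^2)), n^2 / (1 + n^2))
    expect_equal(out * (1 + n^2) / n, s) # same direction
    expect_lt(sqrt(sum(out^2)), 1)
  }
  expect_error(squash(c(1, NA)), "non-finite")
})

test_that("squash norm is monotone increasing in the input norm", {
  ns <- 10^seq(-3, 3, length.out = 50)
  out <- vapply(ns, function(n) sqrt(sum(squash(c(n, 0))^2)), numeric(1))
  expect_true(all(diff(out) > 0))
})

test_that("coupling coefficients are a softmax: uniform at start, sum to 1", {
  set.seed(7)
  uh <- array(rnorm(6 * 3 * 4), c(6, 3, 4))
  r <- dynamic_routing(uh, iterations = 4)
  expect_equal(r$c_history[[1]], matrix(1 / 3, 6, 3))
  for (cc in r$c_history) {
    expect_equal(unname(rowSums(cc)), rep(1, 6))
    expect_true(all(cc >= 0))
  }
  # a single higher capsule receives everything
  r1 <- dynamic_routing(array(rnorm(5 * 1 * 4), c(5, 1, 4)), iterations = 3)
  expect_equal(r1$c, matrix(1, 5, 1))
})

test_that("routing matches a hand-unrolled trace of the update equations", {
  # 2 lower capsules, 2 higher capsules, 2-d predictions: both lower
  # capsules agree with capsule A and oppose B
  uh <- array(0, c(2, 2, 2))
  uh[1, 1, ] <- c(1, 0.5); uh[2, 1, ] <- c(0.9, 0.6)   # toward A
  uh[1, 2, ] <- c(-1, 0.2); uh[2, 2, ] <- c(1, -0.4)   # conflicting for B
  sq <- function(s) { n2 <- sum(s^2); s * sqrt(n2) / (1 + n2) }
  b <- matrix(0, 2, 2)
  cc <- v <- NULL
  for (it in 1:3) {
    e <- exp(b)
    cc <- e / rowSums(e)
    v <- matrix(0, 2, 2)
    for (j in 1:2) v[j, ] <- sq(cc[1, j] * uh[1, j, ] + cc[2, j] * uh[2, j, ])
    for (i in 1:2) for (j in 1:2) b[i, j] <- b[i, j] + sum(uh[i, j, ] * v[j, ])
  }
  r <- dynamic_routing(uh, iterations = 3)
  expect_equal(r$c, cc, tolerance = 1e-14)
  expect_equal(r$v, v, tolerance = 1e-14)
  # agreement drives coupling toward A monotonically
  cA <- vapply(r$c_history, function(m) mean(m[, 1]), numeric(1))
  expect_true(all(diff(cA) > 0))
  expect_true(all(r$c[, 1] > 0.5))
})

test_that("margin loss hits its closed-form values at the hinge points", {
  cfg <- capsnet_config(conv_filters = 4, primary_channels = 4,
                        emotion_capsule_dim = 2, decoder_units = c(4, 4))
  expect_equal(margin_loss(matrix(c(0.9, 0.1), 1), 0L, cfg)$margin, 0)
  expect_equal(margin_loss(matrix(c(0.95, 0.05), 1), 0L, cfg)$margin, 0)
  expect_equal(margin_loss(matrix(c(0, 0), 1), 0L, cfg)$margin, 0.81)
  # wrong-class penalty: ||v|| = 1 for an absent class
  expect_equal(margin_loss(matrix(c(0.9, 1), 1), 0L, cfg)$margin,
               0.5 * 0.81)
  # batch averaging
  vn <- rbind(c(0.9, 0.1), c(0, 0))
  expect_equal(margin_loss(vn, c(0L, 0L), cfg)$margin, 0.81 / 2)
  expect_error(margin_loss(vn, c(0L, 2L), cfg), "class set")
})

test_that("total loss combines margin and weighted reconstruction", {
  cfg <- capsnet_config(conv_filters = 4, primary_channels = 4,
                        emotion_capsule_dim = 2, decoder_units = c(4, 4),
                        recon_weight = 5e-4)
  expect_equal(total_loss(list(margin = 0.2, reconstruction = 100), cfg), 0.25)
  cfg0 <- capsnet_config(conv_filters = 4, primary_channels = 4,
                         emotion_capsule_dim = 2, decoder_units = c(4, 4),
                         recon_weight = 0)
  expect_equal(total_loss(list(margin = 0.3, reconstruction = 50), cfg0), 0.3)
  expect_equal(total_loss(list(margin = 0.3, reconstruction = 0), cfg), 0.3)
})

test_that("the reference architecture honors its shape contract", {
  cfg <- capsnet_preset("model_A")
  expect_identical(cfg$conv_side, 16L)     # (18 - 3)/1 + 1
  expect_identical(cfg$primary_side, 7L)   # (16 - 3)/2 + 1
  expect_identical(cfg$n_primary, 49L)
  model <- capsnet_init(cfg)
  fw <- capsnet_forward(model, array(runif(18 * 18), c(1, 18, 18)))
  expect_equal(fw$shapes$conv, c(16, 16, 256))
  expect_equal(fw$shapes$primary, c(49, 256))
  expect_equal(fw$shapes$emotion, c(2, 32))
  expect_identical(ncol(fw$recon), 324L)
  expect_identical(dim(fw$v), c(1L, 2L, 32L))
  expect_true(all(fw$v_norm > 0 & fw$v_norm < 1))
})

test_that("capsule-type grouping reshapes the primary volume correctly", {
  cfg <- capsnet_preset("model_C")
  expect_identical(cfg$conv_side, 10L)    # (18 - 9)/1 + 1
  expect_identical(cfg$primary_side, 4L)  # (10 - 3)/2 + 1
  expect_identical(cfg$n_types, 32L)
  expect_identical(cfg$n_primary, 4L * 4L * 32L)
  model <- capsnet_init(cfg)
  fw <- capsnet_forward(model, matrix(runif(324), 18, 18))
  expect_equal(fw$shapes$primary, c(512, 8))
})

test_that("coupling sums to one for every sample inside a forward pass", {
  model <- capsnet_init(small_capsnet())
  fw <- capsnet_forward(model, array(runif(3 * 324), c(3, 18, 18)))
  expect_equal(unname(rowSums(fw$coupling)), rep(1, 3 * 49))
})

test_that("analytic gradients match central finite differences", {
  # one routing iteration: the constant-coupling treatment is exact there
  cfg <- capsnet_config(conv_filters = 6, primary_channels = 8,
                        primary_capsule_dim = 8, emotion_capsule_dim = 4,
                        decoder_units = c(10, 12), routing_iterations = 1,
                        seed = 2)
  model <- capsnet_init(cfg)
  set.seed(9)
  X <- matrix(runif(4 * 324), 4, 324)
  y <- c(0L, 1L, 1L, 0L)
  gr <- eegcaps:::capsnet_grad(model, X, y)
  h <- 1e-5
  relu_mask <- function(m) {
    ca <- capsnet_forward(m, X, targets = y, keep_cache = TRUE)$cache
    list(ca$Z1 > 0, ca$H1 > 0, ca$H2 > 0)
  }
  checked <- 0L
  for (nm in names(model$params)) {
    set.seed(match(nm, names(model$params)))
    for (ki in sample(length(model$params[[nm]]),
                      min(4L, length(model$params[[nm]])))) {
      mp <- model; mp$params[[nm]][ki] <- mp$params[[nm]][ki] + h
      mm <- model; mm$params[[nm]][ki] <- mm$params[[nm]][ki] - h
      # skip probes whose perturbation crosses a ReLU kink, where the
      # finite difference itself is invalid
      if (!identical(relu_mask(mp), relu_mask(mm))) next
      fd <- (eegcaps:::capsnet_grad(mp, X, y)$loss -
             eegcaps:::capsnet_grad(mm, X, y)$loss) / (2 * h)
      an <- gr$grads[[nm]][ki]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-4)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 30L)
})

test_that("a small capsule net overfits clearly separated toy MFMs", {
  d <- toy_mfms(40, seed = 2)
  model <- capsnet_init(small_capsnet(seed = 5))
  model <- capsnet_train(model, d$x, d$y, epochs = 20, batch_size = 20)
  expect_gte(mean(predict(model, d$x) == d$y), 0.95)
  expect_identical(nrow(model$log), 20L)
  expect_true(all(model$log$margin >= 0))
  norms <- predict(model, d$x, type = "norm")
  expect_true(all(norms > 0 & norms < 1))
})

test_that("configuration validation rejects inconsistent geometry", {
  expect_error(capsnet_config(m_plus = 0.1, m_minus = 0.9), "below")
  expect_error(capsnet_config(routing_iterations = 0), ">= 1")
  expect_error(capsnet_config(primary_channels = 10, primary_capsule_dim = 4),
               "divide")
})
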