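test_that("bootstrap loss takes its closed-form values", {
  expect_equal(byol_loss(c(1, 2), c(2, 4)), 0)       # aligned
  expect_equal(byol_loss(c(1, 0), c(0, 3)), 2)       # orthogonal
  expect_equal(byol_loss(c(1, 0), c(-2, 0)), 4)      # antipodal
  # invariant to positive rescaling and symmetric in its arguments
  p <- c(0.3, -1.2, 2); z <- c(1.5, 0.4, -0.7)
  expect_equal(byol_loss(p, z), byol_loss(7 * p, z))
  expect_equal(byol_loss(p, z), byol_loss(p, 0.01 * z))
  expect_equal(byol_loss(p, z), byol_loss(z, p))
  expect_true(byol_loss(p, z) >= 0 && byol_loss(p, z) <= 4)
  expect_error(byol_loss(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(byol_loss(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("symmetrized loss adds the two view-swapped terms", {
  ov <- list(p = c(1, 0), z_target = c(2, 0))
  ovp <- list(p = c(3, 0), z_target = c(5, 0))
  expect_equal(symmetric_loss(ov, ovp), 0)
  # both cross terms orthogonal: p(v) against z'(v_prime) and vice versa
  ov2 <- list(p = c(1, 0), z_target = c(5, 0))
  ovp2 <- list(p = c(0, 2), z_target = c(0, 3))
  expect_equal(symmetric_loss(ov2, ovp2), 4)
  # first term aligned, second antipodal
  ov3 <- list(p = c(1, 0), z_target = c(1, 0))
  ovp3 <- list(p = c(-2, 0), z_target = c(1, 0))
  expect_equal(symmetric_loss(ov3, ovp3), 4)
})

test_that("EMA update interpolates and contracts geometrically", {
  th <- list(w = matrix(2, 2, 2), b = c(2, 2))
  xi <- list(w = matrix(0, 2, 2), b = c(0, 0))
  expect_equal(ema_update(th, xi, 1), xi)
  expect_equal(ema_update(th, xi, 0), th)
  expect_equal(ema_update(th, xi, 0.75)$b, c(0.5, 0.5))
  # ||xi_k - theta|| = tau^k ||xi_0 - theta|| under constant theta
  tau <- 0.9
  cur <- xi
  for (k in 1:5) {
    cur <- ema_update(th, cur, tau)
    expect_equal(sqrt(sum((cur$w - th$w)^2) + sum((cur$b - th$b)^2)),
                 tau^k * sqrt(sum(th$w^2) + sum(th$b^2)))
  }
  expect_error(ema_update(th, list(w = matrix(0, 3, 3), b = c(0, 0)), 0.5),
               "shapes|structure")
  expect_error(ema_update(th, xi, 1.5), "\\[0, 1\\]")
})

test_that("pretraining reduces the symmetric loss on structured patches", {
  x <- fixture_unlabeled_patches(6, seed = 31, max_patches = 64)
  cfg <- byol_config(batch_size = 16L, epochs = 3L, seed = 1L,
                     encoder_channels = c(4L, 6L, 8L, 8L), proj_dim = 16L)
  st <- pretrain(x, cfg)
  steps_per_epoch <- nrow(st$log) / 3
  first <- mean(st$log$loss[seq_len(steps_per_epoch)])
  last <- mean(st$log$loss[(nrow(st$log) - steps_per_epoch + 1):nrow(st$log)])
  expect_lt(last, first)
  expect_true(all(st$log$loss >= 0 & st$log$loss <= 8))
})

test_that("pretraining is deterministic and the target obeys the EMA contract", {
  x <- fixture_unlabeled_patches(3, seed = 32, max_patches = 24)
  cfg <- byol_config(batch_size = 8L, epochs = 1L, seed = 4L,
                     encoder_channels = c(3L, 4L, 4L, 4L), proj_dim = 8L)
  s1 <- pretrain(x, cfg)
  s2 <- pretrain(x, cfg)
  expect_identical(s1$online, s2$online)
  expect_identical(s1$log, s2$log)

  # tau = 1 freezes the target at its initialization (the online init copy);
  # gradient steps must move only the online branch
  cfg1 <- byol_config(batch_size = 8L, epochs = 1L, tau = 1, seed = 4L,
                      encoder_channels = c(3L, 4L, 4L, 4L), proj_dim = 8L)
  cfg0 <- cfg1; cfg0$epochs <- 0L
  init <- pretrain(x, cfg0)   # no steps: target == online initialization
  run <- pretrain(x, cfg1)
  expect_identical(run$target$encoder, init$target$encoder)
  expect_identical(run$target$projector, init$target$projector)
  expect_false(identical(run$online$encoder, init$online$encoder))

  expect_error(pretrain(list(), cfg), "non-empty|one patch")
})
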