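test_that("checklist score sums the three binary flags", {
  expect_identical(checklist_score(c(0, 0, 0)), 0L)
  expect_identical(checklist_score(c(1, 1, 1)), 3L)
  expect_identical(checklist_score(c(1, 0, 1)), 2L)
  expect_identical(checklist_score(rbind(c(0, 1, 0), c(1, 1, 0))),
                   c(1L, 2L))
  expect_error(checklist_score(c(1, 2, 0)), "binary")
})

test_that("ranking target follows the score ordering with 0.5 ties", {
  expect_equal(ranking_target(3, 1), 1)
  expect_equal(ranking_target(2, 2), 0.5)
  expect_equal(ranking_target(0, 3), 0)
  expect_equal(ranking_target(c(1, 2), c(2, 2)), c(0, 0.5))
  expect_error(ranking_target(4, 0), "0..3")
})

test_that("ranking loss has its closed-form values on simple pairs", {
  # equal scores, equal logits: P = Pbar = 0.5, the entropy of a fair coin
  expect_equal(ranking_loss(c(0.7, 0.7), c(2, 2)), log(2))
  # decisive pair with a +20 margin: C = log(1 + exp(-20))
  expect_equal(ranking_loss(c(20, 0), c(3, 0)), log1p(exp(-20)))
  expect_equal(ranking_loss(c(20, 0), c(3, 0)), 2.061154e-09,
               tolerance = 1e-6)
})

test_that("ranking loss matches the brute-force pair oracle", {
  set.seed(101)
  for (rep in 1:5) {
    f <- rnorm(16, sd = 2)
    s <- sample(0:3, 16, replace = TRUE)
    expect_equal(ranking_loss(f, s), oracle_ranking_loss(f, s),
                 tolerance = 1e-8)
  }
})

test_that("ranking loss is translation invariant and antisymmetry-consistent", {
  set.seed(102)
  f <- rnorm(10); s <- sample(0:3, 10, replace = TRUE)
  expect_equal(ranking_loss(f, s), ranking_loss(f + 37.5, s),
               tolerance = 1e-9)
  perm <- sample(10)
  expect_equal(ranking_loss(f, s), ranking_loss(f[perm], s[perm]),
               tolerance = 1e-12)
})

test_that("ranking loss decreases as a correctly ordered margin grows", {
  margins <- c(0.5, 1, 2, 4, 8)
  losses <- vapply(margins,
                   function(m) ranking_loss(c(m, 0), c(3, 0)), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("ranking loss on a sub-pair batch is zero with a warning", {
  expect_warning(l <- ranking_loss(1.5, 2), "at least 2")
  expect_equal(l, 0)
})

test_that("disease cross-entropy matches the per-sample oracle", {
  n <- 12
  expect_equal(disease_supervised_loss(matrix(0, 2, n),
                                       rep(c(0, 1), n / 2)), log(2))
  big <- rbind(rep(30, n), rep(-30, n))
  expect_lt(disease_supervised_loss(big, rep(1, n)), 1e-10)
  set.seed(103)
  for (rep in 1:5) {
    z <- matrix(rnorm(2 * n, sd = 3), 2, n)
    y <- sample(0:1, n, replace = TRUE)
    expect_equal(disease_supervised_loss(z, y), oracle_disease_ce(z, y),
                 tolerance = 1e-8)
  }
  expect_error(disease_supervised_loss(matrix(0, 2, 3), c(0, 1, 2)), "0/1")
})

test_that("feature BCE matches the elementwise oracle and honors weights", {
  n <- 10
  y <- matrix(rbinom(3 * n, 1, 0.5), 3, n)
  expect_equal(feature_supervised_loss(matrix(0, 3, n), y), log(2))
  set.seed(104)
  for (rep in 1:5) {
    z <- matrix(rnorm(3 * n, sd = 3), 3, n)
    y <- matrix(rbinom(3 * n, 1, 0.5), 3, n)
    expect_equal(feature_supervised_loss(z, y), oracle_feature_bce(z, y),
                 tolerance = 1e-8)
    w <- c(2, 1, 0.5)
    expect_equal(feature_supervised_loss(z, y, w),
                 oracle_feature_bce(z, y, w), tolerance = 1e-8)
  }
  # batch wrong only on asymmetry: emphasizing asymmetry raises the loss
  z <- rbind(rep(-4, n), rep(4, n), rep(4, n))
  y <- matrix(1, 3, n)
  expect_gt(feature_supervised_loss(z, y, c(2, 1, 1)),
            feature_supervised_loss(z, y, c(1, 1, 1)))
  expect_error(feature_supervised_loss(z, y, c(-1, 1, 1)), "nonnegative")
})

test_that("consistency loss is an MSE between predicted distributions", {
  set.seed(105)
  st <- random_outputs(8)
  expect_equal(consistency_loss(st, st), 0)
  # disease softmaxes (1,0) vs (0.5,0.5): mean squared difference 0.25
  a <- list(disease_logits = matrix(c(40, 0), 2, 1),
            feature_logits = matrix(0, 3, 1))
  b <- list(disease_logits = matrix(c(0, 0), 2, 1),
            feature_logits = matrix(0, 3, 1))
  expect_equal(consistency_loss(a, b, mode = "disease_only"), 0.25,
               tolerance = 1e-10)
  for (rep in 1:5) {
    st <- random_outputs(8); te <- random_outputs(8)
    expect_equal(consistency_loss(st, te),
                 oracle_consistency_mse(st, te), tolerance = 1e-8)
  }
  expect_gt(consistency_loss(random_outputs(4), random_outputs(4)), 0)
})

test_that("combined loss selects and weights the enabled terms", {
  parts <- list(dsl = 0.2, fsl = 0.3, rl = 0.1, cl = 0.05)
  expect_equal(combined_loss(parts, loss_weights(1, 1, 1, 1)), 0.65)
  expect_equal(combined_loss(parts, loss_weights(1, 0, 0, 0)), 0.2)
  # disabled terms may be absent entirely
  expect_equal(combined_loss(list(dsl = 0.4, fsl = NA, rl = NA, cl = NA),
                             loss_weights(1, 0, 0, 0)), 0.4)
  expect_error(combined_loss(list(dsl = NA, fsl = 1, rl = 1, cl = 1),
                             loss_weights(1, 1, 1, 1)), "dsl")
  expect_error(loss_weights(0, 0, 0, 0))
})

test_that("analytic loss gradients match central finite differences", {
  # probe backbone: one convolution + the two heads
  m <- build_model("probe", seed = 31)
  set.seed(106)
  x <- array(runif(3 * 8 * 8 * 4), c(3, 8, 8, 4))
  y_dis <- c(1, 0, 1, 0)
  y_fea <- matrix(rbinom(12, 1, 0.5), 3, 4)
  scores <- c(3, 0, 2, 1)
  teacher <- m$teacher
  teacher$head_d.W <- teacher$head_d.W + 0.3   # make CL nonzero

  loss_of <- function(params) {
    out <- model_forward(m, x, params = params)
    t_out <- model_forward(m, x, params = teacher)
    disease_supervised_loss(out$disease_logits, y_dis) +
      feature_supervised_loss(out$feature_logits, y_fea) +
      ranking_loss(out$disease_logits[1, ], scores) +
      consistency_loss(out, t_out)
  }

  out <- model_forward(m, x, keep_cache = TRUE)
  t_out <- model_forward(m, x, params = teacher)
  rd <- disease_supervised_loss(out$disease_logits, y_dis, grad = TRUE)
  rf <- feature_supervised_loss(out$feature_logits, y_fea, grad = TRUE)
  rr <- ranking_loss(out$disease_logits[1, ], scores, grad = TRUE)
  rc <- consistency_loss(out, t_out, grad = TRUE)
  d_dis <- rd$grad + rc$grad_disease
  d_dis[1, ] <- d_dis[1, ] + rr$grad
  d_fea <- rf$grad + rc$grad_feature
  grads <- dermrank:::model_backward(m, x, out, d_dis, d_fea)

  eps <- 1e-5
  for (nm in names(m$params)) {
    pv <- m$params
    gn <- m$params[[nm]] * 0
    for (i in seq_along(gn)) {
      pv[[nm]][i] <- m$params[[nm]][i] + eps
      lp <- loss_of(pv)
      pv[[nm]][i] <- m$params[[nm]][i] - eps
      lm <- loss_of(pv)
      pv[[nm]][i] <- m$params[[nm]][i]
      gn[i] <- (lp - lm) / (2 * eps)
    }
    rel <- max(abs(grads[[nm]] - gn)) / max(max(abs(gn)), 1e-6)
    expect_lt(rel, 1e-4)
  }
})
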