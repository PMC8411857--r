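test_that("a single archetype is the column mean and seeds are reproducible", {
  for (s in 1:3) {
    set.seed(100 + s)
    X <- matrix(rnorm(30 * 6, sd = 3), 30, 6)
    m <- fit_archetypes(X, 1, seed = s)
    expect_lt(max(abs(m$archetypes[1, ] - colMeans(X))), 1e-6)
    expect_equal(unname(m$relative_weight), 1)
  }
  X <- matrix(rnorm(40 * 5), 40, 5)
  m1 <- fit_archetypes(X, 3, seed = 9)
  m2 <- fit_archetypes(X, 3, seed = 9)
  expect_identical(m1$rss, m2$rss)
  expect_identical(m1$archetypes, m2$archetypes)
})

test_that("archetypes recover the vertices of a sampled triangle", {
  set.seed(5)
  V <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  W <- matrix(rgamma(200 * 3, 0.3), 200, 3)
  W <- W / rowSums(W)
  X <- W %*% V
  m <- fit_archetypes(X, 3, seed = 5)
  # each vertex has a fitted archetype within 0.5 data units
  dmin <- apply(V, 1, function(v) {
    min(sqrt(rowSums((m$archetypes - matrix(v, 3, 2, byrow = TRUE))^2)))
  })
  expect_lt(max(dmin), 0.5)
})

test_that("fit input contracts are enforced", {
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_archetypes(X, 6), "exceeds")
  expect_warning(fit_archetypes(X, 5, seed = 1), "equals")
  X[1, 1] <- NA
  expect_error(fit_archetypes(X, 2), "finite")
})

test_that("the training objective is nonincreasing and archetypes ordered", {
  set.seed(12)
  sim <- simulate_mixture(120, planted4(), 0.3, 1, seed = 12)
  m <- fit_archetypes(sim$td, 4, seed = 12)
  h <- m$rss_history
  expect_true(all(diff(h) <= 1e-6 * pmax(1, h[-length(h)])))
  expect_true(all(diff(m$relative_weight) <= 1e-12))
  expect_true(all(m$relative_weight >= 0))
  expect_equal(sum(m$relative_weight), 1, tolerance = 1e-9)
  expect_equal(unname(m$average_td), unname(rowMeans(m$archetypes)))
})

test_that("every archetype lies in the convex hull of the training rows", {
  set.seed(13)
  sim <- simulate_mixture(80, planted4(), 0.3, 1.5, seed = 13)
  m <- fit_archetypes(sim$td, 3, seed = 13)
  # decompose Z against the training rows: residual must be ~0
  hull_model <- structure(list(
    k = nrow(sim$td), archetypes = sim$td, M = m$M,
    grid = sprintf("generic/%d", ncol(sim$td))
  ), class = "archetype_model")
  d <- decompose(hull_model, m$archetypes)
  expect_lt(max(d$residual_norm), 1e-4)
})

test_that("decompose returns simplex weights matching identity and oracle", {
  set.seed(21)
  sim <- simulate_mixture(60, planted4(), 0.3, 1, seed = 21)
  m <- fit_archetypes(sim$td, 4, seed = 21)
  # identity case: a field equal to an archetype gets 100% on it
  d <- decompose(m, m$archetypes)
  expect_equal(unname(diag(d$weights)), rep(100, 4), tolerance = 1e-6)
  expect_lt(max(d$residual_norm), 1e-5)
  # any field: weights sum to 100
  d2 <- decompose(m, sim$td)
  expect_equal(unname(rowSums(d2$weights)), rep(100, 60), tolerance = 1e-6)
  expect_true(all(d2$weights >= -1e-9))
  # grid mismatch
  expect_error(decompose(m, matrix(0, 1, 10)), "grid mismatch")
  # brute-force simplex-grid oracle on a 2-coordinate toy model
  set.seed(22)
  Xt <- matrix(runif(40, -5, 5), 20, 2)
  mt <- fit_archetypes(Xt, 3, seed = 22)
  for (i in 1:5) {
    td <- runif(2, -6, 6)
    dt <- decompose(mt, td)
    obj_fit <- dt$residual_norm^2
    obj_grid <- simplex_grid_obj(mt$archetypes, td, step = 1e-3)
    expect_lt(abs(obj_fit - obj_grid), 1e-4)
  }
})

test_that("model_rss is consistent and additive", {
  set.seed(31)
  sim <- simulate_mixture(50, planted4(), 0.3, 1, seed = 31)
  m <- fit_archetypes(sim$td, 3, seed = 31)
  expect_equal(model_rss(sim$td, m), m$rss, tolerance = 1e-6)
  expect_lt(model_rss(m$archetypes, m), 1e-8)
  # duplicating a row adds exactly its residual contribution
  r1 <- model_rss(sim$td[1, , drop = FALSE], m)
  expect_equal(model_rss(rbind(sim$td, sim$td[1, ]), m), m$rss + r1,
               tolerance = 1e-8)
})

test_that("model JSON round trip preserves the fit exactly", {
  set.seed(41)
  sim <- simulate_mixture(40, planted4(), 0.3, 1, seed = 41)
  m <- fit_archetypes(sim$td, 3, seed = 41)
  tmp <- withr::local_tempfile(fileext = ".json")
  serialize_model(m, tmp)
  m2 <- load_model(tmp)
  expect_identical(m2$archetypes, m$archetypes)
  expect_identical(m2$relative_weight, m$relative_weight)
  expect_equal(model_rss(sim$td, m2), model_rss(sim$td, m))
  # k mismatch and version errors
  p <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  p$k <- 5
  jsonlite::write_json(p, tmp, auto_unbox = TRUE, digits = I(17))
  expect_error(load_model(tmp), "inconsistent")
  p$k <- 3; p$version <- "0.9"
  jsonlite::write_json(p, tmp, auto_unbox = TRUE, digits = I(17))
  expect_error(load_model(tmp), "version")
})

test_that("planted prototypes and mixing weights are recovered", {
  sim <- simulate_mixture(500, planted4(), 0.3, 1, seed = 77)
  m <- fit_archetypes(sim$td, 4, seed = 77)
  mm <- match_prototypes(planted4(), m$archetypes)
  expect_gte(mm$mean_cosine, 0.95)
  W <- decompose(m, sim$td)$weights[, mm$perm] / 100
  expect_gte(cor(as.vector(sim$weights), as.vector(W)), 0.9)
})
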