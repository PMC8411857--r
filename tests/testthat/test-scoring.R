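test_that("meaningful-weight calls are boundary-inclusive", {
  w <- c(91, 9, 0, 0)
  expect_equal(meaningful_archetypes(w, 9)[[1]], c(1L, 2L))
  expect_equal(meaningful_archetypes(c(5, 3, 92), 93)[[1]], integer(0))
  expect_equal(meaningful_archetypes(c(100, 0, 0), 9)[[1]], 1L)
  expect_error(meaningful_archetypes(w, 0), "positive")
  # count never exceeds floor(100 / threshold)
  set.seed(2)
  W <- matrix(rgamma(200 * 12, 0.5), 200, 12)
  W <- W / rowSums(W) * 100
  counts <- lengths(meaningful_archetypes(W, 9))
  expect_true(all(counts <= 11))
})

test_that("dominant archetypes require a unique majority weight", {
  expect_equal(dominant_archetype(c(57, 30, 13)), 1L)
  expect_true(is.na(dominant_archetype(c(49.9, 30, 20.1))))
  expect_warning(d <- dominant_archetype(c(50, 50, 0)), "tie")
  expect_true(is.na(d))
})

test_that("sign assignment splits archetypes by average TD", {
  mk_model <- function(avg_td) {
    k <- length(avg_td)
    Z <- matrix(avg_td, k, 4, dimnames = list(paste0("AT", 1:k), NULL))
    structure(list(k = k, archetypes = Z,
                   average_td = setNames(avg_td, paste0("AT", 1:k)),
                   relative_weight = rep(1 / k, k)),
              class = "archetype_model")
  }
  m14 <- mk_model(seq(2, -24, length.out = 14))
  s14 <- assign_signs(m14)
  expect_equal(sum(s14 == 1), 7)
  expect_equal(sum(s14 == -1), 7)
  # better average TD -> positive
  expect_true(all(s14[order(-m14$average_td)][1:7] == 1))
  m2 <- mk_model(c(1, -10))
  expect_equal(as.vector(unclass(assign_signs(m2))), c(1, -1))
  # odd k puts the median archetype positive
  m5 <- mk_model(c(0, -2, -5, -9, -20))
  expect_equal(sum(assign_signs(m5) == 1), 3)
  # explicit override
  se <- assign_signs(m5, rule = "explicit", positive = c("AT1", "AT4"))
  expect_equal(as.vector(unclass(se)), c(1, -1, -1, 1, -1))
  expect_error(assign_signs(m5, rule = "explicit", positive = "AT9"),
               "subset")
})

test_that("the signed archetype sum is the bounded composite", {
  signs <- structure(setNames(c(1, -1, -1), paste0("AT", 1:3)),
                     class = "sign_assignment")
  expect_equal(at_sum(c(100, 0, 0), signs), 100)
  expect_equal(at_sum(c(0, 100, 0), signs), -100)
  expect_equal(at_sum(c(50, 50, 0), signs), 0)
  expect_equal(at_sum(c(60, 25, 15), signs), 20)
  expect_error(at_sum(c(50, 50), signs), "covers")
  # bounded on arbitrary simplex weights
  set.seed(4)
  W <- matrix(rgamma(300, 0.4), 100, 3)
  W <- W / rowSums(W) * 100
  v <- at_sum(W, signs)
  expect_true(all(v >= -100 - 1e-6 & v <= 100 + 1e-6))
})

test_that("classification matching is set-based and symmetric", {
  expect_equal(match_classification(c("arcuate_inferior", "blind_spot_enlargement"),
                                    c("blind_spot_enlargement", "arcuate_inferior")),
               "exact")
  expect_equal(match_classification("general_depression_mild",
                                    c("arcuate_superior", "arcuate_inferior")),
               "different")
  expect_equal(match_classification(c("blind_spot_enlargement", "arcuate_inferior"),
                                    "blind_spot_enlargement"),
               "partial")
  # symmetry
  a <- c("nasal_defect", "normal"); b <- "nasal_defect"
  expect_equal(match_classification(a, b), match_classification(b, a))
  expect_error(match_classification(character(0), "normal"), "no feature tags")
})

test_that("cohort reports tabulate frequencies, counts and correlations", {
  set.seed(6)
  k <- 4
  n <- 120
  # construct weights where AT1 increases monotonically with a covariate
  u <- sort(runif(n))
  W <- cbind(60 * u + 5, 30 * (1 - u) + 5, 15, runif(n, 0, 10))
  W <- W / rowSums(W) * 100
  colnames(W) <- paste0("AT", 1:k)
  md <- -8 + 8 * u + rnorm(n, 0, 0.2)
  rep1 <- cohort_report(W, threshold = 9,
                        covariates = data.frame(md = md))
  expect_equal(nrow(rep1$frequencies), k)
  expect_equal(sum(rep1$meaningful_counts$n_fields), n)
  r_at1 <- rep1$correlations$r[rep1$correlations$variable == "AT1"]
  expect_gte(r_at1, 0.9)
  # constant weight -> correlation skipped with note
  Wc <- W; Wc[, 3] <- 15
  Wc <- Wc / rowSums(Wc) * 100
  Wc[, 3] <- 15  # force exact constancy
  rep2 <- cohort_report(Wc, threshold = 9,
                        covariates = data.frame(md = md))
  expect_match(rep2$correlations$note[rep2$correlations$variable == "AT3"],
               "skipped")
  # identical groups: Wilcoxon p ~ 1 and chi-square ~ 0
  Wg <- rbind(W, W)
  g <- rep(c("a", "b"), each = n)
  rep3 <- cohort_report(Wg, threshold = 9, group = g)
  expect_true(all(rep3$group_tests$p > 0.99))
  expect_lt(rep3$chisq$statistic, 1e-8)
  # archetype-sum correlation rows appear when signs are provided
  signs <- structure(setNames(c(1, 1, -1, -1), paste0("AT", 1:4)),
                     class = "sign_assignment")
  rep4 <- cohort_report(W, threshold = 9, signs = signs,
                        covariates = data.frame(md = md))
  expect_true("AT_sum" %in% rep4$correlations$variable)
})
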