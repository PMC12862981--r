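test_that("expected code matrix matches a naive double loop", {
  # 3 patients x 2 topics x 4 codes, arbitrary mixtures
  co <- mk_corpus(patient = c("p1", "p2", "p3"), modality = rep("ICD", 3),
                  code = c("E110", "E113", "C911"), count = c(1, 2, 1))
  co <- mk_corpus(patient = c("p1", "p1", "p2", "p3"),
                  modality = rep("ICD", 4),
                  code = c("E110", "C911", "E113", "Z999"), count = 1)
  seeds <- build_seed_map(tiny_map(), co, 1)
  st <- sage_init_state(co, seeds, beta = 0.4, mu = 0.3, seed = 2)
  set.seed(2)
  st$n$ICD[] <- runif(length(st$n$ICD), 0, 5)
  st$s <- st$smask * matrix(runif(length(st$s), 0, 2), nrow(st$s))
  st$n_col$ICD <- colSums(st$n$ICD)
  st$s_col <- colSums(st$s)
  st$pi[] <- c(0.7, 0.4)
  theta <- rbind(c(0.2, 0.8), c(0.5, 0.5), c(0.9, 0.1))
  got <- expected_icd_matrix(theta, st)
  tp <- expected_topics(st)
  V <- length(co$vocab$ICD)
  want <- matrix(0, 3, V)
  for (d in 1:3) for (j in 1:V) for (k in 1:2) {
    want[d, j] <- want[d, j] + theta[d, k] *
      (st$pi[k] * tp$phi_s[k, j] + (1 - st$pi[k]) * tp$phi_r$ICD[k, j])
  }
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_equal(unname(rowSums(got)), rep(1, 3), tolerance = 1e-9)
  # one-hot theta returns that topic's marginal word distribution
  hot <- expected_icd_matrix(rbind(c(1, 0)), st)
  expect_equal(unname(hot[1, ]),
               unname(st$pi[1] * tp$phi_s[1, ] +
                        (1 - st$pi[1]) * tp$phi_r$ICD[1, ]),
               tolerance = 1e-12)
})

test_that("calibration matches the IRLS oracle and preserves ranking", {
  set.seed(41)
  for (trial in 1:5) {
    n <- 400
    yt <- runif(n, 0, 0.05)
    y <- rbinom(n, 1, plogis(-2.5 + 60 * yt))
    if (sum(y) %in% c(0, n)) next
    f <- calibrate_code(y, yt)
    or <- suppressWarnings(glm(y ~ yt, family = binomial))
    expect_equal(f$slope, unname(coef(or)[2]), tolerance = 1e-6)
    expect_equal(f$intercept, unname(coef(or)[1]), tolerance = 1e-6)
    if (f$slope > 0) {
      expect_equal(cor(yt, f$yhat, method = "spearman"), 1)
    }
  }
})

test_that("label-independent features drive the slope toward zero", {
  set.seed(8)
  n <- 4000
  yt <- runif(n, 0, 1)
  y <- rbinom(n, 1, 0.3)  # independent of yt
  f <- calibrate_code(y, yt)
  expect_lt(abs(f$slope), 0.35)
  expect_equal(mean(f$yhat), mean(y), tolerance = 0.02)
})

test_that("constant and separable responses are flagged", {
  f0 <- calibrate_code(rep(0, 10), runif(10))
  expect_false(f0$converged)
  expect_equal(f0$yhat, f0$yhat)  # pass-through, no NA
  ysep <- rep(c(0, 1), each = 15)
  xsep <- c(runif(15, 0, 0.2), runif(15, 0.8, 1))
  fs <- calibrate_code(ysep, xsep)
  expect_equal(abs(fs$slope), 30)
  expect_false(fs$converged)
  # still monotone
  expect_equal(cor(xsep, fs$yhat, method = "spearman"), 1)
})

test_that("PheCode aggregation follows the noisy-OR and max closed forms", {
  co <- mk_corpus(patient = c("p1", "p2"), modality = rep("ICD", 2),
                  code = c("E110", "E113"), count = 1)
  seeds <- build_seed_map(tiny_map()[1:2, ], co, 1)  # one 2-code PheCode
  yhat <- rbind(p1 = c(0.5, 0.5), p2 = c(0.9, 0.1))
  colnames(yhat) <- co$vocab$ICD
  no <- aggregate_to_phecodes(yhat, seeds, rule = "noisy_or")
  mx <- aggregate_to_phecodes(yhat, seeds, rule = "max")
  expect_equal(unname(no$scores[, 1]), c(0.75, 1 - 0.1 * 0.9))
  expect_equal(unname(mx$scores[, 1]), c(0.5, 0.9))
  # expected sample sizes are column sums
  sc <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  expect_equal(unname(colSums(sc)), c(1.7, 0.3))
  expect_equal(unname(no$expected_n), unname(colSums(no$scores)),
               tolerance = 1e-12)
})

test_that("aggregation is monotone and order-invariant", {
  co <- mk_corpus(patient = c("p1", "p2"), modality = rep("ICD", 2),
                  code = c("E110", "E113"), count = 1)
  seeds <- build_seed_map(tiny_map()[1:2, ], co, 1)
  yhat <- rbind(p1 = c(0.3, 0.4), p2 = c(0.6, 0.2))
  colnames(yhat) <- co$vocab$ICD
  base <- aggregate_to_phecodes(yhat, seeds)$scores
  up <- yhat
  up[1, 1] <- 0.5
  expect_gte(aggregate_to_phecodes(up, seeds)$scores[1, 1], base[1, 1])
  perm <- aggregate_to_phecodes(yhat[2:1, ], seeds)
  expect_equal(unname(perm$expected_n),
               unname(aggregate_to_phecodes(yhat, seeds)$expected_n))
})

test_that("PLINK trait export round-trips and honors the threshold", {
  sc <- structure(list(
    scores = matrix(c(0.9123456, 0.1, 0.002, 0.001), 2, 2,
                    dimnames = list(c("p1", "p2"), c("250.2", "204.1"))),
    expected_n = c("250.2" = 1.0123456, "204.1" = 0.003),
    rule = "noisy_or", dropped_topics = character()),
    class = "sage_scores")
  path <- withr::local_tempfile(fileext = ".pheno")
  man <- export_quantitative_traits(sc, path = path, min_expected_n = 0.01)
  df <- read.table(path, header = TRUE)
  expect_equal(nrow(df), 2L)
  expect_equal(names(df), c("FID", "IID", "PHE_250.2"))
  expect_equal(df$PHE_250.2, c(0.912346, 0.1), tolerance = 1e-7)
  expect_false(man$included[man$phecode == "204.1"])
  # missing patients coded -9
  ids <- data.frame(FID = c("f1", "f2", "f3"), IID = c("i1", "i2", "i3"),
                    patient_id = c("p1", "p2", "ghost"))
  export_quantitative_traits(sc, ids, path = path)
  df2 <- read.table(path, header = TRUE)
  expect_equal(df2[3, 3], -9)
  expect_error(export_quantitative_traits(
    sc, data.frame(FID = 1:2, IID = c("a", "a"), patient_id = c("p1", "p2")),
    path = path), "duplicate IIDs")
})

test_that("end-to-end phenotype scores stay in [0,1] with consistent totals", {
  sim <- simulate_corpus(sim_config(D = 80, K = 3, V = c(40, 20, 20),
                                    seed = 23))
  pr <- fit_gmm_prior(phecode_count_matrix(sim$corpus, sim$seeds))
  fit <- sage(sim$corpus, sim$seeds, pr,
              control = sage_control(max_epochs = 5, seed = 2))
  sc <- phenotype_scores(fit, sim$corpus)
  expect_true(all(sc$scores >= 0 & sc$scores <= 1))
  expect_equal(unname(sc$expected_n), unname(colSums(sc$scores)),
               tolerance = 1e-6)
  expect_equal(nrow(sc$calibration), length(sim$corpus$vocab$ICD))
})
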