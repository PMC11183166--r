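test_that("permutation test degenerates correctly on identical groups", {
  x <- c(1.2, 3.4, 2.2, 0.8)
  r <- permutation_test_auc(x, x, n_perm = 200, seed = 1)
  expect_equal(r$observed, 0)
  expect_equal(r$p_value, 1)
})

test_that("permutation p is symmetric under group-label swap", {
  set.seed(2)
  a <- rnorm(8); b <- rnorm(8) + 0.7
  r1 <- permutation_test_auc(a, b, n_perm = 4000, seed = 5)
  r2 <- permutation_test_auc(b, a, n_perm = 4000, seed = 5)
  expect_equal(r1$observed, -r2$observed)
  expect_equal(r1$p_value, r2$p_value, tolerance = 0.03)
})

test_that("Monte-Carlo p matches exhaustive enumeration on 3 vs 3", {
  set.seed(3)
  a <- rnorm(3); b <- rnorm(3) + 1
  ex <- permutation_test_auc(a, b, exhaustive = "always")
  expect_equal(ex$n_perm, choose(6, 3))
  mc <- permutation_test_auc(a, b, n_perm = 20000, seed = 4,
                             exhaustive = "never")
  expect_lt(abs(mc$p_value - ex$p_value), 0.02)
})

test_that("permutation test is calibrated and powered", {
  # type-I error under a common distribution
  set.seed(6)
  n_rep <- 400
  rej <- 0
  for (i in seq_len(n_rep)) {
    a <- rnorm(10); b <- rnorm(10)
    rej <- rej + (permutation_test_auc(a, b, n_perm = 200)$p_value < 0.05)
  }
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(rej / n_rep, ci[1])
  expect_lte(rej / n_rep, ci[2])
  # power: 2-pooled-SD shift at n = 38 per group detected essentially always
  set.seed(7)
  hits <- 0
  for (i in 1:50) {
    a <- rnorm(38); b <- rnorm(38) + 2
    hits <- hits + (permutation_test_auc(a, b, n_perm = 500)$p_value < 0.05)
  }
  expect_gte(hits / 50, 0.99)
})

test_that("BH-FDR reproduces the hand-executed step-up rule", {
  f <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(f$significant))
  expect_equal(f$adjusted, rep(0.05, 5))
  f1 <- bh_fdr(rep(1, 4))
  expect_false(any(f1$significant))
  expect_equal(f1$adjusted, rep(1, 4))
  expect_true(bh_fdr(0.04)$significant)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # never more discoveries than uncorrected thresholding; adjusted >= raw
  set.seed(8)
  p <- runif(50)^2
  f2 <- bh_fdr(p)
  expect_lte(sum(f2$significant), sum(p < 0.05))
  expect_true(all(f2$adjusted >= f2$raw))
})

make_stack <- function(n_sub, n_nodes, seed, shift_edges = NULL,
                       shift = 0, shift_subjects = integer()) {
  set.seed(seed)
  stack <- lapply(seq_len(n_sub), function(s) {
    W <- matrix(runif(n_nodes^2, 0.3, 0.7), n_nodes)
    W <- (W + t(W)) / 2
    diag(W) <- 1
    dimnames(W) <- list(sprintf("R%03d", 1:n_nodes),
                        sprintf("R%03d", 1:n_nodes))
    W
  })
  for (s in shift_subjects) {
    for (e in seq_len(nrow(shift_edges))) {
      i <- shift_edges[e, 1]; j <- shift_edges[e, 2]
      stack[[s]][i, j] <- stack[[s]][j, i] <- stack[[s]][i, j] + shift
    }
  }
  stack
}

test_that("NBS finds a single size-1 component for one suprathreshold edge", {
  stack <- make_stack(40, 2, seed = 9, shift_edges = cbind(1, 2),
                      shift = 0.5, shift_subjects = 1:20)
  labels <- rep(c("patient", "control"), each = 20)
  r <- nbs(stack, labels, node_mask = 1:2, primary_t = 3.2, n_perm = 200,
           seed = 10)
  expect_length(r$components, 1)
  expect_equal(r$components[[1]]$n_edges, 1)
  expect_setequal(r$components[[1]]$nodes, c("R001", "R002"))
})

test_that("NBS returns an empty result when nothing is suprathreshold", {
  stack <- make_stack(20, 5, seed = 11)
  r <- nbs(stack, rep(c("patient", "control"), each = 10),
           primary_t = 6, n_perm = 100, seed = 12)
  expect_length(r$components, 0)
})

test_that("NBS recovers a planted clique with corrected significance", {
  # 6-node clique shifted by ~2 SDs in patients, 38 per group
  clique <- t(combn(1:6, 2))
  hits <- 0; overlaps <- numeric(10)
  for (rep in 1:10) {
    stack <- make_stack(76, 12, seed = 100 + rep, shift_edges = clique,
                        shift = 0.23, shift_subjects = 1:38)
    r <- nbs(stack, rep(c("patient", "control"), each = 38),
             primary_t = 3.2, n_perm = 300, seed = 200 + rep)
    if (length(r$components)) {
      big <- which.max(vapply(r$components, `[[`, numeric(1), "n_edges"))
      comp <- r$components[[big]]
      got <- paste(comp$edges$from, comp$edges$to)
      want <- paste(sprintf("R%03d", clique[, 1]),
                    sprintf("R%03d", clique[, 2]))
      overlaps[rep] <- length(intersect(got, want)) / length(want)
      if (overlaps[rep] >= 0.8 && comp$corrected_p <= 0.05) hits <- hits + 1
    }
  }
  expect_gte(hits / 10, 0.9)
})

test_that("NBS familywise error under the null is near nominal", {
  set.seed(13)
  false_pos <- 0
  n_rep <- 40
  for (rep in seq_len(n_rep)) {
    stack <- make_stack(30, 8, seed = 300 + rep)
    r <- nbs(stack, rep(c("patient", "control"), each = 15),
             primary_t = 3.2, n_perm = 200, seed = 400 + rep)
    any_sig <- length(r$components) &&
      any(vapply(r$components, `[[`, numeric(1), "corrected_p") < 0.05)
    false_pos <- false_pos + any_sig
  }
  # binomial 95% CI around 0.05 at n_rep = 40
  expect_lte(false_pos / n_rep, qbinom(0.975, n_rep, 0.05) / n_rep)
})

test_that("demographic comparison matches closed forms", {
  clin <- data.frame(
    subject_id = sprintf("S%02d", 1:20),
    group = rep(c("patient", "control"), each = 10),
    age = c(rnorm(10, 10, 3), rnorm(10, 10, 3)),
    sex = rep(c("M", "M", "M", "F", "F"), 4))
  # identical ages across groups -> t = 0, p = 1
  clin$age <- rep(seq(6, 15), 2)
  out <- compare_demographics(clin)
  expect_equal(out$statistic[out$variable == "age"], 0)
  expect_equal(out$p_value[out$variable == "age"], 1)
  # balanced sex table -> chi-square 0, p = 1
  expect_equal(out$statistic[out$variable == "sex (M:F)"], 0)
  expect_equal(out$p_value[out$variable == "sex (M:F)"], 1)
})

test_that("demographic t-statistic matches the pooled-variance formula", {
  set.seed(14)
  a <- rnorm(12, 11, 3); b <- rnorm(15, 9, 2)
  clin <- data.frame(subject_id = sprintf("S%02d", 1:27),
                     group = rep(c("patient", "control"), c(12, 15)),
                     age = c(a, b),
                     sex = sample(c("M", "F"), 27, replace = TRUE))
  out <- compare_demographics(clin)
  sp2 <- ((12 - 1) * var(a) + (15 - 1) * var(b)) / (12 + 15 - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 12 + 1 / 15))
  expect_equal(out$statistic[out$variable == "age"], t_manual,
               tolerance = 1e-12)
})
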