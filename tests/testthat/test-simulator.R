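test_that("instantaneous coaggregation matches hand enumeration", {
  # star with an unbonded bystander: green hub (1) bonded to 2 red and 2
  # green partners, cell 6 has no bonds and is excluded; per-cell
  # different-colour fractions {2/4, 1, 1, 0, 0} average to 0.5
  colors <- c("green", "red", "red", "green", "green", "green")
  bonds <- data.frame(i = c(1, 1, 1, 1), j = c(2, 3, 4, 5))
  expect_equal(instantaneous_coag(bonds, colors), 0.5)

  same <- data.frame(i = c(1, 4), j = c(5, 6))
  expect_equal(instantaneous_coag(same, colors), 0)
  cross <- data.frame(i = c(1, 4), j = c(2, 3))
  expect_equal(instantaneous_coag(cross, colors), 1)
  expect_true(is.na(instantaneous_coag(NULL, colors)))

  # duplicate bonds between one pair count one partner, not two
  dup <- data.frame(i = c(1, 1), j = c(2, 2))
  expect_equal(instantaneous_coag(dup, colors), 1)
})

test_that("bond lifetimes follow the gene-pair rules", {
  genes <- gene_table(c("A", "B"), c(2, 1))
  cfg <- sim_config(seed = 1)
  free <- matrix(5L, 2, 2, dimnames = list(NULL, c("A", "B")))
  pureA <- matrix(c(5L, 5L, 0L, 0L), 2, 2,
                  dimnames = list(NULL, c("A", "B")))
  set.seed(1)
  # both cells pure A, affinity ratio 2: lifetime 3 * 2 = 6
  res <- attempt_bind(1, 2, pureA, genes, cfg, baseline_affinity = 1)
  expect_equal(res$bond$life, 6)
  expect_equal(unname(res$free[1, "A"]), 4L)

  # one pure A, one pure B: mismatched genes persist one step
  mixed <- matrix(c(5L, 0L, 0L, 5L), 2, 2,
                  dimnames = list(NULL, c("A", "B")))
  res2 <- attempt_bind(1, 2, mixed, genes, cfg, baseline_affinity = 1)
  expect_equal(sort(c(res2$bond$gene_i, res2$bond$gene_j)), c("A", "B"))
  expect_equal(res2$bond$life, 1)

  # a cell with every token bound cannot form a bond
  empty <- matrix(c(0L, 0L, 5L, 5L), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, c("A", "B")))
  expect_null(attempt_bind(1, 2, empty, genes, cfg, 1)$bond)
})

test_that("speed dating is distance-biased and honours date_success", {
  expect_equal(nrow(propose_dates(matrix(rnorm(20), 10, 2), 0)), 0)

  # two tight clusters far apart: within-cluster pairings dominate
  set.seed(5)
  pos <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 30, 0.1), 10, 2))
  within <- 0; total <- 0
  for (k in 1:300) {
    d <- propose_dates(pos, 1)
    same <- (d[, 1] <= 10) == (d[, 2] <= 10)
    within <- within + sum(same); total <- total + nrow(d)
  }
  expect_gt(within / total, 0.8)

  # uniform positions: every cell is dated at a near-equal rate
  set.seed(6)
  posu <- matrix(runif(24, 0, 1), 12, 2)
  freq <- integer(12)
  for (k in 1:2000) {
    d <- propose_dates(posu, 1)
    freq[c(d[, 1], d[, 2])] <- freq[c(d[, 1], d[, 2])] + 1L
  }
  expect_gt(min(freq) / max(freq), 0.5)
})

test_that("force-directed layout separates bonded cliques", {
  cliq <- expand.grid(i = 1:5, j = 1:5)
  cliq <- cliq[cliq$i < cliq$j, ]
  cliq2 <- cliq + 5
  bonds <- rbind(cliq, cliq2)
  intra_wins <- 0
  for (s in 1:10) {
    set.seed(s)
    pos <- layout_positions(10, bonds)
    d <- as.matrix(dist(pos))
    intra <- mean(d[1:5, 1:5][upper.tri(diag(5))])
    inter <- mean(d[1:5, 6:10])
    if (intra < inter) intra_wins <- intra_wins + 1
  }
  expect_equal(intra_wins, 10)
  # an edgeless graph still gets dispersed, distinct positions
  set.seed(1)
  p0 <- layout_positions(8, NULL)
  expect_gt(min(dist(p0)), 0)
})

test_that("simulation runs are seeded, bounded, and colour-symmetric", {
  pops <- list(population_spec("green", 8, c(A = 6)),
               population_spec("red", 8, c(A = 6, B = 4)))
  genes <- gene_table(c("A", "B"), c(2, 1))
  cfg <- sim_config(n_steps = 25, n_repeats = 2, seed = 11)
  r1 <- run_simulation(pops, genes, cfg)
  r2 <- run_simulation(pops, genes, cfg)
  expect_identical(r1$per_step, r2$per_step)      # bit-reproducible
  vals <- r1$per_step[!is.na(r1$per_step)]
  expect_true(all(vals >= 0 & vals <= 1))
  # overall equals the mean of recorded post-burn-in values exactly
  post <- r1$per_step[(r1$burn_in_steps + 1):cfg$n_steps, ]
  expect_equal(r1$overall, mean(colMeans(post, na.rm = TRUE)))

  # swapping the colour labels changes nothing: colour never enters the
  # binding dynamics and "different colour" is a symmetric relation
  pops_swap <- list(population_spec("red", 8, c(A = 6)),
                    population_spec("green", 8, c(A = 6, B = 4)))
  r3 <- run_simulation(pops_swap, genes, cfg)
  expect_identical(r1$per_step, r3$per_step)
})

test_that("date_success zero leaves every step undefined and flagged", {
  pops <- list(population_spec("green", 5, c(A = 3)),
               population_spec("red", 5, c(A = 3)))
  res <- run_simulation(pops, gene_table("A", 1),
                        sim_config(n_steps = 10, n_repeats = 1,
                                   date_success = 0, seed = 2))
  expect_true(all(is.na(res$per_step)))
  expect_true(is.na(res$overall) || is.nan(res$overall))
  expect_equal(res$n_undefined_steps,
               10 - res$burn_in_steps)
})

test_that("sweep grids produce one row per grid point", {
  sw <- sweep_simulation(affinity_ratios = c(1, 4), expr_ratios = c(1, 20),
                         preset = "full_mismatch",
                         config = sim_config(n_steps = 12, n_repeats = 2,
                                             seed = 3),
                         n_cells = 6)
  expect_equal(nrow(sw), 4)
  expect_true(all(c("affinity_ratio", "expr_ratio", "overall", "mc_sd")
                  %in% names(sw)))
  expect_error(sweep_simulation(affinity_ratios = numeric(0)), "non-empty")
})

test_that("token splits keep a floor of one token per expressed gene", {
  pr <- sim_preset("single_vs_double", affinity_ratio = 2, expr_ratio = 20)
  expr <- pr$populations[[2]]$expression
  expect_equal(sum(expr), 20)
  expect_true(all(expr >= 1))
  expect_equal(unname(expr["A"]), 19)
})
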