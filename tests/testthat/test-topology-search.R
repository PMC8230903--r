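test_that("candidate generation honours counts, samples and the null model", {
  cands <- generate_candidates(6, c(1, 2, 3, 4, 5, 10, 15, 20),
                               samples_per_count = 20, include_null = TRUE,
                               seed = 81)
  expect_length(cands, 8 * 21 + 1)  # base + 20 rewired samples per E + null
  nulls <- Filter(function(cd) cd$n_edges == 0, cands)
  expect_length(nulls, 1)
  for (cd in cands) {
    if (is.na(cd$sample_id)) next
    expect_equal(cd$n_edges, cd$E)
    expect_equal(sum(cd$adjacency != 0), cd$n_edges)
    expect_true(all(cd$adjacency %in% c(-1L, 0L, 1L)))
    expect_true(all(diag(cd$adjacency) == 0))
  }
  # deterministic under seed
  cands2 <- generate_candidates(6, c(1, 2, 3, 4, 5, 10, 15, 20),
                                samples_per_count = 20, include_null = TRUE,
                                seed = 81)
  expect_identical(cands, cands2)
  expect_error(generate_candidates(4, 20), "edge counts")
})

test_that("base topologies are right-skewed in out-degree at moderate density", {
  # preferential attachment should concentrate out-edges on hubs; at high
  # density (E near the complete graph) the 2x-median bound is arithmetically
  # unreachable with 6 nodes, so it is asserted where attainable
  skew_hits <- function(E, n_seeds) {
    sum(vapply(seq_len(n_seeds), function(s) {
      base <- generate_candidates(6, E, samples_per_count = 1,
                                  include_null = FALSE, seed = 500 + s)[[1]]
      outd <- rowSums(base$adjacency != 0)
      max(outd) >= 2 * stats::median(outd)
    }, logical(1)))
  }
  expect_equal(skew_hits(6, 20), 20)
  expect_gte(skew_hits(10, 20), 12)
})

test_that("fitness reproduces the anchor scores of the divergence scale", {
  set.seed(82)
  m <- matrix(rnorm(6 * 10), 6, 10)
  expect_equal(fitness(m, m)$score, 0)
  # per-gene orthogonal profiles: no similarity -> score = n_genes
  e <- matrix(rep(c(-1, 0, 1, 0), 3), 6, 12, byrow = TRUE)
  s <- matrix(rep(c(0, 1, 0, -1), 3), 6, 12, byrow = TRUE)
  expect_equal(fitness(e, s)$score, 6)
  expect_equal(fitness(e, -e)$score, 12)
  # constant profiles score r = 0 rather than failing
  flat <- matrix(1, 6, 12)
  expect_equal(fitness(e, flat)$score, 6)
  # bounds on random pairs
  for (i in 1:20) {
    f <- fitness(matrix(rnorm(60), 6), matrix(rnorm(60), 6))
    expect_gte(f$score, 0)
    expect_lte(f$score, 12)
  }
  expect_error(fitness(m, m[, 1:5]), "dimension")
})

test_that("parameter optimization is reproducible and never worse than its start", {
  prog <- prog_uncoupled6()
  dat <- gen_expression_from_network(prog, 9, noise_sd = 0.05, seed = 83)
  cand <- generate_candidates(6, 2, samples_per_count = 1,
                              include_null = FALSE, seed = 84)[[1]]
  dimnames(cand$adjacency) <- dimnames(dat$truth_adjacency)
  a <- optimize_parameters(cand, dat$ts, n_runs = 1, seed = 85,
                           max_eval = 300)
  b <- optimize_parameters(cand, dat$ts, n_runs = 1, seed = 85,
                           max_eval = 300)
  expect_identical(serialize_program(a$program), serialize_program(b$program))
  expect_equal(a$score$score, b$score$score)
  expect_error(optimize_parameters(cand, expression_ts(matrix(1:8, 2, 4)),
                                   n_runs = 1), "node set")
})

test_that("the true topology is recoverable and beats the null on coupled data", {
  prog <- regulatory_program(
    factors = list(program_factor("fa", 0.4), program_factor("fb", 0.5),
                   program_factor("fc", 0.3)),
    genes = list(
      program_gene("a", "fa", list(el_constitutive(0.5))),
      program_gene("b", "fb", list(el_activate("fa", 2, 1))),
      program_gene("c", "fc", list(el_constitutive(0.6),
                                   el_repress("fb", 1.5, 0.8))))
  )
  dat <- gen_expression_from_network(prog, 9, noise_sd = 0, seed = 1)
  sgn <- dat$truth_adjacency
  sgn["a", "b"] <- 1L; sgn["b", "c"] <- -1L
  true_cand <- structure(list(adjacency = sgn, n_nodes = 3, n_edges = 2,
                              E = 2L, sample_id = 0L),
                         class = "candidate_topology")
  null_cand <- structure(list(adjacency = sgn * 0L, n_nodes = 3, n_edges = 0,
                              E = 0L, sample_id = NA_integer_),
                         class = "candidate_topology")
  ok_true <- ok_null <- 0
  for (s in 1:5) {
    st <- optimize_parameters(true_cand, dat$ts, n_runs = 3, seed = s,
                              max_eval = 800)$score$score
    sn <- optimize_parameters(null_cand, dat$ts, n_runs = 3, seed = s,
                              max_eval = 800)$score$score
    if (st <= 0.1) ok_true <- ok_true + 1
    if (sn >= st) ok_null <- ok_null + 1
  }
  expect_gte(ok_true, 4)   # noise-free self-recovery in >= 80% of seeds
  expect_equal(ok_null, 5) # the empty model never beats the true one
})

test_that("discrimination ranks candidates independently of input order", {
  prog <- prog_uncoupled6()
  dat <- gen_expression_from_network(prog, 9, noise_sd = 0.05, seed = 86)
  cands <- generate_candidates(6, c(1, 3), samples_per_count = 2,
                               include_null = TRUE, seed = 87)
  cands <- lapply(cands, function(cd) {
    dimnames(cd$adjacency) <- dimnames(dat$truth_adjacency)
    cd
  })
  d1 <- discriminate(cands, dat$ts, n_runs = 1, seed = 88, max_eval = 200)
  d2 <- discriminate(rev(cands), dat$ts, n_runs = 1, seed = 88,
                     max_eval = 200)
  expect_equal(d1$results, d2$results)
  expect_equal(nrow(d1$results), length(cands))
  expect_true(!is.unsorted(d1$results$score))
  expect_true(all(c("median", "iqr") %in% colnames(d1$summary)))
  # a single candidate yields a one-row table
  d3 <- discriminate(cands[1], dat$ts, n_runs = 1, seed = 89, max_eval = 100)
  expect_equal(nrow(d3$results), 1)
})
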