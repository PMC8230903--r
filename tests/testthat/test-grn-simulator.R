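test_that("Michaelis-Menten promoter algebra matches the closed formula", {
  p <- regulatory_program(
    factors = list(program_factor("A", 0.1), program_factor("B", 0.1)),
    genes = list(
      program_gene("a", "A", list(el_constitutive(0.3))),
      program_gene("b", "B", list(el_activate("A", vmax = 1, km = 1)))
    )
  )
  # at c = KM the factor exerts half its maximal effect
  expect_equal(expression_rate(p, "b", c(A = 1, B = 0)), 0.5)
  expect_equal(expression_rate(p, "b", c(A = 0, B = 0)), 0)
  # repression clamps the total rate at zero
  p2 <- regulatory_program(
    factors = list(program_factor("A", 0.1), program_factor("B", 0.1)),
    genes = list(program_gene("b", "B",
                              list(el_constitutive(0.3),
                                   el_repress("A", vmax = 1, km = 1))))
  )
  expect_equal(expression_rate(p2, "b", c(A = 1e9, B = 0)), 0)
  expect_error(expression_rate(p, "nope", c(A = 1)), "unknown gene")
})

test_that("expression rates agree with an independent re-evaluation on random programs", {
  set.seed(41)
  for (rep in 1:50) {
    prog <- random_program()
    state <- setNames(runif(length(prog$factors), 0, 5),
                      names(prog$factors))
    for (g in prog$genes) {
      # independent oracle: evaluate the promoter sum directly
      expect_rate <- 0
      for (el in g$promoter) {
        expect_rate <- expect_rate + switch(el$type,
          constitutive = el$rate,
          activate = el$vmax * state[[el$factor]] / (el$km + state[[el$factor]]),
          repress = -el$vmax * state[[el$factor]] / (el$km + state[[el$factor]]))
      }
      expect_equal(expression_rate(prog, g$name, state),
                   max(0, expect_rate), tolerance = 1e-12)
    }
  }
})

test_that("simulation reproduces analytic fixed point and geometric decay", {
  sim <- simulate_program(prog_single(0.5, 0.1), c(A = 0), 250)
  expect_lt(abs(sim$values[1, 201] - 5), 1e-6)
  # pure decay, no production: c(t) = c0 (1-d)^t exactly
  p <- regulatory_program(list(program_factor("A", 0.3)), list())
  sim2 <- simulate_program(p, c(A = 2), 12)
  expect_equal(as.numeric(sim2$values), 2 * 0.7^(0:12))
})

test_that("constitutive-only programs follow the affine recursion closed form", {
  # c(t+1) = (1-d) c(t) + r  =>  c(t) = r/d + (c0 - r/d)(1-d)^t
  r <- 0.7; d <- 0.35; c0 <- 3
  sim <- simulate_program(prog_single(r, d), c(A = c0), 50)
  expect_equal(as.numeric(sim$values),
               r / d + (c0 - r / d) * (1 - d)^(0:50), tolerance = 1e-10)
})

test_that("trajectories stay non-negative and bounded on random programs", {
  set.seed(42)
  for (rep in 1:200) {
    prog <- random_program()
    init <- setNames(runif(length(prog$factors), 0, 3), names(prog$factors))
    sim <- simulate_program(prog, init, 50)
    expect_true(all(sim$values >= 0))
    max_rate <- sum(vapply(prog$genes, function(g) {
      sum(vapply(g$promoter, function(el) {
        if (el$type == "repress") 0 else
          if (el$type == "constitutive") el$rate else el$vmax
      }, numeric(1)))
    }, numeric(1)))
    decays <- vapply(prog$factors, function(f) f$decay, numeric(1))
    bound <- max(init) + max_rate / min(decays)
    expect_true(all(sim$values <= bound + 1e-8))
  }
})

test_that("increasing an activator's concentration never decreases the rate", {
  set.seed(43)
  p <- regulatory_program(
    factors = list(program_factor("A", 0.1), program_factor("B", 0.2)),
    genes = list(program_gene("b", "B",
                              list(el_constitutive(0.2),
                                   el_activate("A", vmax = 2, km = 0.7))))
  )
  cs <- sort(runif(50, 0, 10))
  rates <- vapply(cs, function(c) expression_rate(p, "b", c(A = c, B = 0)),
                  numeric(1))
  expect_true(all(diff(rates) >= -1e-12))
})

test_that("knockout silences a gene and leaves the rest untouched", {
  p <- prog_cascade()
  ko <- knockout(p, "a")
  # the knocked-out gene produces nothing: A decays geometrically
  sim <- simulate_program(ko, c(A = 1, B = 0), 10)
  expect_equal(as.numeric(sim$values["A", ]), 0.8^(0:10))
  # idempotent
  expect_identical(knockout(ko, "a"), ko)
  expect_error(knockout(p, "zz"), "unknown gene")
  # B's steady state collapses to its constitutive-only fixed point
  sim_wt <- simulate_program(p, NULL, 400)
  sim_ko <- simulate_program(ko, NULL, 400)
  b_wt <- sim_wt$values["B", 401]
  b_ko <- sim_ko$values["B", 401]
  a_ss <- 0.4 / 0.2
  b_expected_wt <- (0.1 + 1 * a_ss / (0.5 + a_ss)) / 0.25
  expect_lt(abs(b_wt - b_expected_wt), 1e-6)
  expect_lt(abs(b_ko - 0.1 / 0.25), 1e-6)
})

test_that("program text round-trips and errors carry locations", {
  p <- prog_single()
  expect_identical(parse_program(serialize_program(p)), p)
  # 100 random programs round-trip bit-identically
  set.seed(44)
  for (rep in 1:100) {
    prog <- random_program()
    txt <- serialize_program(prog)
    expect_identical(parse_program(txt), prog)
    expect_identical(serialize_program(parse_program(txt)), txt)
  }
  expect_error(parse_program("factor A decay=0.1\ngene g product=B\n  constitutive 1"),
               "undeclared factor 'B'")
  expect_error(parse_program("factor A decay=oops"), "line 1")
  expect_error(parse_program("factor A decay=0.1\nwibble x"), "line 2")
})

test_that("program files survive a disk round trip", {
  p <- prog_cascade()
  path <- withr::local_tempfile(fileext = ".grn")
  write_program(p, path)
  expect_identical(read_program(path), p)
})
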