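# Shared fixtures, all generated in code.

# One-factor, one-gene constitutive program: analytic fixed point rate/decay.
prog_single <- function(rate = 0.5, decay = 0.1) {
  regulatory_program(
    factors = list(program_factor("A", decay)),
    genes = list(program_gene("a", "A", list(el_constitutive(rate))))
  )
}

# Two-gene activation cascade a -> B used for knockout fixed-point checks.
prog_cascade <- function() {
  regulatory_program(
    factors = list(program_factor("A", 0.2), program_factor("B", 0.25)),
    genes = list(
      program_gene("a", "A", list(el_constitutive(0.4))),
      program_gene("b", "B", list(el_constitutive(0.1),
                                  el_activate("A", vmax = 1, km = 0.5)))
    )
  )
}

# Uncoupled six-gene program (independent constitutive genes): the data
# source for the null-model replication.
prog_uncoupled6 <- function() {
  decays <- c(0.3, 0.5, 0.4, 0.6, 0.35, 0.45)
  rates <- c(0.5, 0.8, 0.3, 0.9, 0.6, 0.4)
  regulatory_program(
    factors = lapply(1:6, function(i)
      program_factor(sprintf("f%d", i), decays[i])),
    genes = lapply(1:6, function(i)
      program_gene(sprintf("n%d", i), sprintf("f%d", i),
                   list(el_constitutive(rates[i]))))
  )
}

# Random valid regulatory program for property sweeps; draws from the
# caller's RNG stream.
random_program <- function(n_factors = 3, n_genes = 3) {
  fnames <- sprintf("F%d", seq_len(n_factors))
  factors <- lapply(fnames, function(f) program_factor(f, runif(1, 0.05, 1)))
  genes <- lapply(seq_len(n_genes), function(i) {
    promoter <- list()
    if (runif(1) < 0.8) promoter <- c(promoter, list(el_constitutive(runif(1, 0, 1))))
    n_reg <- sample(0:2, 1)
    for (k in seq_len(n_reg)) {
      f <- sample(fnames, 1)
      el <- if (runif(1) < 0.5) {
        el_activate(f, vmax = runif(1, 0, 3), km = runif(1, 0.05, 3))
      } else {
        el_repress(f, vmax = runif(1, 0, 3), km = runif(1, 0.05, 3))
      }
      promoter <- c(promoter, list(el))
    }
    program_gene(sprintf("G%d", i), sample(fnames, 1), promoter)
  })
  regulatory_program(factors, genes)
}

# Planted two-cluster data with gross outliers for the robust clustering
# tests: separation 10 sd in 5 of 50 features, 10% outliers.
planted_clusters <- function(seed, n_per = 45, n_out = 10, p = 50) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p), n_per, p))
  x[(n_per + 1):(2 * n_per), 1:5] <- x[(n_per + 1):(2 * n_per), 1:5] + 10
  out <- matrix(rnorm(n_out * p) + sample(c(-25, 25), n_out * p, TRUE),
                n_out, p)
  list(x = rbind(x, out),
       truth = c(rep(1L, n_per), rep(2L, n_per), rep(NA_integer_, n_out)))
}

# Direct per-pixel green fraction by counting raw pixel colours against the
# generator's palettes (the oracle for the image generator's truth).
pixel_green_fraction <- function(image, greens, yellows) {
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  g <- sum(key(px) %in% key(greens))
  y <- sum(key(px) %in% key(yellows))
  g / (g + y)
}
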