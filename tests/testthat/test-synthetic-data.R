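test_that("gen_counts plants exactly the requested number of DE genes", {
  cm0 <- gen_counts(50, c("GS10", "GS90"), reps = 3, de_fraction = 0,
                    seed = 1)
  expect_equal(sum(cm0$truth$status == "DE"), 0)
  cm <- gen_counts(100, c("GS10", "GS50", "GS90"), reps = 3,
                   de_fraction = 0.1, log2fc = 2, seed = 1)
  expect_equal(sum(cm$truth$status == "DE"), 10)
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$counts == round(cm$counts)))
  expect_false(anyDuplicated(cm$gene_ids) > 0)
  expect_true(all(cm$stage_labels %in% wheat_stages()))
  # determinism
  expect_identical(cm, gen_counts(100, c("GS10", "GS50", "GS90"), reps = 3,
                                  de_fraction = 0.1, log2fc = 2, seed = 1))
  expect_error(gen_counts(100, c("GS10", "GSXX"), reps = 3), "unknown stage")
  expect_error(gen_counts(1, "GS10", reps = 3), "n_genes")
  expect_error(gen_counts(10, "GS10", reps = 1), "reps")
})

test_that("null-gene count means match the programmed negative-binomial moments", {
  # Monte-Carlo oracle: across many replicates the sample mean of a null
  # gene must sit within 3 standard errors of its programmed mean
  reps <- 60
  cm <- gen_counts(40, c("GS10", "GS90"), reps = reps, de_fraction = 0,
                   dispersion = 0.05, seed = 7)
  n <- 2 * reps
  mu <- cm$truth$base_mean
  se <- sqrt((mu + 0.05 * mu^2) / n)
  dev <- abs(rowMeans(cm$counts) - mu) / se
  # allow a single 3-se excursion among 40 genes (P(|z|>3) ~ 0.003)
  expect_lte(sum(dev > 3), 1)
})

test_that("network expression generator reduces to the simulator at zero noise", {
  prog <- example_grn6()
  out <- gen_expression_from_network(prog, n_steps = 10, noise_sd = 0,
                                     seed = 3)
  clean <- simulate_program(prog, NULL, 10)
  expect_equal(unname(out$ts$values), unname(clean$values))
  expect_identical(rownames(out$ts$values), names(prog$genes))
  # no activate/repress elements -> all-zero truth adjacency
  out0 <- gen_expression_from_network(prog_uncoupled6(), n_steps = 5,
                                      noise_sd = 0, seed = 1)
  expect_true(all(out0$truth_adjacency == 0))
  expect_error(gen_expression_from_network(prog, 10, noise_sd = -1),
               "noise_sd")
})

test_that("observation noise has the programmed standard deviation", {
  # run the system at a high steady state so zero-truncation is negligible
  prog <- prog_single(rate = 5, decay = 0.5)  # steady state 10
  out <- gen_expression_from_network(prog, n_steps = 9999, noise_sd = 0.2,
                                     initial = c(A = 10), seed = 11)
  resid <- out$ts$values - out$noiseless$values
  expect_lt(abs(sd(resid) - 0.2) / 0.2, 0.05)
})

test_that("process noise produces a reproducible stochastic trajectory", {
  prog <- example_grn6()
  a <- gen_expression_from_network(prog, 20, noise_sd = 0.05,
                                   noise = "process", seed = 5)
  b <- gen_expression_from_network(prog, 20, noise_sd = 0.05,
                                   noise = "process", seed = 5)
  expect_identical(a$ts$values, b$ts$values)
  expect_true(all(a$ts$values >= 0))
  # noise propagates: differs from the deterministic path
  expect_gt(max(abs(a$ts$values - a$noiseless$values)), 0)
})

test_that("plant image series encode the programmed senescence trajectory", {
  s <- gen_plant_images(n_timepoints = 6, onset = 3, width = 48, height = 64,
                        seed = 9)
  expect_length(s$images, 6)
  expect_true(all(s$truth_green_fraction >= 0 & s$truth_green_fraction <= 1))
  expect_true(all(diff(s$truth_green_fraction) <= 0))
  # pixel-count oracle: direct counting on the rasters reproduces the truth
  greens <- plant_green_palette <- s$plant_palette[1:5, , drop = FALSE]
  yellows <- s$plant_palette[6:10, , drop = FALSE]
  for (t in seq_along(s$images)) {
    expect_equal(pixel_green_fraction(s$images[[t]], greens, yellows),
                 s$truth_green_fraction[t])
  }
  # every pixel is either plant-palette or background-palette
  img <- s$images[[1]]
  px <- unique(cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                     as.vector(img[, , 3])))
  allowed <- rbind(s$plant_palette, s$background_palette)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(px) %in% key(allowed)))
})

test_that("image generator degenerate cases and determinism", {
  s <- gen_plant_images(4, onset = 4, width = 32, height = 48, seed = 2)
  expect_equal(s$truth_green_fraction, rep(1, 4))
  expect_identical(s, gen_plant_images(4, 4, 32, 48, seed = 2))
  expect_error(gen_plant_images(4, onset = 5), "onset")
  expect_error(gen_plant_images(4, onset = 0), "onset")
})

test_that("plain-text PPM round-trips an image exactly", {
  s <- gen_plant_images(1, onset = 1, width = 16, height = 20, seed = 3)
  path <- withr::local_tempfile(fileext = ".ppm")
  write_ppm(s$images[[1]], path)
  expect_identical(read_ppm(path), s$images[[1]])
})
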