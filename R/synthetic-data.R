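#' Wheat developmental-stage vocabulary
#'
#' The Zadoks-scale growth-stage codes used for sample labels, from seedling
#' growth (GS10) to ripening (GS90).
#'
#' @return character vector `GS10 ... GS90`.
#' @export
wheat_stages <- function() {
  c("GS10", "GS20", "GS30", "GS40", "GS50",
    "GS60", "GS70", "GS80", "GS90")
}

#' Generate a negative-binomial count matrix with planted differential expression
#'
#' Draws per-gene baseline means log-uniformly in `[20, 2000]` and samples
#' counts from a negative-binomial distribution with variance
#' `mu + dispersion * mu^2`. A fraction of genes carries a planted
#' stage-dependent fold change: their log2 mean interpolates linearly from the
#' baseline at the first stage to `baseline * 2^log2fc` at the last stage
#' (sign drawn at random per gene), so the last-vs-first contrast of the
#' differential-expression test targets exactly `+/- log2fc`.
#'
#' @param n_genes number of genes (`>= 2`).
#' @param stages ordered stage labels, drawn from [wheat_stages()].
#' @param reps replicates per stage (`>= 2`).
#' @param de_fraction fraction of genes carrying the planted effect.
#' @param log2fc absolute planted log2 fold change (last vs first stage).
#' @param dispersion negative-binomial dispersion `alpha > 0`.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return a list of class `count_matrix`: `counts` (integer matrix, genes x
#'   samples), `gene_ids`, `stage_labels` (per sample), and `truth`
#'   (data frame with per-gene `status` "DE"/"null" and `true_log2fc`).
#' @export
gen_counts <- function(n_genes, stages, reps, de_fraction = 0.1,
                       log2fc = 2, dispersion = 0.05, seed = NULL) {
  if (!is.numeric(n_genes) || n_genes < 2) stopf("'n_genes' must be >= 2")
  if (!is.numeric(reps) || reps < 2) stopf("'reps' must be >= 2 per stage")
  if (!is.numeric(de_fraction) || de_fraction < 0 || de_fraction > 1) {
    stopf("'de_fraction' must lie in [0, 1]")
  }
  if (!is.numeric(dispersion) || dispersion <= 0) stopf("'dispersion' must be > 0")
  stages <- as.character(stages)
  bad <- setdiff(stages, wheat_stages())
  if (length(bad)) stopf("unknown stage label '%s'", bad[1])
  if (length(stages) < 1L) stopf("at least one stage is required")
  n_genes <- as.integer(n_genes); reps <- as.integer(reps)
  with_seed(seed, {
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    n_de <- round(n_genes * de_fraction)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))
    sign <- ifelse(stats::runif(n_genes) < 0.5, -1, 1)
    true_lfc <- ifelse(is_de, sign * log2fc, 0)
    base_mu <- exp(stats::runif(n_genes, log(20), log(2000)))
    n_stage <- length(stages)
    stage_labels <- rep(stages, each = reps)
    # per-stage log2 offset: 0 at first stage, true_lfc at last
    frac <- if (n_stage == 1L) 0 else (seq_len(n_stage) - 1) / (n_stage - 1)
    counts <- matrix(0L, n_genes, n_stage * reps,
                     dimnames = list(gene_ids,
                                     paste0(stage_labels, "_r",
                                            rep(seq_len(reps), times = n_stage))))
    for (s in seq_len(n_stage)) {
      mu_s <- base_mu * 2^(true_lfc * frac[s])
      cols <- ((s - 1L) * reps + 1L):(s * reps)
      draws <- stats::rnbinom(n_genes * reps, mu = rep(mu_s, times = reps),
                              size = 1 / dispersion)
      counts[, cols] <- matrix(as.integer(draws), n_genes, reps)
    }
    structure(list(
      counts = counts,
      gene_ids = gene_ids,
      stage_labels = stage_labels,
      truth = data.frame(gene_id = gene_ids,
                         status = ifelse(is_de, "DE", "null"),
                         true_log2fc = true_lfc,
                         base_mean = base_mu,
                         stringsAsFactors = FALSE)
    ), class = "count_matrix")
  })
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d genes x %d samples (%d stage(s), %d DE)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$stage_labels)),
              sum(x$truth$status == "DE")))
  invisible(x)
}

#' Generate an expression time course from a known network
#'
#' Simulates the given regulatory program and adds i.i.d. Gaussian noise of
#' standard deviation `noise_sd`, truncated at zero so expression stays in
#' the simulator's non-negative state space. The program's promoter elements
#' define the ground-truth adjacency used by network-recovery tests.
#'
#' @param program a [regulatory_program()].
#' @param n_steps number of simulation steps (`>= 2`).
#' @param noise_sd non-negative noise standard deviation.
#' @param initial optional named initial state (see [simulate_program()]).
#' @param noise `"observation"` (default): the deterministic simulation plus
#'   i.i.d. Gaussian measurement noise, truncated at 0. `"process"`:
#'   intrinsic expression noise, added to the state *inside* every update
#'   (and truncated at 0) so that it propagates through the dynamics — the
#'   stochastic excitation that makes regulatory edges identifiable from a
#'   single trajectory (see the vignette).
#' @param seed integer seed.
#' @return a list: `ts` (noisy [expression_ts()], rows named after the
#'   producing genes), `noiseless` (the clean simulation), and
#'   `truth_adjacency` (binary gene x gene matrix from
#'   [program_adjacency()]).
#' @export
gen_expression_from_network <- function(program, n_steps, noise_sd = 0.05,
                                        initial = NULL,
                                        noise = c("observation", "process"),
                                        seed = NULL) {
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (!is.numeric(n_steps) || n_steps < 2) stopf("'n_steps' must be >= 2")
  noise <- match.arg(noise)
  clean <- simulate_program(program, initial = initial, n_steps = n_steps)
  # relabel factor rows by the gene producing each factor, so the series and
  # the truth adjacency share identifiers
  producer <- character(0)
  for (g in program$genes) producer[g$product] <- g$name
  relabel <- function(m) {
    keep <- rownames(m) %in% names(producer)
    m <- m[keep, , drop = FALSE]
    rownames(m) <- unname(producer[rownames(m)])
    m
  }
  vals <- relabel(clean$values)
  with_seed(seed, {
    noisy <- if (noise_sd == 0) {
      vals
    } else if (noise == "observation") {
      pmax(vals + matrix(stats::rnorm(length(vals), 0, noise_sd),
                         nrow(vals), ncol(vals)), 0)
    } else {
      relabel(simulate_program_noisy(program, initial, n_steps, noise_sd))
    }
    list(ts = expression_ts(noisy, dt = clean$dt),
         noiseless = expression_ts(vals, dt = clean$dt),
         truth_adjacency = program_adjacency(program))
  })
}

# One stochastic simulation: synchronous updates with Gaussian process noise
# injected into the state each step, truncated at zero. Draws from the
# caller's RNG stream.
simulate_program_noisy <- function(program, initial, n_steps, noise_sd) {
  fnames <- factor_names(program)
  state <- stats::setNames(numeric(length(fnames)), fnames)
  if (!is.null(initial)) state[names(initial)] <- as.numeric(initial)
  decay <- vapply(program$factors, function(f) f$decay, numeric(1))
  out <- matrix(0, length(fnames), n_steps + 1L,
                dimnames = list(fnames, paste0("t", 0:n_steps)))
  out[, 1L] <- state
  for (s in seq_len(n_steps)) {
    production <- stats::setNames(numeric(length(fnames)), fnames)
    for (g in program$genes) {
      production[[g$product]] <- production[[g$product]] +
        expression_rate(program, g$name, state)
    }
    state <- pmax(state * (1 - decay) + production +
                    stats::rnorm(length(state), 0, noise_sd), 0)
    out[, s + 1L] <- state
  }
  out
}

#' Example six-gene regulatory program with five edges
#'
#' A fixed benchmark network for recovery experiments: a constitutive source
#' gene activates a two-step cascade (g1 -> g2 -> g3), represses g4 (which
#' in turn activates g5), and g3 activates g6. Michaelis constants sit at
#' each regulator's steady-state concentration and `vmax = 2 * km`, so every
#' edge has the same linearized gain (0.5) and no gene's expression rate is
#' clamped at zero in the operating regime — each edge is, in principle,
#' equally recoverable.
#'
#' @return a [regulatory_program()] with genes `g1 ... g6` and 5 directed
#'   regulatory edges.
#' @export
example_grn6 <- function() {
  regulatory_program(
    factors = list(
      program_factor("f1", 0.5), program_factor("f2", 0.4),
      program_factor("f3", 0.6), program_factor("f4", 0.5),
      program_factor("f5", 0.3), program_factor("f6", 0.45)
    ),
    genes = list(
      program_gene("g1", "f1", list(el_constitutive(0.4))),
      program_gene("g2", "f2", list(el_activate("f1", 1.6, 0.8))),
      program_gene("g3", "f3", list(el_activate("f2", 4, 2))),
      program_gene("g4", "f4", list(el_constitutive(1.3),
                                    el_repress("f1", 1.6, 0.8))),
      program_gene("g5", "f5", list(el_activate("f4", 2, 1))),
      program_gene("g6", "f6", list(el_constitutive(0.2),
                                    el_activate("f3", 6.67, 3.33)))
    )
  )
}

# --- synthetic plant images -------------------------------------------------

# Fixed palettes. Plant greens/yellows are spread out so quantization has
# something to merge; background colours are greys and browns far from both.
plant_green_palette <- function() {
  rbind(c(20, 120, 20), c(30, 140, 25), c(45, 160, 40),
        c(60, 170, 50), c(35, 150, 60))
}
plant_yellow_palette <- function() {
  rbind(c(210, 190, 20), c(225, 200, 35), c(235, 210, 25),
        c(200, 180, 45), c(240, 220, 30))
}
default_background_palette <- function() {
  rbind(c(40, 40, 45), c(90, 90, 95), c(120, 100, 80),
        c(200, 200, 205), c(70, 55, 40))
}

#' Generate a synthetic plant image series with a programmed senescence trajectory
#'
#' Draws a procedural stem-and-leaves silhouette on a background, then colours
#' plant pixels from a green palette before the senescence onset and turns an
#' increasing fraction yellow afterwards, from the top of the plant downwards
#' (senescence progresses basipetally in the rendering purely so that the
#' yellow fraction is spatially coherent). The realized green fraction of
#' plant pixels is recorded per image as machine-readable truth.
#'
#' @param n_timepoints number of images.
#' @param onset 1-based time index at which yellowing starts
#'   (`1 <= onset <= n_timepoints`); `onset = n_timepoints` keeps every image
#'   fully green.
#' @param width,height image size in pixels.
#' @param seed integer seed; identical seeds give identical images.
#' @return a list of class `synthetic_image_set`: `images` (list of integer
#'   `height x width x 3` arrays in `[0, 255]`), `truth_green_fraction`,
#'   `plant_pixels` (count per image), `background_palette` and
#'   `plant_palette` (matrices of RGB triples).
#' @export
gen_plant_images <- function(n_timepoints, onset, width = 64, height = 96,
                             seed = NULL) {
  if (!is.numeric(n_timepoints) || n_timepoints < 1) {
    stopf("'n_timepoints' must be >= 1")
  }
  if (!is.numeric(onset) || onset < 1 || onset > n_timepoints) {
    stopf("'onset' must lie in [1, n_timepoints]")
  }
  n_timepoints <- as.integer(n_timepoints); onset <- as.integer(onset)
  greens <- plant_green_palette()
  yellows <- plant_yellow_palette()
  bg <- default_background_palette()
  with_seed(seed, {
    mask <- plant_mask(width, height)
    plant_idx <- which(mask)          # column-major order, top rows first
    n_plant <- length(plant_idx)
    ord <- order((plant_idx - 1L) %% height)  # by row: top of image first
    bg_choice <- matrix(sample.int(nrow(bg), width * height, replace = TRUE),
                        height, width)
    green_choice <- sample.int(nrow(greens), n_plant, replace = TRUE)
    yellow_choice <- sample.int(nrow(yellows), n_plant, replace = TRUE)
    images <- vector("list", n_timepoints)
    truth <- numeric(n_timepoints)
    for (t in seq_len(n_timepoints)) {
      # target green fraction: 1 before onset, then linear decline to 0.1
      gf <- if (t < onset || onset == n_timepoints) 1 else {
        span <- n_timepoints - onset
        if (span == 0) 1 else 1 - 0.9 * (t - onset) / span
      }
      n_yellow <- round((1 - gf) * n_plant)
      img <- array(0L, c(height, width, 3L))
      for (ch in 1:3) {
        plane <- matrix(bg[cbind(as.vector(bg_choice), ch)], height, width)
        pal_col <- greens[cbind(green_choice, ch)]
        if (n_yellow > 0) {
          yellow_set <- ord[seq_len(n_yellow)]
          pal_col[yellow_set] <- yellows[cbind(yellow_choice[yellow_set], ch)]
        }
        plane[plant_idx] <- pal_col
        img[, , ch] <- plane
      }
      storage.mode(img) <- "integer"
      images[[t]] <- img
      truth[t] <- (n_plant - n_yellow) / n_plant
    }
    structure(list(images = images,
                   truth_green_fraction = truth,
                   plant_pixels = rep(n_plant, n_timepoints),
                   background_palette = bg,
                   plant_palette = rbind(greens, yellows)),
              class = "synthetic_image_set")
  })
}

# Procedural stem + leaf silhouette as a logical height x width matrix.
# Deterministic given dimensions; no RNG so the plant pixel set is stable
# across time points.
plant_mask <- function(width, height) {
  mask <- matrix(FALSE, height, width)
  cx <- round(width / 2)
  stem_w <- max(1L, round(width / 24))
  top <- round(height * 0.08)
  for (r in top:height) {
    mask[r, max(1, cx - stem_w):min(width, cx + stem_w)] <- TRUE
  }
  # leaf triangles at fixed heights, alternating sides
  leaf_rows <- round(height * c(0.25, 0.45, 0.65, 0.82))
  leaf_len <- round(width * 0.35)
  for (i in seq_along(leaf_rows)) {
    r0 <- leaf_rows[i]
    dir <- if (i %% 2 == 0) 1L else -1L
    for (d in 0:leaf_len) {
      r <- r0 - round(d * 0.25)
      if (r < 1 || r > height) next
      c0 <- cx + dir * d
      if (c0 < 1 || c0 > width) next
      half <- max(0L, round((leaf_len - d) / 6))
      cols <- max(1, c0 - half):min(width, c0 + half)
      mask[max(1, r - half):min(height, r + half), cols] <- TRUE
    }
  }
  mask
}

#' @export
print.synthetic_image_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("Synthetic image set: %d image(s), %dx%d px, plant pixels per image: %d\n",
              length(x$images), d[2], d[1], x$plant_pixels[1]))
  cat("Truth green fraction:", paste(sprintf("%.2f", x$truth_green_fraction),
                                     collapse = " "), "\n")
  invisible(x)
}

#' Read / write an RGB image as plain-text PPM (P3)
#'
#' Minimal interop format for the image pipeline: images are integer
#' `height x width x 3` arrays with values in `[0, 255]`.
#'
#' @param image integer `h x w x 3` array.
#' @param path file path.
#' @return `read_ppm` returns an image array; `write_ppm` returns `path`
#'   invisibly.
#' @export
write_ppm <- function(image, path) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stopf("'image' must be an h x w x 3 array")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), "255"), con)
  # PPM is row-major, pixel-interleaved
  vals <- aperm(image, c(3, 2, 1))  # channel fastest, then column, then row
  writeLines(paste(as.integer(vals), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") stopf("only plain-text P3 PPM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.integer(toks[4])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h * 3L) stopf("PPM payload has wrong length")
  arr <- aperm(array(vals, c(3L, w, h)), c(3, 2, 1))
  storage.mode(arr) <- "integer"
  arr
}
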