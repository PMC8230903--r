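#' Two-gene senescence demonstration program
#'
#' Builds the minimal molecular model of senescence onset: a zero-decay
#' `age` factor accumulates a constant rate per step (the simplest monotone
#' developmental clock); it activates `NAM_gene`, whose product represses
#' `chlorophyll_gene`; chlorophyll is otherwise produced constitutively and
#' starts at its pre-senescence steady state. As the clock advances, the NAM
#' product rises and chlorophyll falls — senescence is triggered.
#'
#' The repression `km` is calibrated at construction time by bisection
#' (deterministic) so that the chlorophyll concentration first falls below
#' `threshold_frac` of its initial steady state exactly at simulation step
#' `onset_step` (1-based, step 1 = emergence/germination; the alternative
#' "counted from emergence" convention is simply `onset_step - 1`).
#'
#' @param onset_step target step of senescence onset (default 7, anthesis).
#' @param threshold_frac fraction of the initial chlorophyll level defining
#'   onset (default 0.3; this matches the hue at which the rendered colour
#'   crosses from the green to the yellow hue class, see [render_plant()]).
#' @param horizon number of steps over which the calibration is checked.
#' @return a [regulatory_program()] with factors `age`, `NAM`, `chlorophyll`
#'   and attributes `initial_state`, `onset_step`, `threshold` (absolute
#'   concentration).
#' @export
two_gene_program <- function(onset_step = 7, threshold_frac = 0.3,
                             horizon = 3 * onset_step) {
  if (onset_step < 2) stopf("'onset_step' must be >= 2")
  chl_rate <- 0.5; chl_decay <- 0.25
  chl0 <- chl_rate / chl_decay          # pre-senescence steady state = 2
  threshold <- threshold_frac * chl0
  nam_vmax <- 0.6; nam_km <- 2; nam_decay <- 0.2
  rep_vmax <- 1.5
  build <- function(rep_km) {
    regulatory_program(
      factors = list(program_factor("age", decay = 0),
                     program_factor("NAM", decay = nam_decay),
                     program_factor("chlorophyll", decay = chl_decay)),
      genes = list(
        program_gene("clock_gene", product = "age",
                     promoter = list(el_constitutive(0.5))),
        program_gene("NAM_gene", product = "NAM",
                     promoter = list(el_activate("age", vmax = nam_vmax,
                                                 km = nam_km))),
        program_gene("chlorophyll_gene", product = "chlorophyll",
                     promoter = list(el_constitutive(chl_rate),
                                     el_repress("NAM", vmax = rep_vmax,
                                                km = rep_km)))
      )
    )
  }
  initial <- c(age = 0, NAM = 0, chlorophyll = chl0)
  onset_of <- function(rep_km) {
    sim <- simulate_program(build(rep_km), initial = initial,
                            n_steps = horizon)
    below <- which(sim$values["chlorophyll", -1] < threshold)
    if (!length(below)) Inf else below[1]
  }
  # smaller km -> repression saturates earlier -> earlier onset; bisect for
  # the largest km whose first crossing is at or before the target step
  lo <- 1e-4; hi <- 100
  if (onset_of(lo) > onset_step) stopf("onset_step %d is not reachable", onset_step)
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    if (onset_of(mid) <= onset_step) lo <- mid else hi <- mid
  }
  rep_km <- lo
  if (onset_of(rep_km) != onset_step) {
    stopf("calibration failed: no repression km lands the onset on step %d",
          onset_step)
  }
  prog <- build(rep_km)
  attr(prog, "initial_state") <- initial
  attr(prog, "onset_step") <- onset_step
  attr(prog, "threshold") <- threshold
  prog
}

#' Default L-system production rules
#'
#' The apex produces an internode plus a leaf each step and terminates in an
#' ear at `ear_step`; existing segments persist. Rule set is a plain list so
#' alternative architectures can be supplied to [grow_plant()].
#'
#' @param ear_step step at which the apex differentiates into an ear.
#' @param max_segments growth cap guarding against non-terminating rule sets.
#' @return list with entries `ear_step` and `max_segments`.
#' @export
default_rules <- function(ear_step = 8, max_segments = 200) {
  list(ear_step = ear_step, max_segments = max_segments)
}

#' Grow an L-system plant coupled to a regulatory program
#'
#' At every step the production rules are applied (apex -> internode + leaf
#' + apex; apex -> ear at the configured step) and then each segment's own
#' copy of the regulatory-program state is advanced by one simulator update.
#' Segments are created inheriting the apex's current state, so older
#' segments are molecularly older. Expression is collected from the grown
#' structure as the mean concentration per factor over segments, per step.
#'
#' @param program a [regulatory_program()], e.g. [two_gene_program()].
#' @param rules production rules from [default_rules()].
#' @param n_steps number of growth steps (`>= 1`).
#' @param initial named initial concentrations (defaults to the program's
#'   `initial_state` attribute, if any).
#' @return object of class `plant_growth`: `snapshots` (list, one
#'   `plant_structure` per step: data frame of segments plus a `states`
#'   matrix) and `expression` (factors x steps pooled matrix, an
#'   [expression_ts()]).
#' @export
grow_plant <- function(program, rules = default_rules(), n_steps,
                       initial = NULL) {
  stopifnot(inherits(program, "regulatory_program"))
  if (n_steps < 1) stopf("'n_steps' must be >= 1")
  initial <- initial %||% attr(program, "initial_state")
  fnames <- factor_names(program)
  state0 <- stats::setNames(numeric(length(fnames)), fnames)
  if (!is.null(initial)) state0[names(initial)] <- initial
  decay <- vapply(program$factors, function(f) f$decay, numeric(1))
  step_state <- function(state) {
    production <- stats::setNames(numeric(length(fnames)), fnames)
    for (g in program$genes) {
      production[[g$product]] <- production[[g$product]] +
        expression_rate(program, g$name, state)
    }
    state * (1 - decay) + production
  }
  segments <- data.frame(type = "apex", length = 1,
                         stringsAsFactors = FALSE)
  states <- matrix(state0, nrow = 1,
                   dimnames = list(NULL, fnames))
  snapshots <- vector("list", n_steps)
  # column t0 holds the pre-growth pooled state so that a one-segment,
  # no-growth rule set reproduces simulate_program() output exactly
  pooled <- matrix(0, length(fnames), n_steps + 1L,
                   dimnames = list(fnames, paste0("t", 0:n_steps)))
  pooled[, 1L] <- colMeans(states)
  for (s in seq_len(n_steps)) {
    apex <- which(segments$type == "apex")
    if (length(apex)) {
      a_state <- states[apex[1], ]
      if (s >= rules$ear_step) {
        segments$type[apex[1]] <- "ear"
      } else {
        # apex -> internode + leaf + apex (apex stays, new organs inserted)
        segments$type[apex[1]] <- "internode"
        add <- data.frame(type = c("leaf", "apex"), length = c(1, 1),
                          stringsAsFactors = FALSE)
        segments <- rbind(segments, add)
        states <- rbind(states, matrix(rep(a_state, 2), 2, byrow = TRUE,
                                       dimnames = list(NULL, fnames)))
      }
    }
    if (nrow(segments) > rules$max_segments) {
      stopf("growth cap exceeded: rule set produced more than %d segments",
            rules$max_segments)
    }
    states <- t(apply(states, 1, step_state))
    if (nrow(segments) == 1L) states <- matrix(states, 1,
                                               dimnames = list(NULL, fnames))
    pooled[, s + 1L] <- colMeans(states)
    snapshots[[s]] <- list(segments = cbind(segments,
                                            as.data.frame(states)),
                           states = states, step = s)
  }
  structure(list(snapshots = snapshots,
                 expression = expression_ts(pooled, dt = 1),
                 program = program),
            class = "plant_growth")
}

#' @export
print.plant_growth <- function(x, ...) {
  n <- length(x$snapshots)
  cat(sprintf("Plant growth: %d step(s), final structure of %d segment(s)\n",
              n, nrow(x$snapshots[[n]]$segments)))
  invisible(x)
}

# Endpoint colours chosen so that the linear green->yellow interpolation
# crosses the green/yellow hue boundary (70 degrees) exactly when the
# chlorophyll fraction passes 0.3 of its initial level, aligning the visual
# onset with the molecular threshold of two_gene_program().
senescence_green <- c(0, 170, 0)
senescence_yellow <- c(244, 220, 0)

#' Render a growing plant as an image series
#'
#' Paints each segment of each snapshot into a schematic raster (stem
#' polyline of internodes, leaf triangles, ear block) on a uniform dark
#' background. Segment colour interpolates linearly from green to yellow as
#' its chlorophyll concentration falls from the initial level toward zero.
#' The reported senescence onset is the first step at which any segment's
#' chlorophyll drops below `threshold`.
#'
#' @param growth a [grow_plant()] result.
#' @param chlorophyll_factor factor name carrying the chlorophyll signal.
#' @param threshold onset concentration (defaults to the program's calibrated
#'   `threshold` attribute, else 30% of the initial level).
#' @param width,height raster size in pixels.
#' @return object of class `plant_rendering`: `images` (list of integer
#'   `h x w x 3` arrays), `onset_step` (integer or `NA` if never crossed),
#'   `background` (RGB triple).
#' @export
render_plant <- function(growth, chlorophyll_factor = "chlorophyll",
                         threshold = NULL, width = 64, height = 96) {
  stopifnot(inherits(growth, "plant_growth"))
  fnames <- colnames(growth$snapshots[[1]]$states)
  if (!chlorophyll_factor %in% fnames) {
    stopf("unknown factor '%s'", chlorophyll_factor)
  }
  c0 <- growth$snapshots[[1]]$states[1, chlorophyll_factor]
  if (c0 <= 0) c0 <- max(vapply(growth$snapshots,
                                function(s) max(s$states[, chlorophyll_factor]),
                                numeric(1)), 1e-9)
  threshold <- threshold %||% attr(growth$program, "threshold") %||% (0.3 * c0)
  background <- c(30, 30, 35)
  images <- vector("list", length(growth$snapshots))
  onset <- NA_integer_
  for (s in seq_along(growth$snapshots)) {
    snap <- growth$snapshots[[s]]
    chl <- snap$states[, chlorophyll_factor]
    if (is.na(onset) && any(chl < threshold)) onset <- s
    frac <- pmin(pmax(chl / c0, 0), 1)
    cols <- t(vapply(frac, function(f) {
      round(f * senescence_green + (1 - f) * senescence_yellow)
    }, numeric(3)))
    images[[s]] <- paint_structure(snap$segments$type, cols, width, height,
                                   background)
  }
  structure(list(images = images, onset_step = onset,
                 threshold = threshold, background = background),
            class = "plant_rendering")
}

# Schematic raster: internodes stack upwards from the bottom; leaves attach
# as triangles alternating sides; apex/ear caps the stem.
paint_structure <- function(types, cols, width, height, background) {
  img <- array(0L, c(height, width, 3L))
  for (ch in 1:3) img[, , ch] <- background[ch]
  cx <- round(width / 2)
  stem_w <- max(1L, round(width / 28))
  internodes <- which(types == "internode")
  n_int <- length(internodes)
  seg_h <- max(3L, floor((height - 6L) / max(6L, n_int + 2L)))
  y <- height - 2L
  leaf_i <- 0L
  fill <- function(img, rows, colsx, rgb) {
    rows <- rows[rows >= 1 & rows <= height]
    colsx <- colsx[colsx >= 1 & colsx <= width]
    for (ch in 1:3) img[rows, colsx, ch] <- rgb[ch]
    img
  }
  for (i in seq_along(types)) {
    type <- types[i]; rgb <- cols[i, ]
    if (type == "internode") {
      img <- fill(img, (y - seg_h + 1L):y, (cx - stem_w):(cx + stem_w), rgb)
      y <- y - seg_h
    } else if (type == "leaf") {
      leaf_i <- leaf_i + 1L
      dir <- if (leaf_i %% 2L == 0L) 1L else -1L
      base_y <- y + seg_h %/% 2L
      leaf_len <- round(width * 0.3)
      for (d in 0:leaf_len) {
        r <- base_y - round(d * 0.2)
        c0 <- cx + dir * d
        half <- max(0L, round((leaf_len - d) / 5))
        img <- fill(img, max(1L, r - half):min(height, r + half),
                    max(1L, c0 - half):min(width, c0 + half), rgb)
      }
    } else {  # apex or ear
      cap <- if (type == "ear") 3L * stem_w else stem_w
      img <- fill(img, max(1L, y - 2L * cap):y, (cx - cap):(cx + cap), rgb)
    }
  }
  storage.mode(img) <- "integer"
  img
}

#' Recover the senescence onset from rendered images
#'
#' Feeds a rendered image series through the colour-phenotyping pipeline
#' (shared-palette quantization, background filtering, hue-class trajectory)
#' and reports the first step at which the yellow fraction of plant pixels
#' exceeds `min_yellow`.
#'
#' @param rendering a [render_plant()] result.
#' @param n_colors quantization budget.
#' @param min_yellow minimum yellow fraction calling onset (default 0.02).
#' @return list: `onset_step` (integer or `NA`), `trajectory` (the
#'   [senescence_trajectory()] data frame).
#' @export
phenotype_onset <- function(rendering, n_colors = 128, min_yellow = 0.02) {
  stopifnot(inherits(rendering, "plant_rendering"))
  q <- quantize_image_set(rendering$images, n_colors = n_colors)
  freq <- frequency_matrix(q, background_palette = rbind(rendering$background),
                           tolerance = 10)
  traj <- senescence_trajectory(freq)
  hit <- which(traj$yellow_fraction > min_yellow)
  list(onset_step = if (length(hit)) hit[1] else NA_integer_,
       trajectory = traj)
}
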