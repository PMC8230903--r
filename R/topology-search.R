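#' Generate candidate network topologies
#'
#' For each requested edge count `E`, builds one scale-free-flavoured base
#' topology by directed preferential attachment (sources drawn proportional
#' to out-degree + 1, targets to in-degree + 1, no self-edges, no duplicate
#' edges) and derives `samples_per_count` variants by random rewiring of `E`
#' edge moves. Edge signs (+1 activation, -1 repression) are drawn uniformly.
#' Optionally appends the null model: a topology with no edges between
#' nodes, the baseline any real interaction must beat.
#'
#' @param n_nodes number of genes.
#' @param edge_counts vector of edge counts `E`; each must be at most
#'   `n_nodes * (n_nodes - 1)`.
#' @param samples_per_count rewired samples per `E` (`>= 1`).
#' @param include_null append the zero-edge null model? Default `TRUE`.
#' @param seed integer seed.
#' @return list of candidates, each of class `candidate_topology`: a list
#'   with `adjacency` (signed integer matrix, entry `(j, i)` is +1/-1 for an
#'   edge `j -> i`), `n_nodes`, `n_edges`, `E`, `sample_id` (0 = base
#'   topology, `NA` for the null model).
#' @export
generate_candidates <- function(n_nodes, edge_counts, samples_per_count = 20,
                                include_null = TRUE, seed = NULL) {
  max_e <- n_nodes * (n_nodes - 1)
  if (any(edge_counts < 1) || any(edge_counts > max_e)) {
    stopf("edge counts must lie in [1, %d] for %d nodes", max_e, n_nodes)
  }
  if (samples_per_count < 1) stopf("'samples_per_count' must be >= 1")
  ids <- sprintf("n%d", seq_len(n_nodes))
  with_seed(seed, {
    out <- list()
    for (E in edge_counts) {
      base <- pref_attach_topology(n_nodes, E)
      out[[length(out) + 1L]] <- new_candidate(base, ids, E, 0L)
      for (s in seq_len(samples_per_count)) {
        out[[length(out) + 1L]] <- new_candidate(rewire_topology(base, E),
                                                 ids, E, s)
      }
    }
    if (include_null) {
      null_adj <- matrix(0L, n_nodes, n_nodes, dimnames = list(ids, ids))
      out[[length(out) + 1L]] <-
        structure(list(adjacency = null_adj, n_nodes = n_nodes,
                       n_edges = 0L, E = 0L, sample_id = NA_integer_),
                  class = "candidate_topology")
    }
    out
  })
}

new_candidate <- function(adj, ids, E, sample_id) {
  dimnames(adj) <- list(ids, ids)
  structure(list(adjacency = adj, n_nodes = nrow(adj),
                 n_edges = sum(adj != 0), E = as.integer(E),
                 sample_id = as.integer(sample_id)),
            class = "candidate_topology")
}

# Directed preferential attachment until E distinct off-diagonal slots are
# filled; returns a signed adjacency matrix.
pref_attach_topology <- function(n, E) {
  adj <- matrix(0L, n, n)
  out_deg <- rep(0, n); in_deg <- rep(0, n)
  placed <- 0L
  guard <- 0L
  while (placed < E) {
    guard <- guard + 1L
    if (guard > 100L * E + 1000L) {
      # degenerate corner (nearly full graph): fill uniformly
      empty <- which(adj == 0L & row(adj) != col(adj))
      pick <- sample(empty, E - placed)
      adj[pick] <- sign_draw(length(pick))
      break
    }
    src <- sample.int(n, 1L, prob = out_deg + 1)
    dst <- sample.int(n, 1L, prob = in_deg + 1)
    if (src == dst || adj[src, dst] != 0L) next
    adj[src, dst] <- sign_draw(1L)
    out_deg[src] <- out_deg[src] + 1
    in_deg[dst] <- in_deg[dst] + 1
    placed <- placed + 1L
  }
  adj
}

sign_draw <- function(k) ifelse(stats::runif(k) < 0.5, -1L, 1L)

# E random rewiring moves: relocate an existing edge (keeping its sign) to a
# uniformly chosen empty off-diagonal slot.
rewire_topology <- function(adj, n_moves) {
  n <- nrow(adj)
  for (m in seq_len(n_moves)) {
    edges <- which(adj != 0L)
    empty <- setdiff(which(adj == 0L & row(adj) != col(adj)), edges)
    if (!length(edges) || !length(empty)) break
    e <- if (length(edges) == 1L) edges else sample(edges, 1L)
    slot <- if (length(empty) == 1L) empty else sample(empty, 1L)
    adj[slot] <- adj[e]
    adj[e] <- 0L
  }
  adj
}

#' @export
print.candidate_topology <- function(x, ...) {
  cat(sprintf("Candidate topology: %d nodes, %d edge(s) (E = %d, sample %s)\n",
              x$n_nodes, x$n_edges, x$E,
              ifelse(is.na(x$sample_id), "null", x$sample_id)))
  invisible(x)
}

#' Pearson-based fitness between empirical and synthetic expression
#'
#' The divergence score is the sum over genes of `1 - r`, where `r` is the
#' Pearson correlation between the gene's empirical and synthetic profiles.
#' A score of 0 means every profile pair is perfectly correlated; a score
#' equal to the number of genes means no similarity (all correlations zero);
#' larger scores indicate net negative correlation, up to `2 * n_genes`.
#' A constant profile has undefined Pearson correlation; it is scored as
#' `r = 0` so that flat (e.g. null-model) trajectories count as "no
#' similarity" rather than failing.
#'
#' @param empirical,synthetic [expression_ts()] objects (or matrices) with
#'   matching gene sets and lengths.
#' @return object of class `fitness_score`: `score` and
#'   `per_gene_correlation`.
#' @export
fitness <- function(empirical, synthetic) {
  e <- if (inherits(empirical, "expression_ts")) empirical$values else as.matrix(empirical)
  s <- if (inherits(synthetic, "expression_ts")) synthetic$values else as.matrix(synthetic)
  if (!all(dim(e) == dim(s))) stopf("profile matrices differ in dimension")
  if (!is.null(rownames(e)) && !is.null(rownames(s)) &&
      !identical(rownames(e), rownames(s))) {
    stopf("gene sets do not match")
  }
  r <- vapply(seq_len(nrow(e)), function(i) {
    if (stats::sd(e[i, ]) == 0 || stats::sd(s[i, ]) == 0) return(0)
    stats::cor(e[i, ], s[i, ])
  }, numeric(1))
  names(r) <- rownames(e)
  structure(list(score = sum(1 - r), per_gene_correlation = r),
            class = "fitness_score")
}

#' @export
print.fitness_score <- function(x, ...) {
  cat(sprintf("Fitness score: %.4f over %d gene(s) (0 = identical, n = uncorrelated)\n",
              x$score, length(x$per_gene_correlation)))
  invisible(x)
}

# Instantiate a signed topology as a regulatory program: one factor and one
# gene per node; incoming +1 edges become activate elements, -1 repress.
topology_program <- function(topology, params) {
  ids <- rownames(topology$adjacency)
  factors <- lapply(seq_along(ids), function(i) {
    program_factor(paste0(ids[i], "_p"), decay = params$decay[i])
  })
  edge_idx <- which(topology$adjacency != 0L, arr.ind = TRUE)
  genes <- lapply(seq_along(ids), function(i) {
    promoter <- list(el_constitutive(params$constitutive[i]))
    if (nrow(edge_idx)) {
      inc <- which(edge_idx[, 2] == i)
      for (e in inc) {
        j <- edge_idx[e, 1]
        sgn <- topology$adjacency[edge_idx[e, 1], edge_idx[e, 2]]
        el <- if (sgn > 0) {
          el_activate(paste0(ids[j], "_p"), vmax = params$vmax[e],
                      km = params$km[e])
        } else {
          el_repress(paste0(ids[j], "_p"), vmax = params$vmax[e],
                     km = params$km[e])
        }
        promoter[[length(promoter) + 1L]] <- el
      }
    }
    program_gene(ids[i], product = paste0(ids[i], "_p"), promoter = promoter)
  })
  regulatory_program(factors, genes)
}

default_param_ranges <- function() {
  list(decay = c(0.01, 1), constitutive = c(0, 1),
       vmax = c(0, 5), km = c(0.01, 5))
}

#' Optimize the numeric parameters of a candidate topology
#'
#' Instantiates the topology as a regulatory program, draws all numeric
#' parameters (decay, constitutive rate, and per-edge vmax/km) uniformly
#' from the configured ranges, and locally minimizes the [fitness()] score of
#' the simulated profile against the empirical matrix by Nelder-Mead on
#' transformed parameters (logit for the bounded decay/constitutive rates,
#' log for the positive vmax/km). The best of `n_runs` independent restarts
#' is returned. The simulation starts from the empirical first time point
#' and runs for the empirical number of steps.
#'
#' @param topology a `candidate_topology`.
#' @param empirical an [expression_ts()] whose gene ids match the topology's
#'   node ids.
#' @param n_runs number of random restarts (`>= 1`).
#' @param seed integer seed.
#' @param max_eval objective-evaluation cap per run (default 2000).
#' @param ranges parameter ranges, see `default_param_ranges()`.
#' @return list: `program` (best [regulatory_program()]), `score` (best
#'   [fitness()] score), `runs` (per-run best scores).
#' @export
optimize_parameters <- function(topology, empirical, n_runs = 20,
                                seed = NULL, max_eval = 2000,
                                ranges = default_param_ranges()) {
  stopifnot(inherits(topology, "candidate_topology"),
            inherits(empirical, "expression_ts"))
  ids <- rownames(topology$adjacency)
  if (!identical(ids, rownames(empirical$values))) {
    stopf("topology node set does not match the empirical gene set")
  }
  if (n_runs < 1) stopf("'n_runs' must be >= 1")
  n <- topology$n_nodes
  n_edges <- topology$n_edges
  n_par <- 2L * n + 2L * n_edges
  Tn <- ncol(empirical$values)
  init_state <- stats::setNames(pmax(0, empirical$values[, 1]),
                                paste0(ids, "_p"))
  logit <- function(x) log(x / (1 - x))
  unpack <- function(theta) {
    decay01 <- stats::plogis(theta[seq_len(n)])
    list(
      decay = ranges$decay[1] + decay01 * (ranges$decay[2] - ranges$decay[1]),
      constitutive = ranges$constitutive[1] +
        stats::plogis(theta[n + seq_len(n)]) *
        (ranges$constitutive[2] - ranges$constitutive[1]),
      vmax = if (n_edges) exp(theta[2L * n + seq_len(n_edges)]) else numeric(0),
      km = if (n_edges) exp(theta[2L * n + n_edges + seq_len(n_edges)]) else numeric(0)
    )
  }
  sim_profiles <- function(prog) {
    m <- simulate_program(prog, initial = init_state, n_steps = Tn - 1L)$values
    rownames(m) <- ids  # factor rows are declared in node order
    m
  }
  objective <- function(theta) {
    fitness(empirical$values, sim_profiles(topology_program(topology,
                                                           unpack(theta))))$score
  }
  clamp01 <- function(x) pmin(pmax(x, 1e-4), 1 - 1e-4)
  best <- NULL
  run_scores <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    res <- with_seed(child_seed(seed, 1000L + r), {
      d0 <- stats::runif(n, ranges$decay[1], ranges$decay[2])
      c0 <- stats::runif(n, ranges$constitutive[1], ranges$constitutive[2])
      v0 <- stats::runif(n_edges, max(ranges$vmax[1], 1e-3), ranges$vmax[2])
      k0 <- stats::runif(n_edges, ranges$km[1], ranges$km[2])
      theta0 <- c(
        logit(clamp01((d0 - ranges$decay[1]) /
                        (ranges$decay[2] - ranges$decay[1]))),
        logit(clamp01((c0 - ranges$constitutive[1]) /
                        (ranges$constitutive[2] - ranges$constitutive[1]))),
        if (n_edges) log(v0) else numeric(0),
        if (n_edges) log(k0) else numeric(0)
      )
      o0 <- objective(theta0)
      opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                          control = list(maxit = max_eval))
      # never worse than the evaluated initialization
      if (opt$value <= o0) list(theta = opt$par, value = opt$value)
      else list(theta = theta0, value = o0)
    })
    run_scores[r] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  prog <- topology_program(topology, unpack(best$theta))
  list(program = prog,
       score = fitness(empirical$values, sim_profiles(prog)),
       runs = run_scores)
}

#' Discriminate candidate topologies against an empirical matrix
#'
#' Optimizes every candidate with [optimize_parameters()] and ranks them by
#' their best divergence score, ascending. The per-`E` summary (median and
#' interquartile range of scores) supports the comparison of edge-count
#' levels against the null model.
#'
#' @param candidates list from [generate_candidates()].
#' @param empirical an [expression_ts()].
#' @param n_runs restarts per candidate.
#' @param seed integer seed; each candidate gets an independent derived
#'   stream, so the ranking does not depend on candidate input order.
#' @param max_eval evaluation cap per run.
#' @return list of class `topology_discrimination`: `results` (data frame
#'   with `E`, `sample_id`, `n_edges`, `score`, sorted ascending by score),
#'   `programs` (best program per candidate, in `results` order), `summary`
#'   (per-E median/IQR/quartiles).
#' @export
discriminate <- function(candidates, empirical, n_runs = 20, seed = NULL,
                         max_eval = 2000) {
  if (!length(candidates)) stopf("'candidates' must be non-empty")
  rows <- vector("list", length(candidates))
  progs <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    # seed stream keyed by candidate identity, not list position
    key <- cand$E * 1000L + (if (is.na(cand$sample_id)) 999L else cand$sample_id)
    opt <- optimize_parameters(cand, empirical, n_runs = n_runs,
                               seed = child_seed(seed, key),
                               max_eval = max_eval)
    rows[[i]] <- data.frame(E = cand$E,
                            sample_id = cand$sample_id,
                            n_edges = cand$n_edges,
                            score = opt$score$score)
    progs[[i]] <- opt$program
  }
  results <- do.call(rbind, rows)
  ord <- order(results$score)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  progs <- progs[ord]
  summ <- do.call(rbind, lapply(split(results$score, results$E), function(s) {
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(q25 = q[1], median = q[2], q75 = q[3], iqr = q[3] - q[1],
               n = length(s))
  }))
  summ$E <- as.integer(rownames(summ))
  rownames(summ) <- NULL
  structure(list(results = results, programs = progs,
                 summary = summ[order(summ$E), ]),
            class = "topology_discrimination")
}

#' @export
print.topology_discrimination <- function(x, ...) {
  cat("Topology discrimination (ascending divergence scores):\n")
  print(utils::head(x$results, 10))
  cat("\nPer-E summary:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
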