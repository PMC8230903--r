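#' Regulatory programs: a declarative genome for the expression simulator
#'
#' A regulatory program declares *factors* (gene products, each with a decay
#' rate) and *genes* (each producing one factor under the control of a list of
#' promoter elements). Promoter elements are either `constitutive` (a fixed
#' expression rate), or `activate`/`repress` elements naming a trans-acting
#' factor whose effect follows a Michaelis-Menten function with maximal effect
#' `vmax` and half-effect concentration `km`.
#'
#' The simulator applies discrete synchronous updates: at each step every
#' factor concentration decays by its decay rate and receives the summed
#' expression rates of the genes producing it. Multiple promoter elements
#' combine additively; repression subtracts and the total rate is clamped at
#' zero (a documented dialect choice, see the package vignette).
#'
#' @param factors list of factors created with [program_factor()].
#' @param genes list of genes created with [program_gene()].
#' @return an object of class `regulatory_program`.
#' @examples
#' p <- regulatory_program(
#'   factors = list(program_factor("A", decay = 0.1)),
#'   genes = list(program_gene("a", product = "A",
#'                             promoter = list(el_constitutive(0.5))))
#' )
#' sim <- simulate_program(p, initial = c(A = 0), n_steps = 100)
#' @export
regulatory_program <- function(factors, genes) {
  fnames <- vapply(factors, function(f) f$name, character(1))
  gnames <- vapply(genes, function(g) g$name, character(1))
  if (anyDuplicated(fnames)) stopf("factor names must be unique")
  if (anyDuplicated(gnames)) stopf("gene names must be unique")
  for (g in genes) {
    if (!g$product %in% fnames) {
      stopf("gene '%s' produces undeclared factor '%s'", g$name, g$product)
    }
    for (el in g$promoter) {
      if (el$type != "constitutive" && !el$factor %in% fnames) {
        stopf("promoter element of gene '%s' references undeclared factor '%s'",
              g$name, el$factor)
      }
    }
  }
  names(factors) <- fnames
  names(genes) <- gnames
  structure(list(factors = factors, genes = genes),
            class = "regulatory_program")
}

#' @param name factor or gene name.
#' @param decay decay rate in `[0, 1]`: the fraction of the concentration
#'   lost per time step.
#' @rdname regulatory_program
#' @export
program_factor <- function(name, decay) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("factor name must be a non-empty string")
  }
  if (!is.numeric(decay) || decay < 0 || decay > 1) {
    stopf("decay rate of factor '%s' must lie in [0, 1]", name)
  }
  list(name = name, decay = as.numeric(decay))
}

#' @param product name of the factor this gene produces.
#' @param promoter list of promoter elements ([el_constitutive()],
#'   [el_activate()], [el_repress()]).
#' @rdname regulatory_program
#' @export
program_gene <- function(name, product, promoter = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("gene name must be a non-empty string")
  }
  list(name = name, product = product, promoter = promoter)
}

#' @param rate constitutive expression rate, `>= 0`.
#' @rdname regulatory_program
#' @export
el_constitutive <- function(rate) {
  if (!is.numeric(rate) || rate < 0) stopf("constitutive rate must be >= 0")
  list(type = "constitutive", rate = as.numeric(rate))
}

#' @param factor name of the trans-acting factor.
#' @param vmax maximal regulatory effect, `>= 0`.
#' @param km concentration at which the factor exerts half its maximal
#'   effect, `> 0`.
#' @rdname regulatory_program
#' @export
el_activate <- function(factor, vmax, km) {
  if (!is.numeric(vmax) || vmax < 0) stopf("vmax must be >= 0")
  if (!is.numeric(km) || km <= 0) stopf("km must be > 0")
  list(type = "activate", factor = factor,
       vmax = as.numeric(vmax), km = as.numeric(km))
}

#' @rdname regulatory_program
#' @export
el_repress <- function(factor, vmax, km) {
  if (!is.numeric(vmax) || vmax < 0) stopf("vmax must be >= 0")
  if (!is.numeric(km) || km <= 0) stopf("km must be > 0")
  list(type = "repress", factor = factor,
       vmax = as.numeric(vmax), km = as.numeric(km))
}

#' @export
print.regulatory_program <- function(x, ...) {
  cat(sprintf("Regulatory program: %d factor(s), %d gene(s)\n",
              length(x$factors), length(x$genes)))
  cat(serialize_program(x))
  invisible(x)
}

factor_names <- function(program) {
  vapply(program$factors, function(f) f$name, character(1))
}

#' Expression rate of a single gene
#'
#' Evaluates the promoter of one gene at the given factor concentrations:
#' the sum of constitutive rates, plus Michaelis-Menten activation terms
#' `vmax * c / (km + c)`, minus the corresponding repression terms, clamped
#' at zero.
#'
#' @param program a [regulatory_program()].
#' @param gene gene name.
#' @param state named numeric vector of factor concentrations covering every
#'   factor referenced by the gene's promoter.
#' @return a non-negative scalar rate.
#' @export
expression_rate <- function(program, gene, state) {
  stopifnot(inherits(program, "regulatory_program"))
  g <- program$genes[[gene]]
  if (is.null(g)) stopf("unknown gene '%s'", gene)
  rate <- 0
  for (el in g$promoter) {
    if (el$type == "constitutive") {
      rate <- rate + el$rate
    } else {
      c_ta <- state[[el$factor]]
      if (is.null(c_ta) || is.na(c_ta)) {
        stopf("state does not cover factor '%s'", el$factor)
      }
      mm <- el$vmax * c_ta / (el$km + c_ta)
      rate <- rate + if (el$type == "activate") mm else -mm
    }
  }
  max(0, rate)
}

#' Simulate a regulatory program
#'
#' Runs discrete synchronous updates
#' `c_f(t+1) = c_f(t) * (1 - decay_f) + sum of rates of genes producing f`
#' and collects the trajectory of every factor.
#'
#' @param program a [regulatory_program()].
#' @param initial named numeric vector of starting concentrations; factors
#'   not named start at 0.
#' @param n_steps number of update steps (`>= 1`).
#' @return an [expression_ts()] with one row per factor and columns
#'   `t = 0 ... n_steps`.
#' @export
simulate_program <- function(program, initial = NULL, n_steps) {
  stopifnot(inherits(program, "regulatory_program"))
  if (!is.numeric(n_steps) || n_steps < 1) stopf("'n_steps' must be >= 1")
  n_steps <- as.integer(n_steps)
  fnames <- factor_names(program)
  state <- stats::setNames(numeric(length(fnames)), fnames)
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), fnames)
    if (length(bad)) stopf("initial state names unknown factor '%s'", bad[1])
    state[names(initial)] <- as.numeric(initial)
  }
  if (any(state < 0)) stopf("initial concentrations must be >= 0")
  decay <- vapply(program$factors, function(f) f$decay, numeric(1))
  out <- matrix(0, nrow = length(fnames), ncol = n_steps + 1L,
                dimnames = list(fnames, paste0("t", 0:n_steps)))
  out[, 1L] <- state
  for (s in seq_len(n_steps)) {
    production <- stats::setNames(numeric(length(fnames)), fnames)
    for (g in program$genes) {
      production[[g$product]] <- production[[g$product]] +
        expression_rate(program, g$name, state)
    }
    state <- state * (1 - decay) + production
    out[, s + 1L] <- state
  }
  expression_ts(out, dt = 1)
}

#' Knock out a gene
#'
#' Returns a program in which the named gene's expression rate is identically
#' zero: its promoter elements are removed and no constitutive rate remains.
#' All other declarations are untouched, so the factor it produced still
#' decays from whatever initial concentration it is given.
#'
#' @param program a [regulatory_program()].
#' @param gene_name name of the gene to silence.
#' @return the knocked-out `regulatory_program`.
#' @export
knockout <- function(program, gene_name) {
  stopifnot(inherits(program, "regulatory_program"))
  if (!gene_name %in% names(program$genes)) {
    stopf("unknown gene '%s'", gene_name)
  }
  program$genes[[gene_name]]$promoter <- list()
  program
}

#' Ground-truth adjacency of a program
#'
#' Derives the directed gene-gene network implied by a program's promoter
#' elements: an edge from the gene producing factor F to gene G exists iff
#' G's promoter has an activate or repress element naming F.
#'
#' @param program a [regulatory_program()].
#' @return a binary adjacency matrix (rows = regulator genes, columns =
#'   target genes) with gene names as dimnames.
#' @export
program_adjacency <- function(program) {
  gnames <- names(program$genes)
  producer <- stats::setNames(rep(NA_character_, length(program$factors)),
                              names(program$factors))
  for (g in program$genes) producer[[g$product]] <- g$name
  adj <- matrix(0L, length(gnames), length(gnames),
                dimnames = list(gnames, gnames))
  for (g in program$genes) {
    for (el in g$promoter) {
      if (el$type %in% c("activate", "repress")) {
        src <- producer[[el$factor]]
        if (!is.na(src)) adj[src, g$name] <- 1L
      }
    }
  }
  adj
}

# --- program text format ----------------------------------------------------

num_tok <- function(x) sprintf("%.17g", x)

#' Parse and serialize regulatory-program text
#'
#' The text dialect is line oriented:
#' \preformatted{
#' factor NAME decay=R
#' gene NAME product=FACTOR
#'   constitutive R
#'   activate FACTOR vmax=R km=R
#'   repress FACTOR vmax=R km=R
#' }
#' Promoter lines are indented and attach to the preceding `gene` line.
#' `parse_program(serialize_program(p))` reproduces `p` exactly.
#'
#' @param text a single string, a character vector of lines, or the path of
#'   an existing file.
#' @return `parse_program` returns a [regulatory_program()];
#'   `serialize_program` returns a single string.
#' @export
parse_program <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  factors <- list()
  genes <- list()
  current <- NULL  # gene under construction
  flush_gene <- function() {
    if (!is.null(current)) genes[[length(genes) + 1L]] <<- current
    current <<- NULL
  }
  kv <- function(tok, key, lineno) {
    m <- regmatches(tok, regexec(paste0("^", key, "=(.+)$"), tok))[[1]]
    if (length(m) != 2L) {
      stopf("parse error at line %d: expected '%s=<number>', got '%s'",
            lineno, key, tok)
    }
    v <- suppressWarnings(as.numeric(m[2]))
    if (is.na(v)) stopf("parse error at line %d: '%s' is not a number", lineno, m[2])
    v
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || grepl("^\\s*#", line)) next
    indented <- grepl("^\\s", line)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!indented) {
      if (tok[1] == "factor") {
        flush_gene()
        if (length(tok) != 3L) stopf("parse error at line %d: malformed factor declaration", i)
        factors[[length(factors) + 1L]] <-
          program_factor(tok[2], kv(tok[3], "decay", i))
      } else if (tok[1] == "gene") {
        flush_gene()
        if (length(tok) != 3L) stopf("parse error at line %d: malformed gene declaration", i)
        m <- regmatches(tok[3], regexec("^product=(.+)$", tok[3]))[[1]]
        if (length(m) != 2L) stopf("parse error at line %d: expected product=FACTOR", i)
        current <- list(name = tok[2], product = m[2], promoter = list())
      } else {
        stopf("parse error at line %d: unknown declaration '%s'", i, tok[1])
      }
    } else {
      if (is.null(current)) {
        stopf("parse error at line %d: promoter element outside a gene block", i)
      }
      el <- switch(tok[1],
        constitutive = {
          if (length(tok) != 2L) stopf("parse error at line %d: constitutive takes one rate", i)
          v <- suppressWarnings(as.numeric(tok[2]))
          if (is.na(v)) stopf("parse error at line %d: '%s' is not a number", i, tok[2])
          el_constitutive(v)
        },
        activate = {
          if (length(tok) != 4L) stopf("parse error at line %d: malformed activate element", i)
          el_activate(tok[2], kv(tok[3], "vmax", i), kv(tok[4], "km", i))
        },
        repress = {
          if (length(tok) != 4L) stopf("parse error at line %d: malformed repress element", i)
          el_repress(tok[2], kv(tok[3], "vmax", i), kv(tok[4], "km", i))
        },
        stopf("parse error at line %d: unknown promoter element '%s'", i, tok[1])
      )
      current$promoter[[length(current$promoter) + 1L]] <- el
    }
  }
  flush_gene()
  regulatory_program(factors, genes)
}

#' @param program a [regulatory_program()].
#' @rdname parse_program
#' @export
serialize_program <- function(program) {
  stopifnot(inherits(program, "regulatory_program"))
  lines <- character(0)
  for (f in program$factors) {
    lines <- c(lines, sprintf("factor %s decay=%s", f$name, num_tok(f$decay)))
  }
  for (g in program$genes) {
    lines <- c(lines, sprintf("gene %s product=%s", g$name, g$product))
    for (el in g$promoter) {
      lines <- c(lines, switch(el$type,
        constitutive = sprintf("  constitutive %s", num_tok(el$rate)),
        activate = sprintf("  activate %s vmax=%s km=%s",
                           el$factor, num_tok(el$vmax), num_tok(el$km)),
        repress = sprintf("  repress %s vmax=%s km=%s",
                          el$factor, num_tok(el$vmax), num_tok(el$km))
      ))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @param path file path ending the program text dialect (conventionally
#'   `.grn`).
#' @rdname parse_program
#' @export
write_program <- function(program, path) {
  writeLines(sub("\n$", "", serialize_program(program)), path)
  invisible(path)
}

#' @rdname parse_program
#' @export
read_program <- function(path) parse_program(readLines(path))
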