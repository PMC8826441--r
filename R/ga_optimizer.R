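# Element-wise genetic optimization of the lattice density field.
#
# Compliance c(rho) = U'KU is minimized subject to KU = F, a volume
# constraint mean(rho) <= V0, and density bounds. Each element is an
# individual of the population: its relative density is coded as a binary
# gene, its fitness is the element strain energy dc_e = u_e' k_e u_e.
# Per generation, father and mother genes are drawn by roulette-wheel
# selection over element fitness, children are produced by uniform per-bit
# crossover, and a directional mutation pushes elements above the median
# fitness toward higher density and those below toward lower density. The
# best feasible design seen so far is tracked and returned (elitism).

#' Genetic-algorithm configuration
#'
#' @param crossover_factor probability that a child bit comes from the
#'   mother gene (uniform crossover).
#' @param mutation_factor per-element probability of a directional mutation
#'   per generation.
#' @param volume_fraction volume constraint `V0` on the mean relative
#'   density.
#' @param rho_bounds admissible per-element density interval.
#' @param bits_per_gene bits of the binary density encoding.
#' @param tol convergence threshold on `|c_k - c_(k-1)| / c_1`.
#' @param max_iters generation cap.
#' @param seed integer seed for the single random generator of the run.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(crossover_factor = 0.3, mutation_factor = 0.2,
                      volume_fraction = 0.4, rho_bounds = c(0.2, 0.7),
                      bits_per_gene = 8L, tol = 1e-3, max_iters = 100L,
                      seed = 1L) {
  stopifnot(crossover_factor >= 0, crossover_factor <= 1,
            mutation_factor >= 0, mutation_factor <= 1,
            length(rho_bounds) == 2L, rho_bounds[1] > 0, rho_bounds[2] < 1,
            rho_bounds[1] < rho_bounds[2],
            bits_per_gene >= 2L, tol > 0, max_iters >= 1L)
  if (volume_fraction < rho_bounds[1] || volume_fraction > rho_bounds[2]) {
    stop("infeasible config: `volume_fraction` must lie within `rho_bounds`",
         call. = FALSE)
  }
  structure(list(crossover_factor = crossover_factor,
                 mutation_factor = mutation_factor,
                 volume_fraction = volume_fraction,
                 rho_bounds = rho_bounds,
                 bits_per_gene = as.integer(bits_per_gene),
                 tol = tol, max_iters = as.integer(max_iters),
                 seed = as.integer(seed)),
            class = "ga_config")
}

## quantization step of the encoding
ga_step <- function(cfg) diff(cfg$rho_bounds) / (2^cfg$bits_per_gene - 1)

#' Encode densities as binary genes / decode genes back
#'
#' Densities are quantized linearly onto `2^bits` levels of
#' `[rho_lo, rho_hi]`: the all-zero gene is `rho_lo`, the all-one gene
#' `rho_hi`. Out-of-bounds densities are clamped with a warning.
#'
#' @param rho per-element densities.
#' @param cfg a [ga_config()].
#' @return `encode_density()`: integer 0/1 matrix (elements x bits, most
#'   significant bit first); `decode_gene()`: numeric densities.
#' @export
encode_density <- function(rho, cfg, mode = c("round", "floor")) {
  mode <- match.arg(mode)
  lo <- cfg$rho_bounds[1]; hi <- cfg$rho_bounds[2]
  if (any(rho < lo - 1e-12) || any(rho > hi + 1e-12)) {
    warning("densities outside rho_bounds clamped", call. = FALSE)
  }
  rho <- pmin(pmax(rho, lo), hi)
  b <- cfg$bits_per_gene
  frac <- (rho - lo) / (hi - lo) * (2^b - 1)
  lev <- as.integer(if (mode == "round") round(frac) else floor(frac + 1e-9))
  genes <- matrix(0L, length(rho), b)
  for (k in seq_len(b)) {           # MSB first
    w <- 2^(b - k)
    genes[, k] <- (lev %/% w) %% 2L
  }
  genes
}

#' @rdname encode_density
#' @param genes integer 0/1 matrix as produced by `encode_density()`.
#' @export
decode_gene <- function(genes, cfg) {
  b <- cfg$bits_per_gene
  stopifnot(ncol(genes) == b)
  lev <- as.vector(genes %*% 2^((b - 1):0))
  cfg$rho_bounds[1] + lev / (2^b - 1) * diff(cfg$rho_bounds)
}

#' Element fitness of a solved state
#'
#' The fitness of element `e` is its strain energy `dc_e = u_e' k_e u_e`
#' (the sensitivity of the compliance); fitnesses sum to the compliance.
#'
#' @param state an [fe_solve()] solution.
#' @return non-negative numeric vector.
#' @export
ga_fitness <- function(state) {
  if (!inherits(state, "fe_solution")) {
    stop("`state` must be a solved fe_solution", call. = FALSE)
  }
  pmax(state$element_energy, 0)
}

#' Roulette-wheel parent selection
#'
#' Draws a father and a mother element index for every element, with
#' probability proportional to fitness; all-zero fitness falls back to
#' uniform selection.
#'
#' @param fitness non-negative per-element fitness.
#' @param n number of children (defaults to `length(fitness)`).
#' @return list with integer vectors `father` and `mother`.
#' @export
select_parents <- function(fitness, n = length(fitness)) {
  if (any(fitness < 0)) stop("fitness must be non-negative", call. = FALSE)
  prob <- if (sum(fitness) > 0) fitness / sum(fitness) else NULL
  list(father = sample.int(length(fitness), n, replace = TRUE, prob = prob),
       mother = sample.int(length(fitness), n, replace = TRUE, prob = prob))
}

#' Uniform per-bit crossover
#'
#' Each child bit is taken from the mother gene with probability
#' `crossover_factor`, otherwise from the father gene.
#'
#' @param gene_a,gene_b father and mother gene matrices (elements x bits).
#' @param cfg a [ga_config()].
#' @return child gene matrix.
#' @export
crossover <- function(gene_a, gene_b, cfg) {
  if (!all(dim(gene_a) == dim(gene_b))) {
    stop("gene length mismatch in crossover", call. = FALSE)
  }
  take_b <- matrix(stats::runif(length(gene_a)) < cfg$crossover_factor,
                   nrow(gene_a))
  out <- gene_a
  out[take_b] <- gene_b[take_b]
  out
}

#' Directional mutation
#'
#' Each bit mutates independently with probability `mutation_factor`
#' (the classic per-bit binary-GA mutation rate): mutated bits are set to 1
#' when the element's fitness rank is above the median (evolving the element
#' toward higher density) and to 0 when below (toward lower density), so a
#' mutation never moves the decoded density against the bias direction.
#' This is the evolutionary pressure that lets high-strain-energy elements
#' densify and unloaded elements empty out.
#'
#' @param genes gene matrix (elements x bits).
#' @param fitness_rank per-element fitness percentile in `[0, 1]`.
#' @param cfg a [ga_config()].
#' @return mutated gene matrix.
#' @export
mutate <- function(genes, fitness_rank, cfg) {
  stopifnot(all(fitness_rank >= 0), all(fitness_rank <= 1),
            length(fitness_rank) == nrow(genes))
  hit <- matrix(stats::runif(length(genes)) < cfg$mutation_factor,
                nrow(genes))
  target <- matrix(ifelse(fitness_rank > 0.5, 1L, 0L),
                   nrow(genes), ncol(genes))
  genes[hit] <- target[hit]
  genes
}

#' Enforce the volume constraint on a density field
#'
#' Fields whose mean density exceeds `V0` are scaled multiplicatively toward
#' the lower density bound (`rho <- rho_lo + s (rho - rho_lo)`), re-clipped
#' and re-encoded; the scaling repeats until the decoded mean satisfies the
#' constraint. Feasible fields pass through unchanged.
#'
#' @param rho per-element densities within bounds.
#' @param cfg a [ga_config()].
#' @return list with `rho` (decoded, feasible) and `genes`.
#' @export
enforce_volume <- function(rho, cfg) {
  lo <- cfg$rho_bounds[1]; v0 <- cfg$volume_fraction
  if (v0 < lo) stop("infeasible config: V0 below the lower density bound",
                    call. = FALSE)
  rho <- pmin(pmax(rho, lo), cfg$rho_bounds[2])
  if (mean(rho) > v0 + 1e-12) {
    s <- (v0 - lo) / (mean(rho) - lo)
    rho <- lo + s * (rho - lo)
    rho <- pmin(pmax(rho, lo), cfg$rho_bounds[2])
    # quantize downward so rounding can never re-violate the constraint
    genes <- encode_density(rho, cfg, mode = "floor")
  } else {
    genes <- encode_density(rho, cfg)
    if (mean(decode_gene(genes, cfg)) > v0 + 1e-12) {
      genes <- encode_density(rho, cfg, mode = "floor")
    }
  }
  list(rho = decode_gene(genes, cfg), genes = genes)
}

#' Optimize the element density field by the genetic algorithm
#'
#' Initializes every element at the volume-constraint density `V0`, then per
#' generation: solve the macro FE problem, take element strain energies as
#' fitness, produce children by roulette selection and uniform crossover,
#' apply the directional mutation, enforce the volume constraint, and
#' re-solve. Terminates when the relative compliance change
#' `|c_k - c_(k-1)| / c_1` drops below `tol` or at `max_iters`. The best
#' feasible design encountered is returned (elitism), so the result is never
#' worse than the uniform initial design.
#'
#' @param mesh a [macro_mesh()] carrying loads and supports.
#' @param surrogate a `lattice_surrogate` supplying `E(rho)`, `nu(rho)`.
#' @param cfg a [ga_config()]; its `seed` drives all randomness.
#' @param design_elements indices of the designable elements (default: all).
#'   Only these evolve, carry the volume constraint, and contribute fitness.
#' @param base_material material of the non-design elements (and default for
#'   design elements before override): list with per-element or scalar `E`
#'   (MPa) and `nu`. Required when `design_elements` is a strict subset.
#' @return an object of class `fg_design`: `rho` (per design element),
#'   `genes`, `compliance`, `history` (data frame with `iter`, `compliance`,
#'   `volume`), `converged_at` (or `NA`), `config`, `design_elements`, and
#'   the initial fitness snapshot `fitness0`.
#' @export
optimize_lattice_density <- function(mesh, surrogate, cfg = ga_config(),
                                     design_elements = NULL,
                                     base_material = NULL) {
  stopifnot(inherits(mesh, "macro_mesh"),
            inherits(surrogate, "lattice_surrogate"),
            inherits(cfg, "ga_config"))
  dom <- surrogate$rho_domain
  if (cfg$rho_bounds[1] < dom[1] - 1e-9 || cfg$rho_bounds[2] > dom[2] + 1e-9) {
    stop("ga_config rho_bounds outside the surrogate domain", call. = FALSE)
  }
  nel_all <- nrow(mesh$elements)
  if (is.null(design_elements)) design_elements <- seq_len(nel_all)
  design_elements <- sort(unique(as.integer(design_elements)))
  if (length(design_elements) < nel_all && is.null(base_material)) {
    stop("`base_material` is required when only a subset of elements is designed",
         call. = FALSE)
  }
  set.seed(cfg$seed)
  nel <- length(design_elements)
  field <- enforce_volume(rep(cfg$volume_fraction, nel), cfg)
  solve_field <- function(rho) {
    pr <- predict(surrogate, rho, clamp = FALSE)
    if (is.null(base_material)) {
      mat <- list(E = pr$E, nu = pr$nu)
    } else {
      E <- rep_len(base_material$E, nel_all)
      nu <- rep_len(base_material$nu, nel_all)
      E[design_elements] <- pr$E
      nu[design_elements] <- pr$nu
      mat <- list(E = E, nu = nu)
    }
    fe_solve(mesh, stiff = assemble(mesh, material = mat))
  }
  state <- solve_field(field$rho)
  c1 <- state$compliance
  hist_c <- state$compliance
  hist_v <- mean(field$rho)
  best <- list(rho = field$rho, genes = field$genes,
               compliance = state$compliance)
  fitness0 <- ga_fitness(state)[design_elements]
  converged_at <- NA_integer_
  if (c1 == 0) {                      # zero load: nothing to optimize
    converged_at <- 2L
    hist_c <- c(hist_c, 0); hist_v <- c(hist_v, mean(field$rho))
  } else {
    c_prev <- c1
    for (k in 2:cfg$max_iters) {
      fit <- ga_fitness(state)[design_elements]
      # the element's own gene is the father; the mother is drawn by
      # fitness-proportional roulette, so dense high-energy genes spread
      # while each element keeps its local identity
      par <- select_parents(fit)
      child <- crossover(field$genes,
                         field$genes[par$mother, , drop = FALSE], cfg)
      rk <- (rank(fit, ties.method = "average") - 0.5) / nel
      child <- mutate(child, rk, cfg)
      field <- enforce_volume(decode_gene(child, cfg), cfg)
      state <- solve_field(field$rho)
      hist_c <- c(hist_c, state$compliance)
      hist_v <- c(hist_v, mean(field$rho))
      if (state$compliance < best$compliance) {
        best <- list(rho = field$rho, genes = field$genes,
                     compliance = state$compliance)
      }
      if (abs(state$compliance - c_prev) / c1 < cfg$tol) {
        converged_at <- k
        break
      }
      c_prev <- state$compliance
    }
  }
  structure(list(
    rho = best$rho, genes = best$genes, compliance = best$compliance,
    history = data.frame(iter = seq_along(hist_c), compliance = hist_c,
                         volume = hist_v),
    converged_at = converged_at, config = cfg,
    design_elements = design_elements, fitness0 = fitness0
  ), class = "fg_design")
}

#' @export
print.fg_design <- function(x, ...) {
  cat(sprintf(
    "graded lattice design: %d elements, compliance %.6g N mm, mean rho %.4f, rho in [%.3f, %.3f]\n",
    length(x$rho), x$compliance, mean(x$rho), min(x$rho), max(x$rho)))
  cat(sprintf("  %d generations, %s; V0 = %g, seed = %d\n",
              nrow(x$history),
              if (is.na(x$converged_at)) "not converged (hit max_iters)"
              else sprintf("converged at iteration %d", x$converged_at),
              x$config$volume_fraction, x$config$seed))
  invisible(x)
}

#' Plot the convergence history of a GA run
#'
#' @param x an `fg_design`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fg_design <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$history$iter, x$history$compliance, type = "b", pch = 16,
                 xlab = "generation", ylab = "compliance (N mm)", ...)
  graphics::plot(x$history$iter, x$history$volume, type = "b", pch = 16,
                 xlab = "generation", ylab = "volume fraction", ...)
  graphics::abline(h = x$config$volume_fraction, lty = 2)
  invisible(x)
}

#' Write a GA history as CSV
#'
#' @param design an `fg_design`.
#' @param path output CSV path.
#' @export
write_history_csv <- function(design, path) {
  utils::write.csv(design$history, path, row.names = FALSE)
  invisible(path)
}
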