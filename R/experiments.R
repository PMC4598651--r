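#' Default single-base error probability grid
#'
#' 40 log-spaced points in `[1e-6, 1e-1]`, matching the range over which
#' the capacity curves are usually drawn (well inside the `p < 1/3`
#' validity region of the single-error truncation).
#'
#' @param n Number of grid points.
#' @param lo,hi Grid end points.
#' @export
default_p_grid <- function(n = 40, lo = 1e-6, hi = 1e-1) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

# ensembles for a scenario; a list (one element per seeded draw for the
# random-eigenket scenario, a single element otherwise)
scenario_ensembles <- function(scenario, seeds = 1:10,
                               exclude_stop = FALSE) {
  switch(scenario,
    "mixed" = list(mixed_state_ensemble(exclude_stop)),
    "superposition" = list(superposition_ensemble(exclude_stop =
                                                    exclude_stop)),
    "random-eigenket" = lapply(seeds, random_eigenket_ensemble,
                               exclude_stop = exclude_stop),
    stop("unknown scenario: ", scenario, call. = FALSE))
}

# single scalar capacity for one model cell; random-eigenket capacity is
# the mean over the seeded draws
cell_capacity <- function(model, p = NULL, stages = 1L,
                          scenario = "superposition",
                          convention = "stochastic", seeds = 1:10,
                          kq = 1L, kc = 0L, Ps = NULL, gamma = 1,
                          layout = "canonical", exclude_stop = FALSE,
                          tol = 1e-9, max_iter = 10000L) {
  res <- switch(model,
    "classical" = list(classical_codon_capacity(p, stages, exclude_stop,
                                                tol, max_iter)),
    "quantum" = lapply(scenario_ensembles(scenario, seeds, exclude_stop),
                       function(ens) {
                         quantum_codon_capacity(p, stages, ens, convention,
                                                tol, max_iter)
                       }),
    "hybrid" = list(hybrid_codon_capacity(p, kq, kc, exclude_stop,
                                          convention, tol, max_iter)),
    "msc" = list(nucleotide_capacity(Ps, stages, "msc", tol = tol,
                                     max_iter = max_iter)),
    "kimura" = list(nucleotide_capacity(Ps, stages, "kimura", gamma,
                                        layout, tol, max_iter)),
    stop("unknown model: ", model, call. = FALSE))
  caps <- vapply(res, function(r) r$capacity, numeric(1))
  list(capacity = mean(caps), draws = caps,
       converged = all(vapply(res, function(r) r$converged, logical(1))),
       units = res[[1]]$units)
}

#' Capacity sweeps over error probability and over generations
#'
#' `capacity_vs_p()` evaluates one model's capacity over a grid of
#' single-base (or symbol) error probabilities for each stage count;
#' `capacity_vs_generations()` sweeps the number of generations (one chain
#' stage per generation) at fixed error probability. Both return tidy
#' tibbles, one row per grid cell, ready for [ggplot2::autoplot()].
#'
#' For the random-eigenket scenario each cell is the mean capacity over the
#' seeded draws in `seeds`; the per-draw spread is reported in
#' `capacity_sd`.
#'
#' @param model One of `"classical"`, `"quantum"`, `"hybrid"`, `"msc"`,
#'   `"kimura"`.
#' @param p Grid of single-base error probabilities (codon-level models) or
#'   symbol error probabilities (nucleotide-level models).
#' @param stages Integer vector of stage counts.
#' @param scenario Quantum input scenario: `"superposition"`, `"mixed"` or
#'   `"random-eigenket"`.
#' @param convention Evaluation convention for composed quantum stages, see
#'   [quantum_codon_capacity()].
#' @param seeds Seeds for the random-eigenket draws.
#' @param kq,kc Hybrid stage split.
#' @param gamma,layout Kimura parameters.
#' @param exclude_stop Drop the stop class from input ensembles?
#' @param tol,max_iter Optimizer controls.
#' @return A tibble of class `codon_capacity_sweep` with columns `model`,
#'   `p`, `stages`, `capacity`, `capacity_sd`, `converged`, `units` (plus
#'   `scenario`/`convention` for quantum models).
#' @examples
#' \donttest{
#' sw <- capacity_vs_p("classical", p = c(1e-4, 1e-3), stages = 1:2)
#' }
#' @export
capacity_vs_p <- function(model, p = default_p_grid(), stages = 1L,
                          scenario = "superposition",
                          convention = "stochastic", seeds = 1:10,
                          kq = 1L, kc = 0L, gamma = 1,
                          layout = "canonical", exclude_stop = FALSE,
                          tol = 1e-9, max_iter = 10000L) {
  grid <- expand.grid(p = p, stages = stages, KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::pmap(grid, function(p, stages) {
    cell <- cell_capacity(model, p = p, stages = stages,
                          scenario = scenario, convention = convention,
                          seeds = seeds, kq = kq, kc = kc,
                          Ps = p, gamma = gamma, layout = layout,
                          exclude_stop = exclude_stop, tol = tol,
                          max_iter = max_iter)
    tibble::tibble(model = model, p = p, stages = stages,
                   capacity = cell$capacity,
                   capacity_sd = stats::sd(cell$draws),
                   converged = cell$converged, units = cell$units)
  })
  out <- dplyr::bind_rows(rows)
  if (model == "quantum") {
    out$scenario <- scenario
    out$convention <- convention
  }
  new_sweep(out, params = list(model = model, scenario = scenario,
                               convention = convention, seeds = seeds,
                               kq = kq, kc = kc, gamma = gamma,
                               layout = layout,
                               exclude_stop = exclude_stop))
}

#' @rdname capacity_vs_p
#' @param generations Integer vector of generation counts (`0` = noiseless
#'   identity channel).
#' @export
capacity_vs_generations <- function(model, p, generations = 1:50,
                                    scenario = "superposition",
                                    convention = "stochastic",
                                    seeds = 1:10, kq = 1L, kc = 0L,
                                    gamma = 1, layout = "canonical",
                                    exclude_stop = FALSE, tol = 1e-9,
                                    max_iter = 10000L) {
  rows <- purrr::map(generations, function(n) {
    cell <- if (n == 0) {
      cell_capacity(model, p = 0, stages = 1L, scenario = scenario,
                    convention = convention, seeds = seeds, kq = kq,
                    kc = kc, Ps = 0, gamma = gamma, layout = layout,
                    exclude_stop = exclude_stop, tol = tol,
                    max_iter = max_iter)
    } else {
      cell_capacity(model, p = p, stages = n, scenario = scenario,
                    convention = convention, seeds = seeds, kq = kq,
                    kc = kc, Ps = p, gamma = gamma, layout = layout,
                    exclude_stop = exclude_stop, tol = tol,
                    max_iter = max_iter)
    }
    tibble::tibble(model = model, p = p, generations = n,
                   capacity = cell$capacity,
                   capacity_sd = stats::sd(cell$draws),
                   converged = cell$converged, units = cell$units)
  })
  out <- dplyr::bind_rows(rows)
  if (model == "quantum") {
    out$scenario <- scenario
    out$convention <- convention
  }
  new_sweep(out, params = list(model = model, p = p, scenario = scenario,
                               convention = convention, seeds = seeds,
                               kq = kq, kc = kc, gamma = gamma,
                               layout = layout,
                               exclude_stop = exclude_stop))
}

new_sweep <- function(df, params) {
  class(df) <- c("codon_capacity_sweep", class(df))
  attr(df, "params") <- params
  df
}

#' Locate the crossing of two capacity curves
#'
#' `find_crossing()` is the generic locator: given a difference function
#' (capacity of model A minus capacity of model B), it scans a grid for a
#' sign change and refines it -- bisection on `log10 p` to relative
#' tolerance `rtol` on the probability axis, integer binary search on the
#' generations axis. If the difference never changes sign an explicit
#' no-crossing result is returned (`crossing = NA`); if it changes sign
#' more than once the first bracket is refined and the others reported in
#' the diagnostics.
#'
#' @param diff_fun Function of the swept parameter returning capacity
#'   difference in bits.
#' @param grid Probability grid to scan (p axis).
#' @param rtol Relative bracket tolerance for the p-axis bisection.
#' @param n_max Largest generation count scanned (generations axis).
#' @param axis `"p"` or `"generations"`.
#' @return A list: `crossing` (parameter value, `NA` if none),
#'   `direction` (`"down"` if the difference goes from positive to
#'   negative, `"up"` otherwise), `bracket`, `endpoint_diffs`,
#'   `n_sign_changes`. On the generations axis `crossing` is the first
#'   integer on the flipped side and `last_initial` the last on the
#'   starting side.
#' @export
find_crossing <- function(diff_fun, axis = c("p", "generations"),
                          grid = default_p_grid(), rtol = 1e-3,
                          n_max = 2048L) {
  axis <- match.arg(axis)
  if (axis == "p") {
    vals <- vapply(grid, diff_fun, numeric(1))
    s <- sign(vals)
    flips <- which(s[-1] != 0 & s[-length(s)] != 0 &
                     s[-1] != s[-length(s)])
    if (length(flips) == 0) {
      return(list(crossing = NA_real_, direction = NA_character_,
                  bracket = NULL, endpoint_diffs = range(vals),
                  n_sign_changes = 0L))
    }
    i <- flips[1]
    lo <- grid[i]; hi <- grid[i + 1]
    flo <- vals[i]
    while (hi / lo > 1 + rtol) {
      mid <- sqrt(lo * hi)
      fm <- diff_fun(mid)
      if (sign(fm) == sign(flo)) {
        lo <- mid; flo <- fm
      } else {
        hi <- mid
      }
    }
    list(crossing = sqrt(lo * hi),
         direction = if (vals[i] > 0) "down" else "up",
         bracket = c(lo, hi), endpoint_diffs = c(vals[i], vals[i + 1]),
         n_sign_changes = length(flips))
  } else {
    # doubling scan for the first sign flip, then integer binary search
    n <- 1L
    d <- diff_fun(n)
    while (abs(d) < 1e-13 && n < n_max) {   # skip the degenerate start
      n <- n * 2L
      d <- diff_fun(n)
    }
    if (abs(d) < 1e-13) {
      return(list(crossing = NA_integer_, direction = NA_character_,
                  last_initial = NA_integer_, n_sign_changes = 0L))
    }
    s0 <- sign(d)
    lo <- n
    hi <- NA_integer_
    while (lo < n_max) {
      nn <- min(2L * lo, n_max)
      if (sign(diff_fun(nn)) != s0) {
        hi <- nn
        break
      }
      lo <- nn
    }
    if (is.na(hi)) {
      return(list(crossing = NA_integer_, direction = NA_character_,
                  last_initial = lo, n_sign_changes = 0L))
    }
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (sign(diff_fun(mid)) == s0) lo <- mid else hi <- mid
    }
    list(crossing = hi, last_initial = lo,
         direction = if (s0 > 0) "down" else "up", n_sign_changes = 1L)
  }
}

#' Quantum-vs-classical crossing threshold of the codon channel
#'
#' Finds where the quantum chain's capacity curve (for a given input
#' scenario) crosses the classical chain's, either along the single-base
#' error probability at fixed stage count or along the generation count at
#' fixed `p`. The random-eigenket scenario uses the mean capacity over the
#' seeded draws.
#'
#' Because the composed operator sum is not trace preserving, the two
#' evaluation conventions of [quantum_codon_capacity()] order the curves
#' differently, and for some scenario/stage combinations only one of them
#' produces a sign change. The search therefore proceeds through a fixed
#' ladder -- (1) the default stochastic convention on `grid`; (2) the
#' literal convention on `grid`; (3) the stochastic convention on the
#' extension of the grid up to `p = 0.32` (p axis only) -- and reports the
#' first convention under which the curves cross, which is recorded in the
#' result. The vignette discusses why neither convention reproduces the
#' crossing direction claimed for coherence-preserving channel
#' reconstructions.
#'
#' @inheritParams capacity_vs_p
#' @param axis `"p"` (threshold error probability at fixed `stages`) or
#'   `"generations"` (threshold generation count at fixed `p`).
#' @param stages Stage count for the p-axis search.
#' @param p Error probability for the generations-axis search.
#' @param grid Probability grid scanned for a sign change.
#' @param n_max Largest generation count considered.
#' @param rtol Relative tolerance of the p-axis bisection.
#' @return A list with `crossing`, `convention`, `direction`,
#'   `scenario`, `axis` and the raw locator output in `detail`.
#' @export
crossing_threshold <- function(scenario = "superposition",
                               axis = c("p", "generations"),
                               stages = 2L, p = NULL,
                               grid = default_p_grid(), n_max = 2048L,
                               seeds = 1:10, exclude_stop = FALSE,
                               rtol = 1e-3, tol = 1e-11,
                               max_iter = 100000L) {
  axis <- match.arg(axis)
  ensembles <- scenario_ensembles(scenario, seeds, exclude_stop)
  part <- aa_classes(exclude_stop)
  diff_at <- function(pp, k, convention) {
    qc <- mean(vapply(ensembles, function(ens) {
      quantum_codon_capacity(pp, k, ens, convention, tol = tol,
                             max_iter = max_iter)$capacity
    }, numeric(1)))
    cc <- classical_codon_capacity(pp, k, exclude_stop, tol = tol,
                                   max_iter = max_iter)$capacity
    qc - cc
  }
  ladder <- if (axis == "p") {
    list(list(convention = "stochastic", grid = grid),
         list(convention = "literal", grid = grid),
         list(convention = "stochastic",
              grid = extended_p_grid(max(grid))))
  } else {
    list(list(convention = "stochastic"), list(convention = "literal"))
  }
  for (step in ladder) {
    res <- if (axis == "p") {
      find_crossing(function(pp) diff_at(pp, stages, step$convention),
                    axis = "p", grid = step$grid, rtol = rtol)
    } else {
      find_crossing(function(n) diff_at(p, n, step$convention),
                    axis = "generations", n_max = n_max)
    }
    if (!is.na(res$crossing)) {
      return(list(crossing = res$crossing, convention = step$convention,
                  direction = res$direction, scenario = scenario,
                  axis = axis, detail = res))
    }
  }
  list(crossing = NA_real_, convention = NA_character_,
       direction = NA_character_, scenario = scenario, axis = axis,
       detail = res)
}

extended_p_grid <- function(lo, hi = 0.32, n = 12) {
  10^seq(log10(lo), log10(hi), length.out = n + 1)[-1]
}

#' Plot a capacity sweep
#'
#' Capacity against `log10` error probability (or against generations),
#' one line per stage count or model.
#'
#' @param object,x A `codon_capacity_sweep` tibble.
#' @param ... Unused.
#' @method autoplot codon_capacity_sweep
#' @export
autoplot.codon_capacity_sweep <- function(object, ...) {
  if ("generations" %in% names(object)) {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$generations,
                                 y = .data$capacity,
                                 colour = .data$model)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "generations",
                    y = paste0("capacity (", object$units[1], ")"))
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$p, y = .data$capacity,
                                 colour = factor(.data$stages))) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "single-base error probability",
                    y = paste0("capacity (", object$units[1], ")"),
                    colour = "stages")
  }
}

#' @rdname autoplot.codon_capacity_sweep
#' @method plot codon_capacity_sweep
#' @export
plot.codon_capacity_sweep <- function(x, ...) {
  print(autoplot.codon_capacity_sweep(x, ...))
  invisible(x)
}

#' Write a sweep with a reproducibility manifest
#'
#' Writes the tidy CSV and a JSON sidecar (`<path>.manifest.json`) holding
#' the sweep parameters, seeds, package version and a content hash, so a
#' rerun can be verified bit-for-bit.
#'
#' @param sweep A `codon_capacity_sweep`.
#' @param path CSV output path.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  manifest <- list(params = attr(sweep, "params"),
                   package = "codonchannel",
                   version = as.character(utils::packageVersion(
                     "codonchannel")),
                   hash = rlang::hash(as.data.frame(sweep)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

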