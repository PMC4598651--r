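#' Amino-acid input ensembles over codon basekets
#'
#' The channel input is an amino acid; each of the 21 classes (stop
#' included by default) contributes one prior probability and one density
#' matrix over the 64 codon basekets. Three preparations are supported:
#'
#' * `mixed_state_ensemble()` -- scenario "mixed": each class is the uniform
#'   statistical mixture of its synonymous basekets (a diagonal, essentially
#'   semi-classical state).
#' * `superposition_ensemble()` -- scenario "superposition": each class is a
#'   pure state. By default the equal-amplitude superposition
#'   `(1/sqrt(s)) sum_i |b_i>` of its synonymous codons is used; a table of
#'   per-class eigenkets (e.g. derived from a codon Hamiltonian) may be
#'   supplied instead.
#' * `random_eigenket_ensemble()` -- scenario "random-eigenket": each class
#'   is one of its synonymous basekets, drawn uniformly at random under a
#'   seed.
#'
#' Initial priors are uniform over classes; the capacity optimizer adjusts
#' them.
#'
#' @param exclude_stop Drop the stop class from the ensemble?
#' @return A `codon_ensemble`: a tibble with columns `class`, `prior` and
#'   `state` (list of 64 x 64 density matrices), and a `scenario`
#'   attribute.
#' @examples
#' ens <- mixed_state_ensemble()
#' diag(ens$state[[which(ens$class == "F")]])[codon_index(c("UUU", "UUC"))]
#' @export
mixed_state_ensemble <- function(exclude_stop = FALSE) {
  cls <- aa_classes(exclude_stop)
  states <- lapply(cls, mixed_density)
  new_codon_ensemble(names(cls), states, scenario = "mixed")
}

#' @rdname mixed_state_ensemble
#' @param eigenkets Optional per-class kets: a complex matrix with one row
#'   per class (rownames = class labels, 64 columns, unit norm rows), as
#'   read by [read_eigenket_csv()]. Defaults to the equal-amplitude
#'   synonymous superposition.
#' @export
superposition_ensemble <- function(eigenkets = NULL, exclude_stop = FALSE) {
  cls <- aa_classes(exclude_stop)
  if (is.null(eigenkets)) {
    states <- lapply(cls, function(ix) {
      v <- numeric(64)
      v[ix] <- 1 / sqrt(length(ix))
      pure_state_density(v)
    })
  } else {
    stopifnot(is.matrix(eigenkets), ncol(eigenkets) == 64,
              !is.null(rownames(eigenkets)))
    missing <- setdiff(names(cls), rownames(eigenkets))
    if (length(missing) > 0) {
      stop("eigenket table lacks classes: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    nrm <- sqrt(rowSums(Mod(eigenkets)^2))
    if (max(abs(nrm - 1)) > 1e-8) {
      stop("user eigenkets must have unit norm (max deviation ",
           format(max(abs(nrm - 1))), ")", call. = FALSE)
    }
    states <- lapply(names(cls), function(cl) {
      pure_state_density(eigenkets[cl, ])
    })
  }
  new_codon_ensemble(names(cls), states, scenario = "superposition")
}

#' @rdname mixed_state_ensemble
#' @param seed Integer seed controlling the per-class codon draw
#'   (reproducible; the caller's RNG state is untouched).
#' @export
random_eigenket_ensemble <- function(seed, exclude_stop = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cls <- aa_classes(exclude_stop)
  picks <- withr::with_seed(as.integer(seed), {
    vapply(cls, function(ix) ix[sample.int(length(ix), 1L)], integer(1))
  })
  states <- lapply(picks, mixed_density)
  ens <- new_codon_ensemble(names(cls), states, scenario = "random-eigenket")
  attr(ens, "picks") <- picks
  ens
}

new_codon_ensemble <- function(classes, states, scenario,
                               priors = rep(1 / length(classes),
                                            length(classes))) {
  out <- tibble::tibble(class = classes, prior = priors,
                        state = unname(states))
  class(out) <- c("codon_ensemble", class(out))
  attr(out, "scenario") <- scenario
  out
}

#' @rdname mixed_state_ensemble
#' @param ens A `codon_ensemble`.
#' @return `ensemble_average()`: the prior-weighted average density matrix
#'   `sum_x p_x rho_x`.
#' @export
ensemble_average <- function(ens, priors = ens$prior) {
  stopifnot(abs(sum(priors) - 1) < 1e-8)
  Reduce(`+`, Map(`*`, ens$state, priors))
}

#' @rdname mixed_state_ensemble
#' @export
ensemble_scenario <- function(ens) attr(ens, "scenario")

#' Read or write a per-class eigenket table
#'
#' CSV interchange format for user-supplied class kets: one row per
#' amino-acid class, a `class` column, then `re1, im1, ..., re64, im64`
#' amplitude columns in the fixed codon order.
#'
#' @param path CSV file path.
#' @return `read_eigenket_csv()`: a complex matrix (classes x 64) with
#'   class rownames, suitable for [superposition_ensemble()].
#' @export
read_eigenket_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot("class" %in% names(df), ncol(df) == 129)
  m <- as.matrix(df[, setdiff(names(df), "class")])
  kets <- m[, seq(1, 127, by = 2), drop = FALSE] +
    1i * m[, seq(2, 128, by = 2), drop = FALSE]
  rownames(kets) <- df$class
  colnames(kets) <- codon_alphabet()
  kets
}

#' @rdname read_eigenket_csv
#' @param kets Complex matrix (classes x 64) with class rownames.
#' @export
write_eigenket_csv <- function(kets, path) {
  stopifnot(is.matrix(kets), ncol(kets) == 64, !is.null(rownames(kets)))
  out <- data.frame(class = rownames(kets))
  for (j in 1:64) {
    out[[paste0("re", j)]] <- Re(kets[, j])
    out[[paste0("im", j)]] <- Im(kets[, j])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
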