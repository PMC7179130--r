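# Synthetic training data ---------------------------------------------------
#
# The fitting machinery is exercised with synthetic training sets: sparse
# non-negative group-count vectors of full column rank, with targets built
# from known "true" contributions plus Gaussian noise.  The defaults mirror
# the study conditions of the liquid fit: contributions drawn from the
# shipped liquid table and a noise level of 8 J/mol/K, the standard
# deviation reported for that fit.

#' Specify a synthetic training set
#'
#' @param group_keys group keys to use as columns; defaults to a seeded
#'   sample of `n_groups` valid atom-group keys from the bundled liquid
#'   table.
#' @param true_contributions true contribution values (J/mol/K); defaults to
#'   the table values of `group_keys`.
#' @param n_molecules number of synthetic compounds (at least the number of
#'   groups).
#' @param noise_sigma Gaussian noise on the targets, J/mol/K.
#' @param seed integer seed; the whole generation is deterministic under it.
#' @param n_groups number of groups when `group_keys` is NULL.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(group_keys = NULL, true_contributions = NULL,
                       n_molecules = 500L, noise_sigma = 8, seed = 1L,
                       n_groups = 30L) {
  if (is.null(group_keys)) {
    tab <- cp_table("liquid")
    pool <- tab[tab$valid & !tab$special, ]
    group_keys <- withr::with_seed(seed,
      sample(pool$key, min(n_groups, nrow(pool))))
    if (is.null(true_contributions)) {
      true_contributions <- pool$contribution[match(group_keys, pool$key)]
    }
  }
  if (is.null(true_contributions)) {
    true_contributions <- withr::with_seed(seed,
      stats::runif(length(group_keys), -100, 150))
  }
  stopifnot(length(group_keys) == length(true_contributions),
            n_molecules >= length(group_keys), noise_sigma >= 0)
  structure(list(group_keys = group_keys,
                 true_contributions = stats::setNames(true_contributions,
                                                      group_keys),
                 n_molecules = as.integer(n_molecules),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic training set
#'
#' Draws sparse non-negative count vectors (2-6 distinct groups per compound,
#' counts of 1-4) until the count matrix has full column rank, then computes
#' targets as the additivity sum plus Gaussian noise.
#'
#' @param spec a [synth_spec()].
#' @param max_retries rank-repair attempts before giving up.
#' @return A tibble (`name`, `cp`) with the count matrix attached as
#'   attribute `"counts"`; pass both to [cp_design_from_counts()] or use
#'   [synth_design()] directly.
#' @export
generate_synthetic_training <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_molecules
  p <- length(spec$group_keys)
  withr::with_seed(spec$seed, {
    G <- matrix(0L, n, p, dimnames = list(sprintf("synth_%04d", seq_len(n)),
                                          spec$group_keys))
    for (i in seq_len(n)) {
      ng <- sample(2:min(6, p), 1)
      cols <- sample.int(p, ng)
      G[i, cols] <- 1L + stats::rpois(ng, 1.2)
    }
    tries <- 0L
    while (qr(G)$rank < p) {
      tries <- tries + 1L
      if (tries > max_retries) {
        stop("could not reach full column rank after ", max_retries,
             " retries", call. = FALSE)
      }
      # re-draw the sparsest rows to repair rank deficiency
      i <- sample.int(n, 1)
      ng <- sample(2:min(6, p), 1)
      G[i, ] <- 0L
      G[i, sample.int(p, ng)] <- 1L + stats::rpois(ng, 1.2)
    }
    cp <- as.numeric(G %*% spec$true_contributions) +
      stats::rnorm(n, 0, spec$noise_sigma)
  })
  out <- tibble::tibble(name = rownames(G), cp = cp)
  attr(out, "counts") <- G
  out
}

#' Build a `cp_design` straight from a synthetic specification
#'
#' @inheritParams generate_synthetic_training
#' @return A `cp_design`.
#' @export
synth_design <- function(spec, max_retries = 50L) {
  d <- generate_synthetic_training(spec, max_retries = max_retries)
  cp_design_from_counts(attr(d, "counts"), d$cp)
}
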