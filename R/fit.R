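# Contribution fitting ------------------------------------------------------
#
# Re-deriving group contributions from a training set follows the published
# recipe: build the M x N occurrence matrix of group counts, normalise it to
# the (symmetric, positive-definite) normal equations, balance those with the
# iterative Gauss-Seidel calculus, judge the result by 10-fold
# cross-validation, and iteratively drop compounds whose residual exceeds
# three cross-validated standard deviations.

#' Assemble the occurrence design matrix from structures
#'
#' @param data data frame with columns `smiles` and `cp` (experimental
#'   heat capacities, J/mol/K); an optional `name` column labels rows.
#' @param cohn_mode polyol counting convention, see [count_special_groups()].
#' @param refine apply the hydroxy O(prim)/O(sec)/O(tert) refinement.
#' @return A `cp_design`: list with the count matrix `G` (compounds x
#'   groups), target vector `y`, per-group kind, and the number of distinct
#'   supporting molecules per group.  Compounds whose perception fails are
#'   skipped with a warning.
#' @export
cp_design <- function(data, cohn_mode = "n_minus_one", refine = TRUE) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("smiles", "cp") %in% names(data)))
  if (nrow(data) == 0) stop("no usable compounds", call. = FALSE)
  name <- if ("name" %in% names(data)) data$name else data$smiles
  counts <- vector("list", nrow(data))
  keep <- logical(nrow(data))
  for (i in seq_len(nrow(data))) {
    gc <- tryCatch(
      perceive_groups(parse_smiles(data$smiles[[i]]),
                      cohn_mode = cohn_mode, refine = refine),
      error = function(e) e
    )
    if (inherits(gc, "error")) {
      warning("compound '", name[[i]], "' skipped: ", conditionMessage(gc),
              call. = FALSE)
    } else {
      counts[[i]] <- gc
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) stop("no usable compounds", call. = FALSE)
  counts <- counts[keep]
  keys <- sort(unique(unlist(lapply(counts, `[[`, "key"))))
  G <- matrix(0L, nrow = length(counts), ncol = length(keys),
              dimnames = list(name[keep], keys))
  for (i in seq_along(counts)) {
    G[i, counts[[i]]$key] <- counts[[i]]$count
  }
  kind <- vapply(keys, function(k) {
    if (k %in% SPECIAL_KEYS) "special" else "atom"
  }, character(1))
  new_cp_design(G, data$cp[keep], kind)
}

#' Assemble a design from a precomputed count matrix
#'
#' @param counts numeric matrix (compounds x groups) of occurrence counts,
#'   with column names as group keys.
#' @param cp experimental values, one per row.
#' @return A `cp_design`.
#' @export
cp_design_from_counts <- function(counts, cp) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(cp), !is.null(colnames(counts)))
  if (nrow(counts) == 0) stop("no usable compounds", call. = FALSE)
  kind <- ifelse(colnames(counts) %in% SPECIAL_KEYS, "special", "atom")
  new_cp_design(counts, cp, kind)
}

new_cp_design <- function(G, y, kind) {
  empty <- colSums(G != 0) == 0
  if (any(empty)) {
    G <- G[, !empty, drop = FALSE]
    kind <- kind[!empty]
  }
  structure(list(G = G, y = as.numeric(y), kind = kind,
                 support = colSums(G != 0)),
            class = "cp_design")
}

#' @export
print.cp_design <- function(x, ...) {
  cat("<cp_design> ", nrow(x$G), " compounds x ", ncol(x$G), " groups (",
      sum(x$kind == "special"), " special)\n", sep = "")
  invisible(x)
}

#' Solve a least-squares system by Gauss-Seidel iteration
#'
#' Forms the normal equations G'G x = G'y and sweeps the classical
#' Gauss-Seidel update until the largest coordinate change falls below `tol`.
#' On the symmetric positive-definite normal equations the iteration is
#' guaranteed to converge to the least-squares solution.
#'
#' @param G design matrix (or a `cp_design`).
#' @param y target vector (ignored when `G` is a `cp_design`).
#' @param tol convergence threshold on the maximum coordinate change.
#' @param max_iter sweep limit.
#' @return The solution vector with attributes `iterations` and `converged`.
#' @examples
#' G <- cbind(a = c(2, 2), b = c(0, 4))
#' solve_gauss_seidel(G, c(74.06, 194.30))
#' @export
solve_gauss_seidel <- function(G, y = NULL, tol = 1e-9, max_iter = 200000L) {
  if (inherits(G, "cp_design")) {
    y <- G$y
    G <- G$G
  }
  A <- crossprod(G)
  b <- crossprod(G, y)
  n <- ncol(A)
  d <- diag(A)
  if (any(d == 0)) {
    stop("degenerate column(s) with zero diagonal: ",
         paste(colnames(G)[d == 0], collapse = ", "), call. = FALSE)
  }
  x <- numeric(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta <- 0
    for (j in seq_len(n)) {
      xj <- (b[j] - sum(A[j, ] * x) + A[j, j] * x[j]) / d[j]
      delta <- max(delta, abs(xj - x[j]))
      x[j] <- xj
    }
    if (delta < tol) break
    if (iter >= max_iter) {
      res <- sqrt(sum((G %*% x - y)^2))
      stop("Gauss-Seidel did not converge in ", max_iter,
           " sweeps (last residual norm ", format(res), ")", call. = FALSE)
    }
  }
  structure(stats::setNames(as.numeric(x), colnames(G)),
            iterations = iter, converged = TRUE)
}

#' K-fold cross-validation of a contribution fit
#'
#' Compounds are shuffled (seeded) into `k` near-equal folds; each compound is
#' predicted exactly once from a model fitted without its fold.  A held-out
#' compound that requires a group supported by fewer than `support_min`
#' distinct molecules of its training folds cannot be predicted reliably and
#' is excluded from the pooled cross-validation statistics (this is what makes
#' the cross-validated compound count smaller than the fitted count).
#'
#' @param design a `cp_design`.
#' @param k number of folds (at least 2, at most the number of compounds).
#' @param seed integer seed for the fold shuffle.
#' @param support_min minimum distinct-molecule support required of every
#'   group of a held-out compound.
#' @param folds optional explicit fold assignment (integer vector, one entry
#'   per compound), overriding the seeded shuffle.
#' @param tol,max_iter forwarded to [solve_gauss_seidel()].
#' @return A tibble (compound, fold, cp_exp, cp_cv, excluded).
#' @export
cp_cross_validate <- function(design, k = 10, seed = 1, support_min = 3L,
                              folds = NULL, tol = 1e-9, max_iter = 200000L) {
  stopifnot(inherits(design, "cp_design"))
  m <- nrow(design$G)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  k <- min(k, m)
  if (is.null(folds)) {
    perm <- withr::with_seed(seed, sample.int(m))
    fold <- integer(m)
    fold[perm] <- rep_len(seq_len(k), m)
  } else {
    stopifnot(length(folds) == m)
    fold <- as.integer(folds)
    k <- max(fold)
  }
  cp_cv <- rep(NA_real_, m)
  excluded <- logical(m)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    Gtr <- design$G[train, , drop = FALSE]
    supp <- colSums(Gtr != 0)
    usable <- supp > 0
    x <- solve_gauss_seidel(Gtr[, usable, drop = FALSE], design$y[train],
                            tol = tol, max_iter = max_iter)
    for (i in test) {
      need <- design$G[i, ] != 0
      if (any(supp[need] < support_min)) {
        excluded[i] <- TRUE
      } else {
        cp_cv[i] <- sum(design$G[i, usable] * x)
      }
    }
  }
  tibble::tibble(compound = rownames(design$G), fold = fold,
                 cp_exp = design$y, cp_cv = cp_cv, excluded = excluded)
}

#' Prediction statistics
#'
#' @param pred,exp paired numeric vectors (predicted and experimental).
#' @return One-row tibble: `r2` (squared Pearson correlation), `r2_ss`
#'   (1 - SSE/SST), `avg_dev` (mean absolute deviation), `std_dev`
#'   (root mean square deviation with n - 1 denominator), `mapd` (mean
#'   absolute percentage deviation) and `n`.
#' @examples
#' cp_statistics(c(100, 200), c(110, 190))
#' @export
cp_statistics <- function(pred, exp) {
  stopifnot(length(pred) == length(exp))
  ok <- !is.na(pred) & !is.na(exp)
  pred <- pred[ok]; exp <- exp[ok]
  if (length(pred) < 2) stop("need at least two paired values", call. = FALSE)
  if (any(exp == 0)) stop("experimental values must be non-zero", call. = FALSE)
  d <- pred - exp
  tibble::tibble(
    r2 = if (stats::sd(pred) == 0 || stats::sd(exp) == 0) NA_real_
         else stats::cor(pred, exp)^2,
    r2_ss = 1 - sum(d^2) / sum((exp - mean(exp))^2),
    avg_dev = mean(abs(d)),
    std_dev = sqrt(sum(d^2) / (length(d) - 1)),
    mapd = 100 * mean(abs(d) / abs(exp)),
    n = length(d)
  )
}

#' Fit group contributions with cross-validation and outlier elimination
#'
#' Repeats fit -> cross-validate -> remove all compounds whose absolute
#' residual exceeds `outlier_limit` times the cross-validated standard
#' deviation, until no compound is removed.  Contributions supported by fewer
#' than `support_min` distinct molecules are kept in the result but flagged
#' invalid, and the headline statistics are computed only over compounds all
#' of whose groups are valid.
#'
#' @param data data frame with `smiles` and `cp` columns (and optionally
#'   `name`); alternatively pass a prebuilt `design`.
#' @param design a `cp_design`, bypassing perception.
#' @param k folds for cross-validation.
#' @param seed integer seed (fold assignment; recorded in the result).
#' @param support_min validity threshold (distinct molecules per group).
#' @param outlier_limit residual limit in multiples of the cross-validated
#'   standard deviation.
#' @param max_rounds cap on outlier-elimination rounds.
#' @param cohn_mode,refine forwarded to [cp_design()].
#' @param tol,max_iter forwarded to [solve_gauss_seidel()].
#' @return A `cp_fit` object; see [tidy.cp_fit()], [glance.cp_fit()],
#'   [autoplot.cp_fit()], [as_cp_table()].
#' @export
cp_fit <- function(data = NULL, design = NULL, k = 10, seed = 1,
                   support_min = 3L, outlier_limit = 3,
                   max_rounds = 25L, cohn_mode = "n_minus_one", refine = TRUE,
                   tol = 1e-9, max_iter = 200000L) {
  if (is.null(design)) {
    if (is.null(data)) stop("supply `data` or `design`", call. = FALSE)
    design <- cp_design(data, cohn_mode = cohn_mode, refine = refine)
  }
  stopifnot(inherits(design, "cp_design"))
  if (nrow(design$G) < 2) stop("need at least two compounds", call. = FALSE)

  keep <- seq_len(nrow(design$G))
  outliers <- tibble::tibble(compound = character(0), cp_exp = numeric(0),
                             cp_fit = numeric(0), residual = numeric(0),
                             round = integer(0))
  round <- 0L
  removal_log <- integer(0)
  repeat {
    round <- round + 1L
    if (round > max_rounds) {
      stop("outlier elimination did not settle in ", max_rounds,
           " rounds (removals per round: ",
           paste(removal_log, collapse = ", "), ")", call. = FALSE)
    }
    cur <- new_cp_design(design$G[keep, , drop = FALSE], design$y[keep],
                         design$kind)
    x <- solve_gauss_seidel(cur, tol = tol, max_iter = max_iter)
    fitted <- as.numeric(cur$G %*% x)
    cv <- cp_cross_validate(cur, k = k, seed = seed,
                            support_min = support_min,
                            tol = tol, max_iter = max_iter)
    pool <- !cv$excluded
    std_cv <- if (sum(pool) >= 2) {
      sqrt(sum((cv$cp_cv[pool] - cv$cp_exp[pool])^2) / (sum(pool) - 1))
    } else {
      NA_real_
    }
    res <- fitted - cur$y
    drop <- if (!is.na(std_cv) && std_cv > 1e-8) {
      which(abs(res) > outlier_limit * std_cv)
    } else {
      integer(0)
    }
    if (length(drop) == 0 || length(drop) >= nrow(cur$G) - 1) break
    removal_log <- c(removal_log, length(drop))
    outliers <- rbind(outliers, tibble::tibble(
      compound = rownames(cur$G)[drop], cp_exp = cur$y[drop],
      cp_fit = fitted[drop], residual = res[drop], round = round))
    keep <- keep[-drop]
  }

  valid <- cur$support >= support_min
  contributions <- tibble::tibble(
    key = colnames(cur$G), kind = cur$kind, contribution = as.numeric(x),
    occurrences = as.integer(colSums(cur$G)),
    molecules = as.integer(cur$support), valid = unname(valid)
  )
  all_valid <- rowSums(cur$G[, !valid, drop = FALSE] != 0) == 0
  fit_tbl <- tibble::tibble(compound = rownames(cur$G), cp_exp = cur$y,
                            cp_fit = fitted, all_valid = all_valid)
  sub <- fit_tbl[fit_tbl$all_valid, ]
  stats_fit <- cp_statistics(sub$cp_fit, sub$cp_exp)
  cv_sub <- cv[!cv$excluded & all_valid, ]
  stats_cv <- cp_statistics(cv_sub$cp_cv, cv_sub$cp_exp)

  structure(list(
    contributions = contributions,
    fitted = fit_tbl,
    cv = cv,
    outliers = outliers,
    stats = tibble::tibble(
      n_total = nrow(cur$G), n_fit = stats_fit$n, n_cv = stats_cv$n,
      n_groups = ncol(cur$G), n_valid_groups = sum(valid),
      r2 = stats_fit$r2, r2_ss = stats_fit$r2_ss,
      avg_dev = stats_fit$avg_dev, std_dev = stats_fit$std_dev,
      mapd = stats_fit$mapd,
      q2 = stats_cv$r2, avg_dev_cv = stats_cv$avg_dev,
      std_dev_cv = stats_cv$std_dev, mapd_cv = stats_cv$mapd),
    k = k, seed = seed, support_min = support_min,
    outlier_limit = outlier_limit
  ), class = "cp_fit")
}

#' @export
print.cp_fit <- function(x, ...) {
  s <- x$stats
  cat("<cp_fit> ", s$n_total, " compounds, ", s$n_groups, " groups (",
      s$n_valid_groups, " valid), ", nrow(x$outliers), " outliers removed\n",
      sprintf("  r2 %.4f  q2 %.4f  sd %.2f  sd(cv) %.2f  MAPD %.2f%%  (n = %d / %d)\n",
              s$r2, s$q2, s$std_dev, s$std_dev_cv, s$mapd, s$n_fit, s$n_cv),
      sep = "")
  invisible(x)
}

#' Turn a fit into a contribution table usable for prediction
#'
#' @param fit a `cp_fit`.
#' @param phase phase label to attach.
#' @param support_min validity threshold.
#' @return A `cp_table` tibble equivalent to one loaded with [cp_table()].
#' @export
as_cp_table <- function(fit, phase = "liquid", support_min = 3L) {
  stopifnot(inherits(fit, "cp_fit"))
  co <- fit$contributions
  rev_map <- stats::setNames(names(SPECIAL_TYPE_MAP), SPECIAL_TYPE_MAP)
  atom_type <- ifelse(co$kind == "special", rev_map[co$key],
                      sub("\\|.*$", "", co$key))
  neighbours <- ifelse(co$kind == "special", "", sub("^.*\\|", "", co$key))
  out <- tibble::tibble(
    entry = as.character(seq_len(nrow(co))), atom_type = unname(atom_type),
    neighbours = neighbours, key = co$key, special = co$kind == "special",
    contribution = co$contribution, occurrences = co$occurrences,
    molecules = co$molecules, valid = co$molecules >= support_min
  )
  attr(out, "phase") <- phase
  class(out) <- c("cp_table", class(out))
  out
}

#' Write a contribution table as TSV
#'
#' The layout is identical to the bundled tables, so the file can be loaded
#' back with [cp_table()].
#'
#' @param table a `cp_table` (e.g. from [as_cp_table()]).
#' @param path output path.
#' @export
write_cp_table <- function(table, path) {
  utils::write.table(
    table[, c("entry", "atom_type", "neighbours", "contribution",
              "occurrences", "molecules")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
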