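# Multilocus Hudson-Kreitman-Aguade test (classical 1987 method-of-moments
# fit, population-size ratio f fixed at 1) with per-locus "partial HKA"
# contributions to the chi-square statistic.
#
# Model, per locus i with n_i sampled chromosomes in the focal species:
#   E[S_i] = theta_i * L_pol_i * a(n_i),        a(n) = sum_{j<n} 1/j
#   E[D_i] = theta_i * L_div_i * (T + 1)
# where theta_i is per site and the divergence observation D_i is the mean
# cross-species pairwise difference count (not a single random pair; this
# reduces the observation's variance relative to the classical
# formulation and is documented as a deviation).

harmonic_a <- function(n) if (n < 2L) 0 else sum(1 / seq_len(n - 1L))
harmonic_b <- function(n) if (n < 2L) 0 else sum(1 / seq_len(n - 1L)^2)

#' Build per-locus HKA inputs from a gene panel
#'
#' For every gene: complete deletion of columns with any gap/ambiguity
#' across focal plus other species, then `S` = segregating sites within the
#' focal species, `D` = mean cross-species pairwise difference count, and
#' `L_pol = L_div` = surviving column count. Genes with fewer than two
#' focal strains are excluded with a warning.
#'
#' @param panel A [gene_panel()].
#' @param focal_species,other_species Species labels.
#' @return data.frame with columns `locus_id`, `nsam`, `S`, `D`, `L_pol`,
#'   `L_div`.
#' @export
build_hka_input <- function(panel, focal_species = "speciesA",
                            other_species = "speciesB") {
  rows <- list()
  for (gid in names(panel$genes)) {
    aln <- panel$genes[[gid]]
    foc <- strains_of_species(aln, focal_species)
    oth <- strains_of_species(aln, other_species)
    if (length(foc) < 2L) {
      warning("gene '", gid, "' excluded: fewer than 2 focal strains")
      next
    }
    if (!length(oth)) {
      warning("gene '", gid, "' excluded: no strains of other species")
      next
    }
    m <- aln_matrix(aln, c(foc, oth))
    keep <- complete_cols(m, aln$alphabet)
    m <- m[, keep, drop = FALSE]
    mf <- m[foc, , drop = FALSE]
    S <- if (ncol(mf))
      sum(apply(mf, 2L, function(col) length(unique(col))) >= 2L) else 0L
    mo <- m[oth, , drop = FALSE]
    diffs <- 0; npair <- 0L
    for (i in seq_len(nrow(mf))) for (j in seq_len(nrow(mo))) {
      diffs <- diffs + sum(mf[i, ] != mo[j, ])
      npair <- npair + 1L
    }
    rows[[gid]] <- data.frame(locus_id = gid, nsam = length(foc), S = S,
                              D = diffs / npair, L_pol = ncol(m),
                              L_div = ncol(m), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no usable loci")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_hka_input <- function(inputs) {
  need <- c("locus_id", "nsam", "S", "D", "L_pol", "L_div")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("HKA input lacks column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(inputs$nsam >= 2L), all(inputs$S >= 0), all(inputs$D >= 0),
            all(inputs$L_pol > 0), all(inputs$L_div > 0))
  invisible(inputs)
}

theta_given_T <- function(inputs, Tt, a_n) {
  (inputs$S + inputs$D) / (inputs$L_pol * a_n + inputs$L_div * (Tt + 1))
}

#' Fit the multilocus HKA model (parameters only)
#'
#' Method-of-moments fit with f = 1: per locus,
#' `S_i + D_i = theta_i * (L_pol_i * a(n_i) + L_div_i * (T + 1))`, and `T`
#' solves `sum(D_i) = sum(theta_i(T) * L_div_i * (T + 1))` by bisection on
#' the monotone residual. If the residual at `T = 0` is already
#' non-negative, `T_hat = 0`.
#'
#' @param inputs data.frame from [build_hka_input()] (columns `locus_id`,
#'   `nsam`, `S`, `D`, `L_pol`, `L_div`).
#' @param max_iter,tol Bisection control.
#' @return An object of class `hka_fit` with `theta` (per-site, named by
#'   locus), `T_hat`, `f`, `df`; the chi-square fields are filled by
#'   [hka_statistic()].
#' @export
fit_hka <- function(inputs, max_iter = 200L, tol = 1e-10) {
  check_hka_input(inputs)
  if (nrow(inputs) < 2L) stop("HKA needs >= 2 loci")
  if (all(inputs$S + inputs$D == 0)) stop("no polymorphism or divergence in any locus")
  a_n <- vapply(inputs$nsam, harmonic_a, numeric(1))
  g <- function(Tt) sum(theta_given_T(inputs, Tt, a_n) * inputs$L_div * (Tt + 1)) -
    sum(inputs$D)
  if (g(0) >= 0) {
    T_hat <- 0
  } else {
    lo <- 0; hi <- 1
    expand <- 0L
    while (g(hi) < 0) {
      lo <- hi; hi <- hi * 2
      expand <- expand + 1L
      if (expand > 60L) stop("HKA bisection failed to bracket T")
    }
    iter <- 0L
    while (hi - lo > tol) {
      iter <- iter + 1L
      if (iter > max_iter) stop("HKA bisection did not converge in ",
                                max_iter, " steps")
      mid <- (lo + hi) / 2
      if (g(mid) < 0) lo <- mid else hi <- mid
    }
    T_hat <- (lo + hi) / 2
  }
  theta <- theta_given_T(inputs, T_hat, a_n)
  names(theta) <- inputs$locus_id
  structure(list(theta = theta, T_hat = T_hat, f = 1,
                 df = nrow(inputs) - 1L, inputs = inputs,
                 X2 = NULL, p_value = NULL, partials = NULL, table = NULL),
            class = "hka_fit")
}

#' Complete an HKA fit with the chi-square statistic and per-locus partials
#'
#' `E[S_i] = theta_i L_pol a(n_i)`, `Var[S_i] = E[S_i] + (theta_i L_pol)^2
#' b(n_i)`; `E[D_i] = theta_i L_div (T+1)`, `Var[D_i] = E[D_i] +
#' (theta_i L_div)^2`. The partial contribution of locus i is the sum of
#' its squared standardized S and D deviations; `X2` is the sum of
#' partials, compared to a chi-square with `L - 1` degrees of freedom.
#' Loci with zero variance (theta_i = 0) contribute 0 with a warning.
#'
#' @param inputs data.frame of per-locus inputs (as in [fit_hka()]).
#' @param model An `hka_fit` from [fit_hka()].
#' @return The completed `hka_fit` (fields `X2`, `p_value`, `partials`,
#'   `table`).
#' @export
hka_statistic <- function(inputs, model) {
  check_hka_input(inputs)
  stopifnot(inherits(model, "hka_fit"))
  a_n <- vapply(inputs$nsam, harmonic_a, numeric(1))
  b_n <- vapply(inputs$nsam, harmonic_b, numeric(1))
  theta <- model$theta[inputs$locus_id]
  E_S <- theta * inputs$L_pol * a_n
  V_S <- E_S + (theta * inputs$L_pol)^2 * b_n
  E_D <- theta * inputs$L_div * (model$T_hat + 1)
  V_D <- E_D + (theta * inputs$L_div)^2
  partial <- numeric(nrow(inputs))
  zero <- V_S == 0 | V_D == 0
  if (any(zero))
    warning(sum(zero), " locus/loci with zero variance contribute 0 to X2")
  ok <- !zero
  partial[ok] <- (inputs$S[ok] - E_S[ok])^2 / V_S[ok] +
    (inputs$D[ok] - E_D[ok])^2 / V_D[ok]
  model$partials <- stats::setNames(partial, inputs$locus_id)
  model$X2 <- sum(partial)
  model$df <- nrow(inputs) - 1L
  model$p_value <- stats::pchisq(model$X2, df = model$df, lower.tail = FALSE)
  model$table <- data.frame(locus_id = inputs$locus_id, nsam = inputs$nsam,
                            S = inputs$S, D = inputs$D, E_S = E_S, E_D = E_D,
                            theta = unname(theta), partial = partial,
                            stringsAsFactors = FALSE)
  model
}

#' Fit and test in one call
#'
#' @inheritParams fit_hka
#' @return A completed `hka_fit`.
#' @export
hka_test <- function(inputs) hka_statistic(inputs, fit_hka(inputs))

#' @export
print.hka_fit <- function(x, ...) {
  cat(sprintf("Multilocus HKA fit (f = %g): %d loci\n", x$f, length(x$theta)))
  cat(sprintf("  T_hat = %.6g\n", x$T_hat))
  if (!is.null(x$X2))
    cat(sprintf("  X2 = %.4f on %d df, p = %.4g\n", x$X2, x$df, x$p_value))
  else cat("  (chi-square statistic not yet computed; see hka_statistic())\n")
  invisible(x)
}

#' @export
summary.hka_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$table)) {
    cat("\nPer-locus contributions:\n")
    tab <- object$table[order(-object$table$partial), ]
    print(utils::head(tab, 10), row.names = FALSE)
    if (nrow(tab) > 10) cat("  ... (", nrow(tab) - 10, " more)\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.hka_fit <- function(object, ...) {
  c(T_hat = object$T_hat, stats::setNames(object$theta,
                                          paste0("theta.", names(object$theta))))
}
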