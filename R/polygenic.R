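# Pedigree kinship and polygenic variance-component inference.

#' Kinship matrix from a pedigree
#'
#' Recursive kinship coefficients: founders are non-inbred and unrelated
#' (`Phi_ii = 0.5`, `Phi_ij = 0`); for an individual i with parents f, m,
#' `Phi_ii = 0.5 * (1 + Phi_fm)` and `Phi_ij = 0.5 * (Phi_jf + Phi_jm)` for
#' any j that is not a descendant of i.
#'
#' @param pedigree a `pedigree` data frame (columns id, father, mother;
#'   founders with `NA` parents), or a path to such a CSV.
#' @return symmetric kinship matrix with subject ids as dimnames.
#' @export
kinship_matrix <- function(pedigree) {
  if (is.character(pedigree))
    pedigree <- read.csv(pedigree, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "father", "mother") %in% names(pedigree)))
  ids <- pedigree$id
  if (anyDuplicated(ids)) stop("duplicate pedigree id")
  n <- length(ids)
  fa <- match(pedigree$father, ids)
  mo <- match(pedigree$mother, ids)
  if (any(!is.na(pedigree$father) & is.na(fa)) ||
      any(!is.na(pedigree$mother) & is.na(mo)))
    stop("unknown parent id in pedigree")

  # topological order (parents before children); cycle check
  placed <- logical(n); ord <- integer(0)
  repeat {
    ok <- vapply(seq_len(n), function(i)
      !placed[i] && (is.na(fa[i]) || placed[fa[i]]) &&
        (is.na(mo[i]) || placed[mo[i]]), TRUE)
    ready <- which(ok)
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) stop("cycle detected in pedigree")

  Phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ord) {
    if (is.na(fa[i]) || is.na(mo[i])) {
      Phi[i, i] <- 0.5
    } else {
      Phi[i, i] <- 0.5 * (1 + Phi[fa[i], mo[i]])
    }
    for (j in ord) {
      if (j == i) break
      pij <- if (is.na(fa[i]) || is.na(mo[i])) 0
             else 0.5 * (Phi[j, fa[i]] + Phi[j, mo[i]])
      Phi[i, j] <- Phi[j, i] <- pij
    }
  }
  Phi
}

#' Fit the polygenic mixed model
#'
#' Maximizes the Gaussian likelihood of `y = X beta + g + e` with
#' `cov(g) = 2 * Phi * sigma_g^2` and iid `e`, by eigen-decomposing
#' `2 * Phi` once and profiling the likelihood down to a one-dimensional
#' search over the heritability `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`.
#' ML (default) supports likelihood-ratio tests on fixed effects; REML is
#' available for variance reporting.
#'
#' When all subjects are unrelated (`2 * Phi` proportional to the
#' identity), only the total variance is identifiable; the fit is then
#' flagged `aliased` and `h2` is reported as `NA`.
#'
#' @param y numeric trait vector.
#' @param X fixed-effect design matrix (include the intercept column).
#' @param kinship kinship matrix aligned to `y`.
#' @param method `"ML"` or `"REML"`.
#' @param decomp optional precomputed `eigen(2 * kinship, symmetric = TRUE)`
#'   to reuse across fits on the same subjects.
#' @return a `polygenic_fit`: `beta`, `se_beta`, `sigma2_g`, `sigma2_e`,
#'   `h2`, `loglik`, `aliased`, `n`.
#' @export
fit_polygenic <- function(y, X, kinship, method = c("ML", "REML"),
                          decomp = NULL) {
  method <- match.arg(method)
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (n < 2L || n <= p)
    stop("degenerate input: need more observations than fixed effects")
  stopifnot(nrow(X) == n)
  eg <- if (is.null(decomp)) {
    stopifnot(nrow(kinship) == n, ncol(kinship) == n)
    eigen(2 * kinship, symmetric = TRUE)
  } else decomp
  if (length(eg$values) != n) stop("decomposition size mismatch")
  d <- eg$values
  if (min(d) < -1e-8) stop("2*Phi is not positive semidefinite")
  d <- pmax(d, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)

  aliased <- (max(d) - min(d)) < 1e-8 * max(d)

  prof <- function(h2) {
    w <- h2 * d + (1 - h2)
    if (any(w <= 0)) return(list(obj = Inf))
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    XtWy <- crossprod(Xw, yt)
    beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(beta)) return(list(obj = Inf))
    r <- yt - Xt %*% beta
    rss <- sum(r^2 / w)
    if (method == "ML") {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    } else {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
                      determinant(XtWX, logarithm = TRUE)$modulus[1] -
                      determinant(crossprod(X), logarithm = TRUE)$modulus[1] +
                      (n - p))
    }
    list(obj = -ll, beta = beta, s2 = s2, ll = ll, XtWX = XtWX)
  }

  if (aliased) {
    warning("all subjects unrelated: sigma2_g and sigma2_e are aliased; ",
            "only their sum is identifiable", call. = FALSE)
    best_h2 <- 0
  } else {
    op <- optimize(function(h) prof(h)$obj, c(0, 1 - 1e-9), tol = 1e-9)
    cand <- c(0, op$minimum, 1 - 1e-9)
    objs <- vapply(cand, function(h) prof(h)$obj, 0)
    best_h2 <- cand[which.min(objs)]
  }
  fit <- prof(best_h2)
  if (!is.finite(fit$ll)) stop("polygenic fit failed to converge")
  se <- sqrt(diag(solve(fit$XtWX)) * fit$s2)
  structure(list(
    beta = stats::setNames(as.numeric(fit$beta), colnames(X)),
    se_beta = stats::setNames(se, colnames(X)),
    sigma2_g = if (aliased) NA_real_ else best_h2 * fit$s2,
    sigma2_e = if (aliased) fit$s2 else (1 - best_h2) * fit$s2,
    sigma2_total = fit$s2,
    h2 = if (aliased) NA_real_ else best_h2,
    loglik = fit$ll, method = method, aliased = aliased, n = n),
    class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf("polygenic_fit (%s, n=%d): h2=%s, sigma2_g=%.4g, sigma2_e=%.4g, logLik=%.4f%s\n",
              x$method, x$n,
              if (is.na(x$h2)) "NA (aliased)" else sprintf("%.3f", x$h2),
              x$sigma2_g, x$sigma2_e, x$loglik,
              if (x$aliased) " [variance components aliased]" else ""))
  print(data.frame(beta = x$beta, se = x$se_beta))
  invisible(x)
}

#' Likelihood-ratio test for a group effect under the polygenic model
#'
#' Compares ML fits with and without the group label, both adjusted for age
#' and sex and both carrying the polygenic component; the statistic is
#' referred to a chi-square with one degree of freedom.
#'
#' @param y trait vector.
#' @param age,sex covariates (sex coded `"F"`/`"M"` or 0/1).
#' @param group two-level group label.
#' @param kinship kinship matrix aligned to `y`.
#' @return list: `LR`, `df`, `p_value`, `effect` (group coefficient),
#'   `se_effect`, `h2`, and both fits.
#' @export
lrt_group_effect <- function(y, age, sex, group, kinship) {
  sexn <- if (is.numeric(sex)) sex else as.numeric(sex == "M")
  keep <- is.finite(y) & is.finite(age) & !is.na(sexn) & !is.na(group)
  y <- y[keep]; age <- age[keep]; sexn <- sexn[keep]
  group <- group[keep]
  kinship <- kinship[keep, keep, drop = FALSE]
  X0 <- cbind(intercept = 1, age = age, sexM = sexn)
  decomp <- eigen(2 * kinship, symmetric = TRUE)
  glev <- unique(group)
  if (length(glev) < 2L) {
    fit0 <- fit_polygenic(y, X0, kinship, decomp = decomp)
    return(list(LR = 0, df = 1L, p_value = 1, effect = 0, se_effect = NA_real_,
                h2 = fit0$h2, fit_full = fit0, fit_null = fit0))
  }
  if (length(glev) > 2L) stop("group must have two levels")
  gind <- as.numeric(group == sort(glev)[2])
  X1 <- cbind(X0, group = gind)
  fit0 <- fit_polygenic(y, X0, kinship, decomp = decomp)
  fit1 <- fit_polygenic(y, X1, kinship, decomp = decomp)
  LR <- max(0, 2 * (fit1$loglik - fit0$loglik))
  list(LR = LR, df = 1L, p_value = pchisq(LR, 1, lower.tail = FALSE),
       effect = unname(fit1$beta[["group"]]),
       se_effect = unname(fit1$se_beta[["group"]]),
       h2 = fit1$h2, fit_full = fit1, fit_null = fit0,
       effect_level = sort(glev)[2])
}
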