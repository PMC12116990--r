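# Guild-metabolite association: random-intercept linear model on
# arcsine-square-root transformed guild abundance.

#' Arcsine square-root transform
#'
#' Variance-stabilizing transform for proportions: `asin(sqrt(p))`, mapping
#' `[0, 1]` onto `[0, pi/2]`.
#'
#' @param p proportions in `[0, 1]`.
#' @return transformed values.
#' @export
ast_transform <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Random-intercept linear model by profile maximum likelihood
#'
#' Fits `y = b0 + b1 * x + u_subject + e`, `u ~ N(0, s_u^2)`,
#' `e ~ N(0, s_e^2)`, by maximizing the likelihood profiled down to the
#' variance ratio `lambda = s_u^2 / s_e^2` (1-D optimization on
#' `log(lambda)`; the `lambda = 0` boundary, i.e. ordinary least squares,
#' is always considered as a candidate). The subject blocks are inverted in
#' closed form, so the fit has no iterative linear-algebra component.
#'
#' @param y response vector.
#' @param x covariate vector (non-constant).
#' @param subjects subject id per observation (>= 2 subjects).
#' @return `list(intercept, slope, var_subject, var_residual, slope_se,
#'   loglik, n, n_subjects)`.
#' @export
random_intercept_fit <- function(y, x, subjects) {
  ok <- stats::complete.cases(y, x, subjects)
  y <- y[ok]; x <- x[ok]; subjects <- as.character(subjects[ok])
  n <- length(y)
  if (n < 3) stop("need >= 3 observations")
  if (length(unique(subjects)) < 2) stop("need >= 2 subjects")
  if (stats::sd(x) == 0) stop("x is constant")
  X <- cbind(1, x)
  groups <- split(seq_len(n), subjects)

  # profile log-likelihood at variance ratio lambda (>= 0); block inverse
  # (I + lambda J)^{-1} = I - lambda/(1 + ni*lambda) J per subject
  prof <- function(lambda) {
    XtVX <- matrix(0, 2, 2); XtVy <- numeric(2)
    yty <- 0; logdet <- 0
    for (ii in groups) {
      ni <- length(ii)
      w <- lambda / (1 + ni * lambda)
      Xi <- X[ii, , drop = FALSE]; yi <- y[ii]
      sx <- colSums(Xi); sy <- sum(yi)
      XtVX <- XtVX + crossprod(Xi) - w * tcrossprod(sx)
      XtVy <- XtVy + crossprod(Xi, yi) - w * sx * sy
      yty <- yty + sum(yi^2) - w * sy^2
      logdet <- logdet + log1p(ni * lambda)
    }
    beta <- solve(XtVX, XtVy)
    rss <- yty - 2 * sum(beta * XtVy) + sum(beta * (XtVX %*% beta))
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
    list(ll = ll, beta = beta, sigma2 = sigma2, XtVX = XtVX)
  }

  obj <- function(loglam) -prof(exp(loglam))$ll
  opt <- stats::optimize(obj, interval = c(-15, 15), tol = 1e-8)
  cand <- exp(opt$minimum)
  f_opt <- prof(cand)
  f_ols <- prof(0)
  if (f_ols$ll >= f_opt$ll) { cand <- 0; f_opt <- f_ols }

  se <- sqrt(f_opt$sigma2 * solve(f_opt$XtVX)[2, 2])
  list(intercept = unname(f_opt$beta[1]), slope = unname(f_opt$beta[2]),
       var_subject = cand * f_opt$sigma2, var_residual = f_opt$sigma2,
       slope_se = se, loglik = f_opt$ll, n = n,
       n_subjects = length(groups))
}

#' Associate guild abundances with metabolite concentrations
#'
#' For every (guild, analyte) pair, fits the analyte concentration on the
#' AST-transformed guild relative abundance with a subject random
#' intercept; two-sided Wald p-values (normal reference) are BH-adjusted
#' across all pairs in the run. A negative slope encodes "guild down,
#' metabolite up". Pairs with fewer than 3 complete observations are
#' flagged, not fit.
#'
#' @param guild_table guilds x samples relative-abundance matrix or
#'   [abundance_table] (e.g. from [guild_abundance]).
#' @param metabolite_table analytes x samples concentration matrix.
#' @param metadata metadata covering the shared samples.
#' @return data.frame with one row per (guild, analyte) pair: `guild_id`,
#'   `analyte_id`, `slope`, `se`, `wald_z`, `p`, `bh_q`, `n`, `n_subjects`,
#'   `fitted` flag; sorted by q then |slope| decreasing.
#' @export
associate <- function(guild_table, metabolite_table, metadata) {
  shared <- Reduce(intersect, list(colnames(guild_table),
                                   colnames(metabolite_table),
                                   metadata$sample_id))
  if (!length(shared)) stop("no samples shared across the three inputs")
  g <- unclass(guild_table)[, shared, drop = FALSE]
  met <- metabolite_table[, shared, drop = FALSE]
  md <- metadata[match(shared, metadata$sample_id), , drop = FALSE]
  subj <- md$subject_id

  rows <- vector("list", nrow(g) * nrow(met))
  k <- 0L
  for (gi in seq_len(nrow(g))) {
    ast <- ast_transform(pmin(pmax(g[gi, ], 0), 1))
    for (mi in seq_len(nrow(met))) {
      k <- k + 1L
      y <- met[mi, ]
      ok <- stats::complete.cases(y, ast)
      row <- data.frame(guild_id = rownames(g)[gi],
                        analyte_id = rownames(met)[mi],
                        slope = NA_real_, se = NA_real_, wald_z = NA_real_,
                        p = NA_real_, bh_q = NA_real_,
                        n = sum(ok), n_subjects = length(unique(subj[ok])),
                        fitted = FALSE, stringsAsFactors = FALSE)
      if (sum(ok) >= 3 && stats::sd(ast[ok]) > 0 &&
          length(unique(subj[ok])) >= 2) {
        fit <- random_intercept_fit(y[ok], ast[ok], subj[ok])
        z <- fit$slope / fit$slope_se
        row$slope <- fit$slope; row$se <- fit$slope_se
        row$wald_z <- z
        row$p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
        row$fitted <- TRUE
      }
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$bh_q[out$fitted] <- benjamini_hochberg(out$p[out$fitted])
  out <- out[order(out$bh_q, -abs(out$slope)), ]
  rownames(out) <- NULL
  out
}
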