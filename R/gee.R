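# Generalized estimating equations for two-eyed designs: marginal linear
# model (identity link), exchangeable working correlation within subject,
# robust (sandwich) standard errors. Written directly on the normal
# equations — cluster sizes here are tiny (<= 2 eyes), so the exchangeable
# inverse has a cheap closed form.

#' Fit a linear GEE with exchangeable working correlation
#'
#' Estimates a marginal linear model by iteratively reweighted estimating
#' equations with an exchangeable intra-cluster correlation, and reports the
#' robust sandwich covariance. With singleton clusters this reduces to OLS
#' with heteroskedasticity-robust (HC0) errors.
#'
#' @param formula model formula (identity link, Gaussian-type outcome).
#' @param data data frame.
#' @param cluster name of the clustering column (e.g. subject id).
#' @param max_iter,tol iteration controls.
#' @return A list of class `gee_fit`: `coefficients`, `vcov` (sandwich),
#'   `alpha` (working correlation), `phi` (dispersion), `n_obs`,
#'   `n_clusters`, `formula`.
#' @export
gee_fit <- function(formula, data, cluster, max_iter = 25L, tol = 1e-10) {
  stopifnot(is.data.frame(data), cluster %in% names(data))
  vars <- unique(c(all.vars(formula), cluster))
  dat <- data[stats::complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  if (nrow(dat) == 0) stop("no complete cases")
  mf <- stats::model.frame(formula, dat)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  id <- as.character(dat[[cluster]])
  p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design matrix")
  cl_idx <- split(seq_along(y), id)
  n_cl <- length(cl_idx)

  beta <- qr.solve(X, y)  # OLS start
  alpha <- 0
  for (iter in seq_len(max_iter)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (length(y) - p)
    num <- 0; npairs <- 0
    for (ix in cl_idx) {
      m <- length(ix)
      if (m < 2) next
      ri <- r[ix]
      num <- num + (sum(ri)^2 - sum(ri^2)) / 2
      npairs <- npairs + m * (m - 1) / 2
    }
    alpha <- if (npairs > p) num / phi / (npairs - p) else 0
    mmax <- max(lengths(cl_idx))
    alpha <- min(max(alpha, -1 / max(1, mmax - 1) + 1e-6), 0.999)

    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ix in cl_idx) {
      m <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      yi <- y[ix]
      # R^{-1} = (I - alpha/(1+(m-1)alpha) J) / (1-alpha)
      if (m == 1) {
        XtW <- t(Xi)
      } else {
        f <- alpha / (1 + (m - 1) * alpha)
        XtW <- (t(Xi) - f * matrix(colSums(Xi), p, m)) / (1 - alpha)
      }
      A <- A + XtW %*% Xi
      b <- b + XtW %*% yi
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }

  # sandwich covariance
  r <- y - X %*% beta
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (ix in cl_idx) {
    m <- length(ix)
    Xi <- X[ix, , drop = FALSE]
    ri <- r[ix]
    if (m == 1) {
      XtW <- t(Xi)
    } else {
      f <- alpha / (1 + (m - 1) * alpha)
      XtW <- (t(Xi) - f * matrix(colSums(Xi), p, m)) / (1 - alpha)
    }
    A <- A + XtW %*% Xi
    g <- XtW %*% ri
    B <- B + g %*% t(g)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% t(Ainv)
  beta <- drop(beta)
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = V, alpha = alpha,
                 phi = sum(r^2) / (length(y) - p), n_obs = length(y),
                 n_clusters = n_cl, formula = formula),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("<gee_fit> %d obs in %d clusters, alpha = %.3f\n",
              x$n_obs, x$n_clusters, x$alpha))
  se <- sqrt(diag(x$vcov))
  print(cbind(estimate = x$coefficients, robust_se = se,
              z = x$coefficients / se,
              p = 2 * stats::pnorm(-abs(x$coefficients / se))))
  invisible(x)
}

eye_class <- function(cohort) {
  ifelse(cohort$group == "HC", "HC",
         ifelse(cohort$on_history == 1, "NMOSD_ON", "NMOSD_NON"))
}

#' Pairwise adjusted group comparisons with inter-eye clustering
#'
#' Classifies eyes as healthy-control, NMOSD without, or NMOSD with
#' optic-neuritis history, fits one GEE of the outcome on the class plus
#' covariates with subjects as clusters, and reports every pairwise adjusted
#' mean difference with its robust Wald test.
#'
#' @param cohort a `cohort_table`, typically restricted to one layer via
#'   `layer`.
#' @param outcome outcome column name (default `"dbox"`, falling back to
#'   `"dbox_true"` when absent).
#' @param covariates adjustment columns; constant or missing columns are
#'   dropped automatically.
#' @param cluster clustering column (default `subject_id`).
#' @param layer optional capillary layer filter.
#' @return A data frame with one row per group pair: `outcome`, `layer`,
#'   `group1`, `group2`, `difference` (group2 minus group1), `robust_se`,
#'   `wald_z`, `p_value`, `n_eyes`, `n_subjects`, `covariates`.
#' @export
gee_compare <- function(cohort, outcome = NULL,
                        covariates = c("age", "sex", "sq"),
                        cluster = "subject_id", layer = NULL) {
  tab <- as.data.frame(cohort)
  if (!is.null(layer)) tab <- tab[tab$layer == layer, , drop = FALSE]
  if (is.null(outcome))
    outcome <- if ("dbox" %in% names(tab)) "dbox" else "dbox_true"
  stopifnot(outcome %in% names(tab))
  tab$.class <- factor(eye_class(tab), levels = c("HC", "NMOSD_NON", "NMOSD_ON"))
  tab$.class <- droplevels(tab$.class)
  levs <- levels(tab$.class)
  if (length(levs) < 2) stop("need at least 2 groups")
  use_cov <- covariates[vapply(covariates, function(v)
    v %in% names(tab) && !anyNA(tab[[v]]) && length(unique(tab[[v]])) > 1,
    logical(1))]
  fml <- stats::reformulate(c(".class", use_cov), response = outcome)
  fit <- gee_fit(fml, tab, cluster)

  cn <- names(fit$coefficients)
  lvec <- function(lev) {
    v <- numeric(length(cn))
    nm <- paste0(".class", lev)
    if (nm %in% cn) v[match(nm, cn)] <- 1
    v
  }
  pairs <- utils::combn(levs, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    L <- lvec(g2) - lvec(g1)
    est <- sum(L * fit$coefficients)
    se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
    z <- est / se
    data.frame(outcome = outcome,
               layer = if (is.null(layer)) NA_character_ else layer,
               group1 = g1, group2 = g2, difference = est, robust_se = se,
               wald_z = z, p_value = 2 * stats::pnorm(-abs(z)),
               n_eyes = fit$n_obs, n_subjects = fit$n_clusters,
               covariates = paste(use_cov, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
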