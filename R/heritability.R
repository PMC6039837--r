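#' @title Twin variance-components heritability
#'
#' @description
#' Narrow-sense heritability of a quantitative trait on a twin pedigree
#' under the AE model: the phenotypic covariance is
#' Omega = 2*Phi*sigma_g^2 + I*sigma_e^2, where 2*Phi is the expected
#' relatedness matrix (1 for MZ co-twins, 1/2 for DZ co-twins and siblings,
#' 0 across families) and h^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2).
#' Components are estimated by maximum likelihood with fixed-effect
#' covariates, using a single eigendecomposition of 2*Phi and a 1-D profile
#' of the likelihood over h^2; significance is a boundary-corrected
#' likelihood-ratio test of sigma_g^2 = 0.
#' @name heritability
NULL

#' Build the 2*Phi kinship matrix from a zygosity-annotated pedigree
#'
#' @param pedigree data.frame with columns `family_id`, `individual_id` and
#'   `zygosity` (`MZ`, `DZ` or `NT`). Co-members of a family marked MZ get
#'   relatedness 1; any other two members of the same family (DZ co-twins,
#'   siblings) get 1/2; individuals of different families 0; diagonal 1.
#' @return named n x n relatedness matrix (class `matrix`).
#' @export
build_kinship <- function(pedigree) {
  stopifnot(all(c("family_id", "individual_id", "zygosity") %in%
                  names(pedigree)))
  ids <- pedigree$individual_id
  if (anyDuplicated(ids)) stop("duplicated individual ids in pedigree")
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (f in unique(pedigree$family_id)) {
    idx <- which(pedigree$family_id == f)
    mz <- idx[pedigree$zygosity[idx] == "MZ"]
    if (length(mz) %% 2L != 0L || length(mz) > 2L)
      stop("family ", f, ": an MZ pair must have exactly 2 members")
    if (length(idx) > 1) K[idx, idx] <- 0.5
    if (length(mz) == 2L) K[mz, mz] <- 1
  }
  diag(K) <- 1
  K
}

#' Rank-based inverse normal transformation
#'
#' Ranks (ties share the mean rank) are mapped through the Blom offset
#' (r - 3/8) / (n + 1/4) to standard-normal quantiles, assuring normality of
#' the trait before the variance-components fit.
#'
#' @param values numeric vector, at least 3 finite values, not all equal.
#' @return transformed vector.
#' @export
inverse_normal_transform <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (diff(range(values)) == 0)
    stop("all values identical: transform undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

# profile log-likelihood machinery: with K = U D U', y* = U'y, X* = U'X and
# Var(y*) = sigma_p^2 * W(h2), W = h2*D + (1-h2)*I diagonal, so each h2 gives
# a weighted GLS fit and a closed-form ML sigma_p^2.
vc_profile <- function(ys, Xs, d) {
  n <- length(ys)
  function(h2) {
    w <- h2 * d + (1 - h2)
    if (any(w <= 0)) return(list(loglik = -Inf))
    sw <- 1 / sqrt(w)
    Xw <- Xs * sw
    yw <- ys * sw
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    s2 <- rss / n                           # ML estimate of sigma_p^2
    if (s2 <= 0) return(list(loglik = -Inf))
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    list(loglik = ll, beta = fit$coefficients, sigma_p2 = s2,
         Xw = Xw, rss = rss)
  }
}

#' Maximum-likelihood AE variance-components fit
#'
#' Fits y ~ N(X beta, 2*Phi*sigma_g^2 + I*sigma_e^2) by eigendecomposing
#' 2*Phi once and profiling the likelihood over the heritability ratio on
#' `[0, 1]` (bounded 1-D optimization, tolerance 1e-6), with a GLS fit of
#' the fixed effects at each ratio. Covariates (if any) enter as fixed
#' effects next to an intercept.
#'
#' @param trait numeric trait vector (transform beforehand if desired, e.g.
#'   with [inverse_normal_transform()]).
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (no intercept column; one is added).
#' @param kinship the 2*Phi matrix from [build_kinship()].
#' @return object of class `vc_fit`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `loglik`, `loglik_null`, `p_lrt`, `betas` (estimate/SE/p Wald table),
#'   `covariate_variance_explained` (covariates-only R^2; `NA` without
#'   covariates).
#' @export
fit_variance_components <- function(trait, covariates = NULL, kinship) {
  n <- length(trait)
  stopifnot(is.matrix(kinship), nrow(kinship) == n, ncol(kinship) == n)
  X <- cbind(`(intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    cm <- as.matrix(covariates)
    storage.mode(cm) <- "double"
    X <- cbind(X, cm)
  }
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  eg <- eigen(kinship, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values))
    stop("kinship matrix is not positive semidefinite")
  d <- pmax(eg$values, 0)
  ys <- drop(crossprod(eg$vectors, trait))
  Xs <- crossprod(eg$vectors, X)
  prof <- vc_profile(ys, Xs, d)

  ll_fun <- function(h2) prof(h2)$loglik
  opt <- stats::optimize(ll_fun, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-6)
  # the interior optimizer can miss a boundary optimum; compare explicitly
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll_fun(0), ll_fun(1))
  h2 <- cand[which.max(lls)]
  at <- prof(h2)
  null <- prof(0)

  # Wald tests for the fixed effects at the ML ratio
  XtX <- crossprod(at$Xw)
  vb <- at$sigma_p2 * solve(XtX) * n / max(n - ncol(X), 1)  # small-n dof scale
  se <- sqrt(diag(vb))
  z <- at$beta / se
  betas <- data.frame(term = colnames(X), estimate = at$beta, se = se,
                      p_value = 2 * stats::pnorm(-abs(z)),
                      row.names = NULL)

  cov_r2 <- NA_real_
  if (!is.null(covariates)) {
    ols <- stats::lm.fit(X, trait)
    cov_r2 <- 1 - sum(ols$residuals^2) / sum((trait - mean(trait))^2)
  }

  fit <- structure(list(sigma_g2 = h2 * at$sigma_p2,
                        sigma_e2 = (1 - h2) * at$sigma_p2,
                        h2 = h2, loglik = at$loglik,
                        loglik_null = null$loglik,
                        betas = betas,
                        covariate_variance_explained = cov_r2),
                   class = "vc_fit")
  fit$p_lrt <- lrt_h2(fit)
  fit
}

#' Boundary-corrected likelihood-ratio test for h^2 > 0
#'
#' Lambda = 2*(loglik_full - loglik_null); because sigma_g^2 = 0 lies on the
#' boundary of the parameter space, the null distribution is the mixture
#' (1/2) chi^2_0 + (1/2) chi^2_1, so p = (1/2) P(chi^2_1 >= Lambda).
#' Lambda is clipped at zero; a full likelihood materially below the null
#' signals an optimizer failure and errors.
#'
#' @param fit a `vc_fit` (uses its stored log-likelihoods), or the full
#'   model's log-likelihood as a number.
#' @param null_fit the null `vc_fit` or log-likelihood; ignored when `fit`
#'   is a `vc_fit` with a stored null.
#' @return the p-value.
#' @export
lrt_h2 <- function(fit, null_fit = NULL) {
  if (inherits(fit, "vc_fit")) {
    ll_full <- fit$loglik
    ll_null <- if (is.null(null_fit)) fit$loglik_null
               else if (inherits(null_fit, "vc_fit")) null_fit$loglik
               else as.numeric(null_fit)
  } else {
    ll_full <- as.numeric(fit)
    ll_null <- if (inherits(null_fit, "vc_fit")) null_fit$loglik
               else as.numeric(null_fit)
  }
  lambda <- 2 * (ll_full - ll_null)
  if (lambda < -1e-6) stop("full-model likelihood below null: optimizer failure")
  lambda <- max(lambda, 0)
  0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE)
}

#' Standard covariate design for the heritability fits
#'
#' Sex, age, age^2, age x sex and age^2 x sex. Age is standardized
#' internally for numerical conditioning (the fit and h^2 are invariant to
#' this linear reparameterization).
#'
#' @param age numeric age vector.
#' @param sex `"M"`/`"F"` (or 0/1) vector.
#' @return numeric design matrix (no intercept).
#' @export
covariate_design <- function(age, sex) {
  sexf <- if (is.numeric(sex)) sex else as.numeric(sex == "F")
  a <- as.numeric(scale(age))
  cbind(sex = sexf, age = a, age2 = a^2, age_sex = a * sexf,
        age2_sex = a^2 * sexf)
}

#' Heritability table for graph features
#'
#' For every measure x band trait in `features` (run-averaged values), the
#' trait is inverse-normal transformed, then fitted with the standard
#' covariate design against the pedigree kinship; mirrors the layout
#' h^2 / p-value / covariate variance explained (%).
#'
#' @param features data.frame with columns `subject_id`, `band`,
#'   `modularity`, `transitivity`, `cpl`, `age`, `sex`.
#' @param pedigree pedigree data.frame (see [build_kinship()]) whose
#'   `individual_id` matches `features$subject_id`.
#' @param min_n_covariates smallest sample size at which the 5-term
#'   covariate design is used; below it the fit is intercept-only (the full
#'   design would saturate a small pedigree).
#' @return data.frame: measure, band, h2, p_value,
#'   covariate_variance_explained_pct.
#' @export
h2_table <- function(features, pedigree, min_n_covariates = 15L) {
  K <- build_kinship(pedigree)
  use_cov <- nrow(pedigree) >= min_n_covariates
  out <- list()
  for (meas in c("cpl", "transitivity", "modularity")) {
    for (b in unique(features$band)) {
      sub <- features[features$band == b, ]
      sub <- sub[match(pedigree$individual_id, sub$subject_id), ]
      if (any(is.na(sub$subject_id)))
        stop("features missing for some pedigree individuals")
      y <- inverse_normal_transform(sub[[meas]])
      X <- if (use_cov) covariate_design(sub$age, sub$sex) else NULL
      fit <- fit_variance_components(y, X, K)
      out[[length(out) + 1L]] <- data.frame(
        measure = meas, band = b, h2 = fit$h2, p_value = fit$p_lrt,
        covariate_variance_explained_pct =
          100 * fit$covariate_variance_explained)  # NA without covariates
    }
  }
  do.call(rbind, out)
}
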