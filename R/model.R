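#' Removal N-mixture model specification
#'
#' Defines the structure of the removal multinomial-Poisson N-mixture
#' model: which standardized covariates enter the abundance (log link,
#' density per km2) and detection (logit link, per-interval detection
#' probability) components, the effective sampled area entering the model
#' as an offset, and the number of removal intervals.
#'
#' The default abundance structure uses grassland, agriculture and urban
#' proportions plus maximum temperature and precipitation, with forest as
#' the reference land-cover class: on a fully labelled four-class mosaic
#' the four proportions sum to one, so one class must be omitted for the
#' model to be identifiable.
#'
#' @param abund character vector of abundance covariate names.
#' @param det character vector of detection covariate names.
#' @param offset_area_km2 effective sampled area A (km2); default the area
#'   of a 100-m-radius circle, `pi * 0.1^2`.
#' @param J number of removal intervals (2-min bins), default 5.
#' @return An object of class `removal_model_spec`.
#' @export
removal_model_spec <- function(abund = c("grassland", "agriculture", "urban",
                                         "tmax", "precip"),
                               det = c("jdate"),
                               offset_area_km2 = pi * 0.1^2,
                               J = 5L) {
  stopifnot(offset_area_km2 > 0, J >= 1L)
  structure(list(abund = abund, det = det,
                 offset_area_km2 = offset_area_km2, J = as.integer(J)),
            class = "removal_model_spec")
}

#' Removal-sampling interval probabilities
#'
#' Under the removal protocol an individual present at a site is first
#' detected in interval `j` with probability `p (1-p)^(j-1)` and never
#' detected with probability `(1-p)^J`; the J+1 cell probabilities sum to
#' one exactly.
#'
#' @param p per-interval detection probability in `[0, 1]` (vectorized).
#' @param J number of intervals.
#' @return For scalar `p`, a named numeric of length `J + 1`
#'   (`pi1..piJ, miss`); for vector `p`, a matrix with one row per element.
#' @export
removal_cell_probs <- function(p, J) {
  if (any(p < 0 | p > 1)) stop("domain error: p must be in [0, 1]")
  stopifnot(J >= 1L)
  out <- cbind(outer(p, seq_len(J) - 1, function(pp, j) pp * (1 - pp)^j),
               (1 - p)^J)
  colnames(out) <- c(paste0("pi", seq_len(J)), "miss")
  if (length(p) == 1L) out[1, ] else out
}

# Internal: design matrices + count matrix from counts/covariates/spec.
model_frames <- function(counts, covariates, spec) {
  J <- spec$J
  ycols <- paste0("y", seq_len(J))
  if (!all(ycols %in% names(counts)))
    stop("counts must have columns ", paste(ycols, collapse = ", "))
  y <- as.matrix(counts[ycols])
  n <- nrow(y)
  Xa <- coef_design(stats::setNames(rep(0, length(spec$abund) + 1L),
                                    c("intercept", spec$abund)),
                    covariates, n)
  Xd <- coef_design(stats::setNames(rep(0, length(spec$det) + 1L),
                                    c("intercept", spec$det)),
                    covariates, n)
  if (any(!is.finite(Xa)) || any(!is.finite(Xd)))
    stop("numeric error: non-finite covariate values")
  list(y = y, T = rowSums(y), S = drop(y %*% (seq_len(J) - 1)),
       lgam = rowSums(lgamma(y + 1)), Xa = Xa, Xd = Xd, n = n, J = J)
}

# Marginal negative log-likelihood and analytic gradient.  The latent site
# abundance N is integrated out in closed form: the total count is Poisson
# with mean lambda*A*(1-(1-p)^J) and the interval split is conditionally
# multinomial, which collapses to
#   ll_i = T_i log(lambda_i A) - lambda_i A pidet_i
#          + T_i log p_i + S_i log(1-p_i) - sum_j lgamma(y_ij + 1)
# with S_i = sum_j y_ij (j-1).
nll_core <- function(par, fr, A, grad = FALSE) {
  ka <- ncol(fr$Xa)
  ba <- par[seq_len(ka)]
  bd <- par[-seq_len(ka)]
  eta <- drop(fr$Xa %*% ba)
  zeta <- drop(fr$Xd %*% bd)
  if (any(!is.finite(eta)) || any(!is.finite(zeta)))
    stop("numeric error: non-finite linear predictor")
  # clamp against overflow far from the optimum (exp(30) per km2 is far
  # beyond any plausible density); keeps intermediate optimizer steps finite
  eta <- pmin(eta, 30)
  lam <- exp(eta)
  p <- stats::plogis(zeta)
  q <- 1 - p
  pidet <- 1 - q^fr$J
  # 0 * log(0) := 0 for degenerate p
  tlp <- ifelse(fr$T > 0, fr$T * log(p), 0)
  slq <- ifelse(fr$S > 0, fr$S * log(q), 0)
  ll <- fr$T * (eta + log(A)) - lam * A * pidet + tlp + slq - fr$lgam
  val <- -sum(ll)
  if (!grad) return(val)
  ga <- -drop(crossprod(fr$Xa, fr$T - A * lam * pidet))
  gd <- -drop(crossprod(fr$Xd,
                        fr$T * q - fr$S * p - A * lam * fr$J * p * q^fr$J))
  list(value = val, gradient = c(ga, gd))
}

#' Marginal negative log-likelihood of the removal N-mixture model
#'
#' The exact latent-abundance-marginalized likelihood: the Poisson site
#' abundance is integrated out analytically, factorizing into a Poisson
#' term for the total count (mean `lambda*A*(1-(1-p)^J)`) and a conditional
#' multinomial over intervals.  Includes all normalizing constants, so it
#' matches the brute-force truncated sum over latent N exactly.
#'
#' @param params numeric parameter vector, ordered abundance coefficients
#'   (intercept first) then detection coefficients (intercept first).
#' @param counts `removal_counts` data.frame (columns `y1..yJ`).
#' @param covariates standardized covariate data.frame aligned with
#'   `counts`.
#' @param spec a [removal_model_spec()].
#' @return Nonnegative scalar negative log-likelihood.
#' @export
removal_negloglik <- function(params, counts, covariates, spec) {
  fr <- model_frames(counts, covariates, spec)
  stopifnot(length(params) == ncol(fr$Xa) + ncol(fr$Xd))
  nll_core(params, fr, spec$offset_area_km2)
}

#' Fit the removal N-mixture model by maximum likelihood
#'
#' Quasi-Newton (BFGS) minimization of the marginal negative
#' log-likelihood with analytic gradients, starting from a zero coefficient
#' vector, restarting once from a perturbed start if the first attempt does
#' not converge.  The covariance matrix is the inverse observed
#' information (numeric Hessian at the optimum); standard errors carry an
#' overdispersion multiplier `sqrt(c-hat)` (initially 1, see
#' [overdispersion_adjust()]).
#'
#' @param counts `removal_counts` data.frame.
#' @param covariates standardized covariates aligned with `counts`.
#' @param spec a [removal_model_spec()].
#' @param scaling optional `scaling_params` used to standardize
#'   `covariates`, stored for prediction.
#' @param control passed to [stats::optim()]; defaults
#'   `maxit = 500, reltol = 1e-8`.
#' @return An object of class `removal_fit` with elements `beta_abund`,
#'   `beta_det`, `vcov`, `se`, `loglik`, `converged`, `chat`, plus the data
#'   and spec needed for prediction and diagnostics.
#' @export
fit_removal <- function(counts, covariates, spec = removal_model_spec(),
                        scaling = NULL, control = list()) {
  fr <- model_frames(counts, covariates, spec)
  npar <- ncol(fr$Xa) + ncol(fr$Xd)
  if (fr$n < npar + 1L)
    stop("too few sites (", fr$n, ") to fit ", npar, " parameters")
  A <- spec$offset_area_km2
  fn <- function(par) nll_core(par, fr, A)
  gr <- function(par) nll_core(par, fr, A, grad = TRUE)$gradient
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-8), control)
  run <- function(start) {
    tryCatch(stats::optim(start, fn, gr, method = "BFGS", control = ctl,
                          hessian = TRUE),
             error = function(e) NULL)
  }
  # moment start for the abundance intercept (mean count against the
  # offset at p = 0.5 detectability); remaining coefficients start at zero
  start0 <- rep(0, npar)
  start0[1] <- log(max(mean(fr$T), 0.05) /
                     (A * (1 - 0.5^fr$J)))
  opt <- run(start0)
  if (is.null(opt) || opt$convergence != 0) {
    opt2 <- with_seed(1L, run(start0 + stats::rnorm(npar, 0, 0.25)))
    if (!is.null(opt2) && (is.null(opt) || opt2$value <= opt$value))
      opt <- opt2
  }
  if (is.null(opt)) stop("optimization failed from both starts")
  pnames <- c(paste0("abund.", colnames(fr$Xa)),
              paste0("det.", colnames(fr$Xd)))
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(vc)))
    stop("singular information matrix: model not identifiable on these data")
  vc <- (vc + t(vc)) / 2
  dv <- diag(vc)
  converged <- opt$convergence == 0 && all(dv > 0)
  se <- sqrt(pmax(dv, 0))
  names(se) <- pnames
  dimnames(vc) <- list(pnames, pnames)
  ka <- ncol(fr$Xa)
  structure(list(
    beta_abund = stats::setNames(opt$par[seq_len(ka)], colnames(fr$Xa)),
    beta_det = stats::setNames(opt$par[-seq_len(ka)], colnames(fr$Xd)),
    vcov_raw = vc, se_raw = se, vcov = vc, se = se,
    loglik = -opt$value, converged = converged, chat = 1,
    spec = spec, scaling = scaling,
    counts = counts, covariates = covariates, n = fr$n
  ), class = "removal_fit")
}

#' @export
print.removal_fit <- function(x, ...) {
  cat(sprintf("removal N-mixture fit: %d sites, logLik = %.2f, %s, c-hat = %.2f\n",
              x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$chat))
  est <- c(x$beta_abund, x$beta_det)
  tab <- data.frame(estimate = est, se = x$se,
                    row.names = names(x$se))
  print(round(tab, 4))
  invisible(x)
}

# fitted lambda (density per km2), p, and expected totals for a model on
# arbitrary standardized covariates
fit_linpred <- function(model, covariates, n = nrow(covariates)) {
  Xa <- coef_design(model$beta_abund, covariates, n)
  Xd <- coef_design(model$beta_det, covariates, n)
  lam <- exp(drop(Xa %*% model$beta_abund))
  p <- stats::plogis(drop(Xd %*% model$beta_det))
  pidet <- 1 - (1 - p)^model$spec$J
  list(lambda = lam, p = p, pidet = pidet,
       etotal = lam * model$spec$offset_area_km2 * pidet)
}

#' Apply an overdispersion correction to a fitted model
#'
#' Floors the overdispersion estimate at 1 (models with c-hat below 1 are
#' assigned 1) and inflates standard errors by `sqrt(c-hat)`; point
#' estimates are unchanged, Wald intervals widen accordingly.
#'
#' @param model a `removal_fit`.
#' @param chat overdispersion estimate (> 0), e.g. from
#'   [gof_parametric_bootstrap()].
#' @return The adjusted `removal_fit`.
#' @export
overdispersion_adjust <- function(model, chat) {
  stopifnot(inherits(model, "removal_fit"))
  if (!is.finite(chat) || chat <= 0)
    stop("domain error: c-hat must be a positive number")
  ceff <- max(chat, 1)
  model$chat <- ceff
  model$se <- model$se_raw * sqrt(ceff)
  model$vcov <- model$vcov_raw * ceff
  model
}

#' Predict expected density with coefficient-shift error propagation
#'
#' Point density per km2 is `exp(x' beta)` (the offset makes predictions
#' area-free rates); the error-propagation layers shift all abundance
#' coefficients jointly by plus or minus `1.96 * SE` (c-hat-adjusted)
#' before exponentiating.  No ordering between the three layers is
#' guaranteed when covariates change sign.
#'
#' @param model a `removal_fit`.
#' @param covariates data.frame of covariates standardized with the
#'   model's scaling.
#' @return data.frame with columns `point`, `minus`, `plus` (densities per
#'   km2, one row per input row).
#' @export
predict_expected_density <- function(model, covariates) {
  stopifnot(inherits(model, "removal_fit"))
  n <- nrow(covariates)
  Xa <- coef_design(model$beta_abund, covariates, n)
  se_a <- model$se[paste0("abund.", names(model$beta_abund))]
  data.frame(
    point = exp(drop(Xa %*% model$beta_abund)),
    minus = exp(drop(Xa %*% (model$beta_abund - 1.96 * se_a))),
    plus = exp(drop(Xa %*% (model$beta_abund + 1.96 * se_a)))
  )
}

#' Effect size of one abundance covariate
#'
#' Compares the predicted density at all covariates held at their means
#' (standardized 0) with the prediction at +1 standard deviation of the
#' named covariate, holding the others at their means.  On the log link
#' the density ratio is exactly `exp(b)`; the Wald interval uses the
#' c-hat-adjusted standard error.
#'
#' @param model a `removal_fit`.
#' @param covariate_name one abundance covariate name.
#' @param level confidence level for the ratio interval, default 0.95.
#' @return list with `density_at_mean`, `density_plus1sd`, `absolute`
#'   (difference), `ratio`, and `ratio_ci`.
#' @export
covariate_effect_size <- function(model, covariate_name, level = 0.95) {
  stopifnot(inherits(model, "removal_fit"))
  if (!covariate_name %in% names(model$beta_abund))
    stop("unknown abundance covariate: ", covariate_name)
  b <- model$beta_abund[[covariate_name]]
  se <- model$se[[paste0("abund.", covariate_name)]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  d0 <- exp(model$beta_abund[["intercept"]])
  d1 <- d0 * exp(b)
  list(density_at_mean = d0, density_plus1sd = d1,
       absolute = d1 - d0, ratio = exp(b),
       ratio_ci = exp(b + c(-1, 1) * z * se))
}
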