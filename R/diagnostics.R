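# Model assessment: parametric-bootstrap goodness of fit and
# overdispersion, holdout cross-validation, AUC, Spearman's rho, and a
# binned Moran's I residual correlogram.

# Pearson chi-square over site x interval cells; expectations floored to
# avoid division blow-ups at tiny fitted cells.
pearson_chisq <- function(y, lam, p, J, A, floor_e = 1e-4) {
  piJ <- outer(p, seq_len(J) - 1, function(pp, j) pp * (1 - pp)^j)
  E <- lam * A * piJ
  sum((y - E)^2 / pmax(E, floor_e))
}

# Simulate counts from a fitted model on its own covariates.  Marginally
# the interval counts are independent Poissons (Poisson thinning), which
# is distributionally identical to Poisson-N + multinomial removal.
simulate_from_fit <- function(model) {
  lp <- fit_linpred(model, model$covariates)
  J <- model$spec$J
  piJ <- outer(lp$p, seq_len(J) - 1, function(pp, j) pp * (1 - pp)^j)
  E <- lp$lambda * model$spec$offset_area_km2 * piJ
  y <- matrix(stats::rpois(length(E), E), nrow(E), J)
  out <- data.frame(site_id = model$counts$site_id, y)
  names(out) <- c("site_id", paste0("y", seq_len(J)))
  out$total <- rowSums(y)
  out
}

#' Parametric-bootstrap goodness-of-fit test and overdispersion estimate
#'
#' Computes the Pearson chi-square of the observed site-by-interval counts
#' against fitted expectations, then simulates `nboot` datasets from the
#' fitted model, refits each, and recomputes the statistic.  The bootstrap
#' p-value is the fraction of bootstrap statistics at or above the
#' observed one; the overdispersion estimate is
#' `c-hat = observed / mean(bootstrap)`.
#'
#' @param model a converged `removal_fit`.
#' @param nboot number of bootstrap replicates (> 0).
#' @param seed integer seed.
#' @param max_fail_frac tolerated fraction of bootstrap refit failures.
#' @return list of class `removal_gof`: `chisq_obs`, `chisq_boot`,
#'   `p_value`, `chat`, `n_failed`.
#' @export
gof_parametric_bootstrap <- function(model, nboot = 100L, seed = 1L,
                                     max_fail_frac = 0.2) {
  stopifnot(inherits(model, "removal_fit"))
  if (nboot <= 0L) stop("nboot must be a positive integer")
  if (!model$converged)
    stop("goodness of fit requires a converged model")
  J <- model$spec$J
  A <- model$spec$offset_area_km2
  yobs <- as.matrix(model$counts[paste0("y", seq_len(J))])
  lp <- fit_linpred(model, model$covariates)
  obs <- pearson_chisq(yobs, lp$lambda, lp$p, J, A)
  boot <- rep(NA_real_, nboot)
  with_seed(seed, {
    for (b in seq_len(nboot)) {
      yb <- simulate_from_fit(model)
      fb <- tryCatch(
        fit_removal(yb, model$covariates, model$spec),
        error = function(e) NULL
      )
      if (is.null(fb) || !fb$converged) next
      lpb <- fit_linpred(fb, model$covariates)
      boot[b] <- pearson_chisq(as.matrix(yb[paste0("y", seq_len(J))]),
                               lpb$lambda, lpb$p, J, A)
    }
  })
  failed <- sum(is.na(boot))
  if (failed > max_fail_frac * nboot)
    stop("too many bootstrap refit failures: ", failed, " of ", nboot)
  boot <- boot[!is.na(boot)]
  structure(list(chisq_obs = obs, chisq_boot = boot,
                 p_value = mean(boot >= obs),
                 chat = obs / mean(boot), n_failed = failed),
            class = "removal_gof")
}

#' @export
print.removal_gof <- function(x, ...) {
  cat(sprintf("parametric-bootstrap GOF: chi-square = %.2f, p = %.3f, c-hat = %.2f (%d replicates)\n",
              x$chisq_obs, x$p_value, x$chat, length(x$chisq_boot)))
  invisible(x)
}

#' Holdout cross-validation of predicted site totals
#'
#' Fits on a random 70% of sites (by default), predicts the expected total
#' count `lambda*A*(1-(1-p)^J)` on the held-out 30%, and reports RMSE and
#' MAE against the observed totals.
#'
#' @param counts,covariates,spec as in [fit_removal()].
#' @param holdout_frac fraction held out, in (0, 1).
#' @param seed integer seed.
#' @return list: `rmse`, `mae`, `n_test`, `converged` (training fit flag).
#' @export
crossval_holdout <- function(counts, covariates, spec = removal_model_spec(),
                             holdout_frac = 0.3, seed = 1L) {
  if (holdout_frac <= 0 || holdout_frac >= 1)
    stop("holdout_frac must be in (0, 1)")
  n <- nrow(counts)
  with_seed(seed, {
    test <- sort(sample.int(n, max(1L, round(holdout_frac * n))))
    train <- setdiff(seq_len(n), test)
    fit <- fit_removal(counts[train, , drop = FALSE],
                       covariates[train, , drop = FALSE], spec)
    pred <- fit_linpred(fit, covariates[test, , drop = FALSE])$etotal
    obs <- rowSums(counts[test, paste0("y", seq_len(spec$J)), drop = FALSE])
    list(rmse = sqrt(mean((obs - pred)^2)), mae = mean(abs(obs - pred)),
         n_test = length(test), converged = fit$converged)
  })
}

# Mann-Whitney rank AUC
auc_rank <- function(score, label) {
  pos <- label > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated-holdout AUC of detection/non-detection
#'
#' Per repetition: fit on a random 70%, compute the predicted probability
#' of at least one detection `1 - exp(-lambda*A*(1-(1-p)^J))` on the held
#' out 30%, and score it against the observed detection indicator with the
#' rank (Mann-Whitney) AUC.  Repetitions whose test split has a single
#' class are skipped with a warning.  Mean AUC above 0.6 is flagged as
#' acceptable predictive accuracy.
#'
#' @param counts,covariates,spec as in [fit_removal()].
#' @param holdout_frac test fraction.
#' @param reps number of repetitions, default 10.
#' @param seed integer seed.
#' @return list: `mean_auc`, `auc` (per rep, NA where skipped),
#'   `acceptable` (mean AUC > 0.6).
#' @export
auc_holdout <- function(counts, covariates, spec = removal_model_spec(),
                        holdout_frac = 0.3, reps = 10L, seed = 1L) {
  if (holdout_frac <= 0 || holdout_frac >= 1)
    stop("holdout_frac must be in (0, 1)")
  n <- nrow(counts)
  obs_total <- rowSums(counts[paste0("y", seq_len(spec$J))])
  aucs <- rep(NA_real_, reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      test <- sort(sample.int(n, max(1L, round(holdout_frac * n))))
      lab <- obs_total[test] > 0
      if (all(lab) || !any(lab)) {
        warning("AUC repetition ", r, " skipped: single-class test split")
        next
      }
      train <- setdiff(seq_len(n), test)
      fit <- tryCatch(
        fit_removal(counts[train, , drop = FALSE],
                    covariates[train, , drop = FALSE], spec),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      lp <- fit_linpred(fit, covariates[test, , drop = FALSE])
      aucs[r] <- auc_rank(1 - exp(-lp$etotal), lab)
    }
  })
  if (all(is.na(aucs))) stop("all AUC repetitions were skipped")
  m <- mean(aucs, na.rm = TRUE)
  list(mean_auc = m, auc = aucs, acceptable = m > 0.6)
}

#' Spearman rank correlation between observed and predicted totals
#'
#' @param model a `removal_fit`.
#' @return list: `rho` (NA with a note when predictions are constant),
#'   `note`.
#' @export
spearman_obs_pred <- function(model) {
  stopifnot(inherits(model, "removal_fit"))
  obs <- rowSums(model$counts[paste0("y", seq_len(model$spec$J))])
  pred <- fit_linpred(model, model$covariates)$etotal
  if (stats::sd(pred) == 0)
    return(list(rho = NA_real_, note = "constant predictions: rho undefined"))
  list(rho = stats::cor(obs, pred, method = "spearman"), note = NULL)
}

#' Binned Moran's I correlogram of model residuals
#'
#' Pearson residuals `(T - E[T]) / sqrt(E[T])` are assessed for residual
#' spatial autocorrelation with Moran's I computed per distance bin
#' (binary in-bin weights, global-variance normalization), against a null
#' envelope built from `nboot` random permutations of the residuals over
#' sites.  Lack of residual spatial autocorrelation is declared when the
#' observed I falls within the envelope (which straddles zero) in every
#' non-empty bin.  Bins with fewer than 2 pairs are reported empty (NA).
#'
#' @param model a `removal_fit`.
#' @param sites data.frame with `x`, `y` coordinates (m) aligned with the
#'   model's sites.
#' @param max_dist maximum pair distance (m), default 30 km.
#' @param n_bins number of equal-width distance bins.
#' @param nboot number of permutation resamples for the envelope.
#' @param envelope two-sided envelope coverage, default 0.95.
#' @param seed integer seed.
#' @return list of class `moran_correlogram`: data.frame `bins`
#'   (`dist_lo`, `dist_hi`, `n_pairs`, `I`, `lo`, `hi`, `in_envelope`) and
#'   overall flag `no_autocorrelation`.
#' @export
residual_moran_correlogram <- function(model, sites, max_dist = 30000,
                                       n_bins = 10L, nboot = 100L,
                                       envelope = 0.95, seed = 1L) {
  stopifnot(inherits(model, "removal_fit"), nrow(sites) == model$n)
  obs <- rowSums(model$counts[paste0("y", seq_len(model$spec$J))])
  E <- fit_linpred(model, model$covariates)$etotal
  z <- (obs - E) / sqrt(E)
  n <- length(z)
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  brk <- seq(0, max_dist, length.out = n_bins + 1L)
  bin_of <- matrix(findInterval(d, brk, left.open = TRUE), n, n)
  bin_of[d > max_dist | row(bin_of) == col(bin_of)] <- 0L
  moran_by_bin <- function(zz) {
    zc <- zz - mean(zz)
    denom <- sum(zc^2)
    cp <- outer(zc, zc)
    vapply(seq_len(n_bins), function(b) {
      sel <- bin_of == b
      s0 <- sum(sel)
      if (s0 < 4L || denom == 0) return(NA_real_)  # < 2 symmetric pairs
      (n / s0) * sum(cp[sel]) / denom
    }, 0)
  }
  I_obs <- moran_by_bin(z)
  perm <- with_seed(seed, {
    vapply(seq_len(nboot), function(b) moran_by_bin(z[sample.int(n)]),
           numeric(n_bins))
  })
  a <- (1 - envelope) / 2
  lo <- apply(perm, 1, stats::quantile, probs = a, na.rm = TRUE)
  hi <- apply(perm, 1, stats::quantile, probs = 1 - a, na.rm = TRUE)
  bins <- data.frame(
    dist_lo = brk[-length(brk)], dist_hi = brk[-1],
    n_pairs = vapply(seq_len(n_bins),
                     function(b) sum(bin_of == b) / 2, 0),
    I = I_obs, lo = lo, hi = hi,
    in_envelope = is.na(I_obs) | (I_obs >= lo & I_obs <= hi)
  )
  structure(list(bins = bins,
                 no_autocorrelation = all(bins$in_envelope)),
            class = "moran_correlogram")
}

#' @export
print.moran_correlogram <- function(x, ...) {
  cat("binned Moran's I correlogram;",
      if (x$no_autocorrelation) "no residual spatial autocorrelation detected\n"
      else "residual spatial autocorrelation outside the null envelope\n")
  print(round(x$bins, 4))
  invisible(x)
}
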