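# Explanatory regression stages. The dataset-level overlap proportions are
# modelled by a beta regression (logit mean link, mean-precision
# parameterization) fitted by direct maximum likelihood; richness pairs by a
# negative-binomial random-intercept GLMM and the per-species abundance
# indices by a beta random-intercept model, both Laplace-fitted via glmmTMB.
# Proportions are boundary-smoothed with y' = (y (n - 1) + 0.5) / n before
# beta likelihoods since exact 0s and 1s occur.

#' Boundary smoothing for proportions
#' @param y proportions in \[0,1\].
#' @param n number of observations (defaults to `length(y)`).
#' @return values in (0,1).
#' @export
smooth_proportion <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

new_edna_fit <- function(coefs, family, link, n, converged, extra = list()) {
  structure(c(list(coefficients = coefs, family = family, link = link,
                   n = n, converged = converged), extra),
            class = "edna_fit")
}

#' @export
print.edna_fit <- function(x, ...) {
  cat("<edna_fit>", x$family, "(", x$link, "), n =", x$n,
      if (!x$converged) "[NOT CONVERGED]", "\n")
  print(as.data.frame(x$coefficients), digits = 4)
  if (!is.null(x$phi)) cat("precision phi =", signif(x$phi, 4), "\n")
  if (!is.null(x$theta)) cat("NB dispersion theta =", signif(x$theta, 4), "\n")
  if (!is.null(x$sigma2_u)) {
    cat("random-intercept variance =", signif(x$sigma2_u, 4), "\n")
    cat("R2 marginal =", signif(x$r2_marginal, 3),
        "| conditional =", signif(x$r2_conditional, 3), "\n")
  }
  invisible(x)
}

#' @method tidy edna_fit
#' @export
tidy.edna_fit <- function(x, ...) x$coefficients

#' @method glance edna_fit
#' @export
glance.edna_fit <- function(x, ...) {
  tibble(
    family = x$family, n = x$n, converged = x$converged,
    logLik = x$logLik %||% NA_real_,
    phi = x$phi %||% NA_real_, theta = x$theta %||% NA_real_,
    sigma2_u = x$sigma2_u %||% NA_real_,
    r2_marginal = x$r2_marginal %||% NA_real_,
    r2_conditional = x$r2_conditional %||% NA_real_
  )
}

coef_table <- function(est, se) {
  z <- est / se
  tibble(term = names(est), estimate = unname(est), std.error = unname(se),
         statistic = unname(z), p.value = unname(2 * pnorm(-abs(z))))
}

beta_negll <- function(par, x, y) {
  k <- ncol(x)
  eta <- drop(x %*% par[1:k])
  mu <- plogis(eta)
  phi <- exp(par[k + 1])
  -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
         (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
}

beta_negll_grad <- function(par, x, y) {
  k <- ncol(x)
  eta <- drop(x %*% par[1:k])
  mu <- plogis(eta)
  phi <- exp(par[k + 1])
  ystar <- qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dmu <- mu * (1 - mu)
  gbeta <- -drop(crossprod(x, phi * (ystar - mustar) * dmu))
  dphi <- sum(mu * (ystar - mustar) + digamma(phi) - digamma((1 - mu) * phi) +
                log1p(-y))
  c(gbeta, -dphi * phi)
}

#' Beta regression for overlap proportions
#'
#' Direct maximum likelihood in the mean-precision parameterization with a
#' logit mean link; Wald standard errors from the numerically differentiated
#' Hessian. Proportions are boundary-smoothed first. Non-convergence (or a
#' singular Hessian, as under separation) yields a flagged fit, not an error.
#'
#' @param data data frame holding the response and predictors.
#' @param formula model formula, e.g.
#'   `p_sp ~ log(median_fish_reads) + year + richness + refdb_type`.
#' @return an `edna_fit` with a coefficient table (estimate, SE, z, p),
#'   precision `phi`, `logLik`, and pseudo-R2 (squared correlation of the
#'   linear predictor with the logit response).
#' @export
fit_beta_glm <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0 | y > 1)) abort("response must be proportions in [0,1]")
  x <- model.matrix(formula, mf)
  if (nrow(x) < ncol(x) + 2) abort("too few observations for beta regression")
  y <- smooth_proportion(y)
  init <- c(solve(crossprod(x), crossprod(x, qlogis(y))), log_phi = 1)
  opt <- tryCatch(
    optim(init, beta_negll, beta_negll_grad, x = x, y = y, method = "BFGS",
          control = list(maxit = 1000, reltol = 1e-14), hessian = TRUE),
    error = function(e) NULL
  )
  terms_x <- colnames(x)
  if (is.null(opt)) {
    return(new_edna_fit(coef_table(setNames(rep(NA_real_, ncol(x)), terms_x),
                                   rep(NA_real_, ncol(x))),
                        "beta", "logit", length(y), FALSE))
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  converged <- opt$convergence == 0 && !is.null(vc) &&
    all(diag(vc)[seq_along(terms_x)] > 0)
  se <- if (is.null(vc)) rep(NA_real_, ncol(x)) else
    sqrt(pmax(diag(vc)[seq_along(terms_x)], 0))
  est <- setNames(opt$par[seq_along(terms_x)], terms_x)
  eta <- drop(x %*% est)
  new_edna_fit(
    coef_table(est, setNames(se, terms_x)), "beta", "logit", length(y),
    converged,
    extra = list(phi = unname(exp(opt$par[ncol(x) + 1])), logLik = -opt$value,
                 pseudo_r2 = if (var(eta) > 0) stats::cor(eta, qlogis(y))^2
                             else NA_real_,
                 fitted = plogis(eta))
  )
}

glmmtmb_fit <- function(formula, data, family, family_label) {
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(formula, data = data, family = family)),
    error = function(e) NULL
  )
  bad <- is.null(fit) || !is.finite(logLik(fit)) ||
    isTRUE(fit$fit$convergence != 0)
  if (bad) {
    return(new_edna_fit(tibble(term = character(), estimate = double(),
                               std.error = double(), statistic = double(),
                               p.value = double()),
                        family_label, "mixed", nrow(data), FALSE,
                        extra = list(diagnostics = "optimizer failed")))
  }
  sm <- summary(fit)$coefficients$cond
  coefs <- tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
                  statistic = sm[, 3], p.value = sm[, 4])
  vc <- glmmTMB::VarCorr(fit)$cond
  sigma2_u <- if (length(vc)) as.numeric(vc[[1]][1, 1]) else 0
  list(fit = fit, coefs = coefs, sigma2_u = sigma2_u,
       converged = !anyNA(sm[, 2]))
}

# Marginal / conditional R2 on the link scale: fixed-effect variance over
# fixed + random + observation-level variance. The NB observation-level term
# uses the lognormal approximation ln(1 + 1/nu_bar + 1/theta); the beta term
# a delta-method logit-scale variance averaged over fitted means.
nakagawa_r2 <- function(var_fixed, sigma2_u, var_obs) {
  tot <- var_fixed + sigma2_u + var_obs
  list(marginal = var_fixed / tot, conditional = (var_fixed + sigma2_u) / tot)
}

#' Negative-binomial richness GLMM
#'
#' Reanalyzed per-site richness regressed on original per-site richness with
#' a dataset-level random intercept, NB2 family, log link, Laplace-fitted.
#' Marginal and conditional R2 follow the lognormal observation-level
#' variance approximation `ln(1 + 1/nu_bar + 1/theta)`.
#'
#' @param data data frame with columns `original_richness`,
#'   `reanalyzed_richness`, `dataset_id`.
#' @param formula optional override of the fixed-effect formula.
#' @return an `edna_fit` with theta, random-intercept variance and R2s.
#' @export
fit_nb_glmm_richness <- function(data,
                                 formula = reanalyzed_richness ~
                                   original_richness + (1 | dataset_id)) {
  if (length(unique(data$dataset_id)) < 2) abort("need >= 2 datasets")
  res <- glmmtmb_fit(formula, data, glmmTMB::nbinom2(), "nbinom2")
  theta <- if (!inherits(res, "edna_fit")) stats::sigma(res$fit) else NA
  if (inherits(res, "edna_fit") || !is.finite(theta) || theta > 1e6) {
    # Underdispersed counts push the NB dispersion to its Poisson boundary
    # (theta -> infinity), where the NB Hessian is singular; refit in the
    # Poisson limit and report theta = Inf.
    res_p <- glmmtmb_fit(formula, data, stats::poisson(), "nbinom2")
    if (inherits(res_p, "edna_fit")) return(res_p)
    res <- res_p
    theta <- Inf
  }
  fit <- res$fit
  xb <- drop(stats::model.matrix(fit) %*% glmmTMB::fixef(fit)$cond)
  var_fixed <- var(xb)
  nu_bar <- mean(exp(xb))
  var_obs <- log1p(1 / nu_bar + 1 / theta)
  r2 <- nakagawa_r2(var_fixed, res$sigma2_u, var_obs)
  new_edna_fit(res$coefs, "nbinom2", "log", nrow(data), res$converged,
               extra = list(theta = theta, sigma2_u = res$sigma2_u,
                            r2_marginal = r2$marginal,
                            r2_conditional = r2$conditional,
                            logLik = as.numeric(logLik(fit)), tmb = fit))
}

#' Richness pairs for the GLMM stage
#'
#' Per-site (original, reanalyzed) richness for every dataset with an
#' original presence table, at the requested correction scale (`"global"` =
#' uncorrected).
#'
#' @param collection an `edna_collection`.
#' @param scale `"global"`, `"basin"`, `"country"`, or `"continent"`.
#' @return tibble (dataset_id, site, original_richness, reanalyzed_richness).
#' @export
richness_pairs <- function(collection, scale = "global") {
  collection <- index_pools(harmonize_collection(collection))
  ds <- collection$datasets
  rows <- map(seq_len(nrow(ds)), function(i) {
    pres <- ds$original_presence[[i]]
    if (is.null(pres) || !nrow(pres)) return(NULL)
    reads <- ds$reads[[i]]
    if (scale != "global") {
      reads <- correct_to_pool(reads,
                               dataset_pool(collection, ds$dataset_id[i], scale))
    }
    rean <- richness_per_site(reads)
    pm <- as.matrix(pres[, -1, drop = FALSE])
    orig <- tibble(site = colnames(pm),
                   original_richness = as.integer(colSums(pm > 0)))
    dplyr::inner_join(orig, rean, by = "site") %>%
      rename(reanalyzed_richness = "richness") %>%
      mutate(dataset_id = ds$dataset_id[i], .before = 1)
  })
  bind_rows(rows)
}

#' Beta mixed model for abundance indices
#'
#' Models a per-species relative-abundance index (`a` or `b`) on the
#' shared/unique flag, reference-database type and year, with a dataset-level
#' random intercept (beta family, logit link, Laplace via glmmTMB). The
#' `shared_flagTRUE` coefficient is the shared-vs-unique contrast.
#'
#' @param records output of [abundance_table()] (or compatible).
#' @param index `"a"` or `"b"`.
#' @param predictors character vector of fixed-effect terms besides
#'   `shared_flag`.
#' @return an `edna_fit` with phi, random-intercept variance and R2s.
#' @export
fit_abundance_mixed <- function(records, index = c("a", "b"),
                                predictors = c("refdb_type", "year")) {
  index <- match.arg(index)
  dat <- records
  dat$y <- smooth_proportion(dat[[index]])
  dat$year_c <- dat$year - min(dat$year)
  predictors <- sub("^year$", "year_c", predictors)
  rhs <- paste(c("shared_flag", predictors, "(1 | dataset_id)"),
               collapse = " + ")
  res <- glmmtmb_fit(stats::as.formula(paste("y ~", rhs)), dat,
                     glmmTMB::beta_family(), "beta")
  if (inherits(res, "edna_fit")) return(res)
  fit <- res$fit
  phi <- stats::sigma(fit)
  xb <- drop(stats::model.matrix(fit) %*% glmmTMB::fixef(fit)$cond)
  mu <- plogis(xb)
  var_obs <- mean(1 / ((1 + phi) * mu * (1 - mu)))
  r2 <- nakagawa_r2(var(xb), res$sigma2_u, var_obs)
  new_edna_fit(res$coefs, "beta", "logit", nrow(dat), res$converged,
               extra = list(phi = phi, sigma2_u = res$sigma2_u,
                            r2_marginal = r2$marginal,
                            r2_conditional = r2$conditional,
                            logLik = as.numeric(logLik(fit)), tmb = fit))
}

#' Drop datasets with low fish-read depth
#'
#' @param collection an `edna_collection`.
#' @param min_median_fish_reads threshold (>= 0) on the per-dataset median
#'   per-site fish reads.
#' @return list with the filtered `collection` and a `report` tibble of
#'   removed datasets. Removing every dataset is an error.
#' @export
sensitivity_filter <- function(collection, min_median_fish_reads) {
  if (min_median_fish_reads < 0) abort("threshold must be >= 0")
  ds <- collection$datasets
  drop <- ds$median_fish_reads < min_median_fish_reads
  if (all(drop)) abort("sensitivity filter removed every dataset")
  report <- ds %>%
    filter(drop) %>%
    select("dataset_id", "continent", "median_fish_reads")
  collection$datasets <- ds[!drop, , drop = FALSE]
  collection$pools <- collection$pools %>%
    filter(.data$dataset_id %in% collection$datasets$dataset_id)
  list(collection = collection, report = report)
}
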