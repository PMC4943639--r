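# Mixed-effects resource-selection models: Gelman 2-SD standardization,
# use-availability logistic GLMMs with nested random intercepts (year
# within individual), Wald confidence intervals at 95/90/85%, AIC model
# comparison, interaction reduction, selection inference, prediction maps,
# and k-fold cross-validation with Spearman bin correlation.

.continuous_covariates <- function(table) {
  cand <- c(names(.covariate_names()), "elevation", "slope")
  intersect(cand, names(table))
}

#' Gelman 2-SD standardization
#'
#' Rescales every continuous covariate to (x - mean) / (2 sd), with mean
#' and sd computed over all rows (used and available pooled), so that
#' continuous coefficients are comparable to those of binary predictors
#' such as the male dummy (which is left unscaled).  The scaling is stored
#' in \code{attr(, "scaling")} for back-transformation and prediction.
#'
#' @param table an \code{"rsf_data"} table (see \code{\link{build_table}}).
#' @param covariates columns to rescale; defaults to the distance
#'   covariates plus elevation and slope present in the table.
#' @return The table with covariates rescaled and the scaling recorded.
#' @export
standardize_gelman <- function(table, covariates = .continuous_covariates(table)) {
  mu <- vapply(covariates, function(v) mean(table[[v]]), numeric(1))
  sdv <- vapply(covariates, function(v) stats::sd(table[[v]]), numeric(1))
  if (any(sdv == 0))
    stop("zero-variance covariate: ",
         paste(covariates[sdv == 0], collapse = ", "))
  for (v in covariates) table[[v]] <- (table[[v]] - mu[[v]]) / (2 * sdv[[v]])
  attr(table, "scaling") <- data.frame(covariate = covariates, mean = mu,
                                       sd = sdv, row.names = NULL)
  table
}

.rsf_formula <- function(covariates, interactions, sex_term, random = TRUE) {
  rhs <- covariates
  if (sex_term) rhs <- c(rhs, "sex_male")
  if (length(interactions)) rhs <- c(rhs, paste0(interactions, ":sex_male"))
  if (random) rhs <- c(rhs, "(1 | animal_id / year)")
  stats::as.formula(paste("response ~", paste(rhs, collapse = " + ")))
}

#' Fit a mixed-effects resource-selection function
#'
#' A binomial (logit) GLMM contrasting used (1) against available (0)
#' pixels, with random intercepts for individual and for year nested in
#' individual, fitted by Laplace-approximate maximum likelihood through
#' \code{lme4::glmer}.  Sex-specific selection enters as interactions of
#' covariates with the male dummy.  Covariates are Gelman 2-SD standardized
#' before fitting unless the table already carries a scaling attribute.
#'
#' @param table an \code{"rsf_data"} table.
#' @param covariates character vector of fixed-effect covariates.
#' @param interactions covariates whose interaction with \code{sex_male} is
#'   included (default none).
#' @param null_model fit the intercept + random-effects null model,
#'   ignoring \code{covariates}.
#' @param nAGQ integer, number of adaptive Gauss-Hermite quadrature points;
#'   the default 1 is the Laplace approximation.  Values > 1 are only
#'   available for models with a single grouping term
#'   (\code{random = "individual"}).
#' @param random \code{"nested"} (default: year within individual) or
#'   \code{"individual"} (a single random intercept).
#' @return An object of class \code{"rsf_fit"} with coefficients, standard
#'   errors, Wald confidence intervals at 95/90/85\%, random-intercept
#'   variances, log-likelihood, AIC, and the stored scaling.
#' @export
rsf_fit <- function(table, covariates, interactions = character(0),
                    null_model = FALSE, nAGQ = 1L,
                    random = c("nested", "individual")) {
  random <- match.arg(random)
  if (length(unique(table$animal_id)) < 2L)
    stop("need at least 2 individuals to estimate random-intercept variance")
  if (is.null(attr(table, "scaling"))) table <- standardize_gelman(table)
  sex_term <- "sex_male" %in% names(table) && length(unique(table$sex_male)) > 1L
  if (null_model) { covariates <- character(0); interactions <- character(0); sex_term <- FALSE }
  if (length(interactions) && !sex_term)
    stop("sex interactions requested but sex_male does not vary")
  table$animal_id <- factor(table$animal_id)
  table$year <- factor(table$year)
  re <- if (random == "nested") "(1 | animal_id / year)" else "(1 | animal_id)"
  rhs <- c(covariates,
           if (sex_term) "sex_male",
           if (length(interactions)) paste0(interactions, ":sex_male"),
           re)
  if (!length(rhs)) rhs <- "1"
  form <- stats::as.formula(paste("response ~", paste(rhs, collapse = " + ")))
  ctrl <- lme4::glmerControl(optimizer = "bobyqa",
                             check.conv.singular = "ignore")
  model <- lme4::glmer(form, data = table, family = stats::binomial(),
                       nAGQ = nAGQ, control = ctrl)
  beta <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  ci <- lapply(c(0.95, 0.90, 0.85), function(lv) {
    z <- stats::qnorm(1 - (1 - lv) / 2)
    cbind(lower = beta - z * se, upper = beta + z * se)
  })
  names(ci) <- c("95", "90", "85")
  vc <- lme4::VarCorr(model)
  vnames <- names(vc)
  var_ind <- if ("animal_id" %in% vnames) as.numeric(vc[["animal_id"]]) else NA_real_
  var_yr <- if ("year:animal_id" %in% vnames) as.numeric(vc[["year:animal_id"]]) else NA_real_
  ll <- as.numeric(stats::logLik(model))
  structure(list(model = model, formula = form,
                 covariates = covariates, interactions = interactions,
                 sex_term = sex_term,
                 beta = beta, se = se, ci = ci,
                 var_individual = var_ind, var_year_in_individual = var_yr,
                 loglik = ll, npar = attr(stats::logLik(model), "df"),
                 aic = stats::AIC(model),
                 scaling = attr(table, "scaling"),
                 n_used = sum(table$response == 1),
                 n_avail = sum(table$response == 0),
                 nobs = nrow(table)),
            class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("Use-availability resource-selection GLMM\n")
  cat(sprintf("  %d used / %d available rows; logLik %.1f; AIC %.1f\n",
              x$n_used, x$n_avail, x$loglik, x$aic))
  cat(sprintf("  random-intercept variances: individual %.3f, year-in-individual %.3f\n",
              x$var_individual, x$var_year_in_individual))
  print(round(cbind(beta = x$beta, se = x$se,
                    `95l` = x$ci[["95"]][, 1], `95u` = x$ci[["95"]][, 2]), 3))
  invisible(x)
}

#' @export
coef.rsf_fit <- function(object, ...) object$beta

#' @export
logLik.rsf_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$nobs,
            class = "logLik")
}

#' @export
confint.rsf_fit <- function(object, parm, level = 0.95, ...) {
  key <- format(100 * level)
  ci <- if (key %in% names(object$ci)) object$ci[[key]] else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    cbind(lower = object$beta - z * object$se,
          upper = object$beta + z * object$se)
  }
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.rsf_fit <- function(object, ...) {
  tab <- data.frame(beta = object$beta,
                    lcl95 = object$ci[["95"]][, 1], ucl95 = object$ci[["95"]][, 2],
                    lcl90 = object$ci[["90"]][, 1], ucl90 = object$ci[["90"]][, 2])
  sig95 <- tab$lcl95 > 0 | tab$ucl95 < 0
  sig90 <- tab$lcl90 > 0 | tab$ucl90 < 0
  tab$signif <- ifelse(sig95, "95%", ifelse(sig90, "90%", ""))
  structure(list(coefficients = tab,
                 var_individual = object$var_individual,
                 var_year_in_individual = object$var_year_in_individual,
                 aic = object$aic, loglik = object$loglik,
                 n_used = object$n_used, n_avail = object$n_avail),
            class = "summary.rsf_fit")
}

#' @export
print.summary.rsf_fit <- function(x, ...) {
  cat("Resource selection at feeding sites (beta, 95% and 90% CIs)\n\n")
  print(cbind(round(x$coefficients[1:5], 2),
              signif = x$coefficients$signif), right = TRUE)
  cat(sprintf("\nRandom intercepts: individual %.3f, year-in-individual %.3f\n",
              x$var_individual, x$var_year_in_individual))
  cat(sprintf("AIC %.1f (logLik %.1f), %d used / %d available\n",
              x$aic, x$loglik, x$n_used, x$n_avail))
  invisible(x)
}

# fixed-effect linear predictor for new data rows on the standardized scale
.rsf_lp <- function(fit, newdata, standardize = TRUE, intercept = FALSE) {
  if (standardize && !is.null(fit$scaling)) {
    for (i in seq_len(nrow(fit$scaling))) {
      v <- fit$scaling$covariate[i]
      if (v %in% names(newdata))
        newdata[[v]] <- (newdata[[v]] - fit$scaling$mean[i]) /
          (2 * fit$scaling$sd[i])
    }
  }
  has_ic <- "(Intercept)" %in% names(fit$beta)
  lp <- rep(if (intercept && has_ic) fit$beta[["(Intercept)"]] else 0,
            nrow(newdata))
  for (nm in names(fit$beta)) {
    if (nm == "(Intercept)") next
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      val <- newdata[[parts[1]]] * newdata[[parts[2]]]
    } else val <- newdata[[nm]]
    if (is.null(val)) stop("newdata lacks covariate ", nm)
    lp <- lp + fit$beta[[nm]] * val
  }
  lp
}

#' Predict relative probability of use
#'
#' @param object an \code{"rsf_fit"}.
#' @param newdata \code{data.frame} of covariates on the raw (meter/percent)
#'   scale; standardization is applied from the stored scaling.
#' @param type \code{"relative"} (default): exp of the fixed-effect linear
#'   predictor without the intercept, a relative probability of use;
#'   \code{"link"}: the full fixed-effect linear predictor.
#' @param standardize set \code{FALSE} when \code{newdata} is already on
#'   the standardized scale.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.rsf_fit <- function(object, newdata, type = c("relative", "link"),
                            standardize = TRUE, ...) {
  type <- match.arg(type)
  if (type == "relative")
    exp(.rsf_lp(object, newdata, standardize, intercept = FALSE))
  else .rsf_lp(object, newdata, standardize, intercept = TRUE)
}

#' Compare models by AIC
#'
#' Ranks fits by AIC and reports differences from the best model.  A more
#' complex model is flagged as strongly supported over a simpler one when
#' the simpler model's delta exceeds the support threshold.
#'
#' @param fits named list of \code{"rsf_fit"} objects on identical data.
#' @param support_threshold delta-AIC above which support is called strong
#'   (default 5).
#' @return \code{data.frame} of class \code{"rsf_aic"}: model, npar, AIC,
#'   delta, sorted ascending; attribute \code{"strong_support"} is TRUE
#'   when the runner-up delta exceeds the threshold.
#' @export
compare_aic <- function(fits, support_threshold = 5) {
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  nobs <- vapply(fits, function(f) f$nobs, numeric(1))
  if (length(unique(nobs)) != 1L)
    stop("fits were made on differing row counts; AIC is not comparable")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  out <- data.frame(model = names(fits),
                    npar = vapply(fits, function(f) f$npar, numeric(1)),
                    aic = aic)
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  attr(out, "support_threshold") <- support_threshold
  attr(out, "strong_support") <- nrow(out) > 1 && out$delta_aic[2] > support_threshold
  class(out) <- c("rsf_aic", "data.frame")
  out
}

#' @export
print.rsf_aic <- function(x, ...) {
  cat("Model comparison (AIC)\n")
  print.data.frame(transform(x, aic = round(aic, 1),
                             delta_aic = round(delta_aic, 1)))
  if (isTRUE(attr(x, "strong_support")))
    cat(sprintf("Best model strongly supported (runner-up delta > %g)\n",
                attr(x, "support_threshold")))
  invisible(x)
}

#' Reduce sex interactions by 85% confidence interval
#'
#' Keeps every main effect but retains only the interactions whose 85\%
#' confidence interval excludes zero (interactions that indicate or
#' approach significance).
#'
#' @param full_fit an \code{"rsf_fit"} containing interaction terms.
#' @param retain_level confidence level for retention (default 0.85).
#' @return List with \code{covariates} and the retained
#'   \code{interactions}, ready to pass to \code{\link{rsf_fit}}.
#' @export
reduce_interactions <- function(full_fit, retain_level = 0.85) {
  key <- format(100 * retain_level)
  ci <- if (key %in% names(full_fit$ci)) full_fit$ci[[key]] else
    confint(full_fit, level = retain_level)
  keep <- character(0)
  for (cv in full_fit$interactions) {
    nm <- intersect(c(paste0(cv, ":sex_male"), paste0("sex_male:", cv)),
                    rownames(ci))[1]
    if (!is.na(nm) && (ci[nm, 1] > 0 || ci[nm, 2] < 0)) keep <- c(keep, cv)
  }
  list(covariates = full_fit$covariates, interactions = keep)
}

#' Classify selection and avoidance from a fitted RSF
#'
#' Distance-based covariates: a negative coefficient means used sites were
#' closer to the feature than available ones, i.e. selection; positive
#' means avoidance.  Classification-based covariates (elevation, slope) use
#' the opposite convention (positive = selection).  The 95\% interval
#' excluding zero gives a firm call, 90\%-only exclusion gives
#' \code{"marginal"}, otherwise \code{"none"}.
#'
#' @param fit an \code{"rsf_fit"}.
#' @return \code{data.frame}: term, beta, CI bounds, covariate kind, label
#'   in \code{selected / avoided / marginal / none}.
#' @export
infer_selection <- function(fit) {
  terms <- fit$covariates
  kind <- ifelse(terms %in% c("elevation", "slope"), "classification",
                 ifelse(startsWith(terms, "d_"), "distance", NA))
  if (anyNA(kind)) stop("unknown covariate kind: ",
                        paste(terms[is.na(kind)], collapse = ", "))
  out <- data.frame(term = terms, kind = kind,
                    beta = fit$beta[terms],
                    lcl95 = fit$ci[["95"]][terms, 1],
                    ucl95 = fit$ci[["95"]][terms, 2],
                    lcl90 = fit$ci[["90"]][terms, 1],
                    ucl90 = fit$ci[["90"]][terms, 2],
                    row.names = NULL)
  sig95 <- out$lcl95 > 0 | out$ucl95 < 0
  sig90 <- out$lcl90 > 0 | out$ucl90 < 0
  towards <- ifelse(out$kind == "distance", out$beta < 0, out$beta > 0)
  out$label <- ifelse(sig95, ifelse(towards, "selected", "avoided"),
                      ifelse(sig90, "marginal", "none"))
  out
}

#' Map the relative probability of use
#'
#' Evaluates exp of the fixed-effect linear predictor (without intercept)
#' per pixel at the given sex, then min-max rescales to [0, 1] over the
#' mapped extent.
#'
#' @param fit an \code{"rsf_fit"}.
#' @param ls a \code{"landscape"}.
#' @param dstack distance rasters from \code{\link{distance_stack}}.
#' @param sex_male 0 (female) or 1 (male).
#' @return Matrix (same shape as the landscape grid) of relative
#'   probability of use in [0, 1].
#' @export
predict_map <- function(fit, ls, dstack = NULL, sex_male = 0) {
  need <- unique(c(fit$covariates, fit$interactions))
  dneed <- intersect(need, names(.covariate_names()))
  if (is.null(dstack)) dstack <- distance_stack(ls, dneed)
  miss <- setdiff(dneed, names(dstack))
  if (length(miss)) stop("missing distance raster: ", paste(miss, collapse = ", "))
  nd <- data.frame(row.names = seq_len(ls$n_rows * ls$n_cols))
  for (nm in dneed) nd[[nm]] <- as.vector(dstack[[nm]])
  if ("elevation" %in% need) nd$elevation <- as.vector(ls$elevation)
  if ("slope" %in% need) nd$slope <- as.vector(ls$slope)
  nd$sex_male <- sex_male
  w <- exp(.rsf_lp(fit, nd, standardize = TRUE, intercept = FALSE))
  rng <- range(w)
  w <- if (diff(rng) == 0) rep(0, length(w)) else (w - rng[1]) / diff(rng)
  matrix(w, ls$n_rows, ls$n_cols)
}

#' k-fold cross-validation of an RSF
#'
#' Used locations are partitioned into k folds, stratified by animal; every
#' training set keeps the full availability sample (availability defines
#' the score range).  Each fold's model scores its held-out used locations;
#' scores are binned into \code{n_bins} probability bins spanning the range
#' of predictions over the availability domain, and the held-out
#' frequencies accumulated over folds are rank-correlated (Spearman) with
#' bin rank.  Bins of equal availability mass (quantile bins, the default)
#' make the expected frequencies flat under no selection and increasing
#' under selection; equal-width bins over the min-max scaled scores are
#' available as an option but are dominated by the skew of the exponential
#' score scale.  A model with predictive ability concentrates held-out
#' feeding sites in the high-probability bins.
#'
#' @param table an \code{"rsf_data"} table.
#' @param covariates,interactions model specification as in
#'   \code{\link{rsf_fit}}.
#' @param k folds (default 5: 80\% train / 20\% test).
#' @param n_bins probability bins (default 10).
#' @param seed integer seed for the fold assignment.
#' @param bin_type \code{"quantile"} (default) or \code{"width"}.
#' @param random passed to \code{\link{rsf_fit}}.
#' @return Object of class \code{"rsf_cv"}: \code{k}, \code{n_bins},
#'   \code{bin_frequencies}, \code{spearman_r}.
#' @export
kfold_cv <- function(table, covariates, interactions = character(0), k = 5,
                     n_bins = 10, seed = 1L,
                     bin_type = c("quantile", "width"), random = "nested") {
  bin_type <- match.arg(bin_type)
  if (k < 2) stop("k must be at least 2")
  used_idx <- which(table$response == 1)
  if (length(used_idx) < k) stop("fewer used locations than folds")
  fold <- .with_seed(seed, {
    f <- integer(length(used_idx))
    for (aid in unique(table$animal_id[used_idx])) {
      sel <- which(table$animal_id[used_idx] == aid)
      f[sel] <- (sample(seq_along(sel)) + sample(k, 1)) %% k + 1L
    }
    f
  })
  freq <- rep(0, n_bins)
  avail <- which(table$response == 0)
  pre_std <- !is.null(attr(table, "scaling"))
  for (fd in seq_len(k)) {
    test_used <- used_idx[fold == fd]
    if (!length(test_used)) stop("fold ", fd, " holds no used locations")
    train <- c(used_idx[fold != fd], avail)
    sub <- table[train, , drop = FALSE]
    if (pre_std) attr(sub, "scaling") <- attr(table, "scaling")
    fit <- rsf_fit(sub, covariates, interactions, random = random)
    s_avail <- predict(fit, table[avail, , drop = FALSE], type = "relative",
                       standardize = !pre_std)
    s_test <- predict(fit, table[test_used, , drop = FALSE], type = "relative",
                      standardize = !pre_std)
    if (bin_type == "quantile") {
      edges <- stats::quantile(s_avail, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE)
      inner <- edges[-c(1, n_bins + 1L)]
      bins <- findInterval(s_test, inner) + 1L
    } else {
      rng <- range(s_avail)
      sc <- pmin(1, pmax(0, (s_test - rng[1]) / diff(rng)))
      bins <- pmin(n_bins, floor(sc * n_bins) + 1L)
    }
    freq <- freq + tabulate(bins, nbins = n_bins)
  }
  rs <- suppressWarnings(stats::cor(seq_len(n_bins), freq, method = "spearman"))
  structure(list(k = k, n_bins = n_bins, bin_frequencies = freq,
                 spearman_r = rs, n_used = length(used_idx)),
            class = "rsf_cv")
}

#' @export
print.rsf_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d used locations)\n", x$k, x$n_used))
  cat("  bin frequencies:", paste(x$bin_frequencies, collapse = " "), "\n")
  cat(sprintf("  Spearman rank correlation r_s = %.2f\n", x$spearman_r))
  invisible(x)
}
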