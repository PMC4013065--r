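# Longitudinal mixed-effects models per descriptor and pairwise contrasts.
#
# Model (one descriptor at a time, usually after apply_transforms()):
#   y_ij = ecotype_i + b1 * das + [b2 * das^2] + (ecotype:das)_i
#          + u_plant + e_ij,   u_plant ~ N(0, sigma_b^2),
#   e_ij AR(1)-correlated across imaging occasions within a plant.
# The quadratic time term is included for Area-group descriptors, whose
# time courses rise monotonically over the experiment.

#' Model specification for one descriptor
#'
#' @param descriptor response column name.
#' @param area_group logical: include the quadratic time term. Defaults to
#'   the descriptor's group in [descriptor_groups()] (`"A"` group: yes);
#'   descriptors not in the canonical list (e.g. `rragr`) default to
#'   `FALSE`.
#' @return a list with the fixed-effects formula and metadata.
#' @export
lme_spec <- function(descriptor, area_group = NULL) {
  if (is.null(area_group)) {
    grp <- descriptor_groups()
    area_group <- !is.na(grp[descriptor]) && grp[descriptor] == "A"
  }
  fixed <- if (area_group)
    stats::reformulate(c("ecotype", "das", "I(das^2)", "ecotype:das"),
                       response = descriptor)
  else
    stats::reformulate(c("ecotype", "das", "ecotype:das"),
                       response = descriptor)
  list(descriptor = descriptor, area_group = area_group, fixed = fixed)
}

#' Fit the longitudinal mixed model for one descriptor
#'
#' Fixed effects: ecotype, time (days after stratification, plus its
#' square for Area-group descriptors) and the ecotype-by-time interaction.
#' Random effect: an intercept per plant. Within-plant errors follow an
#' AR(1) process over imaging occasions (the rank of `das` within the
#' design), capturing the serial correlation of repeated measurements.
#' Estimation is REML via [nlme::lme()]. Time is centred at the mean
#' imaging date before fitting (an equivalent reparameterisation), so
#' the ecotype coefficients are differences at the average date rather
#' than extrapolations to day 0. Effect-level P-values for ecotype, time
#' and interaction are Wald F tests of the corresponding coefficient
#' blocks, with denominator degrees of freedom taken from the fit's
#' within/between-group decomposition.
#'
#' With a single time point the model degenerates gracefully to a one-way
#' layout on ecotype (no time terms, no correlation structure).
#'
#' @param table a descriptor table with `plant_id`, `ecotype`, `das` and
#'   the response column; transformed beforehand if desired.
#' @param descriptor response column name (or an [lme_spec()]).
#' @param area_group override the quadratic-time default; see [lme_spec()].
#' @param method `"REML"` (default) or `"ML"`.
#' @return an object of class `lme_result`: a list with the `nlme` fit,
#'   the spec, fixed-effect estimates, effect tests (`$effects`), the
#'   estimated AR(1) parameter (`$phi`), variance components and
#'   residuals.
#' @export
fit_lme <- function(table, descriptor, area_group = NULL, method = "REML") {
  spec <- if (is.list(descriptor)) descriptor
          else lme_spec(descriptor, area_group = area_group)
  need <- c("plant_id", "ecotype", "das", spec$descriptor)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  d <- table[!is.na(table[[spec$descriptor]]), need, drop = FALSE]
  d$ecotype <- factor(d$ecotype)
  d$plant_id <- factor(d$plant_id)
  d$das <- as.numeric(d$das)
  if (nlevels(d$ecotype) < 2L) stop("need at least 2 ecotypes")
  if (any(table(d$ecotype[!duplicated(d$plant_id)],
                exclude = NULL) < 2L))
    stop("singular design: need at least 2 plants per ecotype")
  das_levels <- sort(unique(d$das))
  one_time <- length(das_levels) < 2L
  d$.occ <- match(d$das, das_levels)
  # centre time at the mean imaging date: the ecotype coefficient block
  # then tests differences at the average date instead of an
  # extrapolation to day 0 (the fitted model is equivalent)
  das_centre <- mean(das_levels)
  d$das <- d$das - das_centre

  fixed <- spec$fixed
  if (one_time)
    fixed <- stats::reformulate("ecotype", response = spec$descriptor)
  corr <- if (one_time) NULL else
    nlme::corAR1(form = ~ .occ | plant_id)
  fit <- nlme::lme(fixed = fixed, random = ~ 1 | plant_id,
                   correlation = corr, data = d, method = method,
                   control = nlme::lmeControl(returnObject = TRUE,
                                              msMaxIter = 100))

  beta <- nlme::fixef(fit)
  V <- stats::vcov(fit)
  dfs <- fit$fixDF$X
  nm <- names(beta)
  blocks <- list(
    ecotype = grepl("^ecotype", nm) & !grepl(":", nm),
    time = nm %in% c("das", "I(das^2)"),
    interaction = grepl(":", nm)
  )
  effects <- do.call(rbind, lapply(names(blocks), function(ef) {
    sel <- blocks[[ef]]
    if (!any(sel)) return(NULL)
    b <- beta[sel]
    W <- tryCatch(drop(t(b) %*% solve(V[sel, sel, drop = FALSE], b)),
                  error = function(e) NA_real_)
    q <- sum(sel)
    den <- min(dfs[sel])
    data.frame(effect = ef, numDF = q, denDF = den, F = W / q,
               p = stats::pf(W / q, q, den, lower.tail = FALSE))
  }))
  rownames(effects) <- NULL

  phi <- NA_real_
  if (!is.null(fit$modelStruct$corStruct))
    phi <- unname(stats::coef(fit$modelStruct$corStruct,
                              unconstrained = FALSE))
  vc <- nlme::VarCorr(fit)
  structure(list(fit = fit, spec = spec, data = d,
                 coefficients = beta, vcov = V,
                 effects = effects, phi = phi,
                 sigma_b = suppressWarnings(as.numeric(vc["(Intercept)",
                                                         "StdDev"])),
                 sigma = fit$sigma,
                 residuals = stats::residuals(fit, type = "response"),
                 das_levels = das_levels, das_centre = das_centre),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("<lme_result> %s ~ ecotype * das%s | AR(1) phi = %.3f\n",
              x$spec$descriptor,
              if (x$spec$area_group) " + das^2" else "", x$phi))
  print(x$effects)
  invisible(x)
}

# Model-matrix row(s) for a prediction grid, using the fit's contrasts.
emm_rows <- function(result, grid) {
  fixed <- stats::formula(result$fit)
  rhs <- stats::delete.response(stats::terms(fixed))
  grid$ecotype <- factor(grid$ecotype,
                         levels = levels(result$data$ecotype))
  stats::model.matrix(rhs, data = grid)
}

#' Pairwise comparisons over a fitted mixed model
#'
#' All pairwise contrasts of estimated marginal means for one factor:
#' ecotypes compared at the average of the observed imaging dates, or
#' imaging dates compared averaging over ecotypes. P-values come from
#' two-sided t tests of the contrast (denominator df from the fit) and
#' are adjusted with the Bonferroni correction over the C(L, 2)
#' contrasts. Each contrast is assigned a significance tier: `"ns"`,
#' `"<0.05"` or `"<0.01"`, based on the adjusted P.
#'
#' @param result an [fit_lme()] result.
#' @param factor `"ecotype"` or `"das"`.
#' @param alpha significance threshold for the `significant` flag.
#' @return a `data.frame` of contrasts with estimates, standard errors,
#'   raw and Bonferroni-adjusted P-values and tiers.
#' @export
tukey_pairwise <- function(result, factor = c("ecotype", "das"),
                           alpha = 0.05) {
  stopifnot(inherits(result, "lme_result"))
  factor <- match.arg(factor)
  ecolev <- levels(result$data$ecotype)
  daslev <- result$das_levels - result$das_centre  # model-scale time
  labels <- if (factor == "ecotype") ecolev else result$das_levels
  if (factor == "ecotype") {
    lev <- ecolev
    rows <- lapply(lev, function(e) {
      g <- expand.grid(ecotype = e, das = daslev)
      colMeans(emm_rows(result, g))
    })
    dfsel <- grepl("^ecotype", names(result$coefficients)) &
      !grepl(":", names(result$coefficients))
  } else {
    if (length(daslev) < 2L) stop("need at least 2 time points")
    lev <- daslev
    rows <- lapply(lev, function(t) {
      g <- expand.grid(ecotype = ecolev, das = t)
      colMeans(emm_rows(result, g))
    })
    dfsel <- names(result$coefficients) == "das"
  }
  if (!any(dfsel)) dfsel <- rep(TRUE, length(result$coefficients))
  den_df <- min(result$fit$fixDF$X[dfsel])
  npair <- choose(length(lev), 2L)
  out <- vector("list", npair)
  idx <- 0L
  for (i in seq_along(lev)[-length(lev)]) for (j in (i + 1L):length(lev)) {
    L <- rows[[i]] - rows[[j]]
    est <- drop(L %*% result$coefficients)
    se <- sqrt(drop(t(L) %*% result$vcov %*% L))
    tval <- est / se
    p <- 2 * stats::pt(abs(tval), df = den_df, lower.tail = FALSE)
    idx <- idx + 1L
    out[[idx]] <- data.frame(contrast = paste(labels[i], "-", labels[j]),
                             estimate = est, se = se, t = tval,
                             df = den_df, p_raw = p)
  }
  res <- do.call(rbind, out)
  res$p_adjusted <- pmin(1, res$p_raw * npair)
  res$tier <- cut(res$p_adjusted, breaks = c(-Inf, 0.01, 0.05, Inf),
                  labels = c("<0.01", "<0.05", "ns"))
  res$significant <- res$p_adjusted < alpha
  rownames(res) <- NULL
  res
}
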