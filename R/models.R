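# Candidate mixed models for the three behavioral traits. Movement and
# activity are fit as Gaussian additive mixed models (penalized cubic
# regression splines, random-effect smooths for the nested bear / bear-year
# intercepts, AR1 residual correlation at fixed rho estimated from a pilot
# fit); daily distance to road is fit with linear mixed models
# (nlme::lme, nested random intercepts, corAR1). Candidates are ranked by
# small-sample AICc with a parsimony tie-break.

#' Declarative model specification
#'
#' @param name Short label.
#' @param trait One of "movement", "activity", "distance".
#' @param linear_terms Character vector of linear covariates.
#' @param smooth_terms List of lists with fields `var`, optional `by`,
#'   optional `k` (basis dimension).
#' @param random Include the nested bear / bear-year random intercepts.
#' @param ar1 Include AR1 residual correlation within bear-years.
#' @param engine "bam" (additive, mgcv) or "lme" (linear, nlme); "auto"
#'   picks lm/gls for degenerate specs without random terms.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name, trait, linear_terms = character(),
                       smooth_terms = list(), random = TRUE, ar1 = TRUE,
                       engine = c("auto", "bam", "lme")) {
  trait <- match.arg(trait, c("movement", "activity", "distance"))
  engine <- match.arg(engine)
  has_fate <- "fate" %in% linear_terms ||
    any(vapply(smooth_terms, function(s) identical(s$by, "fate"), TRUE))
  if (has_fate && "remaining_lifespan" %in% linear_terms)
    stop("fate and remaining_lifespan are alternative longevity variables ",
         "and cannot co-occur in one model")
  for (s in smooth_terms) {
    if (!is.null(s$by) && !s$by %in% linear_terms)
      stop("by-factor smooths require the factor as a main effect: ", s$by)
  }
  response <- switch(trait, movement = "log_rate", activity = "index",
                     distance = "log_dist")
  structure(list(name = name, trait = trait, response = response,
                 linear_terms = linear_terms, smooth_terms = smooth_terms,
                 random = random, ar1 = ar1, engine = engine,
                 log_response = trait %in% c("movement", "distance"),
                 uses_lifespan = "remaining_lifespan" %in% linear_terms,
                 uses_fate = has_fate),
            class = "model_spec")
}

#' Smooth-term shorthand for model specs
#'
#' @param var Covariate name.
#' @param by Optional by-factor (one smooth per level).
#' @param k Basis dimension of the cubic regression spline.
#' @return List consumed by [model_spec()]'s `smooth_terms`.
#' @export
sm <- function(var, by = NULL, k = 8) list(var = var, by = by, k = k)

#' Hierarchical candidate model set for a trait
#'
#' Reconstructs the hierarchical ladder used in the analysis: an
#' intercept-only baseline, control covariates (age, Julian date, and hour of
#' day for movement), then either the hunting-season fate (with by-fate
#' smooths for movement) or the remaining lifespan as the longevity variable.
#' Every candidate carries the fixed nested random-intercept + AR1 structure.
#' Distance candidates are purely linear; movement and activity use smooths.
#'
#' @param trait One of "movement", "activity", "distance".
#' @return Named list of `model_spec`s.
#' @export
build_candidate_set <- function(trait) {
  trait <- match.arg(trait, c("movement", "activity", "distance"))
  if (trait == "movement") {
    list(
      null = model_spec("null", trait, engine = "bam"),
      age = model_spec("age", trait, smooth_terms = list(sm("age", k = 5)),
                       engine = "bam"),
      controls = model_spec("controls", trait,
                            smooth_terms = list(sm("age", k = 5),
                                                sm("julian_date"), sm("hour")),
                            engine = "bam"),
      fate_hour = model_spec("fate_hour", trait, linear_terms = "fate",
                             smooth_terms = list(sm("age", k = 5),
                                                 sm("julian_date"),
                                                 sm("hour", by = "fate", k = 6)),
                             engine = "bam"),
      fate_hour_jdate = model_spec("fate_hour_jdate", trait,
                                   linear_terms = "fate",
                                   smooth_terms = list(
                                     sm("age", k = 5),
                                     sm("julian_date", by = "fate", k = 6),
                                     sm("hour", by = "fate", k = 6)),
                                   engine = "bam"),
      lifespan = model_spec("lifespan", trait,
                            linear_terms = "remaining_lifespan",
                            smooth_terms = list(sm("age", k = 5),
                                                sm("julian_date"), sm("hour")),
                            engine = "bam")
    )
  } else if (trait == "activity") {
    list(
      null = model_spec("null", trait, engine = "bam"),
      age = model_spec("age", trait, smooth_terms = list(sm("age", k = 5)),
                       engine = "bam"),
      controls = model_spec("controls", trait,
                            smooth_terms = list(sm("age", k = 5),
                                                sm("julian_date")),
                            engine = "bam"),
      fate = model_spec("fate", trait, linear_terms = "fate",
                        smooth_terms = list(sm("age", k = 5),
                                            sm("julian_date")),
                        engine = "bam"),
      lifespan = model_spec("lifespan", trait,
                            linear_terms = "remaining_lifespan",
                            smooth_terms = list(sm("age", k = 5),
                                                sm("julian_date")),
                            engine = "bam")
    )
  } else {
    list(
      null = model_spec("null", trait, engine = "lme"),
      age = model_spec("age", trait, linear_terms = "age", engine = "lme"),
      controls = model_spec("controls", trait,
                            linear_terms = c("age", "julian_date"),
                            engine = "lme"),
      roads = model_spec("roads", trait,
                         linear_terms = c("age", "julian_date", "road_density"),
                         engine = "lme"),
      fate = model_spec("fate", trait,
                        linear_terms = c("age", "julian_date", "road_density",
                                         "fate"),
                        engine = "lme"),
      lifespan = model_spec("lifespan", trait,
                            linear_terms = c("age", "julian_date",
                                             "road_density",
                                             "remaining_lifespan"),
                            engine = "lme")
    )
  }
}

# --- fitting -----------------------------------------------------------

prepare_model_data <- function(spec, data) {
  need <- unique(c(spec$response, spec$linear_terms,
                   vapply(spec$smooth_terms, function(s) s$var, ""),
                   if (spec$random) c("bear_id", "bear_year")))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  d <- data
  if (spec$random) {
    d$bear_id <- factor(d$bear_id)
    d$bear_year <- factor(d$bear_year)
  }
  if ("fate" %in% names(d)) d$fate <- factor(d$fate, levels = c("survived", "died"))
  keep <- stats::complete.cases(d[, need, drop = FALSE])
  d <- d[keep, , drop = FALSE]
  if (spec$random) {
    ord_time <- if (!is.null(d$timestamp)) as.numeric(d$timestamp)
                else if (!is.null(d$date)) as.numeric(d$date)
                else seq_len(nrow(d))
    d <- d[order(d$bear_year, ord_time), , drop = FALSE]
    d$.ar_start <- !duplicated(d$bear_year)
  }
  droplevels(d)
}

bam_formula <- function(spec, data) {
  rhs <- spec$linear_terms
  for (s in spec$smooth_terms) {
    k <- min(s$k %||% 8, max(4, length(unique(data[[s$var]]))))
    rhs <- c(rhs, if (is.null(s$by))
      sprintf("s(%s, bs = 'cr', k = %d)", s$var, k)
      else sprintf("s(%s, by = %s, bs = 'cr', k = %d)", s$var, s$by, k))
  }
  if (spec$random)
    rhs <- c(rhs, "s(bear_id, bs = 're')", "s(bear_year, bs = 're')")
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

lag1_rho <- function(res, start) {
  a <- res[-length(res)]
  b <- res[-1]
  ok <- !start[-1]
  if (sum(ok) < 10) return(0)
  r <- stats::cor(a[ok], b[ok])
  max(min(r, 0.95), -0.95)
}

re_labels <- function(fit) {
  labs <- vapply(fit$smooth, function(s) s$label, "")
  cls <- vapply(fit$smooth, function(s) inherits(s, "random.effect"), TRUE)
  labs[cls]
}

fit_bam <- function(spec, data, rho = NULL) {
  fml <- bam_formula(spec, data)
  if (spec$ar1 && is.null(rho)) {
    pilot <- do.call(mgcv::bam, list(formula = fml, data = data,
                                     method = "fREML", discrete = TRUE))
    rho <- lag1_rho(stats::residuals(pilot, type = "response"), data$.ar_start)
  }
  if (!spec$ar1) rho <- 0
  args <- list(formula = fml, data = data, method = "fREML", discrete = TRUE,
               rho = rho)
  if (spec$ar1) args$AR.start <- data$.ar_start
  fit <- do.call(mgcv::bam, args)
  list(fit = fit, rho = rho)
}

lme_formula <- function(spec) {
  rhs <- if (length(spec$linear_terms)) paste(spec$linear_terms, collapse = " + ") else "1"
  stats::as.formula(paste(spec$response, "~", rhs))
}

fit_lme <- function(spec, data, method = "ML") {
  corr <- if (spec$ar1) nlme::corAR1(form = ~ 1 | bear_id / bear_year) else NULL
  nlme::lme(lme_formula(spec), data = data,
            random = ~ 1 | bear_id / bear_year,
            correlation = corr, method = method,
            control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                       msMaxIter = 200, returnObject = TRUE))
}

#' Fit one candidate model
#'
#' Dispatches on the spec's engine: additive models through [mgcv::bam()]
#' with penalized cubic splines, random-effect smooths for bear and
#' bear-year, and AR1 working residuals at fixed `rho` (estimated from the
#' lag-1 autocorrelation of a pilot fit when not supplied); linear models
#' through [nlme::lme()] with nested random intercepts and `corAR1`.
#' Degenerate specs (no random terms) collapse to [stats::lm()] /
#' [nlme::gls()].
#'
#' @param spec A `model_spec`.
#' @param data Trait data frame (rows with missing model columns dropped;
#'   rows ordered by bear-year and time for the AR1 structure).
#' @param rho Optional fixed AR1 coefficient for the bam engine.
#' @param method Likelihood flavor for the lme engine ("ML" for ranking,
#'   "REML" for reporting).
#' @return Object of class `fit_result`: coefficients with 95% CI, smooth
#'   edf/p-values, variance components, AR1 phi, logLik, effective parameter
#'   count `k`, `n`, AICc and marginal R-squared.
#' @export
fit_model <- function(spec, data, rho = NULL, method = "ML") {
  d <- prepare_model_data(spec, data)
  if (nrow(d) < 10) stop("too few rows to fit: ", nrow(d))
  engine <- spec$engine
  if (engine == "auto")
    engine <- if (length(spec$smooth_terms)) "bam"
              else if (spec$random) "lme" else "fixed"

  converged <- TRUE
  if (engine == "bam") {
    fb <- tryCatch(fit_bam(spec, d, rho), error = function(e) e)
    if (inherits(fb, "error")) {
      return(failed_fit(spec, conditionMessage(fb)))
    }
    fit <- fb$fit
    res <- extract_bam(spec, fit, d, fb$rho)
  } else if (engine == "lme") {
    fit <- tryCatch(fit_lme(spec, d, method), error = function(e) e)
    if (inherits(fit, "error")) return(failed_fit(spec, conditionMessage(fit)))
    res <- extract_lme(spec, fit, d)
  } else {
    if (spec$ar1) {
      fit <- nlme::gls(lme_formula(spec), data = d,
                       correlation = nlme::corAR1(), method = method)
      res <- extract_gls(spec, fit, d)
    } else {
      fit <- stats::lm(lme_formula(spec), data = d)
      res <- extract_lm(spec, fit, d)
    }
  }
  res$converged <- converged
  res$data <- d
  class(res) <- "fit_result"
  res
}

failed_fit <- function(spec, msg) {
  structure(list(spec = spec, converged = FALSE, message = msg,
                 aicc = Inf, logLik = NA_real_, k = NA_real_, n = NA_integer_),
            class = "fit_result")
}

varcomp_vec <- function(s2_bear, s2_by, s2_res) {
  c(bear = unname(s2_bear), bear_year = unname(s2_by), residual = unname(s2_res))
}

extract_bam <- function(spec, fit, d, rho) {
  sy <- summary(fit, re.test = FALSE)
  pt <- sy$p.table
  coefs <- data.frame(term = rownames(pt), estimate = pt[, 1], se = pt[, 2],
                      lower = pt[, 1] - 1.96 * pt[, 2],
                      upper = pt[, 1] + 1.96 * pt[, 2],
                      p = pt[, 4], row.names = NULL)
  st <- sy$s.table
  rel <- re_labels(fit)
  smooths <- if (!is.null(st) && nrow(st)) {
    sdf <- data.frame(term = rownames(st), edf = st[, 1],
                      p = st[, ncol(st)], row.names = NULL)
    sdf[!sdf$term %in% rel, , drop = FALSE]
  } else data.frame(term = character(), edf = numeric(), p = numeric())

  vc <- tryCatch({
    tmp <- NULL
    utils::capture.output(tmp <- mgcv::gam.vcomp(fit, rescale = TRUE))
    tmp
  }, error = function(e) NULL)
  get_sd <- function(lbl) {
    if (is.null(vc)) return(0)
    if (is.matrix(vc)) {
      i <- match(lbl, rownames(vc))
      if (is.na(i)) 0 else vc[i, 1]
    } else {
      i <- match(lbl, names(vc))
      if (is.na(i)) 0 else vc[i]
    }
  }
  s2b <- get_sd("s(bear_id)")^2
  s2y <- get_sd("s(bear_year)")^2
  s2r <- fit$sig2

  ll <- stats::logLik(fit)
  k <- as.numeric(attr(ll, "df"))
  n <- stats::nobs(fit)
  fixed <- as.numeric(stats::predict(fit, newdata = d, exclude = rel,
                                     discrete = FALSE, newdata.guaranteed = TRUE))
  vf <- stats::var(fixed)
  list(spec = spec, fit = fit, coefficients = coefs, smooths = smooths,
       varcomp = varcomp_vec(s2b, s2y, s2r), ar1_phi = rho,
       reml_score = as.numeric(fit$gcv.ubre),
       logLik = as.numeric(ll), k = k, n = n,
       aicc = aicc_value(as.numeric(ll), k, n),
       marginal_r2 = vf / (vf + s2b + s2y + s2r),
       log_response = spec$log_response)
}

extract_lme <- function(spec, fit, d) {
  # summary.lme warns (pt NaN) when a term's denominator df collapses in
  # small nested designs; the Wald columns we use are unaffected
  tt <- suppressWarnings(summary(fit)$tTable)
  coefs <- data.frame(term = rownames(tt), estimate = tt[, 1], se = tt[, 2],
                      lower = tt[, 1] - 1.96 * tt[, 2],
                      upper = tt[, 1] + 1.96 * tt[, 2],
                      p = tt[, ncol(tt)], row.names = NULL)
  vc <- nlme::VarCorr(fit)
  # nested VarCorr: first (Intercept) row is bear, second bear-year
  ints <- which(rownames(vc) == "(Intercept)")
  s2b <- as.numeric(vc[ints[1], "Variance"])
  s2y <- as.numeric(vc[ints[2], "Variance"])
  s2r <- fit$sigma^2
  phi <- if (!is.null(fit$modelStruct$corStruct))
    as.numeric(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  else 0
  ll <- stats::logLik(fit)
  k <- as.numeric(attr(ll, "df"))
  n <- fit$dims$N
  fixed <- as.numeric(stats::predict(fit, level = 0))
  vf <- stats::var(fixed)
  list(spec = spec, fit = fit, coefficients = coefs,
       smooths = data.frame(term = character(), edf = numeric(), p = numeric()),
       varcomp = varcomp_vec(s2b, s2y, s2r), ar1_phi = phi,
       logLik = as.numeric(ll), k = k, n = n,
       aicc = aicc_value(as.numeric(ll), k, n),
       marginal_r2 = vf / (vf + s2b + s2y + s2r),
       log_response = spec$log_response)
}

extract_lm <- function(spec, fit, d) {
  sm_ <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm_), estimate = sm_[, 1], se = sm_[, 2],
                      lower = sm_[, 1] - 1.96 * sm_[, 2],
                      upper = sm_[, 1] + 1.96 * sm_[, 2],
                      p = sm_[, 4], row.names = NULL)
  ll <- stats::logLik(fit)
  s2r <- summary(fit)$sigma^2
  vf <- stats::var(as.numeric(stats::fitted(fit)))
  list(spec = spec, fit = fit, coefficients = coefs,
       smooths = data.frame(term = character(), edf = numeric(), p = numeric()),
       varcomp = varcomp_vec(0, 0, s2r), ar1_phi = 0,
       logLik = as.numeric(ll), k = as.numeric(attr(ll, "df")),
       n = stats::nobs(fit),
       aicc = aicc_value(as.numeric(ll), as.numeric(attr(ll, "df")),
                         stats::nobs(fit)),
       marginal_r2 = vf / (vf + s2r), log_response = spec$log_response)
}

extract_gls <- function(spec, fit, d) {
  tt <- summary(fit)$tTable
  coefs <- data.frame(term = rownames(tt), estimate = tt[, 1], se = tt[, 2],
                      lower = tt[, 1] - 1.96 * tt[, 2],
                      upper = tt[, 1] + 1.96 * tt[, 2],
                      p = tt[, ncol(tt)], row.names = NULL)
  phi <- as.numeric(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  ll <- stats::logLik(fit)
  s2r <- fit$sigma^2
  vf <- stats::var(as.numeric(stats::predict(fit)))
  list(spec = spec, fit = fit, coefficients = coefs,
       smooths = data.frame(term = character(), edf = numeric(), p = numeric()),
       varcomp = varcomp_vec(0, 0, s2r), ar1_phi = phi,
       logLik = as.numeric(ll), k = as.numeric(attr(ll, "df")),
       n = length(stats::residuals(fit)),
       aicc = aicc_value(as.numeric(ll), as.numeric(attr(ll, "df")),
                         length(stats::residuals(fit))),
       marginal_r2 = vf / (vf + s2r), log_response = spec$log_response)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model '%s' (%s): n = %s, k = %.1f, AICc = %.2f\n",
              x$spec$name, x$spec$trait, x$n, x$k, x$aicc))
  if (!isTRUE(x$converged)) {
    cat("  NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  variance components: bear %.4f, bear-year %.4f, residual %.4f; phi = %.3f\n",
              x$varcomp["bear"], x$varcomp["bear_year"], x$varcomp["residual"],
              x$ar1_phi))
  cat(sprintf("  marginal R2 = %.3f\n", x$marginal_r2))
  invisible(x)
}

# --- AICc, ranking, marginal R2, predictions ---------------------------

aicc_value <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1).
#'
#' @param object A `fit_result`, or a numeric log-likelihood.
#' @param k,n Effective parameter count and sample size (numeric input only).
#' @return AICc value.
#' @export
aicc <- function(object, k = NULL, n = NULL) {
  if (inherits(object, "fit_result"))
    return(aicc_value(object$logLik, object$k, object$n))
  aicc_value(object, k, n)
}

#' Rank candidate fits by AICc
#'
#' Ascending AICc with Delta-AICc relative to the best; among models within
#' 2 AICc units of the best, the one with the fewest effective parameters is
#' selected (most parsimonious). Non-converged fits are excluded.
#'
#' @param fits Named list of `fit_result`s.
#' @return Data frame `model`, `k`, `logLik`, `AICc`, `delta`, `selected`,
#'   ordered by AICc, with attribute `best` (the selected model name).
#' @export
rank_models <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(ok)) stop("no candidate model converged")
  fits <- fits[ok]
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) f$k, 0),
    logLik = vapply(fits, function(f) f$logLik, 0),
    AICc = vapply(fits, function(f) f$aicc, 0), row.names = NULL
  )
  tab <- tab[order(tab$AICc), ]
  tab$delta <- tab$AICc - tab$AICc[1]
  near <- tab$delta < 2
  best <- tab$model[near][which.min(tab$k[near])]
  tab$selected <- tab$model == best
  rownames(tab) <- NULL
  attr(tab, "best") <- best
  tab
}

#' Marginal R-squared of a mixed-model fit
#'
#' Proportion of total variance attributable to the fixed effects:
#' var(fixed-effect predictions) divided by that variance plus the bear,
#' bear-year and residual variance components.
#'
#' @param fit A converged `fit_result`.
#' @return Proportion in [0, 1].
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "fit_result"), isTRUE(fit$converged))
  tot <- fit$marginal_r2
  if (is.na(tot)) stop("marginal R2 undefined (zero total variance)")
  tot
}

#' Fixed-effect prediction curve with 95% confidence band
#'
#' Predictions along a grid of one covariate, holding all other covariates at
#' their data means (numerics) or reference/first level (factors) unless
#' overridden via `holding`. Random effects are excluded. For
#' log-transformed responses the curve is back-transformed to the original
#' scale (m/h or m).
#'
#' @param fit A converged `fit_result`.
#' @param covariate Covariate name to vary.
#' @param grid Numeric grid; defaults to 50 points over the observed range.
#' @param holding Named list of covariate values to hold fixed.
#' @param back_transform Exponentiate log-scale predictions (default: the
#'   spec's `log_response` flag).
#' @return Data frame `grid`, `fit`, `lower`, `upper`.
#' @export
predict_curve <- function(fit, covariate, grid = NULL, holding = list(),
                          back_transform = fit$log_response) {
  stopifnot(inherits(fit, "fit_result"), isTRUE(fit$converged))
  d <- fit$data
  if (!covariate %in% names(d)) stop("unknown covariate: ", covariate)
  obs <- d[[covariate]]
  if (is.null(grid)) grid <- seq(min(obs), max(obs), length.out = 50)
  if (any(grid < min(obs) | grid > max(obs)))
    warning("grid extends outside the observed covariate range; extrapolating")

  spec <- fit$spec
  vars <- unique(c(spec$linear_terms,
                   vapply(spec$smooth_terms, function(s) s$var, "")))
  nd <- data.frame(row.names = seq_along(grid))
  for (v in vars) {
    if (v == covariate) next
    nd[[v]] <- if (!is.null(holding[[v]])) holding[[v]]
    else if (is.factor(d[[v]])) factor(levels(d[[v]])[1], levels = levels(d[[v]]))
    else mean(d[[v]], na.rm = TRUE)
  }
  nd[[covariate]] <- grid
  if (!is.null(holding[[covariate]])) nd[[covariate]] <- grid

  if (inherits(fit$fit, "gam")) {
    nd$bear_id <- factor(levels(d$bear_id)[1], levels = levels(d$bear_id))
    nd$bear_year <- factor(levels(d$bear_year)[1], levels = levels(d$bear_year))
    pr <- stats::predict(fit$fit, newdata = nd, se.fit = TRUE,
                         exclude = re_labels(fit$fit), discrete = FALSE,
                         newdata.guaranteed = TRUE)
    est <- as.numeric(pr$fit); se <- as.numeric(pr$se.fit)
  } else if (inherits(fit$fit, "lme")) {
    fml <- stats::formula(fit$fit)
    X <- stats::model.matrix(fml[-2], nd)
    beta <- nlme::fixef(fit$fit)
    est <- as.numeric(X %*% beta)
    se <- sqrt(rowSums((X %*% fit$fit$varFix) * X))
  } else {
    pr <- stats::predict(fit$fit, newdata = nd, se.fit = TRUE)
    est <- as.numeric(pr$fit); se <- as.numeric(pr$se.fit)
  }
  lo <- est - 1.96 * se
  hi <- est + 1.96 * se
  if (back_transform) {
    est <- exp(est); lo <- exp(lo); hi <- exp(hi)
  }
  data.frame(grid = grid, fit = est, lower = lo, upper = hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
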