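# Adjusted behavioral repeatability from the variance components of a fitted
# mixed model: R = S2_bear / (S2_bear + S2_bearyear + S2_residual),
# conditional on the model's fixed effects. R = 0 means no among-individual
# variation; R = 1 means all variation is among individuals.

#' Adjusted repeatability of a fitted model
#'
#' Computes R from the fit's variance components and attaches a significance
#' statement. The default test is a boundary-corrected likelihood-ratio test
#' of the bear-level intercept: the model is refit without the bear term and
#' twice the log-likelihood difference is referred to an equal mixture of a
#' point mass at zero and a chi-squared with 1 df (the null places the
#' variance on its boundary). A permutation alternative shuffles which bear
#' each bear-year belongs to and refits.
#'
#' @param fit A converged `fit_result` with both random intercepts.
#' @param test "lrt" (default), "permutation", or "none".
#' @param n_perm Number of permutations for the permutation test.
#' @param seed Seed for the permutation test.
#' @return Object of class `repeatability_result` with fields `R`, `p_value`,
#'   `method` and the echoed variance `components`.
#' @export
repeatability <- function(fit, test = c("lrt", "permutation", "none"),
                          n_perm = 199, seed = 1) {
  test <- match.arg(test)
  stopifnot(inherits(fit, "fit_result"), isTRUE(fit$converged))
  v <- fit$varcomp
  if (any(v < 0)) stop("negative variance component; upstream fit is invalid")
  if (!fit$spec$random) stop("fit carries no bear-level random intercept")
  r <- if (sum(v) == 0) 0 else unname(v["bear"] / sum(v))

  p <- NA_real_
  if (test == "lrt") {
    red <- refit_without_bear(fit)
    # bam(fREML) reports the minimized negative restricted log-likelihood;
    # lme reports logLik directly. Either way the reduced model cannot beat
    # the full one beyond numerical noise.
    stat <- if (!is.null(fit$reml_score) && !is.null(red$reml_score))
      2 * (red$reml_score - fit$reml_score)
    else 2 * (fit$logLik - red$logLik)
    stat <- max(0, stat)
    p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else if (test == "permutation") {
    set.seed(seed)
    d <- fit$data
    map <- unique(d[, c("bear_year", "bear_id")])
    rperm <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      shuf <- map
      shuf$bear_id <- sample(shuf$bear_id)
      dp <- d
      dp$bear_id <- shuf$bear_id[match(dp$bear_year, shuf$bear_year)]
      fp <- fit_model(fit$spec, dp, rho = fit$ar1_phi)
      rperm[i] <- if (isTRUE(fp$converged))
        unname(fp$varcomp["bear"] / sum(fp$varcomp)) else NA_real_
    }
    rperm <- rperm[!is.na(rperm)]
    p <- (1 + sum(rperm >= r)) / (length(rperm) + 1)
  }

  structure(list(R = r, p_value = p,
                 method = switch(test,
                                 lrt = "boundary-corrected likelihood ratio",
                                 permutation = "bear-identity permutation",
                                 none = "none"),
                 components = v), class = "repeatability_result")
}

refit_without_bear <- function(fit) {
  spec <- fit$spec
  d <- fit$data
  if (inherits(fit$fit, "gam")) {
    rhs <- attr(stats::terms(stats::formula(fit$fit)), "term.labels")
    rhs <- rhs[!grepl("bear_id", rhs, fixed = TRUE)]
    if (length(rhs) == 0) rhs <- "1"
    fml <- stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
    args <- list(formula = fml, data = d, method = "fREML", discrete = TRUE,
                 rho = if (spec$ar1) fit$ar1_phi else 0)
    if (spec$ar1) args$AR.start <- d$.ar_start
    f <- do.call(mgcv::bam, args)
    list(logLik = as.numeric(stats::logLik(f)),
         reml_score = as.numeric(f$gcv.ubre))
  } else if (inherits(fit$fit, "lme")) {
    corr <- if (spec$ar1) nlme::corAR1(form = ~ 1 | bear_year) else NULL
    f <- nlme::lme(lme_formula(spec), data = d, random = ~ 1 | bear_year,
                   correlation = corr, method = fit$fit$method,
                   control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                              msMaxIter = 200,
                                              returnObject = TRUE))
    list(logLik = as.numeric(stats::logLik(f)))
  } else {
    stop("fit has no random structure to reduce")
  }
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Adjusted repeatability R = %.3f (p = %.4g, %s)\n",
              x$R, x$p_value, x$method))
  cat(sprintf("  components: bear %.4f, bear-year %.4f, residual %.4f\n",
              x$components["bear"], x$components["bear_year"],
              x$components["residual"]))
  invisible(x)
}

#' Simulation-based recovery check for repeatability
#'
#' Repeatedly generates a synthetic dataset, extracts log movement rates,
#' fits the control additive mixed model (age, Julian date, hour smooths with
#' nested random intercepts and AR1), computes R, and summarizes bias against
#' the configuration's implied repeatability. Both sexes are pooled (the
#' generator is sex-symmetric), so the number of individuals equals
#' `2 * n_bears_per_sex`.
#'
#' @param config A `synthetic_config`; its variance-component fields define
#'   the truth.
#' @param n_replicates Number of simulation replicates.
#' @return List with `truth` (implied R, SDs, phi), a per-replicate
#'   `estimates` data frame (R, the three variance components as SDs, phi),
#'   `mean_R` and `bias`.
#' @export
repeatability_recovery_check <- function(config, n_replicates = 20) {
  truth <- list(R = implied_repeatability(config), sd_bear = config$sd_bear,
                sd_bearyear = config$sd_bearyear, sd_resid = config$sd_resid,
                ar1_phi = config$ar1_phi)
  est <- data.frame(R = numeric(n_replicates), sd_bear = NA_real_,
                    sd_bearyear = NA_real_, sd_resid = NA_real_,
                    phi = NA_real_)
  spec <- build_candidate_set("movement")$controls
  no_act <- data.frame(bear_id = character(),
                       timestamp = as.POSIXct(character()), value = numeric())
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * i
    ds <- simulate_dataset(cfg, activity = FALSE)
    tt <- build_trait_table(ds$relocations, no_act, ds$roads, ds$bear_years)
    fit <- fit_model(spec, tt$movement)
    est$R[i] <- repeatability(fit, test = "none")$R
    est$sd_bear[i] <- sqrt(fit$varcomp["bear"])
    est$sd_bearyear[i] <- sqrt(fit$varcomp["bear_year"])
    est$sd_resid[i] <- sqrt(fit$varcomp["residual"])
    est$phi[i] <- fit$ar1_phi
  }
  list(truth = truth, estimates = est, mean_R = mean(est$R),
       bias = mean(est$R) - truth$R)
}
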