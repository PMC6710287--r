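# End-to-end orchestration: per sex and trait, restrict the data, fit and
# rank the candidate sets, compute repeatability on the best model, and
# produce prediction curves, collected into a structured report.

#' Restrict a trait data frame for the remaining-lifespan analysis
#'
#' Remaining-lifespan candidate models are fit only on bears that died from
#' hunting (the only bears whose remaining lifespan is defined); fate-variable
#' models use all harvestable bear-years. Bears alive at study end or dead
#' from other causes are excluded here but keep contributing to fate models.
#'
#' @param df One trait data frame from a `trait_table` (carries a
#'   `death_cause` column).
#' @return The subset with `death_cause == "hunting"` and defined
#'   `remaining_lifespan`.
#' @export
restrict_for_lifespan_analysis <- function(df) {
  stopifnot(!is.null(df$death_cause))
  out <- df[!is.na(df$death_cause) & df$death_cause == "hunting" &
              !is.na(df$remaining_lifespan), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 32-bit FNV-1a over a string, as a hex config fingerprint for provenance
fnv1a <- function(s) {
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(s)) {
    # xor touches only the low byte (b < 256); keep h a double throughout
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply in 16-bit halves (doubles lose bits past 2^53)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

count_rows <- function(df) {
  list(observations = nrow(df), bears = length(unique(df$bear_id)),
       bear_years = length(unique(df$bear_year)))
}

analyze_trait <- function(df, trait, repeatability_test = "lrt") {
  specs <- build_candidate_set(trait)
  fate_specs <- specs[!vapply(specs, function(s) s$uses_lifespan, TRUE)]
  life_specs <- specs[!vapply(specs, function(s) s$uses_fate, TRUE)]
  df_l <- restrict_for_lifespan_analysis(df)

  fit_family <- function(fam, data) {
    if (nrow(data) < 30) return(NULL)
    rho <- NULL
    fits <- list()
    # fit the richest spec first so its pilot rho is shared by the family
    ord <- order(-vapply(fam, function(s)
      length(s$linear_terms) + length(s$smooth_terms), 0))
    for (i in ord) {
      f <- fit_model(fam[[i]], data, rho = rho)
      if (is.null(rho) && isTRUE(f$converged) && fam[[i]]$engine == "bam")
        rho <- f$ar1_phi
      fits[[names(fam)[i]]] <- f
    }
    fits[names(fam)]
  }

  fate_fits <- fit_family(fate_specs, df)
  life_fits <- fit_family(life_specs, df_l)
  if (is.null(fate_fits)) stop("too few observations for trait ", trait)

  rank_fate <- rank_models(fate_fits)
  best_fate <- fate_fits[[attr(rank_fate, "best")]]
  rank_life <- if (!is.null(life_fits)) rank_models(life_fits) else NULL
  best_life <- if (!is.null(rank_life)) life_fits[[attr(rank_life, "best")]] else NULL
  life_fit <- if (!is.null(life_fits)) life_fits[["lifespan"]] else NULL
  if (is.null(life_fits))
    warning("no hunting-killed bears; lifespan models skipped for ", trait)

  rep_best <- repeatability(best_fate, test = repeatability_test)

  curves <- list()
  if (trait == "movement") {
    for (lv in levels(df$fate)) {
      curves[[paste0("hour_", lv)]] <-
        tryCatch(predict_curve(best_fate, "hour", holding = list(fate = lv)),
                 error = function(e) NULL)
    }
  }
  if (!is.null(life_fit) && isTRUE(life_fit$converged)) {
    curves$remaining_lifespan <-
      tryCatch(predict_curve(life_fit, "remaining_lifespan"),
               error = function(e) NULL)
  }

  lifespan_coef <- if (!is.null(life_fit) && isTRUE(life_fit$converged)) {
    cf <- life_fit$coefficients
    cf[cf$term == "remaining_lifespan", , drop = FALSE]
  } else NULL

  list(counts = count_rows(df), counts_lifespan = count_rows(df_l),
       ranking_fate = rank_fate, ranking_lifespan = rank_life,
       best_fate = best_fate, best_lifespan = best_life,
       lifespan_fit = life_fit, lifespan_coef = lifespan_coef,
       repeatability = rep_best, curves = curves)
}

#' Run the full analysis per sex and trait
#'
#' For each sex and each of the three behavioral traits: build the candidate
#' set, fit the fate family on all harvestable bear-years and the
#' remaining-lifespan family on hunting-killed bears, rank each family by
#' AICc, compute the adjusted repeatability of the best fate-family model,
#' and produce prediction curves (hour-of-day by fate for movement; remaining
#' lifespan for all traits with a converged lifespan model).
#'
#' @param x A dataset list as returned by [simulate_dataset()] (raw
#'   telemetry), or a prebuilt `trait_table`.
#' @param sexes Sexes to analyze separately.
#' @param traits Traits to analyze.
#' @param repeatability_test Passed to [repeatability()].
#' @return Object of class `analysis_report`.
#' @export
run_analysis <- function(x, sexes = c("male", "female"),
                         traits = c("movement", "activity", "distance"),
                         repeatability_test = "lrt") {
  if (inherits(x, "trait_table")) {
    tt <- x
    provenance <- list(source = "trait_table")
  } else {
    stopifnot(is.list(x), !is.null(x$relocations), !is.null(x$bear_years))
    act <- x$activity
    if (is.null(act))
      act <- data.frame(bear_id = character(),
                        timestamp = as.POSIXct(character()), value = numeric())
    tt <- build_trait_table(x$relocations, act, x$roads, x$bear_years)
    provenance <- list(source = "raw telemetry",
                       seed = if (!is.null(x$config)) x$config$seed else NA,
                       config_hash = if (!is.null(x$config))
                         fnv1a(paste(deparse(x$config), collapse = "")) else NA)
  }
  provenance$package_version <- as.character(utils::packageVersion("harvestsel"))
  provenance$r_version <- R.version.string

  results <- list()
  for (sx in sexes) {
    results[[sx]] <- list()
    for (tr in traits) {
      df <- tt[[tr]]
      df <- df[df$sex == sx, , drop = FALSE]
      results[[sx]][[tr]] <- analyze_trait(df, tr,
                                           repeatability_test = repeatability_test)
    }
  }
  structure(list(results = results, screening = tt$screening,
                 provenance = provenance), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report\n")
  for (sx in names(x$results)) {
    for (tr in names(x$results[[sx]])) {
      r <- x$results[[sx]][[tr]]
      cat(sprintf("%-6s %-9s n=%6d (%d bears, %d bear-years)  best: %-16s R=%.3f (p=%.3g)\n",
                  sx, tr, r$counts$observations, r$counts$bears,
                  r$counts$bear_years, attr(r$ranking_fate, "best"),
                  r$repeatability$R, r$repeatability$p_value))
      if (!is.null(r$lifespan_coef) && nrow(r$lifespan_coef))
        cat(sprintf("       remaining-lifespan beta = %.4f [%.4f, %.4f]\n",
                    r$lifespan_coef$estimate, r$lifespan_coef$lower,
                    r$lifespan_coef$upper))
    }
  }
  invisible(x)
}

#' Run the pipeline on an external dataset
#'
#' Entry point for real telemetry exports coerced to the documented CSV/
#' GeoJSON schema. The pipeline can be entered with raw telemetry (fixes +
#' activity + roads + bear-year metadata) or directly with pre-derived trait
#' tables (a directory holding movement.csv, activity.csv, distance.csv).
#'
#' @param fixes,activity,meta Paths to CSV files (see the readers in this
#'   package for required columns).
#' @param roads Path to a GeoJSON file of road LineStrings.
#' @param trait_dir Alternatively, a directory of pre-derived trait CSVs.
#' @param ... Passed to [run_analysis()].
#' @return An `analysis_report`.
#' @export
analyze_dataset <- function(fixes = NULL, activity = NULL, roads = NULL,
                            meta = NULL, trait_dir = NULL, ...) {
  if (!is.null(trait_dir)) {
    tt <- read_trait_table(trait_dir)
    return(run_analysis(tt, ...))
  }
  if (is.null(fixes) || is.null(roads) || is.null(meta))
    stop("supply either trait_dir or fixes + roads + meta paths")
  ds <- list(
    relocations = read_relocations(fixes),
    activity = if (!is.null(activity)) read_activity(activity) else NULL,
    roads = read_roads_geojson(roads),
    bear_years = read_bear_years(meta)
  )
  run_analysis(ds, ...)
}
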