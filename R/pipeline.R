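# Pipeline driver: many exposure traits against one outcome from a single
# configuration.

.DEFAULT_PARAMS <- list(n_boot = 1000, n_sim = 1000, phi = 1,
                        outlier_threshold = 0.05, penalty_scale = 20,
                        robust_tuning = 1.345)

.MIN_SNPS_REASON <- function(min) sprintf("requires more than %d variants", min - 1L)

.normalizeConfig <- function(config) {
  baseDir <- NULL
  if (is.character(config) && length(config) == 1L) {
    baseDir <- dirname(normalizePath(config, mustWork = TRUE))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  # paths in a YAML config are relative to the config file's directory
  resolve <- function(p) {
    if (is.null(baseDir) || is.null(p) || grepl("^(/|~|[A-Za-z]:)", p)) p
    else file.path(baseDir, p)
  }
  config$outcome <- resolve(config$outcome)
  config$traits <- lapply(config$traits, function(tr) {
    tr$exposure <- resolve(tr$exposure)
    tr$exclusions <- resolve(tr$exclusions)
    tr
  })
  if (is.null(config$outcome)) stop("config$outcome (outcome table path) is required")
  if (is.null(config$traits) || !length(config$traits))
    stop("config$traits must list at least one trait")
  if (is.null(config$methods)) config$methods <- names(.ESTIMATOR_REGISTRY)
  unknown <- setdiff(config$methods, names(.ESTIMATOR_REGISTRY))
  if (length(unknown))
    stop("unknown method(s) in config: ", paste(unknown, collapse = ", "))
  stochastic <- intersect(config$methods,
                          c("simple_median", "weighted_median",
                            "weighted_mbe", "mr_presso"))
  if (length(stochastic) && is.null(config$seed))
    stop("config$seed is required when stochastic methods are requested: ",
         paste(stochastic, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  params <- .DEFAULT_PARAMS
  params[names(config$parameters)] <- config$parameters
  config$parameters <- params
  if (is.null(config$palindromic_policy)) config$palindromic_policy <- "infer_by_eaf"
  if (is.null(config$eaf_threshold)) config$eaf_threshold <- 0.42
  nms <- vapply(config$traits, function(tr) tr$name %||% NA_character_,
                character(1))
  if (any(is.na(nms)) || anyDuplicated(nms))
    stop("every trait needs a unique 'name'")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.runMethod <- function(method, data, params, seed) {
  switch(method,
    ivw = mrIVW(data),
    ivw_fixed = mrIVW(data, model = "fixed"),
    ivw_penalized_robust = mrIVWRobust(data, params$penalty_scale,
                                       params$robust_tuning),
    mr_egger = mrEgger(data),
    simple_median = mrSimpleMedian(data, params$n_boot, seed),
    weighted_median = mrWeightedMedian(data, params$n_boot, seed),
    weighted_mbe = mrWeightedMBE(data, params$phi, params$n_boot, seed),
    mr_presso = mrPresso(data, params$n_sim, params$outlier_threshold, seed),
    stop("unhandled method ", method))
}

#' Run the full analysis for every configured trait
#'
#' For each trait: read the exposure table, apply its exclusion list,
#' harmonize against the shared outcome table, optionally flip the exposure
#' direction, then run every requested estimator whose minimum-instrument
#' precondition the trait meets (methods needing more variants than are
#' available are skipped with a recorded reason, never silently), plus
#' Cochran's Q, optional leave-one-out, and the per-variant effect table.
#' A trait whose harmonization fails is recorded as failed and the run
#' continues with the remaining traits.
#'
#' `config` is a list or the path of a YAML file with fields:
#' `outcome` (outcome table path), `traits` (list of
#' `name`/`exposure`/optional `exclusions`/`exposure_scale`/`sign_flip`),
#' `methods` (subset of ivw, ivw_fixed, ivw_penalized_robust, mr_egger,
#' simple_median, weighted_median, weighted_mbe, mr_presso; default all),
#' `seed` (required when stochastic methods are requested), `parameters`
#' (n_boot, n_sim, phi, outlier_threshold, penalty_scale, robust_tuning),
#' `palindromic_policy`, `eaf_threshold`, `leave_one_out` (trait names),
#' and optional `column_map` / `outcome_column_map`.  Per-method RNG seeds
#' are derived deterministically from `seed`, so identical configurations
#' give identical results.
#'
#' `sign_flip: true` negates the exposure coefficients before analysis so
#' estimates are reported per unit *lower* exposure (e.g. to express
#' declining pancreatic beta-cell function as a risk factor).
#'
#' @param config list or YAML path; see Details.
#' @return A results bundle: list with `traits` (per-trait list: name,
#'   status, data, estimates, results table, heterogeneity, loo, variants,
#'   reports, skipped) and `manifest` (config, seed, package version, and
#'   reconciled requested/run/skipped/failed counts).
#' @export
runAnalysis <- function(config) {
  config <- .normalizeConfig(config)
  outcomeTab <- readSummaryTable(config$outcome,
                                 columnMap = config$outcome_column_map)
  looTraits <- config$leave_one_out %||% character(0)
  params <- config$parameters
  traitResults <- list()
  counts <- c(requested = 0L, run = 0L, skipped = 0L, failed = 0L)
  anyFailed <- FALSE

  for (ti in seq_along(config$traits)) {
    tr <- config$traits[[ti]]
    res <- list(name = tr$name, status = "ok", skipped = list(),
                estimates = list())
    counts["requested"] <- counts["requested"] + length(config$methods)
    harmonized <- tryCatch({
      expoTab <- readSummaryTable(tr$exposure, columnMap = tr$column_map)
      exclReport <- NULL
      if (!is.null(tr$exclusions)) {
        excl <- readExclusionList(tr$exclusions)
        filtered <- applyExclusions(expoTab, excl)
        expoTab <- filtered$kept
        exclReport <- filtered$report
      }
      h <- harmonize(expoTab, outcomeTab,
                     palindromicPolicy = config$palindromic_policy,
                     eafThreshold = config$eaf_threshold,
                     traitName = tr$name,
                     exposureScale = tr$exposure_scale %||% "1-SD")
      list(h = h, exclReport = exclReport)
    }, error = function(e) e)
    if (inherits(harmonized, "error")) {
      res$status <- "failed"
      res$error <- conditionMessage(harmonized)
      counts["failed"] <- counts["failed"] + length(config$methods)
      anyFailed <- TRUE
      traitResults[[tr$name]] <- res
      next
    }
    data <- harmonized$h$data
    if (isTRUE(tr$sign_flip))
      data <- MRData(data@snpIds, -data@betaExposure, data@seExposure,
                     data@betaOutcome, data@seOutcome,
                     data@traitName, data@exposureScale)
    res$harmonization_report <- harmonized$h$report
    res$exclusion_report <- harmonized$exclReport
    res$data <- data
    J <- length(data@snpIds)

    for (mi in seq_along(config$methods)) {
      m <- config$methods[[mi]]
      minJ <- .ESTIMATOR_REGISTRY[[m]]$min
      if (J < minJ) {
        res$skipped[[m]] <- .MIN_SNPS_REASON(minJ)
        counts["skipped"] <- counts["skipped"] + 1L
        next
      }
      seedM <- (config$seed + 1000L * ti + mi) %% .Machine$integer.max
      fit <- tryCatch(.runMethod(m, data, params, seedM),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        res$skipped[[m]] <- paste("failed:", conditionMessage(fit))
        counts["failed"] <- counts["failed"] + 1L
        anyFailed <- TRUE
      } else {
        res$estimates[[m]] <- fit
        counts["run"] <- counts["run"] + 1L
      }
    }
    if (length(res$estimates))
      res$results <- resultsTable(unname(res$estimates))
    if (J >= 2L) res$heterogeneity <- cochranQ(data)
    if (tr$name %in% looTraits && J >= 3L)
      res$loo <- leaveOneOut(data, "ivw")
    refEst <- res$estimates$ivw %||% res$estimates[[1]] %||% NULL
    if (!is.null(refEst))
      res$variants <- variantEffectTable(data, refEst)
    traitResults[[tr$name]] <- res
  }

  list(traits = traitResults,
       manifest = list(config = config, seed = config$seed,
                       package_version = as.character(utils::packageVersion("SummaryMR")),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                       counts = as.list(counts),
                       any_failed = anyFailed))
}

.fmtOrCi <- function(or, lo, hi) sprintf("%.2f(%.2f-%.2f)", or, lo, hi)

#' Write tables and figures for a results bundle
#'
#' Produces a combined trait-by-method results table (full-precision numeric
#' columns plus a display column rounded to two decimals in the
#' `OR(low-high)` style), per-trait harmonization, leave-one-out and
#' per-variant tables, forest-plot data across traits, and, when `"pdf"` is
#' requested, simple forest and scatter figures.
#'
#' @param bundle results bundle from [runAnalysis()].
#' @param dir output directory (created if needed).
#' @param formats subset of `c("tsv", "pdf")`.
#' @return invisibly, character vector of files written.
#' @export
renderOutputs <- function(bundle, dir, formats = c("tsv", "pdf")) {
  if (!is.list(bundle) || is.null(bundle$traits) || !length(bundle$traits))
    stop("empty results bundle")
  unknown <- setdiff(formats, c("tsv", "pdf"))
  if (length(unknown))
    stop("unknown output format(s): ", paste(unknown, collapse = ", "))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  slug <- function(x) gsub("[^A-Za-z0-9]+", "_", tolower(x))

  combined <- list(); forest <- list()
  for (res in bundle$traits) {
    if (!is.null(res$error) || is.null(res$results)) next
    tab <- res$results
    tab <- cbind(trait = res$name, tab,
                 or_ci = .fmtOrCi(tab$OR, tab$OR_low, tab$OR_high),
                 significant = !is.na(tab$p) & tab$p < 0.05)
    combined[[res$name]] <- tab
    if (length(res$skipped))
      combined[[paste0(res$name, ".skipped")]] <- data.frame(
        trait = res$name,
        method = names(res$skipped),
        n_snps = NA, theta = NA, se = NA, ci_low = NA, ci_high = NA, p = NA,
        OR = NA, OR_low = NA, OR_high = NA,
        or_ci = paste("skipped:", unlist(res$skipped)), significant = NA)
    ivwRow <- tab[tab$method == "IVW", , drop = FALSE]
    if (nrow(ivwRow)) forest[[res$name]] <- ivwRow[1, ]
    if (!is.null(res$harmonization_report))
      emit(res$harmonization_report,
           sprintf("harmonization_%s.tsv", slug(res$name)))
    if (!is.null(res$loo))
      emit(res$loo, sprintf("leave_one_out_%s.tsv", slug(res$name)))
    if (!is.null(res$variants))
      emit(res$variants, sprintf("variants_%s.tsv", slug(res$name)))
  }
  if (!length(combined)) stop("bundle contains no successful trait results")
  combinedDf <- do.call(rbind, c(combined, list(make.row.names = FALSE)))
  forestDf <- do.call(rbind, c(forest, list(make.row.names = FALSE)))
  if ("tsv" %in% formats) {
    emit(combinedDf, "results_table.tsv")
    emit(forestDf, "forest_data.tsv")
  }
  if ("pdf" %in% formats) {
    path <- file.path(dir, "forest.pdf")
    grDevices::pdf(path, width = 7, height = 1 + nrow(forestDf) * 0.6)
    plotForest(forestDf$trait, forestDf$OR, forestDf$OR_low, forestDf$OR_high)
    grDevices::dev.off()
    written <- c(written, path)
    for (res in bundle$traits) {
      if (is.null(res$variants)) next
      path <- file.path(dir, sprintf("scatter_%s.pdf", slug(res$name)))
      grDevices::pdf(path, width = 6, height = 5)
      plotScatter(res$variants, main = res$name)
      grDevices::dev.off()
      written <- c(written, path)
    }
  }
  invisible(written)
}
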