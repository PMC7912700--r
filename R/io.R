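# Plain-text model I/O and JSON report serialization.
#
# Loadings CSV dialect: comma-separated, UTF-8, header row with factor
# names, first column the variable names, optional final column
# "uniqueness".  Factor correlation CSV: m x m with factor names in the
# header and first column.  Groups JSON: {"groups": {"name": ["X1", ...]}}.

#' Read a loading matrix (and optional uniquenesses) from CSV
#'
#' @param path CSV file: first column variable names, header the factor
#'   names, optional column \code{uniqueness}.
#' @return list with \code{loadings} (matrix) and \code{uniqueVars}
#'   (numeric or NULL).
#' @export
readLoadings <- function(path) {
  if (!file.exists(path)) stop("loadings file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("loadings CSV needs a name column plus factor columns")
  vars <- as.character(df[[1L]])
  num <- df[-1L]
  uniq <- NULL
  uc <- which(tolower(names(num)) == "uniqueness")
  if (length(uc)) {
    uniq <- suppressWarnings(as.numeric(num[[uc]]))
    num <- num[-uc]
  }
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing loading at row '%s', column '%s' in %s",
                   vars[bad[1L]], names(num)[j], path))
    num[[j]] <- v
  }
  if (!is.null(uniq) && anyNA(uniq))
    stop("non-numeric or missing value in 'uniqueness' column of ", path)
  L <- as.matrix(num)
  rownames(L) <- vars
  list(loadings = L, uniqueVars = uniq)
}

#' Write a model's loadings (with uniquenesses) to CSV
#'
#' @param model a \linkS4class{FactorModel}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeLoadings <- function(model, path) {
  stopifnot(is(model, "FactorModel"))
  df <- data.frame(variable = rownames(model@loadings),
                   model@loadings,
                   uniqueness = model@uniqueVars,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an m x m factor correlation matrix from CSV
#'
#' @param path CSV with factor names as header and first column.
#' @return numeric matrix.
#' @export
readFactorCorr <- function(path) {
  if (!file.exists(path)) stop("factor correlation file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("factor correlation CSV contains non-numeric cells")
  M
}

#' Read a group specification from JSON
#'
#' Expected shape: \code{{"groups": {"name": ["X1", "X2"], ...}}}; a bare
#' object of name arrays is also accepted.
#'
#' @param path JSON file path.
#' @return named list of character vectors.
#' @export
readGroups <- function(path) {
  if (!file.exists(path)) stop("groups file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- if (is.list(obj) && !is.null(obj[["groups"]])) obj[["groups"]] else obj
  if (!is.list(groups) || is.null(names(groups)) || length(groups) == 0L)
    stop("groups JSON must map group names to arrays of variable names")
  lapply(groups, as.character)
}

#' Load a model described by an analysis configuration
#'
#' The configuration is a plain list with exactly one model source:
#' \code{fixture} (a built-in example name) or \code{loadings} (CSV path,
#' with optional \code{phi} and \code{uniqueness} paths).  A
#' \code{recomputeUniqueness} flag requests uniquenesses as 1 -
#' communality; if a uniqueness column or file is also present the flag
#' wins, with a warning.
#'
#' @param config named list; see Details.
#' @return a \linkS4class{FactorModel}.
#' @export
loadModel <- function(config) {
  hasFixture <- !is.null(config[["fixture"]])
  hasFiles <- !is.null(config[["loadings"]])
  if (hasFixture == hasFiles)
    stop("specify exactly one model source: 'fixture' or 'loadings'")
  if (hasFixture) {
    model <- exampleModel(config[["fixture"]])
    message(sprintf("loaded fixture '%s': p = %d, m = %d (uniquenesses 1 - communality)",
                    config[["fixture"]], nManifest(model), nFactors(model)))
    return(model)
  }
  ld <- readLoadings(config[["loadings"]])
  Phi <- if (!is.null(config[["phi"]])) readFactorCorr(config[["phi"]]) else NULL
  uniq <- ld$uniqueVars
  if (!is.null(config[["uniqueness"]])) {
    udf <- utils::read.csv(config[["uniqueness"]], check.names = FALSE)
    uniq <- as.numeric(udf[[ncol(udf)]])
  }
  recompute <- isTRUE(config[["recomputeUniqueness"]])
  model <- factorModel(ld$loadings, Phi, uniqueVars = uniq,
                       recomputeUniqueness = recompute || is.null(uniq))
  message(sprintf("loaded model: p = %d, m = %d (uniquenesses %s)",
                  nManifest(model), nFactors(model),
                  if (recompute || is.null(uniq)) "1 - communality" else "as supplied"))
  model
}

# ---- plain-list serialization of the S4 result objects -------------------

.listify <- function(x) {
  if (is(x, "ContributionReport"))
    return(list(total_kl = x@totalKL,
                per_variable = as.list(x@perVariable),
                per_group = as.list(x@perGroup),
                per_factor = as.list(x@perFactor),
                ecd = x@ecd,
                rc = as.list(x@rc),
                rc_tilde = as.list(x@rcTilde)))
  if (is(x, "CanonicalDecomposition"))
    return(list(subset = x@subset,
                rho_sq = x@rhoSq,
                contributions = x@contributions,
                factor_coefs = apply(x@factorCoefs, 2L, identity, simplify = FALSE),
                manifest_coefs = apply(x@manifestCoefs, 2L, identity, simplify = FALSE),
                total_kl = x@totalKL,
                rc = x@rc,
                rc_tilde = x@rcTilde,
                capped = x@capped))
  if (is(x, "DerivedFactorSystem"))
    return(list(coef_matrix = asplit(x@coefMatrix, 1L),
                new_loadings = asplit(x@newLoadings, 1L),
                factor_corr_new = asplit(x@factorCorrNew, 1L),
                contributions_full = as.list(x@contributionsFull),
                contributions_groups = x@contributionsGroups,
                uniqueness = as.list(x@uniqueVars)))
  x
}

#' Run a configured analysis and return a report document
#'
#' Chains the package's operations according to a configuration list and
#' returns a JSON-ready document.  Sections are produced on demand through
#' \code{config$outputs}, a non-empty subset of \code{"contributions"},
#' \code{"cca"} (full-vector canonical factor analysis), \code{"subgroups"}
#' (per-group canonical analysis; requires \code{config$groups}) and
#' \code{"derive"} (derived oblique factor system from the groups).  The
#' document always carries a schema version and a model summary.
#'
#' @param config named list: model source as in \code{\link{loadModel}},
#'   plus \code{outputs}, optional \code{groups} (named list or JSON path)
#'   and optional \code{out} (path to also write the JSON to).
#' @return the report document (a list), invisibly if written to file.
#' @export
runAnalysis <- function(config) {
  outputs <- config[["outputs"]]
  if (is.null(outputs) || length(outputs) == 0L)
    stop("config$outputs must name at least one of: contributions, cca, subgroups, derive")
  bad <- setdiff(outputs, c("contributions", "cca", "subgroups", "derive"))
  if (length(bad)) stop("unknown output(s): ", paste(bad, collapse = ", "))

  model <- loadModel(config)
  groups <- config[["groups"]]
  if (is.character(groups) && length(groups) == 1L) groups <- readGroups(groups)

  doc <- list(
    schema_version = "1.0",
    model = list(
      p = nManifest(model),
      m = nFactors(model),
      variables = variableNames(model),
      factors = factorNames(model),
      loadings = asplit(loadingMatrix(model), 1L),
      factor_corr = asplit(factorCorr(model), 1L),
      uniqueness = as.list(uniqueVars(model))))

  if ("contributions" %in% outputs)
    doc$contributions <- .listify(contributionReport(model, groups = groups))
  if ("cca" %in% outputs)
    doc$cca <- .listify(canonicalDecomposition(model))
  if ("subgroups" %in% outputs) {
    if (is.null(groups)) stop("'subgroups' output requires config$groups")
    doc$subgroups <- lapply(subgroupAnalysis(model, groups), .listify)
  }
  if ("derive" %in% outputs) {
    if (is.null(groups)) stop("'derive' output requires config$groups")
    doc$derived <- .listify(deriveFactorSystem(model, groups = groups))
  }

  if (!is.null(config[["out"]])) {
    jsonlite::write_json(doc, config[["out"]], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(doc))
  }
  doc
}
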