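cohort_columns <- c("baby_id", "mother_id", "country_id", "birthweight",
                    "gestational_age", "sex", "stature_cat", "age_cat",
                    "marital", "smoking", "income_cat", "hypertension",
                    "diabetes", "wb_class")

#' Write a cohort as delimiter-separated text
#'
#' One row per baby, header exactly the birth-record field names.
#'
#' @param cohort a cohort data frame.
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = "\t") {
  cols <- intersect(cohort_columns, names(cohort))
  utils::write.table(cohort[, c(cols, setdiff(names(cohort), cols))],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' Reads a delimiter-separated cohort. External tables with different
#' headers can be adapted with `col_map`, a named character vector mapping
#' canonical column names to the names used in the file, e.g.
#' `c(birthweight = "bw_grams", country_id = "mcb")`.
#'
#' @param path input path.
#' @param sep field delimiter.
#' @param col_map optional named character vector renaming file columns to
#'   the canonical birth-record names.
#' @return a `data.frame`, one row per baby.
#' @export
read_cohort <- function(path, sep = "\t", col_map = NULL) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(df))
      if (is.na(j)) {
        stop(sprintf("column '%s' (mapped to '%s') not found in %s",
                     col_map[[canon]], canon, path), call. = FALSE)
      }
      names(df)[j] <- canon
    }
  }
  df
}

#' Read a generator configuration from a YAML file
#'
#' Any field present overrides the corresponding [synth_config()] default;
#' omitted fields fall back to the published-study defaults. Nested maps
#' (`covariate_freqs`, `true_fixed_effects`) are merged field-wise.
#'
#' @param path YAML file mirroring the `synth_config` fields.
#' @return a `"synth_config"` object.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(synth_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("covariate_freqs", "true_fixed_effects")) {
    if (!is.null(raw[[nm]])) {
      base <- if (nm == "covariate_freqs") default_covariate_freqs()
              else default_fixed_effects()
      for (k in names(raw[[nm]])) base[[k]] <- unlist(raw[[nm]][[k]])
      raw[[nm]] <- base
    }
  }
  for (nm in c("parity_probs", "wb_class_probs", "true_variances")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(synth_config, raw)
}

#' Write a flat machine-readable fit summary
#'
#' One line per fixed-effect term (`term, estimate, se`), one per variance
#' component, plus deviance/DIC rows.
#'
#' @param fit a fitted model from [nested_lmm()], [fit_mom()] or
#'   [fit_gibbs()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path, sep = "\t") {
  fx <- fit$fixed
  rows <- data.frame(kind = "fixed", term = fx$term,
                     estimate = fx$estimate, se = fx$se,
                     stringsAsFactors = FALSE)
  s2 <- fit$variances$sigma2
  se2 <- fit$variances$se
  for (lv in names(s2)) {
    if (is.na(s2[[lv]])) next
    rows <- rbind(rows, data.frame(
      kind = "variance", term = paste0("sigma2_", lv),
      estimate = s2[[lv]],
      se = if (!is.null(se2) && lv %in% names(se2)) se2[[lv]] else NA_real_,
      stringsAsFactors = FALSE))
  }
  for (nm in c("deviance_bar", "pD", "dic")) {
    if (!is.null(fit[[nm]]) && !is.na(fit[[nm]])) {
      rows <- rbind(rows, data.frame(kind = "fit", term = nm,
                                     estimate = fit[[nm]], se = NA_real_,
                                     stringsAsFactors = FALSE))
    }
  }
  utils::write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dump retained posterior draws as delimiter-separated text
#'
#' @param fit a Gibbs fit with retained chains.
#' @param path output path.
#' @param sep field delimiter.
#' @param what which chains to write: any of `"beta"`, `"sigma2"`, `"v"`.
#' @return `path`, invisibly.
#' @export
write_chains <- function(fit, path, sep = "\t", what = c("beta", "sigma2")) {
  ch <- fit$chains
  if (is.null(ch)) stop("fit has no retained chains", call. = FALSE)
  keep <- intersect(what, names(ch))
  tab <- do.call(cbind, lapply(keep, function(nm) {
    m <- ch[[nm]]
    colnames(m) <- paste(nm, colnames(m), sep = ".")
    m
  }))
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
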