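# Term block -> cohort column and canonical level set.
term_column <- c(stature = "stature_cat", age = "age_cat", sex = "sex",
                 gestational_age = "gestational_age", income = "income_cat",
                 marital = "marital", smoking = "smoking",
                 hypertension = "hypertension", diabetes = "diabetes",
                 wb_class = "wb_class")
term_levels_key <- c(stature = "stature_cat", age = "age_cat", sex = "sex",
                     income = "income_cat", marital = "marital",
                     smoking = "smoking", hypertension = "hypertension",
                     diabetes = "diabetes", wb_class = "wb_class")

# Cumulative covariate blocks of the five-model sequence.
model_blocks <- list(
  "1" = character(0),
  "2" = "stature",
  "3" = c("stature", "age"),
  "4" = c("stature", "age", "sex", "gestational_age", "income", "marital",
          "smoking", "hypertension", "diabetes"),
  "5" = c("stature", "age", "sex", "gestational_age", "income", "marital",
          "smoking", "hypertension", "diabetes", "wb_class")
)

#' Model specification for a nested random-intercept fit
#'
#' Defines which fixed-effect blocks and which random levels a fit
#' includes. The intercept is always present; the baby-level residual is
#' always present. `model = 1` is the 'empty' model (random intercepts
#' only); models 2-5 add the cumulative covariate blocks of the published
#' sequence (2: maternal stature; 3: + maternal age; 4: + sex,
#' gestational age, household income, marital status, smoking,
#' hypertension, diabetes; 5: + country income class).
#'
#' @param model integer 1-5 selecting a cumulative covariate block, or
#'   `NULL` if `fixed_terms` is given explicitly.
#' @param fixed_terms character vector of term blocks from
#'   `c("stature","age","sex","gestational_age","income","marital",
#'   "smoking","hypertension","diabetes","wb_class")`; the intercept is
#'   implicit.
#' @param random_levels subset of `c("country", "mother")`; order is
#'   immaterial.
#' @param reference_categories named character vector overriding the
#'   default reference category of any block.
#' @return an object of class `"model_spec"`.
#' @examples
#' model_spec(1)            # empty three-level model
#' model_spec(4)$fixed_terms
#' model_spec(fixed_terms = "stature", random_levels = "country")
#' @export
model_spec <- function(model = NULL, fixed_terms = NULL,
                       random_levels = c("country", "mother"),
                       reference_categories = NULL) {
  if (!is.null(model)) {
    model <- as.character(model)
    if (!model %in% names(model_blocks)) {
      stop("model must be 1..5", call. = FALSE)
    }
    fixed_terms <- model_blocks[[model]]
  }
  fixed_terms <- as.character(fixed_terms %||% character(0))
  unknown <- setdiff(fixed_terms, names(term_column))
  if (length(unknown)) {
    stop("unknown fixed-effect blocks: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  random_levels <- match.arg(random_levels, c("country", "mother"),
                             several.ok = TRUE)
  refs <- default_reference_categories
  if (!is.null(reference_categories)) {
    refs[names(reference_categories)] <- reference_categories
  }
  structure(list(fixed_terms = fixed_terms,
                 random_levels = random_levels,
                 reference_categories = refs,
                 model = if (is.null(model)) NA_character_ else model),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec",
      if (!is.na(x$model)) sprintf("(Model %s)", x$model), "\n")
  cat("  fixed: intercept",
      if (length(x$fixed_terms)) paste("+", paste(x$fixed_terms, collapse = " + ")),
      "\n")
  cat("  random intercepts:", paste(x$random_levels, collapse = ", "),
      "+ residual\n")
  invisible(x)
}

#' Fixed-effects design matrix
#'
#' Dummy coding against the reference categories, with "missing" treated
#' as an ordinary category. Gestational age enters as a single continuous
#' column centered at its grand mean (so the intercept stays interpretable
#' as the mean birthweight at reference covariates and average gestation).
#'
#' @param cohort cohort data frame.
#' @param spec a [model_spec()].
#' @param ga_center center for the gestational-age column; defaults to the
#'   cohort grand mean. Pass the training value when building a matrix for
#'   new data.
#' @return list with elements `X` (n x p numeric matrix), `terms`
#'   (data frame mapping columns to blocks and categories) and
#'   `ga_center`.
#' @examples
#' coh <- sample_cohort(synth_config(n_countries = 5, n_mothers = 50), seed = 1)
#' dm <- design_matrix(coh, model_spec(2))
#' colnames(dm$X)
#' @export
design_matrix <- function(cohort, spec, ga_center = NULL) {
  n <- nrow(cohort)
  cols <- list(intercept = rep(1, n))
  terms <- data.frame(column = "intercept", block = "intercept",
                      category = NA_character_, stringsAsFactors = FALSE)
  for (blk in spec$fixed_terms) {
    col <- term_column[[blk]]
    if (is.null(cohort[[col]])) {
      stop(sprintf("cohort lacks column '%s' needed by block '%s'", col, blk),
           call. = FALSE)
    }
    if (blk == "gestational_age") {
      if (is.null(ga_center)) ga_center <- mean(cohort[[col]])
      cols[["gestational_age"]] <- cohort[[col]] - ga_center
      terms <- rbind(terms, data.frame(column = "gestational_age",
                                       block = blk, category = NA_character_,
                                       stringsAsFactors = FALSE))
      next
    }
    levs <- cohort_levels[[term_levels_key[[blk]]]]
    vals <- cohort[[col]]
    bad <- which(!vals %in% levs)
    if (length(bad)) {
      stop(sprintf("unknown category '%s' in column '%s' (first at row %d)",
                   vals[bad[1L]], col, bad[1L]), call. = FALSE)
    }
    ref <- spec$reference_categories[[blk]]
    present <- levs[levs %in% unique(vals)]   # absent categories get no column
    for (lv in setdiff(present, ref)) {
      nm <- paste0(blk, ":", lv)
      cols[[nm]] <- as.numeric(vals == lv)
      terms <- rbind(terms, data.frame(column = nm, block = blk,
                                       category = lv,
                                       stringsAsFactors = FALSE))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, terms = terms, ga_center = ga_center)
}
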