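#' Shrunken country-level effects
#'
#' Posterior summaries of the country random effects: each country's
#' shrunken deviation from the grand mean (posterior mean of the country
#' effect), an equal-tailed 95% interval from the retained chain, and the
#' rank (1 = lowest). Small countries are pulled harder towards zero than
#' large ones — the empirical-Bayes shrinkage behind 'league tables'.
#'
#' @param fit a `"nested_lmm"` Gibbs fit whose spec includes the country
#'   level (the country-effect chain must be retained, as it is by
#'   default).
#' @return an object of class `"shrunken_effects"`: data frame with
#'   columns `country_id`, `n_babies`, `effect`, `lower`, `upper`,
#'   `rank`.
#' @export
country_effects <- function(fit) {
  if (!inherits(fit, "nested_lmm") || !"country" %in% fit$spec$random_levels) {
    stop("fit does not include a country random level", call. = FALSE)
  }
  vch <- fit$chains$v
  if (is.null(vch)) {
    stop("fit carries no retained country-effect chain", call. = FALSE)
  }
  eff <- colMeans(vch)
  qs <- apply(vch, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(
    country_id = fit$country_levels,
    n_babies = fit$country_sizes,
    effect = unname(eff),
    lower = unname(qs[1L, ]),
    upper = unname(qs[2L, ]),
    stringsAsFactors = FALSE
  )
  ord <- order(out$effect, out$country_id)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  class(out) <- c("shrunken_effects", "data.frame")
  out
}

#' League table of countries
#'
#' Countries sorted ascending by shrunken effect (ties broken by country
#' id, so the order is deterministic), with a flag for countries whose
#' 95% interval excludes zero.
#'
#' @param effects a [country_effects()] table.
#' @return the table sorted by rank, with an added logical column
#'   `distinct` (interval excludes 0).
#' @export
league_table <- function(effects) {
  stopifnot(is.data.frame(effects))
  out <- effects[order(effects$effect, effects$country_id), , drop = FALSE]
  out$distinct <- out$lower > 0 | out$upper < 0
  rownames(out) <- NULL
  out
}

#' Five-number box-plot summaries of birthweight per country
#'
#' Tukey convention: quartiles by linear interpolation, whiskers at the
#' most extreme observations within 1.5 interquartile ranges of the
#' quartiles. These are the data behind overlap ('box and whisker')
#' displays of within-country birthweight distributions.
#'
#' @param cohort cohort data frame.
#' @param countries character vector of country ids; all must be present.
#' @return data frame with columns `country_id`, `n`, `whisker_low`,
#'   `q1`, `median`, `q3`, `whisker_high`.
#' @export
overlap_summary <- function(cohort, countries = unique(cohort$country_id)) {
  missing_c <- setdiff(countries, unique(cohort$country_id))
  if (length(missing_c)) {
    stop("unknown countries: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(countries, function(cid) {
    x <- cohort$birthweight[cohort$country_id == cid]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    lo <- min(x[x >= q[1L] - 1.5 * iqr])
    hi <- max(x[x <= q[3L] + 1.5 * iqr])
    data.frame(country_id = cid, n = length(x), whisker_low = lo,
               q1 = q[1L], median = q[2L], q3 = q[3L], whisker_high = hi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write shrunken effects / league table as delimiter-separated text
#'
#' @param effects a [country_effects()] or [league_table()] table.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_league_table <- function(effects, path, sep = "\t") {
  utils::write.table(as.data.frame(effects), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
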