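#' Variance components container
#'
#' A light container for the variance components of a nested
#' random-intercept model: the super-cluster level (maternal country of
#' birth, "mcb"), the cluster level (mother, "m") and the individual
#' residual (baby, "b"). Two-level models set the absent component to `NA`;
#' partition statistics treat an absent component as 0 and flag it.
#'
#' @param sigma2_mcb country-level variance (g^2), or `NA` if the level is
#'   absent from the model.
#' @param sigma2_m mother-level variance (g^2), or `NA` if absent.
#' @param sigma2_b individual-level residual variance (g^2).
#' @param se optional named numeric vector of standard errors.
#' @return an object of class `"variance_components"`.
#' @examples
#' variance_components(7699, 111583, 119871)
#' @export
variance_components <- function(sigma2_mcb, sigma2_m, sigma2_b, se = NULL) {
  vc <- c(mcb = as.numeric(sigma2_mcb), m = as.numeric(sigma2_m),
          b = as.numeric(sigma2_b))
  if (any(vc < 0, na.rm = TRUE)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  structure(list(sigma2 = vc, se = se), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (g^2):\n")
  print(x$sigma2)
  invisible(x)
}

# Components with absent (NA) levels treated as zero.
vc_filled <- function(vc) {
  s <- vc$sigma2
  s[is.na(s)] <- 0
  s
}

#' Variance partition coefficients
#'
#' The share of the total outcome variance attributable to each level of
#' the nested hierarchy: `100 * sigma2_level / (sigma2_mcb + sigma2_m +
#' sigma2_b)`. The country-level VPC is the headline measure of general
#' contextual influence: if it is low, differences between country means
#' carry little information about individual outcomes.
#'
#' @param vc a [variance_components] object (or a numeric vector of length
#'   3 in the order country, mother, individual).
#' @return named numeric vector `c(vpc_mcb, vpc_m, vpc_b)` in percent, at
#'   full precision (use [round_half_up] for table display).
#' @examples
#' vpc(variance_components(7699, 111583, 119871))  # 3.2 / 46.7 / 50.1
#' @export
vpc <- function(vc) {
  s <- if (inherits(vc, "variance_components")) vc_filled(vc) else {
    stopifnot(length(vc) == 3L)
    ifelse(is.na(vc), 0, as.numeric(vc))
  }
  tot <- sum(s)
  if (tot <= 0) stop("all variance components are zero: VPC undefined",
                     call. = FALSE)
  stats::setNames(100 * s / tot, c("vpc_mcb", "vpc_m", "vpc_b"))
}

#' Intra-class correlations
#'
#' The expected correlation in the outcome between two individuals sharing
#' a cluster. For the top (country) level this equals the country-level
#' VPC; for the mother level two babies share both the country and the
#' mother effect, so `icc_m = 100 * (sigma2_mcb + sigma2_m) / total`.
#'
#' @inheritParams vpc
#' @return named numeric vector `c(icc_mcb, icc_m)` in percent.
#' @examples
#' icc(variance_components(7699, 111583, 119871))  # 3.2 / 49.9
#' @export
icc <- function(vc) {
  v <- vpc(vc)
  c(icc_mcb = unname(v["vpc_mcb"]),
    icc_m = unname(v["vpc_mcb"] + v["vpc_m"]))
}

#' Proportional change in variance
#'
#' Relative change of each variance component (and of the total) between a
#' covariate-adjusted model and a reference model, conventionally the
#' 'empty' model: `100 * (sigma2_model - sigma2_ref) / sigma2_ref`.
#' Negative values mean the added covariates explained that share of the
#' level's variance.
#'
#' @param vc_model components of the adjusted model.
#' @param vc_reference components of the reference (empty) model.
#' @return named numeric vector `c(pcv_mcb, pcv_m, pcv_b, pcv_total)` in
#'   percent.
#' @examples
#' m1 <- variance_components(7699, 111583, 119871)
#' m2 <- variance_components(4922, 104640, 120491)
#' pcv(m2, m1)  # country level -36.1
#' @export
pcv <- function(vc_model, vc_reference) {
  sm <- if (inherits(vc_model, "variance_components")) vc_filled(vc_model)
        else as.numeric(vc_model)
  sr <- if (inherits(vc_reference, "variance_components")) vc_filled(vc_reference)
        else as.numeric(vc_reference)
  lv <- c("mcb", "m", "b")
  compared <- !is.na(sm) & sm >= 0
  if (any(sr[compared] <= 0)) {
    stop("reference variance component is zero at a compared level: PCV undefined",
         call. = FALSE)
  }
  out <- 100 * (sm - sr) / sr
  tot <- 100 * (sum(sm) - sum(sr)) / sum(sr)
  stats::setNames(c(out, tot), c("pcv_mcb", "pcv_m", "pcv_b", "pcv_total"))
}

#' Partition report across a model sequence
#'
#' Assembles the variance-decomposition table of a model sequence: raw
#' components and total, VPC per level, ICC at the country and mother
#' level, and PCV of every model against the reference (first) model.
#' This is the package's analogue of the printed variance table of a
#' multilevel birthweight analysis.
#'
#' @param vcs named list of [variance_components], in model order; the
#'   first element is the PCV reference.
#' @param digits decimal places for the displayed statistics (components
#'   and totals are kept at full precision).
#' @return an object of class `"partition_report"`: a list with matrices
#'   `components` (4 x models: mcb, m, b, total), `vpc` (3 x models),
#'   `icc` (2 x models), `pcv` (4 x models, reference column 0), and the
#'   `reference` model name.
#' @export
partition_report <- function(vcs, digits = 1) {
  stopifnot(is.list(vcs), length(vcs) >= 1L)
  nm <- names(vcs)
  if (is.null(nm)) nm <- paste0("Model ", seq_along(vcs))
  comp <- vapply(vcs, vc_filled, numeric(3))
  tots <- colSums(comp)
  vpcs <- vapply(vcs, function(v) round_half_up(vpc(v), digits), numeric(3))
  iccs <- vapply(vcs, function(v) round_half_up(icc(v), digits), numeric(2))
  pcvs <- vapply(vcs, function(v) round_half_up(pcv(v, vcs[[1L]]), digits),
                 numeric(4))
  components <- rbind(comp, total = tots)
  rownames(components) <- c("sigma2_mcb", "sigma2_m", "sigma2_b", "total")
  colnames(components) <- colnames(vpcs) <- colnames(iccs) <-
    colnames(pcvs) <- nm
  structure(list(components = components, vpc = vpcs, icc = iccs,
                 pcv = pcvs, reference = nm[1L]),
            class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat("Variance partition report (reference:", x$reference, ")\n\n")
  cat("Components (g^2):\n")
  print(round(x$components, 1))
  cat("\nVPC (%):\n"); print(x$vpc)
  cat("\nICC (%):\n"); print(x$icc)
  cat("\nPCV vs", x$reference, "(%):\n"); print(x$pcv)
  invisible(x)
}

#' Write a partition report as delimiter-separated text
#'
#' Rows are statistics, columns are models.
#'
#' @param report a [partition_report].
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_partition_report <- function(report, path, sep = "\t") {
  tab <- rbind(report$components, report$vpc, report$icc, report$pcv)
  df <- data.frame(statistic = rownames(tab), tab, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
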