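#' Fit a qPCR standard curve
#'
#' Fits the least-squares line of mean threshold cycle (Ct) on log10
#' concentration for a dilution series of a known template, the classic
#' absolute-quantification calibration. The amplification efficiency is
#' derived from the slope as `E = 10^(-1/slope) - 1`, where `E = 1` is
#' perfect per-cycle doubling (slope `-1/log10(2) ~ -3.3219`). The curve
#' also carries the reliable Ct window (default 5-28 cycles) outside of
#' which readings are flagged.
#'
#' @param dilution_series Data frame with a `conc` column (concentration,
#'   ng/ul, all > 0; at least 3 distinct values) and one or more `ct`
#'   replicate columns (any columns matching `^ct`), or long format with
#'   columns `conc` and `ct`.
#' @param ct_min,ct_max Reliable Ct window.
#' @param conc_unit Unit label for the concentration axis.
#' @return Object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `ct_min`, `ct_max`,
#'   `conc_unit`, `fit` (the underlying `lm`) and `data` (mean Ct per
#'   concentration). Supports `print()`, `summary()`, `coef()`,
#'   `predict()` (concentration -> Ct), `residuals()`, `plot()` and
#'   `simulate()`.
#' @seealso [standard_curve()] to build a curve from known coefficients,
#'   [ct_to_concentration()] for the inverse map,
#'   [efficiency_from_slope()].
#' @export
fit_standard_curve <- function(dilution_series, ct_min = 5, ct_max = 28,
                               conc_unit = "ng/ul") {
  df <- as.data.frame(dilution_series)
  if (!"conc" %in% names(df)) stop("dilution_series needs a 'conc' column")
  ct_cols <- grep("^ct", names(df), value = TRUE)
  if (!length(ct_cols)) stop("dilution_series needs Ct columns (named 'ct*')")
  if (any(df$conc <= 0)) stop("all concentrations must be positive")
  long <- data.frame(
    conc = rep(df$conc, length(ct_cols)),
    ct = unlist(df[ct_cols], use.names = FALSE)
  )
  long <- long[!is.na(long$ct), , drop = FALSE]
  mean_ct <- tapply(long$ct, long$conc, mean)
  concs <- as.numeric(names(mean_ct))
  if (length(concs) < 3) stop("need at least 3 distinct concentrations")
  d <- data.frame(log_conc = log10(concs), mean_ct = as.numeric(mean_ct))
  fit <- stats::lm(mean_ct ~ log_conc, data = d)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) {
    stop("fitted slope is non-negative; Ct must decrease with concentration")
  }
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         efficiency = efficiency_from_slope(slope),
         ct_min = ct_min, ct_max = ct_max, conc_unit = conc_unit,
         fit = fit, data = d),
    class = "standard_curve"
  )
}

#' Build a standard curve from known coefficients
#'
#' For replaying a calibration whose regression line is already known
#' (e.g. a published `y = slope * log10(conc) + intercept` curve) without
#' the underlying dilution data.
#'
#' @param slope Ct change per tenfold concentration change (must be < 0).
#' @param intercept Ct at 1 concentration unit.
#' @param r_squared Optional fit quality to record.
#' @param ct_min,ct_max Reliable Ct window.
#' @param conc_unit Unit label.
#' @return A `standard_curve` (without `fit`/`data` components).
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_,
                           ct_min = 5, ct_max = 28, conc_unit = "ng/ul") {
  stopifnot(slope < 0)
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         efficiency = efficiency_from_slope(slope),
         ct_min = ct_min, ct_max = ct_max, conc_unit = conc_unit,
         fit = NULL, data = NULL),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: Ct = %.4f * log10(conc) + %.4f\n",
              x$slope, x$intercept))
  cat(sprintf("  efficiency %.2f%%, r^2 %s, reliable Ct [%g, %g], conc in %s\n",
              100 * x$efficiency,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$ct_min, x$ct_max, x$conc_unit))
  invisible(x)
}

#' @export
summary.standard_curve <- function(object, ...) {
  print(object)
  if (!is.null(object$fit)) {
    cat("\nUnderlying regression of mean Ct on log10(conc):\n")
    print(summary(object$fit))
  }
  invisible(object)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict Ct from concentration (forward map of the curve)
#'
#' @param object A `standard_curve`.
#' @param conc Concentrations (> 0) in the curve's unit.
#' @param ... Unused.
#' @return Predicted Ct values.
#' @export
predict.standard_curve <- function(object, conc, ...) {
  stopifnot(all(conc > 0))
  object$slope * log10(conc) + object$intercept
}

#' @export
residuals.standard_curve <- function(object, ...) {
  if (is.null(object$fit)) stop("curve was built from coefficients; no residuals")
  stats::residuals(object$fit)
}

#' Simulate replicate Ct readings through a standard curve
#'
#' @param object A `standard_curve`.
#' @param nsim Replicates per concentration.
#' @param seed Optional seed.
#' @param conc Concentrations to simulate at.
#' @param noise_sd_ct Gaussian Ct noise SD (0 gives the deterministic
#'   forward map).
#' @param ... Unused.
#' @return Matrix of Ct values, `length(conc)` rows x `nsim` columns.
#' @export
simulate.standard_curve <- function(object, nsim = 3, seed = NULL,
                                    conc, noise_sd_ct = 0.1, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, conc)
  noise <- if (noise_sd_ct > 0) {
    matrix(stats::rnorm(length(conc) * nsim, 0, noise_sd_ct),
           length(conc), nsim)
  } else {
    matrix(0, length(conc), nsim)
  }
  sweep(noise, 1, mu, `+`)
}

#' @export
plot.standard_curve <- function(x, ...) {
  if (!is.null(x$data)) {
    graphics::plot(x$data$log_conc, x$data$mean_ct,
                   xlab = sprintf("log10(conc, %s)", x$conc_unit),
                   ylab = "mean Ct", main = "Standard curve", ...)
  } else {
    lc <- seq(-8, 1, length.out = 2)
    graphics::plot(lc, predict(x, 10^lc), type = "n",
                   xlab = sprintf("log10(conc, %s)", x$conc_unit),
                   ylab = "Ct", main = "Standard curve", ...)
  }
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' Closed form `E = 10^(-1/slope) - 1`; `E = 1` corresponds to 100%
#' (perfect doubling each cycle).
#'
#' @param slope Slope of Ct on log10 concentration (< 0).
#' @return Efficiency as a fraction (e.g. `1.0949` = 109.49%).
#' @export
efficiency_from_slope <- function(slope) {
  stopifnot(all(slope < 0))
  10^(-1 / slope) - 1
}

#' Invert a standard curve: concentration from Ct
#'
#' @param curve A `standard_curve`.
#' @param ct Ct values.
#' @param flag_window If `TRUE` (default) attach a logical attribute
#'   `"flagged"` marking Ct values outside the curve's reliable window
#'   (they are converted anyway, not dropped, so excluded wells stay
#'   visible).
#' @return Concentrations `10^((ct - intercept) / slope)` in the curve's
#'   unit.
#' @export
ct_to_concentration <- function(curve, ct, flag_window = TRUE) {
  stopifnot(inherits(curve, "standard_curve"))
  conc <- 10^((ct - curve$intercept) / curve$slope)
  if (flag_window) {
    attr(conc, "flagged") <- ct < curve$ct_min | ct > curve$ct_max
  }
  conc
}

#' Convert template mass to attomoles
#'
#' `amol = ng * 1e9 / (length_bp * m)` with a per-base molar mass `m` of
#' 660 g/mol/bp for double-stranded template (default) or 330 for
#' single-stranded cDNA. The model in use should be reported alongside
#' results so conversions stay auditable.
#'
#' @param mass_ng Mass in nanograms (>= 0).
#' @param length_bp Template length in bp (> 0); for transcripts, the
#'   coding-region length.
#' @param mass_model `"ds"` (660) or `"ss"` (330).
#' @return Amount in attomoles.
#' @export
ng_to_amol <- function(mass_ng, length_bp, mass_model = c("ds", "ss")) {
  mass_model <- match.arg(mass_model)
  stopifnot(all(length_bp > 0), all(mass_ng >= 0))
  m <- if (mass_model == "ds") 660 else 330
  mass_ng * 1e9 / (length_bp * m)
}

#' Convert attomoles to template mass
#'
#' Inverse of [ng_to_amol()].
#'
#' @param amol Amount in attomoles (>= 0).
#' @param length_bp Template length in bp (> 0).
#' @param mass_model `"ds"` or `"ss"`.
#' @return Mass in nanograms.
#' @export
amol_to_ng <- function(amol, length_bp, mass_model = c("ds", "ss")) {
  mass_model <- match.arg(mass_model)
  stopifnot(all(length_bp > 0), all(amol >= 0))
  m <- if (mass_model == "ds") 660 else 330
  amol * length_bp * m / 1e9
}

#' Flag replicate Ct outliers
#'
#' Retains replicates within `max_dev` cycles of the replicate median.
#' When no replicate is that close to the median (possible with an even
#' replicate count and discordant wells), the replicates closest to the
#' median are retained so that a mean can still be formed; at least one
#' replicate is always retained, and at least two whenever two are equally
#' consistent.
#'
#' @param cts Numeric vector of replicate Ct values (length >= 2).
#' @param max_dev Maximum allowed absolute deviation from the median
#'   (default 0.5 cycles).
#' @return Logical mask of retained replicates.
#' @export
remove_outliers <- function(cts, max_dev = 0.5) {
  stopifnot(length(cts) >= 2)
  dev <- abs(cts - stats::median(cts))
  mask <- dev <= max_dev
  if (!any(mask)) mask <- dev == min(dev)
  mask
}

#' Normalize a target amount to a reference amount
#'
#' @param target Target amounts (amol).
#' @param reference Reference-gene amounts (amol, > 0), recycled.
#' @return Dimensionless ratio `target / reference`.
#' @export
normalize_amount <- function(target, reference) {
  stopifnot(all(reference > 0))
  target / reference
}

#' Pairwise stability ratios of reference genes
#'
#' Computes, for every ordered pair of reference genes and every sample,
#' the mean and SD of the per-replicate mole ratios. Stable references
#' give ratios that fluctuate little across samples; by construction
#' `mean(a/b) * mean(b/a)` is close to 1 only when replicate noise is
#' small, so large reciprocal products are themselves a noise diagnostic.
#'
#' @param amounts Long data frame with columns `gene`, `sample`,
#'   `replicate`, `amount` (amol); replicates are paired across genes by
#'   the `replicate` value.
#' @return Data frame of class `stability_table`: `sample`, `numerator`,
#'   `denominator`, `mean_ratio`, `sd_ratio`.
#' @export
stability_ratios <- function(amounts) {
  need <- c("gene", "sample", "replicate", "amount")
  stopifnot(all(need %in% names(amounts)))
  genes <- unique(amounts$gene)
  if (length(genes) < 2) stop("need at least 2 reference genes")
  samples <- unique(amounts$sample)
  rows <- list()
  for (s in samples) {
    sub <- amounts[amounts$sample == s, , drop = FALSE]
    for (a in genes) for (b in genes) {
      if (a == b) next
      xa <- sub[sub$gene == a, , drop = FALSE]
      xb <- sub[sub$gene == b, , drop = FALSE]
      reps <- intersect(xa$replicate, xb$replicate)
      if (!length(reps)) next
      r <- xa$amount[match(reps, xa$replicate)] /
        xb$amount[match(reps, xb$replicate)]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, numerator = a, denominator = b,
        mean_ratio = mean(r),
        sd_ratio = if (length(r) > 1) stats::sd(r) else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("stability_table", class(out))
  out
}

#' Family contribution percentages
#'
#' Expresses each family-common amount as a percentage of the per-sample
#' total over all families (the families' sets must partition the total
#' transcript pool). Rows sum to 100 within rounding.
#'
#' @param amounts Data frame with columns `sample`, `family`, `amount`
#'   (normalized or raw; percentages are scale-invariant).
#' @return Data frame `sample`, `family`, `percent`.
#' @export
contribution_report <- function(amounts) {
  stopifnot(all(c("sample", "family", "amount") %in% names(amounts)))
  totals <- tapply(amounts$amount, amounts$sample, sum)
  if (any(totals <= 0)) stop("non-positive per-sample total")
  data.frame(
    sample = amounts$sample, family = amounts$family,
    percent = 100 * amounts$amount / as.numeric(totals[as.character(amounts$sample)]),
    stringsAsFactors = FALSE
  )
}

#' Share of a part within its enclosing group
#'
#' E.g. a subgroup's percentage of its subfamily, both given either as
#' amounts or as percentages of a common total. A part exceeding its whole
#' is flagged (attribute `"flagged"`), not rejected: measurement noise in
#' independently measured primer sets can produce it.
#'
#' @param part,whole Non-negative scalars (whole > 0), on a common scale.
#' @return `100 * part / whole` (percent).
#' @export
subgroup_share <- function(part, whole) {
  stopifnot(whole > 0, part >= 0)
  out <- 100 * part / whole
  if (part > whole) attr(out, "flagged") <- TRUE
  out
}

#' Coverage of a family total by its individually measured members
#'
#' How much of a family-common signal the member-specific assays account
#' for; shortfall indicates members with no working specific assay or
#' alleles absent from the studied cultivar.
#'
#' @param members Numeric vector of member amounts (possibly empty).
#' @param family Family-common amount (> 0), same scale.
#' @return `100 * sum(members) / family` (percent); 0 for an empty member
#'   list.
#' @export
member_coverage <- function(members, family) {
  stopifnot(family > 0)
  if (!length(members)) return(0)
  100 * sum(members) / family
}
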