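#' Standardize ratings within each participant
#'
#' Absolute magnitude estimates are on an arbitrary per-participant scale,
#' so every participant's ratings (practice and main, pre and post pooled)
#' are transformed into z-scores using that participant's own mean and SD.
#' Rank order is preserved and the result is invariant to positive affine
#' transformations of a participant's scale.
#'
#' @param table a rating `data.frame` with columns `participant` and `raw`.
#' @param sd_convention `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @return the table with a `z` column added.
#' @export
zscore_by_participant <- function(table,
                                  sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(all(c("participant", "raw") %in% names(table)))
  table$z <- NA_real_
  for (p in unique(table$participant)) {
    i <- table$participant == p
    x <- table$raw[i]
    if (length(x) < 2) {
      heftr_error("heftr_degenerate_participant",
                  sprintf("participant %s has fewer than 2 ratings", p))
    }
    s <- stats::sd(x)
    if (sd_convention == "population") s <- s * sqrt((length(x) - 1) / length(x))
    if (!is.finite(s) || s == 0) {
      heftr_error("heftr_degenerate_participant",
                  sprintf("participant %s has zero rating variance", p))
    }
    table$z[i] <- (x - mean(x)) / s
  }
  table
}

#' Convert a judged CoM position into a rating pair
#'
#' A CoM judgment `x` (measured from the half-1 end of the object, in the
#' same units as `L`) is used directly as the rating of the half that
#' contains the judged CoM and `L - x` as the rating of the other half, so
#' the larger number always belongs to the half toward which the CoM was
#' perceived and the pair always sums to `L`.
#'
#' @param x judged CoM position(s), `0 <= x <= L`.
#' @param L object length (same units as `x`; default 10 cm).
#' @return a matrix with columns `half1` (`L - x`) and `half2` (`x`).
#' @examples
#' com_to_half_ratings(6.2)  # half2 = 6.2, half1 = 3.8
#' @export
com_to_half_ratings <- function(x, L = 10) {
  if (any(x < 0 | x > L)) {
    heftr_error("heftr_range_error", "judged CoM outside [0, L]")
  }
  cbind(half1 = L - x, half2 = x)
}

#' Per-participant weight-illusion index
#'
#' The illusion index is the mean standardized rating of the
#' heavier-looking target minus that of the lighter-looking target,
#' computed separately from pre-lift (expectation) and post-lift
#' (perception) ratings. Positive = the heavier-looking target was rated
#' heavier (integration / inverted illusion); negative = contrast
#' (classic illusion).
#'
#' @param table a rating table with columns `participant`, `phase`, `z`,
#'   and the label column.
#' @param heavy_label,light_label values of `label_col` identifying the
#'   heavier- and lighter-looking targets.
#' @param label_col column holding the target labels (`"material"` for
#'   half-level indices, `"object_id"` for whole-object indices).
#' @return `data.frame` with columns `participant`, `pre`, `post`.
#' @export
illusion_index <- function(table, heavy_label, light_label,
                           label_col = "material") {
  stopifnot(all(c("participant", "phase", "z", label_col) %in% names(table)))
  lab <- table[[label_col]]
  out <- lapply(unique(table$participant), function(p) {
    one <- function(phase, label) {
      v <- table$z[table$participant == p & table$phase == phase & lab == label]
      if (!length(v)) {
        heftr_error("heftr_incomplete_data",
                    sprintf("participant %s lacks %s-phase ratings for '%s'",
                            p, phase, label))
      }
      mean(v)
    }
    data.frame(participant = p,
               pre = one("pre", heavy_label) - one("pre", light_label),
               post = one("post", heavy_label) - one("post", light_label))
  })
  do.call(rbind, out)
}

#' Repeated-measures / mixed-design ANOVA
#'
#' Fits a fully balanced within-subject (optionally with one
#' between-subject factor) ANOVA on cell means per participant, and
#' applies the Greenhouse-Geisser correction to within-subject effects
#' with more than one numerator df. By default the correction is applied
#' when Mauchly's sphericity test is significant at 0.05
#' (`sphericity = "mauchly"`); `"always"` and `"never"` are available.
#' Two-level within factors have epsilon = 1 by construction and are
#' never altered.
#'
#' @param data long-format `data.frame`.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor columns.
#' @param between optional name of one between-subject factor column.
#' @param participant name of the participant id column.
#' @param sphericity correction policy.
#' @return `data.frame` with one row per effect: `effect`, `df1`, `df2`,
#'   `F`, `p`, `epsilon`, `p_gg`, `mauchly_p`, `corrected`, and the
#'   reported (possibly fractional) `df1_rep`, `df2_rep`, `p_rep`.
#' @export
rm_or_mixed_anova <- function(data, dv, within, between = NULL,
                              participant = "participant",
                              sphericity = c("mauchly", "always", "never")) {
  sphericity <- match.arg(sphericity)
  stopifnot(all(c(dv, within, between, participant) %in% names(data)))
  for (f in c(within, between)) data[[f]] <- factor(data[[f]])
  data[[participant]] <- factor(data[[participant]])

  # aggregate to one cell mean per participant x within-cell
  agg <- stats::aggregate(data[[dv]],
                          by = c(lapply(data[c(participant, between, within)],
                                        identity)),
                          FUN = mean)
  names(agg) <- c(participant, between, within, ".dv")

  idata <- do.call(expand.grid, lapply(data[within], levels))
  names(idata) <- within
  cell_of <- interaction(agg[within], lex.order = TRUE)
  lev <- levels(interaction(idata[within], lex.order = TRUE))
  wide_rows <- split(agg, agg[[participant]], drop = TRUE)
  Y <- t(vapply(wide_rows, function(d) {
    d$.dv[match(lev, interaction(d[within], lex.order = TRUE))]
  }, numeric(length(lev))))
  if (anyNA(Y)) {
    heftr_error("heftr_design_error", "design has missing within-subject cells")
  }
  idata <- idata[match(lev, interaction(idata[within], lex.order = TRUE)), ,
                 drop = FALSE]
  grp <- if (!is.null(between)) {
    vapply(wide_rows, function(d) as.character(d[[between]][1]), "")
  } else NULL
  if (!is.null(between) && min(table(grp)) < 2) {
    heftr_error("heftr_design_error",
                "need >= 2 participants per between-subject cell")
  }

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  wide <- data.frame(Y)
  fml <- if (is.null(between)) {
    stats::as.formula("as.matrix(wide) ~ 1")
  } else {
    wide$.grp <- factor(grp)
    stats::as.formula("as.matrix(wide[, seq_along(lev)]) ~ .grp")
  }
  mlm <- stats::lm(fml, data = wide)
  av <- car::Anova(mlm, idata = idata,
                   idesign = stats::as.formula(paste("~", paste(within, collapse = "*"))),
                   type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))

  ut <- s$univariate.tests
  eff <- rownames(ut)
  keep <- eff != "(Intercept)"
  res <- data.frame(effect = gsub("\\.grp", between %||% "", eff[keep]),
                    df1 = ut[keep, "num Df"], df2 = ut[keep, "den Df"],
                    F = ut[keep, "F value"], p = ut[keep, "Pr(>F)"],
                    epsilon = NA_real_, p_gg = NA_real_,
                    mauchly_p = NA_real_, stringsAsFactors = FALSE)
  pa <- s$pval.adjustments
  if (!is.null(pa) && nrow(pa)) {
    i <- match(rownames(pa), eff[keep])
    res$epsilon[i] <- pmin(pa[, "GG eps"], 1)
    res$p_gg[i] <- pa[, "Pr(>F[GG])"]
  }
  # within effects with a single numerator df (2-level factors) have
  # epsilon = 1 by construction and are unaffected by the correction
  is_within <- vapply(eff[keep], function(e) {
    any(vapply(within, function(w) grepl(w, e, fixed = TRUE), TRUE))
  }, TRUE)
  one_df <- is_within & is.na(res$epsilon)
  res$epsilon[one_df] <- 1
  res$p_gg[one_df] <- res$p[one_df]
  sph <- s$sphericity.tests
  if (!is.null(sph) && nrow(sph)) {
    i <- match(rownames(sph), eff[keep])
    res$mauchly_p[i] <- sph[, "p-value"]
  }
  res$corrected <- switch(sphericity,
    never = rep(FALSE, nrow(res)),
    always = !is.na(res$epsilon) & res$epsilon < 1,
    mauchly = !is.na(res$mauchly_p) & res$mauchly_p < 0.05 &
      !is.na(res$epsilon))
  res$df1_rep <- ifelse(res$corrected, res$df1 * res$epsilon, res$df1)
  res$df2_rep <- ifelse(res$corrected, res$df2 * res$epsilon, res$df2)
  res$p_rep <- pmax(ifelse(res$corrected, res$p_gg, res$p), 1e-16)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-sample, paired and Welch t-tests
#'
#' Thin wrapper around [stats::t.test()] returning a tidy one-row result.
#' Two-sample comparisons default to the Welch unequal-variance test
#' (fractional Welch-Satterthwaite df). All tests are two-sided. A
#' zero-variance one-sample test with a nonzero mean shift is flagged as
#' an infinite statistic rather than an error.
#'
#' @param x numeric vector (first sample / differences).
#' @param y optional second sample.
#' @param kind `"one-sample"`, `"paired"`, or `"welch"`.
#' @param mu null value.
#' @return `data.frame` with `kind`, `statistic`, `df`, `p`, `estimate`,
#'   `infinite` flag.
#' @export
t_tests <- function(x, y = NULL, kind = c("one-sample", "paired", "welch"),
                    mu = 0) {
  kind <- match.arg(kind)
  if (length(x) < 2 || (kind != "one-sample" && length(y) < 2)) {
    heftr_error("heftr_design_error", "need n >= 2 per group")
  }
  res <- tryCatch({
    tt <- switch(kind,
      "one-sample" = stats::t.test(x, mu = mu),
      "paired" = stats::t.test(x, y, paired = TRUE, mu = mu),
      "welch" = stats::t.test(x, y, var.equal = FALSE, mu = mu))
    data.frame(kind = kind, statistic = unname(tt$statistic),
               df = unname(tt$parameter),
               p = max(tt$p.value, 1e-16),
               estimate = unname(tt$estimate[1] - if (length(tt$estimate) > 1)
                 tt$estimate[2] else 0),
               infinite = FALSE, stringsAsFactors = FALSE)
  }, error = function(e) {
    shift <- mean(if (kind == "paired") x - y else x) - mu
    if (grepl("constant", conditionMessage(e)) && shift != 0) {
      data.frame(kind = kind, statistic = sign(shift) * Inf,
                 df = length(x) - 1, p = 1e-16, estimate = shift,
                 infinite = TRUE, stringsAsFactors = FALSE)
    } else stop(e)
  })
  res
}

#' Bonferroni-adjusted alpha
#'
#' @param alpha family-wise error rate.
#' @param m number of comparisons.
#' @return adjusted alpha `alpha / m`, reported at 4 decimals.
#' @examples
#' bonferroni(0.05, 3)  # 0.0167
#' @export
bonferroni <- function(alpha = 0.05, m) {
  if (missing(m) || length(m) == 0 || any(m < 1)) {
    heftr_error("heftr_config_error", "number of comparisons must be >= 1")
  }
  round(alpha / m, 4)
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Default-prior Bayes factor in favor of the null (`BF01`) for an
#' observed one-sample (or paired) t-statistic: the effect size under the
#' alternative carries a zero-centered Cauchy prior with scale `r`, and
#' the marginal likelihood is computed by numerical integration over the
#' g-prior representation. `BF01 > 1` favors the null.
#'
#' @param t observed t-statistic.
#' @param n sample size (pairs for a paired design).
#' @param r Cauchy prior scale (default `0.707`).
#' @return the Bayes factor `BF01` (numeric).
#' @export
bf01_one_sample <- function(t, n, r = sqrt(2) / 2) {
  if (!is.finite(t)) heftr_error("heftr_config_error", "t must be finite")
  if (n < 2) heftr_error("heftr_config_error", "need n >= 2")
  nu <- n - 1
  like_null <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    q <- 1 + n * g * r^2
    q^(-1 / 2) * (1 + t^2 / (q * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  like_alt <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                               subdivisions = 500L)$value
  like_null / like_alt
}
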