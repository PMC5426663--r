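# Per-location and pooled analysis of plot-level trial data: one-pass
# studentized-residual outlier screening, backward elimination of
# polynomial row/column trend covariates (sequential Type-1 tests with a
# hierarchy rule), least-squares genotype means, and single degree of
# freedom contrasts against the mid-parent value.

#' Analysis settings for a field-trial model
#'
#' @param max_poly_degree highest polynomial degree of the row/column
#'   trend covariates considered (default 4).
#' @param alpha_covariate significance level of the sequential Type-1
#'   tests used during covariate elimination.
#' @param outlier_threshold externally studentized residual magnitude
#'   above which a plot is dropped (default 3).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(max_poly_degree = 4, alpha_covariate = 0.05,
                       outlier_threshold = 3) {
  stopifnot(max_poly_degree >= 1, max_poly_degree <= 4,
            alpha_covariate > 0, alpha_covariate < 1, outlier_threshold > 0)
  structure(list(max_poly_degree = as.integer(max_poly_degree),
                 alpha_covariate = alpha_covariate,
                 outlier_threshold = outlier_threshold),
            class = "model_spec")
}

#' Mid-parent difference
#'
#' The elementary heterosis quantity: the F1 (or F2) mean minus the
#' arithmetic mean of the two parents.
#'
#' @param f1_mean,p1_mean,p2_mean finite numeric trait means.
#' @return `f1_mean - (p1_mean + p2_mean) / 2`.
#' @examples
#' mid_parent_difference(2204, 1934, 2096)  # 189
#' @export
mid_parent_difference <- function(f1_mean, p1_mean, p2_mean) {
  stopifnot(is.finite(f1_mean), is.finite(p1_mean), is.finite(p2_mean))
  f1_mean - (p1_mean + p2_mean) / 2
}

# Centred power covariates row1..row4 / col1..col4; constant axes yield
# no columns. Powers of the centred position, not orthogonal polynomials,
# so "degree" has its face meaning in the elimination rules.
trend_columns <- function(plots, max_degree = 4) {
  out <- list()
  for (axis in c("row", "column")) {
    x <- plots[[axis]]
    if (length(unique(x)) <= 1) next
    xc <- x - mean(x)
    sc <- max(abs(xc)); if (sc == 0) sc <- 1
    for (d in seq_len(max_degree))
      out[[paste0(substr(axis, 1, 3), d)]] <- (xc / sc)^d
  }
  if (!length(out)) return(plots[, FALSE, drop = FALSE])
  as.data.frame(out)
}

cov_axis <- function(terms) substr(terms, 1, 3)
cov_degree <- function(terms) as.integer(sub("^(row|col)", "", terms))

build_trial_formula <- function(trait, covariates, has_block) {
  rhs <- "genotype"
  if (has_block) rhs <- c(rhs, "block")
  if (length(covariates)) {
    ord <- order(cov_degree(covariates), cov_axis(covariates))
    rhs <- c(rhs, covariates[ord])
  }
  stats::as.formula(paste(sprintf("`%s`", trait), "~", paste(rhs, collapse = " + ")))
}

prepare_trial_frame <- function(plots, trait, spec) {
  stopifnot(trait %in% names(plots))
  df <- plots
  df$genotype <- factor(df$genotype)
  has_block <- "block" %in% names(df) && length(unique(df$block)) > 1
  if (has_block) df$block <- factor(df$block)
  tc <- trend_columns(df, spec$max_poly_degree)
  list(data = cbind(df, tc), covariates = names(tc), has_block = has_block)
}

#' Flag outlying plots by externally studentized residuals
#'
#' Fits, separately within each location, the full screening model
#' (genotype + block + all row/column power covariates up to the maximum
#' degree) and drops plots whose externally studentized residual exceeds
#' the threshold in magnitude. A single pass: the model is not refitted
#' after removals.
#'
#' @param plots plot-observation data frame (see [read_plot_table()]).
#' @param trait trait column to screen.
#' @param spec a [model_spec()].
#' @return list with elements `retained` and `dropped` (data frames; the
#'   dropped rows carry a `studentized_residual` column).
#' @export
flag_outliers <- function(plots, trait, spec = model_spec()) {
  res <- studentized_residuals(plots, trait, spec)
  drop <- !is.na(res) & abs(res) > spec$outlier_threshold
  dropped <- plots[drop, , drop = FALSE]
  if (nrow(dropped)) dropped$studentized_residual <- res[drop]
  list(retained = plots[!drop, , drop = FALSE], dropped = dropped)
}

#' Externally studentized residuals of the screening model
#'
#' The residual of each plot scaled by the error estimate computed with
#' that plot left out, under the per-location screening model
#' (genotype + block + full row/column power covariates).
#'
#' @inheritParams flag_outliers
#' @return numeric vector aligned with the rows of `plots`.
#' @export
studentized_residuals <- function(plots, trait, spec = model_spec()) {
  res <- rep(NA_real_, nrow(plots))
  for (loc in unique(plots$location)) {
    idx <- which(plots$location == loc)
    pr <- prepare_trial_frame(plots[idx, , drop = FALSE], trait, spec)
    fml <- build_trial_formula(trait, pr$covariates, pr$has_block)
    fit <- stats::lm(fml, data = pr$data)
    if (stats::df.residual(fit) < 2)
      stop("fewer than 2 residual degrees of freedom at location '", loc,
           "'; cannot studentize residuals", call. = FALSE)
    # a numerically perfect fit has no outliers, only rounding fuzz
    scale <- stats::sd(pr$data[[trait]])
    if (is.na(scale) || scale == 0 ||
        stats::sigma(fit) < 1e-10 * max(scale, 1)) {
      res[idx] <- 0
    } else {
      res[idx] <- stats::rstudent(fit)
    }
  }
  res
}

#' Backward elimination of polynomial trend covariates
#'
#' Starting from all row/column powers up to the maximum degree, tests
#' sequential (Type-1) sums of squares and repeatedly removes the
#' highest-order non-significant covariate. Only the highest remaining
#' degree on each axis is ever eligible for removal, so any degree below
#' a retained significant degree stays in the model (the hierarchy rule).
#' When both axes offer an eligible non-significant term, the one with
#' the larger p-value is removed first.
#'
#' @inheritParams flag_outliers
#' @return character vector of retained covariate names (e.g.
#'   `c("row1", "row2")`), possibly empty.
#' @export
select_trend_covariates <- function(plots, trait, spec = model_spec()) {
  pr <- prepare_trial_frame(plots, trait, spec)
  remaining <- pr$covariates
  repeat {
    if (!length(remaining)) break
    fml <- build_trial_formula(trait, remaining, pr$has_block)
    fit <- stats::lm(fml, data = pr$data)
    if (stats::df.residual(fit) < 1)
      stop("no residual degrees of freedom for covariate testing", call. = FALSE)
    at <- stats::anova(fit)
    pvals <- stats::setNames(at[["Pr(>F)"]], rownames(at))
    top <- remaining[vapply(remaining, function(tm) {
      deg <- cov_degree(tm)
      !any(cov_axis(remaining) == cov_axis(tm) & cov_degree(remaining) > deg)
    }, logical(1))]
    # aliased terms are absent from the anova table: nothing to test, drop
    pv <- stats::setNames(pvals[match(top, names(pvals))], top)
    pv[is.na(pv)] <- Inf
    cand <- top[pv >= spec$alpha_covariate]
    if (!length(cand)) break
    remaining <- setdiff(remaining, cand[which.max(pv[cand])])
  }
  remaining
}

#' Fit the per-location genotype model
#'
#' Least-squares fit of `trait ~ genotype + block + <covariates>` and
#' genotype adjusted means (evaluated at equal block weights and mean
#' covariate values), their covariance, the residual variance and the
#' residual degrees of freedom. Outliers are assumed already removed and
#' covariates already selected.
#'
#' @inheritParams flag_outliers
#' @param covariates retained covariate names from
#'   [select_trend_covariates()].
#' @return an object of class `trial_fit`.
#' @export
fit_location_model <- function(plots, trait, covariates = character(0),
                               spec = model_spec()) {
  pr <- prepare_trial_frame(plots, trait, spec)
  covariates <- intersect(covariates, pr$covariates)
  fml <- build_trial_formula(trait, covariates, pr$has_block)
  fit <- stats::lm(fml, data = pr$data)
  geno <- levels(pr$data$genotype)
  n_obs <- table(pr$data$genotype)
  if (any(n_obs == 0))
    stop("genotype level(s) with no plots: ",
         paste(geno[n_obs == 0], collapse = ", "), call. = FALSE)
  tt <- stats::delete.response(stats::terms(fit))
  # L matrix: one prediction row per genotype at equal block weight and
  # mean covariate values
  L <- t(vapply(geno, function(g) {
    nd <- pr$data[1, , drop = FALSE]
    if (pr$has_block) {
      nd <- nd[rep(1, nlevels(pr$data$block)), , drop = FALSE]
      nd$block <- factor(levels(pr$data$block), levels = levels(pr$data$block))
    }
    nd$genotype <- factor(g, levels = geno)
    for (cv in covariates) nd[[cv]] <- mean(pr$data[[cv]])
    mm <- stats::model.matrix(tt, nd)
    colMeans(mm)
  }, numeric(length(stats::coef(fit)))))
  beta <- stats::coef(fit)
  ok <- !is.na(beta)
  means <- drop(L[, ok, drop = FALSE] %*% beta[ok])
  names(means) <- geno
  df_res <- stats::df.residual(fit)
  if (df_res > 0) {
    V <- L[, ok, drop = FALSE] %*% stats::vcov(fit, complete = FALSE) %*%
      t(L[, ok, drop = FALSE])
    sigma2 <- stats::sigma(fit)^2
  } else {
    V <- matrix(NA_real_, length(geno), length(geno))
    sigma2 <- NA_real_
  }
  dimnames(V) <- list(geno, geno)
  structure(list(means = means, vcov = V, sigma2 = sigma2, df = df_res,
                 trait = trait, covariates = covariates,
                 location = if (length(unique(plots$location)) == 1)
                   unique(plots$location) else NA_character_,
                 lm_fit = fit),
            class = "trial_fit")
}

#' @export
print.trial_fit <- function(x, digits = 4, ...) {
  cat("Field-trial fit:", x$trait,
      if (!is.na(x$location)) paste0("(", x$location, ")"), "\n")
  cat("Adjusted genotype means:\n")
  print(round(x$means, digits))
  cat("Residual df:", x$df,
      " residual SD:", format(sqrt(x$sigma2), digits = digits), "\n")
  if (length(x$covariates))
    cat("Trend covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.trial_fit <- function(object, ...) object$means

#' @export
vcov.trial_fit <- function(object, ...) object$vcov

#' @export
summary.trial_fit <- function(object, ...) summary(object$lm_fit, ...)

#' Single degree of freedom genotype contrast
#'
#' @param fit a [fit_location_model()] object.
#' @param coefficients named numeric vector of contrast coefficients over
#'   genotypes; must sum to zero and name each genotype once. The
#'   mid-parent contrast is `c(F1 = 1, P1 = -0.5, P2 = -0.5)`.
#' @param one_sided if `TRUE` the p-value tests the alternative that the
#'   contrast is positive: half the two-sided p when the estimate is
#'   positive, one minus half otherwise.
#' @param label optional contrast label.
#' @return an object of class `contrast_result`: a one-row data frame
#'   with label, estimate, std_error, df, p_value and one_sided.
#' @export
trial_contrast <- function(fit, coefficients, one_sided = FALSE, label = NULL) {
  stopifnot(inherits(fit, "trial_fit"))
  if (anyDuplicated(names(coefficients)))
    stop("duplicated genotype in contrast coefficients", call. = FALSE)
  if (!all(names(coefficients) %in% names(fit$means)))
    stop("unknown genotype(s): ",
         paste(setdiff(names(coefficients), names(fit$means)), collapse = ", "),
         call. = FALSE)
  if (abs(sum(coefficients)) > 1e-8)
    stop("contrast coefficients must sum to zero", call. = FALSE)
  g <- names(coefficients)
  est <- sum(coefficients * fit$means[g])
  if (fit$df > 0 && !anyNA(fit$vcov[g, g])) {
    se <- sqrt(drop(t(coefficients) %*% fit$vcov[g, g] %*% coefficients))
    tval <- est / se
    p <- if (one_sided) stats::pt(tval, fit$df, lower.tail = FALSE)
         else 2 * stats::pt(-abs(tval), fit$df)
  } else {
    se <- NA_real_; p <- NA_real_
  }
  structure(data.frame(label = label %||% "contrast", estimate = est,
                       std_error = se, df = fit$df, p_value = p,
                       one_sided = one_sided, stringsAsFactors = FALSE),
            class = c("contrast_result", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pool per-location contrasts by inverse-variance weighting
#'
#' Combines independent per-location contrast estimates with weights
#' 1/SE^2; the pooled degrees of freedom use the Satterthwaite
#' approximation. With a single estimable location the result is that
#' location's contrast, flagged with a warning attribute.
#'
#' @param results list of `contrast_result` rows from [trial_contrast()].
#' @param one_sided as in [trial_contrast()].
#' @param label optional label.
#' @return a `contrast_result`.
#' @export
pooled_contrast <- function(results, one_sided = FALSE, label = NULL) {
  stopifnot(length(results) >= 1)
  df <- do.call(rbind, results)
  ok <- is.finite(df$std_error) & df$std_error > 0
  if (sum(ok) == 0) {
    out <- df[1, , drop = FALSE]
    out$estimate <- mean(df$estimate)
    out$std_error <- NA_real_; out$p_value <- NA_real_; out$df <- NA_real_
    out$label <- label %||% out$label
    return(structure(out, class = c("contrast_result", "data.frame")))
  }
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 1) {
    out <- df
    out$label <- label %||% out$label
    attr(out, "single_location") <- TRUE
    warning("only one location estimable; returning its contrast", call. = FALSE)
    return(structure(out, class = c("contrast_result", "data.frame")))
  }
  w <- 1 / df$std_error^2
  W <- sum(w)
  est <- sum(w * df$estimate) / W
  V <- 1 / W
  v_i <- w / W^2                       # per-location contribution to V
  df_sat <- V^2 / sum(v_i^2 / df$df)
  se <- sqrt(V)
  tval <- est / se
  p <- if (one_sided) stats::pt(tval, df_sat, lower.tail = FALSE)
       else 2 * stats::pt(-abs(tval), df_sat)
  structure(data.frame(label = label %||% df$label[1], estimate = est,
                       std_error = se, df = df_sat, p_value = p,
                       one_sided = one_sided, stringsAsFactors = FALSE),
            class = c("contrast_result", "data.frame"))
}

#' Per-trait heterosis contrast report
#'
#' Runs the full per-location pipeline for each trait — outlier screen,
#' trend-covariate elimination, genotype model — then computes F1 vs
#' mid-parent and F2 vs mid-parent contrasts per location and pooled over
#' locations (inverse-variance weighting). Yield-type traits can be
#' tested one-sided, as is conventional when the direction of heterosis
#' is the hypothesis. If `harvestable_protein` is requested but absent
#' it is derived per plot as yield x protein / 100 (kg/ha).
#'
#' Degenerate inputs with a single plot per genotype (e.g. a table of
#' published means) are fitted means-only: estimates are exact,
#' standard errors and p-values are `NA`.
#'
#' @param plots plot-observation data frame with columns location, block,
#'   row, column, genotype, entry_class and one column per trait.
#'   `entry_class` identifies parent1, parent2, F1 and F2 rows.
#' @param traits trait columns to analyse (default: all trait columns).
#' @param one_sided_traits traits tested one-sided (greater), by default
#'   yield and harvestable_protein.
#' @param spec a [model_spec()].
#' @param screen_outliers,select_covariates logical toggles for the two
#'   preprocessing stages (enabled when the design supports them).
#' @return an object of class `heterosis_report`: a data frame (trait,
#'   location, contrast, estimate, std_error, df, p_value, one_sided)
#'   with an `inbreeding_depression` attribute flagging locations where
#'   the F2 trait mean falls below the F1's for yield.
#' @export
heterosis_report <- function(plots, traits = NULL,
                             one_sided_traits = c("yield", "harvestable_protein"),
                             spec = model_spec(),
                             screen_outliers = TRUE, select_covariates = TRUE) {
  design_cols <- c("location", "block", "row", "column", "genotype", "entry_class")
  if (!"entry_class" %in% names(plots))
    stop("plots must have an entry_class column", call. = FALSE)
  if (is.null(traits))
    traits <- setdiff(names(plots), design_cols)
  if ("harvestable_protein" %in% traits &&
      !"harvestable_protein" %in% names(plots)) {
    if (!all(c("yield", "protein") %in% names(plots)))
      stop("cannot derive harvestable_protein without yield and protein",
           call. = FALSE)
    plots$harvestable_protein <- plots$yield * plots$protein / 100
  }
  roles <- c("parent1", "parent2", "F1", "F2")
  geno_of <- vapply(roles, function(r) {
    g <- unique(plots$genotype[plots$entry_class == r])
    if (length(g) == 1) g else NA_character_
  }, "")
  missing_roles <- roles[is.na(geno_of)]
  contrasts_def <- list()
  if (!any(is.na(geno_of[c("parent1", "parent2", "F1")])))
    contrasts_def$F1_vs_midparent <-
      stats::setNames(c(1, -0.5, -0.5), geno_of[c("F1", "parent1", "parent2")])
  if (!any(is.na(geno_of[c("parent1", "parent2", "F2")])))
    contrasts_def$F2_vs_midparent <-
      stats::setNames(c(1, -0.5, -0.5), geno_of[c("F2", "parent1", "parent2")])
  if (!length(contrasts_def))
    stop("need both parents and at least one of F1/F2 to form contrasts",
         call. = FALSE)
  locs <- unique(plots$location)
  rows <- list()
  inbreeding <- NULL
  for (trait in traits) {
    per_loc <- list()
    for (loc in locs) {
      sub <- plots[plots$location == loc, , drop = FALSE]
      degenerate <- max(table(sub$genotype)) == 1
      if (!degenerate && screen_outliers)
        sub <- flag_outliers(sub, trait, spec)$retained
      covs <- character(0)
      if (!degenerate && select_covariates)
        covs <- tryCatch(select_trend_covariates(sub, trait, spec),
                         error = function(e) character(0))
      fit <- fit_location_model(sub, trait, covs, spec)
      for (cn in names(contrasts_def)) {
        cr <- trial_contrast(fit, contrasts_def[[cn]],
                             one_sided = trait %in% one_sided_traits,
                             label = cn)
        per_loc[[cn]] <- c(per_loc[[cn]], list(cr))
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(trait = trait, location = loc,
                           stringsAsFactors = FALSE), cr)
      }
      if (trait == "yield" && all(c("F1", "F2") %in% names(geno_of)) &&
          !any(is.na(geno_of[c("F1", "F2")])))
        inbreeding <- rbind(inbreeding, data.frame(
          location = loc,
          f2_below_f1 = unname(fit$means[geno_of[["F2"]]] <
                                 fit$means[geno_of[["F1"]]]),
          stringsAsFactors = FALSE))
    }
    if (length(locs) >= 2) {
      for (cn in names(per_loc)) {
        pc <- suppressWarnings(
          pooled_contrast(per_loc[[cn]],
                          one_sided = trait %in% one_sided_traits, label = cn))
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(trait = trait, location = "pooled",
                           stringsAsFactors = FALSE), pc)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[names(out) == "label"] <- "contrast"
  out <- out[, c("trait", "location", "contrast", "estimate", "std_error",
                 "df", "p_value", "one_sided")]
  structure(out, class = c("heterosis_report", "data.frame"),
            inbreeding_depression = inbreeding,
            missing_roles = missing_roles)
}

#' @export
print.heterosis_report <- function(x, digits = 3, ...) {
  cat("Heterosis contrast report\n")
  df <- as.data.frame(x)
  for (loc in unique(df$location)) {
    cat("\n--", loc, "--\n")
    sub <- df[df$location == loc, , drop = FALSE]
    wide <- stats::reshape(
      sub[, c("trait", "contrast", "estimate", "p_value")],
      idvar = "contrast", timevar = "trait", direction = "wide")
    est <- wide[, grep("^estimate", names(wide)), drop = FALSE]
    p <- wide[, grep("^p_value", names(wide)), drop = FALSE]
    traits <- sub("^estimate\\.", "", names(est))
    for (i in seq_len(nrow(wide))) {
      cat(format(wide$contrast[i], width = 18))
      cat(paste0(format(signif(unlist(est[i, ]), digits)),
                 " [", ifelse(is.na(unlist(p[i, ])), "NA",
                              format(round(unlist(p[i, ]), 2))), "]",
                 collapse = "  "), "\n")
      cat(format("", width = 18), paste(traits, collapse = "  "), "\n")
    }
  }
  ib <- attr(x, "inbreeding_depression")
  if (!is.null(ib) && any(ib$f2_below_f1))
    cat("\nInbreeding depression for yield (F2 < F1) at:",
        paste(ib$location[ib$f2_below_f1], collapse = ", "), "\n")
  invisible(x)
}
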