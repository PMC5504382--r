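#' Factorial treatment model for community-weighted means
#'
#' Ordinary least squares with soil type, nutrient, precipitation and all
#' their interactions as fixed effects plus the irrigation line as a fixed
#' block term, tested with Type II F-tests (each term against the model
#' containing all terms that do not contain it). Pairwise soil contrasts
#' are estimated marginal means with Tukey-adjusted p-values.
#'
#' @param cwm Data.frame with \code{sample} and \code{cwm} columns (one
#'   trait), e.g. from \code{\link{community_weighted_mean}}, or a named
#'   numeric vector of responses.
#' @param metadata Data.frame with \code{soil}, \code{nutrient},
#'   \code{precipitation}, \code{line} and sample rownames.
#' @param include_block Include the line block term (default TRUE).
#' @param soil_contrasts Compute Tukey-adjusted pairwise soil contrasts
#'   (default TRUE; switch off in bulk simulations where only the F-tests
#'   are consumed).
#' @return List of class \code{model_result}: \code{terms} (data.frame of
#'   term, F, df, df_resid, p), \code{soil_contrasts} (contrast, estimate,
#'   SE, t, p Tukey-adjusted; NULL when not requested), \code{fit} (the lm
#'   object).
#' @export
factorial_model <- function(cwm, metadata, include_block = TRUE,
                            soil_contrasts = TRUE) {
  d <- response_frame(cwm, metadata)
  if (stats::var(d$response) == 0) stop("constant response")
  cell_n <- table(d$soil, d$nutrient, d$precipitation)
  if (any(cell_n == 0)) stop("rank-deficient design: empty design cell(s): ",
                             paste(utils::head(which(cell_n == 0)), collapse = ", "))
  if (any(cell_n < 2)) warning("fewer than 2 samples in some design cell(s)")
  form <- if (include_block && length(unique(d$line)) > 1L)
    response ~ soil * nutrient * precipitation + line
  else response ~ soil * nutrient * precipitation
  fit <- stats::lm(form, data = d)
  if (any(is.na(stats::coef(fit)))) {
    al <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased coefficient(s): ",
         paste(utils::head(al, 5), collapse = ", "))
  }
  a2 <- car::Anova(fit, type = 2)
  keep <- setdiff(rownames(a2), "Residuals")
  terms_df <- data.frame(term = keep, F = a2[keep, "F value"],
                         df = a2[keep, "Df"], df_resid = a2["Residuals", "Df"],
                         p = a2[keep, "Pr(>F)"],
                         stringsAsFactors = FALSE, row.names = NULL)
  contrasts_df <- NULL
  if (soil_contrasts) {
    # averaging soil means over the treatment factors is intended here, so
    # silence the standard emmeans interaction note
    emm <- suppressMessages(emmeans::emmeans(fit, ~soil))
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
    contrasts_df <- data.frame(contrast = as.character(prs$contrast),
                               estimate = prs$estimate, se = prs$SE,
                               t = prs$t.ratio, p = prs$p.value,
                               stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(terms = terms_df, soil_contrasts = contrasts_df, fit = fit),
            class = "model_result")
}

# Merge a CWM record list (or named vector) with metadata into a modeling
# frame with factor treatments.
response_frame <- function(cwm, metadata) {
  if (is.data.frame(cwm)) {
    resp <- stats::setNames(cwm$cwm, cwm$sample)
  } else resp <- cwm
  ids <- intersect(rownames(metadata), names(resp))
  if (!length(ids)) stop("no samples shared between response and metadata")
  resp <- resp[ids]
  ok <- !is.na(resp)
  ids <- ids[ok]
  d <- data.frame(response = unname(resp[ok]),
                  soil = factor(metadata[ids, "soil"]),
                  nutrient = factor(metadata[ids, "nutrient"]),
                  precipitation = factor(metadata[ids, "precipitation"]),
                  line = factor(metadata[ids, "line"]),
                  row.names = ids)
  extra <- setdiff(colnames(metadata), colnames(d))
  for (cn in extra) d[[cn]] <- metadata[ids, cn]
  d
}

#' Covariate mediation screen
#'
#' Re-fits the factorial model with each soil property, in turn, added as
#' a covariate, and compares each treatment's Type II p-value with and
#' without it. A covariate is flagged as a candidate mediator of a
#' treatment when it renders a significant treatment effect
#' (p_without <= 0.05) non-significant (p_with > 0.10).
#'
#' @param cwm Response (data.frame with sample/cwm, or named vector).
#' @param metadata Sample metadata containing the covariates.
#' @param covariates Character vector of metadata column names to screen.
#' @param treatments Treatment terms to track.
#' @return Data.frame: covariate, treatment, p_without, p_with, flagged,
#'   aliased.
#' @export
covariate_screen <- function(cwm, metadata, covariates,
                             treatments = c("nutrient", "precipitation")) {
  miss <- setdiff(covariates, colnames(metadata))
  if (length(miss)) stop("covariate(s) not in metadata: ", paste(miss, collapse = ", "))
  base <- factorial_model(cwm, metadata)
  p_without <- stats::setNames(base$terms$p, base$terms$term)[treatments]
  d <- response_frame(cwm, metadata)
  out <- list()
  for (cv in covariates) {
    v <- d[[cv]]
    ok <- !is.na(v)
    aliased <- FALSE
    p_with <- rep(NA_real_, length(treatments))
    # perfect collinearity with the design makes the treatment term untestable
    r2 <- suppressWarnings(summary(stats::lm(v[ok] ~ soil * nutrient * precipitation,
                                             data = d[ok, ])))$r.squared
    if (r2 > 1 - 1e-8) {
      aliased <- TRUE
    } else {
      form <- stats::as.formula(paste(
        "response ~ soil * nutrient * precipitation +",
        if (length(unique(d$line)) > 1L) "line +" else "", cv))
      fit <- stats::lm(form, data = d[ok, ])
      a2 <- car::Anova(fit, type = 2)
      p_with <- a2[treatments, "Pr(>F)"]
    }
    out[[cv]] <- data.frame(covariate = cv, treatment = treatments,
                            p_without = unname(p_without), p_with = p_with,
                            flagged = !aliased & !is.na(p_with) &
                              unname(p_without) <= 0.05 & p_with > 0.10,
                            aliased = aliased,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Pearson correlations between soil properties and a response
#'
#' @param cwm Response (data.frame with sample/cwm, or named vector).
#' @param metadata Sample metadata.
#' @param properties Metadata columns to correlate.
#' @return Data.frame: property, n, r, p (two-sided, t transform);
#'   constant or too-short properties get NA with a warning.
#' @export
soil_correlations <- function(cwm, metadata, properties) {
  miss <- setdiff(properties, colnames(metadata))
  if (length(miss)) stop("property(ies) not in metadata: ", paste(miss, collapse = ", "))
  d <- response_frame(cwm, metadata)
  out <- lapply(properties, function(pr) {
    v <- d[[pr]]
    ok <- !is.na(v) & !is.na(d$response)
    if (sum(ok) < 3 || stats::sd(v[ok]) == 0 || stats::sd(d$response[ok]) == 0) {
      warning("property ", pr, " constant or < 3 complete pairs; returning NA")
      return(data.frame(property = pr, n = sum(ok), r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(v[ok], d$response[ok], method = "pearson")
    data.frame(property = pr, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Derived soil ratios
#'
#' Adds the two standard derived columns: extractable N:P =
#' (NH4-N + NO3-N) / Olsen P, and Ca:Mg. Zero denominators or missing
#' components yield NA (with a warning for zero denominators), never Inf.
#'
#' @param metadata Sample metadata with NH4_N, NO3_N, olsen_P, Ca, Mg.
#' @return \code{metadata} with \code{ext_NP} and \code{ca_mg} columns.
#' @export
derive_ratios <- function(metadata) {
  need <- c("NH4_N", "NO3_N", "olsen_P", "Ca", "Mg")
  miss <- setdiff(need, colnames(metadata))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  np_den <- metadata$olsen_P
  ca_den <- metadata$Mg
  if (any(np_den == 0, na.rm = TRUE) || any(ca_den == 0, na.rm = TRUE))
    warning("zero denominator in derived ratio; returning NA")
  np <- (metadata$NH4_N + metadata$NO3_N) / ifelse(np_den == 0, NA, np_den)
  cm <- metadata$Ca / ifelse(ca_den == 0, NA, ca_den)
  metadata$ext_NP <- np
  metadata$ca_mg <- cm
  metadata
}

#' Increaser/decreaser trait comparison
#'
#' Identifies OTUs present in both control and treatment plots (pooled
#' across soils; "present" = mean abundance above \code{presence_threshold}
#' on the rarefaction-depth scale), sorts them by percent change in mean
#' abundance between control and treatment, cuts the sorted list into
#' \code{n_groups} equal sequential groups (earlier, more-decreasing
#' groups take the extra OTUs when sizes don't divide; ties in percent
#' change broken by OTU label), and compares trait values of the top group
#' (increasers) and bottom group (decreasers) with a two-tailed Welch
#' t-test (increasers minus decreasers).
#'
#' @param table Samples x OTUs matrix on the rarefaction-depth scale (rows
#'   sum to the depth; e.g. the rarefied-averaged table).
#' @param metadata Sample metadata with the treatment column.
#' @param treatment \code{"nutrient"} or \code{"precipitation"}.
#' @param traits Per-OTU trait values (named vector or estimate data.frame).
#' @param n_groups Number of sequential groups (default 4: quartiles).
#' @param presence_threshold Presence cutoff on mean abundance (default 1).
#' @return List of class \code{incdec_result}: treatment, n_increasers,
#'   n_decreasers, means/SEs, t, df, p, n_groups, presence_threshold, and
#'   the per-OTU classification.
#' @export
increaser_decreaser <- function(table, metadata, treatment, traits,
                                n_groups = 4, presence_threshold = 1) {
  treatment <- match.arg(treatment, c("nutrient", "precipitation"))
  if (is.data.frame(traits)) traits <- stats::setNames(traits$estimate, traits$taxon)
  ids <- intersect(rownames(table), rownames(metadata))
  if (!length(ids)) stop("no samples shared between table and metadata")
  tr <- metadata[ids, treatment]
  ctrl <- table[ids[tr == 0], , drop = FALSE]
  trt <- table[ids[tr == 1], , drop = FALSE]
  if (!nrow(ctrl) || !nrow(trt)) stop("need samples in both control and treatment")
  m_ctrl <- colMeans(ctrl)
  m_trt <- colMeans(trt)
  present <- m_ctrl > presence_threshold & m_trt > presence_threshold
  otus <- colnames(table)[present]
  if (length(otus) < 2 * n_groups) stop("too few present OTUs for ", n_groups, " groups")
  stopifnot(all(m_ctrl[otus] > 0))
  pct <- (m_trt[otus] - m_ctrl[otus]) / m_ctrl[otus] * 100
  ord <- otus[order(pct, otus)]
  n <- length(ord)
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- rep(seq_len(n_groups), times = sizes)
  decreasers <- ord[grp == 1L]
  increasers <- ord[grp == n_groups]
  t_inc <- traits[increasers]; t_dec <- traits[decreasers]
  if (anyNA(t_inc) || anyNA(t_dec)) stop("missing trait values for classified OTUs")
  wt <- welch_t(t_inc, t_dec)
  structure(list(treatment = treatment,
                 n_increasers = length(increasers), n_decreasers = length(decreasers),
                 mean_increasers = mean(t_inc),
                 se_increasers = stats::sd(t_inc) / sqrt(length(t_inc)),
                 mean_decreasers = mean(t_dec),
                 se_decreasers = stats::sd(t_dec) / sqrt(length(t_dec)),
                 t = wt$t, df = wt$df, p = wt$p,
                 n_groups = n_groups, presence_threshold = presence_threshold,
                 classification = data.frame(otu = ord, pct_change = pct[ord],
                                             group = grp, stringsAsFactors = FALSE,
                                             row.names = NULL)),
            class = "incdec_result")
}

#' Robustness of the increaser/decreaser result to group number
#'
#' Re-runs \code{\link{increaser_decreaser}} for every group count in
#' \code{group_range} (default 3 to 30) and collects the Welch p-values.
#'
#' @inheritParams increaser_decreaser
#' @param group_range Integer vector of group counts.
#' @return Data.frame: n_groups, t, df, p, n_increasers, n_decreasers.
#' @export
robustness_sweep <- function(table, metadata, treatment, traits,
                             group_range = 3:30, presence_threshold = 1) {
  out <- lapply(group_range, function(g) {
    r <- increaser_decreaser(table, metadata, treatment, traits,
                             n_groups = g, presence_threshold = presence_threshold)
    data.frame(n_groups = g, t = r$t, df = r$df, p = r$p,
               n_increasers = r$n_increasers, n_decreasers = r$n_decreasers)
  })
  do.call(rbind, out)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value (thin wrapper over
#' \code{stats::t.test}).
#'
#' @param a,b Numeric vectors (length >= 2 each).
#' @return List: t, df, p, mean_a, mean_b.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1, mean_a = mean(a), mean_b = mean(b)))
    stop("both groups constant with different means; t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b))
}

#' Benjamini-Yekutieli FDR control
#'
#' Step-up procedure valid under arbitrary dependence: reject the
#' hypotheses with the i smallest p-values for the largest i with
#' p_(i) <= i q / (m c(m)), c(m) = sum_{j=1}^{m} 1/j. Adjusted p-values
#' are \code{stats::p.adjust(method = "BY")}; the explicit step-up rule is
#' computed alongside (the two agree).
#'
#' @param pvalues Numeric vector in [0, 1] (NA allowed, never rejected).
#' @param q Target false discovery rate.
#' @return Data.frame: p, p_adjusted, threshold, reject (in input order).
#' @export
by_fdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  ok <- !is.na(pvalues)
  m <- sum(ok)
  adj <- rep(NA_real_, length(pvalues))
  rej <- rep(FALSE, length(pvalues))
  thr <- rep(NA_real_, length(pvalues))
  if (m > 0) {
    p <- pvalues[ok]
    adj[ok] <- stats::p.adjust(p, method = "BY")
    cm <- sum(1 / seq_len(m))
    ord <- order(p)
    thresholds <- seq_len(m) * q / (m * cm)
    below <- p[ord] <= thresholds
    k <- if (any(below)) max(which(below)) else 0L
    r <- logical(m)
    if (k > 0) r[ord[seq_len(k)]] <- TRUE
    rej[ok] <- r
    thr_ok <- numeric(m); thr_ok[ord] <- thresholds
    thr[ok] <- thr_ok
  }
  data.frame(p = pvalues, p_adjusted = adj, threshold = thr, reject = rej)
}

#' @export
print.incdec_result <- function(x, ...) {
  cat(sprintf("%s: increasers %.3f +/- %.3f (n=%d) vs decreasers %.3f +/- %.3f (n=%d)\n",
              x$treatment, x$mean_increasers, x$se_increasers, x$n_increasers,
              x$mean_decreasers, x$se_decreasers, x$n_decreasers))
  cat(sprintf("  Welch t(%.1f) = %.3f, p = %.4g (%d groups, presence > %g)\n",
              x$df, x$t, x$p, x$n_groups, x$presence_threshold))
  invisible(x)
}

#' @export
print.model_result <- function(x, ...) {
  cat("Type II factorial model\n")
  print(x$terms, row.names = FALSE)
  invisible(x)
}
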