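# Agreement-statistics battery for validating one measurement system
# against another (paired limb-angle series) and for inter-rater
# reliability of REBA scores: RMSE, Spearman's rho, intraclass correlation,
# proportion agreement, linearly weighted Cohen's kappa and the paired
# t-test. Standard model machinery (cor.test, t.test) is used where it
# exists; the ICC mean-squares decomposition and the weighted kappa are
# computed here.

#' A paired measurement series
#'
#' Two equal-length series of the same quantity measured by a reference
#' system and a test system on the same occasions.
#'
#' @param reference,test Numeric vectors of equal, nonzero length with no
#'   missing values.
#' @param label Optional description.
#' @return An object of class \code{"paired_series"}.
#' @export
paired_series <- function(reference, test, label = "") {
  stop_unless(length(reference) == length(test),
              "shape error: reference and test lengths differ")
  stop_unless(length(reference) > 0, "shape error: empty series")
  stop_unless(!anyNA(reference) && !anyNA(test),
              "paired series must not contain missing values")
  structure(list(reference = as.numeric(reference),
                 test = as.numeric(test), label = label),
            class = "paired_series")
}

as_pair <- function(x, y) {
  if (inherits(x, "paired_series")) list(r = x$reference, t = x$test)
  else unclass(paired_series(x, y))[c("reference", "test")] |>
    stats::setNames(c("r", "t"))
}

#' Root mean squared error between paired series
#'
#' @param x A \code{\link{paired_series}}, or the reference vector.
#' @param y Test vector when \code{x} is a vector.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(25 / 2)
rmse <- function(x, y = NULL) {
  p <- as_pair(x, y)
  sqrt(mean((p$t - p$r)^2))
}

#' Spearman rank correlation between paired series
#'
#' Rank correlation with average ranks for ties, with a two-sided p-value.
#'
#' @inheritParams rmse
#' @return List with \code{rho} and \code{p_value}.
#' @export
spearman_rho <- function(x, y = NULL) {
  p <- as_pair(x, y)
  stop_unless(length(p$r) >= 3, "need at least 3 pairs for a correlation")
  if (stats::sd(p$r) == 0 || stats::sd(p$t) == 0) {
    stop("undefined correlation: a series is constant", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(p$r, p$t, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Intraclass correlation coefficient
#'
#' Single-rater ICC from the two-way mean-squares decomposition of a
#' subjects-by-raters matrix. \code{"two_way_random_absolute"} is ICC(2,1):
#' raters are a random sample and absolute agreement matters (the default
#' for inter-rater reliability). \code{"two_way_mixed_consistency"} is
#' ICC(3,1): these raters only, consistency of ranking.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (at least 2 of each).
#' @param model ICC model, see above.
#' @return List with \code{icc}, \code{model} and the mean squares.
#' @export
icc <- function(ratings, model = c("two_way_random_absolute",
                                   "two_way_mixed_consistency")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  stop_unless(nrow(ratings) >= 2 && ncol(ratings) >= 2,
              "need at least 2 subjects and 2 raters")
  stop_unless(!anyNA(ratings), "ratings must not contain missing values")
  n <- nrow(ratings); k <- ncol(ratings)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- if (model == "two_way_random_absolute") {
    msr + (k - 1) * mse + k * (msc - mse) / n
  } else {
    msr + (k - 1) * mse
  }
  if (!is.finite(denom) || denom <= 0) {
    stop("undefined ICC: degenerate variance decomposition", call. = FALSE)
  }
  list(icc = (msr - mse) / denom, model = model,
       ms = c(rows = msr, cols = msc, error = mse))
}

#' Proportion agreement index
#'
#' Fraction of positions where two integer rating lists agree exactly.
#'
#' @param a,b Equal-length vectors.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' proportion_agreement(c(1, 2, 3, 4), c(1, 2, 3, 5))  # 0.75
proportion_agreement <- function(a, b) {
  stop_unless(length(a) == length(b), "shape error: lengths differ")
  stop_unless(length(a) > 0, "shape error: empty lists")
  mean(a == b)
}

#' Linearly weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordered categories with linear weights
#' \eqn{w_{ij} = 1 - |i - j| / (k - 1)}. With two categories this reduces
#' exactly to the unweighted kappa. The two-sided p-value uses the
#' large-sample standard error under the null hypothesis of chance
#' agreement.
#'
#' @param a,b Equal-length rating vectors.
#' @param categories Ordered vector of all possible categories; defaults to
#'   the sorted union of observed values.
#' @return List with \code{kappa}, \code{p_value}, \code{p_observed},
#'   \code{p_expected}.
#' @export
weighted_kappa <- function(a, b, categories = sort(unique(c(a, b)))) {
  stop_unless(length(a) == length(b), "shape error: lengths differ")
  ia <- match(a, categories); ib <- match(b, categories)
  stop_unless(!anyNA(ia) && !anyNA(ib),
              "all ratings must be members of categories")
  k <- length(categories)
  if (k < 2) {
    stop("undefined kappa: a single observed category in both lists",
         call. = FALSE)
  }
  n <- length(a)
  counts <- matrix(0, k, k)
  for (idx in seq_len(n)) {
    counts[ia[idx], ib[idx]] <- counts[ia[idx], ib[idx]] + 1
  }
  p <- counts / n
  w <- 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  pa <- rowSums(p); pb <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pa, pb))
  if (1 - pe <= .Machine$double.eps) {
    stop("undefined kappa: no chance-corrected variation", call. = FALSE)
  }
  kap <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt null standard error for weighted kappa
  wbar_a <- as.vector(w %*% pb)   # expected weight given row i
  wbar_b <- as.vector(t(w) %*% pa)
  var0 <- (sum(outer(pa, pb) * (w - outer(wbar_a, wbar_b, "+"))^2) - pe^2) /
    (n * (1 - pe)^2)
  p_value <- if (var0 > 0) {
    2 * stats::pnorm(-abs(kap / sqrt(var0)))
  } else NA_real_
  list(kappa = kap, p_value = p_value, p_observed = po, p_expected = pe)
}

#' Paired t-test for two measurement systems
#'
#' Two-sided paired t-test on the differences (test minus reference), with
#' a significance flag at the 5 percent level.
#'
#' @inheritParams rmse
#' @param alpha Significance level for the flag.
#' @return List with \code{t}, \code{p_value}, \code{significant}.
#' @export
paired_t_test <- function(x, y = NULL, alpha = 0.05) {
  p <- as_pair(x, y)
  stop_unless(length(p$r) >= 2, "need at least 2 pairs")
  d <- p$t - p$r
  if (stats::sd(d) == 0) {
    stop("degenerate test: zero variance of paired differences",
         call. = FALSE)
  }
  tt <- stats::t.test(p$t, p$r, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Landis-Koch strength-of-agreement label for a kappa value
#'
#' Bands: below 0 poor; 0-0.20 slight; 0.21-0.40 fair; 0.41-0.60 moderate;
#' 0.61-0.80 substantial; above 0.80 almost perfect.
#'
#' @param kappa Kappa value in \[-1, 1\].
#' @return Character label.
#' @export
#' @examples
#' strength_of_agreement(0.71)  # "substantial"
strength_of_agreement <- function(kappa) {
  stop_unless(is.numeric(kappa) && length(kappa) == 1L && is.finite(kappa) &&
                kappa >= -1 && kappa <= 1, "kappa must be in [-1, 1]")
  if (kappa < 0) "poor"
  else if (kappa <= 0.2) "slight"
  else if (kappa <= 0.4) "fair"
  else if (kappa <= 0.6) "moderate"
  else if (kappa <= 0.8) "substantial"
  else "almost perfect"
}

#' Agreement report for two paired measurement tables
#'
#' Compares two data frames column by column (same column names, one row
#' per measurement occasion): continuous columns get RMSE, Spearman's rho
#' and the paired t-test; integer-valued columns (scores) additionally get
#' the proportion agreement index and linearly weighted kappa with its
#' Landis-Koch label. A pooled row summarises all columns together. The
#' two columns of each pair are also treated as two raters for a
#' per-column ICC when variation allows.
#'
#' @param reference,test Data frames with identical numeric columns.
#' @param icc_model ICC model passed to \code{\link{icc}}.
#' @return An object of class \code{"agreement_report"}: a data frame with
#'   one row per column plus a \code{"(pooled)"} row.
#' @export
agreement_report <- function(reference, test,
                             icc_model = "two_way_random_absolute") {
  stop_unless(is.data.frame(reference) && is.data.frame(test),
              "reference and test must be data frames")
  cols <- intersect(names(reference), names(test))
  cols <- cols[vapply(reference[cols], is.numeric, logical(1))]
  stop_unless(length(cols) > 0, "no shared numeric columns to compare")
  stop_unless(nrow(reference) == nrow(test),
              "shape error: row counts differ")
  one <- function(r, t, label) {
    # pairwise-complete: occluded joints leave NA angles in one table
    cc <- is.finite(r) & is.finite(t)
    r <- r[cc]; t <- t[cc]
    stop_unless(length(r) >= 2,
                sprintf("fewer than 2 complete pairs in '%s'", label))
    out <- data.frame(series = label, n = length(r),
                      rmse = rmse(r, t),
                      rho = NA_real_, rho_p = NA_real_,
                      icc = NA_real_,
                      t = NA_real_, t_p = NA_real_, significant = NA,
                      p0 = NA_real_, kappa = NA_real_, kappa_p = NA_real_,
                      strength = NA_character_,
                      stringsAsFactors = FALSE)
    if (length(r) >= 3 && stats::sd(r) > 0 && stats::sd(t) > 0) {
      sp <- spearman_rho(r, t)
      out$rho <- sp$rho; out$rho_p <- sp$p_value
    }
    ic <- tryCatch(icc(cbind(r, t), icc_model)$icc, error = function(e) NA)
    out$icc <- ic
    if (length(r) >= 2 && stats::sd(t - r) > 0) {
      tt <- paired_t_test(r, t)
      out$t <- tt$t; out$t_p <- tt$p_value; out$significant <- tt$significant
    } else if (length(r) >= 2) {
      out$t <- 0; out$t_p <- 1; out$significant <- FALSE
    }
    integral <- all(r == round(r)) && all(t == round(t))
    if (integral) {
      out$p0 <- proportion_agreement(r, t)
      kp <- tryCatch(weighted_kappa(r, t), error = function(e) NULL)
      if (!is.null(kp)) {
        out$kappa <- kp$kappa; out$kappa_p <- kp$p_value
        out$strength <- strength_of_agreement(max(-1, min(1, kp$kappa)))
      }
    }
    out
  }
  rows <- lapply(cols, function(cn) one(reference[[cn]], test[[cn]], cn))
  pooled <- one(unlist(reference[cols], use.names = FALSE),
                unlist(test[cols], use.names = FALSE), "(pooled)")
  rep <- do.call(rbind, c(rows, list(pooled)))
  rownames(rep) <- NULL
  class(rep) <- c("agreement_report", "data.frame")
  rep
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Agreement report (reference vs test)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
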