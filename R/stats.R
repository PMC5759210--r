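#' Mann-Whitney U test
#'
#' U for the first group is the number of (x, y) pairs with x > y, counting
#' ties as 1/2. The two-sided p value comes from the exact permutation
#' distribution of U over all group relabelings when the smaller group has
#' at most `exactMax` observations (valid with ties), and otherwise from
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (each non-empty; ties allowed).
#' @param exactMax use the exact distribution when `min(n1, n2) <= exactMax`
#'   (default 8).
#' @return list with `U` (for x), `p` (two-sided), `n1`, `n2`, `method`.
#' @examples
#' mannWhitney(c(1, 3), c(2, 4))$U  # 1
#' @export
mannWhitney <- function(x, y, exactMax = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must contain at least one value")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (min(n1, n2) <= exactMax) {
    # exact permutation distribution of U (handles ties): enumerate every
    # choice of n1 positions out of N for group x
    combs <- utils::combn(N, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal"
  }
  list(U = U, p = p, n1 = n1, n2 = n2, method = method)
}

#' Benjamini-Hochberg step-up decisions
#'
#' Applies the BH step-up rule at level `q`: with sorted p values
#' p_(1) <= ... <= p_(m), reject hypotheses 1..k where k is the largest
#' index with p_(i) <= i q / m. Adjusted p values are the standard BH
#' monotone adjustment; `reject` is equivalent to `p_adj <= q`.
#'
#' @param p numeric vector of p values in [0, 1] (NA allowed; NA entries
#'   are never rejected and do not count toward m).
#' @param q target false discovery rate (default 0.1).
#' @return data.frame: p, p_adj, reject.
#' @export
bhAdjust <- function(p, q = 0.1) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), q > 0, q < 1)
  ok <- !is.na(p)
  m <- sum(ok)
  reject <- rep(FALSE, length(p))
  if (m > 0) {
    ps <- p[ok]
    ord <- order(ps)
    passing <- which(ps[ord] <= seq_len(m) * q / m)
    if (length(passing)) {
      k <- max(passing)
      reject[ok][ord[seq_len(k)]] <- TRUE
    }
  }
  data.frame(p = p, p_adj = stats::p.adjust(p, method = "BH"),
             reject = reject)
}

#' Pearson correlation with t-based p value
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearsonCorr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for a zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA (between/within mean-square
#' ratio) with degrees of freedom (k - 1, N - k).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`; >= 2 groups with
#'   >= 2 observations each.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
oneWayAnova <- function(values, groups) {
  groups <- droplevels(factor(groups))
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2,
            all(table(groups) >= 2))
  if (stats::var(values) == 0)
    stop("ANOVA is undefined when all observations are identical")
  fit <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value,
       df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]))
}

#' Site-by-site two-group comparison of editing levels
#'
#' Runs the Mann-Whitney U test at every site between two levels of a
#' metadata factor and applies Benjamini-Hochberg correction at level `q`
#' across the sites of this comparison family. Directions (which group has
#' the higher median) are annotated post hoc; the tests are two-sided.
#'
#' @param x an [EditingExperiment-class] (normally after [filterEditing()]).
#' @param group colData column name defining the comparison.
#' @param levels optional character(2), the two factor levels to compare
#'   (defaults to the first two observed).
#' @param q false discovery rate (default 0.1).
#' @param exactMax passed to [mannWhitney()].
#' @return data.frame of class `ComparisonResult`: site_id, category,
#'   group1, group2, n1, n2, median1, median2, mean1, mean2, U, p, p_adj,
#'   significant, direction. The comparison family is recorded in
#'   `attr(, "family")`, and a per-category significant/total roll-up in
#'   `attr(, "categorySummary")`.
#' @export
compareGroups <- function(x, group, levels = NULL, q = 0.1, exactMax = 8L) {
  stopifnot(is(x, "EditingExperiment"))
  g <- factor(colData(x)[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("comparison factor must have at least 2 levels")
  if (is.null(levels)) levels <- levels(g)[1:2]
  stopifnot(length(levels) == 2, all(levels %in% levels(g)))
  ed <- editingMatrix(x)
  cat_ <- if ("category" %in% names(rowData(x)))
    as.character(rowData(x)$category) else rep(NA_character_, nrow(ed))
  rows <- lapply(seq_len(nrow(ed)), function(i) {
    xi <- ed[i, g %in% levels[1]]
    yi <- ed[i, g %in% levels[2]]
    xi <- xi[!is.na(xi)]; yi <- yi[!is.na(yi)]
    if (length(xi) == 0L || length(yi) == 0L)
      return(data.frame(site_id = rownames(ed)[i], category = cat_[i],
                        group1 = levels[1], group2 = levels[2],
                        n1 = length(xi), n2 = length(yi),
                        median1 = NA_real_, median2 = NA_real_,
                        mean1 = NA_real_, mean2 = NA_real_,
                        U = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    mw <- mannWhitney(xi, yi, exactMax = exactMax)
    data.frame(site_id = rownames(ed)[i], category = cat_[i],
               group1 = levels[1], group2 = levels[2],
               n1 = mw$n1, n2 = mw$n2,
               median1 = stats::median(xi), median2 = stats::median(yi),
               mean1 = mean(xi), mean2 = mean(yi),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  adj <- bhAdjust(res$p, q = q)
  res$p_adj <- adj$p_adj
  res$significant <- adj$reject
  res$direction <- ifelse(is.na(res$median1) | res$median1 == res$median2,
                          "equal",
                          ifelse(res$median1 > res$median2,
                                 levels[1], levels[2]))
  attr(res, "family") <- sprintf("%s: %s vs %s (q = %g, %d sites)",
                                 group, levels[1], levels[2], q, nrow(res))
  cats <- unique(res$category)
  cs <- do.call(rbind, lapply(cats, function(cc) {
    idx <- if (is.na(cc)) is.na(res$category)
           else !is.na(res$category) & res$category == cc
    data.frame(category = cc,
               significant = sum(res$significant[idx], na.rm = TRUE),
               total = sum(idx), stringsAsFactors = FALSE)
  }))
  attr(res, "categorySummary") <- cs
  class(res) <- c("ComparisonResult", class(res))
  res
}

#' @describeIn compareGroups per-category counts of significant and tested
#'   sites (Table-1-style roll-up).
#' @param result a `ComparisonResult`.
#' @export
categorySummary <- function(result) attr(result, "categorySummary")
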