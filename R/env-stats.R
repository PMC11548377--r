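# Environmental drivers of coverage: ordinary least-squares fits with R^2
# and slope p-value, the depth/transparency light-limitation ratio, and a
# seasonal group comparison with a compact letter display.

#' Ordinary least-squares fit of y on x
#'
#' Standard simple linear regression via [stats::lm()]: least-squares slope
#' and intercept, R^2 = 1 - SS_res/SS_tot, and the two-sided t-test p-value
#' for slope != 0.
#'
#' @param x,y Equal-length numeric vectors; pairs with missing values are
#'   dropped.
#' @return A `fit_result`: list with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `slope_se`, `n`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("insufficient data for a linear fit: n = ", length(x), " (need >= 3)")
  if (stats::sd(x) == 0)
    stop("degenerate fit: predictor x is constant")
  if (stats::sd(y) == 0)
    # flat response: slope 0 and no variance explained, by convention
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          p_value = 1, slope_se = 0, n = length(x)),
                     class = "fit_result"))
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exactly collinear (noise-free) response;
  # a perfect fit is a legitimate input here, so keep it quiet
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(slope = unname(co["x", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 r_squared = sm$r.squared,
                 p_value = unname(co["x", "Pr(>|t|)"]),
                 slope_se = unname(co["x", "Std. Error"]),
                 n = length(x)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "linear fit (n = %d): y = %.4g + %.4g x   R^2 = %.3f, p = %.3g\n",
    x$n, x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Depth-to-transparency ratio Z_M / Z_SD
#'
#' The ratio of water depth to Secchi-disk depth is a proxy for underwater
#' light availability at the lake bottom; large values mean the photic zone
#' ends well above the sediment and submerged vegetation is light-starved.
#'
#' @param z_m Water depth in metres.
#' @param z_sd Secchi depth in metres; must be positive.
#' @return Z_M / Z_SD (vectorized).
#' @export
zm_zsd_ratio <- function(z_m, z_sd) {
  if (any(!is.finite(z_sd)) || any(z_sd <= 0))
    stop("Secchi depth must be positive to form Z_M/Z_SD")
  z_m / z_sd
}

#' Flag light limitation severe enough for SAV loss
#'
#' TRUE where the depth/transparency ratio strictly exceeds the threshold.
#' The default 5.17 is the ratio above which submerged vegetation was
#' observed to disappear in Bao'an Lake.
#'
#' @param ratio Z_M/Z_SD value(s).
#' @param threshold Disappearance threshold (default 5.17).
#' @return Logical vector.
#' @export
flag_light_limitation <- function(ratio, threshold = 5.17) {
  stopifnot(is.finite(threshold))
  ratio > threshold
}

# compact letter display from a logical "differs" matrix (insert-and-absorb)
cld_letters <- function(groups, differs) {
  sets <- list(groups)
  for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
    if (!differs[i, j]) next
    gi <- groups[i]; gj <- groups[j]
    new_sets <- list()
    for (s in sets) {
      if (gi %in% s && gj %in% s)
        new_sets <- c(new_sets, list(setdiff(s, gi), setdiff(s, gj)))
      else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another set; drop duplicates/empties
    new_sets <- new_sets[vapply(new_sets, length, 1L) > 0]
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets))
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b))
        keep[a] <- FALSE
    sets <- new_sets[keep]
  }
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets))
    for (g in sets[[k]])
      letters_out[g] <- paste0(letters_out[g], letters[k])
  letters_out
}

#' Seasonal comparison of a water-quality variable
#'
#' Per-season mean and sd, pairwise Welch two-sample t-tests with Holm
#' correction at alpha, and a compact letter display: seasons sharing no
#' letter differ significantly.  Seasons with fewer than two observations
#' are summarised without a letter.
#'
#' @param data Data frame with a `season` column and the variable column.
#' @param variable Name of the numeric column to compare (e.g. `"TP"`).
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `season`, `n`, `mean`, `sd`, `letters`,
#'   plus an attribute `"pairwise_p"` carrying the Holm-adjusted p-value
#'   matrix.
#' @export
seasonal_compare <- function(data, variable, alpha = 0.05) {
  stopifnot("season" %in% names(data), variable %in% names(data))
  v <- data[[variable]]
  season <- as.character(data$season)
  keep <- !is.na(v) & !is.na(season)
  v <- v[keep]; season <- season[keep]
  order_all <- c("spring", "summer", "autumn", "winter")
  seasons <- intersect(order_all, unique(season))
  if (!length(seasons)) stop("no seasons with data")
  summ <- data.frame(
    season = seasons,
    n = vapply(seasons, function(s) sum(season == s), 1L),
    mean = vapply(seasons, function(s) mean(v[season == s]), 1),
    sd = vapply(seasons, function(s) stats::sd(v[season == s]), 1),
    letters = NA_character_, stringsAsFactors = FALSE)
  testable <- summ$season[summ$n >= 2]
  pmat <- matrix(NA_real_, length(testable), length(testable),
                 dimnames = list(testable, testable))
  if (length(testable) >= 2) {
    pairs <- utils::combn(testable, 2, simplify = FALSE)
    praw <- vapply(pairs, function(pr)
      stats::t.test(v[season == pr[1]], v[season == pr[2]])$p.value, 1)
    padj <- stats::p.adjust(praw, method = "holm")
    for (k in seq_along(pairs)) {
      pmat[pairs[[k]][1], pairs[[k]][2]] <- padj[k]
      pmat[pairs[[k]][2], pairs[[k]][1]] <- padj[k]
    }
    differs <- !is.na(pmat) & pmat < alpha
    lets <- cld_letters(testable, differs)
    summ$letters[match(testable, summ$season)] <- unname(lets)
  } else if (length(testable) == 1) {
    summ$letters[match(testable, summ$season)] <- "a"
  }
  rownames(summ) <- NULL
  attr(summ, "pairwise_p") <- pmat
  summ
}
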