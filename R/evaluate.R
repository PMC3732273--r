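#' Dice's similarity index
#'
#' Overlap between an automated region A and a manual region B:
#' \eqn{2 |A \cap B| / (|A| + |B|)}.
#'
#' @param a,b [label_map()]s on one grid; not both empty.
#' @return A value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_grid(a, b, "label maps")
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0L)
    stop("Dice's index is undefined for two empty masks", call. = FALSE)
  2 * sum(a$values & b$values) / (na + nb)
}

#' Foreground volume of a label map in cubic millimetres
#'
#' @param a A [label_map()].
#' @return Foreground voxel count times the voxel volume (mm^3).
#' @export
volume_mm3 <- function(a) sum(a$values) * prod(a$grid$spacing)

#' Mean and SD of paired manual-minus-automated differences
#'
#' @param manual,automated Paired numeric vectors of volumes (mm^3).
#' @return Named vector `c(mean_diff, sd_diff)` of `manual - automated`
#'   (sample SD, n-1 denominator).
#' @export
mean_difference <- function(manual, automated) {
  if (length(manual) != length(automated))
    stop("`manual` and `automated` must be paired (same length)", call. = FALSE)
  d <- manual - automated
  c(mean_diff = mean(d), sd_diff = stats::sd(d))
}

#' Per-group volume summary
#'
#' @param group Group label.
#' @param volumes Numeric vector of volumes (mm^3), or alternatively pass
#'   `mean` and `sd` directly (e.g. when working from published summary
#'   statistics).
#' @param mean,sd Optional published mean/SD overriding `volumes`.
#' @param n Group size (required with `mean`/`sd`).
#' @return An object of class `group_volume_stats`.
#' @export
group_volume_stats <- function(group, volumes = NULL, mean = NULL, sd = NULL,
                               n = NULL) {
  if (!is.null(volumes)) {
    n <- length(volumes)
    mean <- base::mean(volumes)
    sd <- stats::sd(volumes)
  }
  if (is.null(mean) || is.null(n))
    stop("supply `volumes` or (`mean`, `sd`, `n`)", call. = FALSE)
  if (n < 1L) stop("group size must be >= 1", call. = FALSE)
  if (!is.null(sd) && sd < 0) stop("SD must be >= 0", call. = FALSE)
  structure(list(group = group, n = as.integer(n), mean = mean, sd = sd),
            class = "group_volume_stats")
}

#' Effect sizes of MCI and AD volume loss relative to controls
#'
#' Group-mean differences scaled by the impaired group's SD:
#' \eqn{ES_{MCI} = (\mu_{MCI} - \mu_{CN}) / \sigma_{MCI}} and
#' \eqn{ES_{AD} = (\mu_{AD} - \mu_{CN}) / \sigma_{AD}}. Used to compare how
#' well manual and automated volumes separate the diagnostic groups.
#'
#' @param cn,mci,ad [group_volume_stats()] for the control, MCI and AD
#'   groups; `mci` and `ad` need a positive SD.
#' @return Named vector `c(es_mci, es_ad)`.
#' @export
effect_sizes <- function(cn, mci, ad) {
  if (is.null(mci$sd) || is.null(ad$sd) || mci$sd <= 0 || ad$sd <= 0)
    stop("MCI and AD group SDs must be > 0", call. = FALSE)
  c(es_mci = (mci$mean - cn$mean) / mci$sd,
    es_ad = (ad$mean - cn$mean) / ad$sd)
}

#' Bland-Altman agreement quantities
#'
#' For each pair the average and the difference (automated - manual sign
#' convention is the caller's choice; here `manual - automated`), plus the
#' mean difference and the limits of agreement at mean +/- 1.96 SD.
#'
#' @inheritParams mean_difference
#' @return List with `pairs` (data.frame of per-pair `mean` and `diff`),
#'   `mean_diff`, `lower`, `upper`.
#' @export
bland_altman <- function(manual, automated) {
  if (length(manual) != length(automated))
    stop("`manual` and `automated` must be paired (same length)", call. = FALSE)
  d <- manual - automated
  m <- (manual + automated) / 2
  md <- mean(d)
  s <- stats::sd(d)
  list(pairs = data.frame(mean = m, diff = d),
       mean_diff = md, lower = md - 1.96 * s, upper = md + 1.96 * s)
}

#' Two-tailed paired t-test from the textbook formula
#'
#' Self-contained paired comparison used for technique-vs-technique Dice
#' comparisons: \eqn{t = \bar d / (s_d / \sqrt n)} with n-1 degrees of
#' freedom and a two-sided p-value from the t distribution.
#'
#' @param x,y Paired numeric vectors.
#' @return Named vector `c(t, df, p)`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must be paired (same length)", call. = FALSE)
  d <- x - y
  n <- length(d)
  if (n < 2L) stop("need >= 2 pairs", call. = FALSE)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  c(t = tstat, df = n - 1,
    p = 2 * stats::pt(-abs(tstat), df = n - 1))
}
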