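#' One-way repeated-measures ANOVA over ROIs
#'
#' For one quantitative map, tests for myelin differences across the six
#' ROIs with hemisphere as the repeated-measures unit, via [stats::aov()]
#' with an `Error(hemisphere)` stratum. The per-map Bonferroni-corrected
#' significance level across the three maps is 0.05 / 3 = 0.0167. No
#' sphericity correction is applied. A table with no between-ROI variance
#' returns F = 0, p = 1.
#'
#' @param records Long records tibble.
#' @param map_type Which map to test (`"MT"`, `"R1"`, `"R2star"`); `NULL`
#'   tests all maps present.
#' @param rois ROI labels (default [roi_labels()]).
#' @param alpha Per-map significance level (default 0.05 / 3).
#' @return Tibble with `map`, `statistic` (F), `df1`, `df2`, `p_value`,
#'   `significant`.
#' @export
rm_anova_roi <- function(records, map_type = NULL, rois = roi_labels(),
                         alpha = 0.05 / 3) {
  maps <- map_type %||% unique(records$map)
  purrr::map_dfr(maps, function(mt) {
    d <- records |>
      dplyr::filter(.data$map == mt, .data$roi %in% rois) |>
      dplyr::select("hemisphere_id", "roi", "myelin")
    counts <- d |> dplyr::count(.data$hemisphere_id)
    if (nrow(d) == 0L || any(counts$n != length(rois)) ||
        nrow(counts) < 2L) {
      stop_input("incomplete ROI x hemisphere table for map ", mt)
    }
    d$hemisphere_id <- factor(d$hemisphere_id)
    d$roi <- factor(d$roi)
    ss_roi <- {
      cell <- tapply(d$myelin, d$roi, mean)
      nrow(counts) * sum((cell - mean(d$myelin))^2)
    }
    if (ss_roi < 1e-24 * max(1, sum(d$myelin^2))) {
      return(tibble(map = mt, statistic = 0, df1 = length(rois) - 1L,
                    df2 = (length(rois) - 1L) * (nrow(counts) - 1L),
                    p_value = 1, significant = FALSE))
    }
    fit <- aov(myelin ~ roi + Error(hemisphere_id), data = d)
    s <- summary(fit)[["Error: Within"]][[1]]
    rn <- trimws(rownames(s))
    f <- s[rn == "roi", "F value"]
    p <- s[rn == "roi", "Pr(>F)"]
    tibble(map = mt, statistic = f,
           df1 = s[rn == "roi", "Df"], df2 = s[rn == "Residuals", "Df"],
           p_value = p, significant = p < alpha)
  })
}

#' Post-hoc pairwise comparisons between ROIs
#'
#' Two-sided paired t-tests over all 15 ROI pairs for one map, flagged at
#' the Bonferroni-corrected level 0.05 / 15 = 0.0033.
#'
#' @inheritParams rm_anova_roi
#' @param alpha Per-comparison significance level (default 0.05 / 15).
#' @return Tibble with `map`, `roi1`, `roi2`, `statistic` (t), `df`,
#'   `p_value`, `significant`.
#' @export
posthoc_pairwise <- function(records, map_type = NULL, rois = roi_labels(),
                             alpha = 0.05 / 15) {
  maps <- map_type %||% unique(records$map)
  pairs <- utils::combn(rois, 2)
  purrr::map_dfr(maps, function(mt) {
    wide <- records |>
      dplyr::filter(.data$map == mt, .data$roi %in% rois) |>
      dplyr::select("hemisphere_id", "roi", "myelin") |>
      tidyr::pivot_wider(names_from = "roi", values_from = "myelin") |>
      dplyr::arrange(.data$hemisphere_id)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      a <- wide[[pairs[1, k]]]; b <- wide[[pairs[2, k]]]
      tt <- t.test(a, b, paired = TRUE)
      tibble(map = mt, roi1 = pairs[1, k], roi2 = pairs[2, k],
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value, significant = tt$p.value < alpha)
    })
  })
}
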