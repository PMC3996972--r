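# Regeneration of the reference numerical grids: RPB and NB for hypothetical
# markers across odds ratios and prevalences, with utility-loss weights for
# three cancers (esophageal adenocarcinoma f2=0.03, breast 0.06, ovarian 0.15).

cancer_f2 <- c(ea = 0.03, breast = 0.06, ovarian = 0.15)

#' Reference benefit grid for binary markers
#'
#' Crosses marker prevalence (0.1, 1, 10, 30, 70 percent) with odds ratio
#' (1.5, 2, 4, 10, 20, 50) at a fixed disease prevalence and evaluates PAR%,
#' sensitivity, specificity, and RPB / net benefit under the three cancer
#' utility-loss weights (`f2` = 0.03, 0.06, 0.15; `f1` = 1; NB cost weight
#' `f2`). Values are carried at full precision; use [render_benefit_table()]
#' for display rounding.
#'
#' @param disease_prev Disease prevalence (default 0.01).
#' @param odds_ratios,prevalences Grid axes (prevalences as fractions).
#' @param f2 Named vector of utility-loss weights, one RPB/NB column pair per
#'   element.
#' @return A tibble of class `benefit_table` with one row per
#'   (prevalence, odds ratio) cell.
#' @examples
#' benefit_table_binary() |> render_benefit_table()
#' @export
benefit_table_binary <- function(disease_prev = 0.01,
                                 odds_ratios = c(1.5, 2, 4, 10, 20, 50),
                                 prevalences = c(0.001, 0.01, 0.10, 0.30, 0.70),
                                 f2 = cancer_f2) {
  grid <- tidyr::expand_grid(marker_prev = prevalences, odds_ratio = odds_ratios)
  tab <- solve_two_by_two(grid$odds_ratio, grid$marker_prev, disease_prev)
  out <- two_by_two_metrics(tab)
  out$odds_ratio <- grid$odds_ratio
  out <- dplyr::select(
    out, "odds_ratio", "marker_prev",
    "par_percent", "sensitivity", "specificity"
  )
  out$prevalence_pct <- out$marker_prev * 100
  for (nm in names(f2)) {
    out[[paste0("rpb_", nm)]] <- rpb_detection(tab, f1 = 1, f2 = f2[[nm]])
    out[[paste0("nb_", nm)]] <- net_benefit(tab, nb_weight = f2[[nm]])
  }
  out <- dplyr::relocate(out, "prevalence_pct", .after = "odds_ratio")
  structure(out, disease_prev = disease_prev, class = c("benefit_table", class(out)))
}

#' Reference benefit grid for continuous markers
#'
#' Crosses three threshold policies (fixed sensitivity 95%, fixed specificity
#' 95%, balanced) with odds ratio (1.5, 2, 4, 10, 20, 50) for the calibrated
#' binormal marker model (`sigma` 0.5) and evaluates PAR%, sensitivity,
#' specificity, and RPB / net benefit under the three cancer utility-loss
#' weights.
#'
#' @inheritParams benefit_table_binary
#' @param policies Threshold policies to cross with the odds ratios.
#' @param level Target rate for the fixed policies.
#' @param sigma Common class-conditional standard deviation.
#' @return A tibble of class `benefit_table`.
#' @examples
#' benefit_table_continuous() |> render_benefit_table()
#' @export
benefit_table_continuous <- function(disease_prev = 0.01,
                                     odds_ratios = c(1.5, 2, 4, 10, 20, 50),
                                     policies = c(
                                       "fixed_sensitivity",
                                       "fixed_specificity", "balanced"
                                     ),
                                     level = 0.95, sigma = 0.5,
                                     f2 = cancer_f2) {
  grid <- tidyr::expand_grid(policy = policies, odds_ratio = odds_ratios)
  grid$disease_prev <- disease_prev
  base <- continuous_benefit(grid, f2 = f2[[1]], level = level, sigma = sigma)
  out <- dplyr::select(
    base, "policy", "odds_ratio", "threshold",
    "par_percent", "sensitivity", "specificity"
  )
  w <- disease_prev
  for (nm in names(f2)) {
    out[[paste0("rpb_", nm)]] <-
      (w * out$sensitivity - (1 - w) * f2[[nm]] * (1 - out$specificity)) /
        (w + (1 - w) * f2[[nm]])
    out[[paste0("nb_", nm)]] <-
      w * out$sensitivity - f2[[nm]] * (1 - w) * (1 - out$specificity)
  }
  structure(out, disease_prev = disease_prev, class = c("benefit_table", class(out)))
}

#' Render a benefit grid at reference display precision
#'
#' Formats sensitivity, specificity, RPB and NB columns to 3 decimals and
#' PAR% to 2 decimals, as character columns. Signed zero is kept (a small
#' negative value prints as `-0.000`), matching the reference tables'
#' idiosyncratic rounding; the unrendered tibble carries full precision.
#'
#' @param table A `benefit_table` from [benefit_table_binary()] or
#'   [benefit_table_continuous()].
#' @return A tibble of character columns.
#' @export
render_benefit_table <- function(table) {
  check_table_cols(table, cols = c("par_percent", "sensitivity", "specificity"))
  three_dp <- grep("^(sensitivity|specificity|rpb_|nb_)", names(table), value = TRUE)
  out <- tibble::as_tibble(table)
  out$par_percent <- sprintf("%.2f", out$par_percent)
  for (col in three_dp) out[[col]] <- sprintf("%.3f", out[[col]])
  if ("threshold" %in% names(out)) out$threshold <- sprintf("%.4f", out$threshold)
  out
}

#' Write a benefit grid (or any report tibble) as TSV or JSON
#'
#' TSV output is tab-delimited UTF-8 with LF line endings; JSON output is an
#' array of row objects at full precision.
#'
#' @param data A data frame.
#' @param path Output path, or `""` for standard output (TSV only).
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(data, path, format = c("tsv", "json")) {
  format <- rlang::arg_match(format)
  if (format == "tsv") {
    readr::write_tsv(tibble::as_tibble(data), path)
  } else {
    jsonlite::write_json(tibble::as_tibble(data), path,
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(path)
}

#' @rdname benefit_table_binary
#' @param object,x A `benefit_table`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.benefit_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with("rpb_"),
    names_to = "cancer", names_prefix = "rpb_", values_to = "rpb"
  )
  facet <- if ("policy" %in% names(long)) "policy" else "prevalence_pct"
  ggplot2::ggplot(long, ggplot2::aes(
    .data$odds_ratio, .data$rpb,
    colour = .data$cancer, group = .data$cancer
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(facet) +
    ggplot2::labs(
      x = "Odds ratio (log scale)", y = "Ratio of population benefit",
      colour = "Utility-loss\nsetting"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname benefit_table_binary
#' @export
plot.benefit_table <- function(x, ...) print(autoplot.benefit_table(x, ...))
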