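#' Assemble a figure-style summary report
#'
#' Writes group summary tables (mean ± standard deviation per design
#' cell), the decomposition table, the validation summary and a small set
#' of figures to a directory. Cells absent from the data appear as
#' explicit gaps (`n = 0`, `NA` mean) rather than being dropped.
#'
#' @param cohort per-animal data.frame (needs `animal_id` plus the group
#'   columns in `by`).
#' @param outDir output directory (created if needed).
#' @param responses response columns to summarize.
#' @param metrics optional per-animal table (e.g. section morphometry)
#'   keyed by `animal_id`; ids absent from the cohort raise a
#'   reconciliation error.
#' @param decomposition optional table from [decomposeCohort()].
#' @param deltas optional table from [computeDeltas()]; enables the
#'   predicted-versus-measured figure and regression summary.
#' @param by group columns (default sex, genotype, treatment, timepoint).
#' @param figures write PNG figures (default `TRUE`).
#' @return (invisibly) list with `summary` (the long summary table),
#'   `files` (paths written), and `validation` (a
#'   [ValidationRegression-class] when `deltas` was supplied).
#' @export
buildReport <- function(cohort, outDir, responses = c("ss_mass_mg"),
                        metrics = NULL, decomposition = NULL, deltas = NULL,
                        by = c("sex", "genotype", "treatment", "timepoint"),
                        figures = TRUE) {
  if (!all(by %in% names(cohort)))
    stop("cohort lacks group column(s): ",
         paste(setdiff(by, names(cohort)), collapse = ", "), call. = FALSE)
  if (!is.null(metrics)) {
    if (!"animal_id" %in% names(metrics))
      stop("'metrics' must carry an animal_id column", call. = FALSE)
    orphans <- setdiff(metrics$animal_id, cohort$animal_id)
    if (length(orphans))
      stop("animal id(s) in metrics but not in cohort: ",
           paste(orphans, collapse = ", "), call. = FALSE)
    cohort <- merge(cohort, metrics, by = "animal_id", all.x = TRUE)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  grid <- unique(cohort[by])
  full <- expand.grid(lapply(cohort[by], function(x) sort(unique(x))),
                      stringsAsFactors = FALSE)
  key <- interaction(cohort[by], drop = FALSE)
  fullKey <- interaction(full, drop = FALSE)
  summ <- do.call(rbind, lapply(responses, function(resp) {
    vals <- cohort[[resp]]
    cellStats <- t(vapply(levels(fullKey), function(cell) {
      v <- vals[key == cell]
      v <- v[is.finite(v)]
      c(n = length(v), mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) sd(v) else NA_real_)
    }, numeric(3)))
    cbind(full[match(levels(fullKey), fullKey), , drop = FALSE],
          data.frame(response = resp, n = cellStats[, "n"],
                     mean = cellStats[, "mean"], sd = cellStats[, "sd"],
                     row.names = NULL))
  }))
  rownames(summ) <- NULL
  f <- file.path(outDir, "group_summary.csv")
  write.csv(summ, f, row.names = FALSE)
  files <- c(files, f)

  if (!is.null(decomposition)) {
    f <- file.path(outDir, "decomposition.csv")
    write.csv(decomposition, f, row.names = FALSE)
    files <- c(files, f)
  }

  validation <- NULL
  if (!is.null(deltas) && nrow(deltas) >= 3L &&
      var(deltas$predicted_deficit) > 0) {
    validation <- validatePredictions(deltas$predicted_deficit,
                                      deltas$measured_deficit)
    f <- file.path(outDir, "validation.json")
    jsonlite::write_json(as.list(resultValues(validation)), f,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }

  if (figures) {
    resp <- responses[1L]
    p1 <- ggplot2::ggplot(
      cohort[is.finite(cohort[[resp]]), ],
      ggplot2::aes(x = .data$timepoint, y = .data[[resp]],
                   fill = .data$treatment)) +
      ggplot2::stat_summary(fun = mean, geom = "col",
                            position = ggplot2::position_dodge(0.9)) +
      ggplot2::geom_point(position =
                            ggplot2::position_dodge(0.9), size = 0.7) +
      ggplot2::facet_grid(genotype ~ sex) +
      ggplot2::labs(y = resp) + ggplot2::theme_bw()
    f <- file.path(outDir, "group_means.png")
    ggplot2::ggsave(f, p1, width = 7, height = 5, dpi = 120)
    files <- c(files, f)

    if (!is.null(decomposition)) {
      long <- do.call(rbind, lapply(c("fl", "fn", "csa"), function(s)
        data.frame(decomposition[c("sex", "timepoint")],
                   source = s, share = decomposition[[paste0("share_", s)]])))
      p2 <- ggplot2::ggplot(long,
        ggplot2::aes(x = .data$timepoint, y = .data$share,
                     fill = .data$source)) +
        ggplot2::geom_col() + ggplot2::facet_wrap(~sex) +
        ggplot2::labs(y = "share of predicted deficit") +
        ggplot2::theme_bw()
      f <- file.path(outDir, "contribution_shares.png")
      ggplot2::ggsave(f, p2, width = 6, height = 4, dpi = 120)
      files <- c(files, f)
    }
    if (!is.null(validation)) {
      p3 <- ggplot2::ggplot(deltas,
        ggplot2::aes(x = .data$predicted_deficit,
                     y = .data$measured_deficit)) +
        ggplot2::geom_point() +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
        ggplot2::theme_bw()
      f <- file.path(outDir, "predicted_vs_measured.png")
      ggplot2::ggsave(f, p3, width = 5, height = 5, dpi = 120)
      files <- c(files, f)
    }
  }
  invisible(list(summary = summ, files = files, validation = validation))
}
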