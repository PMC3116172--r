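# Results grids, descriptor-set difference (sigma) columns, the paired
# t-test between division schemes, and table rendering.

#' Construct a results grid
#'
#' A long-format grid of metric values with one row per (model, metric,
#' cell line, descriptor set).
#'
#' @param df Data frame with columns `model`, `metric`, `cell_line`,
#'   `descriptor_set` (`"general"` or `"drug_like"`), `value`, and
#'   optionally `division`.
#' @param division Division-scheme tag recycled into the grid if `df`
#'   lacks the column.
#' @return A `bq_grid` data frame.
#' @export
results_grid <- function(df, division = NULL) {
  need <- c("model", "metric", "cell_line", "descriptor_set", "value")
  stopifnot(all(need %in% names(df)))
  if (!"division" %in% names(df))
    df$division <- if (is.null(division)) NA_character_ else division
  df <- df[, c("division", "model", "metric", "cell_line", "descriptor_set", "value")]
  structure(df, class = c("bq_grid", "data.frame"))
}

#' Compute sigma (descriptor-set difference) columns
#'
#' For every (model, metric, cell line) cell with both descriptor-set
#' entries, sigma = drug_like - general, kept at full precision (display
#' rounding to 3 decimals happens only in rendering). Cells missing a
#' counterpart get `NA` sigma.
#'
#' @param grid A `bq_grid` (long format).
#' @return Wide data frame: division, model, metric, cell_line, general,
#'   drug_like, sigma.
#' @export
sigma_columns <- function(grid) {
  g <- as.data.frame(grid)
  gen <- g[g$descriptor_set == "general", ]
  dli <- g[g$descriptor_set == "drug_like", ]
  key <- function(d) paste(d$division, d$model, d$metric, d$cell_line, sep = "\r")
  out <- gen[, c("division", "model", "metric", "cell_line")]
  out$general <- gen$value
  out$drug_like <- dli$value[match(key(gen), key(dli))]
  extra <- dli[!key(dli) %in% key(gen), c("division", "model", "metric", "cell_line")]
  if (nrow(extra)) {
    extra$general <- NA_real_
    extra$drug_like <- dli$value[!key(dli) %in% key(gen)]
    out <- rbind(out, extra)
  }
  out$sigma <- out$drug_like - out$general
  rownames(out) <- NULL
  out
}

#' Paired t-test between two results grids
#'
#' Pairs every corresponding non-sigma cell — all (model, metric, cell
#' line, descriptor set) combinations present in both grids — and runs a
#' two-sided paired t-test. If the paired differences have zero variance
#' the test is degenerate: no p-value is fabricated.
#'
#' @param gridA,gridB Two `bq_grid` objects with identical axes (e.g. the
#'   two division schemes).
#' @return List with `t`, `p`, `n` (pairs), `degenerate`, and the pairing
#'   universe description.
#' @export
paired_ttest <- function(gridA, gridB) {
  a <- as.data.frame(gridA); b <- as.data.frame(gridB)
  key <- function(d) paste(d$model, d$metric, d$cell_line, d$descriptor_set,
                           sep = "\r")
  m <- match(key(a), key(b))
  if (anyNA(m)) stop("grids do not share identical axes", call. = FALSE)
  x <- a$value; y <- b$value[m]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- y - x
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, n = n, degenerate = TRUE,
                universe = "all (model, metric, cell line, descriptor set) cells"))
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, n = n, degenerate = FALSE,
       universe = "all (model, metric, cell line, descriptor set) cells")
}

#' Render a results grid with its sigma columns
#'
#' Produces the wide CSV form (full precision plus 3-decimal display
#' columns) and an aligned text table in which the per-cell-line maximum
#' independent-test accuracy (Ap) is marked with `*`.
#'
#' @param grid A `bq_grid`.
#' @param csv_path Optional path; when given the wide table is written as
#'   CSV with 3-decimal display rounding.
#' @return Invisibly, a list with `wide` (data frame) and `text`
#'   (character vector of rendered lines).
#' @export
render_grid <- function(grid, csv_path = NULL) {
  wide <- sigma_columns(grid)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  disp <- wide
  disp$general <- fmt(wide$general)
  disp$drug_like <- fmt(wide$drug_like)
  disp$sigma <- fmt(wide$sigma)
  # mark the per-cell-line best Ap
  ap <- wide$metric == "Ap"
  if (any(ap)) {
    for (cl in unique(wide$cell_line[ap])) {
      rows <- which(ap & wide$cell_line == cl)
      best <- max(c(wide$general[rows], wide$drug_like[rows]), na.rm = TRUE)
      for (r in rows) {
        if (!is.na(wide$general[r]) && wide$general[r] == best)
          disp$general[r] <- paste0(disp$general[r], "*")
        if (!is.na(wide$drug_like[r]) && wide$drug_like[r] == best)
          disp$drug_like[r] <- paste0(disp$drug_like[r], "*")
      }
    }
  }
  disp[] <- lapply(disp, function(col) ifelse(is.na(col), "NA", as.character(col)))
  widths <- vapply(names(disp), function(nm) max(nchar(c(nm, disp[[nm]]))), 0L)
  pad <- function(x, w) formatC(x, width = w, flag = "-")
  lines <- paste(mapply(pad, c(names(disp)), widths), collapse = "  ")
  for (i in seq_len(nrow(disp)))
    lines <- c(lines, paste(mapply(pad, unlist(disp[i, ], use.names = FALSE), widths),
                            collapse = "  "))
  if (!is.null(csv_path)) utils::write.csv(disp, csv_path, row.names = FALSE)
  invisible(list(wide = wide, text = lines))
}

#' Load the reference results grid shipped with the package
#'
#' Published per-model metric values for a 93-compound cyclopamine-series
#' inhibitor study against four cell lines, under both division schemes
#' and both descriptor sets, together with the sigma values as printed
#' (column `sigma_printed`). Used by the sigma-arithmetic checks; one
#' printed sigma cell is known to disagree in sign with its own row
#' (a transcription error in the source table).
#'
#' @return Data frame: division, model, metric, cell_line, general,
#'   drug_like, sigma_printed.
#' @export
reference_grid <- function() {
  path <- system.file("extdata", "reference_grid.csv", package = "bqsar",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, colClasses = c(
    division = "character", model = "character", metric = "character",
    cell_line = "character", general = "numeric", drug_like = "numeric",
    sigma_printed = "numeric"))
}
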