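#' Construct an indicator panel
#'
#' An indicator panel holds one numeric value per (region, indicator, period)
#' triple — the raw material from which composite indices are built. Values
#' may be missing (`NA`); downstream index construction refuses missing cells
#' unless an imputation policy is chosen explicitly (see
#' [validate_panel()]).
#'
#' @param values numeric array of dimension `n_regions x n_indicators x
#'   n_periods`, or a long data frame with columns `region`, `indicator`,
#'   `period`, `value`.
#' @param region_ids,indicator_ids,period_ids character identifiers for the
#'   three axes; required when `values` is an array, ignored (derived) when it
#'   is a long data frame. `period_ids` are opaque labels whose order is taken
#'   as chronological.
#' @return an object of class `indicator_panel`: a list with the value array
#'   and the three id vectors.
#' @examples
#' p <- indicator_panel(array(1:12, c(3, 2, 2)),
#'                      region_ids = c("r1", "r2", "r3"),
#'                      indicator_ids = c("i1", "i2"),
#'                      period_ids = c("t1", "t2"))
#' dim(p)
#' @export
indicator_panel <- function(values, region_ids = NULL, indicator_ids = NULL,
                            period_ids = NULL) {
  if (is.data.frame(values)) {
    return(panel_from_long(values, period_order = period_ids))
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stopf("`values` must be a 3-d array (regions x indicators x periods) or a long data frame")
  }
  region_ids <- as.character(region_ids %||% dimnames(values)[[1]])
  indicator_ids <- as.character(indicator_ids %||% dimnames(values)[[2]])
  period_ids <- as.character(period_ids %||% dimnames(values)[[3]])
  d <- dim(values)
  if (length(region_ids) != d[1] || length(indicator_ids) != d[2] ||
      length(period_ids) != d[3]) {
    stopf("id vectors do not match the array dimensions (%d x %d x %d)",
          d[1], d[2], d[3])
  }
  if (anyDuplicated(region_ids)) stopf("duplicate region ids")
  if (anyDuplicated(indicator_ids)) stopf("duplicate indicator ids")
  if (anyDuplicated(period_ids)) stopf("duplicate period ids")
  if (d[1] < 2L) stopf("a panel needs at least 2 regions")
  storage.mode(values) <- "double"
  dimnames(values) <- list(region_ids, indicator_ids, period_ids)
  structure(list(values = values,
                 region_ids = region_ids,
                 indicator_ids = indicator_ids,
                 period_ids = period_ids),
            class = "indicator_panel")
}

panel_from_long <- function(df, period_order = NULL) {
  need <- c("region", "indicator", "period", "value")
  if (!all(need %in% names(df))) {
    stopf("long panel needs columns %s", paste(need, collapse = ", "))
  }
  region <- as.character(df$region)
  indicator <- as.character(df$indicator)
  period <- as.character(df$period)
  if (!is.numeric(df$value)) {
    bad <- suppressWarnings(is.na(as.numeric(as.character(df$value))) &
                              !is.na(df$value))
    if (any(bad)) {
      stopf("non-numeric value in row %d of the panel table", which(bad)[1])
    }
    df$value <- as.numeric(as.character(df$value))
  }
  key <- paste(region, indicator, period, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    parts <- strsplit(d, "\r", fixed = TRUE)[[1]]
    stopf("duplicate (region, indicator, period) triple: (%s, %s, %s)",
          parts[1], parts[2], parts[3])
  }
  regions <- unique(region)
  indicators <- unique(indicator)
  periods <- period_order %||% unique(period)
  if (!all(period %in% periods)) {
    stopf("period label(s) not covered by the stated period order: %s",
          paste(setdiff(period, periods), collapse = ", "))
  }
  arr <- array(NA_real_, c(length(regions), length(indicators), length(periods)),
               dimnames = list(regions, indicators, periods))
  arr[cbind(match(region, regions), match(indicator, indicators),
            match(period, periods))] <- df$value
  indicator_panel(arr, regions, indicators, periods)
}

#' @export
dim.indicator_panel <- function(x) dim(x$values)

#' @export
print.indicator_panel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Indicator panel: %d regions x %d indicators x %d period(s)\n",
              d[1], d[2], d[3]))
  cat("  periods:", paste(x$period_ids, collapse = ", "), "\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf("  missing cells: %d\n", nmiss))
  invisible(x)
}

#' @export
as.data.frame.indicator_panel <- function(x, ...) {
  d <- dim(x$values)
  out <- expand.grid(region = x$region_ids, indicator = x$indicator_ids,
                     period = x$period_ids, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$value <- as.vector(x$values)
  out
}

#' Read an indicator panel from CSV
#'
#' The canonical on-disk layout is long CSV with columns `region`,
#' `indicator`, `period`, `value`. A wide layout (one row per region and
#' period, one column per indicator) is accepted on input only.
#'
#' @param path CSV file path.
#' @param layout `"long"` (default) or `"wide"`. In the wide layout the file
#'   must have columns `region` and `period`; every remaining column is taken
#'   as an indicator.
#' @param period_order optional character vector fixing the chronological
#'   order of period labels; by default the order of first appearance in the
#'   file is used (labels are never parsed as dates).
#' @return an [indicator_panel()].
#' @export
read_panel <- function(path, layout = c("long", "wide"), period_order = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "long") {
    return(panel_from_long(df, period_order))
  }
  need <- c("region", "period")
  if (!all(need %in% names(df))) stopf("wide panel needs columns region, period")
  ind_cols <- setdiff(names(df), need)
  if (length(ind_cols) == 0L) stopf("wide panel has no indicator columns")
  long <- data.frame(
    region = rep(as.character(df$region), times = length(ind_cols)),
    indicator = rep(ind_cols, each = nrow(df)),
    period = rep(as.character(df$period), times = length(ind_cols)),
    value = unlist(lapply(ind_cols, function(cn) {
      v <- df[[cn]]
      if (!is.numeric(v)) {
        bad <- suppressWarnings(is.na(as.numeric(as.character(v))) & !is.na(v))
        if (any(bad)) stopf("non-numeric value in row %d, column %s",
                            which(bad)[1], cn)
        v <- as.numeric(as.character(v))
      }
      v
    }), use.names = FALSE),
    stringsAsFactors = FALSE)
  panel_from_long(long, period_order)
}

#' Write an indicator panel as long CSV
#'
#' @param panel an [indicator_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "indicator_panel"))
  df <- as.data.frame(panel)
  df <- df[!is.na(df$value) | TRUE, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

valid_categories <- function() c(paste0("A.", 1:7), "B.1")

#' Construct a criteria specification
#'
#' Each indicator is assigned to one category (`A.1` … `A.7` for determinant
#' categories, `B.1` for health condition) and an optimization direction:
#' `maximize` when more of the indicator is better, `minimize` when less is
#' better. Weights default to equal weights within the category
#' (`1/k` for a `k`-indicator category).
#'
#' @param indicator_id character vector of indicator identifiers.
#' @param category character vector of category labels (`A.1`–`A.7`, `B.1`).
#' @param direction character vector, each `"maximize"` or `"minimize"`.
#' @param weight optional positive weights; defaults to equal weights within
#'   each category.
#' @return a data frame of class `criteria_spec` with one row per indicator.
#' @export
criteria_spec <- function(indicator_id, category, direction, weight = NULL) {
  indicator_id <- as.character(indicator_id)
  category <- as.character(category)
  direction <- as.character(direction)
  n <- length(indicator_id)
  if (length(category) != n || length(direction) != n) {
    stopf("indicator_id, category and direction must have equal length")
  }
  if (anyDuplicated(indicator_id)) {
    stopf("duplicate criteria for indicator: %s",
          indicator_id[duplicated(indicator_id)][1])
  }
  bad_cat <- setdiff(unique(category), valid_categories())
  if (length(bad_cat)) stopf("unknown category label: %s", bad_cat[1])
  bad_dir <- setdiff(unique(direction), c("maximize", "minimize"))
  if (length(bad_dir)) stopf("direction must be maximize or minimize, got: %s",
                             bad_dir[1])
  if (is.null(weight)) {
    weight <- stats::ave(rep(1, n), category, FUN = function(w) w / sum(w))
  } else {
    weight <- as.numeric(weight)
    fill <- is.na(weight)
    if (any(fill)) {
      eq <- stats::ave(rep(1, n), category, FUN = function(w) w / sum(w))
      weight[fill] <- eq[fill]
    }
    if (any(weight <= 0)) stopf("weights must be positive")
  }
  structure(data.frame(indicator_id = indicator_id, category = category,
                       direction = direction, weight = weight,
                       stringsAsFactors = FALSE),
            class = c("criteria_spec", "data.frame"))
}

#' Read a criteria specification from CSV
#'
#' Expected columns: `indicator_id`, `category`, `direction`, and optionally
#' `weight` (missing weights are filled with equal weights within category).
#'
#' @param path CSV file path.
#' @return a [criteria_spec()] data frame.
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) stopf("criteria file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("indicator_id", "category", "direction")
  if (!all(need %in% names(df))) {
    stopf("criteria file needs columns %s", paste(need, collapse = ", "))
  }
  criteria_spec(df$indicator_id, df$category, df$direction,
                if ("weight" %in% names(df)) df$weight else NULL)
}

#' Write a criteria specification as CSV
#' @param specs a [criteria_spec()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(specs, path) {
  utils::write.csv(as.data.frame(specs), path, row.names = FALSE)
  invisible(path)
}

check_criteria_cover <- function(panel, specs) {
  missing_spec <- setdiff(panel$indicator_ids, specs$indicator_id)
  if (length(missing_spec)) {
    stopf("panel indicator(s) without a criteria spec: %s",
          paste(missing_spec, collapse = ", "))
  }
  invisible(TRUE)
}

#' Validate a panel against its criteria, with a missing-data policy
#'
#' Checks that every panel indicator has exactly one criteria row and applies
#' the missing-data policy: `"error"` (the default) aborts on any missing
#' cell, naming it; `"mean_impute"` replaces each missing cell with the mean
#' of that indicator within the same period and emits one message per
#' imputation. An indicator that is missing for every region within a period
#' cannot be imputed and is always an error.
#'
#' @param panel an [indicator_panel()].
#' @param specs a [criteria_spec()], or `NULL` to skip the coverage check.
#' @param policy `"error"` or `"mean_impute"`.
#' @return the validated (possibly imputed) panel.
#' @export
validate_panel <- function(panel, specs = NULL,
                           policy = c("error", "mean_impute")) {
  policy <- match.arg(policy)
  stopifnot(inherits(panel, "indicator_panel"))
  if (!is.null(specs)) check_criteria_cover(panel, specs)
  miss <- which(is.na(panel$values), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(panel)
  if (policy == "error") {
    m <- miss[1, ]
    stopf("missing value at (region %s, indicator %s, period %s); use policy = \"mean_impute\" to impute",
          panel$region_ids[m[1]], panel$indicator_ids[m[2]],
          panel$period_ids[m[3]])
  }
  v <- panel$values
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; j <- miss[r, 2]; t <- miss[r, 3]
    col <- v[, j, t]
    if (all(is.na(col))) {
      stopf("indicator %s has no observed value in period %s; cannot impute",
            panel$indicator_ids[j], panel$period_ids[t])
    }
    imp <- mean(col, na.rm = TRUE)
    v[i, j, t] <- imp
    message(sprintf("imputed (%s, %s, %s) <- %.6g (indicator mean, period %s)",
                    panel$region_ids[i], panel$indicator_ids[j],
                    panel$period_ids[t], imp, panel$period_ids[t]))
  }
  indicator_panel(v, panel$region_ids, panel$indicator_ids, panel$period_ids)
}

#' Define an ordered pair of periods for temporal comparison
#'
#' @param earlier,later period labels present in `panel`; `earlier` must
#'   precede `later` in the panel's chronological order.
#' @param panel the [indicator_panel()] the labels refer to.
#' @return a list of class `period_pair`.
#' @export
period_pair <- function(earlier, later, panel) {
  stopifnot(inherits(panel, "indicator_panel"))
  pe <- match(earlier, panel$period_ids)
  pl <- match(later, panel$period_ids)
  if (is.na(pe)) stopf("period %s not in panel", earlier)
  if (is.na(pl)) stopf("period %s not in panel", later)
  if (pe >= pl) stopf("%s does not precede %s in the panel's period order",
                      earlier, later)
  structure(list(earlier = earlier, later = later), class = "period_pair")
}
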